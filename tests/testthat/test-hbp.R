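test_that("site enumeration finds donors/acceptors with the right categories", {
  methanol <- fixture_mol("CO", "methanol")
  s <- enumerate_sites(methanol)
  expect_equal(sum(s$kind == "donor"), 1)
  expect_equal(s$category[s$kind == "donor"], "hydroxyl_OH")
  expect_equal(s$category[s$kind == "acceptor"], "hydroxyl_O")

  benzene <- fixture_mol("c1ccccc1", "benzene")
  expect_equal(nrow(enumerate_sites(benzene)), 0)

  nic <- fixture_coformers()$nicotinamide
  s <- enumerate_sites(nic)
  don <- s[s$kind == "donor", ]
  acc <- s[s$kind == "acceptor", ]
  expect_equal(nrow(don), 2)                     # the two amide hydrogens
  expect_true(all(don$category == "amide_NH"))
  expect_setequal(acc$category, c("aromatic_N", "carbonyl_O"))
  # the amide nitrogen itself must not be an acceptor
  expect_false(any(acc$atom %in% don$atom))

  acid <- fixture_mol("CC(=O)O", "acetic")
  s <- enumerate_sites(acid)
  expect_equal(s$category[s$kind == "donor"], "carboxylic_OH")

  # deterministic order: repeated enumeration is identical
  expect_identical(enumerate_sites(nic), enumerate_sites(nic))
})

test_that("geometric detector: worked examples and the missing-hydrogen error", {
  don <- list(element = "O", xyz = c(0, 0, 0), h_xyz = c(0.96, 0, 0))
  # O (1.52) + N (1.55) + 0.1 = 3.17 A limit
  expect_true(detect_hbond(don, list(element = "N", xyz = c(3.10, 0, 0))))
  expect_false(detect_hbond(don, list(element = "N", xyz = c(3.30, 0, 0))))
  # tight distance but 100-degree angle fails
  h <- c(0.96, 0, 0)
  dir <- c(cos(pi - 100 * pi / 180), sin(pi - 100 * pi / 180), 0)
  acc <- list(element = "N", xyz = h + 2.0 * dir)
  expect_false(detect_hbond(don, acc))
  expect_error(detect_hbond(list(element = "O", xyz = c(0, 0, 0)),
                            list(element = "N", xyz = c(3, 0, 0))),
               "hydrogen")
})

test_that("detector agrees with an independent distance/angle oracle on random geometries", {
  radii <- bondi_radii()
  oracle <- function(d_xyz, h_xyz, a_xyz, d_el, a_el) {
    lim <- radii$vdw_radius[radii$element == d_el] +
      radii$vdw_radius[radii$element == a_el] + 0.1
    v1 <- d_xyz - h_xyz; v2 <- a_xyz - h_xyz
    ang <- acos(max(-1, min(1, sum(v1 * v2) /
                              sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
    sqrt(sum((d_xyz - a_xyz)^2)) <= lim && ang > 120
  }
  set.seed(101)
  els <- c("N", "O", "S")
  agree <- vapply(1:400, function(k) {
    d_el <- sample(els, 1); a_el <- sample(els, 1)
    d <- runif(3, -1, 1)
    h <- d + runif(3, -0.6, 0.6)
    a <- d + runif(3, -4, 4)
    got <- detect_hbond(list(element = d_el, xyz = d, h_xyz = h),
                        list(element = a_el, xyz = a))
    got == oracle(d, h, a, d_el, a_el)
  }, logical(1))
  expect_true(all(agree))
})

test_that("observation extraction: planted, bifurcated and distant clusters", {
  obs1 <- extract_observations(plant_hbond_cluster(2.9, 165))
  expect_equal(sum(obs1$formed), 1)
  expect_equal(obs1$distance, 2.9, tolerance = 1e-6)
  expect_equal(obs1$angle, 165, tolerance = 1e-6)

  obs2 <- extract_observations(plant_hbond_cluster(c(3.0, 3.05), c(150, 145)))
  expect_equal(sum(obs2$formed), 2)           # bifurcated donor: two observations
  expect_equal(length(unique(obs2$donor_h)), 1)

  obs3 <- extract_observations(plant_hbond_cluster(2.9, 110))
  expect_equal(sum(obs3$formed), 0)           # angle violates the criterion

  far <- extract_observations(plant_hbond_cluster(8.5, 170))
  expect_equal(sum(far$formed), 0)            # beyond the prefilter entirely

  expect_error(plant_hbond_cluster(1.0, 160), "covalent")
  expect_error(extract_observations(list(fixture_mol("CO", "m"))), "two molecules")
})

test_that("featurization: competition ratio, steric density, closed taxonomy", {
  cl <- plant_hbond_cluster(2.9, 165)
  obs <- extract_observations(cl)
  # methanol: 1 donor H + 1 acceptor O; amine: 1 acceptor N
  # competition = acceptors / (donor H + acceptors) = 2 / 3
  expect_equal(obs$competition[1], 2 / 3)

  # methanol hydroxyl: only non-bonded neighbours beyond 2 bonds count; none
  s <- enumerate_sites(cl[[1]])
  expect_true(all(s$steric_density == 0))

  X <- featurize(obs)
  expect_equal(colnames(X), hbp_feature_names())
  expect_equal(unname(X[1, "donor_cat_hydroxyl_OH"]), 1)
  expect_equal(sum(X[1, startsWith(colnames(X), "donor_cat_")]), 1)

  bad <- obs
  bad$acceptor_category <- "mystery_site"
  expect_error(featurize(bad), "closed")
})

test_that("intercept-only fit matches the closed-form logit exactly", {
  obs <- tibble::tibble(
    donor_category = "hydroxyl_OH", acceptor_category = "carbonyl_O",
    donor_steric = 0, acceptor_steric = 0, competition = 0,
    donor_aromatic = 0L, acceptor_aromatic = 0L,
    formed = rep(c(1L, 0L), c(70, 30)))
  m <- fit_hbp(obs, regularization = 0)
  # with all continuous features 0, the intercept is spread over the constant
  # one-hot columns; the linear predictor must equal logit(0.7)
  eta <- m$alpha + m$betas[["donor_cat_hydroxyl_OH"]] +
    m$betas[["acceptor_cat_carbonyl_O"]]
  expect_equal(eta, qlogis(0.7), tolerance = 1e-6)
  expect_true(m$fit_diagnostics$converged)
  expect_equal(predict(m, obs[1, ]), plogis(qlogis(0.7)), tolerance = 1e-6)
})

test_that("fit errors: one-class data and separation without regularization", {
  one_class <- generate_observations(50, alpha = 50, seed = 1)
  expect_error(fit_hbp(one_class), "one formed and one unformed")

  sep <- tibble::tibble(
    donor_category = rep(c("hydroxyl_OH", "amide_NH"), each = 20),
    acceptor_category = "carbonyl_O",
    donor_steric = 0, acceptor_steric = 0, competition = 0,
    donor_aromatic = 0L, acceptor_aromatic = 0L,
    formed = rep(c(1L, 0L), each = 20))
  expect_error(fit_hbp(sep, regularization = 0), "separation")
  expect_s3_class(fit_hbp(sep, regularization = 1e-3), "hbp_model")
})

test_that("fit matches glm predictions on the same design", {
  obs <- generate_observations(800, alpha = -0.5,
                               betas = c(competition = 1.2, donor_steric = -0.8),
                               seed = 5)
  mine <- fit_hbp(obs, regularization = 1e-8)
  X <- featurize(obs)
  df <- as.data.frame(X[, colSums(abs(X)) > 0])
  df$formed <- obs$formed
  ref <- suppressWarnings(stats::glm(formed ~ ., data = df, family = binomial()))
  expect_equal(unname(predict(mine, obs)),
               unname(predict(ref, type = "response")), tolerance = 1e-4)
})

test_that("synthetic parameter recovery within 3 SE and consistency in n", {
  truth <- c(competition = 1.5, donor_steric = -1.0, acceptor_steric = 0.5)
  alpha <- -0.8
  fit_err <- function(n, seed) {
    obs <- generate_observations(n, alpha = alpha, betas = truth, seed = seed)
    m <- fit_hbp(obs)
    est <- tidy(m)
    err <- vapply(names(truth), function(f) {
      row <- est[est$term == f, ]
      c(abs(row$estimate - truth[[f]]) / row$std.error,
        (row$estimate - truth[[f]])^2)
    }, numeric(2))
    list(max_z = max(err[1, ]), rmse = sqrt(mean(err[2, ])))
  }
  big <- fit_err(5000, seed = 42)
  expect_lt(big$max_z, 3)
  small <- fit_err(500, seed = 42)
  expect_lt(big$rmse, small$rmse)
})

test_that("propensity prediction: logistic identities and monotonicity", {
  flat <- manual_model(alpha = 0)
  nic <- fixture_coformers()$nicotinamide
  s <- enumerate_sites(nic)
  don <- s[s$kind == "donor", ][1, ]
  acc <- s[s$kind == "acceptor", ][1, ]
  expect_equal(predict_propensity(flat, don, acc, s), 0.5)

  at28 <- manual_model(alpha = qlogis(0.28))
  expect_equal(predict_propensity(at28, don, acc, s), 0.28, tolerance = 1e-12)

  # monotone in a positively weighted feature
  m <- manual_model(alpha = -1, betas = c(donor_steric = 2))
  obs <- tibble::tibble(
    donor_category = "amide_NH", acceptor_category = "carbonyl_O",
    donor_steric = seq(0, 1, 0.1), acceptor_steric = 0, competition = 0.5,
    donor_aromatic = 0L, acceptor_aromatic = 0L)
  p <- predict(m, obs)
  expect_true(all(diff(p) > 0))
  expect_true(all(p > 0 & p < 1))
})

test_that("multi-component score: arithmetic, homo-preferring and tied patterns", {
  api <- fixture_api()
  pam <- fixture_coformers()$pamoic_acid

  # flat model: every pair identical -> score 0, tie resolved toward hetero
  flat <- manual_model(alpha = qlogis(0.3))
  mcs0 <- multicomponent_score(flat, api, pam)
  expect_equal(mcs0$score, 0)
  expect_equal(mcs0$max_hetero, mcs0$max_homo)
  expect_true(mcs0$direction %in% c("api_to_coformer", "coformer_to_api"))

  # boost the carboxylic-donor/hydroxyl-acceptor combination: both site types
  # exist only in the coformer, so the best pairing is coformer-with-itself
  homo <- manual_model(alpha = -1, betas = c(acceptor_cat_hydroxyl_O = 2,
                                             donor_cat_carboxylic_OH = 1))
  mcs_h <- multicomponent_score(homo, api, pam)
  expect_lt(mcs_h$score, 0)
  expect_equal(mcs_h$direction, "coformer_to_coformer")

  # hetero-favouring: pyridine-type acceptors live only on the API side and
  # carboxylic donors only on the coformer side, so the boosted combination
  # is necessarily a hetero pairing
  het <- manual_model(alpha = -1, betas = c(acceptor_cat_aromatic_N = 2,
                                            donor_cat_carboxylic_OH = 1))
  mcs_t <- multicomponent_score(het, api, pam)
  expect_gt(mcs_t$score, 0)
  expect_equal(mcs_t$direction, "coformer_to_api")
  expect_true(abs(mcs_t$score) <= 1)

  # no hetero pairing possible
  alkane <- fixture_mol("CCCC", "butane")
  none <- multicomponent_score(flat, alkane, fixture_mol("CCC", "propane"))
  expect_false(none$possible)
  expect_equal(none$direction, "none")

  # stability: repeated evaluation gives identical results
  expect_identical(tidy(mcs_h), tidy(multicomponent_score(homo, api, pam)))
})

test_that("model JSON round trip preserves coefficients and predictions", {
  obs <- generate_observations(500, alpha = -0.3,
                               betas = c(competition = 0.9), seed = 9)
  m <- fit_hbp(obs)
  path <- withr::local_tempfile(fileext = ".json")
  write_hbp_model(m, path)
  m2 <- read_hbp_model(path)
  expect_equal(m2$alpha, m$alpha)
  expect_equal(m2$betas, m$betas)
  expect_equal(predict(m2, obs), predict(m, obs))
})
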