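test_that("screen_pair deltas, boundary conventions, and symmetry", {
  cut <- default_cutoffs()
  api <- desc_row("api", dipole = 6.4, fpv = 0.30)

  same <- screen_pair(api, api, cut)
  expect_true(same$overall_pass)
  expect_true(all(as.numeric(same[paste0("delta_",
    c("dipole", "fpv", "m_over_l", "s_over_l", "S"))]) == 0))

  # dipole boundary is inclusive ("within 5.94 D")
  at_cut <- screen_pair(api, desc_row("c", dipole = 6.4 - 5.94, fpv = 0.30), cut)
  expect_true(at_cut$pass_dipole)
  over <- screen_pair(api, desc_row("c", dipole = 6.4 - 6.0, fpv = 0.30), cut)
  expect_false(over$pass_dipole)
  expect_false(over$overall_pass)

  # FPV boundary is strict ("less than 0.294")
  fpv_at <- screen_pair(api, desc_row("c", dipole = 6.4, fpv = 0.30 - 0.294), cut)
  expect_false(fpv_at$pass_fpv)
  fpv_under <- screen_pair(api, desc_row("c", dipole = 6.4, fpv = 0.30 - 0.293), cut)
  expect_true(fpv_under$pass_fpv)

  cof <- desc_row("c", dipole = 2.2, fpv = 0.11)
  expect_equal(screen_pair(api, cof, cut), screen_pair(cof, api, cut))
})

test_that("optimal deviancy endpoints, linearity and the not-rankable error", {
  cut <- default_cutoffs()
  api <- desc_row("api", dipole = 5, fpv = 0.3, m_over_l = 0.6,
                  s_over_l = 0.4, S = 5)

  expect_equal(optimal_deviancy(screen_pair(api, api, cut), cut), 0)

  at_cutoff <- desc_row("c", dipole = 5 - 5.94, fpv = 0.3 - 0.294 + 1e-9,
                        m_over_l = 0.6 - 0.25, s_over_l = 0.4 - 0.25,
                        S = 5 - 2.5)
  expect_equal(optimal_deviancy(screen_pair(api, at_cutoff, cut), cut), 100,
               tolerance = 1e-6)

  halfway <- desc_row("c", dipole = 5 - 5.94 / 2, fpv = 0.3 - 0.294 / 2,
                      m_over_l = 0.6 - 0.125, s_over_l = 0.4 - 0.125,
                      S = 5 - 1.25)
  expect_equal(optimal_deviancy(screen_pair(api, halfway, cut), cut), 50,
               tolerance = 1e-9)

  # scale covariance: halving every delta halves the score
  quarter <- desc_row("c", dipole = 5 - 5.94 / 4, fpv = 0.3 - 0.294 / 4,
                      m_over_l = 0.6 - 0.0625, s_over_l = 0.4 - 0.0625,
                      S = 5 - 0.625)
  expect_equal(optimal_deviancy(screen_pair(api, quarter, cut), cut), 25,
               tolerance = 1e-9)

  failed <- desc_row("c", dipole = 5 - 7)
  expect_error(optimal_deviancy(screen_pair(api, failed, cut), cut),
               "not rankable")
})

test_that("cutoff tightening never increases the pass count", {
  api <- desc_row("api", dipole = 5, fpv = 0.3)
  set.seed(11)
  lib <- dplyr::bind_rows(lapply(1:12, function(k) {
    desc_row(paste0("c", k), dipole = 5 + rnorm(1, sd = 3),
             fpv = max(0, 0.3 + rnorm(1, sd = 0.2)),
             m_over_l = runif(1, 0.3, 0.9), s_over_l = runif(1, 0.1, 0.5),
             S = runif(1, 3, 8))
  }))
  loose <- default_cutoffs()
  tight <- cutoff_set(dipole_delta_max = 2.9, fpv_delta_max = 0.15,
                      ml_ratio_delta_max = 0.12, sl_ratio_delta_max = 0.12,
                      s_axis_delta_max = 1.2)
  n_loose <- sum(screen_library(api, lib, loose)$pass_count)
  n_tight <- sum(screen_library(api, lib, tight)$pass_count)
  expect_lte(n_tight, n_loose)
})

test_that("library screening aggregates pass fractions and the advance rule", {
  cut <- default_cutoffs()
  # API ensemble: 9 conformations with drifting dipole
  api <- dplyr::bind_rows(lapply(1:9, function(k) desc_row("api", dipole = k)))
  # coformer at dipole 0: passes conformations with dipole <= 5.94 -> 5 of 9
  lib <- dplyr::bind_rows(
    desc_row("five_of_nine", dipole = 0),
    desc_row("none", dipole = 40),
    desc_row("all", dipole = 5)
  )
  res <- screen_library(api, lib, cut)
  expect_equal(res$pass_count[res$coformer == "five_of_nine"], 5)
  expect_true(res$advance[res$coformer == "five_of_nine"])   # 5/9 > 0.5
  expect_false(res$advance[res$coformer == "none"])
  expect_false(res$rankable[res$coformer == "none"])
  expect_true(is.na(res$optimal_deviancy[res$coformer == "none"]))
  expect_true(res$advance[res$coformer == "all"])
  expect_equal(res$pass_fraction, res$pass_count / 9)

  # the 6-of-10 advance pattern: strict majority passes
  api10 <- dplyr::bind_rows(lapply(1:10, function(k) desc_row("api", dipole = k)))
  res10 <- screen_library(api10, desc_row("six_of_ten", dipole = 0.06), cut)
  expect_equal(res10$pass_count, 6)
  expect_true(res10$advance)
})

test_that("cutoff configs load from YAML and reject missing geometric limits", {
  cfg <- read_cutoffs(system.file("extdata", "cutoffs.yaml", package = "coformr"))
  expect_s3_class(cfg, "cutoff_set")
  expect_equal(cfg$dipole, 5.94)
  expect_equal(cfg$fpv, 0.294)
  expect_error(cutoff_set(), "no published defaults")
  expect_error(cutoff_set(ml_ratio_delta_max = -1, sl_ratio_delta_max = 0.2,
                          s_axis_delta_max = 2), "strictly positive")
})
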