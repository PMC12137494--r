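#' Logistic hydrogen-bond propensity model
#'
#' The propensity of a donor--acceptor pair to form a hydrogen bond is
#' modelled as
#' \deqn{\pi = \frac{\exp(\alpha + \sum_k \chi_k \beta_k)}
#'                  {1 + \exp(\alpha + \sum_k \chi_k \beta_k)}}
#' where the \eqn{\chi_k} are the pair descriptors (competition, steric
#' densities, functional-group categories, aromaticity) and \eqn{\alpha},
#' \eqn{\beta_k} are fitted to true/false bond observations by (optionally
#' L2-penalised) maximum likelihood via iteratively reweighted least
#' squares.
#'
#' @name hbp_model
NULL

#' Fit the propensity model
#'
#' @param observations Observation tibble (see [read_observations()] for the
#'   schema) with at least one formed and one unformed observation.
#' @param regularization L2 penalty weight on the non-intercept
#'   coefficients. The small default guards against quasi-separation on
#'   small closed taxonomies; set to 0 for a pure maximum-likelihood fit.
#' @param max_iter,tol IRLS iteration cap and convergence tolerance on the
#'   coefficient step.
#' @return An `hbp_model`: `alpha`, named `betas`, `feature_names` and
#'   `fit_diagnostics` (log-likelihood, iterations, convergence flag).
#' @export
fit_hbp <- function(observations, regularization = 1e-6,
                    max_iter = 100, tol = 1e-10) {
  y <- observations$formed
  if (length(unique(y)) < 2) {
    abort("need at least one formed and one unformed observation")
  }
  X <- cbind(`(intercept)` = 1, featurize(observations))
  p <- ncol(X)
  penalty <- c(0, rep(regularization, p - 1))   # never penalise the intercept
  beta <- rep(0, p)
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(t(X) %*% (y - mu)) - 2 * penalty * beta
    H <- t(X * w) %*% X + diag(2 * penalty + 1e-12, p)
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + step
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  if (regularization == 0 && (!converged || max(abs(beta)) > 30)) {
    abort(paste0("fit did not stabilise (likely perfect separation); ",
                 "use regularization > 0"))
  }
  eta <- drop(X %*% beta)
  ll <- sum(y * eta - ifelse(eta > 30, eta, log1p(exp(eta))))
  structure(
    list(alpha = unname(beta[1]),
         betas = setNames(beta[-1], colnames(X)[-1]),
         feature_names = colnames(X)[-1],
         regularization = regularization,
         hessian = t(X * pmax(plogis(eta) * (1 - plogis(eta)), 1e-10)) %*% X +
           diag(2 * penalty, p),
         fit_diagnostics = list(log_likelihood = ll, iterations = iter,
                                converged = converged,
                                n_obs = length(y), n_formed = sum(y))),
    class = "hbp_model"
  )
}

#' @export
print.hbp_model <- function(x, ...) {
  d <- x$fit_diagnostics
  cat("<hbp_model> logistic hydrogen-bond propensity model\n")
  cat(sprintf("  alpha = %.4f; %d features; logLik = %.2f; %s after %d iterations\n",
              x$alpha, length(x$betas), d$log_likelihood,
              if (d$converged) "converged" else "NOT converged", d$iterations))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.hbp_model <- function(x, ...) {
  se <- if (is.null(x$hessian)) NA_real_ else sqrt(diag(solve(x$hessian)))
  tibble::tibble(
    term = c("(intercept)", x$feature_names),
    estimate = c(x$alpha, unname(x$betas)),
    std.error = se
  )
}

#' @exportS3Method generics::glance
glance.hbp_model <- function(x, ...) {
  d <- x$fit_diagnostics
  tibble::tibble(
    logLik = d$log_likelihood, nobs = d$n_obs, n_formed = d$n_formed,
    iterations = d$iterations, converged = d$converged,
    regularization = x$regularization
  )
}

# linear predictor -> propensity for a design matrix
model_propensity <- function(model, X) {
  plogis(model$alpha + drop(X %*% model$betas[colnames(X)]))
}

#' Predict the hydrogen-bond propensity of a donor--acceptor pair
#'
#' @param model A fitted `hbp_model`.
#' @param donor,acceptor One-row site tibbles (rows of [enumerate_sites()]).
#' @param system Site tibble of the full molecular system (both components),
#'   used for the competition feature.
#' @return Propensity in (0, 1).
#' @export
predict_propensity <- function(model, donor, acceptor, system) {
  stopifnot(inherits(model, "hbp_model"),
            donor$kind == "donor", acceptor$kind == "acceptor")
  obs <- tibble::tibble(
    donor_category = donor$category,
    acceptor_category = acceptor$category,
    donor_steric = donor$steric_density,
    acceptor_steric = acceptor$steric_density,
    competition = competition_value(system),
    donor_aromatic = as.integer(donor$aromatic_attached),
    acceptor_aromatic = as.integer(acceptor$aromatic_attached)
  )
  unname(model_propensity(model, featurize(obs)))
}

#' Propensities for an observation table
#'
#' @param object A fitted `hbp_model`.
#' @param newdata Observation tibble (feature columns as in
#'   [read_observations()]).
#' @param ... Ignored.
#' @return Numeric vector of propensities.
#' @export
predict.hbp_model <- function(object, newdata, ...) {
  model_propensity(object, featurize(newdata))
}

#' Model persistence as JSON
#'
#' @param model A fitted `hbp_model`.
#' @param path Output path.
#' @export
write_hbp_model <- function(model, path) {
  jsonlite::write_json(
    list(alpha = model$alpha, feature_names = model$feature_names,
         betas = as.list(model$betas), regularization = model$regularization,
         diagnostics = model$fit_diagnostics),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hbp_model
#' @export
read_hbp_model <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(alpha = obj$alpha,
         betas = setNames(as.numeric(obj$betas[obj$feature_names]),
                          obj$feature_names),
         feature_names = obj$feature_names,
         regularization = obj$regularization %||% NA_real_,
         hessian = NULL,
         fit_diagnostics = as.list(obj$diagnostics)),
    class = "hbp_model")
}

# ---- multi-component score ---------------------------------------------------

#' Multi-component (heterosynthon vs homosynthon) score
#'
#' Evaluates the propensity of every donor--acceptor pairing in the
#' two-component system, splits them into hetero (API donor to coformer
#' acceptor, or the reverse) and homo (API--API, coformer--coformer)
#' classes, and reports `score = max_hetero - max_homo`. A positive score
#' means hydrogen bonds between unlike molecules (heterosynthons, the
#' precondition for cocrystal formation) are more likely than like--like
#' bonds; a negative score flags a homosynthon-preferring pair. The reported
#' direction is the class of the single most likely interaction, ties broken
#' toward hetero pairings and then lowest atom indices.
#'
#' @param model A fitted `hbp_model`.
#' @param api,coformer `coformr_molecule`s.
#' @return A `multicomponent_score`: `possible`, `max_hetero`, `max_homo`,
#'   `score`, `max_interaction`, `direction` (one of `api_to_coformer`,
#'   `coformer_to_api`, `api_to_api`, `coformer_to_coformer`) and the full
#'   `pairs` tibble.
#' @export
multicomponent_score <- function(model, api, coformer) {
  s_api <- enumerate_sites(api)
  s_cof <- enumerate_sites(coformer)
  system <- dplyr::bind_rows(s_api, s_cof)
  comp <- competition_value(system)
  pair_block <- function(don, acc, direction, hetero) {
    don <- dplyr::filter(don, .data$kind == "donor")
    acc <- dplyr::filter(acc, .data$kind == "acceptor")
    if (nrow(don) == 0 || nrow(acc) == 0) return(NULL)
    grid <- tidyr::expand_grid(di = seq_len(nrow(don)), ai = seq_len(nrow(acc)))
    obs <- tibble::tibble(
      donor_category = don$category[grid$di],
      acceptor_category = acc$category[grid$ai],
      donor_steric = don$steric_density[grid$di],
      acceptor_steric = acc$steric_density[grid$ai],
      competition = comp,
      donor_aromatic = as.integer(don$aromatic_attached[grid$di]),
      acceptor_aromatic = as.integer(acc$aromatic_attached[grid$ai])
    )
    tibble::tibble(
      direction = direction, hetero = hetero,
      donor_molecule = don$molecule[grid$di], donor_atom = don$atom[grid$di],
      donor_h = don$h_atom[grid$di],
      acceptor_molecule = acc$molecule[grid$ai],
      acceptor_atom = acc$atom[grid$ai],
      propensity = predict.hbp_model(model, obs)
    )
  }
  pairs <- dplyr::bind_rows(
    pair_block(s_api, s_cof, "api_to_coformer", TRUE),
    pair_block(s_cof, s_api, "coformer_to_api", TRUE),
    pair_block(s_api, s_api, "api_to_api", FALSE),
    pair_block(s_cof, s_cof, "coformer_to_coformer", FALSE)
  )
  if (is.null(pairs) || nrow(pairs) == 0 || !any(pairs$hetero)) {
    return(structure(
      list(possible = FALSE, max_hetero = NA_real_, max_homo = NA_real_,
           score = NA_real_, max_interaction = NA_real_,
           direction = "none", pairs = pairs,
           api = api$name, coformer = coformer$name),
      class = "multicomponent_score"))
  }
  max_hetero <- max(pairs$propensity[pairs$hetero])
  max_homo <- if (any(!pairs$hetero)) max(pairs$propensity[!pairs$hetero]) else 0
  # deterministic argmax: highest propensity, hetero before homo, then
  # lowest donor/acceptor atom indices
  ord <- order(-pairs$propensity, !pairs$hetero, pairs$donor_atom,
               pairs$acceptor_atom)
  top <- pairs[ord[1], ]
  structure(
    list(possible = TRUE, max_hetero = max_hetero, max_homo = max_homo,
         score = max_hetero - max_homo, max_interaction = top$propensity,
         direction = top$direction, pairs = pairs,
         api = api$name, coformer = coformer$name),
    class = "multicomponent_score")
}

#' @export
print.multicomponent_score <- function(x, ...) {
  cat("<multicomponent_score> ", x$api, " + ", x$coformer, "\n", sep = "")
  if (!x$possible) {
    cat("  no hetero interaction possible\n")
    return(invisible(x))
  }
  cat(sprintf("  max hetero %.3f, max homo %.3f, score %+.3f (%s)\n",
              x$max_hetero, x$max_homo, x$score, x$direction))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.multicomponent_score <- function(x, ...) {
  tibble::tibble(
    api = x$api, coformer = x$coformer, possible = x$possible,
    max_hetero = x$max_hetero, max_homo = x$max_homo, score = x$score,
    max_interaction = x$max_interaction, direction = x$direction
  )
}
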