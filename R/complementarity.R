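#' Complementarity screening
#'
#' Pass/fail comparison of coformer descriptors against each API
#' conformation, plus the "optimal deviancy" closeness metric. The screen
#' compares five descriptors: dipole moment, fractional polar volume (FPV),
#' the M/L and S/L box-axis ratios and the short axis S. A coformer passes a
#' conformation when every descriptor delta is within its cutoff; it
#' advances to hydrogen-bond propensity screening when it passes more than
#' half (by default) of the API conformations.
#'
#' @name complementarity
NULL

SCREEN_DESCRIPTORS <- c("dipole", "fpv", "m_over_l", "s_over_l", "S")

#' Complementarity cutoff set
#'
#' The dipole and FPV cutoffs default to the published values (a coformer
#' within 5.94 D and with an FPV delta below 0.294 is polarity-complementary).
#' The geometric cutoffs (M/L, S/L ratio deltas and the S-axis delta) have no
#' published defaults and must be supplied — by value or via a YAML/CSV
#' config ([read_cutoffs()]).
#'
#' Boundary convention follows the published wording: dipole and axis deltas
#' pass when `delta <= cutoff` ("within"), the FPV delta passes only when
#' `delta < cutoff` ("less than").
#'
#' @param dipole_delta_max Debye.
#' @param fpv_delta_max FPV fraction.
#' @param ml_ratio_delta_max,sl_ratio_delta_max Dimensionless ratio deltas.
#' @param s_axis_delta_max Angstrom.
#' @return A `cutoff_set`.
#' @export
#' @examples
#' cutoff_set(ml_ratio_delta_max = 0.2, sl_ratio_delta_max = 0.2,
#'            s_axis_delta_max = 2.5)
cutoff_set <- function(dipole_delta_max = 5.94, fpv_delta_max = 0.294,
                       ml_ratio_delta_max, sl_ratio_delta_max,
                       s_axis_delta_max) {
  if (missing(ml_ratio_delta_max) || missing(sl_ratio_delta_max) ||
      missing(s_axis_delta_max)) {
    abort(paste0("Geometric cutoffs (ml_ratio_delta_max, sl_ratio_delta_max, ",
                 "s_axis_delta_max) have no published defaults and must be ",
                 "supplied explicitly or via a cutoff config file."))
  }
  vals <- c(dipole = dipole_delta_max, fpv = fpv_delta_max,
            m_over_l = ml_ratio_delta_max, s_over_l = sl_ratio_delta_max,
            S = s_axis_delta_max)
  if (any(vals <= 0)) abort("all cutoffs must be strictly positive")
  structure(as.list(vals), class = "cutoff_set")
}

#' Read a cutoff config (YAML or CSV)
#'
#' YAML files carry the five keys `dipole_delta_max`, `fpv_delta_max`,
#' `ml_ratio_delta_max`, `sl_ratio_delta_max`, `s_axis_delta_max`; CSV files
#' carry `name,value` rows with the same names.
#'
#' @param path Config file path.
#' @return A `cutoff_set`.
#' @export
read_cutoffs <- function(path) {
  if (!file.exists(path)) abort(paste0("Cutoff file not found: ", path))
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    tab <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
    as.list(setNames(tab$value, tab$name))
  }
  do.call(cutoff_set, vals[intersect(names(vals), names(formals(cutoff_set)))])
}

#' @export
print.cutoff_set <- function(x, ...) {
  cat("<cutoff_set>\n")
  cat(sprintf("  dipole delta   <= %.3f D\n", x$dipole))
  cat(sprintf("  FPV delta      <  %.3f\n", x$fpv))
  cat(sprintf("  M/L delta      <= %.3f\n", x$m_over_l))
  cat(sprintf("  S/L delta      <= %.3f\n", x$s_over_l))
  cat(sprintf("  S axis delta   <= %.3f A\n", x$S))
  invisible(x)
}

#' Screen one coformer conformation pair against one API conformation
#'
#' Computes `delta = |API - coformer|` for the five screen descriptors and
#' the per-descriptor pass flags; the overall pass is their conjunction.
#' Symmetric in its two arguments.
#'
#' @param api_desc,cof_desc One-row descriptor tibbles ([descriptor_vector()]).
#' @param cutoffs A `cutoff_set`.
#' @return A one-row tibble with `delta_*`, `pass_*` columns and
#'   `overall_pass`.
#' @export
screen_pair <- function(api_desc, cof_desc, cutoffs) {
  stopifnot(inherits(cutoffs, "cutoff_set"))
  deltas <- map_dbl(SCREEN_DESCRIPTORS, function(d) {
    abs(api_desc[[d]] - cof_desc[[d]])
  })
  names(deltas) <- SCREEN_DESCRIPTORS
  passes <- map_lgl(SCREEN_DESCRIPTORS, function(d) {
    if (d == "fpv") deltas[[d]] < cutoffs[[d]] else deltas[[d]] <= cutoffs[[d]]
  })
  names(passes) <- SCREEN_DESCRIPTORS
  out <- tibble::as_tibble(c(
    setNames(as.list(deltas), paste0("delta_", SCREEN_DESCRIPTORS)),
    setNames(as.list(passes), paste0("pass_", SCREEN_DESCRIPTORS))
  ))
  out$overall_pass <- all(passes)
  out
}

#' Optimal deviancy of a screened coformer
#'
#' The percentage closeness of a coformer's descriptors to the pass/fail
#' limits, averaged over the API conformations it passed: 100 times the mean
#' (over passed conformations) of the mean (over the five descriptors) of
#' `delta / cutoff`. 0% means identical descriptors; 100% means every delta
#' sits exactly at its limit. Lower is more complementary. Undefined (error)
#' when no conformation passed.
#'
#' @param results Per-conformer screen results ([screen_pair()] rows, one per
#'   API conformation), as a tibble or list of one-row tibbles.
#' @param cutoffs The `cutoff_set` used for screening.
#' @return Percentage (scalar).
#' @export
optimal_deviancy <- function(results, cutoffs) {
  stopifnot(inherits(cutoffs, "cutoff_set"))
  results <- dplyr::bind_rows(results)
  passed <- dplyr::filter(results, .data$overall_pass)
  if (nrow(passed) == 0) {
    abort("optimal deviancy is undefined: no conformation passed (not rankable)")
  }
  per_conf <- map_dbl(seq_len(nrow(passed)), function(r) {
    mean(map_dbl(SCREEN_DESCRIPTORS, function(d) {
      passed[[paste0("delta_", d)]][r] / cutoffs[[d]]
    }))
  })
  100 * mean(per_conf)
}

#' Screen a coformer library against an API conformer ensemble
#'
#' Runs [screen_pair()] for every (coformer, API conformation) pair and
#' aggregates per coformer: pass count, pass fraction, optimal deviancy
#' (over passed conformations only; `NA` when none passed) and the advance
#' flag (`pass_fraction > advance_threshold`, strict).
#'
#' @param api_desc Descriptor tibble for the API ensemble, one row per
#'   conformation ([descriptor_table()]).
#' @param library_desc Descriptor tibble for the coformers, one row per
#'   coformer (column `molecule` identifies them).
#' @param cutoffs A `cutoff_set`.
#' @param advance_threshold Pass-fraction threshold for advancing to
#'   propensity screening (default 0.5).
#' @return A tibble, one row per coformer: `coformer`, `pass_count`,
#'   `n_conformers`, `pass_fraction`, `optimal_deviancy`, `rankable`,
#'   `advance`, plus mean polarity/geometry closeness summaries used by the
#'   final ranking. The per-pair detail table is attached as attribute
#'   `"detail"`.
#' @export
screen_library <- function(api_desc, library_desc, cutoffs,
                           advance_threshold = 0.5) {
  stopifnot(nrow(api_desc) >= 1, nrow(library_desc) >= 1)
  detail <- dplyr::bind_rows(map(seq_len(nrow(library_desc)), function(ci) {
    cof <- library_desc[ci, ]
    dplyr::bind_rows(map(seq_len(nrow(api_desc)), function(ai) {
      dplyr::mutate(screen_pair(api_desc[ai, ], cof, cutoffs),
                    coformer = cof$molecule,
                    api_conformer = ai, .before = 1)
    }))
  }))
  summary <- detail |>
    dplyr::group_by(.data$coformer) |>
    dplyr::summarise(
      pass_count = sum(.data$overall_pass),
      n_conformers = dplyr::n(),
      pass_fraction = mean(.data$overall_pass),
      optimal_deviancy = if (any(.data$overall_pass)) {
        optimal_deviancy(dplyr::pick(dplyr::everything()), cutoffs)
      } else NA_real_,
      polarity_closeness = if (any(.data$overall_pass)) {
        mean((.data$delta_dipole[.data$overall_pass] / cutoffs$dipole +
              .data$delta_fpv[.data$overall_pass] / cutoffs$fpv) / 2)
      } else NA_real_,
      geometry_closeness = if (any(.data$overall_pass)) {
        mean((.data$delta_m_over_l[.data$overall_pass] / cutoffs$m_over_l +
              .data$delta_s_over_l[.data$overall_pass] / cutoffs$s_over_l +
              .data$delta_S[.data$overall_pass] / cutoffs$S) / 3)
      } else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      rankable = !is.na(.data$optimal_deviancy),
      advance = .data$pass_fraction > advance_threshold
    )
  # preserve library order
  summary <- summary[match(unique(library_desc$molecule), summary$coformer), ]
  attr(summary, "detail") <- detail
  class(summary) <- c("coformr_screen", class(summary))
  summary
}

#' Plot a complementarity screening summary
#'
#' Bar chart of pass fractions with the advance threshold, coloured by
#' advancement.
#'
#' @param object A [screen_library()] result.
#' @param advance_threshold Threshold line to draw.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.coformr_screen <- function(object, advance_threshold = 0.5, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = stats::reorder(.data$coformer, .data$pass_fraction),
    y = .data$pass_fraction, fill = .data$advance)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = advance_threshold, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fraction of API conformations passed",
                  fill = "advance") +
    ggplot2::theme_minimal()
}
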