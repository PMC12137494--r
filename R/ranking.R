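#' Final coformer ranking
#'
#' Combines the complementarity and propensity stages into a ranked
#' short-list. The sort is lexicographic: (1) number of API conformations
#' passed, descending; (2) multi-component score, descending (coformers
#' without a score sort after scored ones); (3) polarity closeness
#' (dipole/FPV deltas relative to their cutoffs), ascending — polarity is
#' given importance over geometry; (4) geometry closeness (axis deltas),
#' ascending; (5) coformer id, for a deterministic total order.
#'
#' @param entries A tibble with columns `coformer`, `pass_count`,
#'   `multicomponent_score` (may be `NA`), `polarity_closeness`,
#'   `geometry_closeness`, plus any carried columns
#'   (e.g. `optimal_deviancy`, `max_interaction`, `direction`).
#' @param exclude Optional character vector of coformer ids to drop before
#'   ranking (stand-in for expert exclusions: disorder, cost, duplicates).
#' @return The entries, filtered and ordered, with a `rank` column
#'   (a permutation of `1..n`).
#' @export
rank_coformers <- function(entries, exclude = character()) {
  required <- c("coformer", "pass_count", "multicomponent_score",
                "polarity_closeness", "geometry_closeness")
  missing <- setdiff(required, names(entries))
  if (length(missing)) {
    abort(paste0("ranking entries are missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  entries <- dplyr::filter(entries, !.data$coformer %in% exclude)
  key_mcs <- ifelse(is.na(entries$multicomponent_score), -Inf,
                    entries$multicomponent_score)
  key_pol <- ifelse(is.na(entries$polarity_closeness), Inf,
                    entries$polarity_closeness)
  key_geo <- ifelse(is.na(entries$geometry_closeness), Inf,
                    entries$geometry_closeness)
  ord <- order(-entries$pass_count, -key_mcs, key_pol, key_geo,
               entries$coformer)
  entries <- entries[ord, ]
  entries$rank <- seq_len(nrow(entries))
  entries
}

# ---- packaged screening-table fixtures ---------------------------------------

#' Load a packaged screening-table fixture
#'
#' `table2` mirrors the published jet-dispensing screening table: one row
#' per experimental trial (coformer, reported max interaction,
#' multi-component score, optimal deviancy, solvent system, API:coformer
#' ratio, cocrystal outcome flag). `table1` carries the complementarity-
#' screen facts quoted in the prose (ranks, per-coformer notes).
#'
#' @param table `"table1"` or `"table2"`, or a path to a CSV with the same
#'   layout.
#' @return A tibble.
#' @export
load_screening_fixture <- function(table = c("table2", "table1")) {
  path <- if (file.exists(table[1])) {
    table[1]
  } else {
    table <- match.arg(table)
    system.file("extdata", paste0(table, ".csv"), package = "coformr")
  }
  readr::read_csv(path, show_col_types = FALSE, comment = "#")
}

#' Summary statistics over a screening-table fixture
#'
#' @param fixture A fixture tibble ([load_screening_fixture()]).
#' @param query One of `positive_trial_count`, `min_optdev`, `max_optdev`,
#'   `max_mcs`, `min_mcs`, `top_max_interaction`.
#' @return A single number, exact with respect to the fixture decimals.
#' @export
evaluate_fixture <- function(fixture, query) {
  if (nrow(fixture) == 0) abort("empty fixture")
  switch(query,
    positive_trial_count = sum(fixture$outcome),
    min_optdev = min(fixture$optimal_deviancy, na.rm = TRUE),
    max_optdev = max(fixture$optimal_deviancy, na.rm = TRUE),
    max_mcs = max(fixture$multicomponent_score, na.rm = TRUE),
    min_mcs = min(fixture$multicomponent_score, na.rm = TRUE),
    top_max_interaction = {
      # the max interaction of the top-ranked (lowest optimal deviancy) coformer
      per <- fixture |>
        dplyr::group_by(.data$coformer) |>
        dplyr::summarise(optdev = .data$optimal_deviancy[1],
                         maxint = .data$max_interaction[1], .groups = "drop")
      per$maxint[which.min(per$optdev)]
    },
    abort(paste0("unknown fixture query: ", query))
  )
}

#' Plot ranking entries
#'
#' Dot plot of multi-component score against complementarity pass count,
#' labelled by rank.
#'
#' @param object A [rank_coformers()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
plot_ranking <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$pass_count, y = .data$multicomponent_score,
    label = paste0(.data$rank, ": ", .data$coformer))) +
    ggplot2::geom_point() +
    ggplot2::geom_text(hjust = -0.1, size = 3) +
    ggplot2::labs(x = "API conformations passed", y = "multi-component score") +
    ggplot2::theme_minimal()
}
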