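#' Run the full screening funnel
#'
#' Conformer generation for the API, descriptor computation for every API
#' conformation and library coformer, complementarity screening against the
#' cutoffs, hydrogen-bond propensity scoring of the advancing coformers
#' (limited to the `hbp_top_k` most complementary, mirroring the published
#' protocol of propensity-screening only the top of the complementarity
#' ranking), and the final combined ranking. Every stage is written as a
#' plain CSV audit trail carrying the tool version, a config hash and the
#' seed; identical config and seed give byte-identical reports.
#'
#' @param config A named list or a YAML file path. Fields: `api_path`,
#'   `library_path` (SMILES/SDF), `cutoff_file` (YAML/CSV; or `cutoffs`, a
#'   [cutoff_set()]), `n_conformers` (default 9), `seed` (default 1),
#'   `advance_threshold` (default 0.5), `hbp` (path to a model JSON or a
#'   training-observation CSV; `NULL` skips propensity scoring),
#'   `hbp_top_k` (default 60), `exclude` (coformer ids), `resolution`
#'   (voxel size, default 0.2), `output_dir` (`NULL` for no files).
#' @return A list: `ranking` (ranked tibble), `screen` (complementarity
#'   summary), `api_descriptors`, `coformer_descriptors`, `scores`
#'   (propensity tibble or NULL), `files` (written paths).
#' @export
screen_coformers <- function(config) {
  cfg <- load_run_config(config)
  api <- read_structures(cfg$api_path, seed = cfg$seed)
  if (length(api) != 1) abort("the API file must contain exactly one molecule")
  api <- api[[1]]
  library_mols <- read_structures(cfg$library_path, seed = cfg$seed)

  ens <- generate_conformers(api, n = cfg$n_conformers, seed = cfg$seed)
  ens <- validate_geometry(ens)
  api_desc <- descriptor_table(ens, resolution = cfg$resolution)
  lib_desc <- descriptor_table(library_mols, resolution = cfg$resolution)

  screen <- screen_library(api_desc, lib_desc, cfg$cutoffs,
                           advance_threshold = cfg$advance_threshold)
  if (!any(screen$rankable)) {
    warn("no coformer passed the complementarity screen for any conformation")
  }

  scores <- NULL
  entries <- dplyr::mutate(screen,
                           multicomponent_score = NA_real_,
                           max_interaction = NA_real_,
                           direction = NA_character_)
  if (!is.null(cfg$hbp)) {
    model <- load_hbp_stage(cfg$hbp)
    advancing <- screen |>
      dplyr::filter(.data$advance, .data$rankable) |>
      dplyr::arrange(.data$optimal_deviancy, .data$coformer)
    top <- head(advancing$coformer, cfg$hbp_top_k)
    if (length(top) > 0) {
      scores <- dplyr::bind_rows(map(top, function(id) {
        tidy(multicomponent_score(model, api, library_mols[[id]]))
      }))
      entries <- entries |>
        dplyr::rows_update(
          scores |>
            dplyr::transmute(coformer = .data$coformer,
                             multicomponent_score = .data$score,
                             max_interaction = .data$max_interaction,
                             direction = .data$direction),
          by = "coformer", unmatched = "ignore")
    }
  }

  rankable <- dplyr::filter(entries, .data$rankable)
  ranking <- rank_coformers(rankable, exclude = cfg$exclude)
  not_rankable <- entries |>
    dplyr::filter(!.data$rankable, !.data$coformer %in% cfg$exclude) |>
    dplyr::mutate(rank = NA_integer_)
  ranking <- dplyr::bind_rows(ranking, not_rankable)

  files <- character()
  if (!is.null(cfg$output_dir)) {
    meta <- report_meta(cfg)
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    out <- function(name) file.path(cfg$output_dir, name)
    files <- c(
      write_report_csv(api_desc, out("01_api_descriptors.csv"), meta),
      write_report_csv(lib_desc, out("02_coformer_descriptors.csv"), meta),
      write_report_csv(as_tibble(screen), out("03_complementarity.csv"), meta),
      if (!is.null(scores)) {
        write_report_csv(scores, out("04_multicomponent.csv"), meta)
      },
      write_report_csv(ranking, out("05_ranking.csv"), meta)
    )
    jsonlite::write_json(ranking, out("ranking.json"), auto_unbox = TRUE,
                         digits = NA, na = "null")
    files <- c(files, out("ranking.json"))
  }
  list(ranking = ranking, screen = screen, api_descriptors = api_desc,
       coformer_descriptors = lib_desc, scores = scores,
       ensemble = ens, files = files)
}

load_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(n_conformers = 9L, seed = 1L, advance_threshold = 0.5,
                   hbp = NULL, hbp_top_k = 60L, exclude = character(),
                   resolution = 0.2, output_dir = NULL, cutoffs = NULL,
                   cutoff_file = NULL)
  cfg <- modifyList(defaults, config)
  for (f in c("api_path", "library_path")) {
    if (is.null(cfg[[f]])) abort(paste0("config field '", f, "' is required"))
    if (!file.exists(cfg[[f]])) abort(paste0(f, " does not exist: ", cfg[[f]]))
  }
  if (is.null(cfg$cutoffs)) {
    if (is.null(cfg$cutoff_file)) {
      abort("config needs either 'cutoffs' or 'cutoff_file'")
    }
    cfg$cutoffs <- read_cutoffs(cfg$cutoff_file)
  } else if (!inherits(cfg$cutoffs, "cutoff_set")) {
    cfg$cutoffs <- do.call(cutoff_set, as.list(cfg$cutoffs))
  }
  cfg
}

load_hbp_stage <- function(hbp) {
  if (inherits(hbp, "hbp_model")) return(hbp)
  if (grepl("\\.json$", hbp, ignore.case = TRUE)) return(read_hbp_model(hbp))
  fit_hbp(read_observations(hbp))
}

report_meta <- function(cfg) {
  hashable <- cfg[setdiff(names(cfg), "output_dir")]
  c(paste0("coformr ", as.character(utils::packageVersion("coformr"))),
    paste0("config_hash ", rlang::hash(hashable)),
    paste0("seed ", cfg$seed))
}

write_report_csv <- function(df, path, meta) {
  df <- dplyr::mutate(df, dplyr::across(
    dplyr::where(is.numeric), ~ round(.x, 9)))
  body <- sub("\n$", "", readr::format_csv(df))
  writeLines(c(paste0("# ", meta), strsplit(body, "\n", fixed = TRUE)[[1]]),
             path)
  path
}

#' Fit a propensity model from an observation CSV and write it as JSON
#'
#' @param observations_csv Path to an observation CSV
#'   ([read_observations()] schema).
#' @param out Output JSON path.
#' @param regularization L2 penalty weight.
#' @return The fitted model, invisibly; the JSON is written to `out`.
#' @export
fit_hbp_file <- function(observations_csv, out, regularization = 1e-6) {
  model <- fit_hbp(read_observations(observations_csv),
                   regularization = regularization)
  write_hbp_model(model, out)
  invisible(model)
}

#' Query the packaged screening-table fixtures
#'
#' @param query See [evaluate_fixture()].
#' @param table Fixture name or CSV path.
#' @return A single number.
#' @export
fixture_query <- function(query, table = "table2") {
  evaluate_fixture(load_screening_fixture(table), query)
}
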