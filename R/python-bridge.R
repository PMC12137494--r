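# Bridge to the RDKit structure-preparation helper shipped in inst/python.
# One subprocess call handles a whole batch of molecules, so library reads
# cost a single interpreter start-up.

find_python <- function() {
  py <- Sys.getenv("COFORMR_PYTHON", unset = "")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) {
    abort("No python interpreter found; structure preparation needs Python with RDKit.")
  }
  unname(py)
}

prep_script <- function() {
  path <- system.file("python", "prep_molecules.py", package = "coformr")
  if (!nzchar(path)) abort("prep_molecules.py not found in the installed package.")
  path
}

#' @noRd
run_prep <- function(records, n_confs = 1, seed = 1, prune_rms = 0.5,
                     optimize = TRUE, use_input_coords = TRUE) {
  job <- list(records = records, n_confs = n_confs, seed = seed,
              prune_rms = prune_rms, optimize = optimize,
              use_input_coords = use_input_coords)
  jf <- tempfile(fileext = ".json")
  of <- tempfile(fileext = ".json")
  on.exit(unlink(c(jf, of)), add = TRUE)
  jsonlite::write_json(job, jf, auto_unbox = TRUE, digits = NA)
  status <- system2(find_python(), c(prep_script(), jf, of),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(of)) {
    abort(paste0("Structure preparation failed:\n",
                 paste(status, collapse = "\n")))
  }
  jsonlite::read_json(of, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                      simplifyMatrix = FALSE)$results
}
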