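#' Pipeline configuration
#'
#' Aggregates every tunable of the demultiplexing workflow with its standard
#' default: S/N cutoffs `r1 = 3` (MS1) and `r2 = 1` (MS/MS), round-1 apex
#' distance `t = 3`, round-2 score cutoff 0.55 with fallback size 25,
#' round-3 low-mass bound 1500 Da with quota 25, Averagine residue mass
#' 111.1254 Da, and 10 ppm mass tolerances for pair labeling, feature
#' linking and duplicate removal. Serializable to/from JSON so a run is
#' fully described by one text file.
#'
#' @param snr_ms1,snr_ms2 S/N peak-filter ratios (see [noise_model()]).
#' @param t,score_cutoff,min_keep,low_mass_bound,low_quota,avg_residue_mass
#'   Cascade parameters (see [cascade_params()]).
#' @param ppm_tol Mass tolerance in ppm shared by pair labeling, envelope
#'   linking and duplicate removal.
#' @param msalign_dialect Output dialect (see [write_pseudo_spectra()]).
#' @param seed Seed for any randomized step (model training split).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(snr_ms1 = 3, snr_ms2 = 1, t = 3,
                            score_cutoff = 0.55, min_keep = 25,
                            low_mass_bound = 1500, low_quota = 25,
                            avg_residue_mass = 111.1254, ppm_tol = 10,
                            msalign_dialect = "minimal", seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path JSON file.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, obj)
}

as_cascade_params <- function(config) {
  cascade_params(t = config$t, score_cutoff = config$score_cutoff,
                 min_keep = config$min_keep,
                 low_mass_bound = config$low_mass_bound,
                 low_quota = config$low_quota,
                 avg_residue_mass = config$avg_residue_mass)
}

#' Demultiplex one TD-DIA run into pseudo MS/MS spectra
#'
#' Wires the modules into the full per-run workflow: SCPFs lacking a window
#' assignment are assigned from their envelopes (when a layout is given),
#' then each isolation window's SCPFs and fragment features go through the
#' greedy three-round cascade, and the pseudo spectra of all windows are
#' written as one msalign-style file plus a per-window report.
#'
#' @param features Either the path of a feature table TSV
#'   (see [read_feature_table()]) or a list with `scpfs` and `fragments`.
#' @param model A [pair_model()] or the path of a serialized one.
#' @param output Output msalign-style file path, or `NULL` to skip writing.
#' @param config A [pipeline_config()].
#' @param layout Optional [run_layout()] for window assignment of
#'   unassigned SCPFs.
#' @return List of class `demux_result`: `spectra` (all pseudo spectra),
#'   `report` (data.frame: per window, SCPFs assigned, fragments available,
#'   pseudo spectra emitted, round-2 fallback rate) and `output`.
#' @export
run_pipeline <- function(features, model, output = NULL,
                         config = pipeline_config(), layout = NULL) {
  if (is.character(features)) features <- read_feature_table(features)
  if (is.character(model)) model <- read_pair_model(model)
  scpfs <- features$scpfs
  frags <- features$fragments
  if (is.null(scpfs) || !nrow(scpfs)) {
    res <- structure(list(spectra = list(),
                          report = data.frame(window = integer(),
                                              n_scpfs = integer(),
                                              n_fragments = integer(),
                                              n_pseudo = integer(),
                                              fallback_rate = numeric()),
                          output = output), class = "demux_result")
    if (!is.null(output)) write_pseudo_spectra(list(), output,
                                               dialect = config$msalign_dialect)
    return(res)
  }
  if (!is.null(layout) && anyNA(scpfs$window))
    scpfs <- assign_windows(scpfs, layout)
  params <- as_cascade_params(config)
  spectra <- list()
  rep_rows <- list()
  for (w in sort(unique(scpfs$window[!is.na(scpfs$window)]))) {
    sw <- scpfs[!is.na(scpfs$window) & scpfs$window == w, , drop = FALSE]
    fw <- frags[frags$window == w, , drop = FALSE]
    ps <- generate_window_pseudo_spectra(sw, fw, model, params)
    spectra <- c(spectra, ps)
    rep_rows[[length(rep_rows) + 1L]] <- data.frame(
      window = w, n_scpfs = nrow(sw), n_fragments = nrow(fw),
      n_pseudo = length(ps),
      fallback_rate = if (length(ps))
        mean(vapply(ps, `[[`, logical(1), "fallback")) else NA_real_)
  }
  report <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(window = integer(), n_scpfs = integer(),
               n_fragments = integer(), n_pseudo = integer(),
               fallback_rate = numeric())
  if (!is.null(output))
    write_pseudo_spectra(spectra, output, dialect = config$msalign_dialect)
  structure(list(spectra = spectra, report = report, output = output),
            class = "demux_result")
}

#' @export
print.demux_result <- function(x, ...) {
  cat(sprintf("Demultiplexed run: %d pseudo MS/MS spectra over %d windows\n",
              length(x$spectra), nrow(x$report)))
  if (nrow(x$report)) print(x$report, row.names = FALSE)
  invisible(x)
}
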