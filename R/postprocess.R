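#' Duplicate test for two proteoform identifications
#'
#' Two identifications from one run are duplicates when they map to the same
#' protein and their neutral monoisotopic masses agree up to a possible
#' +/- 1.00235 Da deconvolution error: the smallest of `|m1 - m2|`,
#' `|m1 - m2 - 1.00235|` and `|m1 - m2 + 1.00235|` must be within `ppm_tol`
#' (1.00235 Da is the common one-isotope error of top-down deconvolution).
#' The ppm bound is taken relative to the larger of the two masses.
#'
#' @param m1,m2 Neutral monoisotopic masses in Da.
#' @param same_protein Do both identifications map to the same protein
#'   accession?
#' @param ppm_tol Tolerance in ppm (default 10).
#' @return Logical.
#' @export
is_duplicate <- function(m1, m2, same_protein, ppm_tol = 10) {
  if (!same_protein) return(FALSE)
  d <- m1 - m2
  min(abs(d), abs(d - 1.00235), abs(d + 1.00235)) <=
    ppm_tol * 1e-6 * max(m1, m2)
}

#' Remove duplicated proteoform identifications within a run
#'
#' Identifications are ranked by SCPF intensity (descending; ties by mass
#' ascending then accession) and scanned in order: each one is compared with
#' every better-ranked identification and removed if [is_duplicate()] flags
#' any of them, so only the most intense member of each duplicate cluster
#' survives.
#'
#' @param ids Data.frame with columns `protein_accession`, `mono_mass`,
#'   `scpf_intensity` and optionally `run_id`, `evalue`.
#' @param ppm_tol Tolerance in ppm (default 10).
#' @return The surviving rows, in intensity rank order.
#' @export
dedup_run <- function(ids, ppm_tol = 10) {
  stopifnot(all(c("protein_accession", "mono_mass", "scpf_intensity") %in%
                  names(ids)))
  if (nrow(ids) <= 1L) return(ids)
  ord <- order(-ids$scpf_intensity, ids$mono_mass, ids$protein_accession,
               method = "radix")
  ids <- ids[ord, , drop = FALSE]
  keep <- logical(nrow(ids))
  for (i in seq_len(nrow(ids))) {
    dup <- FALSE
    for (j in seq_len(i - 1L)) {   # all better-ranked, kept or removed
      if (is_duplicate(ids$mono_mass[i], ids$mono_mass[j],
                       ids$protein_accession[i] == ids$protein_accession[j],
                       ppm_tol)) { dup <- TRUE; break }
    }
    keep[i] <- !dup
  }
  ids[keep, , drop = FALSE]
}

#' Merge proteoform identifications across gas-phase-fractionated runs
#'
#' Concatenates the per-run (already deduplicated) identification lists,
#' re-ranks the union by SCPF intensity and applies the same duplicate
#' removal, so a proteoform identified in several precursor m/z ranges is
#' reported once, from its most intense run.
#'
#' @param run_lists List of per-run identification data.frames
#'   (see [dedup_run()]).
#' @param ppm_tol Tolerance in ppm (default 10).
#' @return Combined deduplicated data.frame.
#' @export
merge_runs <- function(run_lists, ppm_tol = 10) {
  dedup_run(do.call(rbind, run_lists), ppm_tol = ppm_tol)
}
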