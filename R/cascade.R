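#' Parameters of the three-round fragment-filtering cascade
#'
#' @param t Round-1 apex-cycle-distance parameter in cycles (default 3): a
#'   fragment survives only if its apex is within `min(t, floor(c/2))`
#'   cycles of the SCPF apex, `c` = SCPF observed cycle count.
#' @param score_cutoff Round-2 pair-score cutoff (default 0.55).
#' @param min_keep Round-2 fallback size (default 25): when fewer than
#'   `min_keep` fragments exceed the cutoff, the top `min_keep` of `L` by
#'   score are kept without filtering.
#' @param low_mass_bound Round-3 boundary between the low- and high-mass
#'   fragment groups in Da (default 1500).
#' @param low_quota Round-3 quota for the low-mass group (default 25, the
#'   expected number of theoretical terminal fragments under 1500 Da).
#' @param avg_residue_mass Average amino-acid residue mass of the Averagine
#'   model in Da (default 111.1254), used to estimate precursor length.
#' @return List of class `cascade_params`.
#' @export
cascade_params <- function(t = 3, score_cutoff = 0.55, min_keep = 25,
                           low_mass_bound = 1500, low_quota = 25,
                           avg_residue_mass = 111.1254) {
  stopifnot(t >= 0, score_cutoff > 0, min_keep > 0, low_mass_bound > 0,
            low_quota > 0, avg_residue_mass > 0)
  structure(list(t = t, score_cutoff = score_cutoff, min_keep = min_keep,
                 low_mass_bound = low_mass_bound, low_quota = low_quota,
                 avg_residue_mass = avg_residue_mass),
            class = "cascade_params")
}

#' Round 1: apex-cycle-distance gate
#'
#' Removes every fragment feature whose apex cycle lies more than
#' `min(t, floor(c/2))` cycles from the SCPF's apex cycle, where `c` is the
#' number of cycles in which the SCPF is observed. Narrow precursors (small
#' `c`) therefore get a proportionally tighter gate; `c = 1` keeps only
#' co-apex fragments.
#'
#' @param scpf One-row SCPF table.
#' @param fragments Fragment table of the SCPF's isolation window.
#' @param t Distance parameter in cycles (default 3).
#' @return The surviving fragment rows (`L`), order preserved; may be empty.
#' @export
round1_filter <- function(scpf, fragments, t = 3) {
  stopifnot(nrow(scpf) == 1L)
  if (!nrow(fragments)) return(fragments)
  cutoff <- min(t, scpf$num_cycles %/% 2)
  apex_s <- apex_cycle(scpf$xic[[1]])
  d <- vapply(fragments$xic, function(x) abs(apex_cycle(x) - apex_s),
              numeric(1))
  fragments[d <= cutoff, , drop = FALSE]
}

#' Round 2: logistic score filter with top-`min_keep` fallback
#'
#' Scores every fragment in `L` with the pair model and keeps those scoring
#' strictly above `score_cutoff`. When fewer than `min_keep` fragments pass,
#' the top `min_keep` fragments of `L` by score are kept instead, without
#' filtering (all of `L` if it is smaller) — a low-scoring survivor list is
#' better than an unsearchable, nearly empty pseudo spectrum.
#'
#' @param scpf One-row SCPF table.
#' @param L Round-1 survivor fragment table.
#' @param model A [pair_model()].
#' @param score_cutoff Probability cutoff (default 0.55).
#' @param min_keep Fallback size (default 25).
#' @return `L` subset with a `score` column appended, ordered by score
#'   descending (ties by mass, then id), plus attribute `fallback` (logical).
#' @export
round2_filter <- function(scpf, L, model, score_cutoff = 0.55,
                          min_keep = 25) {
  if (!nrow(L)) {
    L$score <- numeric(0)
    attr(L, "fallback") <- FALSE
    return(L)
  }
  at <- compute_attributes(scpf, L)
  L$score <- predict(model, at)
  ord <- order(-L$score, L$mono_mass, L$feature_id, method = "radix")
  L <- L[ord, , drop = FALSE]
  pass <- L$score > score_cutoff
  fallback <- sum(pass) < min_keep
  out <- if (fallback) utils::head(L, min_keep) else L[pass, , drop = FALSE]
  attr(out, "fallback") <- fallback
  out
}

#' Estimated fragment-mass quota from the precursor mass
#'
#' The number of theoretical N- and C-terminal fragment masses of a
#' proteoform of length `l` is `2(l - 1)`; `l` is estimated as the precursor
#' mass divided by the Averagine average residue mass, rounded to the
#' nearest integer and clamped at 2 so the quota stays positive.
#'
#' @param precursor_mass Neutral monoisotopic precursor mass in Da.
#' @param avg_residue_mass Average residue mass in Da (default 111.1254).
#' @return Even integer quota `T = 2(l - 1) >= 2`, non-decreasing in mass.
#' @examples
#' estimate_fragment_quota(11112.54)  # l = 100, T = 198
#' @export
estimate_fragment_quota <- function(precursor_mass,
                                    avg_residue_mass = 111.1254) {
  if (precursor_mass <= 0) stopf("precursor mass must be positive")
  l <- max(2, round(precursor_mass / avg_residue_mass))
  2L * (as.integer(l) - 1L)
}

#' Round 3: mass-group quotas
#'
#' Splits the scored survivors into a low-mass group (`mass <
#' low_mass_bound`) and a high-mass group and keeps the top scorers of each:
#' up to `min(low_quota, T)` low-mass and up to `max(0, T - low_quota)`
#' high-mass fragments, `T` being the precursor's estimated fragment quota.
#' For very small precursors (`T < low_quota`) the high-mass quota clamps to
#' zero and the low-mass quota to `T`.
#'
#' @param scored Fragment table with `score` and `mono_mass` columns.
#' @param quota_T Total theoretical fragment-mass quota
#'   (see [estimate_fragment_quota()]).
#' @param low_mass_bound Group boundary in Da (default 1500).
#' @param low_quota Low-mass group quota (default 25).
#' @return Retained rows ordered by score descending (ties by mass, id).
#' @export
round3_filter <- function(scored, quota_T, low_mass_bound = 1500,
                          low_quota = 25) {
  if (!nrow(scored)) return(scored)
  ord <- order(-scored$score, scored$mono_mass, scored$feature_id,
               method = "radix")
  scored <- scored[ord, , drop = FALSE]
  low <- scored$mono_mass < low_mass_bound
  n_low <- min(low_quota, quota_T)
  n_high <- max(0L, quota_T - low_quota)
  keep_low <- utils::head(which(low), n_low)
  keep_high <- utils::head(which(!low), n_high)
  scored[sort(c(keep_low, keep_high)), , drop = FALSE]
}

#' Generate pseudo MS/MS spectra for one isolation window
#'
#' The demultiplexing core. SCPFs assigned to the window are processed in
#' decreasing order of total intensity (ties by mass ascending, then id);
#' for each SCPF the three-round cascade is run against the *remaining*
#' fragment pool, the retained fragments form that SCPF's pseudo spectrum,
#' and they are removed from the pool before the next SCPF — a fragment
#' feature is used by at most one pseudo spectrum per window. SCPFs whose
#' round-1 survivor list is empty emit nothing (logged via `message`).
#'
#' @param scpfs SCPF table of the window.
#' @param fragments Fragment table of the window.
#' @param model A [pair_model()].
#' @param params A [cascade_params()].
#' @param verbose Emit a message when an SCPF yields no fragments.
#' @return List of `pseudo_spectrum` objects: `scpf_id`, precursor mass /
#'   charge / intensity, `window`, `fallback` flag and a `fragments`
#'   data.frame (`feature_id`, `mono_mass`, `intensity`, `charge`, `score`).
#' @export
generate_window_pseudo_spectra <- function(scpfs, fragments, model,
                                           params = cascade_params(),
                                           verbose = FALSE) {
  stopifnot(inherits(params, "cascade_params"))
  ord <- feature_order(scpfs$total_intensity, scpfs$mono_mass,
                       scpfs$feature_id)
  pool <- fragments
  out <- list()
  for (i in ord) {
    s <- scpfs[i, ]
    L <- round1_filter(s, pool, t = params$t)
    if (!nrow(L)) {
      if (verbose) message(sprintf("SCPF %s: no co-eluting fragments",
                                   s$feature_id))
      next
    }
    kept <- round2_filter(s, L, model, score_cutoff = params$score_cutoff,
                          min_keep = params$min_keep)
    quota <- estimate_fragment_quota(s$mono_mass, params$avg_residue_mass)
    final <- round3_filter(kept, quota,
                           low_mass_bound = params$low_mass_bound,
                           low_quota = params$low_quota)
    if (!nrow(final)) next
    pool <- pool[!pool$feature_id %in% final$feature_id, , drop = FALSE]
    out[[length(out) + 1L]] <- structure(
      list(scpf_id = s$feature_id,
           precursor_mass = s$mono_mass,
           precursor_charge = s$charge,
           precursor_intensity = s$total_intensity,
           window = s$window,
           fallback = isTRUE(attr(kept, "fallback")),
           fragments = data.frame(feature_id = final$feature_id,
                                  mono_mass = final$mono_mass,
                                  intensity = final$total_intensity,
                                  charge = final$charge,
                                  score = final$score,
                                  stringsAsFactors = FALSE)),
      class = "pseudo_spectrum")
  }
  out
}

#' @export
print.pseudo_spectrum <- function(x, ...) {
  cat(sprintf(
    "Pseudo MS/MS spectrum for SCPF %s (mass %.4f Da, %d+, window %s): %d fragments%s\n",
    x$scpf_id, x$precursor_mass, x$precursor_charge,
    ifelse(is.null(x$window) || is.na(x$window), "?", x$window),
    nrow(x$fragments), if (isTRUE(x$fallback)) " [round-2 fallback]" else ""))
  invisible(x)
}
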