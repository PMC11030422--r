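#' @name features
#' @title SCPF and fragment-feature tables
#'
#' @description
#' Deconvoluted features are held in plain data.frames with one row per
#' feature. A single-charge proteoform feature (SCPF) is the set of isotopic
#' envelopes of one charge state of one proteoform feature; a fragment
#' feature is a deconvoluted fragment mass tracked across the MS/MS scans of
#' one isolation window. Both carry a per-cycle extracted ion chromatogram
#' (XIC): a length-`k` vector whose i-th entry is the feature's total peak
#' intensity in cycle i (`k` = number of cycles in the run).
#'
#' Columns: `feature_id` (character, unique), `mono_mass` (neutral
#' monoisotopic Da), `charge`, `total_intensity` (sum of the XIC),
#' `num_cycles` (cycles with nonzero XIC entry), `window` (isolation-window
#' index; `NA` for an unassigned SCPF), and the list columns `xic` and — for
#' SCPFs — `envelope` (two-column `mz`/`intensity` matrix summarising the
#' observed isotopic peaks).
NULL

new_feature_table <- function(feature_id, mono_mass, charge, xic, window,
                              envelope = NULL) {
  xic <- unname(lapply(xic, as.numeric))
  bad <- which(vapply(xic, function(v) any(v < 0) || all(v == 0), logical(1)))
  if (length(bad))
    stopf("invalid XIC in row %d: entries must be >= 0 with at least one > 0",
          bad[1])
  if (anyDuplicated(feature_id)) stopf("feature_id values must be unique")
  if (any(mono_mass <= 0)) stopf("mono_mass must be positive")
  df <- data.frame(
    feature_id = as.character(feature_id),
    mono_mass = as.numeric(mono_mass),
    charge = as.integer(charge),
    total_intensity = vapply(xic, sum, numeric(1)),
    num_cycles = vapply(xic, function(v) sum(v > 0), integer(1)),
    window = as.integer(window),
    stringsAsFactors = FALSE)
  df$xic <- xic
  if (!is.null(envelope)) df$envelope <- envelope
  df
}

#' Build an SCPF table
#'
#' @param feature_id Unique feature identifiers.
#' @param mono_mass Neutral monoisotopic masses in Da.
#' @param charge Charge states.
#' @param xic List of length-`k` per-cycle intensity vectors.
#' @param envelope List of two-column matrices (`mz`, `intensity`) giving each
#'   SCPF's observed isotopic peaks; used for isolation-window assignment.
#' @param window Isolation-window index, `NA` until assigned (see
#'   [assign_scpf_to_window()]).
#' @return Feature data.frame (see [features]).
#' @export
scpf_table <- function(feature_id, mono_mass, charge, xic, envelope,
                       window = NA_integer_) {
  new_feature_table(feature_id, mono_mass, charge, xic, window,
                    envelope = envelope)
}

#' Build a fragment-feature table
#'
#' @inheritParams scpf_table
#' @param window Isolation-window index each fragment feature was extracted
#'   from (always set; fragments belong to one window's LC-MS/MS map).
#' @return Feature data.frame (see [features]).
#' @export
fragment_table <- function(feature_id, mono_mass, charge, xic, window) {
  if (anyNA(window)) stopf("fragment features must carry a window index")
  new_feature_table(feature_id, mono_mass, charge, xic, window)
}

#' Apex cycle of an XIC
#'
#' The cycle index at which a feature reaches its maximum intensity. Ties are
#' broken toward the earliest cycle so the result is deterministic.
#'
#' @param xic Numeric per-cycle intensity vector.
#' @return Integer cycle index (1-based).
#' @examples
#' apex_cycle(c(0, 5, 9, 3))  # 3
#' @export
apex_cycle <- function(xic) {
  if (!length(xic) || all(xic <= 0)) stopf("empty feature: all-zero XIC")
  which.max(xic)
}

#' Apex cycle distance between two features
#'
#' @param a,b Numeric per-cycle intensity vectors.
#' @return `abs(apex_cycle(a) - apex_cycle(b))`, a non-negative integer.
#' @export
apex_cycle_distance <- function(a, b) abs(apex_cycle(a) - apex_cycle(b))

#' Assign an SCPF to an isolation window
#'
#' An SCPF belongs to a window only if that window contains strictly more
#' than 50% of the SCPF's total isotopic peak intensity; an envelope split
#' 50/50 across two windows stays unassigned. At most one window can qualify
#' because windows do not overlap.
#'
#' @param envelope Two-column matrix (`mz`, `intensity`) of the SCPF's
#'   observed isotopic peaks.
#' @param layout A [run_layout()].
#' @return Window index, or `NA_integer_` if no window holds a strict
#'   majority of the intensity.
#' @export
assign_scpf_to_window <- function(envelope, layout) {
  envelope <- as.matrix(envelope)
  if (!nrow(envelope)) stopf("empty envelope")
  total <- sum(envelope[, 2])
  if (total <= 0) return(NA_integer_)
  w <- layout$windows
  for (j in seq_len(nrow(w))) {
    inside <- envelope[, 1] >= w$mz_start[j] & envelope[, 1] < w$mz_end[j]
    if (sum(envelope[inside, 2]) > 0.5 * total) return(j)
  }
  NA_integer_
}

#' Assign every SCPF in a table to its isolation window
#'
#' @param scpfs SCPF table (see [scpf_table()]).
#' @param layout A [run_layout()].
#' @return The table with its `window` column filled in.
#' @export
assign_windows <- function(scpfs, layout) {
  scpfs$window <- vapply(scpfs$envelope, assign_scpf_to_window,
                         integer(1), layout = layout)
  scpfs
}

#' Link per-scan deconvoluted records into features
#'
#' Plumbing stand-in for full LC-MS feature detection: per-scan records with
#' the same charge whose masses agree within `ppm_tol`, and whose cycles are
#' separated by at most `max_cycle_gap`, are merged into one feature whose
#' XIC sums the record intensities per cycle.
#'
#' @param records Data.frame with columns `cycle`, `mono_mass`, `charge`,
#'   `intensity`.
#' @param num_cycles Run cycle count `k`.
#' @param ppm_tol Mass tolerance in parts per million (default 10).
#' @param max_cycle_gap Largest allowed cycle-index difference between
#'   consecutive observations of one feature (default 1, i.e. adjacent
#'   cycles only).
#' @return Data.frame with columns `mono_mass` (intensity-weighted mean),
#'   `charge` and the `xic` list column; total intensity is conserved.
#' @export
link_envelopes <- function(records, num_cycles, ppm_tol = 10,
                           max_cycle_gap = 1) {
  stopifnot(all(c("cycle", "mono_mass", "charge", "intensity") %in%
                  names(records)))
  out <- list()
  for (z in sort(unique(records$charge))) {
    r <- records[records$charge == z, ]
    r <- r[order(r$mono_mass, r$cycle), ]
    # split at consecutive mass gaps exceeding the ppm tolerance
    gap <- c(FALSE, diff(r$mono_mass) > ppm_tol * 1e-6 * r$mono_mass[-1])
    for (grp in split(r, cumsum(gap))) {
      grp <- grp[order(grp$cycle), ]
      runs <- cumsum(c(FALSE, diff(unique(sort(grp$cycle))) > max_cycle_gap))
      cyc_run <- stats::setNames(runs, unique(sort(grp$cycle)))
      for (piece in split(grp, cyc_run[as.character(grp$cycle)])) {
        xic <- numeric(num_cycles)
        agg <- tapply(piece$intensity, piece$cycle, sum)
        xic[as.integer(names(agg))] <- agg
        out[[length(out) + 1L]] <- data.frame(
          mono_mass = sum(piece$mono_mass * piece$intensity) /
            sum(piece$intensity),
          charge = z, stringsAsFactors = FALSE)
        out[[length(out)]]$xic <- list(xic)
      }
    }
  }
  if (!length(out)) {
    res <- data.frame(mono_mass = numeric(), charge = integer())
    res$xic <- list()
    return(res)
  }
  do.call(rbind, out)
}
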