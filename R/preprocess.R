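#' Spectrum noise level from an intensity histogram
#'
#' Estimates the noise intensity `h` of one centroided spectrum: a histogram
#' of all peak intensities is built and `h` is the centre of the bin with the
#' highest count. Most peaks in a raw top-down spectrum are electronic/chemical
#' noise, so the modal bin sits on the noise floor.
#'
#' Binning: equal-width bins over `[0, max(intensity)]`, `max(10, ceil(sqrt(n)))`
#' bins for `n` peaks; modal-bin ties break toward the lower-intensity bin.
#' The centre is clamped into `[min(intensity), max(intensity)]` so `h` is
#' always an attainable intensity.
#'
#' @param intensities Peak intensities of one spectrum.
#' @param bins Number of histogram bins; `NULL` (default) for the rule above.
#' @return Noise level `h` (same units as the input); 0 with a warning for an
#'   empty spectrum.
#' @examples
#' compute_noise_level(c(1, 1, 1, 1, 10))  # 1.5: modal bin [1, 2)
#' @export
compute_noise_level <- function(intensities, bins = NULL) {
  intensities <- intensities[!is.na(intensities)]
  if (!length(intensities)) {
    warnf("empty spectrum: noise level set to 0")
    return(0)
  }
  if (any(intensities < 0)) stopf("negative peak intensity")
  lo <- min(intensities); hi <- max(intensities)
  if (lo == hi) return(lo)
  if (is.null(bins)) bins <- max(10L, ceiling(sqrt(length(intensities))))
  breaks <- seq(0, hi, length.out = bins + 1L)
  # left-closed bins [b_i, b_{i+1}), last bin closed
  idx <- findInterval(intensities, breaks, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = bins)
  modal <- which.max(counts)            # ties -> lower-intensity bin
  h <- (breaks[modal] + breaks[modal + 1L]) / 2
  min(max(h, lo), hi)
}

#' Noise model for S/N peak filtering
#'
#' Bundles the per-spectrum noise level with the signal-to-noise cutoffs:
#' `r1` for MS1 spectra and `r2` for MS/MS spectra. Peaks with intensity
#' below `r * h` are removed; a peak exactly at the cutoff is retained.
#'
#' @param snr_ms1 S/N ratio `r1` applied to MS1 spectra (default 3).
#' @param snr_ms2 S/N ratio `r2` applied to MS/MS spectra (default 1).
#' @param bins Histogram bin count passed to [compute_noise_level()]
#'   (`NULL` = automatic).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(snr_ms1 = 3, snr_ms2 = 1, bins = NULL) {
  if (snr_ms1 <= 0 || snr_ms2 <= 0) stopf("S/N ratios must be positive")
  structure(list(snr_ms1 = snr_ms1, snr_ms2 = snr_ms2, bins = bins),
            class = "noise_model")
}

#' Remove sub-noise peaks from a centroided spectrum
#'
#' @param spectrum A `centroid_spectrum` (see [read_peak_lists()]): a list
#'   with `cycle`, `ms_level`, `window` and a two-column `peaks` matrix
#'   (`mz`, `intensity`).
#' @param model A [noise_model()].
#' @return The spectrum with peaks of intensity `< r * h` dropped (`r` chosen
#'   by MS level); peak order is preserved and the noise level used is stored
#'   in `$noise_level`. A noise level already recorded on the spectrum is
#'   reused, so filtering is idempotent.
#' @export
filter_peaks <- function(spectrum, model = noise_model()) {
  stopifnot(inherits(model, "noise_model"))
  pk <- spectrum$peaks
  h <- spectrum$noise_level
  if (is.null(h)) h <- compute_noise_level(pk[, "intensity"], bins = model$bins)
  r <- if (spectrum$ms_level == 1L) model$snr_ms1 else model$snr_ms2
  keep <- pk[, "intensity"] >= r * h
  spectrum$peaks <- pk[keep, , drop = FALSE]
  spectrum$noise_level <- h
  spectrum
}
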