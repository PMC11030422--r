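#' Acquisition layout of a TD-DIA run
#'
#' A TD-DIA run is organised in cycles; each cycle contains one MS1 scan
#' followed by one MS/MS scan per isolation window. The layout records the
#' number of cycles, the ordered isolation-window scheme and the precursor
#' m/z range covered by the run (one gas-phase fraction).
#'
#' @param num_cycles Number of acquisition cycles `k` (positive integer).
#' @param windows Two-column matrix or data.frame of isolation windows with
#'   columns `mz_start`, `mz_end`, sorted and non-overlapping.
#' @param precursor_range Length-2 numeric, the MS1 m/z range; defaults to the
#'   span of `windows`.
#'
#' @return An object of class `run_layout` with elements `num_cycles`,
#'   `windows` (data.frame) and `precursor_range`.
#' @examples
#' layout <- run_layout(60, uniform_windows(720, 800, 4))
#' n_windows(layout)  # 20
#' @export
run_layout <- function(num_cycles, windows, precursor_range = NULL) {
  if (!is_count(num_cycles)) stopf("num_cycles must be a positive integer")
  windows <- as.data.frame(windows)
  if (!all(c("mz_start", "mz_end") %in% names(windows)))
    stopf("windows needs columns mz_start, mz_end")
  windows <- windows[order(windows$mz_start), c("mz_start", "mz_end")]
  rownames(windows) <- NULL
  if (any(windows$mz_end <= windows$mz_start))
    stopf("each window must have mz_end > mz_start")
  if (nrow(windows) > 1 &&
      any(windows$mz_start[-1] < windows$mz_end[-nrow(windows)]))
    stopf("isolation windows must not overlap")
  if (is.null(precursor_range))
    precursor_range <- c(min(windows$mz_start), max(windows$mz_end))
  if (min(windows$mz_start) < precursor_range[1] ||
      max(windows$mz_end) > precursor_range[2])
    stopf("all windows must lie within precursor_range")
  structure(
    list(num_cycles = as.integer(num_cycles), windows = windows,
         precursor_range = as.numeric(precursor_range)),
    class = "run_layout")
}

#' Uniform isolation-window scheme
#'
#' @param mz_lo,mz_hi Precursor m/z range covered by the run.
#' @param width Isolation-window width in m/z; must divide the range evenly.
#' @return Data.frame of `(mz_hi - mz_lo) / width` contiguous windows.
#' @export
uniform_windows <- function(mz_lo, mz_hi, width) {
  n <- (mz_hi - mz_lo) / width
  if (abs(n - round(n)) > 1e-9) stopf("width must divide the m/z range evenly")
  n <- round(n)
  starts <- mz_lo + width * (seq_len(n) - 1)
  data.frame(mz_start = starts, mz_end = starts + width)
}

#' @rdname run_layout
#' @param layout A `run_layout`.
#' @export
n_windows <- function(layout) nrow(layout$windows)

#' @export
print.run_layout <- function(x, ...) {
  cat(sprintf(
    "TD-DIA run layout: %d cycles, %d isolation windows over m/z [%g, %g]\n",
    x$num_cycles, n_windows(x), x$precursor_range[1], x$precursor_range[2]))
  invisible(x)
}
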