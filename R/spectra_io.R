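#' Read centroided peak lists for a TD-DIA run
#'
#' Two inputs are supported. The canonical plain-text format is a TSV with
#' header `cycle  ms_level  window  mz  intensity`, one row per peak, in
#' acquisition order; a scan without surviving peaks appears as a single row
#' with empty `mz`/`intensity`. Files ending in `.mzML` are read through the
#' `mzR` package when it is available, with scans mapped to cycles by
#' acquisition order (one MS1 scan followed by one MS/MS scan per window).
#'
#' @param path Input file.
#' @param layout A [run_layout()]; used to validate that every cycle carries
#'   one MS1 scan and exactly one MS/MS scan per isolation window.
#' @return List of `centroid_spectrum` objects, each a list with `cycle`,
#'   `ms_level`, `window` (`NA` for MS1) and a `peaks` matrix with columns
#'   `mz`, `intensity` sorted by m/z.
#' @export
read_peak_lists <- function(path, layout) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (grepl("\\.mzML$", path, ignore.case = TRUE))
    return(read_peak_lists_mzml(path, layout))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!nrow(tab)) {
    warnf("empty peak-list file: %s", path)
    return(list())
  }
  needed <- c("cycle", "ms_level", "window", "mz", "intensity")
  if (!all(needed %in% names(tab))) stopf("peak list needs columns %s",
                                          paste(needed, collapse = ", "))
  if (any(tab$intensity < 0, na.rm = TRUE)) stopf("negative peak intensity")
  W <- n_windows(layout)
  key <- paste(tab$cycle, tab$ms_level, tab$window)
  specs <- list()
  for (grp in split(tab, factor(key, levels = unique(key)))) {
    pk <- grp[!is.na(grp$mz), c("mz", "intensity"), drop = FALSE]
    pk <- as.matrix(pk[order(pk$mz), , drop = FALSE])
    if (!nrow(pk)) pk <- matrix(numeric(), 0, 2,
                                dimnames = list(NULL, c("mz", "intensity")))
    specs[[length(specs) + 1L]] <- structure(
      list(cycle = grp$cycle[1], ms_level = as.integer(grp$ms_level[1]),
           window = if (grp$ms_level[1] == 1L) NA_integer_
                    else as.integer(grp$window[1]),
           peaks = pk),
      class = "centroid_spectrum")
  }
  validate_cycle_structure(specs, W)
  specs
}

validate_cycle_structure <- function(specs, W) {
  cyc <- vapply(specs, `[[`, numeric(1), "cycle")
  lev <- vapply(specs, `[[`, integer(1), "ms_level")
  win <- vapply(specs, `[[`, integer(1), "window")
  for (cc in sort(unique(cyc))) {
    i <- cyc == cc
    if (sum(i & lev == 1L) != 1L)
      stopf("malformed cycle %d: expected exactly 1 MS1 scan, found %d",
            cc, sum(i & lev == 1L))
    ms2 <- sort(win[i & lev == 2L])
    if (length(ms2) != W || !identical(as.integer(ms2), seq_len(W)))
      stopf("malformed cycle %d: expected %d MS/MS scans (one per window), found %d",
            cc, W, length(ms2))
  }
  invisible(TRUE)
}

read_peak_lists_mzml <- function(path, layout) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stopf("reading mzML requires the mzR package")
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms))
  hdr <- mzR::header(ms)
  W <- n_windows(layout)
  specs <- vector("list", nrow(hdr))
  cycle <- 0L; win <- 0L
  for (i in seq_len(nrow(hdr))) {
    lv <- as.integer(hdr$msLevel[i])
    if (lv == 1L) { cycle <- cycle + 1L; win <- 0L }
    else {
      win <- win + 1L
      if (cycle == 0L || win > W)
        stopf("malformed cycle %d: MS/MS scan %d exceeds %d windows",
              max(cycle, 1L), win, W)
    }
    pk <- mzR::peaks(ms, i)
    colnames(pk) <- c("mz", "intensity")
    specs[[i]] <- structure(
      list(cycle = cycle, ms_level = lv,
           window = if (lv == 1L) NA_integer_ else win, peaks = pk),
      class = "centroid_spectrum")
  }
  validate_cycle_structure(specs, W)
  specs
}

#' Write centroided peak lists in the plain-text exchange format
#'
#' @param spectra List of `centroid_spectrum` objects.
#' @param path Output TSV.
#' @export
write_peak_lists <- function(spectra, path) {
  rows <- lapply(spectra, function(s) {
    if (nrow(s$peaks))
      data.frame(cycle = s$cycle, ms_level = s$ms_level,
                 window = if (is.na(s$window)) NA_integer_ else s$window,
                 mz = s$peaks[, "mz"], intensity = s$peaks[, "intensity"])
    else
      data.frame(cycle = s$cycle, ms_level = s$ms_level,
                 window = if (is.na(s$window)) NA_integer_ else s$window,
                 mz = NA_real_, intensity = NA_real_)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(format(tab, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

fmt_num <- function(x) sprintf("%.17g", x)

encode_xic <- function(x) paste(fmt_num(x), collapse = ";")
decode_xic <- function(s) as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
encode_env <- function(m) {
  if (is.null(m) || !nrow(m)) return("")
  paste(paste(fmt_num(m[, 1]), fmt_num(m[, 2]), sep = ":"), collapse = ",")
}
decode_env <- function(s) {
  if (is.na(s) || s == "")
    return(matrix(numeric(), 0, 2, dimnames = list(NULL, c("mz", "intensity"))))
  parts <- do.call(rbind, strsplit(strsplit(s, ",", fixed = TRUE)[[1]], ":"))
  matrix(as.numeric(parts), ncol = 2,
         dimnames = list(NULL, c("mz", "intensity")))
}

#' Write a feature table
#'
#' Serialises SCPF and fragment-feature tables to one TSV. XICs are stored as
#' dense semicolon-separated length-`k` vectors; SCPF envelopes as
#' comma-separated `mz:intensity` pairs. The file round-trips losslessly
#' through [read_feature_table()].
#'
#' @param scpfs SCPF table ([scpf_table()]); may have zero rows.
#' @param fragments Fragment table ([fragment_table()]); may have zero rows.
#' @param path Output TSV.
#' @export
write_feature_table <- function(scpfs, fragments, path) {
  row_of <- function(f, kind, env) data.frame(
    feature_id = f$feature_id, kind = kind,
    mono_mass = fmt_num(f$mono_mass), charge = f$charge,
    window = f$window,
    xic = vapply(f$xic, encode_xic, character(1)),
    envelope = env, stringsAsFactors = FALSE)
  parts <- list()
  if (nrow(scpfs))
    parts$s <- row_of(scpfs, "scpf",
                      vapply(scpfs$envelope, encode_env, character(1)))
  if (nrow(fragments))
    parts$f <- row_of(fragments, "fragment", "")
  tab <- if (length(parts)) do.call(rbind, parts) else
    data.frame(feature_id = character(), kind = character(),
               mono_mass = character(), charge = integer(),
               window = integer(), xic = character(), envelope = character())
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a feature table
#'
#' @param path TSV written by [write_feature_table()].
#' @param num_cycles Expected XIC length `k`; inferred from the first row if
#'   `NULL`. Rows whose XIC length differs raise a validation error.
#' @return List with elements `scpfs` and `fragments` (see [features]).
#' @export
read_feature_table <- function(path, num_cycles = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(mono_mass = "character",
                                          xic = "character",
                                          envelope = "character"))
  if (!nrow(tab)) return(list(scpfs = NULL, fragments = NULL))
  xics <- lapply(tab$xic, decode_xic)
  if (is.null(num_cycles)) num_cycles <- length(xics[[1]])
  for (i in seq_along(xics)) {
    if (length(xics[[i]]) != num_cycles)
      stopf("row %d: XIC length %d != expected %d cycles",
            i, length(xics[[i]]), num_cycles)
    if (any(xics[[i]] < 0)) stopf("row %d: negative XIC intensity", i)
    if (as.numeric(tab$mono_mass[i]) <= 0) stopf("row %d: non-positive mass", i)
  }
  is_s <- tab$kind == "scpf"
  scpfs <- if (any(is_s)) scpf_table(
    tab$feature_id[is_s], as.numeric(tab$mono_mass[is_s]), tab$charge[is_s],
    xics[is_s], lapply(tab$envelope[is_s], decode_env),
    window = tab$window[is_s]) else NULL
  frags <- if (any(!is_s)) fragment_table(
    tab$feature_id[!is_s], as.numeric(tab$mono_mass[!is_s]),
    tab$charge[!is_s], xics[!is_s], window = tab$window[!is_s]) else NULL
  list(scpfs = scpfs, fragments = frags)
}

#' Write pseudo MS/MS spectra in msalign-style text
#'
#' One `BEGIN IONS` / `END IONS` block per pseudo spectrum with precursor
#' mass, charge and intensity headers and one `mass  intensity  charge` line
#' per fragment. Blocks are ordered by precursor (SCPF) intensity rank,
#' fragments by mass ascending, so output is deterministic. The `toppic`
#' dialect adds the spectrum bookkeeping headers (`ID`, `FRACTION_ID`,
#' `SCANS`, `ACTIVATION`) that recent TopPIC-family readers expect; field
#' requirements vary across search-engine versions, hence the option.
#'
#' @param spectra List of `pseudo_spectrum` objects
#'   (see [generate_window_pseudo_spectra()]).
#' @param path Output file.
#' @param dialect `"minimal"` (default) or `"toppic"`.
#' @export
write_pseudo_spectra <- function(spectra, path,
                                 dialect = c("minimal", "toppic")) {
  dialect <- match.arg(dialect)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#tddemux pseudo spectra\t%d spectra\tdialect=%s",
                     length(spectra), dialect), con)
  if (!length(spectra)) return(invisible(path))
  ord <- order(-vapply(spectra, `[[`, numeric(1), "precursor_intensity"),
               vapply(spectra, `[[`, numeric(1), "precursor_mass"))
  id <- 0L
  for (s in spectra[ord]) {
    if (!nrow(s$fragments)) next
    fr <- s$fragments[order(s$fragments$mono_mass), , drop = FALSE]
    writeLines("BEGIN IONS", con)
    if (dialect == "toppic") {
      writeLines(sprintf("ID=%d", id), con)
      writeLines("FRACTION_ID=0", con)
      writeLines(sprintf("SCANS=%d", id + 1L), con)
      writeLines("ACTIVATION=HCD", con)
    }
    writeLines(sprintf("PRECURSOR_ID=%s", s$scpf_id), con)
    writeLines(sprintf("PRECURSOR_MASS=%s", fmt_num(s$precursor_mass)), con)
    writeLines(sprintf("PRECURSOR_CHARGE=%d", s$precursor_charge), con)
    writeLines(sprintf("PRECURSOR_INTENSITY=%s",
                       fmt_num(s$precursor_intensity)), con)
    writeLines(paste(fmt_num(fr$mono_mass), fmt_num(fr$intensity), fr$charge,
                     sep = "\t"), con)
    writeLines("END IONS", con)
    id <- id + 1L
  }
  invisible(path)
}

#' Read back an msalign-style pseudo-spectrum file
#'
#' Inverse of [write_pseudo_spectra()] for the fields both dialects share.
#'
#' @param path File written by [write_pseudo_spectra()].
#' @return List of `pseudo_spectrum` objects.
#' @export
read_pseudo_spectra <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (lines[i] == "BEGIN IONS") {
      hdr <- list(); frag <- list()
      i <- i + 1L
      while (lines[i] != "END IONS") {
        if (grepl("=", lines[i], fixed = TRUE)) {
          kv <- strsplit(lines[i], "=", fixed = TRUE)[[1]]
          hdr[[kv[1]]] <- kv[2]
        } else {
          frag[[length(frag) + 1L]] <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
        }
        i <- i + 1L
      }
      fr <- do.call(rbind, frag)
      out[[length(out) + 1L]] <- structure(
        list(scpf_id = hdr[["PRECURSOR_ID"]],
             precursor_mass = as.numeric(hdr[["PRECURSOR_MASS"]]),
             precursor_charge = as.integer(hdr[["PRECURSOR_CHARGE"]]),
             precursor_intensity = as.numeric(hdr[["PRECURSOR_INTENSITY"]]),
             fragments = data.frame(mono_mass = as.numeric(fr[, 1]),
                                    intensity = as.numeric(fr[, 2]),
                                    charge = as.integer(fr[, 3]))),
        class = "pseudo_spectrum")
    }
    i <- i + 1L
  }
  out
}
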