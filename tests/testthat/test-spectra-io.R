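three_cycle_fixture <- function() {
  run <- simulate_run(sim_config(num_cycles = 20, n_proteoforms = 2,
                                 coisolation_fraction = 0, noise_peaks = 5,
                                 length_range = c(60, 90), seed = 11))
  keep <- vapply(run$peak_lists, `[[`, numeric(1), "cycle") <= 3
  run$peak_lists[keep]
}

test_that("peak lists parse with correct cycle/window bookkeeping", {
  layout <- run_layout(3, uniform_windows(720, 800, 4))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_peak_lists(three_cycle_fixture(), path)
  specs <- read_peak_lists(path, layout)

  expect_length(specs, 3 * (1 + 20))
  cyc <- vapply(specs, `[[`, numeric(1), "cycle")
  lev <- vapply(specs, `[[`, integer(1), "ms_level")
  expect_setequal(unique(cyc), 1:3)
  expect_equal(sum(lev == 2) / 3, n_windows(layout))
  # scan-to-(cycle, window) assignment is a bijection for MS/MS scans
  keys <- paste(cyc[lev == 2],
                vapply(specs[lev == 2], `[[`, integer(1), "window"))
  expect_false(anyDuplicated(keys) > 0)
})

test_that("malformed cycles are rejected with the cycle named", {
  layout <- run_layout(3, uniform_windows(720, 800, 4))
  # drop every row of cycle 2 / window 7: that scan disappears entirely
  path <- withr::local_tempfile(fileext = ".tsv")
  write_peak_lists(three_cycle_fixture(), path)
  tab <- read.delim(path)
  tab <- tab[!(tab$cycle == 2 & tab$ms_level == 2 & tab$window == 7), ]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  expect_error(read_peak_lists(path, layout), "cycle 2")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("cycle\tms_level\twindow\tmz\tintensity", empty)
  expect_warning(out <- read_peak_lists(empty, layout), "empty")
  expect_length(out, 0)
})

test_that("feature tables round-trip losslessly", {
  run <- simulate_run(sim_config(n_proteoforms = 4, emit_peak_lists = FALSE,
                                 seed = 7))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(run$scpfs, run$fragments, path)
  back <- read_feature_table(path)

  expect_equal(nrow(back$scpfs), nrow(run$scpfs))
  expect_equal(nrow(back$fragments), nrow(run$fragments))
  expect_equal(back$scpfs$mono_mass, run$scpfs$mono_mass, tolerance = 1e-12)
  expect_equal(back$fragments$xic, run$fragments$xic, tolerance = 1e-12)
  expect_equal(back$scpfs$envelope[[1]], run$scpfs$envelope[[1]],
               tolerance = 1e-12)
  expect_equal(back$scpfs$total_intensity, run$scpfs$total_intensity,
               tolerance = 1e-12)
})

test_that("feature-table validation flags bad rows by number", {
  run <- simulate_run(sim_config(n_proteoforms = 2, emit_peak_lists = FALSE,
                                 num_cycles = 20, seed = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(run$scpfs, run$fragments, path)
  expect_error(read_feature_table(path, num_cycles = 21), "row 1.*XIC length")
})

test_that("pseudo-spectrum files round-trip and order deterministically", {
  frag <- data.frame(feature_id = c("a", "b", "c"),
                     mono_mass = c(5000.5, 300.25, 1200.125),
                     intensity = c(10, 30, 20), charge = c(2L, 1L, 1L),
                     score = c(0.9, 0.8, 0.7))
  ps <- function(id, mass, inten, fr) structure(
    list(scpf_id = id, precursor_mass = mass, precursor_charge = 10L,
         precursor_intensity = inten, window = 1L, fallback = FALSE,
         fragments = fr), class = "pseudo_spectrum")
  specs <- list(ps("s_lo", 9000.125, 100, frag),
                ps("s_hi", 8000.5, 5000, frag))
  path <- withr::local_tempfile(fileext = ".msalign")
  write_pseudo_spectra(specs, path)
  back <- read_pseudo_spectra(path)

  # ordered by precursor intensity rank, fragments by mass ascending
  expect_equal(vapply(back, `[[`, character(1), "scpf_id"),
               c("s_hi", "s_lo"))
  expect_equal(back[[1]]$fragments$mono_mass, sort(frag$mono_mass),
               tolerance = 1e-12)
  expect_equal(back[[2]]$precursor_mass, 9000.125)

  # empty input yields a valid header-only file
  write_pseudo_spectra(list(), path)
  expect_length(read_pseudo_spectra(path), 0)
  expect_match(readLines(path)[1], "0 spectra")
})

test_that("serialized pseudo spectra match in-memory masses at 1e-9", {
  run <- simulate_run(sim_config(n_proteoforms = 6, emit_peak_lists = FALSE,
                                 seed = 21))
  model <- trained_toy_model()
  res <- run_pipeline(list(scpfs = run$scpfs, fragments = run$fragments),
                      model, output = withr::local_tempfile())
  back <- read_pseudo_spectra(res$output)
  expect_length(back, length(res$spectra))
  mem <- res$spectra[order(-vapply(res$spectra, `[[`, numeric(1),
                                   "precursor_intensity"),
                           vapply(res$spectra, `[[`, numeric(1),
                                  "precursor_mass"))]
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$precursor_mass, mem[[i]]$precursor_mass,
                 tolerance = 1e-9)
    expect_equal(sort(back[[i]]$fragments$mono_mass),
                 sort(mem[[i]]$fragments$mono_mass), tolerance = 1e-9)
  }
})
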