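#' @name synthetic
#' @title Synthetic TD-DIA run generation
#' @description
#' Generates complete synthetic TD-DIA runs — SCPF and fragment-feature
#' tables, optional centroided peak lists, and full ground truth — so every
#' pipeline stage is testable without instrument data. Proteoforms are
#' random amino-acid sequences whose precursor m/z is steered into a chosen
#' isolation window; elution profiles are Gaussians sampled at cycle centres
#' and truncated at 1% of peak height; each proteoform's detectable b/y
#' ions become fragment features sharing the precursor's elution profile
#' (with configurable apex jitter), and decoy fragment features with
#' unrelated profiles and non-ladder masses emulate co-isolated background.
NULL

# Standard monoisotopic amino-acid residue masses (Da).
RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
WATER_MASS <- 18.0105646863
PROTON_MASS <- 1.00727646688

#' Neutral monoisotopic mass of a proteoform sequence
#'
#' @param sequence Amino-acid string (one-letter codes).
#' @return Mass in Da (residue sum plus one water).
#' @export
proteoform_mass <- function(sequence) {
  res <- strsplit(sequence, "")[[1]]
  unknown <- setdiff(res, names(RESIDUE_MASS))
  if (length(unknown)) stopf("unknown residue(s): %s",
                             paste(unique(unknown), collapse = ", "))
  sum(RESIDUE_MASS[res]) + WATER_MASS
}

#' Theoretical b/y fragment masses of a sequence
#'
#' b ions are prefix residue sums; y ions are suffix residue sums plus one
#' water (neutral monoisotopic masses, standard offsets).
#'
#' @param sequence Amino-acid string of length `l >= 2`.
#' @return Data.frame with columns `series` (`"b"`/`"y"`), `index`
#'   (1 .. `l - 1`) and `mass` (Da).
#' @export
by_masses <- function(sequence) {
  res <- RESIDUE_MASS[strsplit(sequence, "")[[1]]]
  l <- length(res)
  if (l < 2L) stopf("sequence must have at least 2 residues")
  b <- cumsum(res)[-l]
  y <- rev(cumsum(rev(res))[-l]) + WATER_MASS
  data.frame(series = rep(c("b", "y"), each = l - 1L),
             index = c(seq_len(l - 1L), rev(seq_len(l - 1L))),
             mass = c(b, y), stringsAsFactors = FALSE)
}

# Random sequence whose mass lands close to a target: random residues up to
# ~250 Da below target, then a glycine/alanine tail chosen by small search
# to close the gap (achievable to within ~7 Da, i.e. < 1 m/z at charge 9+).
random_sequence_near_mass <- function(target_mass) {
  target_res <- target_mass - WATER_MASS
  seqv <- character(0)
  mass <- 0
  while (mass < target_res - 250) {
    aa <- sample(names(RESIDUE_MASS), 1L)
    seqv <- c(seqv, aa)
    mass <- mass + RESIDUE_MASS[[aa]]
  }
  r <- target_res - mass
  best <- c(a = 0L, b = 0L, err = Inf)
  for (nb in 0:floor(r / RESIDUE_MASS[["A"]])) {
    na <- max(0L, round((r - nb * RESIDUE_MASS[["A"]]) / RESIDUE_MASS[["G"]]))
    err <- abs(r - na * RESIDUE_MASS[["G"]] - nb * RESIDUE_MASS[["A"]])
    if (err < best[["err"]]) best <- c(a = na, b = nb, err = err)
  }
  paste(c(seqv, rep("G", best[["a"]]), rep("A", best[["b"]])), collapse = "")
}

# Gaussian elution profile sampled at cycle centres, truncated at 1% of peak.
gaussian_xic <- function(num_cycles, apex, sigma, peak) {
  x <- peak * exp(-((seq_len(num_cycles) - apex)^2) / (2 * sigma^2))
  x[x < 0.01 * peak] <- 0
  x
}

#' Configuration of a synthetic TD-DIA run
#'
#' Defaults mirror the acquisition scheme of a gas-phase-fractionated
#' top-down DIA experiment: one run covering an 80 m/z precursor range with
#' twenty 4-m/z isolation windows. The cycle count and feature counts are
#' kept at desk scale.
#'
#' @param num_cycles Cycles in the run (default 60).
#' @param mz_lo,mz_hi Precursor m/z range (default 720-800).
#' @param window_width Isolation-window width in m/z (default 4, i.e. 20
#'   MS/MS scans per cycle).
#' @param n_proteoforms Number of simulated proteoforms (default 20).
#' @param coisolation_fraction Fraction of proteoforms placed as co-isolated
#'   pairs sharing one window (default 0.3).
#' @param coisolation_apex_sep Minimum apex-cycle separation of co-isolated
#'   pairs (default 4 cycles).
#' @param length_range Proteoform length range in residues (default 60-160).
#' @param charge_range Precursor charge-state range (default 9-18).
#' @param frags_per_series Detectable b/y ions emitted per series, most
#'   intense first (default 25).
#' @param fragment_decay Geometric decay of fragment intensity with ion
#'   index (default 0.95).
#' @param fragment_rel_intensity Fragment-to-precursor peak intensity ratio
#'   for the first ion of a series (default 0.1).
#' @param min_fragment_mass Smallest emitted fragment mass in Da
#'   (default 200).
#' @param apex_jitter_sd Standard deviation, in cycles, of the fragment apex
#'   jitter around the precursor apex (default 0.4).
#' @param decoys_per_window Decoy fragment features per occupied window
#'   (default 40); decoy masses are rejection-sampled at least 50 ppm from
#'   every catalog b/y mass.
#' @param noise_peaks Noise peaks per simulated spectrum in the peak lists
#'   (default 50).
#' @param emit_peak_lists Also simulate centroided peak lists (default TRUE).
#' @param seed Mandatory integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(num_cycles = 60, mz_lo = 720, mz_hi = 800,
                       window_width = 4, n_proteoforms = 20,
                       coisolation_fraction = 0.3, coisolation_apex_sep = 4,
                       length_range = c(60, 160), charge_range = c(9, 18),
                       frags_per_series = 25, fragment_decay = 0.95,
                       fragment_rel_intensity = 0.1, min_fragment_mass = 200,
                       apex_jitter_sd = 0.4, decoys_per_window = 40,
                       noise_peaks = 50, emit_peak_lists = TRUE,
                       seed) {
  if (missing(seed) || !is.numeric(seed)) stopf("a numeric seed is mandatory")
  stopifnot(num_cycles >= 20, n_proteoforms >= 1,
            coisolation_fraction >= 0, coisolation_fraction <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a complete TD-DIA run
#'
#' @param config A [sim_config()].
#' @return List of class `sim_run` with elements:
#'   \describe{
#'     \item{layout}{[run_layout()] of the run.}
#'     \item{scpfs, fragments}{feature tables (see [features]); fragment ids
#'       encode nothing — provenance lives in the truth tables.}
#'     \item{peak_lists}{list of `centroid_spectrum` objects or `NULL`.}
#'     \item{truth}{ground truth: `proteoforms` (sequence, mass, charge,
#'       window, apex, sigma, peak intensity), `features` (feature id ->
#'       source proteoform, type, series, index, theoretical mass),
#'       `catalog` (proteoform id -> b/y mass vector) and `scpf_proteoform`
#'       (named map).}
#'     \item{config}{the configuration used.}
#'   }
#'   Identical configs (including seed) give identical runs.
#' @export
simulate_run <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_run_impl(config))
}

simulate_run_impl <- function(cfg) {
  layout <- run_layout(cfg$num_cycles,
                       uniform_windows(cfg$mz_lo, cfg$mz_hi, cfg$window_width))
  W <- n_windows(layout)
  n <- cfg$n_proteoforms
  n_pair <- floor(cfg$coisolation_fraction * n / 2)
  n_groups <- n_pair + (n - 2L * n_pair)
  if (n_groups > W)
    stopf("infeasible window packing: %d proteoform groups > %d windows",
          n_groups, W)
  group_windows <- sample.int(W, n_groups)
  # group g holds 2 proteoforms for g <= n_pair, else 1
  pf_group <- c(rep(seq_len(n_pair), each = 2L),
                if (n > 2L * n_pair) (n_pair + 1L):n_groups)

  k <- cfg$num_cycles
  pf <- vector("list", n)
  for (i in seq_len(n)) {
    g <- pf_group[i]
    w <- group_windows[g]
    mz_target <- (layout$windows$mz_start[w] + layout$windows$mz_end[w]) / 2 +
      stats::runif(1, -0.4, 0.4)
    z <- sample(seq(cfg$charge_range[1], cfg$charge_range[2]), 1L)
    # keep the Averagine length within the configured range for this charge
    lr <- cfg$length_range
    z <- max(z, ceiling(lr[1] * 111.1254 / (mz_target - PROTON_MASS)))
    z <- min(z, floor(lr[2] * 111.1254 / (mz_target - PROTON_MASS)))
    target_mass <- z * (mz_target - PROTON_MASS)
    sequence <- random_sequence_near_mass(target_mass)
    mass <- proteoform_mass(sequence)
    mz <- mass / z + PROTON_MASS
    second <- i > 1L && pf_group[i - 1L] == g
    if (second) {
      prev <- pf[[i - 1L]]
      sep <- cfg$coisolation_apex_sep + stats::runif(1, 0, 3)
      apex <- if (prev$apex < k / 2) prev$apex + sep else prev$apex - sep
    } else {
      apex <- stats::runif(1, 8, k - 8)
    }
    pf[[i]] <- list(
      proteoform_id = sprintf("P%03d", i), sequence = sequence, mass = mass,
      charge = z, mz = mz, window = w, apex = apex,
      sigma = stats::runif(1, 1.5, 3),
      peak = 10^stats::runif(1, 5.5, 7.5))
  }

  catalog <- lapply(pf, function(p) by_masses(p$sequence)$mass)
  names(catalog) <- vapply(pf, `[[`, character(1), "proteoform_id")

  # SCPF per proteoform (one charge state)
  scpf_rows <- lapply(seq_len(n), function(i) {
    p <- pf[[i]]
    iso <- 0:4
    env_mz <- p$mz + iso * 1.00235 / p$charge
    env_int <- stats::dnorm(iso, mean = 1.5, sd = 1.2)
    env_int <- env_int / sum(env_int)
    list(id = sprintf("S%03d", i),
         xic = gaussian_xic(k, p$apex, p$sigma, p$peak),
         envelope = cbind(mz = env_mz, intensity = env_int * p$peak))
  })
  scpfs <- scpf_table(
    feature_id = vapply(scpf_rows, `[[`, character(1), "id"),
    mono_mass = vapply(pf, `[[`, numeric(1), "mass"),
    charge = vapply(pf, `[[`, numeric(1), "charge"),
    xic = lapply(scpf_rows, `[[`, "xic"),
    envelope = lapply(scpf_rows, `[[`, "envelope"),
    window = vapply(pf, `[[`, numeric(1), "window"))

  # fragment features: detectable b/y ions, geometric intensity decay
  frag_rows <- list()
  feat_truth <- list()
  for (i in seq_len(n)) {
    p <- pf[[i]]
    lad <- by_masses(p$sequence)
    for (series in c("b", "y")) {
      ions <- lad[lad$series == series & lad$mass >= cfg$min_fragment_mass, ]
      ions <- ions[order(ions$index), ]
      ions <- utils::head(ions, cfg$frags_per_series)
      for (j in seq_len(nrow(ions))) {
        inten <- p$peak * cfg$fragment_rel_intensity *
          cfg$fragment_decay^(j - 1L)
        apex_f <- p$apex + stats::rnorm(1, 0, cfg$apex_jitter_sd)
        xic <- gaussian_xic(k, apex_f, p$sigma * stats::runif(1, 0.85, 1.15),
                            inten)
        if (all(xic == 0)) next
        fid <- sprintf("F%05d", length(frag_rows) + 1L)
        frag_rows[[fid]] <- list(mass = ions$mass[j],
                                 charge = sample(1:3, 1L),
                                 window = p$window, xic = xic)
        feat_truth[[fid]] <- data.frame(
          feature_id = fid, proteoform_id = p$proteoform_id, type = "by",
          series = series, index = ions$index[j], theo_mass = ions$mass[j],
          stringsAsFactors = FALSE)
      }
    }
  }

  # decoys: uniform masses kept >= 50 ppm away from every catalog b/y mass
  all_by <- sort(unlist(catalog, use.names = FALSE))
  occupied <- unique(vapply(pf, `[[`, numeric(1), "window"))
  max_mass <- max(vapply(pf, `[[`, numeric(1), "mass"))
  for (w in sort(occupied)) {
    made <- 0L
    while (made < cfg$decoys_per_window) {
      m <- stats::runif(1, cfg$min_fragment_mass, max_mass)
      near <- all_by[findInterval(m, all_by, all.inside = TRUE) + c(0L, 1L)]
      near <- near[!is.na(near)]
      if (length(near) && min(abs(m - near)) <= 50e-6 * m) next
      made <- made + 1L
      fid <- sprintf("F%05d", length(frag_rows) + 1L)
      frag_rows[[fid]] <- list(
        mass = m, charge = sample(1:3, 1L), window = w,
        xic = gaussian_xic(k, stats::runif(1, 2, k - 1),
                           stats::runif(1, 1, 3), 10^stats::runif(1, 4.5, 6.5)))
      feat_truth[[fid]] <- data.frame(
        feature_id = fid, proteoform_id = NA_character_, type = "decoy",
        series = NA_character_, index = NA_integer_, theo_mass = m,
        stringsAsFactors = FALSE)
    }
  }

  fragments <- fragment_table(
    feature_id = names(frag_rows),
    mono_mass = vapply(frag_rows, `[[`, numeric(1), "mass"),
    charge = vapply(frag_rows, `[[`, numeric(1), "charge"),
    xic = lapply(frag_rows, `[[`, "xic"),
    window = vapply(frag_rows, `[[`, numeric(1), "window"))
  rownames(fragments) <- NULL

  scpf_proteoform <- stats::setNames(names(catalog), scpfs$feature_id)

  peak_lists <- if (cfg$emit_peak_lists)
    simulate_peak_lists(layout, scpfs, fragments, cfg) else NULL

  truth <- list(
    proteoforms = data.frame(
      proteoform_id = names(catalog),
      sequence = vapply(pf, `[[`, character(1), "sequence"),
      mono_mass = vapply(pf, `[[`, numeric(1), "mass"),
      charge = vapply(pf, `[[`, numeric(1), "charge"),
      mz = vapply(pf, `[[`, numeric(1), "mz"),
      window = vapply(pf, `[[`, numeric(1), "window"),
      apex = vapply(pf, `[[`, numeric(1), "apex"),
      sigma = vapply(pf, `[[`, numeric(1), "sigma"),
      peak_intensity = vapply(pf, `[[`, numeric(1), "peak"),
      stringsAsFactors = FALSE),
    features = do.call(rbind, c(feat_truth, list(make.row.names = FALSE))),
    catalog = catalog,
    scpf_proteoform = scpf_proteoform)

  structure(list(layout = layout, scpfs = scpfs, fragments = fragments,
                 peak_lists = peak_lists, truth = truth, config = cfg),
            class = "sim_run")
}

simulate_peak_lists <- function(layout, scpfs, fragments, cfg) {
  k <- layout$num_cycles
  W <- n_windows(layout)
  specs <- vector("list", k * (W + 1L))
  idx <- 0L
  frag_by_win <- split(seq_len(nrow(fragments)), fragments$window)
  for (cyc in seq_len(k)) {
    # MS1: isotopic envelopes of eluting SCPFs + exponential noise floor
    sig <- list()
    for (i in seq_len(nrow(scpfs))) {
      a <- scpfs$xic[[i]][cyc]
      if (a > 0) {
        env <- scpfs$envelope[[i]]
        sig[[length(sig) + 1L]] <-
          cbind(mz = env[, "mz"],
                intensity = env[, "intensity"] / sum(env[, "intensity"]) * a)
      }
    }
    noise <- cbind(
      mz = stats::runif(cfg$noise_peaks, layout$precursor_range[1],
                        layout$precursor_range[2]),
      intensity = stats::rexp(cfg$noise_peaks, rate = 1 / 3000))
    pk <- rbind(do.call(rbind, sig), noise)
    pk <- pk[order(pk[, "mz"]), , drop = FALSE]
    idx <- idx + 1L
    specs[[idx]] <- structure(
      list(cycle = cyc, ms_level = 1L, window = NA_integer_, peaks = pk),
      class = "centroid_spectrum")
    for (w in seq_len(W)) {
      rows <- frag_by_win[[as.character(w)]]
      sig <- NULL
      if (!is.null(rows)) {
        a <- vapply(rows, function(r) fragments$xic[[r]][cyc], numeric(1))
        on <- a > 0
        if (any(on))
          sig <- cbind(
            mz = fragments$mono_mass[rows[on]] / fragments$charge[rows[on]] +
              PROTON_MASS,
            intensity = a[on])
      }
      noise <- cbind(
        mz = stats::runif(cfg$noise_peaks, 400, 2000),
        intensity = stats::rexp(cfg$noise_peaks, rate = 1 / 3000))
      pk <- rbind(sig, noise)
      pk <- pk[order(pk[, "mz"]), , drop = FALSE]
      idx <- idx + 1L
      specs[[idx]] <- structure(
        list(cycle = cyc, ms_level = 2L, window = w, peaks = pk),
        class = "centroid_spectrum")
    }
  }
  specs
}

#' Labeled pair training set from a simulated run
#'
#' Builds the SCPF / fragment pair table exactly as the scoring module does
#' ([build_pairs()] + [label_pairs()] on the generator's proteoform catalog)
#' and attaches the generator's own independently computed `truth_label`
#' (vectorized mass match of each fragment against the paired proteoform's
#' ladder). The two label columns agree by construction of the generator and
#' cross-validate the two code paths.
#'
#' @param run A [simulate_run()] result.
#' @param t Round-1 gate parameter used for pairing (default 3).
#' @param ppm_tol b/y match tolerance in ppm (default 10).
#' @return Pair data.frame with `label` and `truth_label` columns.
#' @export
make_pair_training_set <- function(run, t = 3, ppm_tol = 10) {
  stopifnot(inherits(run, "sim_run"))
  pairs <- build_pairs(run$scpfs, run$fragments, t = t)
  pairs <- label_pairs(pairs, run$truth$scpf_proteoform, run$truth$catalog,
                       ppm_tol = ppm_tol)
  # independent generator bookkeeping path: sorted-catalog interval search
  pairs$truth_label <- vapply(seq_len(nrow(pairs)), function(i) {
    theo <- sort(run$truth$catalog[[
      run$truth$scpf_proteoform[[pairs$scpf_id[i]]]]])
    m <- pairs$fragment_mass[i]
    j <- findInterval(m, theo)
    cand <- theo[c(j, j + 1L)[c(j, j + 1L) >= 1 & c(j, j + 1L) <= length(theo)]]
    length(cand) > 0 && min(abs(m - cand)) <= ppm_tol * 1e-6 *
      cand[which.min(abs(m - cand))]
  }, logical(1))
  pairs
}

#' Simulate a labeled pair-attribute set directly
#'
#' Draws pair attributes from class-conditional distributions instead of a
#' full run: positives have elevated shared XIC, a lower (more intense)
#' normalized intensity rank and a cycle-number ratio near 1; negatives are
#' diffuse. Useful for exercising [pair_model()] at scale. The positive
#' prevalence default (0.1355) matches the label mix observed in real
#' training data.
#'
#' @param n Number of pairs.
#' @param seed Integer seed.
#' @param prevalence Positive fraction (default 0.1355).
#' @return Data.frame with the three attribute columns and a logical `label`.
#' @export
simulate_labeled_pairs <- function(n, seed, prevalence = 0.1355) {
  with_seed(seed, {
    y <- stats::runif(n) < prevalence
    npos <- sum(y); nneg <- n - npos
    d <- data.frame(norm_intensity_rank = numeric(n),
                    norm_cycle_number = numeric(n),
                    shared_xic = numeric(n), label = y)
    d$shared_xic[y] <- stats::rbeta(npos, 8, 2)
    d$shared_xic[!y] <- stats::rbeta(nneg, 1.5, 4)
    d$norm_intensity_rank[y] <- stats::rbeta(npos, 1.5, 3)
    d$norm_intensity_rank[!y] <- stats::runif(nneg)
    d$norm_cycle_number[y] <- stats::rlnorm(npos, log(0.9), 0.25)
    d$norm_cycle_number[!y] <- stats::rlnorm(nneg, log(0.45), 0.5)
    d
  })
}

#' Serialize a simulated run to a directory
#'
#' Writes the feature table (`features.tsv`), peak lists (`peaks.tsv`, when
#' present) and ground-truth tables (`truth_proteoforms.tsv`,
#' `truth_features.tsv`) in the package's plain-text formats.
#'
#' @param run A [simulate_run()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(run$scpfs, run$fragments, file.path(dir, "features.tsv"))
  if (!is.null(run$peak_lists))
    write_peak_lists(run$peak_lists, file.path(dir, "peaks.tsv"))
  utils::write.table(run$truth$proteoforms,
                     file.path(dir, "truth_proteoforms.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$truth$features, file.path(dir, "truth_features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @export
print.sim_run <- function(x, ...) {
  cat(sprintf(
    "Synthetic TD-DIA run: %d proteoforms, %d SCPFs, %d fragment features (%d decoys), %d cycles x %d windows\n",
    nrow(x$truth$proteoforms), nrow(x$scpfs), nrow(x$fragments),
    sum(x$truth$features$type == "decoy"), x$layout$num_cycles,
    n_windows(x$layout)))
  invisible(x)
}
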