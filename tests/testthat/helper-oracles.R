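# Independent reference implementations used to cross-check the package.
# These deliberately re-derive each quantity with a different method
# (fine-grid quadrature, plain loops, union-find) and never call the code
# path they verify.

# Fine-grid trapezoid quadrature of the shared area under two unit-area
# piecewise-linear elution profiles (same profile convention: support from
# first to last nonzero cycle, single-cycle spike -> +/- 0.5-cycle triangle).
oracle_shared_xic <- function(a, b, points_per_cycle = 2000) {
  prof <- function(x) {
    nz <- which(x > 0)
    i0 <- nz[1]; i1 <- nz[length(nz)]
    list(x = c(i0 - 0.5, i0:i1, i1 + 0.5),
         y = c(0, as.numeric(x[i0:i1]), 0))
  }
  pa <- prof(a); pb <- prof(b)
  lo <- min(pa$x[1], pb$x[1]); hi <- max(max(pa$x), max(pb$x))
  g <- seq(lo, hi, length.out = ceiling((hi - lo) * points_per_cycle) + 1)
  fa <- approx(pa$x, pa$y, g, yleft = 0, yright = 0)$y
  fb <- approx(pb$x, pb$y, g, yleft = 0, yright = 0)$y
  tz <- function(y) sum((y[-1] + y[-length(y)]) / 2 * diff(g))
  fa <- fa / tz(fa); fb <- fb / tz(fb)
  tz(pmin(fa, fb))
}

# Plain-loop argmax with earliest-tie rule.
oracle_apex <- function(x) {
  best <- 1
  for (i in seq_along(x)) if (x[i] > x[best]) best <- i
  best
}

# Brute-force round-1 gate: keep fragments whose apex distance satisfies the
# printed inequality, one at a time.
oracle_round1 <- function(scpf, fragments, t = 3) {
  cutoff <- min(t, floor(scpf$num_cycles / 2))
  keep <- vapply(seq_len(nrow(fragments)), function(i) {
    abs(oracle_apex(fragments$xic[[i]]) - oracle_apex(scpf$xic[[1]])) <= cutoff
  }, logical(1))
  fragments[keep, , drop = FALSE]
}

# Brute-force round-3 quota: enumerate both mass groups and pick top scorers.
oracle_round3 <- function(scored, quota_T, low_mass_bound = 1500,
                          low_quota = 25) {
  ord <- order(-scored$score, scored$mono_mass, scored$feature_id,
               method = "radix")
  s <- scored[ord, , drop = FALSE]
  low_ids <- s$feature_id[s$mono_mass < low_mass_bound]
  high_ids <- s$feature_id[s$mono_mass >= low_mass_bound]
  c(head(low_ids, min(low_quota, quota_T)),
    head(high_ids, max(0, quota_T - low_quota)))
}

# Independent reference of the whole greedy per-window cascade, written as
# one literal loop over the printed rules.
oracle_window_cascade <- function(scpfs, fragments, model,
                                  params = cascade_params()) {
  cf <- coef(model)
  ord <- order(-scpfs$total_intensity, scpfs$mono_mass, scpfs$feature_id,
               method = "radix")
  pool <- fragments
  out <- list()
  for (i in ord) {
    s <- scpfs[i, , drop = FALSE]
    L <- oracle_round1(s, pool, t = params$t)
    if (!nrow(L)) next
    rk <- order(-L$total_intensity, L$mono_mass, L$feature_id,
                method = "radix")
    rank <- integer(nrow(L)); rank[rk] <- seq_len(nrow(L))
    sx <- vapply(L$xic, function(x) oracle_shared_xic(x, s$xic[[1]]),
                 numeric(1))
    L$score <- 1 / (1 + exp(-(cf[["(Intercept)"]] +
      cf[["norm_intensity_rank"]] * rank / nrow(L) +
      cf[["norm_cycle_number"]] * L$num_cycles / s$num_cycles +
      cf[["shared_xic"]] * sx)))
    L <- L[order(-L$score, L$mono_mass, L$feature_id, method = "radix"), ]
    pass <- L$score > params$score_cutoff
    kept <- if (sum(pass) < params$min_keep) head(L, params$min_keep)
            else L[pass, , drop = FALSE]
    l <- max(2, round(s$mono_mass / params$avg_residue_mass))
    ids <- oracle_round3(kept, 2 * (l - 1), params$low_mass_bound,
                         params$low_quota)
    if (!length(ids)) next
    pool <- pool[!pool$feature_id %in% ids, , drop = FALSE]
    out[[s$feature_id]] <- sort(ids)
  }
  out
}

# Union-find clustering of identifications under the pairwise duplicate
# relation; survivor = the most intense member of each cluster.
oracle_dedup_survivors <- function(ids, ppm_tol = 10) {
  n <- nrow(ids)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    if (is_duplicate(ids$mono_mass[i], ids$mono_mass[j],
                     ids$protein_accession[i] == ids$protein_accession[j],
                     ppm_tol)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  surv <- tapply(seq_len(n), roots, function(m) m[which.max(ids$scpf_intensity[m])])
  sort(as.integer(surv))
}

# Gaussian elution trace sampled at cycle centres, truncated at 1% of peak.
gaussian_xic_test <- function(k, apex, sigma, peak) {
  x <- peak * exp(-((seq_len(k) - apex)^2) / (2 * sigma^2))
  x[x < 0.01 * peak] <- 0
  x
}

# Random sparse XIC with a contiguous positive block (plus optional interior
# zeros avoided so the profile is a valid feature trace).
random_xic <- function(k = 30) {
  len <- sample(1:8, 1)
  start <- sample(1:(k - len + 1), 1)
  x <- numeric(k)
  x[start:(start + len - 1)] <- runif(len, 0.1, 100)
  x
}

random_window_features <- function(n_frag = 50, k = 30) {
  fragment_table(
    feature_id = sprintf("f%03d", seq_len(n_frag)),
    mono_mass = runif(n_frag, 200, 12000),
    charge = sample(1:3, n_frag, replace = TRUE),
    xic = replicate(n_frag, random_xic(k), simplify = FALSE),
    window = 1L)
}

random_scpf <- function(k = 30, mass = NULL) {
  if (is.null(mass)) mass <- runif(1, 5000, 20000)
  scpf_table("s001", mass, 12L, list(random_xic(k)),
             list(cbind(mz = mass / 12 + 1.00728, intensity = 1)),
             window = 1L)
}

trained_toy_model <- function() {
  m <- pair_model(simulate_labeled_pairs(4000, seed = 99), seed = 99)
  m
}
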