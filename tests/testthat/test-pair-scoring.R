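test_that("shared XIC has the identity, disjoint and symmetry properties", {
  expect_equal(shared_xic(c(0, 1, 2, 1, 0), c(0, 1, 2, 1, 0)), 1,
               tolerance = 1e-12)
  expect_equal(shared_xic(c(0, 2, 4, 2, 0), c(0, 1, 2, 1, 0)), 1,
               tolerance = 1e-12)   # scaling is normalized away
  expect_equal(shared_xic(c(1, 1, 1, rep(0, 9)),
                          c(rep(0, 9), 1, 1, 1)), 0)
  set.seed(77)
  for (i in 1:30) {
    a <- random_xic(25); b <- random_xic(25)
    s <- shared_xic(a, b)
    expect_gte(s, 0); expect_lte(s, 1)
    expect_equal(s, shared_xic(b, a), tolerance = 1e-12)
  }
})

test_that("shared XIC matches fine-grid quadrature including edge cases", {
  # the hand-specified overlapping plateaus
  expect_equal(shared_xic(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0)),
               oracle_shared_xic(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0)),
               tolerance = 1e-6)
  # single-cycle spike: unit-area triangle over +/- 0.5 cycle
  expect_equal(shared_xic(c(0, 5, 0, 0), c(0, 5, 0, 0)), 1, tolerance = 1e-9)
  expect_equal(shared_xic(c(0, 5, 0, 0), c(0, 1, 2, 1)),
               oracle_shared_xic(c(0, 5, 0, 0), c(0, 1, 2, 1)),
               tolerance = 1e-6)
  set.seed(123)
  for (i in 1:60) {
    a <- random_xic(30); b <- random_xic(30)
    expect_equal(shared_xic(a, b), oracle_shared_xic(a, b), tolerance = 1e-6)
  }
})

test_that("attributes follow their definitions and ranks are a permutation", {
  k <- 30
  scpf <- scpf_table("s1", 10000, 10L, list(c(rep(0, 10), 1, 2, 5, 8, 5, 2, 1, 1, rep(0, 12))),
                     list(cbind(mz = 1001, intensity = 1)), window = 1L)
  frags <- random_window_features(50, k)
  at <- compute_attributes(scpf, frags)
  expect_equal(nrow(at), 50)
  # ranks are a permutation of 1..|L| / |L|
  expect_setequal(round(at$norm_intensity_rank * 50), 1:50)
  # the most intense fragment has rank 1/|L|
  expect_equal(at$norm_intensity_rank[which.max(frags$total_intensity)],
               1 / 50)
  expect_equal(at$norm_cycle_number, frags$num_cycles / scpf$num_cycles)
  # identical XIC gives shared overlap 1
  f2 <- frags
  f2$xic[[1]] <- scpf$xic[[1]]
  at2 <- compute_attributes(scpf, f2)
  expect_equal(at2$shared_xic[1], 1, tolerance = 1e-9)
})

test_that("pairs are labeled by b/y mass match within ppm tolerance", {
  catalog <- list(P1 = c(1000, 2000, 3000))
  map <- c(s1 = "P1", s2 = "P2")   # s2 has no catalog entry
  pairs <- data.frame(scpf_id = c("s1", "s1", "s1", "s2"),
                      fragment_id = c("f1", "f2", "f3", "f4"),
                      fragment_mass = c(2000, 2000 * (1 + 9e-6),
                                        2000 * (1 + 100e-6), 1000))
  expect_warning(out <- label_pairs(pairs, map, catalog, ppm_tol = 10),
                 "no catalog entry")
  expect_equal(nrow(out), 3)
  expect_equal(out$label, c(TRUE, TRUE, FALSE))
})

test_that("scoring equals the closed-form logistic and is monotone", {
  m <- structure(list(coefficients = c("(Intercept)" = 0.3,
                                       norm_intensity_rank = -2,
                                       norm_cycle_number = 0.7,
                                       shared_xic = 4)),
                 class = "pair_model")
  set.seed(9)
  at <- data.frame(norm_intensity_rank = runif(100),
                   norm_cycle_number = runif(100, 0, 2),
                   shared_xic = runif(100))
  p <- predict(m, at)
  expect_equal(p, 1 / (1 + exp(-(0.3 - 2 * at$norm_intensity_rank +
                                   0.7 * at$norm_cycle_number +
                                   4 * at$shared_xic))), tolerance = 1e-12)
  # zero model scores 0.5 everywhere
  m0 <- m; m0$coefficients[] <- 0
  expect_equal(predict(m0, at), rep(0.5, 100))
  # monotone in shared_xic at positive weight
  grid <- data.frame(norm_intensity_rank = 0.5, norm_cycle_number = 1,
                     shared_xic = seq(0, 1, 0.1))
  expect_true(all(diff(predict(m, grid)) > 0))
  expect_equal(score_pair(m, grid[1, ]), predict(m, grid)[1])
})

test_that("model training is seed-reproducible and sane on edge cases", {
  d <- simulate_labeled_pairs(2000, seed = 4)
  m1 <- pair_model(d, seed = 10)
  m2 <- pair_model(d, seed = 10)
  expect_identical(coef(m1), coef(m2))
  expect_identical(m1$metrics, m2$metrics)
  m3 <- pair_model(d, seed = 11)
  expect_false(identical(coef(m1), coef(m3)))

  # single class errors
  d1 <- d[d$label, ]
  expect_error(pair_model(d1), "both positive and negative")

  # perfectly separable attributes reach validation AUC 1
  sep <- data.frame(norm_intensity_rank = runif(400),
                    norm_cycle_number = 1,
                    shared_xic = c(runif(200, 0.8, 1), runif(200, 0, 0.2)),
                    label = rep(c(TRUE, FALSE), each = 200))
  # glm warns about perfect separation here, which is the point of the case
  m_sep <- suppressWarnings(pair_model(sep, seed = 2))
  expect_equal(m_sep$metrics$auc, 1)

  # labels independent of attributes: AUC near 0.5
  set.seed(31)
  null <- d
  null$label <- sample(rep(c(TRUE, FALSE), length.out = nrow(d)))
  expect_lt(abs(pair_model(null, seed = 3)$metrics$auc - 0.5), 0.08)
})

test_that("pair models survive JSON round trips", {
  m <- pair_model(simulate_labeled_pairs(1500, seed = 6), seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_pair_model(m, path)
  back <- read_pair_model(path)
  expect_equal(coef(back), coef(m), tolerance = 1e-12)
  at <- data.frame(norm_intensity_rank = 0.1, norm_cycle_number = 1,
                   shared_xic = 0.9)
  expect_equal(predict(back, at), predict(m, at), tolerance = 1e-12)
})
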