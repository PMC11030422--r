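#' Shared XIC between two features
#'
#' Chromatographic co-elution score used by the pair model. Each per-cycle
#' XIC is treated as a piecewise-linear elution profile through the points
#' `(cycle, intensity)` over its support (first to last nonzero cycle),
#' ramped to zero over half a cycle beyond each edge so the profile is
#' continuous; a single-cycle feature thus becomes a triangle over
#' +/- 0.5 cycle. Both profiles are linearly interpolated onto a
#' common uniform grid (100 points per cycle unit) spanning the union of the
#' supports and scaled to unit area; the shared XIC is the area under their
#' pointwise minimum. Within each grid cell the minimum of the two linear
#' pieces is integrated exactly (the crossing point is solved for), so the
#' value matches fine-grid quadrature to well below 1e-6.
#'
#' @param a,b Numeric per-cycle intensity vectors with at least one positive
#'   entry each.
#' @return Overlap fraction in `[0, 1]`; 1 exactly when the normalized
#'   profiles coincide, 0 when the supports are disjoint. Symmetric in its
#'   arguments.
#' @examples
#' shared_xic(c(0, 1, 2, 1, 0), c(0, 1, 2, 1, 0))  # 1
#' shared_xic(c(1, 1, 0, 0), c(0, 0, 1, 1))        # 0
#' @export
shared_xic <- function(a, b) {
  pa <- xic_profile(a)
  pb <- xic_profile(b)
  lo <- min(pa$x[1], pb$x[1])
  hi <- max(pa$x[length(pa$x)], pb$x[length(pb$x)])
  if (hi <= lo) return(0)
  grid <- seq(lo, hi, by = 0.01)
  if (grid[length(grid)] < hi) grid <- c(grid, hi)
  fa <- profile_at(pa, grid)
  fb <- profile_at(pb, grid)
  fa <- fa / trapz(grid, fa)
  fb <- fb / trapz(grid, fb)
  n <- length(grid)
  h <- diff(grid)
  f1 <- fa[-n]; f2 <- fa[-1]; g1 <- fb[-n]; g2 <- fb[-1]
  d1 <- f1 - g1; d2 <- f2 - g2
  m1 <- pmin(f1, g1); m2 <- pmin(f2, g2)
  area <- (m1 + m2) / 2 * h
  cross <- d1 * d2 < 0
  if (any(cross)) {
    tau <- d1[cross] / (d1[cross] - d2[cross])
    v <- f1[cross] + (f2[cross] - f1[cross]) * tau
    area[cross] <- ((m1[cross] + v) / 2 * tau +
                    (v + m2[cross]) / 2 * (1 - tau)) * h[cross]
  }
  min(max(sum(area), 0), 1)
}

# Piecewise-linear elution profile of an XIC over its support, ramped to
# zero over half a cycle at each edge so the profile is continuous (a
# single-cycle spike becomes a unit-base triangle).
xic_profile <- function(xic) {
  nz <- which(xic > 0)
  if (!length(nz)) stopf("empty feature: all-zero XIC")
  i0 <- nz[1]; i1 <- nz[length(nz)]
  list(x = c(i0 - 0.5, i0:i1, i1 + 0.5),
       y = c(0, as.numeric(xic[i0:i1]), 0))
}

profile_at <- function(p, xout) {
  y <- stats::approx(p$x, p$y, xout = xout, yleft = 0, yright = 0)$y
  y
}

trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

#' Match attributes for the SCPF / fragment pairs of a survivor list
#'
#' Computes, for every fragment feature in the round-1 survivor list `L` of
#' one SCPF, the three attributes the logistic pair model scores:
#' \describe{
#'   \item{norm_intensity_rank}{intensity rank of the fragment within `L`
#'     (descending; ties broken by mass ascending, then id) divided by `|L|`
#'     — in `(0, 1]`, small for intense fragments.}
#'   \item{norm_cycle_number}{fragment's observed cycle count divided by the
#'     SCPF's observed cycle count `c`; may exceed 1.}
#'   \item{shared_xic}{co-elution overlap of the two unit-area elution
#'     profiles, see [shared_xic()].}
#' }
#'
#' @param scpf One-row SCPF table.
#' @param L Fragment table, the round-1 survivors for this SCPF.
#' @return Data.frame with `scpf_id`, `fragment_id` and the three attribute
#'   columns, one row per fragment in `L` (same order).
#' @export
compute_attributes <- function(scpf, L) {
  stopifnot(nrow(scpf) == 1L)
  if (!nrow(L))
    return(data.frame(scpf_id = character(), fragment_id = character(),
                      norm_intensity_rank = numeric(),
                      norm_cycle_number = numeric(), shared_xic = numeric()))
  ord <- feature_order(L$total_intensity, L$mono_mass, L$feature_id)
  rank <- integer(nrow(L)); rank[ord] <- seq_len(nrow(L))
  sx <- vapply(L$xic, shared_xic, numeric(1), b = scpf$xic[[1]])
  data.frame(
    scpf_id = scpf$feature_id, fragment_id = L$feature_id,
    norm_intensity_rank = rank / nrow(L),
    norm_cycle_number = L$num_cycles / scpf$num_cycles,
    shared_xic = sx, stringsAsFactors = FALSE)
}

#' Enumerate candidate SCPF / fragment pairs for model training
#'
#' Pairs every window-assigned SCPF with the fragment features of its window
#' that pass the round-1 apex-distance gate (see [round1_filter()]), and
#' attaches the three match attributes. A fragment feature may appear in
#' pairs with several SCPFs.
#'
#' @param scpfs SCPF table with windows assigned.
#' @param fragments Fragment table for the same run.
#' @param t Apex-distance parameter of the round-1 gate (default 3 cycles).
#' @return Data.frame of pairs with attribute columns.
#' @export
build_pairs <- function(scpfs, fragments, t = 3) {
  out <- list()
  for (i in seq_len(nrow(scpfs))) {
    s <- scpfs[i, ]
    if (is.na(s$window)) next
    pool <- fragments[fragments$window == s$window, , drop = FALSE]
    L <- round1_filter(s, pool, t = t)
    if (nrow(L)) {
      at <- compute_attributes(s, L)
      at$fragment_mass <- L$mono_mass
      out[[length(out) + 1L]] <- at
    }
  }
  if (!length(out))
    return(data.frame(scpf_id = character(), fragment_id = character(),
                      norm_intensity_rank = numeric(),
                      norm_cycle_number = numeric(), shared_xic = numeric(),
                      fragment_mass = numeric()))
  do.call(rbind, out)
}

#' Label SCPF / fragment pairs against identified proteoforms
#'
#' A pair is labeled positive when the fragment's neutral monoisotopic mass
#' matches a b- or y-ion mass of the proteoform identified for the SCPF
#' within `ppm_tol`, negative otherwise. Pairs whose SCPF has no catalog
#' entry are dropped with a warning.
#'
#' @param pairs Pair table from [build_pairs()] with a `fragment_mass`
#'   column, or any data.frame with `scpf_id` and `fragment_mass`.
#' @param scpf_proteoform Named character vector mapping `scpf_id` to a
#'   proteoform id.
#' @param catalog Named list mapping proteoform id to its numeric vector of
#'   theoretical b/y neutral masses (see [by_masses()]).
#' @param ppm_tol Match tolerance in ppm (default 10), applied relative to
#'   the theoretical mass.
#' @return `pairs` with a logical `label` column appended.
#' @export
label_pairs <- function(pairs, scpf_proteoform, catalog, ppm_tol = 10) {
  known <- pairs$scpf_id %in% names(scpf_proteoform) &
    scpf_proteoform[pairs$scpf_id] %in% names(catalog)
  if (any(!known)) {
    warnf("dropping %d pairs whose SCPF has no catalog entry", sum(!known))
    pairs <- pairs[known, , drop = FALSE]
  }
  pairs$label <- vapply(seq_len(nrow(pairs)), function(i) {
    theo <- catalog[[scpf_proteoform[[pairs$scpf_id[i]]]]]
    any(abs(pairs$fragment_mass[i] - theo) <= ppm_tol * 1e-6 * theo)
  }, logical(1))
  pairs
}

#' Fit the logistic SCPF / fragment pair-scoring model
#'
#' Fits a plain maximum-likelihood logistic regression of the pair label on
#' the three match attributes (no standardization, no regularization — the
#' attributes are already normalized ratios). The labeled pairs are split
#' randomly into training and validation sets and balanced accuracy (at a
#' 0.5 threshold) and ROC-AUC are reported on the held-out part. The fit is
#' reproducible bit-for-bit given the data, `split_ratio` and `seed`.
#'
#' @param pairs Data.frame with columns `norm_intensity_rank`,
#'   `norm_cycle_number`, `shared_xic` and a logical (or `"positive"` /
#'   `"negative"`) `label` column.
#' @param split_ratio Fraction of pairs used for training (default 0.7).
#' @param seed Integer seed for the random split.
#' @return Object of class `pair_model`: coefficients (intercept + 3
#'   weights), validation `metrics` (`auc`, `balanced_accuracy`, counts) and
#'   the split metadata. Supports `print`, `summary`, `coef` and `predict`.
#' @export
pair_model <- function(pairs, split_ratio = 0.7, seed = 1) {
  attrs <- c("norm_intensity_rank", "norm_cycle_number", "shared_xic")
  stopifnot(all(c(attrs, "label") %in% names(pairs)))
  y <- if (is.logical(pairs$label)) pairs$label else pairs$label == "positive"
  if (length(unique(y)) < 2L)
    stopf("training needs both positive and negative pairs")
  n <- nrow(pairs)
  idx <- with_seed(seed, sample.int(n, floor(split_ratio * n)))
  dat <- data.frame(pairs[attrs], y = y)
  fit <- stats::glm(y ~ norm_intensity_rank + norm_cycle_number + shared_xic,
                    family = stats::binomial(), data = dat[idx, ])
  coefs <- stats::coef(fit)
  coefs[is.na(coefs)] <- 0   # aliased (constant/collinear) terms drop out
  valid <- dat[-idx, , drop = FALSE]
  metrics <- list(n_train = length(idx), n_valid = nrow(valid),
                  auc = NA_real_, balanced_accuracy = NA_real_)
  if (nrow(valid) && length(unique(valid$y)) == 2L) {
    p <- logistic_score(coefs, valid[attrs])
    metrics$auc <- as.numeric(pROC::auc(
      pROC::roc(valid$y, p, quiet = TRUE, direction = "<", levels = c(FALSE, TRUE))))
    pred <- p > 0.5
    sens <- mean(pred[valid$y])
    spec <- mean(!pred[!valid$y])
    metrics$balanced_accuracy <- (sens + spec) / 2
  }
  structure(
    list(coefficients = coefs, metrics = metrics,
         training = list(split_ratio = split_ratio, seed = seed,
                         n_pairs = n, n_positive = sum(y))),
    class = "pair_model")
}

logistic_score <- function(coefs, attrs) {
  x <- coefs[1] +
    coefs["norm_intensity_rank"] * attrs$norm_intensity_rank +
    coefs["norm_cycle_number"] * attrs$norm_cycle_number +
    coefs["shared_xic"] * attrs$shared_xic
  as.numeric(stats::plogis(x))
}

#' @export
coef.pair_model <- function(object, ...) object$coefficients

#' Score pairs with a fitted pair model
#'
#' @param object A [pair_model()].
#' @param newdata Data.frame with the three attribute columns.
#' @param ... Unused.
#' @return Match probabilities in `(0, 1)`, the logistic function of the
#'   linear predictor.
#' @export
predict.pair_model <- function(object, newdata, ...) {
  logistic_score(object$coefficients, newdata)
}

#' @rdname predict.pair_model
#' @param model A [pair_model()].
#' @param attributes Data.frame (or one-row list) of attribute values.
#' @export
score_pair <- function(model, attributes) {
  predict.pair_model(model, as.data.frame(attributes))
}

#' @export
print.pair_model <- function(x, ...) {
  cat("Logistic SCPF/fragment pair-scoring model\n")
  cat("Coefficients:\n")
  print(round(x$coefficients, 4))
  cat(sprintf("Validation (%d pairs): AUC = %.4f, balanced accuracy = %.4f\n",
              x$metrics$n_valid, x$metrics$auc, x$metrics$balanced_accuracy))
  invisible(x)
}

#' @export
summary.pair_model <- function(object, ...) {
  cat(sprintf(
    "Trained on %d of %d labeled pairs (%.0f%% split, seed %d), %d positive\n",
    object$metrics$n_train, object$training$n_pairs,
    100 * object$training$split_ratio, object$training$seed,
    object$training$n_positive))
  print(object)
  invisible(object)
}

#' Serialize / restore a pair model
#'
#' The model travels as a small JSON file holding the coefficients and
#' training metadata.
#'
#' @param model A [pair_model()].
#' @param path JSON file path.
#' @export
write_pair_model <- function(model, path) {
  jsonlite::write_json(
    list(coefficients = as.list(model$coefficients),
         metrics = model$metrics, training = model$training),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pair_model
#' @export
read_pair_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(coefficients = unlist(obj$coefficients),
                 metrics = obj$metrics, training = obj$training),
            class = "pair_model")
}
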