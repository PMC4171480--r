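#' Image quality features: inverse coefficient of variation
#'
#' Mean image intensity divided by (population) standard deviation.
#' Scale-invariant: multiplying all intensities by c > 0 leaves it
#' unchanged.
#'
#' @param x numeric matrix.
#' @return scalar.
#' @export
qc_inverse_cv <- function(x) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) stopf("qc_inverse_cv: constant image (zero variance)")
  m / s
}

#' Image quality features: focus score
#'
#' Population variance of intensity divided by the mean. Scales
#' linearly with intensity: under `c * I` the score is `c` times larger.
#' Defocus blur strictly lowers it (variance shrinks, mean preserved).
#'
#' @param x numeric matrix with positive mean.
#' @return scalar (0 for a constant image).
#' @export
qc_focus_score <- function(x) {
  m <- mean(x)
  if (m == 0) stopf("qc_focus_score: zero-mean image")
  mean((x - m)^2) / m
}

#' Image quality features: GLCM correlation
#'
#' Intensities are quantised into eight equal-width levels over the
#' observed range; the grey-level co-occurrence matrix is accumulated
#' symmetrically over the 1-pixel horizontal and vertical offsets, and
#' the Haralick correlation statistic (in \[-1, 1\]) returned.
#'
#' @param x numeric matrix, non-constant.
#' @param levels number of quantisation levels (default 8).
#' @return scalar in \[-1, 1\].
#' @export
qc_glcm_correlation <- function(x, levels = 8) {
  rng <- range(x)
  if (rng[1] == rng[2]) stopf("qc_glcm_correlation: constant image")
  q <- pmin(floor((x - rng[1]) / (rng[2] - rng[1]) * levels) + 1L, levels)
  if (length(unique(as.integer(q))) < 2)
    stopf("qc_glcm_correlation: single level after quantisation")
  acc <- function(a, b) tabulate((a - 1L) * levels + b, nbins = levels * levels)
  h1 <- q[, -ncol(q), drop = FALSE]; h2 <- q[, -1, drop = FALSE]
  v1 <- q[-nrow(q), , drop = FALSE]; v2 <- q[-1, , drop = FALSE]
  cnt <- acc(h1, h2) + acc(h2, h1) + acc(v1, v2) + acc(v2, v1)
  p <- matrix(cnt / sum(cnt), levels, levels)
  i <- seq_len(levels)
  pi_ <- rowSums(p); pj <- colSums(p)
  mi <- sum(i * pi_); mj <- sum(i * pj)
  si <- sqrt(sum((i - mi)^2 * pi_)); sj <- sqrt(sum((i - mj)^2 * pj))
  if (si == 0 || sj == 0) stopf("qc_glcm_correlation: degenerate marginal")
  (sum(outer(i, i) * p) - mi * mj) / (si * sj)
}

#' Image quality features: power log-log slope (PLLS)
#'
#' Computes the 2-D FFT power spectrum; every non-DC coefficient
#' contributes a point (log10 radial frequency, log10 squared
#' magnitude), ignoring orientation. Returns the least-squares slope
#' over the full frequency range, or the slopes within eight equal-width
#' log-frequency bands between the lowest non-DC radial frequency and
#' the radial Nyquist.
#'
#' @param x numeric matrix, side >= 16.
#' @param bands `NULL` for the whole-range slope, or `8` for per-band
#'   slopes.
#' @return scalar, or named vector of 8 slopes.
#' @export
qc_plls <- function(x, bands = NULL) {
  n <- nrow(x); m <- ncol(x)
  if (min(n, m) < 16) stopf("qc_plls: image side must be >= 16")
  if (all(x == 0)) stopf("qc_plls: all-zero image")
  pw <- Mod(fft(x))^2
  fr <- (seq_len(n) - 1); fr <- ifelse(fr > n / 2, fr - n, fr) / n
  fc <- (seq_len(m) - 1); fc <- ifelse(fc > m / 2, fc - m, fc) / m
  r <- sqrt(outer(fr^2, fc^2, `+`))
  keep <- r > 0 & pw > max(pw) * 1e-12
  lr <- log10(r[keep]); lp <- log10(pw[keep])
  fit_slope <- function(lx, ly) {
    if (length(unique(lx)) < 2) return(NA_real_)
    vx <- lx - mean(lx)
    sum(vx * ly) / sum(vx^2)
  }
  if (is.null(bands)) {
    s <- fit_slope(lr, lp)
    if (is.na(s)) stopf("qc_plls: fewer than 2 distinct populated frequencies")
    return(s)
  }
  stopifnot(bands == 8)
  edges <- seq(min(lr), max(lr), length.out = bands + 1)
  idx <- pmin(pmax(findInterval(lr, edges, rightmost.closed = TRUE), 1L), bands)
  out <- vapply(seq_len(bands),
                function(b) fit_slope(lr[idx == b], lp[idx == b]), 0)
  names(out) <- paste0("band", seq_len(bands))
  out
}

#' The twelve-feature image quality vector
#'
#' x1 inverse coefficient of variation, x2 focus score, x3 GLCM
#' correlation, x4 whole-range power log-log slope, x5-x12 the eight
#' band-limited power log-log slopes.
#'
#' @param x numeric matrix (DAPI channel).
#' @return named numeric vector of length 12.
#' @export
qc_features <- function(x) {
  wrap <- function(nm, expr) tryCatch(expr, error = function(e)
    stopf("qc_features [%s]: %s", nm, conditionMessage(e)))
  out <- c(x1 = wrap("x1", qc_inverse_cv(x)),
           x2 = wrap("x2", qc_focus_score(x)),
           x3 = wrap("x3", qc_glcm_correlation(x)),
           x4 = wrap("x4", qc_plls(x)))
  b <- wrap("x5-x12", qc_plls(x, bands = 8))
  names(b) <- paste0("x", 5:12)
  c(out, b)
}

#' Train a logistic quality-control classifier
#'
#' Plain maximum-likelihood logistic regression on standardised
#' features, distinguishing poor- from good-quality images, using
#' either the first four features (x1-x4) or all twelve (x1-x12).
#'
#' @param features matrix or data.frame of QC feature vectors (columns
#'   named x1..x12), one row per image.
#' @param labels factor or character with levels `good` / `poor`.
#' @param subset `"first4"` or `"all12"`.
#' @return list of class `qc_classifier` (coefficients, standardisation
#'   constants, feature subset).
#' @export
qc_train <- function(features, labels, subset = c("all12", "first4")) {
  subset <- match.arg(subset)
  features <- as.matrix(features)
  labels <- as.character(labels)
  if (!all(labels %in% c("good", "poor"))) stopf("labels must be 'good'/'poor'")
  if (length(unique(labels)) < 2) stopf("qc_train: single-class input")
  cols <- if (subset == "first4") paste0("x", 1:4) else paste0("x", 1:12)
  if (!all(cols %in% colnames(features))) stopf("missing feature columns")
  xm <- features[, cols, drop = FALSE]
  ctr <- colMeans(xm); scl <- apply(xm, 2, sd)
  scl[scl == 0] <- 1
  xs <- scale(xm, center = ctr, scale = scl)
  y <- as.integer(labels == "poor")
  df <- data.frame(y = y, xs)
  fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
  structure(list(coef = coef(fit), center = ctr, scale = scl,
                 subset = subset, columns = cols),
            class = "qc_classifier")
}

#' Predict poor-quality probability for new images
#' @param object a `qc_classifier`.
#' @param features feature matrix/data.frame with the training columns.
#' @param ... unused.
#' @return numeric vector of P(poor).
#' @export
predict.qc_classifier <- function(object, features, ...) {
  xm <- as.matrix(features)[, object$columns, drop = FALSE]
  xs <- scale(xm, center = object$center, scale = object$scale)
  eta <- object$coef[1] + drop(xs %*% object$coef[-1])
  1 / (1 + exp(-eta))
}

#' ROC curve and trapezoidal AUC
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param positive logical vector, TRUE for the positive class.
#' @return list: `roc` data.frame (threshold, fpr, tpr), `auc`.
#' @export
roc_auc <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stopf("roc_auc: need both classes")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; p <- positive[o]
  # group tied scores so the ROC steps diagonally across ties
  grp <- cumsum(c(TRUE, diff(s) != 0))
  tp <- as.numeric(tapply(p, grp, sum))
  fp <- as.numeric(tapply(!p, grp, sum))
  ctp <- c(0, cumsum(tp)); cfp <- c(0, cumsum(fp))
  tpr <- ctp / n1; fpr <- cfp / n0
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(roc = data.frame(threshold = c(Inf, s[!duplicated(grp)]),
                        fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Leave-one-out cross-validated evaluation of the QC classifier
#'
#' Each image is scored by a classifier trained on all the others; the
#' held-out scores are summarised as an ROC curve with trapezoidal AUC
#' (positive class: poor quality).
#'
#' @inheritParams qc_train
#' @return list: `scores` (held-out P(poor)), `roc`, `auc`.
#' @export
qc_loocv <- function(features, labels, subset = c("all12", "first4")) {
  subset <- match.arg(subset)
  features <- as.matrix(features)
  labels <- as.character(labels)
  n <- nrow(features)
  if (n < 10) stopf("qc_loocv: need at least 10 images")
  if (length(unique(labels)) < 2) stopf("qc_loocv: single-class input")
  scores <- vapply(seq_len(n), function(i) {
    fit <- qc_train(features[-i, , drop = FALSE], labels[-i], subset)
    predict(fit, features[i, , drop = FALSE])
  }, 0)
  ra <- roc_auc(scores, labels == "poor")
  list(scores = scores, roc = ra$roc, auc = ra$auc)
}
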