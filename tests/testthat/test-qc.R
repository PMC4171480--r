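test_that("inverse CV and focus score match direct arithmetic and scaling laws", {
  x <- matrix(c(2, 2, 4, 4), 2, 2)
  expect_equal(qc_inverse_cv(x), 3)          # mean 3 / population SD 1
  expect_equal(qc_focus_score(x), 1 / 3)     # population variance 1 / mean 3
  expect_error(qc_inverse_cv(matrix(5, 2, 2)), "constant")
  expect_equal(qc_focus_score(matrix(7, 2, 2)), 0)
  expect_error(qc_focus_score(matrix(0, 2, 2)), "zero-mean")
  set.seed(1)
  y <- matrix(runif(64, 1, 9), 8, 8)
  expect_equal(qc_inverse_cv(3.7 * y), qc_inverse_cv(y))
  expect_equal(qc_focus_score(2.5 * y), 2.5 * qc_focus_score(y))
})

test_that("GLCM correlation hits its analytic anchors", {
  chk <- outer(1:32, 1:32, function(i, j) (i + j) %% 2)  # 1-px checkerboard
  expect_equal(qc_glcm_correlation(chk), -1)
  grad <- outer(rep(1, 64), seq(0, 100, length.out = 64))
  expect_gte(qc_glcm_correlation(grad), 0.9)
  vals <- sapply(1:5, function(s) {
    set.seed(s)
    qc_glcm_correlation(matrix(runif(256^2), 256))
  })
  expect_lt(abs(mean(vals)), 0.05)
  expect_error(qc_glcm_correlation(matrix(3, 4, 4)), "constant")
})

test_that("power log-log slope is flat for white noise and drops under blur", {
  slopes <- sapply(1:10, function(s) {
    set.seed(s)
    qc_plls(matrix(rnorm(128^2, 100, 10), 128))
  })
  expect_lte(abs(mean(slopes)), 0.1)
  set.seed(4)
  x <- matrix(rnorm(128^2, 100, 10), 128)
  xb <- synth_degrade(mc_image(list(a = x - min(x))), blur_sigma = 3)$channels$a
  expect_lt(qc_plls(xb), qc_plls(x - min(x)))
  b <- qc_plls(x, bands = 8)
  expect_length(b, 8)
  expect_error(qc_plls(matrix(0, 64, 64)), "all-zero")
  sinus <- matrix(sin(2 * pi * 8 * (1:64) / 64), 64, 64)
  expect_error(qc_plls(sinus), "distinct populated")
})

test_that("the quality feature vector has twelve deterministic entries that move as expected", {
  res <- clean_image()
  x <- res$image$channels$DAPI
  f1 <- qc_features(x)
  expect_length(f1, 12)
  expect_named(f1, paste0("x", 1:12))
  expect_identical(f1, qc_features(x))
  deg <- synth_degrade(res$image, blur_sigma = 4, noise_sigma = 0)$channels$DAPI
  f2 <- qc_features(deg)
  expect_lt(f2["x2"], f1["x2"])   # blur lowers the focus score
  expect_lt(f2["x4"], f1["x4"])   # and steepens the power log-log slope
})

test_that("a separable training set is classified perfectly; errors on one class", {
  set.seed(7)
  n <- 30
  feats <- matrix(rnorm(2 * n * 12), 2 * n, 12,
                  dimnames = list(NULL, paste0("x", 1:12)))
  feats[seq_len(n), 1] <- feats[seq_len(n), 1] + 10
  labels <- rep(c("good", "poor"), each = n)
  clf <- qc_train(feats, labels, subset = "first4")
  pred <- predict(clf, feats) > 0.5
  expect_equal(mean((pred == TRUE) == (labels == "poor")), 1)
  expect_error(qc_train(feats, rep("good", 2 * n)), "single-class")
})

test_that("trapezoidal AUC equals the Mann-Whitney pairwise statistic", {
  brute_auc <- function(s, pos) {
    num <- 0
    for (i in which(pos)) for (j in which(!pos))
      num <- num + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
    num / (sum(pos) * sum(!pos))
  }
  set.seed(3)
  for (k in 1:5) {
    s <- sample(round(rnorm(40), 1))   # rounded: guarantees ties
    pos <- runif(40) < 0.4
    if (!any(pos) || all(pos)) next
    ra <- roc_auc(s, pos)
    expect_equal(ra$auc, brute_auc(s, pos))
    expect_equal(ra$auc + roc_auc(-s, pos)$auc, 1)   # ROC symmetry
  }
})

test_that("LOOCV separates sharp from blurred synthetic fields but not permuted labels", {
  imgs <- fixture("qc_images", function() {
    feats <- matrix(NA_real_, 40, 12, dimnames = list(NULL, paste0("x", 1:12)))
    labels <- character(40)
    for (i in 1:40) {
      blur <- i > 20
      spec <- synth_image_spec(image_size = 80, n_cells = 4,
                               nucleus_radius_range = c(4, 6),
                               cyto_thickness_range = c(2, 3),
                               noise_sigma = 4,
                               blur_sigma = if (blur) 4 else 0,
                               seed = 300 + i)
      feats[i, ] <- qc_features(synth_image(spec)$image$channels$DAPI)
      labels[i] <- if (blur) "poor" else "good"
    }
    list(features = feats, labels = labels)
  })
  cv <- qc_loocv(imgs$features, imgs$labels, subset = "first4")
  expect_gte(cv$auc, 0.9)
  perm_auc <- sapply(1:3, function(s) {
    set.seed(s)
    qc_loocv(imgs$features, sample(imgs$labels), subset = "first4")$auc
  })
  expect_gt(mean(perm_auc), 0.35)
  expect_lt(mean(perm_auc), 0.65)
  expect_equal(roc_auc(cv$scores, imgs$labels == "poor")$auc, cv$auc)
})
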