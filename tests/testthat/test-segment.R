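test_that("preprocessing is identity at zero parameters and removes salt noise", {
  img <- mc_image(list(DAPI = matrix(10, 32, 32)))
  expect_identical(img_preprocess(img, 0, 0)$channels, img$channels)
  salt <- matrix(10, 32, 32)
  salt[16, 16] <- 1000
  out <- img_preprocess(mc_image(list(DAPI = salt)), median_radius = 1,
                        gaussian_sigma = 0)
  # the median filter quantises to 16-bit precision internally
  expect_equal(out$channels$DAPI[16, 16], 10, tolerance = 1e-3)
})

test_that("Gaussian smoothing preserves total intensity of an interior blob", {
  x <- matrix(0, 64, 64)
  x[28:36, 28:36] <- 100
  out <- img_preprocess(mc_image(list(DAPI = x)), median_radius = 0,
                        gaussian_sigma = 2)
  expect_lt(abs(sum(out$channels$DAPI) - sum(x)) / sum(x), 1e-3)
})

test_that("otsu threshold separates bimodal data and matches exhaustive maximiser", {
  x <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  t1 <- otsu_threshold(x)
  expect_gt(t1, 10); expect_lt(t1, 200)
  expect_identical(as.integer(table(x > t1)), c(50L, 50L))

  # brute force over gap midpoints of the weighted histogram
  brute_otsu <- function(vals, w) {
    n <- sum(w)
    cands <- (vals[-length(vals)] + vals[-1]) / 2
    bcv <- sapply(cands, function(t) {
      w0 <- sum(w[vals <= t]) / n; w1 <- 1 - w0
      mu0 <- sum(w[vals <= t] * vals[vals <= t]) / sum(w[vals <= t])
      mu1 <- sum(w[vals > t] * vals[vals > t]) / sum(w[vals > t])
      w0 * w1 * (mu0 - mu1)^2
    })
    cands[which.max(bcv)]
  }
  y <- c(rep(0, 50), rep(100, 25), rep(200, 25))
  expect_equal(otsu_threshold(y), brute_otsu(c(0, 100, 200), c(50, 25, 25)))

  z <- matrix(c(5, 6, 5, 6), 2, 2)
  tz <- otsu_threshold(z)
  expect_gt(tz, 5); expect_lt(tz, 6)
  expect_error(otsu_threshold(matrix(7, 3, 3)), "constant")
})

test_that("nuclei of a clean synthetic image are recovered one-to-one with high overlap", {
  res <- clean_image()
  img <- img_preprocess(res$image, median_radius = 1, gaussian_sigma = 1)
  nuc <- segment_nuclei(img[["DAPI"]])
  truth <- res$truth$nuclear_mask
  expect_equal(max(nuc), max(truth))
  cmp <- compare_segmentations(nuc, truth)
  expect_true(all(cmp$matches$jaccard >= 0.9))
})

test_that("blank images give empty label maps", {
  expect_message(out <- segment_nuclei(matrix(5, 64, 64)), "constant")
  expect_true(all(out == 0))
})

test_that("watershed splits a two-nucleus clump", {
  x <- matrix(5, 128, 128)
  paint <- function(m, cx, cy, r, v) {
    for (i in (cx - r):(cx + r)) for (j in (cy - r):(cy + r))
      if ((i - cx)^2 + (j - cy)^2 <= r^2) m[i, j] <- v
    m
  }
  x <- paint(x, 52, 64, 12, 180)
  x <- paint(x, 72, 64, 12, 180)   # centres 20 px apart: ~30% overlap
  lab <- segment_nuclei(x, levelset_iterations = 10)
  expect_equal(max(lab), 2)
})

test_that("cytoplasm recovers the annulus of an isolated cell", {
  spec <- synth_image_spec(image_size = 128, n_cells = 1,
                           nucleus_radius_range = c(9, 9),
                           cyto_thickness_range = c(5, 5),
                           overlap_fraction = 0, subpop_fraction = 0,
                           noise_sigma = 0, seed = 2)
  res <- synth_image(spec)
  nuc <- segment_nuclei(res$image$channels$DAPI, clear_border = FALSE)
  cyt <- segment_cytoplasm(res$image$channels$CD99, nuc)
  expect_gte(jaccard(cyt == 1, res$truth$cytoplasm_mask == 1), 0.8)
})

test_that("uniform marker splits two equal cells at the perpendicular bisector", {
  cd99 <- matrix(0, 128, 128)
  cd99[abs(row(cd99) - 64) + 0 < 40 & abs(col(cd99) - 64) < 30] <- 100
  nuc <- matrix(0L, 128, 128)
  nuc[(row(nuc) - 44)^2 + (col(nuc) - 64)^2 <= 25] <- 1L
  nuc[(row(nuc) - 84)^2 + (col(nuc) - 64)^2 <= 25] <- 2L
  cyt <- segment_cytoplasm(cd99, nuc)
  r1 <- max(row(cyt)[cyt == 1])   # lowest row reached by cell 1
  r2 <- min(row(cyt)[cyt == 2])   # highest row reached by cell 2
  expect_lte(r1, 65); expect_gte(r2, 63)  # bisector at row 64 within 1 px
})

test_that("a zero marker channel leaves every cell with empty, flagged cytoplasm", {
  nuc <- matrix(0L, 64, 64)
  nuc[10:14, 10:14] <- 1L; nuc[40:44, 40:44] <- 2L
  cyt <- segment_cytoplasm(matrix(0, 64, 64), nuc)
  expect_true(all(cyt == 0))
  expect_equal(attr(cyt, "flagged"), 1:2)
  expect_error(segment_cytoplasm(matrix(0, 32, 32), nuc), "dimensions")
})

test_that("hausdorff distance matches the definition, units and brute force", {
  a <- cbind(c(0, 1, 2), c(0, 1, 2))
  expect_equal(hausdorff_distance(a, a), 0)
  expect_equal(hausdorff_distance(cbind(0, 0), cbind(3, 4)), 5)
  expect_equal(hausdorff_distance(cbind(0, 0), cbind(3, 4), pixel_size = 0.5), 2.5)
  expect_error(hausdorff_distance(a[0, , drop = FALSE], a), "empty")

  brute_hausdorff <- function(p, q) {
    d <- as.matrix(dist(rbind(p, q)))[seq_len(nrow(p)), nrow(p) + seq_len(nrow(q))]
    d <- matrix(d, nrow(p), nrow(q))
    max(max(apply(d, 1, min)), max(apply(d, 2, min)))
  }
  circle <- function(r) {
    th <- seq(0, 2 * pi, length.out = 720)
    unique(round(cbind(r * cos(th), r * sin(th))))
  }
  c10 <- circle(10); c12 <- circle(12)
  h <- hausdorff_distance(c10, c12)
  expect_equal(h, brute_hausdorff(c10, c12))
  expect_lt(abs(h - 2), 0.5)
  # symmetry on random point sets
  set.seed(1)
  for (k in 1:5) {
    p <- matrix(runif(20, 0, 50), ncol = 2)
    q <- matrix(runif(14, 0, 50), ncol = 2)
    expect_equal(hausdorff_distance(p, q), hausdorff_distance(q, p))
    expect_equal(hausdorff_distance(p, q), brute_hausdorff(p, q))
  }
})

test_that("bland-altman summaries match direct arithmetic", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba0$mean_diff, 0); expect_equal(unname(ba0$loa), c(0, 0))
  a <- c(4, 9, 2)
  ba1 <- bland_altman(a, a + 5)
  expect_equal(ba1$mean_diff, -5); expect_equal(ba1$sd_diff, 0)
  a2 <- c(100, 200, 300); b2 <- c(110, 190, 310)
  ba2 <- bland_altman(a2, b2)
  d <- a2 - b2
  expect_equal(ba2$mean_diff, mean(d))
  expect_equal(ba2$sd_diff, sqrt(sum((d - mean(d))^2) / 2))
  expect_equal(unname(ba2$loa),
               mean(d) + c(-1.96, 1.96) * ba2$sd_diff)
  expect_error(bland_altman(1:3, 1:4), "length")
})

test_that("segmentation quality degrades monotonically (on average) with noise", {
  mean_jacc <- function(noise) {
    js <- sapply(1:3, function(s) {
      spec <- synth_image_spec(image_size = 192, n_cells = 5,
                               overlap_fraction = 0, noise_sigma = noise,
                               seed = 50 + s)
      res <- synth_image(spec)
      img <- img_preprocess(res$image, 1, 1)
      nuc <- segment_nuclei(img[["DAPI"]])
      if (max(nuc) == 0) return(0)
      mean(compare_segmentations(nuc, res$truth$nuclear_mask)$matches$jaccard)
    })
    mean(js)
  }
  j <- sapply(c(0, 20, 60), mean_jacc)
  expect_gte(j[1] + 0.05, j[2])
  expect_gte(j[2] + 0.05, j[3])
  expect_gte(j[1], 0.9)
})
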