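test_that("compartment totals, means and log2 ratios are exact on a constructed cell", {
  nuc <- matrix(0L, 16, 16); nuc[5:8, 5:8] <- 1L
  cyt <- matrix(0L, 16, 16); cyt[10:13, 5:8] <- 1L
  ch <- matrix(0, 16, 16); ch[nuc == 1] <- 100; ch[cyt == 1] <- 50
  img <- mc_image(list(M = ch), image_id = "i", patient_id = "p")
  rec <- extract_cell_features(img, list(nuclear_labels = nuc,
                                         cytoplasm_labels = cyt), cd99 = NULL)
  expect_equal(rec$log2_nc_mean_M, 1)               # log2(100/50)
  expect_equal(rec$nuclear_total_M, rec$nuclear_mean_M * rec$nuclear_area)
  expect_equal(rec$cyto_total_M, rec$cyto_mean_M * rec$cytoplasm_area)
})

test_that("features extracted over ground-truth masks reproduce the cell table exactly", {
  res <- clean_image()
  img <- mc_image(res$truth$noiseless, pixel_size = NULL)
  rec <- extract_cell_features(img, list(nuclear_labels = res$truth$nuclear_mask,
                                         cytoplasm_labels = res$truth$cytoplasm_mask))
  tab <- res$truth$cell_table
  for (ch in c("DAPI", "CD99", "Ki67")) {
    expect_equal(rec[[paste0("nuclear_mean_", ch)]],
                 tab[[paste0("nuclear_mean_", ch)]], tolerance = 1e-10)
    expect_equal(rec[[paste0("cyto_mean_", ch)]],
                 tab[[paste0("cyto_mean_", ch)]], tolerance = 1e-10)
  }
  # planted subpopulation is CD99-negative under the fixed rule
  expect_equal(rec$cd99_positive, !tab$subpop)
})

test_that("CD99 status follows the strict mean rule with a missing-cytoplasm convention", {
  expect_equal(as.character(cd99_status(10, 5)), "positive")
  expect_equal(as.character(cd99_status(5, 5)), "negative")
  cyt <- c(10, 5, 7, NA, 3, 12); nuc <- c(5, 5, 9, 4, 1, 11)
  st <- cd99_status(cyt, nuc)
  expect_equal(sum(st == "positive"), 3)   # hand count: cells 1, 5, 6
  expect_equal(attr(st, "missing"), is.na(cyt))
})

test_that("the Ki67 index counts Ki67-positives among CD99-positives", {
  cells <- data.frame(
    patient_id = "P1",
    cd99_positive = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    log2_nc_mean_Ki67 = c(5, 0, 0, 0, 9, 9))
  # pooled 50th centile threshold = 2.5: Ki67+ cells are {5, 9, 9}
  idx <- ki67_index(cells, cd99_rule = "mean", ki67_centile = 50)
  expect_equal(idx$ki67_index, 0.25)
  expect_equal(idx$n_cd99_pos, 4)
  all_pos <- cells
  all_pos$log2_nc_mean_Ki67 <- c(9, 9, 9, 9, 0, 0)
  expect_equal(ki67_index(all_pos, cd99_rule = "mean",
                          ki67_centile = 10)$ki67_index, 1)
  none <- cells; none$cd99_positive <- FALSE
  expect_message(out <- ki67_index(none, cd99_rule = "mean"), "undefined")
  expect_true(is.na(out$ki67_index))
})

test_that("the centile CD99 rule marks cytoplasm-dominant (low-ratio) cells positive", {
  cells <- data.frame(patient_id = "P1",
                      log2_nc_mean_CD99 = c(-2, -1, 0, 1),
                      log2_nc_mean_Ki67 = c(9, 9, 0, 0))
  idx <- ki67_index(cells, cd99_rule = "centile", cd99_centile = 50,
                    ki67_centile = 50)
  # CD99+ = ratios <= median(-2,-1,0,1) = {-2,-1}; both Ki67+
  expect_equal(idx$n_cd99_pos, 2)
  expect_equal(idx$ki67_index, 1)
})

test_that("patient density vectors have 100 points on a shared grid with unit mass", {
  cells <- make_cells(n_patients = 6, cells_per_patient = 80, seed = 21)
  pf <- patient_density_features(cells, "log2_nc_mean_Ki67")
  expect_equal(ncol(pf$matrix), 1 * 3 * 100)
  expect_equal(nrow(pf$matrix), 6)
  expect_true(all(pf$matrix >= 0, na.rm = TRUE))
  expect_length(pf$grids$log2_nc_mean_Ki67, 100)
  expect_true(all(diff(pf$grids$log2_nc_mean_Ki67) > 0))
  # unit mass on an extended grid for every patient (exact KDE evaluation)
  g <- pf$grids$log2_nc_mean_Ki67
  for (p in rownames(pf$matrix)) {
    x <- cells$log2_nc_mean_Ki67[cells$patient_id == p]
    bw <- pf$bandwidths[[paste("log2_nc_mean_Ki67", "all", p, sep = "|")]]
    ext <- seq(min(x) - 6 * bw, max(x) + 6 * bw, length.out = 2000)
    dens <- kde_eval(x, ext, bw)
    mass <- sum(diff(ext) * (dens[-1] + dens[-length(dens)]) / 2)
    expect_lt(abs(mass - 1), 1e-3)
  }
  # strata conserve the cells
  n_pos <- sum(cells$cd99_positive); n_neg <- sum(!cells$cd99_positive)
  expect_equal(n_pos + n_neg, nrow(cells))
})

test_that("degenerate strata yield flagged missing vectors, point masses peak at the value", {
  cells <- data.frame(patient_id = rep(c("A", "B"), c(30, 3)),
                      cd99_positive = TRUE,
                      f = c(rnorm(30), 1, 1, 1))
  pf <- patient_density_features(cells, "f", strata = "all", min_cells = 5)
  expect_true(all(is.na(pf$matrix["B", ])))       # 3 cells < minimum
  expect_false(anyNA(pf$matrix["A", ]))
  cells2 <- data.frame(patient_id = rep("A", 10), f = rep(2.5, 10))
  pf2 <- patient_density_features(cells2, "f", strata = "all")
  g <- pf2$grids$f
  expect_equal(unname(which.max(pf2$matrix[1, ])), which.min(abs(g - 2.5)))
})

test_that("z-scored PCA matches the correlation-matrix eigendecomposition", {
  set.seed(5)
  x <- matrix(rnorm(20), 5, 4)
  out <- zscore_pca(x, n_comp = 2)
  z <- scale(x)
  eg <- eigen(cor(x))
  expect_equal(abs(colSums(out$projections * (z %*% eg$vectors[, 1:2]))) /
                 colSums((z %*% eg$vectors[, 1:2])^2), c(1, 1),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(out$explained, eg$values / sum(eg$values))
  expect_true(all(abs(colMeans(z)) < 1e-10))
  expect_true(all(abs(apply(z, 2, var) - 1) < 1e-10))
  # rank-1 data: first component explains essentially everything
  r1 <- outer(rnorm(6), rnorm(3)) + matrix(rnorm(18, sd = 1e-8), 6, 3)
  out1 <- zscore_pca(r1, n_comp = 1)
  expect_gte(out1$explained[1], 0.999)
  expect_warning(zscore_pca(cbind(x, const = 1)), "constant")
  expect_error(zscore_pca(x, n_comp = 9), "components")
})
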