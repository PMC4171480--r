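# log2 nucleus/cytoplasm ratio; an offset of 1 intensity unit is added
# to BOTH compartments only when one of them is zero, so ratios of
# strictly positive means are exact (log2(100/50) = 1).
log2_nc <- function(nuc, cyt) {
  out <- ifelse(nuc == 0 | cyt == 0,
                log2((nuc + 1) / (cyt + 1)),
                log2(nuc / cyt))
  out
}

#' Extract per-cell compartment features from a segmented image
#'
#' One record per segmented cell: compartment areas and, for every
#' channel, total and mean intensity over nucleus and cytoplasm plus the
#' log2 nucleus/cytoplasm ratios of means and totals. Cells with zero
#' cytoplasm area get missing (`NA`) cytoplasmic values and ratios.
#'
#' @param image an [mc_image].
#' @param seg a `cell_segmentation` (or a list with `nuclear_labels`,
#'   `cytoplasm_labels`).
#' @param cd99 channel name used for the CD99 positivity flag (set to
#'   `NULL` to skip the flag).
#' @return data.frame, one row per cell, with a logical `cd99_positive`
#'   column when `cd99` is present.
#' @export
extract_cell_features <- function(image, seg, cd99 = "CD99") {
  stopifnot(inherits(image, "mc_image"))
  nuc <- seg$nuclear_labels; cyt <- seg$cytoplasm_labels
  if (!all(dim(nuc) == dim(image$channels[[1]])))
    stopf("extract_cell_features: label map / image shape mismatch")
  k <- max(nuc)
  if (k == 0) return(data.frame())
  a_n <- tabulate(nuc, nbins = k)
  a_c <- tabulate(cyt, nbins = k)
  out <- data.frame(cell_id = seq_len(k),
                    image_id = image$image_id, patient_id = image$patient_id,
                    nuclear_area = a_n, cytoplasm_area = a_c)
  if (!is.null(image$pixel_size)) {
    out$nuclear_area_um2 <- a_n * image$pixel_size^2
    out$cytoplasm_area_um2 <- a_c * image$pixel_size^2
  }
  nz_n <- nuc > 0; nz_c <- cyt > 0
  for (ch in names(image$channels)) {
    img <- image$channels[[ch]]
    tn <- drop(rowsum(img[nz_n], nuc[nz_n]))
    tot_n <- numeric(k); tot_n[as.integer(names(tn))] <- tn
    tot_c <- numeric(k)
    if (any(nz_c)) {
      tc <- drop(rowsum(img[nz_c], cyt[nz_c]))
      tot_c[as.integer(names(tc))] <- tc
    }
    mean_n <- tot_n / a_n
    mean_c <- ifelse(a_c > 0, tot_c / a_c, NA_real_)
    out[[paste0("nuclear_total_", ch)]] <- tot_n
    out[[paste0("nuclear_mean_", ch)]] <- mean_n
    out[[paste0("cyto_total_", ch)]] <- ifelse(a_c > 0, tot_c, NA_real_)
    out[[paste0("cyto_mean_", ch)]] <- mean_c
    out[[paste0("log2_nc_mean_", ch)]] <-
      ifelse(a_c > 0, log2_nc(mean_n, mean_c), NA_real_)
    out[[paste0("log2_nc_total_", ch)]] <-
      ifelse(a_c > 0, log2_nc(tot_n, tot_c), NA_real_)
  }
  if (!is.null(cd99) && cd99 %in% names(image$channels)) {
    st <- cd99_status(out[[paste0("cyto_mean_", cd99)]],
                      out[[paste0("nuclear_mean_", cd99)]])
    out$cd99_positive <- st == "positive"
    out$cd99_missing <- attr(st, "missing")
  }
  out
}

#' CD99 positivity of a cell
#'
#' Positive if and only if the mean cytoplasmic CD99 strictly exceeds
#' the mean nuclear CD99. Cells with a missing cytoplasm are negative by
#' convention and flagged in the `missing` attribute.
#'
#' @param cyto_mean,nuclear_mean numeric vectors of compartment means.
#' @return character vector `"positive"`/`"negative"`, with a logical
#'   attribute `missing`.
#' @export
cd99_status <- function(cyto_mean, nuclear_mean) {
  miss <- is.na(cyto_mean)
  out <- ifelse(!miss & cyto_mean > nuclear_mean, "positive", "negative")
  attr(out, "missing") <- miss
  out
}

# pooled centile threshold of a log2-ratio column
pooled_threshold <- function(values, centile) {
  v <- values[is.finite(values)]
  if (!length(v)) stopf("no finite values for threshold")
  unname(quantile(v, centile / 100, type = 7))
}

#' Per-patient Ki67 index
#'
#' The proportion of CD99-positive cells that are Ki67-positive. Ki67
#' positivity thresholds the pooled log2 nucleus/cytoplasm Ki67 ratio at
#' a centile; CD99 positivity uses either the fixed rule (mean
#' cytoplasmic CD99 > mean nuclear CD99) or a centile threshold on the
#' pooled log2 CD99 ratio (positive = ratio at or below the threshold,
#' i.e. cytoplasm-dominant).
#'
#' @param cells cell-record data.frame (from [extract_cell_features()]
#'   or the synthetic cell tables) with a `patient_id` column.
#' @param cd99_rule `"mean"` (fixed rule; requires `cd99_positive`
#'   column) or `"centile"`.
#' @param cd99_centile,ki67_centile centiles (0-100) of the pooled
#'   ratio distributions.
#' @param cd99_col,ki67_col names of the log2-ratio columns.
#' @return data.frame: `patient_id`, `n_cells`, `n_cd99_pos`,
#'   `ki67_index` (`NA` with a message when a patient has no
#'   CD99-positive cell).
#' @export
ki67_index <- function(cells, cd99_rule = c("mean", "centile"),
                       cd99_centile = 62, ki67_centile = 22,
                       cd99_col = "log2_nc_mean_CD99",
                       ki67_col = "log2_nc_mean_Ki67") {
  cd99_rule <- match.arg(cd99_rule)
  if (is.null(cells$patient_id)) cells$patient_id <- "all"
  ki <- cells[[ki67_col]]
  ki_thr <- pooled_threshold(ki, ki67_centile)
  ki_pos <- !is.na(ki) & ki > ki_thr
  if (cd99_rule == "mean") {
    if (is.null(cells$cd99_positive)) stopf("no cd99_positive column")
    cd_pos <- cells$cd99_positive %in% TRUE
  } else {
    cd <- cells[[cd99_col]]
    cd_thr <- pooled_threshold(cd, cd99_centile)
    cd_pos <- !is.na(cd) & cd <= cd_thr
  }
  pid <- as.character(cells$patient_id)
  upid <- unique(pid)
  n_all <- as.integer(table(factor(pid, upid)))
  n_cd <- as.integer(rowsum(as.numeric(cd_pos), factor(pid, upid)))
  n_both <- as.integer(rowsum(as.numeric(cd_pos & ki_pos), factor(pid, upid)))
  idx <- ifelse(n_cd > 0, n_both / n_cd, NA_real_)
  if (any(n_cd == 0))
    message(sprintf("ki67_index undefined for %d patient(s): no CD99-positive cells",
                    sum(n_cd == 0)))
  data.frame(patient_id = upid, n_cells = n_all, n_cd99_pos = n_cd,
             ki67_index = idx, stringsAsFactors = FALSE)
}

#' Evaluate a Gaussian kernel density estimate on an arbitrary grid
#'
#' Exact (non-binned) evaluation: `f(g) = mean(dnorm(g, x_i, bw))`.
#' @param x sample values.
#' @param grid evaluation points.
#' @param bw kernel bandwidth (SD of the Gaussian kernel).
#' @return density values at `grid`.
#' @export
kde_eval <- function(x, grid, bw) {
  stopifnot(bw > 0, length(x) >= 1)
  colMeans(matrix(dnorm(outer(x, grid, `-`) / bw), length(x)) ) / bw
}

# Scott's rule bandwidth with degenerate-sample fallbacks
kde_bandwidth <- function(x) {
  bw <- tryCatch(bw.nrd(x), error = function(e) NA_real_)
  if (!is.finite(bw) || bw <= 0)
    bw <- tryCatch(bw.nrd0(x), error = function(e) NA_real_)
  if (!is.finite(bw) || bw <= 0) bw <- max(sd(x), 1e-8) * 1.06 * length(x)^(-1/5)
  bw
}

#' Encode per-patient cell-feature distributions as 100-point densities
#'
#' For each cell-level feature and stratum (all cells, CD99-positive,
#' CD99-negative), cells from all of a patient's images are pooled and a
#' Gaussian kernel density estimate (Scott's-rule bandwidth on the
#' patient's own sample) is evaluated at 100 equally spaced points of a
#' grid common to all patients. The grid spans the pooled cross-patient
#' 0.5th-99.5th percentile range of the feature, so vectors are
#' comparable across patients — this is the feature space consumed by
#' the random survival forest.
#'
#' @param cells cell-record data.frame with `patient_id` and, for the
#'   CD99 strata, a logical `cd99_positive` column.
#' @param features character vector of cell-feature column names.
#' @param strata subset of `c("all", "CD99+", "CD99-")`.
#' @param n_grid grid points per (feature, stratum) (default 100).
#' @param min_cells minimum cells for a valid density (below: missing
#'   vector, flagged).
#' @param range_quantiles pooled quantiles bounding the common grid.
#' @return object of class `patient_features`: list with `matrix`
#'   (patients x features, dimnames set; missing vectors are `NA`),
#'   `grids` (common grid per feature), `bandwidths`, `features`,
#'   `strata`, `n_grid`.
#' @export
patient_density_features <- function(cells, features,
                                     strata = c("all", "CD99+", "CD99-"),
                                     n_grid = 100, min_cells = 5,
                                     range_quantiles = c(0.005, 0.995)) {
  stopifnot(all(features %in% names(cells)), n_grid >= 2)
  strata <- match.arg(strata, c("all", "CD99+", "CD99-"), several.ok = TRUE)
  if (any(strata != "all") && is.null(cells$cd99_positive))
    stopf("CD99 strata requested but no cd99_positive column")
  pid <- as.character(cells$patient_id)
  upid <- unique(pid)
  grids <- list(); bws <- list()
  blocks <- list()
  for (f in features) {
    v_all <- cells[[f]]
    fin <- is.finite(v_all)
    if (!any(fin)) stopf("feature '%s' has no finite values", f)
    qs <- quantile(v_all[fin], range_quantiles, type = 7)
    if (qs[1] == qs[2]) qs <- qs + c(-0.5, 0.5)
    grid <- seq(qs[1], qs[2], length.out = n_grid)
    grids[[f]] <- grid
    for (s in strata) {
      sel <- switch(s, "all" = rep(TRUE, nrow(cells)),
                    "CD99+" = cells$cd99_positive %in% TRUE,
                    "CD99-" = !(cells$cd99_positive %in% TRUE))
      block <- matrix(NA_real_, length(upid), n_grid,
                      dimnames = list(upid, sprintf("%s|%s@c%03d", f, s,
                                                    seq_len(n_grid))))
      for (p in upid) {
        x <- v_all[sel & pid == p]
        x <- x[is.finite(x)]
        if (length(x) < min_cells) next
        bw <- kde_bandwidth(x)
        bws[[paste(f, s, p, sep = "|")]] <- bw
        block[p, ] <- kde_eval(x, grid, bw)
      }
      blocks[[paste(f, s, sep = "|")]] <- block
    }
  }
  structure(list(matrix = do.call(cbind, blocks), grids = grids,
                 bandwidths = unlist(bws), features = features,
                 strata = strata, n_grid = n_grid),
            class = "patient_features")
}

#' @export
print.patient_features <- function(x, ...) {
  cat(sprintf("<patient_features> %d patients x %d values (%d features x %d strata x %d grid points)\n",
              nrow(x$matrix), ncol(x$matrix), length(x$features),
              length(x$strata), x$n_grid))
  miss <- sum(apply(x$matrix, 1, function(r) anyNA(r)))
  if (miss) cat(sprintf("  %d patient(s) with missing vectors\n", miss))
  invisible(x)
}

#' Z-scored principal component analysis of a patient feature matrix
#'
#' Columns are standardised to mean 0, variance 1 (constant columns
#' dropped with a warning) before the principal components are
#' computed.
#'
#' @param x numeric matrix, patients in rows.
#' @param n_comp number of components to return (2-3 typical).
#' @return list: `projections` (n x n_comp scores), `explained`
#'   (proportion of variance per component, full length), `rotation`,
#'   `dropped` (names of constant columns removed).
#' @export
zscore_pca <- function(x, n_comp = 2) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stopf("zscore_pca: need at least 2 rows")
  if (n_comp > nrow(x)) stopf("zscore_pca: more components than rows")
  sds <- apply(x, 2, sd)
  dropped <- colnames(x)[sds == 0 | is.na(sds)]
  if (length(dropped)) {
    warning(sprintf("dropping %d constant column(s)", length(dropped)))
    x <- x[, !(colnames(x) %in% dropped), drop = FALSE]
  }
  z <- scale(x)
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  list(projections = pc$x[, seq_len(min(n_comp, ncol(pc$x))), drop = FALSE],
       explained = ev / sum(ev), rotation = pc$rotation, dropped = dropped)
}
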