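#' Median + Gaussian pre-filtering of a multi-channel image
#'
#' Each channel is median-filtered (half-window `median_radius`) and
#' then Gaussian-smoothed; zero parameters leave the channel untouched.
#'
#' @param image an [mc_image].
#' @param median_radius half-size of the median window in pixels (0 = off).
#' @param gaussian_sigma Gaussian SD in pixels (0 = off).
#' @return a filtered [mc_image].
#' @export
img_preprocess <- function(image, median_radius = 2, gaussian_sigma = 1) {
  stopifnot(inherits(image, "mc_image"), median_radius >= 0, gaussian_sigma >= 0)
  ch <- lapply(image$channels, function(x) {
    if (median_radius > 0) {
      mx <- max(x)
      if (mx > 0)
        x <- as.matrix(EBImage::medianFilter(x / mx, size = median_radius)) * mx
    }
    if (gaussian_sigma > 0) x <- as.matrix(EBImage::gblur(x, sigma = gaussian_sigma))
    pmax(x, 0)
  })
  mc_image(ch, pixel_size = image$pixel_size, image_id = image$image_id,
           patient_id = image$patient_id)
}

#' Otsu threshold (exact between-class-variance maximiser)
#'
#' Maximises the between-class variance over the empirical intensity
#' histogram; the returned threshold is the midpoint of the optimal gap
#' between consecutive observed values, so `x > threshold` realises the
#' optimal binarisation. For channels with more than 2048 distinct
#' values the histogram is first quantised to 1024 equal-width bins.
#'
#' @param x numeric matrix (or vector) with at least two distinct values.
#' @return scalar threshold.
#' @export
otsu_threshold <- function(x) {
  v <- as.numeric(x)
  u <- sort(unique(v))
  if (length(u) < 2) stopf("otsu_threshold: channel is constant")
  if (length(u) > 2048) {
    br <- seq(min(v), max(v), length.out = 1025)
    mid <- (br[-1] + br[-length(br)]) / 2
    cnt <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins = 1024)
    keep <- cnt > 0
    u <- mid[keep]; w <- cnt[keep]
  } else {
    w <- tabulate(match(v, u), nbins = length(u))
  }
  n <- sum(w)
  cw <- cumsum(w); cm <- cumsum(w * u)
  tot <- cm[length(cm)]
  k <- seq_len(length(u) - 1)     # class 1 = values <= u[k]
  w0 <- cw[k] / n; w1 <- 1 - w0
  mu0 <- cm[k] / cw[k]; mu1 <- (tot - cm[k]) / (n - cw[k])
  bcv <- w0 * w1 * (mu0 - mu1)^2
  i <- which.max(bcv)
  (u[i] + u[i + 1]) / 2
}

# 3x3-neighbour shifts with replicated borders (for finite differences)
shift_up    <- function(m) m[c(1, seq_len(nrow(m) - 1)), , drop = FALSE]
shift_down  <- function(m) m[c(seq_len(nrow(m) - 1) + 1, nrow(m)), , drop = FALSE]
shift_left  <- function(m) m[, c(1, seq_len(ncol(m) - 1)), drop = FALSE]
shift_right <- function(m) m[, c(seq_len(ncol(m) - 1) + 1, ncol(m)), drop = FALSE]

signed_distance <- function(mask) {
  inside <- as.matrix(EBImage::distmap(mask * 1))
  outside <- as.matrix(EBImage::distmap((1 - mask) * 1))
  inside - outside
}

#' Region-based level-set refinement with edge weighting
#'
#' Evolves an implicit contour initialised from a binary mask under a
#' two-phase region energy (piecewise-constant inside/outside means)
#' weighted by an edge-stopping function of the image gradient, plus a
#' curvature smoothing term. A fixed iteration cap and a mask-change
#' tolerance make the evolution reproducible.
#'
#' @param x intensity matrix.
#' @param mask initial binary mask (e.g. Otsu binarisation).
#' @param iterations maximum iterations.
#' @param mu curvature weight relative to the (normalised) region force.
#' @param edge_lambda gradient scale of the edge-stopping function
#'   `1/(1 + (|grad|/edge_lambda)^2)`; `NULL` uses the robust gradient scale
#'   (90th percentile).
#' @param dt time step.
#' @param tol stop when the fraction of pixels changing side per
#'   iteration falls below this.
#' @return refined binary mask (logical matrix).
#' @export
levelset_refine <- function(x, mask, iterations = 40, mu = 0.2,
                            edge_lambda = NULL, dt = 1, tol = 1e-4) {
  mask <- mask > 0
  if (!any(mask) || all(mask)) return(mask)
  gx <- (shift_down(x) - shift_up(x)) / 2
  gy <- (shift_right(x) - shift_left(x)) / 2
  grad <- sqrt(gx^2 + gy^2)
  if (is.null(edge_lambda)) edge_lambda <- max(quantile(grad, 0.9), 1e-8)
  g <- 1 / (1 + (grad / edge_lambda)^2)
  phi <- signed_distance(mask)
  eps <- 1.5
  for (it in seq_len(iterations)) {
    inside <- phi > 0
    c1 <- mean(x[inside]); c2 <- mean(x[!inside])
    region <- (x - c2)^2 - (x - c1)^2
    region <- region / max(abs(region))
    # curvature of phi
    px <- (shift_down(phi) - shift_up(phi)) / 2
    py <- (shift_right(phi) - shift_left(phi)) / 2
    pxx <- shift_down(phi) - 2 * phi + shift_up(phi)
    pyy <- shift_right(phi) - 2 * phi + shift_left(phi)
    pxy <- (shift_right(shift_down(phi)) - shift_right(shift_up(phi)) -
              shift_left(shift_down(phi)) + shift_left(shift_up(phi))) / 4
    den <- (px^2 + py^2)^1.5 + 1e-8
    kappa <- (pxx * py^2 - 2 * pxy * px * py + pyy * px^2) / den
    kappa <- pmin(pmax(kappa, -1), 1)
    delta <- eps / (pi * (eps^2 + phi^2))
    phi <- phi + dt * delta * (g * region + mu * kappa)
    new_inside <- phi > 0
    changed <- mean(new_inside != inside)
    if (it %% 10 == 0) phi <- signed_distance(new_inside)
    if (changed < tol) break
  }
  phi > 0
}

#' Segment nuclei from a DAPI channel
#'
#' Otsu binarisation initialises a region-based level-set refinement;
#' touching nuclei are split by a watershed tessellation seeded from
#' maxima of the Gaussian-smoothed distance transform; objects below a
#' minimum area (and, by default, border-touching objects) are removed.
#'
#' @param dapi intensity matrix (preprocessed DAPI channel).
#' @param min_area minimum nucleus area, pixels.
#' @param clear_border drop nuclei touching the image border.
#' @param levelset_iterations iterations of [levelset_refine()] (0 = skip).
#' @param seed_sigma Gaussian SD (pixels) smoothing the distance
#'   transform before watershed seeding.
#' @param ws_tolerance watershed merge tolerance (minimum seed depth).
#' @return integer label matrix; background 0. Empty foreground yields
#'   an all-zero map with a message.
#' @export
segment_nuclei <- function(dapi, min_area = 30, clear_border = TRUE,
                           levelset_iterations = 40, seed_sigma = 2,
                           ws_tolerance = 1) {
  stopifnot(is.matrix(dapi))
  if (length(unique(as.numeric(dapi))) < 2) {
    message("segment_nuclei: constant channel, no foreground")
    return(matrix(0L, nrow(dapi), ncol(dapi)))
  }
  thr <- otsu_threshold(dapi)
  mask <- dapi > thr
  if (!any(mask)) {
    message("segment_nuclei: empty foreground after thresholding")
    return(matrix(0L, nrow(dapi), ncol(dapi)))
  }
  if (levelset_iterations > 0)
    mask <- levelset_refine(dapi, mask, iterations = levelset_iterations)
  if (!any(mask)) {
    message("segment_nuclei: empty foreground after level set")
    return(matrix(0L, nrow(dapi), ncol(dapi)))
  }
  dm <- as.matrix(EBImage::distmap(mask * 1))
  if (seed_sigma > 0) dm <- as.matrix(EBImage::gblur(dm, sigma = seed_sigma))
  dm[!mask] <- 0
  lab <- EBImage::imageData(EBImage::watershed(EBImage::as.Image(dm),
                                               tolerance = ws_tolerance, ext = 1))
  lab <- matrix(as.integer(lab), nrow(dapi), ncol(dapi))
  # area / border filtering
  if (max(lab) > 0) {
    areas <- tabulate(lab, nbins = max(lab))
    drop <- which(areas < min_area)
    if (clear_border) {
      border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
      drop <- union(drop, border[border > 0])
    }
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  relabel(lab)
}

#' Assign cytoplasm to each nucleus from a cytoplasmic marker channel
#'
#' The outer cell boundary is the Otsu foreground of the marker channel
#' (union of the nuclei); within it, pixels are apportioned between
#' neighbouring cells by gradient-guided propagation from the nuclear
#' seeds (the Voronoi-bounded, intensity-weighted region growing of
#' marker-controlled watershed); the nuclear region itself is excluded.
#' With a spatially uniform marker the inter-cell boundary reduces to
#' the Voronoi perpendicular bisector.
#'
#' @param cd99 intensity matrix of the cytoplasmic marker.
#' @param nuclear_labels integer label matrix from [segment_nuclei()].
#' @param lambda propagation regularisation: small values follow the
#'   intensity landscape, large values approach pure Euclidean Voronoi.
#' @return integer label matrix of cytoplasm regions (same label set as
#'   the nuclei); attribute `flagged` lists labels with zero cytoplasm
#'   area.
#' @export
segment_cytoplasm <- function(cd99, nuclear_labels, lambda = 0.05) {
  if (!all(dim(cd99) == dim(nuclear_labels)))
    stopf("segment_cytoplasm: channel and label map dimensions differ")
  n_cells <- max(nuclear_labels)
  empty <- matrix(0L, nrow(cd99), ncol(cd99))
  if (n_cells == 0) { attr(empty, "flagged") <- integer(0); return(empty) }
  constant <- length(unique(as.numeric(cd99))) < 2
  fg <- if (constant) nuclear_labels > 0 else (cd99 > otsu_threshold(cd99)) | nuclear_labels > 0
  mx <- max(cd99)
  xs <- if (mx > 0) cd99 / mx else cd99
  prop <- EBImage::propagate(EBImage::as.Image(xs),
                             seeds = EBImage::as.Image(nuclear_labels),
                             mask = fg, lambda = lambda)
  cyt <- matrix(as.integer(EBImage::imageData(prop)), nrow(cd99), ncol(cd99))
  cyt[nuclear_labels > 0] <- 0L
  areas <- tabulate(cyt, nbins = n_cells)
  attr(cyt, "flagged") <- which(areas == 0)
  cyt
}

#' Full single-cell segmentation of a multi-channel image
#'
#' Runs [segment_nuclei()] on the DAPI channel and
#' [segment_cytoplasm()] on the cytoplasmic marker channel, pairing the
#' label maps cell by cell.
#'
#' @param image an [mc_image] (preprocess first with [img_preprocess()]).
#' @param dapi,cd99 channel names.
#' @param ... passed to [segment_nuclei()].
#' @return list of class `cell_segmentation`: `nuclear_labels`,
#'   `cytoplasm_labels`, `n_cells`, `flagged` (labels with empty
#'   cytoplasm).
#' @export
segment_cells <- function(image, dapi = "DAPI", cd99 = "CD99", ...) {
  stopifnot(inherits(image, "mc_image"))
  if (!dapi %in% names(image$channels)) stopf("no channel '%s'", dapi)
  nuc <- segment_nuclei(image$channels[[dapi]], ...)
  cyt <- if (cd99 %in% names(image$channels))
    segment_cytoplasm(image$channels[[cd99]], nuc)
  else { z <- matrix(0L, nrow(nuc), ncol(nuc)); attr(z, "flagged") <- seq_len(max(nuc)); z }
  structure(list(nuclear_labels = nuc, cytoplasm_labels = cyt,
                 n_cells = max(nuc), flagged = attr(cyt, "flagged")),
            class = "cell_segmentation")
}

#' @export
print.cell_segmentation <- function(x, ...) {
  cat(sprintf("<cell_segmentation> %d cells (%d with empty cytoplasm)\n",
              x$n_cells, length(x$flagged)))
  invisible(x)
}

#' Boundary pixel coordinates of a binary mask
#'
#' A pixel is a boundary pixel if it is foreground with at least one
#' 4-neighbour outside the mask (or on the image edge).
#' @param mask logical or 0/1 matrix.
#' @return two-column matrix (row, col) of boundary pixels.
#' @export
boundary_points <- function(mask) {
  mask <- mask > 0
  er <- shift_up(mask) & shift_down(mask) & shift_left(mask) & shift_right(mask)
  er[1, ] <- FALSE; er[nrow(er), ] <- FALSE; er[, 1] <- FALSE; er[, ncol(er)] <- FALSE
  which(mask & !er, arr.ind = TRUE)
}

#' Hausdorff distance between two point sets
#'
#' The worst boundary mismatch: the larger of the two directed
#' max-over-min Euclidean distances.
#'
#' @param a,b two-column coordinate matrices (non-empty).
#' @param pixel_size optional micrometres per pixel; if supplied the
#'   distance is returned in micrometres.
#' @return scalar distance (>= 0).
#' @export
hausdorff_distance <- function(a, b, pixel_size = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!nrow(a) || !nrow(b)) stopf("hausdorff_distance: empty point set")
  d <- pracma::hausdorff_dist(a, b)
  if (!is.null(pixel_size)) d <- d * pixel_size
  d
}

#' Bland-Altman agreement analysis of paired area measurements
#'
#' @param a,b matched numeric vectors (method A and B), length >= 2.
#' @param k limits-of-agreement multiplier (default 1.96).
#' @return list: per-pair `mean` and `diff` (A - B), `mean_diff`,
#'   `sd_diff` (sample SD), `loa` lower/upper limits
#'   `mean_diff +/- k * sd_diff`, and `k`.
#' @export
bland_altman <- function(a, b, k = 1.96) {
  if (length(a) != length(b)) stopf("bland_altman: length mismatch")
  if (length(a) < 2) stopf("bland_altman: need at least 2 pairs")
  d <- a - b
  m <- (a + b) / 2
  md <- mean(d); sdd <- sd(d)
  list(mean = m, diff = d, mean_diff = md, sd_diff = sdd,
       loa = c(lower = md - k * sdd, upper = md + k * sdd), k = k)
}

#' Compare a segmentation against a reference label map
#'
#' Matches objects by maximum overlap and reports per-object areas,
#' Jaccard indices, Bland-Altman summary of areas and per-object
#' Hausdorff boundary distances.
#'
#' @param pred,ref integer label matrices.
#' @param pixel_size optional micrometres per pixel for Hausdorff units.
#' @return list: `n_pred`, `n_ref`, `matches` (data.frame: ref label,
#'   pred label, jaccard, area_pred, area_ref, hausdorff),
#'   `bland_altman` summary (NULL if < 2 matches).
#' @export
compare_segmentations <- function(pred, ref, pixel_size = NULL) {
  stopifnot(all(dim(pred) == dim(ref)))
  nr <- max(ref); np <- max(pred)
  rows <- list()
  for (r in seq_len(nr)) {
    rm_ <- ref == r
    cand <- pred[rm_]
    cand <- cand[cand > 0]
    if (!length(cand)) {
      rows[[r]] <- data.frame(ref = r, pred = NA_integer_, jaccard = 0,
                              area_pred = 0, area_ref = sum(rm_),
                              hausdorff = NA_real_)
      next
    }
    p <- as.integer(names(which.max(table(cand))))
    pm <- pred == p
    rows[[r]] <- data.frame(ref = r, pred = p, jaccard = jaccard(pm, rm_),
                            area_pred = sum(pm), area_ref = sum(rm_),
                            hausdorff = hausdorff_distance(boundary_points(pm),
                                                           boundary_points(rm_),
                                                           pixel_size))
  }
  matches <- do.call(rbind, rows)
  ok <- !is.na(matches$pred)
  ba <- if (sum(ok) >= 2)
    bland_altman(matches$area_pred[ok], matches$area_ref[ok]) else NULL
  list(n_pred = np, n_ref = nr, matches = matches, bland_altman = ba)
}
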