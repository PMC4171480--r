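#' Specification for a synthetic multi-channel TMA-like image
#'
#' Describes a field of elliptical cells (nucleus inside a larger
#' concentric cytoplasm) rendered into named intensity channels. The
#' defaults emulate a DAPI / CD99 / Ki67 confocal field of small round
#' cells: bright nuclear DAPI, cytoplasmic CD99, and a planted
#' subpopulation of Ki67-positive, CD99-low cells whose prevalence is
#' the prognostic signal used throughout the package's simulations.
#'
#' @param image_size pixels per side (square image).
#' @param n_cells number of cells to place (may be 0).
#' @param nucleus_radius_range min/max nucleus radius, pixels.
#' @param cyto_thickness_range min/max cytoplasm thickness, pixels.
#' @param overlap_fraction proportion of cells placed as members of
#'   touching 2-3 cell clumps (exercises watershed splitting).
#' @param subpop_fraction expected fraction of cells in the planted
#'   Ki67-positive / CD99-low subpopulation.
#' @param channel_models named list; per channel a list with entries
#'   `nuclear_mean`, `cyto_mean`, `background`, `cell_sd` and optionally
#'   `pos_nuclear_mean`, `pos_cyto_mean` overriding the compartment
#'   means for subpopulation cells.
#' @param noise_sigma additive Gaussian noise SD (intensity units).
#' @param poisson_scale if > 0, apply Poisson resampling at this
#'   photons-per-intensity-unit scale after the Gaussian term.
#' @param blur_sigma Gaussian defocus blur SD in pixels (0 = in focus).
#' @param pixel_size micrometres per pixel.
#' @param seed integer; identical spec + seed reproduces the image and
#'   ground truth bit-for-bit.
#' @return A list of class `synth_image_spec`.
#' @export
synth_image_spec <- function(image_size = 512, n_cells = 50,
                             nucleus_radius_range = c(6, 10),
                             cyto_thickness_range = c(3, 6),
                             overlap_fraction = 0.15,
                             subpop_fraction = 0.2,
                             channel_models = default_channel_models(),
                             noise_sigma = 5, poisson_scale = 0,
                             blur_sigma = 0, pixel_size = 211 / 2048,
                             seed = 1L) {
  stopifnot(image_size >= 16, n_cells >= 0,
            all(nucleus_radius_range > 0), all(cyto_thickness_range > 0),
            blur_sigma >= 0, noise_sigma >= 0, poisson_scale >= 0,
            overlap_fraction >= 0, overlap_fraction <= 1,
            subpop_fraction >= 0, subpop_fraction <= 1)
  structure(list(image_size = image_size, n_cells = n_cells,
                 nucleus_radius_range = sort(nucleus_radius_range),
                 cyto_thickness_range = sort(cyto_thickness_range),
                 overlap_fraction = overlap_fraction,
                 subpop_fraction = subpop_fraction,
                 channel_models = channel_models,
                 noise_sigma = noise_sigma, poisson_scale = poisson_scale,
                 blur_sigma = blur_sigma, pixel_size = pixel_size,
                 seed = as.integer(seed)),
            class = "synth_image_spec")
}

#' Default channel intensity models (DAPI, CD99, Ki67)
#'
#' Intensity units are arbitrary 8-bit-like values. Subpopulation cells
#' are Ki67-positive (bright nuclear Ki67) and CD99-low (cytoplasmic
#' CD99 below nuclear), so the fixed rule `mean cytoplasmic CD99 > mean
#' nuclear CD99` marks them negative.
#' @return named list of per-channel model lists.
#' @export
default_channel_models <- function() {
  list(
    DAPI = list(nuclear_mean = 180, cyto_mean = 20, background = 5, cell_sd = 15),
    CD99 = list(nuclear_mean = 30, cyto_mean = 150, background = 5, cell_sd = 15,
                pos_nuclear_mean = 30, pos_cyto_mean = 22),
    Ki67 = list(nuclear_mean = 25, cyto_mean = 30, background = 5, cell_sd = 8,
                pos_nuclear_mean = 160, pos_cyto_mean = 30)
  )
}

# Place cell centres given per-cell outer radii (r_cell) and nucleus
# radii (r_nuc). Free cells keep disjoint cytoplasm (pairwise distance
# >= sum of outer radii); a fraction are instead attached to a random
# host at nucleus-touching distance, forming 2-3 cell clumps. Bounded
# retries guard against infeasible densities.
place_cells <- function(size, r_cell, r_nuc, overlap_fraction) {
  n <- length(r_cell)
  if (n == 0) return(data.frame(cx = numeric(0), cy = numeric(0)))
  margin <- max(r_cell) + 2
  if (2 * margin >= size) stopf("cells too large for image")
  n_clump <- min(round(overlap_fraction * n), n - 1L)  # need >= 1 free host
  n_free <- n - n_clump
  cx <- cy <- numeric(0)
  tries <- 0L; cap <- 500L * n
  while (length(cx) < n_free) {
    tries <- tries + 1L
    if (tries > cap) stopf("cell placement failed: n_cells too dense for image_size")
    i <- length(cx) + 1L
    x <- runif(1, margin, size - margin); y <- runif(1, margin, size - margin)
    if (!length(cx) ||
        all((cx - x)^2 + (cy - y)^2 >=
              (r_cell[seq_along(cx)] + r_cell[i] + 1)^2)) {
      cx <- c(cx, x); cy <- c(cy, y)
    }
  }
  while (length(cx) < n) {
    tries <- tries + 1L
    if (tries > cap) stopf("cell placement failed: n_cells too dense for image_size")
    i <- length(cx) + 1L
    host <- sample.int(length(cx), 1)
    ang <- runif(1, 0, 2 * pi)
    d <- runif(1, 0.85, 1.0) * (r_nuc[i] + r_nuc[host])
    x <- cx[host] + d * cos(ang); y <- cy[host] + d * sin(ang)
    if (x < margin || x > size - margin || y < margin || y > size - margin) next
    ok <- (cx - x)^2 + (cy - y)^2 >= (r_nuc[seq_along(cx)] + r_nuc[i])^2
    ok[host] <- TRUE
    if (all(ok)) { cx <- c(cx, x); cy <- c(cy, y) }
  }
  data.frame(cx = cx, cy = cy)
}

# Paint an ellipse (centre cx,cy; semi-axes a,b; angle th) into a label
# matrix, overwriting. Returns the modified matrix.
paint_ellipse <- function(lab, cx, cy, a, b, th, value) {
  n <- nrow(lab); m <- ncol(lab)
  r0 <- max(1L, floor(cx - max(a, b))); r1 <- min(n, ceiling(cx + max(a, b)))
  c0 <- max(1L, floor(cy - max(a, b))); c1 <- min(m, ceiling(cy + max(a, b)))
  if (r0 > r1 || c0 > c1) return(lab)
  rr <- r0:r1; cc <- c0:c1
  dx <- outer(rr - cx, rep(1, length(cc)))
  dy <- outer(rep(1, length(rr)), cc - cy)
  u <- cos(th) * dx + sin(th) * dy
  v <- -sin(th) * dx + cos(th) * dy
  inside <- (u / a)^2 + (v / b)^2 <= 1
  sub <- lab[rr, cc, drop = FALSE]
  sub[inside] <- value
  lab[rr, cc] <- sub
  lab
}

#' Generate a synthetic multi-channel image with exact ground truth
#'
#' Renders elliptical cells into per-channel intensity images and
#' returns both the observed (blurred/noised) image and the ground
#' truth: nuclear and cytoplasmic label maps plus a per-cell table of
#' true compartment means computed from the noiseless rendering, so the
#' table agrees exactly with pixel averages over the masks.
#'
#' @param spec a [synth_image_spec()].
#' @return list with elements `image` ([mc_image]), `truth` (list:
#'   `nuclear_mask`, `cytoplasm_mask`, `cell_table`, `noiseless`).
#' @export
synth_image <- function(spec) {
  stopifnot(inherits(spec, "synth_image_spec"))
  with_seed(spec$seed, {
    sz <- spec$image_size
    n <- spec$n_cells
    rr <- spec$nucleus_radius_range; tt <- spec$cyto_thickness_range
    # per-cell geometry first (bounded eccentricity, axis ratio <= 1.25),
    # so placement can use the actual cell radii
    if (n > 0) {
      r <- runif(n, rr[1], rr[2])
      ecc <- runif(n, 1, 1.25)
      th <- runif(n, 0, pi)
      a <- r * ecc; b <- r / ecc
      thick <- runif(n, tt[1], tt[2])
      subpop <- runif(n) < spec$subpop_fraction
    } else {
      r <- a <- b <- th <- thick <- numeric(0); subpop <- logical(0)
    }
    centres <- place_cells(sz, r * 1.25 + thick, r * 1.25,
                           spec$overlap_fraction)
    nuc <- matrix(0L, sz, sz); cyt <- matrix(0L, sz, sz)
    for (i in seq_len(n))
      cyt <- paint_ellipse(cyt, centres$cx[i], centres$cy[i],
                           a[i] + thick[i], b[i] + thick[i], th[i], i)
    for (i in seq_len(n))
      nuc <- paint_ellipse(nuc, centres$cx[i], centres$cy[i],
                           a[i], b[i], th[i], i)
    cyt[nuc > 0] <- 0L
    keep <- which(tabulate(nuc, nbins = max(n, 1)) > 0)
    # drop cells fully overwritten in clumps, relabel 1..k
    if (n > 0 && length(keep) < n) {
      map <- integer(n); map[keep] <- seq_along(keep)
      nuc[nuc > 0] <- map[nuc[nuc > 0]]
      cyt[cyt > 0] <- map[cyt[cyt > 0]]
      cyt[cyt < 0] <- 0L  # cells with no nucleus left
    }
    k <- length(keep)
    # per-cell channel means (cell-to-cell variation, truncated >= 0)
    cms <- spec$channel_models
    cell_means <- list()
    for (ch in names(cms)) {
      m <- cms[[ch]]
      nm <- rep(m$nuclear_mean, k); cm <- rep(m$cyto_mean, k)
      sp <- subpop[keep]
      if (!is.null(m$pos_nuclear_mean)) nm[sp] <- m$pos_nuclear_mean
      if (!is.null(m$pos_cyto_mean)) cm[sp] <- m$pos_cyto_mean
      dev <- rnorm(k, 0, m$cell_sd)
      cell_means[[ch]] <- list(nuc = pmax(0, nm + dev), cyt = pmax(0, cm + dev))
    }
    # render noiseless channels
    noiseless <- list()
    nuc_idx <- which(nuc > 0); cyt_idx <- which(cyt > 0)
    for (ch in names(cms)) {
      img <- matrix(cms[[ch]]$background, sz, sz)
      if (k > 0) {
        img[nuc_idx] <- cell_means[[ch]]$nuc[nuc[nuc_idx]]
        img[cyt_idx] <- cell_means[[ch]]$cyt[cyt[cyt_idx]]
      }
      noiseless[[ch]] <- img
    }
    # ground-truth table from the noiseless rendering (exact by construction)
    areas_n <- tabulate(nuc, nbins = max(k, 1))[seq_len(k)]
    areas_c <- tabulate(cyt, nbins = max(k, 1))[seq_len(k)]
    tab <- data.frame(cell = seq_len(k),
                      cx = centres$cx[keep], cy = centres$cy[keep],
                      nucleus_area = areas_n, cytoplasm_area = areas_c,
                      subpop = subpop[keep])
    for (ch in names(cms)) {
      tab[[paste0("nuclear_mean_", ch)]] <- cell_means[[ch]]$nuc
      tab[[paste0("cyto_mean_", ch)]] <-
        ifelse(areas_c > 0, cell_means[[ch]]$cyt, NA_real_)
    }
    # observed image: blur then noise
    obs <- lapply(noiseless, function(img) {
      if (spec$blur_sigma > 0)
        img <- as.matrix(EBImage::gblur(img, sigma = spec$blur_sigma))
      if (spec$poisson_scale > 0)
        img <- matrix(rpois(length(img), pmax(img, 0) * spec$poisson_scale) /
                        spec$poisson_scale, nrow(img), ncol(img))
      if (spec$noise_sigma > 0)
        img <- img + matrix(rnorm(length(img), 0, spec$noise_sigma),
                            nrow(img), ncol(img))
      pmax(img, 0)
    })
    list(image = mc_image(obs, pixel_size = spec$pixel_size),
         truth = list(nuclear_mask = nuc, cytoplasm_mask = cyt,
                      cell_table = tab, noiseless = noiseless))
  })
}

#' Degrade an image with defocus blur and additive noise
#'
#' Returns a blurred and/or noised copy, leaving the input untouched;
#' used to emulate out-of-focus or poorly preserved fields for quality
#' control experiments.
#'
#' @param image an [mc_image].
#' @param blur_sigma Gaussian blur SD in pixels (0 = none).
#' @param noise_sigma additive Gaussian noise SD (0 = none).
#' @param seed optional RNG seed for the noise draw.
#' @return a degraded [mc_image].
#' @export
synth_degrade <- function(image, blur_sigma = 0, noise_sigma = 0, seed = NULL) {
  stopifnot(inherits(image, "mc_image"), blur_sigma >= 0, noise_sigma >= 0)
  with_seed(seed, {
    ch <- lapply(image$channels, function(img) {
      if (blur_sigma > 0) img <- as.matrix(EBImage::gblur(img, sigma = blur_sigma))
      if (noise_sigma > 0)
        img <- img + matrix(rnorm(length(img), 0, noise_sigma),
                            nrow(img), ncol(img))
      pmax(img, 0)
    })
    mc_image(ch, pixel_size = image$pixel_size, image_id = image$image_id,
             patient_id = image$patient_id)
  })
}

#' Specification for a synthetic survival cohort
#'
#' Each patient carries a latent subpopulation fraction drawn from a
#' Beta distribution; survival is exponential with log-hazard linear in
#' that fraction, censoring independent exponential. With 1-6 images per
#' patient this mirrors the shape of a multi-core TMA cohort.
#'
#' @param n_patients number of patients.
#' @param images_per_patient integer range (min, max), inclusive.
#' @param n_cells_range cells per image range.
#' @param image_size pixels per side of each image.
#' @param fraction_shape `c(alpha, beta)` of the Beta distribution of
#'   the planted subpopulation fraction.
#' @param baseline_rate exponential baseline hazard, events/day. The
#'   default gives a median survival of about four years at fraction 0,
#'   in line with a high-grade sarcoma cohort.
#' @param log_hazard_coef log-hazard coefficient on the fraction.
#' @param censor_rate independent exponential censoring rate (0 = no
#'   censoring: every event observed).
#' @param noise_sigma,blur_sigma image degradation passed to the image specs.
#' @param seed integer master seed.
#' @return list of class `synth_cohort_spec`.
#' @export
synth_cohort_spec <- function(n_patients = 50, images_per_patient = c(1, 6),
                              n_cells_range = c(15, 30), image_size = 256,
                              fraction_shape = c(2, 5),
                              baseline_rate = log(2) / 1500,
                              log_hazard_coef = 1.5,
                              censor_rate = 1 / 4000,
                              noise_sigma = 5, blur_sigma = 0, seed = 1L) {
  stopifnot(n_patients >= 1, all(images_per_patient >= 1),
            images_per_patient[1] <= images_per_patient[2],
            baseline_rate > 0, censor_rate >= 0)
  structure(list(n_patients = n_patients,
                 images_per_patient = as.integer(images_per_patient),
                 n_cells_range = n_cells_range, image_size = image_size,
                 fraction_shape = fraction_shape,
                 baseline_rate = baseline_rate,
                 log_hazard_coef = log_hazard_coef,
                 censor_rate = censor_rate, noise_sigma = noise_sigma,
                 blur_sigma = blur_sigma, seed = as.integer(seed)),
            class = "synth_cohort_spec")
}

#' Generate a synthetic cohort: images, ground truth, survival, manifest
#'
#' @param spec a [synth_cohort_spec()].
#' @param render_images if `TRUE` (default) each image is rendered and
#'   returned with its ground truth; if `FALSE` only per-image
#'   ground-truth cell tables are generated (same cell-level sampling
#'   model, no pixel rendering) — convenient for survival-analysis
#'   simulations at scale.
#' @return list with `survival` (data.frame: patient_id, time_days,
#'   event, cohort, true_fraction), `manifest` (image_id, patient_id),
#'   `images` (named list of `synth_image()` results, or `NULL`),
#'   `cells` (one pooled data.frame of per-cell ground truth), `spec`.
#' @export
synth_cohort <- function(spec, render_images = TRUE) {
  stopifnot(inherits(spec, "synth_cohort_spec"))
  with_seed(spec$seed, {
    np <- spec$n_patients
    f <- rbeta(np, spec$fraction_shape[1], spec$fraction_shape[2])
    rate <- spec$baseline_rate * exp(spec$log_hazard_coef * f)
    t_ev <- rexp(np, rate)
    t_cen <- if (spec$censor_rate > 0) rexp(np, spec$censor_rate) else rep(Inf, np)
    time <- pmin(t_ev, t_cen)
    event <- as.integer(t_ev <= t_cen)
    pid <- sprintf("P%03d", seq_len(np))
    surv <- data.frame(patient_id = pid, time_days = time, event = event,
                       cohort = "synthetic", true_fraction = f,
                       stringsAsFactors = FALSE)
    n_img <- sample(spec$images_per_patient[1]:spec$images_per_patient[2],
                    np, replace = TRUE)
    img_seeds <- sample.int(.Machine$integer.max - 1L, sum(n_img))
    manifest <- data.frame(image_id = character(0), patient_id = character(0),
                           stringsAsFactors = FALSE)
    images <- if (render_images) list() else NULL
    cells <- list()
    k <- 0L
    for (i in seq_len(np)) {
      for (j in seq_len(n_img[i])) {
        k <- k + 1L
        iid <- sprintf("%s_img%d", pid[i], j)
        nc <- round(runif(1, spec$n_cells_range[1], spec$n_cells_range[2]))
        ispec <- synth_image_spec(image_size = spec$image_size, n_cells = nc,
                                  subpop_fraction = f[i],
                                  noise_sigma = spec$noise_sigma,
                                  blur_sigma = spec$blur_sigma,
                                  seed = img_seeds[k])
        if (render_images) {
          res <- synth_image(ispec)
          res$image$image_id <- iid; res$image$patient_id <- pid[i]
          images[[iid]] <- res
          tab <- res$truth$cell_table
        } else {
          tab <- synth_cell_table(ispec)
        }
        if (nrow(tab)) {
          tab$image_id <- iid; tab$patient_id <- pid[i]
          cells[[iid]] <- tab
        }
        manifest <- rbind(manifest,
                          data.frame(image_id = iid, patient_id = pid[i],
                                     stringsAsFactors = FALSE))
      }
    }
    list(survival = surv, manifest = manifest, images = images,
         cells = do.call(rbind, c(cells, list(make.row.names = FALSE))),
         spec = spec)
  })
}

# Cell-level ground truth without pixel rendering: same sampling model
# as synth_image (subpopulation draw + cell-to-cell mean variation),
# areas drawn from the ellipse geometry.
synth_cell_table <- function(spec) {
  with_seed(spec$seed, {
    n <- spec$n_cells
    rr <- spec$nucleus_radius_range; tt <- spec$cyto_thickness_range
    r <- runif(n, rr[1], rr[2]); thick <- runif(n, tt[1], tt[2])
    subpop <- runif(n) < spec$subpop_fraction
    area_n <- round(pi * r^2)
    area_c <- round(pi * ((r + thick)^2 - r^2))
    tab <- data.frame(cell = seq_len(n), cx = NA_real_, cy = NA_real_,
                      nucleus_area = area_n, cytoplasm_area = area_c,
                      subpop = subpop)
    for (ch in names(spec$channel_models)) {
      m <- spec$channel_models[[ch]]
      nm <- rep(m$nuclear_mean, n); cm <- rep(m$cyto_mean, n)
      if (!is.null(m$pos_nuclear_mean)) nm[subpop] <- m$pos_nuclear_mean
      if (!is.null(m$pos_cyto_mean)) cm[subpop] <- m$pos_cyto_mean
      dev <- rnorm(n, 0, m$cell_sd)
      tab[[paste0("nuclear_mean_", ch)]] <- pmax(0, nm + dev)
      tab[[paste0("cyto_mean_", ch)]] <- pmax(0, cm + dev)
    }
    # measurement noise on compartment means, SD ~ noise_sigma/sqrt(area)
    if (spec$noise_sigma > 0) {
      for (ch in names(spec$channel_models)) {
        tab[[paste0("nuclear_mean_", ch)]] <-
          pmax(0, tab[[paste0("nuclear_mean_", ch)]] +
                 rnorm(n, 0, spec$noise_sigma / sqrt(pmax(area_n, 1))))
        tab[[paste0("cyto_mean_", ch)]] <-
          pmax(0, tab[[paste0("cyto_mean_", ch)]] +
                 rnorm(n, 0, spec$noise_sigma / sqrt(pmax(area_c, 1))))
      }
    }
    tab
  })
}

#' Write a synthetic cohort to disk
#'
#' Images go to multi-page TIFF (one page per channel), ground-truth
#' label maps to 16-bit TIFF, cell tables / survival / manifest to CSV.
#'
#' @param cohort result of [synth_cohort()] with rendered images.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$survival, file.path(dir, "survival.csv"),
                   row.names = FALSE)
  if (!is.null(cohort$cells))
    utils::write.csv(cohort$cells, file.path(dir, "cells.csv"),
                     row.names = FALSE)
  man <- cohort$manifest
  man$image_path <- NA_character_
  if (!is.null(cohort$images)) {
    for (iid in names(cohort$images)) {
      res <- cohort$images[[iid]]
      path <- file.path(dir, paste0(iid, ".tif"))
      write_mc_tiff(res$image, path)
      for (what in c("nuclear_mask", "cytoplasm_mask"))
        tiff::writeTIFF(res$truth[[what]] / 65535,
                        file.path(dir, paste0(iid, "_", what, ".tif")),
                        bits.per.sample = 16L)
      man$image_path[man$image_id == iid] <- path
    }
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Write / read a multi-channel image as multi-page TIFF
#'
#' One 32-bit float page per channel; channel names stored in the page
#' description tags.
#' @param image an [mc_image].
#' @param path file path.
#' @return `path` invisibly (write); an [mc_image] (read).
#' @export
write_mc_tiff <- function(image, path) {
  pages <- lapply(names(image$channels), function(nm) {
    m <- image$channels[[nm]]
    attr(m, "description") <- nm
    m
  })
  mx <- max(1, vapply(image$channels, max, 0))
  pages <- lapply(pages, function(m) {
    d <- attr(m, "description"); m <- m / mx; attr(m, "description") <- d; m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  # sidecar with channel names + scale so intensities round-trip
  writeLines(jsonlite::toJSON(list(channels = names(image$channels),
                                   scale = mx,
                                   pixel_size = image$pixel_size),
                              auto_unbox = TRUE, digits = NA),
             paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_mc_tiff
#' @export
read_mc_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::fromJSON(readLines(meta_path))
    nms <- meta$channels; sc <- meta$scale; px <- meta$pixel_size
  } else {
    nms <- paste0("ch", seq_along(pages)); sc <- 1; px <- NULL
  }
  ch <- lapply(pages, function(p) unclass(p) * sc)
  names(ch) <- nms
  mc_image(ch, pixel_size = px)
}
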