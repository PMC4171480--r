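#' Apply image quality control to a cohort manifest
#'
#' Filters a manifest by per-image pass/fail decisions. A case stays
#' informative when at least one of its images passes; the returned
#' accounting follows the conservation identities
#' `images_in = images_passed + images_failed` and
#' `cases_informative + cases_eliminated = cases_imaged`.
#'
#' @param manifest data.frame with `image_id` and `patient_id`.
#' @param pass named logical vector (names = image ids) or data.frame
#'   with columns `image_id`, `pass`; every manifest image must be
#'   covered.
#' @return list: filtered `manifest`, `exclusions` (failed images),
#'   `counts` (images_in/passed/failed, cases_imaged, informative,
#'   eliminated, pct_eliminated rounded to integer, fraction_eliminated
#'   exact).
#' @export
qc_filter <- function(manifest, pass) {
  if (is.data.frame(pass)) pass <- setNames(as.logical(pass$pass), pass$image_id)
  missing <- setdiff(manifest$image_id, names(pass))
  if (length(missing))
    stopf("qc_filter: no QC record for image(s): %s",
          paste(utils::head(missing, 3), collapse = ", "))
  p <- pass[manifest$image_id]
  keep <- manifest[p, , drop = FALSE]
  cases <- unique(manifest$patient_id)
  informative <- unique(keep$patient_id)
  counts <- list(images_in = nrow(manifest), images_passed = sum(p),
                 images_failed = sum(!p), cases_imaged = length(cases),
                 cases_informative = length(informative),
                 cases_eliminated = length(cases) - length(informative),
                 fraction_eliminated =
                   (length(cases) - length(informative)) / length(cases),
                 pct_eliminated =
                   round(100 * (length(cases) - length(informative)) /
                           length(cases)))
  list(manifest = keep, exclusions = manifest[!p, , drop = FALSE],
       counts = counts)
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Orchestrates cohort generation (or a pre-built cohort), image
#' quality control, segmentation, cell-feature extraction, per-patient
#' density encoding and — optionally — the cut-point grid and the
#' random survival forest, writing stage outputs to a run directory.
#' Images failing QC are excluded from feature extraction and all
#' downstream analyses; a patient is informative only while at least
#' one image passes.
#'
#' @param config nested list. Recognised blocks: `seed` (integer);
#'   `synth` (arguments of [synth_cohort_spec()]); `qc` (`mode` one of
#'   `"none"`, `"labels"`, `"classifier"`; for `"labels"` a `labels`
#'   data.frame of `image_id`, `label` in good/poor; for
#'   `"classifier"` the same frame is used to train [qc_train()] and
#'   classify every image at P(poor) 0.5); `segment` (arguments of
#'   [segment_nuclei()]); `features` (`columns`, `strata`, `n_grid`);
#'   `cutpoint` (`enabled`, `cd99_centiles`, `ki67_centiles`); `rsf`
#'   (`enabled`, `ntree`, ...); `out_dir` (optional: write CSV/JSON
#'   outputs there). Unknown top-level keys are rejected.
#' @param cohort optionally, a pre-generated [synth_cohort()] result
#'   (overrides the `synth` block).
#' @return list of class `pipeline_run`: `counts` per stage, `qc`,
#'   `cells`, `patient_features`, `survival`, `cutpoint`, `rsf`,
#'   `config`.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  known <- c("seed", "synth", "qc", "segment", "features", "cutpoint",
             "rsf", "out_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) stopf("unknown config key(s): %s",
                             paste(unknown, collapse = ", "))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  if (is.null(cohort))
    cohort <- pipeline_stage("synth", {
      spec <- do.call(synth_cohort_spec,
                      c(config$synth, list(seed = seed)))
      synth_cohort(spec, render_images = TRUE)
    })
  manifest <- cohort$manifest

  # --- quality control ------------------------------------------------
  qc_mode <- if (is.null(config$qc$mode)) "none" else config$qc$mode
  qc_res <- pipeline_stage("qc", {
    feats <- NULL
    if (qc_mode %in% c("classifier") || isTRUE(config$qc$compute_features)) {
      feats <- t(vapply(manifest$image_id, function(iid)
        qc_features(cohort$images[[iid]]$image$channels[["DAPI"]]),
        numeric(12)))
    }
    pass <- switch(qc_mode,
      none = setNames(rep(TRUE, nrow(manifest)), manifest$image_id),
      labels = {
        lab <- config$qc$labels
        if (is.null(lab)) stopf("qc mode 'labels' needs config$qc$labels")
        setNames(lab$label[match(manifest$image_id, lab$image_id)] == "good",
                 manifest$image_id)
      },
      classifier = {
        lab <- config$qc$labels
        if (is.null(lab)) stopf("qc mode 'classifier' needs training labels")
        tr_idx <- match(lab$image_id, manifest$image_id)
        clf <- qc_train(feats[tr_idx, , drop = FALSE], lab$label)
        setNames(predict(clf, feats) < 0.5, manifest$image_id)
      },
      stopf("unknown qc mode '%s'", qc_mode))
    if (anyNA(pass)) stopf("missing QC label for some images")
    c(qc_filter(manifest, pass), list(features = feats))
  })
  manifest <- qc_res$manifest

  # --- segmentation + cell features ----------------------------------
  cells <- pipeline_stage("segment", {
    out <- list()
    for (iid in manifest$image_id) {
      img <- img_preprocess(cohort$images[[iid]]$image,
                            median_radius = config$segment$median_radius %||% 1,
                            gaussian_sigma = config$segment$gaussian_sigma %||% 1)
      seg_args <- config$segment
      seg_args$median_radius <- NULL; seg_args$gaussian_sigma <- NULL
      seg <- do.call(segment_cells, c(list(img), seg_args))
      tab <- extract_cell_features(img, seg)
      if (nrow(tab)) out[[iid]] <- tab
    }
    do.call(rbind, out)
  })
  if (is.null(cells) || !nrow(cells)) stopf("pipeline: no cells segmented")

  # --- patient distribution features ---------------------------------
  pf <- pipeline_stage("features", {
    cols <- config$features$columns %||%
      c("log2_nc_mean_Ki67", "log2_nc_total_Ki67",
        "nuclear_mean_DAPI", "nuclear_total_DAPI")
    patient_density_features(cells, cols,
                             strata = config$features$strata %||%
                               c("all", "CD99+", "CD99-"),
                             n_grid = config$features$n_grid %||% 100)
  })

  surv <- cohort$survival[cohort$survival$patient_id %in% rownames(pf$matrix), ]
  surv <- surv[match(rownames(pf$matrix), surv$patient_id), ]

  # --- optional analyses ----------------------------------------------
  cut_res <- NULL
  if (isTRUE(config$cutpoint$enabled))
    cut_res <- pipeline_stage("cutpoint",
      cutpoint_grid(cells, surv,
                    cd99_centiles = config$cutpoint$cd99_centiles %||% seq(5, 95, 5),
                    ki67_centiles = config$cutpoint$ki67_centiles %||% seq(5, 95, 5)))

  rsf_res <- NULL
  if (isTRUE(config$rsf$enabled))
    rsf_res <- pipeline_stage("rsf", {
      X <- pf$matrix
      ok <- !apply(X, 1, anyNA)
      X <- X[ok, , drop = FALSE]
      X <- X[, apply(X, 2, function(c) sd(c) > 0), drop = FALSE]
      rsf(x = X, time = surv$time_days[ok], event = surv$event[ok],
          ntree = config$rsf$ntree %||% 1000,
          nsplit = config$rsf$nsplit %||% 10, seed = seed + 1L)
    })

  counts <- c(qc_res$counts,
              list(n_cells = nrow(cells),
                   patients_with_features = nrow(pf$matrix),
                   patients_in_rsf = if (is.null(rsf_res)) NA_integer_
                                     else rsf_res$n))
  run <- structure(list(counts = counts,
                        qc = qc_res[c("exclusions", "counts", "features")],
                        cells = cells, patient_features = pf,
                        survival = surv, cutpoint = cut_res, rsf = rsf_res,
                        config = config),
                   class = "pipeline_run")
  if (!is.null(config$out_dir)) write_pipeline_run(run, config$out_dir)
  run
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pipeline_run <- function(x, ...) {
  c_ <- x$counts
  cat("Pipeline run\n")
  cat(sprintf("  images: %d in, %d passed QC, %d failed\n",
              c_$images_in, c_$images_passed, c_$images_failed))
  cat(sprintf("  cases: %d imaged, %d informative, %d eliminated (%d%%)\n",
              c_$cases_imaged, c_$cases_informative, c_$cases_eliminated,
              c_$pct_eliminated))
  cat(sprintf("  cells segmented: %d; patients with features: %d\n",
              c_$n_cells, c_$patients_with_features))
  if (!is.null(x$rsf))
    cat(sprintf("  RSF: %d patients, OOB error %.3f\n", x$rsf$n, x$rsf$oob_error))
  invisible(x)
}

# CSV/JSON outputs for a run directory (config echoed verbatim)
write_pipeline_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$cells, file.path(dir, "cells.csv"), row.names = FALSE)
  pfm <- data.frame(patient_id = rownames(run$patient_features$matrix),
                    run$patient_features$matrix, check.names = FALSE)
  utils::write.csv(pfm, file.path(dir, "patient_features.csv"), row.names = FALSE)
  utils::write.csv(run$survival, file.path(dir, "survival.csv"), row.names = FALSE)
  if (!is.null(run$cutpoint))
    utils::write.csv(run$cutpoint$grid, file.path(dir, "cutpoint_grid.csv"),
                     row.names = FALSE)
  report <- run$counts
  if (!is.null(run$rsf)) report$rsf_oob_error <- run$rsf$oob_error
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA),
             file.path(dir, "report.json"))
  writeLines(jsonlite::toJSON(run$config, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE),
             file.path(dir, "config.json"))
  invisible(dir)
}
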