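#' Univariate Cox proportional-hazards fit
#'
#' One covariate against right-censored survival, Efron ties; returns
#' the coefficient with its Wald z and p value.
#'
#' @param covariate numeric vector, one value per patient.
#' @param time,event survival time (days) and event indicator (1 =
#'   deceased, 0 = censored).
#' @return list: `b`, `se`, `z`, `p`, `n`, `n_events`.
#' @export
cox_fit <- function(covariate, time, event) {
  stopifnot(length(covariate) == length(time), length(time) == length(event))
  if (sum(event) < 2) stopf("cox_fit: need at least 2 events")
  if (length(unique(covariate)) < 2) stopf("cox_fit: constant covariate")
  fit <- survival::coxph(survival::Surv(time, event) ~ covariate,
                         ties = "efron", model = FALSE, x = FALSE, y = FALSE)
  s <- summary(fit)$coefficients
  list(b = unname(s[1, "coef"]), se = unname(s[1, "se(coef)"]),
       z = unname(s[1, "z"]), p = unname(s[1, "Pr(>|z|)"]),
       n = length(time), n_events = sum(event))
}

#' Exhaustive centile-pair cut-point grid of Cox p values
#'
#' For every pair of centile thresholds on the pooled log2
#' nucleus/cytoplasm ratio distributions of CD99 and Ki67, each
#' patient's Ki67 index is recomputed and a univariate Cox model fitted
#' on it; the full grid of (coefficient, z, p) is returned with the
#' minimising pair. No multiplicity correction is applied inside the
#' grid — the module exists to expose the optimism of reporting the
#' grid minimum as if it were a single pre-specified test.
#'
#' @param cells cell-record data.frame with `patient_id` and log2-ratio
#'   columns.
#' @param survival data.frame: `patient_id`, `time_days`, `event`.
#' @param cd99_centiles,ki67_centiles integer centile vectors (default
#'   1..99).
#' @param cd99_col,ki67_col log2-ratio column names.
#' @return list of class `cutpoint_grid`: `grid` data.frame
#'   (centile_cd99, centile_ki67, b, z, p, valid), `optimal` row of the
#'   minimum-p valid cell, `n_patients`.
#' @export
cutpoint_grid <- function(cells, survival,
                          cd99_centiles = 1:99, ki67_centiles = 1:99,
                          cd99_col = "log2_nc_mean_CD99",
                          ki67_col = "log2_nc_mean_Ki67") {
  pid <- as.character(cells$patient_id)
  sv <- survival[match(unique(pid), as.character(survival$patient_id)), ]
  if (anyNA(sv$time_days)) stopf("cutpoint_grid: patients without survival record")
  upid <- unique(pid)
  fpid <- factor(pid, upid)
  cd <- cells[[cd99_col]]; ki <- cells[[ki67_col]]
  cd_thr <- quantile(cd[is.finite(cd)], cd99_centiles / 100, type = 7)
  ki_thr <- quantile(ki[is.finite(ki)], ki67_centiles / 100, type = 7)
  surv_obj <- survival::Surv(sv$time_days, sv$event)
  ki_pos_list <- lapply(ki_thr, function(t) !is.na(ki) & ki > t)
  out <- vector("list", length(cd99_centiles) * length(ki67_centiles))
  r <- 0L
  for (i in seq_along(cd99_centiles)) {
    cd_pos <- !is.na(cd) & cd <= cd_thr[i]
    n_cd <- as.integer(rowsum(as.numeric(cd_pos), fpid))
    for (j in seq_along(ki67_centiles)) {
      r <- r + 1L
      ki_pos <- ki_pos_list[[j]]
      n_both <- as.integer(rowsum(as.numeric(cd_pos & ki_pos), fpid))
      idx <- ifelse(n_cd > 0, n_both / pmax(n_cd, 1), NA_real_)
      ok <- is.finite(idx)
      if (sum(ok) >= 3 && length(unique(idx[ok])) > 1 && sum(sv$event[ok]) >= 2) {
        fit <- tryCatch(
          survival::coxph(surv_obj[ok] ~ idx[ok], ties = "efron",
                          model = FALSE, x = FALSE, y = FALSE),
          error = function(e) NULL, warning = function(w) NULL)
        if (!is.null(fit) && is.finite(sqrt(fit$var[1, 1])) && fit$var[1, 1] > 0) {
          b <- unname(coef(fit)[1]); se <- sqrt(fit$var[1, 1])
          z <- b / se; p <- 2 * pnorm(-abs(z))
          out[[r]] <- c(cd99_centiles[i], ki67_centiles[j], b, z, p, 1)
          next
        }
      }
      out[[r]] <- c(cd99_centiles[i], ki67_centiles[j], NA, NA, NA, 0)
    }
  }
  grid <- as.data.frame(do.call(rbind, out))
  names(grid) <- c("centile_cd99", "centile_ki67", "b", "z", "p", "valid")
  grid$valid <- grid$valid == 1
  opt <- if (any(grid$valid)) grid[grid$valid, ][which.min(grid$p[grid$valid]), ]
         else NULL
  structure(list(grid = grid, optimal = opt, n_patients = length(upid)),
            class = "cutpoint_grid")
}

#' @export
print.cutpoint_grid <- function(x, ...) {
  cat(sprintf("<cutpoint_grid> %d cells (%d valid), %d patients\n",
              nrow(x$grid), sum(x$grid$valid), x$n_patients))
  if (!is.null(x$optimal))
    cat(sprintf("  optimal: CD99 %d%%tile, Ki67 %d%%tile: b = %.3g, z = %.3g, p = %.3g\n",
                x$optimal$centile_cd99, x$optimal$centile_ki67,
                x$optimal$b, x$optimal$z, x$optimal$p))
  invisible(x)
}

#' Heat-map of a cut-point grid's log10 p values
#' @param x a `cutpoint_grid`.
#' @param ... passed to [graphics::image()].
#' @export
plot.cutpoint_grid <- function(x, ...) {
  cd <- sort(unique(x$grid$centile_cd99)); ki <- sort(unique(x$grid$centile_ki67))
  z <- matrix(log10(x$grid$p), length(ki), length(cd))
  graphics::image(ki, cd, z, xlab = "Ki67 centile", ylab = "CD99 centile",
                  main = "Cox p value (log10)", ...)
  if (!is.null(x$optimal))
    graphics::points(x$optimal$centile_ki67, x$optimal$centile_cd99, pch = 0, cex = 2)
  invisible(x)
}

#' Log-rank test over all dichotomised splits of a ranked index
#'
#' Patients are ordered by the index; for every admissible split point
#' (both groups at least `min_group` patients) the two-group log-rank
#' statistic and p value are computed.
#'
#' @param index per-patient numeric index.
#' @param time,event survival.
#' @param min_group minimum patients per group (default 5).
#' @return data.frame: `split` (size of low group), `threshold` (index
#'   value of the last low-group patient), `chisq`, `p`.
#' @export
logrank_all_splits <- function(index, time, event, min_group = 5) {
  n <- length(index)
  stopifnot(length(time) == n, length(event) == n)
  if (n < 2 * min_group) stopf("logrank_all_splits: fewer than 2*min_group patients")
  o <- order(index)
  time <- time[o]; event <- event[o]; idx <- index[o]
  rows <- lapply(min_group:(n - min_group), function(k) {
    grp <- c(rep(0, k), rep(1, n - k))
    sd_ <- survival::survdiff(survival::Surv(time, event) ~ grp)
    data.frame(split = k, threshold = idx[k], chisq = sd_$chisq,
               p = pchisq(sd_$chisq, df = 1, lower.tail = FALSE))
  })
  do.call(rbind, rows)
}

#' Kaplan-Meier curves with Greenwood confidence intervals
#'
#' Product-limit estimate per group with log-transformed Greenwood
#' standard errors (the survival package's default).
#'
#' @param group group label per patient.
#' @param time,event survival.
#' @param conf confidence level.
#' @return data.frame: `group`, `time`, `n_risk`, `n_event`, `surv`,
#'   `lower`, `upper`.
#' @export
kaplan_meier <- function(group, time, event, conf = 0.95) {
  stopifnot(length(group) == length(time))
  fit <- survival::survfit(survival::Surv(time, event) ~ group,
                           conf.int = conf, conf.type = "log")
  smry <- summary(fit, censored = TRUE)
  grp <- if (is.null(smry$strata)) rep(unique(as.character(group)), length(smry$time))
         else sub("^group=", "", as.character(smry$strata))
  data.frame(group = grp, time = smry$time, n_risk = smry$n.risk,
             n_event = smry$n.event, surv = smry$surv,
             lower = smry$lower, upper = smry$upper,
             stringsAsFactors = FALSE)
}
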