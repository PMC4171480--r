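#' Harrell concordance error of a mortality predictor
#'
#' `1 - C`, where C is the fraction of comparable subject pairs whose
#' predicted-risk ordering matches the observed survival ordering. A
#' pair is comparable when the shorter observed time belongs to an
#' event (for tied times, when exactly one of the pair is an event —
#' the event is taken as the shorter); prediction ties count 1/2.
#' 0 is a perfect predictor, 0.5 is chance, 1 perfectly anti-concordant.
#'
#' @param pred predicted mortality (higher = higher risk).
#' @param time,event observed survival.
#' @return error in \[0, 1\].
#' @export
harrell_cindex_error <- function(pred, time, event) {
  n <- length(pred)
  stopifnot(length(time) == n, length(event) == n)
  ok <- is.finite(pred)
  pred <- pred[ok]; time <- time[ok]; event <- event[ok]
  n <- length(pred)
  Ti <- matrix(time, n, n); Tj <- t(Ti)
  Ei <- matrix(event == 1, n, n); Ej <- t(Ei)
  Pi <- matrix(pred, n, n); Pj <- t(Pi)
  comp <- (Ti < Tj & Ei) | (Ti == Tj & Ei & !Ej)   # i is the shorter
  npairs <- sum(comp)
  if (npairs == 0) stopf("harrell_cindex_error: no comparable pairs")
  conc <- sum(comp & (Pi > Pj))
  ties <- sum(comp & (Pi == Pj))
  1 - (conc + 0.5 * ties) / npairs
}

# resolve (x, time, event) from either a formula+data or explicit args
rsf_data <- function(formula, data, x, time, event) {
  if (!is.null(formula)) {
    mf <- model.frame(formula[c(1, 2)], data = data)   # response only
    y <- mf[[1]]
    if (!survival::is.Surv(y)) stopf("response must be a survival::Surv object")
    time <- as.numeric(y[, 1]); event <- as.integer(y[, 2])
    rhs <- all.vars(formula[[3]])
    x <- if (identical(rhs, ".")) {
      resp_vars <- all.vars(formula[[2]])
      data[, setdiff(names(data), resp_vars), drop = FALSE]
    } else data[, rhs, drop = FALSE]
  }
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stopf("feature matrix must be finite (impute or drop missing patients first)")
  stopifnot(length(time) == nrow(x), length(event) == nrow(x))
  if (all(event == 0)) stopf("all subjects censored: cannot fit a survival forest")
  if (sum(event) < 2) stopf("need at least 2 events")
  list(x = x, time = as.numeric(time), event = as.integer(event))
}

#' Fit a random survival forest
#'
#' Bagged survival trees with the "log-rank random" splitting rule: at
#' each node, for each of `mtry` candidate features a small number of
#' random split points (`nsplit`) is evaluated and the split maximising
#' the standardised log-rank statistic is taken, subject to every child
#' retaining at least `min_terminal_events` events. Terminal nodes
#' carry Nelson-Aalen cumulative hazard estimates over the grid of
#' training event times; a subject's predicted mortality is the sum of
#' its ensemble cumulative hazard over that grid, and the out-of-bag
#' (OOB) ensemble gives an unbiased Harrell concordance error.
#'
#' @param formula a `Surv(time, event) ~ .` formula (optional; use `.`
#'   or name the feature columns).
#' @param data data.frame holding the formula variables.
#' @param x,time,event alternative matrix interface: numeric feature
#'   matrix plus survival vectors.
#' @param ntree number of trees (default 1000).
#' @param mtry features tested per split; default `ceiling(p / 3)`.
#' @param nsplit random split points per candidate feature (default 10).
#' @param min_terminal_events minimum events in any node (default 3).
#' @param seed integer; the same seed reproduces the forest exactly.
#' @return an object of class `rsf`: the forest, `oob_mortality`,
#'   `oob_error`, `mortality` (in-bag ensemble), `times` (event-time
#'   grid), parameters and call.
#' @seealso [predict.rsf()], [rsf_vh()], [rsf_cv()],
#'   [harrell_cindex_error()]
#' @export
rsf <- function(formula = NULL, data = NULL, x = NULL, time = NULL,
                event = NULL, ntree = 1000, mtry = NULL, nsplit = 10,
                min_terminal_events = 3, seed = NULL) {
  d <- rsf_data(formula, data, x, time, event)
  p <- ncol(d$x)
  if (is.null(mtry)) mtry <- ceiling(p / 3)
  stopifnot(ntree >= 1, mtry >= 1, mtry <= p, nsplit >= 1,
            min_terminal_events >= 1)
  forest <- with_seed(seed,
    cf_grow_forest(d$x, d$time, d$event, as.integer(ntree),
                   as.integer(mtry), as.integer(nsplit),
                   as.integer(min_terminal_events)))
  oob_use <- matrix(as.integer(forest$inbag == 0), nrow(d$x))
  oob <- cf_ensemble_chf(forest$trees, d$x, oob_use)
  oob_mort <- rowSums(oob$chf)
  oob_error <- harrell_cindex_error(oob_mort, d$time, d$event)
  all_use <- matrix(1L, nrow(d$x), ntree)
  full <- cf_ensemble_chf(forest$trees, d$x, all_use)
  structure(list(forest = forest, feature_names = colnames(d$x),
                 time = d$time, event = d$event,
                 times = as.numeric(forest$grid),
                 oob_mortality = oob_mort, oob_error = oob_error,
                 oob_ntrees = oob$n_trees_used,
                 mortality = rowSums(full$chf),
                 params = list(ntree = ntree, mtry = mtry, nsplit = nsplit,
                               min_terminal_events = min_terminal_events,
                               seed = seed),
                 n = nrow(d$x), call = match.call()),
            class = "rsf")
}

#' @export
print.rsf <- function(x, ...) {
  cat("Random survival forest\n")
  cat(sprintf("  %d subjects (%d events), %d features\n",
              x$n, sum(x$event), length(x$feature_names)))
  cat(sprintf("  %d trees, mtry %d, nsplit %d, min node events %d\n",
              x$params$ntree, x$params$mtry, x$params$nsplit,
              x$params$min_terminal_events))
  cat(sprintf("  OOB concordance error: %.4f\n", x$oob_error))
  invisible(x)
}

#' @export
summary.rsf <- function(object, ...) {
  out <- list(n = object$n, n_events = sum(object$event),
              p = length(object$feature_names), params = object$params,
              oob_error = object$oob_error,
              min_oob_trees = min(object$oob_ntrees))
  class(out) <- "summary.rsf"
  out
}

#' @export
print.summary.rsf <- function(x, ...) {
  cat(sprintf("rsf: n = %d (%d events), p = %d, OOB error = %.4f (every subject OOB for >= %d trees)\n",
              x$n, x$n_events, x$p, x$oob_error, x$min_oob_trees))
  invisible(x)
}

#' Predict mortality and survival curves from a fitted forest
#'
#' The ensemble-averaged cumulative hazard over the training event-time
#' grid gives each subject a predicted survival curve
#' `S(t) = exp(-H(t))` (non-increasing from 1, supported up to the last
#' training event) and a scalar mortality (the sum of the cumulative
#' hazard over the grid).
#'
#' @param object a fitted [rsf()].
#' @param newdata data.frame or matrix containing the training feature
#'   columns (missing columns are an error).
#' @param ... unused.
#' @return list of class `rsf_pred`: `mortality`, `times`, `chf`
#'   (subjects x times), `surv` (= `exp(-chf)`).
#' @export
predict.rsf <- function(object, newdata, ...) {
  nd <- as.matrix(as.data.frame(newdata)[, object$feature_names, drop = FALSE])
  storage.mode(nd) <- "double"
  missing <- setdiff(object$feature_names, colnames(nd))
  if (length(missing)) stopf("newdata lacks feature(s): %s",
                             paste(utils::head(missing, 3), collapse = ", "))
  use <- matrix(1L, nrow(nd), object$params$ntree)
  res <- cf_ensemble_chf(object$forest$trees, nd, use)
  structure(list(mortality = rowSums(res$chf), times = object$times,
                 chf = res$chf, surv = exp(-res$chf)),
            class = "rsf_pred")
}

#' @export
print.rsf_pred <- function(x, ...) {
  cat(sprintf("<rsf_pred> %d subjects, %d event times; mortality range %.3g-%.3g\n",
              nrow(x$chf), length(x$times), min(x$mortality), max(x$mortality)))
  invisible(x)
}

#' Plot predicted survival curves
#' @param x an `rsf_pred` (or an `rsf`, which plots the OOB curves).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.rsf_pred <- function(x, ...) {
  graphics::matplot(x$times, t(x$surv), type = "s", lty = 1,
                    col = grDevices::grey(0.4, 0.4), xlab = "time (days)",
                    ylab = "predicted survival", ylim = c(0, 1), ...)
  invisible(x)
}

#' OOB mortality by outcome
#' @param x a fitted `rsf`.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.rsf <- function(x, ...) {
  graphics::boxplot(x$oob_mortality ~ factor(x$event, c(0, 1),
                                             c("censored", "deceased")),
                    xlab = "", ylab = "OOB predicted mortality", ...)
  invisible(x)
}

#' Minimal depth of each feature over the forest
#'
#' The depth of the first node splitting on a feature, averaged over
#' trees; features never used in a tree are charged that tree's maximum
#' depth + 1. Smaller = more important.
#'
#' @param object a fitted [rsf()].
#' @return named numeric vector, ascending order of the original columns.
#' @export
rsf_min_depth <- function(object) {
  p <- length(object$feature_names)
  total <- numeric(p)
  for (tr in object$forest$trees) {
    nodes <- tr$nodes
    nn <- nrow(nodes)
    depth <- integer(nn)
    # children appear after parents, so one forward pass fixes depths
    for (i in seq_len(nn)) {
      if (nodes[i, 1] >= 0) {
        depth[nodes[i, 2] + 1] <- depth[i] + 1
        depth[nodes[i, 3] + 1] <- depth[i] + 1
      }
    }
    md <- rep(NA_integer_, p)
    for (i in seq_len(nn)) {
      v <- nodes[i, 1]
      if (v >= 0 && (is.na(md[v + 1]) || depth[i] < md[v + 1]))
        md[v + 1] <- depth[i]
    }
    md[is.na(md)] <- max(depth) + 1L
    total <- total + md
  }
  out <- total / length(object$forest$trees)
  names(out) <- object$feature_names
  out
}

#' Variable hunting: repeated-partition forward feature selection
#'
#' Each iteration draws a fresh random 80/20 train/test partition,
#' ranks the candidate features by minimal depth in a forest grown on
#' the training part, then forward-introduces features in rank order,
#' refitting the forest and keeping a feature only while the internal
#' 20%-test concordance error improves; selection stops at the first
#' non-improving feature. Because iterations are independent, the
#' importance of a feature is measured by how frequently it was
#' selected across iterations.
#'
#' @inheritParams rsf
#' @param n_iter number of independent iterations (default 100).
#' @param test_frac held-out fraction within each iteration (default 0.2).
#' @param ntree trees per forest inside the procedure (reduced from the
#'   final-model default for tractability).
#' @param max_features cap on the number of ranked candidates offered
#'   to the forward pass.
#' @return object of class `rsf_vh`: `counts` (named selection counts,
#'   sorted by descending count, ties broken alphabetically), `ranking`
#'   (feature names in that order), `iterations` (list of per-iteration
#'   `selected` and `test_error`), `n_iter`.
#' @export
rsf_vh <- function(formula = NULL, data = NULL, x = NULL, time = NULL,
                   event = NULL, n_iter = 100, test_frac = 0.2,
                   ntree = 100, mtry = NULL, nsplit = 10,
                   min_terminal_events = 3, max_features = 25,
                   seed = NULL) {
  d <- rsf_data(formula, data, x, time, event)
  n <- nrow(d$x); p <- ncol(d$x)
  counts <- setNames(integer(p), colnames(d$x))
  iterations <- vector("list", n_iter)
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      repeat {
        test_idx <- sample.int(n, max(1, round(test_frac * n)))
        train_idx <- setdiff(seq_len(n), test_idx)
        if (sum(d$event[train_idx]) >= 2 && sum(d$event[test_idx]) >= 1) break
      }
      rank_fit <- rsf(x = d$x[train_idx, , drop = FALSE],
                      time = d$time[train_idx], event = d$event[train_idx],
                      ntree = ntree, mtry = mtry, nsplit = nsplit,
                      min_terminal_events = min_terminal_events)
      ranking <- names(sort(rsf_min_depth(rank_fit)))
      ranking <- utils::head(ranking, max_features)
      selected <- character(0)
      best_err <- Inf
      for (f in ranking) {
        cand <- c(selected, f)
        fit <- rsf(x = d$x[train_idx, cand, drop = FALSE],
                   time = d$time[train_idx], event = d$event[train_idx],
                   ntree = ntree, mtry = min(length(cand), max(1, ceiling(length(cand) / 3))),
                   nsplit = nsplit, min_terminal_events = min_terminal_events)
        pr <- predict(fit, d$x[test_idx, cand, drop = FALSE])
        err <- tryCatch(harrell_cindex_error(pr$mortality, d$time[test_idx],
                                             d$event[test_idx]),
                        error = function(e) Inf)
        if (err < best_err) { selected <- cand; best_err <- err } else break
      }
      counts[selected] <- counts[selected] + 1L
      iterations[[it]] <- list(selected = selected, test_error = best_err)
    }
  })
  ord <- order(-counts, names(counts))
  structure(list(counts = counts[ord], ranking = names(counts)[ord],
                 iterations = iterations, n_iter = n_iter),
            class = "rsf_vh")
}

#' @export
print.rsf_vh <- function(x, ...) {
  cat(sprintf("Variable hunting over %d iterations; top selections:\n", x$n_iter))
  top <- utils::head(x$counts[x$counts > 0], 10)
  for (i in seq_along(top))
    cat(sprintf("  %3d/%d  %s\n", top[i], x$n_iter, names(top)[i]))
  invisible(x)
}

#' Plot variable-hunting selection frequencies
#' @param x an `rsf_vh`.
#' @param top_n number of features to show.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.rsf_vh <- function(x, top_n = 20, ...) {
  top <- utils::head(x$counts, top_n)
  graphics::barplot(rev(top), horiz = TRUE, las = 1,
                    xlab = sprintf("selections out of %d iterations", x$n_iter),
                    ...)
  invisible(x)
}

#' Randomised cross-validation of the forest (with optional selection)
#'
#' Repeatedly partitions the cohort into a two-thirds training and
#' one-third test set, fits the forest on the training part (optionally
#' running variable hunting confined to the training part first) and
#' scores the test-set concordance error; the mean and SD over
#' repetitions summarise expected out-of-sample performance.
#'
#' @inheritParams rsf
#' @param n_rep repetitions (default 50).
#' @param train_frac training fraction (default 2/3).
#' @param vh run [rsf_vh()] inside each training partition and fit on
#'   the selected features only.
#' @param vh_args list of arguments forwarded to [rsf_vh()].
#' @return object of class `rsf_cv`: `errors` (length `n_rep`), `mean`,
#'   `sd`, `n_rep`, `vh`.
#' @export
rsf_cv <- function(formula = NULL, data = NULL, x = NULL, time = NULL,
                   event = NULL, n_rep = 50, train_frac = 2 / 3,
                   vh = FALSE, vh_args = list(), ntree = 1000, mtry = NULL,
                   nsplit = 10, min_terminal_events = 3, seed = NULL) {
  d <- rsf_data(formula, data, x, time, event)
  n <- nrow(d$x)
  errors <- numeric(n_rep)
  with_seed(seed, {
    for (r in seq_len(n_rep)) {
      repeat {
        train_idx <- sample.int(n, round(train_frac * n))
        test_idx <- setdiff(seq_len(n), train_idx)
        if (sum(d$event[train_idx]) >= 2 && sum(d$event[test_idx]) >= 1) break
      }
      cols <- colnames(d$x)
      if (vh) {
        vh_res <- do.call(rsf_vh, c(list(x = d$x[train_idx, , drop = FALSE],
                                         time = d$time[train_idx],
                                         event = d$event[train_idx]),
                                    vh_args))
        sel <- unique(unlist(lapply(vh_res$iterations, `[[`, "selected")))
        if (length(sel)) cols <- sel
      }
      fit <- rsf(x = d$x[train_idx, cols, drop = FALSE],
                 time = d$time[train_idx], event = d$event[train_idx],
                 ntree = ntree,
                 mtry = if (is.null(mtry)) NULL else min(mtry, length(cols)),
                 nsplit = nsplit, min_terminal_events = min_terminal_events)
      pr <- predict(fit, d$x[test_idx, cols, drop = FALSE])
      errors[r] <- harrell_cindex_error(pr$mortality, d$time[test_idx],
                                        d$event[test_idx])
    }
  })
  structure(list(errors = errors, mean = mean(errors), sd = sd(errors),
                 n_rep = n_rep, vh = vh),
            class = "rsf_cv")
}

#' @export
print.rsf_cv <- function(x, ...) {
  cat(sprintf("Randomised cross-validation (%d repetitions%s): error %.3f +/- %.3f (SD)\n",
              x$n_rep, if (x$vh) ", variable hunting" else "", x$mean, x$sd))
  invisible(x)
}

#' Partial-dependence mortality profile of one feature
#'
#' Predicted relative mortality as a function of one feature: the
#' feature column is swept over a grid of its observed range while all
#' other features keep their observed values, averaging the predicted
#' mortality at each grid point. A constant feature yields a
#' single-point (flat) profile.
#'
#' @param object a fitted [rsf()]; requires the training matrix.
#' @param x training feature matrix (rows as used in the fit).
#' @param feature feature name.
#' @param n_points grid resolution.
#' @return data.frame: `value`, `mortality`.
#' @export
mortality_profile <- function(object, x, feature, n_points = 25) {
  stopifnot(inherits(object, "rsf"))
  x <- as.matrix(x)
  if (!feature %in% object$feature_names) stopf("unknown feature '%s'", feature)
  rng <- range(x[, feature])
  grid <- if (rng[1] == rng[2]) rng[1] else seq(rng[1], rng[2], length.out = n_points)
  mort <- vapply(grid, function(v) {
    xv <- x
    xv[, feature] <- v
    mean(predict(object, xv)$mortality)
  }, 0)
  data.frame(value = grid, mortality = mort)
}
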