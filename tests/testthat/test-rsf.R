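test_that("concordance error is exact for perfect and reversed predictors", {
  set.seed(1)
  time <- sample(seq(100, 2000, 100), 20)
  event <- rep(1L, 20)
  pred <- rank(-time)                       # reverse rank of survival time
  expect_equal(harrell_cindex_error(pred, time, event), 0)
  expect_equal(harrell_cindex_error(-pred, time, event), 1)
  expect_equal(harrell_cindex_error(rep(3, 20), time, event), 0.5)
  expect_error(harrell_cindex_error(1:3, c(5, 5, 5), c(0, 0, 0)), "comparable")
})

test_that("concordance error equals brute-force pair enumeration on random instances", {
  set.seed(2)
  for (k in 1:100) {
    n <- sample(3:12, 1)
    time <- sample(1:6, n, replace = TRUE)        # heavy ties
    event <- rbinom(n, 1, 0.6)
    pred <- sample(seq_len(4), n, replace = TRUE) # prediction ties too
    ok <- tryCatch(harrell_cindex_error(pred, time, event),
                   error = function(e) NA_real_)
    if (is.na(ok)) next                           # no comparable pairs
    expect_equal(ok, brute_cindex_error(pred, time, event))
  }
})

test_that("identical seeds reproduce the forest, its OOB error and predictions", {
  set.seed(3)
  n <- 60; x <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("f", 1:5)))
  sv <- signal_survival(x[, 1], 1, seed = 4)
  f1 <- rsf(x = x, time = sv$time, event = sv$event, ntree = 50, seed = 9)
  f2 <- rsf(x = x, time = sv$time, event = sv$event, ntree = 50, seed = 9)
  expect_identical(f1$oob_error, f2$oob_error)
  expect_identical(predict(f1, x)$mortality, predict(f2, x)$mortality)
  f3 <- rsf(x = x, time = sv$time, event = sv$event, ntree = 50, seed = 10)
  expect_false(identical(f1$oob_error, f3$oob_error))
})

test_that("a single-tree forest predicts its own terminal-node curve for training subjects", {
  set.seed(5)
  n <- 40; x <- matrix(rnorm(n * 3), n, dimnames = list(NULL, paste0("f", 1:3)))
  sv <- signal_survival(x[, 1], 1.5, seed = 6)
  fit <- rsf(x = x, time = sv$time, event = sv$event, ntree = 1, seed = 7)
  tr <- fit$forest$trees[[1]]
  # independent R-side traversal of the stored tree
  descend <- function(i) {
    node <- 1
    while (tr$nodes[node, 1] >= 0) {
      node <- if (x[i, tr$nodes[node, 1] + 1] <= tr$split_val[node])
        tr$nodes[node, 2] + 1 else tr$nodes[node, 3] + 1
    }
    tr$nodes[node, 4] + 1
  }
  pr <- predict(fit, x)
  for (i in c(1, 17, 40))
    expect_equal(pr$chf[i, ], unname(tr$chf[descend(i), ]))
  # survival curves are proper non-increasing functions in [0, 1]
  expect_true(all(pr$surv >= 0 & pr$surv <= 1))
  expect_true(all(apply(pr$surv, 1, function(s) all(diff(s) <= 1e-12))))
})

test_that("every subject is out of bag for some trees at realistic forest sizes", {
  set.seed(11)
  n <- 50; x <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("f", 1:4)))
  sv <- null_survival(n, seed = 12)
  fit <- rsf(x = x, time = sv$time, event = sv$event, ntree = 200, seed = 13)
  expect_true(all(fit$oob_ntrees > 0))
  expect_true(all(is.finite(fit$oob_mortality)) && all(fit$oob_mortality >= 0))
})

test_that("a planted prognostic feature pulls the OOB error well below chance", {
  set.seed(15)
  n <- 120
  x <- matrix(rnorm(n * 10), n, dimnames = list(NULL, paste0("f", 1:10)))
  sv <- signal_survival(x[, 1], 2, seed = 16)
  fit <- rsf(x = x, time = sv$time, event = sv$event, ntree = 300, seed = 17)
  expect_lte(fit$oob_error, 0.45)
  # duplicating every feature leaves the error essentially unchanged
  xx <- cbind(x, x); colnames(xx) <- paste0("g", seq_len(20))
  fit2 <- rsf(x = xx, time = sv$time, event = sv$event, ntree = 300, seed = 17)
  expect_lt(abs(fit2$oob_error - fit$oob_error), 0.05)
})

test_that("forest OOB error agrees with an independent survival-forest implementation", {
  skip_if_not_installed("ranger")
  set.seed(19)
  n <- 150
  x <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("f", 1:5)))
  sv <- signal_survival(x[, 1], 1.5, seed = 20)
  fit <- rsf(x = x, time = sv$time, event = sv$event, ntree = 500, seed = 21)
  df <- data.frame(time = sv$time, status = sv$event, x)
  rg <- ranger::ranger(survival::Surv(time, status) ~ ., data = df,
                       num.trees = 500, seed = 21)
  expect_lt(abs(fit$oob_error - rg$prediction.error), 0.1)
})

test_that("variable hunting records iterations and finds a strongly planted feature", {
  set.seed(23)
  n <- 100
  x <- matrix(rnorm(n * 15), n, dimnames = list(NULL, paste0("f", 1:15)))
  sv <- signal_survival(x[, 7], 2, seed = 24)
  vh1 <- rsf_vh(x = x, time = sv$time, event = sv$event, n_iter = 1,
                ntree = 50, seed = 25)
  expect_length(vh1$iterations, 1)
  expect_true(length(vh1$iterations[[1]]$selected) >= 1)
  expect_equal(sum(vh1$counts), length(vh1$iterations[[1]]$selected))
  vh <- rsf_vh(x = x, time = sv$time, event = sv$event, n_iter = 10,
               ntree = 50, max_features = 8, seed = 26)
  expect_equal(names(vh$counts)[1], "f7")
  expect_true(all(vh$counts <= 10))
})

test_that("cross-validation returns the configured repetitions with sane errors", {
  set.seed(27)
  n <- 90
  x <- matrix(rnorm(n * 8), n, dimnames = list(NULL, paste0("f", 1:8)))
  sv <- signal_survival(x[, 1], 2, seed = 28)
  cv <- rsf_cv(x = x, time = sv$time, event = sv$event, n_rep = 5,
               ntree = 150, seed = 29)
  expect_length(cv$errors, 5)
  expect_true(all(cv$errors >= 0 & cv$errors <= 1))
  expect_lt(cv$mean, 0.45)
})

test_that("mortality profiles are monotone for a planted monotone-risk feature and flat for noise", {
  set.seed(31)
  n <- 120
  x <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("f", 1:5)))
  sv <- signal_survival(x[, 1], 2, seed = 32)
  fit <- rsf(x = x, time = sv$time, event = sv$event, ntree = 300, seed = 33)
  prof <- mortality_profile(fit, x, "f1")
  expect_gte(cor(prof$value, prof$mortality, method = "spearman"), 0.8)
  noise_prof <- mortality_profile(fit, x, "f3")
  expect_lt(diff(range(noise_prof$mortality)),
            0.25 * diff(range(prof$mortality)))
  const <- x; const[, 2] <- 1
  expect_equal(nrow(mortality_profile(fit, const, "f2")), 1)
  expect_error(mortality_profile(fit, x, "nope"), "unknown feature")
})

test_that("predicted-mortality halves of a test set separate in survival", {
  set.seed(35)
  n <- 160
  x <- matrix(rnorm(n * 6), n, dimnames = list(NULL, paste0("f", 1:6)))
  sv <- signal_survival(x[, 1], 2, seed = 36)
  tr <- 1:110; te <- 111:160
  fit <- rsf(x = x[tr, ], time = sv$time[tr], event = sv$event[tr],
             ntree = 300, seed = 37)
  pr <- predict(fit, x[te, ])
  grp <- pr$mortality > median(pr$mortality)
  sd_ <- survival::survdiff(survival::Surv(sv$time[te], sv$event[te]) ~ grp)
  expect_lt(pchisq(sd_$chisq, 1, lower.tail = FALSE), 0.05)
})

test_that("the formula interface matches the matrix interface", {
  set.seed(39)
  n <- 50
  d <- data.frame(t = rexp(n, 0.01), e = rbinom(n, 1, 0.8),
                  a = rnorm(n), b = rnorm(n))
  f1 <- rsf(survival::Surv(t, e) ~ ., data = d, ntree = 30, seed = 40)
  f2 <- rsf(x = d[, c("a", "b")], time = d$t, event = d$e, ntree = 30,
            seed = 40)
  expect_equal(f1$oob_error, f2$oob_error)
  expect_error(rsf(x = d[, 3:4], time = d$t, event = rep(0, n)), "censored")
})
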