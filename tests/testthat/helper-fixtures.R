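# Shared fixtures, built in code and memoised for the session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# clean, noiseless, disjoint-cell image: segmentation / feature oracle
clean_image <- function() fixture("clean_image", function() {
  spec <- synth_image_spec(image_size = 256, n_cells = 6,
                           nucleus_radius_range = c(8, 10),
                           cyto_thickness_range = c(4, 5),
                           overlap_fraction = 0, subpop_fraction = 0.5,
                           noise_sigma = 0, blur_sigma = 0, seed = 11L)
  synth_image(spec)
})

# exponential null survival independent of everything
null_survival <- function(n, seed, base_rate = 1e-3, censor_rate = 5e-4) {
  set.seed(seed)
  t_ev <- rexp(n, base_rate)
  t_cn <- rexp(n, censor_rate)
  list(time = pmin(t_ev, t_cn), event = as.integer(t_ev <= t_cn))
}

# survival driven by one standard-normal feature with log-hazard b
signal_survival <- function(x1, b, seed, base_rate = 1e-3, censor_rate = 3e-4) {
  set.seed(seed)
  t_ev <- rexp(length(x1), base_rate * exp(b * x1))
  t_cn <- rexp(length(x1), censor_rate)
  list(time = pmin(t_ev, t_cn), event = as.integer(t_ev <= t_cn))
}

# brute-force Harrell concordance error: direct pair enumeration under
# the package's stated comparability convention
brute_cindex_error <- function(pred, time, event) {
  n <- length(pred)
  num <- 0; den <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    comparable <- (time[i] < time[j] && event[i] == 1) ||
      (time[i] == time[j] && event[i] == 1 && event[j] == 0)
    if (!comparable) next            # i is the shorter survivor
    den <- den + 1
    if (pred[i] > pred[j]) num <- num + 1
    else if (pred[i] == pred[j]) num <- num + 0.5
  }
  1 - num / den
}

# synthetic cell table for feature/cutpoint tests: per-patient cells
# with log2 N/C ratio columns and a CD99 flag, no imaging involved
make_cells <- function(n_patients, cells_per_patient, seed,
                       ki67_shift = 0, shift_fraction = 0) {
  set.seed(seed)
  out <- list()
  for (p in seq_len(n_patients)) {
    n <- cells_per_patient
    shifted <- runif(n) < shift_fraction
    out[[p]] <- data.frame(
      patient_id = sprintf("P%03d", p),
      cd99_positive = runif(n) < 0.6,
      log2_nc_mean_CD99 = rnorm(n),
      log2_nc_mean_Ki67 = rnorm(n) + ifelse(shifted, ki67_shift, 0))
  }
  do.call(rbind, out)
}
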