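#' @useDynLib cellforest, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import stats
NULL

# Run code under a temporarily-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Jaccard overlap of two binary masks
jaccard <- function(a, b) {
  a <- a > 0; b <- b > 0
  u <- sum(a | b)
  if (u == 0) return(NA_real_)
  sum(a & b) / u
}

# Sequentially relabel a label map (positive labels -> 1..k, keep order)
relabel <- function(lab) {
  u <- sort(unique(lab[lab > 0]))
  if (!length(u)) return(lab)
  out <- lab
  out[lab > 0] <- match(lab[lab > 0], u)
  out
}

#' Multi-channel image container
#'
#' Bundles named 2-D intensity channels sharing one pixel grid, with
#' optional pixel size (micrometres per pixel) and identifiers.
#'
#' @param channels named list of numeric matrices, identical dimensions,
#'   finite and non-negative.
#' @param pixel_size micrometres per pixel (scalar, optional).
#' @param image_id,patient_id identifiers carried through the pipeline.
#' @return An object of class `mc_image`.
#' @export
mc_image <- function(channels, pixel_size = NULL, image_id = NA_character_,
                     patient_id = NA_character_) {
  if (!is.list(channels) || is.null(names(channels)) || any(names(channels) == ""))
    stopf("channels must be a named list of matrices")
  dims <- lapply(channels, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stopf("all channels must share dimensions")
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!is.matrix(ch) || !is.numeric(ch)) stopf("channel '%s' is not a numeric matrix", nm)
    if (any(!is.finite(ch)) || any(ch < 0)) stopf("channel '%s' has non-finite or negative intensities", nm)
  }
  structure(list(channels = channels, pixel_size = pixel_size,
                 image_id = image_id, patient_id = patient_id),
            class = "mc_image")
}

#' @export
print.mc_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<mc_image> %dx%d px, channels: %s\n", d[1], d[2],
              paste(names(x$channels), collapse = ", ")))
  if (!is.null(x$pixel_size)) cat(sprintf("  pixel size: %g um/px\n", x$pixel_size))
  invisible(x)
}

#' @export
`[[.mc_image` <- function(x, i) x$channels[[i]]
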