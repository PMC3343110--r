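#' Normal + exponential background correction
#'
#' Replaces each raw intensity by the posterior expected true signal under the
#' convolution model observed = background + signal, with Gaussian background
#' `N(mu, sigma^2)` and exponential signal with mean `1/rate`. Outputs are
#' strictly positive and monotone non-decreasing in the input within each
#' array. Parameters can be supplied per array or estimated by a simple
#' moments fit.
#'
#' @param m Raw-scale matrix (probes x samples).
#' @param par Optional data.frame/matrix with one row per array and columns
#'   `mu`, `sigma`, `rate`. When `NULL`, parameters are estimated per array by
#'   [estimate_normexp_params()].
#' @return Corrected raw-scale matrix.
#' @export
normexp_background_correct <- function(m, par = NULL) {
  if (!is.matrix(m)) m <- as.matrix(m)
  if (any(!is.finite(m))) stop("matrix contains non-finite values", call. = FALSE)
  out <- m
  for (j in seq_len(ncol(m))) {
    pj <- if (is.null(par)) estimate_normexp_params(m[, j]) else
      list(mu = par$mu[j], sigma = par$sigma[j], rate = par$rate[j])
    if (!is.finite(pj$rate) || pj$rate <= 0)
      stop("signal rate must be positive (array ", j, ")", call. = FALSE)
    if (pj$sigma < 0) stop("background sd must be >= 0 (array ", j, ")",
                           call. = FALSE)
    # limma parameterisation: (mu, log sigma, log alpha) with alpha = 1/rate
    lp <- c(pj$mu, log(max(pj$sigma, 1e-8)), log(1 / pj$rate))
    out[, j] <- limma::normexp.signal(lp, m[, j])
  }
  attr(out, "scale") <- "raw"
  out
}

#' Moments-based estimate of normal + exponential parameters
#'
#' Background mean/sd from the lower half of the intensity distribution
#' (assumed signal-poor), exponential mean from the excess of the overall
#' mean over the background mean.
#'
#' @param x Raw intensities of one array.
#' @return List with `mu`, `sigma`, `rate`.
#' @export
estimate_normexp_params <- function(x) {
  mu <- stats::median(x)
  lower <- x[x <= mu]
  sigma <- sqrt(mean((lower - mu)^2)) * sqrt(2)  # half-normal correction
  alpha <- max(mean(x) - mu, sigma / 2, 1e-6)
  list(mu = mu, sigma = max(sigma, 1e-6), rate = 1 / alpha)
}

#' Log2 transform
#'
#' @param m Raw-scale matrix.
#' @param offset Added before taking log2 (guards background-subtracted
#'   intensities that dip below zero; the bead-array pipeline uses 16).
#' @return Log2-scale matrix.
#' @export
log2_transform <- function(m, offset = 0) {
  out <- log2(m + offset)
  if (any(!is.finite(out)))
    stop("log2 transform produced non-finite values; increase the offset",
         call. = FALSE)
  attr(out, "scale") <- "log2"
  out
}

#' Inverse of [log2_transform()]
#' @param m Log2-scale matrix.
#' @param offset Offset used in the forward transform.
#' @return Raw-scale matrix.
#' @export
log2_inverse <- function(m, offset = 0) {
  out <- 2^m - offset
  attr(out, "scale") <- "raw"
  out
}

#' Quantile normalisation
#'
#' Forces every column to the same distribution: the rank-wise mean across
#' columns. Ties within a column receive the mean of the reference values
#' they span. Idempotent; preserves row order; a single-column matrix is
#' returned unchanged.
#'
#' @param m Matrix with no missing values (any scale; typically log2).
#' @return Normalised matrix of the same dimensions.
#' @export
quantile_normalize <- function(m) {
  if (!is.matrix(m)) m <- as.matrix(m)
  if (anyNA(m)) stop("matrix contains missing values", call. = FALSE)
  if (ncol(m) < 2L) return(m)
  n <- nrow(m)
  sorted <- apply(m, 2L, sort)
  ref <- rowMeans(sorted)
  cs <- c(0, cumsum(ref))
  out <- m
  for (j in seq_len(ncol(m))) {
    lo <- rank(m[, j], ties.method = "min")
    hi <- rank(m[, j], ties.method = "max")
    # a tie spanning ranks lo..hi takes the mean of the reference values spanned
    out[, j] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  attributes(out)$dimnames <- dimnames(m)
  attr(out, "scale") <- attr(m, "scale")
  out
}

#' Remove probes absent in every sample (bead-array rule)
#'
#' Keeps exactly the probes called present (detection p below
#' `detection_alpha`, or logical `TRUE`) in at least one sample.
#'
#' @param m Expression matrix (probes x samples).
#' @param detection Matrix of the same shape: logical present calls or
#'   detection p-values.
#' @param detection_alpha Present-call threshold for p-value input.
#' @return The filtered matrix.
#' @export
filter_absent_illumina <- function(m, detection, detection_alpha = 0.01) {
  if (!all(dim(m) == dim(detection)))
    stop("detection matrix shape does not match expression matrix",
         call. = FALSE)
  present <- if (is.logical(detection)) detection else detection < detection_alpha
  keep <- rowSums(present) >= 1L
  out <- m[keep, , drop = FALSE]
  attr(out, "scale") <- attr(m, "scale")
  out
}

#' Keep probes expressed above the array median (25-mer array rule)
#'
#' A probe is retained iff, for at least one condition, its intensity strictly
#' exceeds the per-array median (over all probes) in at least half of that
#' condition's arrays (half rounded up for odd counts).
#'
#' @param m Expression matrix (probes x samples).
#' @param condition_of_sample Named vector mapping sample (column) ids to
#'   condition labels.
#' @return The filtered matrix.
#' @export
filter_present_affymetrix <- function(m, condition_of_sample) {
  cond <- condition_of_sample[colnames(m)]
  if (anyNA(cond)) stop("conditions missing for some samples", call. = FALSE)
  if (any(table(cond) == 0L)) stop("empty condition", call. = FALSE)
  med <- apply(m, 2L, stats::median)
  above <- sweep(m, 2L, med, ">")
  keep <- rep(FALSE, nrow(m))
  for (cc in unique(cond)) {
    cols <- which(cond == cc)
    keep <- keep | rowSums(above[, cols, drop = FALSE]) >= ceiling(length(cols) / 2)
  }
  out <- m[keep, , drop = FALSE]
  attr(out, "scale") <- attr(m, "scale")
  out
}
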