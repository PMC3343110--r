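#' MA table
#'
#' Per-probe average log2 expression (A) and log2 fold change (M) — the
#' numeric content of an MA plot.
#'
#' @param results Data.frame from [de_analysis()] / [fit_two_group()].
#' @return Data.frame with `probe_id`, `A`, `M`.
#' @export
ma_table <- function(results) {
  data.frame(probe_id = results$probe_id, A = results$A, M = results$log_fc,
             stringsAsFactors = FALSE)
}

#' Wilcoxon / Mann-Whitney rank-sum test
#'
#' Two-sided rank-sum test with midranks for ties. For small totals
#' (`n_a + n_b <= exact_threshold`) the p-value is exact, computed by dynamic-
#' programming enumeration of the permutation distribution of the rank sum
#' (valid under ties); otherwise a normal approximation with tie correction
#' and continuity correction is used.
#'
#' @param a,b Numeric vectors (e.g. per-probe log fold changes of two probe
#'   populations).
#' @param exact_threshold Largest pooled size for which the exact distribution
#'   is enumerated.
#' @return Object of class `retro_ranksum`: list with `n_a`, `n_b`, `U`
#'   (statistic for group a), `p_two_sided`, `method`.
#' @export
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p_two_sided  # 0.1
rank_sum_test <- function(a, b, exact_threshold = 30L) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty", call. = FALSE)
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))  # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n <= exact_threshold) {
    p <- ranksum_exact_p(r, n1, U)
    method <- "exact"
  } else {
    p <- ranksum_normal_p(r, n1, n2, U)
    method <- "normal_approx"
  }
  structure(list(n_a = n1, n_b = n2, U = U, p_two_sided = p, method = method),
            class = "retro_ranksum")
}

# exact permutation distribution of the group-a rank sum via subset-sum DP
# over doubled (integer) midranks; counts every C(n, n1) assignment
ranksum_exact_p <- function(r, n1, U) {
  d <- as.integer(round(2 * r))
  n <- length(d)
  smax <- sum(sort(d, decreasing = TRUE)[seq_len(n1)])
  f <- matrix(0, nrow = n1 + 1L, ncol = smax + 1L)  # f[k+1, s+1]
  f[1L, 1L] <- 1
  for (x in d) {
    kmax <- n1
    for (k in seq(kmax, 1L)) {
      idx <- seq_len(smax + 1L - x)
      f[k + 1L, idx + x] <- f[k + 1L, idx + x] + f[k, idx]
    }
  }
  counts <- f[n1 + 1L, ]
  total <- sum(counts)
  # observed doubled rank sum for group a
  s_obs <- as.integer(round(2 * (U + n1 * (n1 + 1) / 2)))
  sums <- seq(0L, smax)
  p_le <- sum(counts[sums <= s_obs]) / total
  p_ge <- sum(counts[sums >= s_obs]) / total
  min(1, 2 * min(p_le, p_ge))
}

ranksum_normal_p <- function(r, n1, n2, U) {
  n <- n1 + n2
  ties <- table(r)
  correction <- sum(ties^3 - ties) / (n * (n - 1))
  v <- n1 * n2 / 12 * ((n + 1) - correction)
  if (v <= 0) return(1)
  mu <- n1 * n2 / 2
  z <- (U - mu - 0.5 * sign(U - mu)) / sqrt(v)
  if (U == mu) z <- 0
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' @export
print.retro_ranksum <- function(x, ...) {
  cat(sprintf("rank-sum test (%s): n = %d vs %d, U = %g, two-sided p = %.4g\n",
              x$method, x$n_a, x$n_b, x$U, x$p_two_sided))
  invisible(x)
}

#' Gaussian kernel density estimate
#'
#' Density evaluated on a regular grid spanning the data plus three
#' bandwidths on each side. The automatic bandwidth is Silverman's
#' rule of thumb.
#'
#' @param values Numeric vector (n >= 2 for automatic bandwidth).
#' @param bandwidth Positive bandwidth, or `"auto"`.
#' @param n_grid Number of grid points.
#' @return Data.frame with `x` and `y`; the bandwidth used is in
#'   `attr(, "bandwidth")`.
#' @export
density_estimate <- function(values, bandwidth = "auto", n_grid = 512L) {
  if (identical(bandwidth, "auto")) {
    if (length(values) < 2L)
      stop("automatic bandwidth needs at least 2 values", call. = FALSE)
    bandwidth <- stats::bw.nrd0(values)
  }
  if (!is.numeric(bandwidth) || bandwidth <= 0)
    stop("bandwidth must be positive", call. = FALSE)
  d <- stats::density(values, bw = bandwidth, kernel = "gaussian",
                      cut = 3, n = n_grid)
  out <- data.frame(x = d$x, y = d$y)
  attr(out, "bandwidth") <- bandwidth
  out
}

#' Compare repeat probe populations against baseline populations
#'
#' For each selector (an element, family or class of repeats), tests whether
#' that group's log fold changes form a distinct population from the expressed
#' non-repeat probes; element selectors are additionally tested against their
#' enclosing family and class populations (excluding the element itself).
#' Only sense-detecting repeat probes are grouped.
#'
#' @param de Differential results ([de_analysis()]).
#' @param annotations Probe annotation ([annotate_platform()]).
#' @param group_specs List of one-element named lists, e.g.
#'   `list(list(element = "MMERVK10C-int"), list(repeat_class = "LTR"))`.
#' @param exact_threshold Passed to [rank_sum_test()].
#' @return Data.frame with one row per performed test: `group_a`, `group_b`,
#'   `n_a`, `n_b`, `U`, `p_two_sided`, `method`.
#' @export
compare_probe_populations <- function(de, annotations, group_specs,
                                      exact_threshold = 30L) {
  idx <- match(de$probe_id, annotations$probe_id)
  if (anyNA(idx)) stop("probe without annotation record", call. = FALSE)
  ann <- annotations[idx, ]
  M <- de$log_fc
  sense <- ann$is_repeat & ann$detects_sense %in% TRUE
  baseline <- M[!ann$is_repeat]
  rows <- list()
  add <- function(ga, gb, va, vb) {
    if (!length(va)) {
      warning("empty group '", ga, "' skipped")
      return()
    }
    t <- rank_sum_test(va, vb, exact_threshold)
    rows[[length(rows) + 1L]] <<- data.frame(
      group_a = ga, group_b = gb, n_a = t$n_a, n_b = t$n_b, U = t$U,
      p_two_sided = t$p_two_sided, method = t$method, stringsAsFactors = FALSE)
  }
  for (spec in group_specs) {
    field <- names(spec)[1L]
    value <- spec[[1L]]
    in_group <- sense & ann[[field]] %in% value
    add(paste0(field, ":", value), "non_repeat", M[in_group], baseline)
    if (field == "element" && any(in_group)) {
      fam <- unique(ann$family[in_group])[1L]
      cls <- unique(ann$repeat_class[in_group])[1L]
      fam_rest <- sense & ann$family %in% fam & !(ann$element %in% value)
      cls_rest <- sense & ann$repeat_class %in% cls & !(ann$element %in% value)
      if (any(fam_rest))
        add(paste0(field, ":", value), paste0("family:", fam),
            M[in_group], M[fam_rest])
      if (any(cls_rest))
        add(paste0(field, ":", value), paste0("class:", cls),
            M[in_group], M[cls_rest])
    }
  }
  if (!length(rows))
    return(data.frame(group_a = character(), group_b = character(),
                      n_a = integer(), n_b = integer(), U = numeric(),
                      p_two_sided = numeric(), method = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
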