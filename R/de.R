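#' Fit the two-group probe-level model
#'
#' Per probe: log fold change (case minus control on the log2 scale), average
#' expression over all samples, pooled within-group variance and its degrees
#' of freedom.
#'
#' @param m Log2-scale matrix (probes x samples).
#' @param condition_of_sample Named vector mapping sample ids to condition
#'   labels; must contain exactly the two levels `case` and `control`.
#' @param case,control Condition labels.
#' @return Data.frame with `probe_id`, `log_fc`, `A`, `s2`, `df`, `n1`, `n2`.
#' @export
fit_two_group <- function(m, condition_of_sample, case, control) {
  cond <- condition_of_sample[colnames(m)]
  i1 <- which(cond == case); i2 <- which(cond == control)
  if (!length(i1)) stop("no samples for condition '", case, "'", call. = FALSE)
  if (!length(i2)) stop("no samples for condition '", control, "'", call. = FALSE)
  if (length(i1) < 2L || length(i2) < 2L)
    warning("a condition has a single sample; variance is pooled from the other group")
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(m[, i1, drop = FALSE])
  m2 <- rowMeans(m[, i2, drop = FALSE])
  ss1 <- rowSums((m[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((m[, i2, drop = FALSE] - m2)^2)
  df <- n1 + n2 - 2L
  data.frame(
    probe_id = rownames(m),
    log_fc = m1 - m2,
    A = rowMeans(m),
    s2 = if (df > 0) (ss1 + ss2) / df else rep(NA_real_, nrow(m)),
    df = df, n1 = n1, n2 = n2,
    stringsAsFactors = FALSE, row.names = NULL)
}

# Newton inversion of the trigamma function (for the moments estimator)
trigamma_inverse <- function(x) {
  if (x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Empirical-Bayes moderation of probe variances
#'
#' Shrinks per-probe variances toward a prior estimated by matching the
#' moments of `log(s2)` to a scaled-F distribution: the prior has `d0` degrees
#' of freedom and scale `s0_sq`. The moderated t statistic uses the posterior
#' variance `(d0 s0_sq + df s2) / (d0 + df)` and gains `d0` degrees of
#' freedom. `d0` estimates above 500 are declared infinite, in which case all
#' probes share the prior variance.
#'
#' @param fit Data.frame from [fit_two_group()].
#' @param d0,s0_sq Optionally force the prior (e.g. `d0 = 0` reproduces the
#'   ordinary pooled t; `d0 = Inf` gives a common denominator).
#' @return `fit` with added columns `s2_post`, `t_mod`, `p`; the prior is in
#'   `attr(, "moderation")` (list with `d0`, `s0_sq`).
#' @export
eb_moderate <- function(fit, d0 = NULL, s0_sq = NULL) {
  df <- fit$df[1L]
  if (is.null(d0)) {
    usable <- which(fit$df > 0 & fit$s2 > 0)
    if (length(usable) < 10L && length(usable) < nrow(fit))
      warning("fewer than 10 usable variances; prior estimate may be unstable")
    if (!length(usable)) {
      warning("all probe variances are zero; falling back to the ordinary t")
      d0 <- 0; s0_sq <- 0
    } else {
      z <- log(fit$s2[usable])
      evar <- stats::var(z) - trigamma(df / 2)
      if (!is.finite(evar) || evar <= 1e-8) {
        d0 <- Inf
      } else {
        d0 <- 2 * trigamma_inverse(evar)
        if (d0 > 500) d0 <- Inf
      }
      emean <- mean(z) - digamma(df / 2) + log(df / 2)
      s0_sq <- if (is.finite(d0))
        exp(emean + digamma(d0 / 2) - log(d0 / 2)) else exp(emean)
    }
  }
  if (is.null(s0_sq))
    stop("s0_sq must be supplied when d0 is forced", call. = FALSE)
  s2 <- ifelse(is.na(fit$s2), 0, fit$s2)
  s2_post <- if (!is.finite(d0)) rep(s0_sq, nrow(fit)) else
    if (d0 == 0) s2 else (d0 * s0_sq + fit$df * s2) / (d0 + fit$df)
  se <- sqrt(s2_post * (1 / fit$n1 + 1 / fit$n2))
  t_mod <- ifelse(se > 0, fit$log_fc / se, ifelse(fit$log_fc == 0, 0, Inf))
  df_total <- fit$df + d0
  p <- ifelse(df_total > 0,
              2 * stats::pt(-abs(t_mod), df = df_total),
              1)
  p[!is.finite(df_total)] <- 2 * stats::pnorm(-abs(t_mod[!is.finite(df_total)]))
  p[!is.finite(t_mod) & fit$log_fc != 0] <- 0
  fit$s2_post <- s2_post
  fit$t_mod <- t_mod
  fit$p <- pmin(pmax(p, 0), 1)
  attr(fit, "moderation") <- list(d0 = d0, s0_sq = s0_sq)
  fit
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment of a p-value vector (original order preserved).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Call changed probes
#'
#' A probe is `up` when `log_fc >= log2(fold_threshold)` (inclusive) and its
#' adjusted p passes `alpha` (strict `<` by default); `down` symmetric;
#' otherwise `unchanged`.
#'
#' @param results Data.frame with `log_fc` and `adj_p`.
#' @param params [retro_params()] (uses `fold_threshold`, `alpha`,
#'   `alpha_inclusive`).
#' @return `results` with a `call` column.
#' @export
call_changed <- function(results, params) {
  lf <- log2(params$fold_threshold)
  sig <- if (params$alpha_inclusive) results$adj_p <= params$alpha
         else results$adj_p < params$alpha
  results$call <- ifelse(sig & results$log_fc >= lf, "up",
                  ifelse(sig & results$log_fc <= -lf, "down", "unchanged"))
  results
}

#' Two-condition differential expression, start to finish
#'
#' Convenience wrapper: [fit_two_group()], [eb_moderate()], [bh_adjust()],
#' [call_changed()].
#'
#' @inheritParams fit_two_group
#' @inheritParams call_changed
#' @param d0,s0_sq Optional forced moderation prior (see [eb_moderate()]).
#' @return Data.frame of per-probe results with columns `probe_id`, `log_fc`,
#'   `A`, `s2`, `df`, `s2_post`, `t_mod`, `p`, `adj_p`, `call`.
#' @export
de_analysis <- function(m, condition_of_sample, case, control, params,
                        d0 = NULL, s0_sq = NULL) {
  fit <- fit_two_group(m, condition_of_sample, case, control)
  fit <- eb_moderate(fit, d0 = d0, s0_sq = s0_sq)
  fit$adj_p <- bh_adjust(fit$p)
  fit <- call_changed(fit, params)
  fit
}

#' Summarise differential calls by repeat element
#'
#' Counts expressed / up / down probes per repeat element over the
#' sense-detecting repeat probes only, with overall changed-probe fractions.
#'
#' @param results Differential results from [de_analysis()] (needs `probe_id`
#'   and `call`).
#' @param annotations Probe annotation from [annotate_platform()].
#' @return Data.frame (element, family, repeat_class, n_probes_expressed,
#'   n_up, n_down) sorted by element, with attribute `fractions`: a list with
#'   `n_expressed_repeat`, `n_changed_repeat`, `changed_fraction`.
#' @export
summarize_by_element <- function(results, annotations) {
  idx <- match(results$probe_id, annotations$probe_id)
  if (anyNA(idx))
    stop("probe without annotation record: ",
         results$probe_id[is.na(idx)][1L], call. = FALSE)
  ann <- annotations[idx, ]
  sense <- which(ann$is_repeat & ann$detects_sense %in% TRUE)
  res <- results[sense, , drop = FALSE]
  ann <- ann[sense, , drop = FALSE]
  if (nrow(res)) {
    tab <- do.call(rbind, lapply(split(seq_len(nrow(res)), ann$element),
      function(i) data.frame(
        element = ann$element[i[1L]],
        family = ann$family[i[1L]],
        repeat_class = ann$repeat_class[i[1L]],
        n_probes_expressed = length(i),
        n_up = sum(res$call[i] == "up"),
        n_down = sum(res$call[i] == "down"),
        stringsAsFactors = FALSE)))
    tab <- tab[order(tab$element), , drop = FALSE]
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(element = character(), family = character(),
                      repeat_class = character(),
                      n_probes_expressed = integer(), n_up = integer(),
                      n_down = integer(), stringsAsFactors = FALSE)
  }
  n_changed <- sum(tab$n_up + tab$n_down)
  attr(tab, "fractions") <- list(
    n_expressed_repeat = nrow(res),
    n_changed_repeat = n_changed,
    changed_fraction = if (nrow(res)) n_changed / nrow(res) else NA_real_)
  tab
}
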