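two_group_matrix <- function(case, control, probe = "p1") {
  m <- matrix(c(case, control), nrow = 1,
              dimnames = list(probe, c(sprintf("c%d", seq_along(case)),
                                       sprintf("k%d", seq_along(control)))))
  cond <- setNames(rep(c("case", "control"), c(length(case), length(control))),
                   colnames(m))
  list(m = m, cond = cond)
}

test_that("two-group fit computes fold change, grand mean and pooled variance", {
  x <- two_group_matrix(c(4, 4), c(2, 2))
  fit <- fit_two_group(x$m, x$cond, "case", "control")
  expect_equal(fit$log_fc, 2)
  expect_equal(fit$A, 3)
  expect_equal(fit$s2, 0)
  expect_equal(fit$df, 2L)
  eq <- two_group_matrix(c(1, 3), c(3, 1))
  expect_equal(fit_two_group(eq$m, eq$cond, "case", "control")$log_fc, 0)
  # 3v3 hand-computed pooled variance
  a <- c(5, 6, 7); b <- c(2, 2, 5)
  y <- two_group_matrix(a, b)
  fit3 <- fit_two_group(y$m, y$cond, "case", "control")
  s2_hand <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / 4
  expect_equal(fit3$s2, s2_hand)
  expect_equal(fit3$log_fc, mean(a) - mean(b))
  expect_equal(fit3$df, 4L)
  expect_error(fit_two_group(x$m, x$cond, "case", "missing"), "no samples")
})

sim_fit <- function(seed, n_probes = 200, sd = 0.5, n = 3) {
  set.seed(seed)
  m <- matrix(rnorm(n_probes * 2 * n, 8, sd), n_probes, 2 * n,
              dimnames = list(sprintf("p%d", 1:n_probes),
                              c(sprintf("c%d", 1:n), sprintf("k%d", 1:n))))
  cond <- setNames(rep(c("case", "control"), each = n), colnames(m))
  fit_two_group(m, cond, "case", "control")
}

test_that("moderation with d0 = 0 reproduces the ordinary pooled t exactly", {
  fit <- sim_fit(41)
  mod <- eb_moderate(fit, d0 = 0, s0_sq = 1)
  t_ord <- fit$log_fc / sqrt(fit$s2 * (1 / 3 + 1 / 3))
  expect_equal(mod$t_mod, t_ord, tolerance = 1e-10)
  expect_equal(mod$p, 2 * pt(-abs(t_ord), df = 4), tolerance = 1e-10)
})

test_that("moderation with infinite prior shares one denominator across probes", {
  fit <- sim_fit(42)
  mod <- eb_moderate(fit, d0 = Inf, s0_sq = 0.33)
  expect_true(all(mod$s2_post == 0.33))
  expect_equal(mod$p, 2 * pnorm(-abs(mod$t_mod)), tolerance = 1e-12)
})

test_that("estimated prior recovers a known common variance and the shrinkage formulas", {
  fit <- sim_fit(43, n_probes = 500, sd = 0.5)
  mod <- eb_moderate(fit)
  md <- attr(mod, "moderation")
  expect_gt(md$s0_sq, 0.25 * 0.8)   # truth 0.25, within 20%
  expect_lt(md$s0_sq, 0.25 * 1.2)
  # step-by-step independent evaluation of the shrinkage formulas
  d0 <- md$d0; s0 <- md$s0_sq
  for (i in c(1, 57, 500)) {
    s2p <- if (is.finite(d0)) (d0 * s0 + 4 * fit$s2[i]) / (d0 + 4) else s0
    tm <- fit$log_fc[i] / sqrt(s2p * (2 / 3))
    expect_equal(mod$s2_post[i], s2p)
    expect_equal(mod$t_mod[i], tm)
    expect_equal(mod$p[i],
                 if (is.finite(d0)) 2 * pt(-abs(tm), 4 + d0)
                 else 2 * pnorm(-abs(tm)))
  }
})

test_that("moderated statistics track limma on heterogeneous-variance data", {
  set.seed(44)
  n_probes <- 400
  s2_true <- 0.25 * 8 / rchisq(n_probes, 8)  # scaled-F structure, d0 = 8
  m <- matrix(rnorm(n_probes * 6, 8, sqrt(s2_true)), n_probes, 6,
              dimnames = list(sprintf("p%d", 1:n_probes),
                              c(sprintf("c%d", 1:3), sprintf("k%d", 1:3))))
  cond <- setNames(rep(c("case", "control"), each = 3), colnames(m))
  mod <- eb_moderate(fit_two_group(m, cond, "case", "control"))
  md <- attr(mod, "moderation")
  design <- cbind(1, rep(c(1, 0), each = 3))
  lf <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(md$d0, lf$df.prior, tolerance = 0.25)
  expect_equal(md$s0_sq, lf$s2.prior, tolerance = 0.2)
  expect_equal(mod$t_mod, unname(lf$t[, 2]), tolerance = 0.05)
  expect_gt(cor(mod$p, lf$p.value[, 2]), 0.999)
})

test_that("all-zero variances fall back to the ordinary t with a warning", {
  x <- two_group_matrix(c(4, 4), c(2, 2))
  m <- rbind(x$m, p2 = c(3, 3, 3, 3))
  fit <- fit_two_group(m, x$cond, "case", "control")
  w <- capture_warnings(mod <- eb_moderate(fit))
  expect_true(any(grepl("ordinary t", w)))
  expect_equal(mod$p[2], 1)   # no change, no evidence
  expect_equal(mod$p[1], 0)   # infinite t under zero variance
})

test_that("BH adjustment equals the hand step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(45)
  for (i in 1:10) {
    p <- runif(sample(3:50, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))  # monotone in p
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(-0.1)), "\\[0, 1\\]")
})

test_that("change calls are inclusive on fold change and strict on alpha", {
  params <- retro_params("illumina50", fold_threshold = 2, alpha = 0.01)
  res <- data.frame(
    log_fc = c(1.2, 0, 1.0, -1.0, 3, 1.0),
    adj_p = c(0.005, 0.001, 0.009, 0.009, 0.01, 0.011))
  out <- call_changed(res, params)
  expect_equal(out$call,
               c("up", "unchanged", "up", "down", "unchanged", "unchanged"))
  incl <- call_changed(res, retro_params("illumina50", alpha_inclusive = TRUE))
  expect_equal(incl$call[5], "up")  # adj_p == alpha accepted when inclusive
})

test_that("per-element summaries count sense-detecting repeat probes only", {
  truth <- null_probe_truth(8, n_repeat = 4, element = "X-int")
  truth$element[3:4] <- "Y-int"
  truth$sense[4] <- FALSE      # antisense probe: excluded from summaries
  ann <- annotation_from_truth(truth)
  res <- data.frame(probe_id = truth$probe_id,
                    call = c("up", "up", "down", "down", rep("unchanged", 4)),
                    stringsAsFactors = FALSE)
  tab <- summarize_by_element(res, ann)
  expect_equal(tab$element, c("X-int", "Y-int"))
  expect_equal(tab$n_up, c(2L, 0L))
  expect_equal(tab$n_down, c(0L, 1L))
  expect_equal(tab$n_probes_expressed, c(2L, 1L))
  fr <- attr(tab, "fractions")
  expect_equal(fr$n_expressed_repeat, 3L)
  expect_equal(fr$changed_fraction, 1)
  expect_error(summarize_by_element(
    data.frame(probe_id = "nope", call = "up"), ann), "without annotation")
})

test_that("relabelling samples within a condition leaves results identical", {
  fit_a <- sim_fit(46)
  set.seed(46)
  m <- matrix(rnorm(200 * 6, 8, 0.5), 200, 6,
              dimnames = list(sprintf("p%d", 1:200),
                              c(sprintf("c%d", 1:3), sprintf("k%d", 1:3))))
  cond <- setNames(rep(c("case", "control"), each = 3), colnames(m))
  perm <- m[, c(3, 1, 2, 5, 6, 4)]
  fit_b <- fit_two_group(perm, cond[colnames(perm)], "case", "control")
  expect_equal(eb_moderate(fit_a)$p, eb_moderate(fit_b)$p)
})
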