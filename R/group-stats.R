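# Exact null distribution of the Wilcoxon signed-rank statistic with
# midranks: convolution over sign assignments on the doubled-rank lattice.
# Ranks are average ranks of |x|, doubled so ties (multiples of 0.5) become
# integers; returns P(2V = w) for w = 0 .. sum(2r).
.signed_rank_null <- function(ranks2) {
  total <- sum(ranks2)
  f <- numeric(total + 1L)  # index w+1 holds P(2V = w) * 2^n
  f[1L] <- 1
  for (r in ranks2) {
    g <- f
    g[(r + 1L):(total + 1L)] <- g[(r + 1L):(total + 1L)] + f[1L:(total + 1L - r)]
    f <- g
  }
  f / 2^length(ranks2)
}

#' One-sample Wilcoxon signed-rank test
#'
#' Nonparametric test of the location of a sample of per-subject estimates
#' against a null value. Zero differences are dropped before ranking
#' (Wilcoxon's original treatment); tied magnitudes receive average ranks.
#' For n <= `exact_limit` the p-value is computed from the exact null
#' distribution of the signed-rank statistic (a convolution over all 2^n
#' sign assignments, valid under ties); above it, a normal approximation
#' with continuity correction and tie-corrected variance is used.
#'
#' @param values numeric vector of per-subject estimates.
#' @param null_value hypothesized location under the null (default 0).
#' @param alternative `"greater"` (default; the positive-tail test used for
#'   connectivity), `"less"` or `"two.sided"`.
#' @param alpha significance threshold (default 0.001).
#' @param exact_limit maximum n for the exact distribution (default 25).
#' @return a `group_result` with fields `statistic` (V, the sum of positive
#'   ranks), `p_value`, `n` (non-zero differences), `alpha`, `significant`,
#'   `alternative`, `per_subject_values`, `exact`.
#' @examples
#' signed_rank_test(rexp(20))           # strongly positive sample
#' signed_rank_test(c(2, -1))$p_value   # 0.5
#' @export
signed_rank_test <- function(values, null_value = 0,
                             alternative = c("greater", "less", "two.sided"),
                             alpha = 0.001, exact_limit = 25) {
  alternative <- match.arg(alternative)
  if (anyNA(values)) stop("missing values in 'values'")
  d <- values - null_value
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    stop("undefined test: all values equal the null value (no non-zero differences)")
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_limit) {
    null <- .signed_rank_null(as.integer(round(2 * r)))
    w <- as.integer(round(2 * v))
    p_ge <- sum(null[(w + 1L):length(null)])
    p_le <- sum(null[1L:(w + 1L)])
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    p_ge <- stats::pnorm((v - 0.5 - mu) / sqrt(sig2), lower.tail = FALSE)
    p_le <- stats::pnorm((v + 0.5 - mu) / sqrt(sig2))
    exact <- FALSE
  }
  p <- switch(alternative,
              greater = p_ge, less = p_le,
              two.sided = min(1, 2 * min(p_ge, p_le)))
  structure(list(statistic = v, p_value = p, n = n, alpha = alpha,
                 significant = p < alpha, alternative = alternative,
                 null_value = null_value, per_subject_values = values,
                 exact = exact),
            class = "group_result")
}

#' @rdname signed_rank_test
#' @details `signed_rank_test_greater()` is the one-sided positive-tail
#'   form used for all connectivity inferences: only significantly positive
#'   correlations are interpreted as representational connectivity.
#' @export
signed_rank_test_greater <- function(values, null_value = 0, alpha = 0.001,
                                     exact_limit = 25) {
  signed_rank_test(values, null_value, alternative = "greater",
                   alpha = alpha, exact_limit = exact_limit)
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank test (%s, %s)\n",
              x$alternative, if (x$exact) "exact" else "normal approximation"))
  cat(sprintf("  n = %d non-zero differences, V = %g, p = %.3g (alpha = %g)%s\n",
              x$n, x$statistic, x$p_value, x$alpha,
              if (x$significant) "  *" else ""))
  invisible(x)
}

#' Equality-of-fits test for two regions
#'
#' Two-sided Wilcoxon signed-rank test on the paired differences of the two
#' regions' per-subject model fits. Part of the model-based connectivity
#' verdict: connectivity through a common model additionally requires that
#' the two regions fit the model about equally well.
#'
#' @param fits_roi1,fits_roi2 paired per-subject model fits (equal length).
#' @param alpha significance threshold for the equality clause
#'   (default 0.001, the global threshold used by all tests here).
#' @return a `group_result` for the paired two-sided test.
#' @export
equality_of_fits_test <- function(fits_roi1, fits_roi2, alpha = 0.001) {
  if (length(fits_roi1) != length(fits_roi2))
    stop("paired fits must have equal length")
  signed_rank_test(fits_roi1 - fits_roi2, null_value = 0,
                   alternative = "two.sided", alpha = alpha)
}

#' Model-based connectivity verdict
#'
#' Two regions are declared connected through a model when (a) both regions'
#' fits to the model are significantly positive across subjects and (b) the
#' two regions' fits are not significantly different. Clause (b) uses a
#' two-sided equality test; failing to reject equality keeps the verdict
#' alive.
#'
#' @param fits_roi1,fits_roi2 paired per-subject model fits.
#' @param alpha_pos one-sided positivity threshold (default 0.001).
#' @param alpha_eq equality-test threshold (default 0.001; the same global
#'   threshold as all other tests, configurable).
#' @return an `rca_verdict` list: `verdict` (logical), the three component
#'   `group_result`s, and the thresholds used.
#' @export
model_based_connectivity_verdict <- function(fits_roi1, fits_roi2,
                                             alpha_pos = 0.001,
                                             alpha_eq = 0.001) {
  pos1 <- signed_rank_test_greater(fits_roi1, alpha = alpha_pos)
  pos2 <- signed_rank_test_greater(fits_roi2, alpha = alpha_pos)
  eq <- equality_of_fits_test(fits_roi1, fits_roi2, alpha = alpha_eq)
  structure(list(verdict = pos1$significant && pos2$significant &&
                   eq$p_value >= alpha_eq,
                 positivity_roi1 = pos1, positivity_roi2 = pos2,
                 equality = eq, alpha_pos = alpha_pos, alpha_eq = alpha_eq),
            class = "rca_verdict")
}

#' @export
print.rca_verdict <- function(x, ...) {
  cat(sprintf("Model-based connectivity verdict: %s\n",
              if (x$verdict) "CONNECTED (through the model)" else "not connected"))
  cat(sprintf("  positivity: roi1 p = %.3g, roi2 p = %.3g (alpha = %g)\n",
              x$positivity_roi1$p_value, x$positivity_roi2$p_value, x$alpha_pos))
  cat(sprintf("  equality of fits: p = %.3g (must be >= %g)\n",
              x$equality$p_value, x$alpha_eq))
  invisible(x)
}

#' Common-input sensitivity as a function of model similarity
#'
#' For each simulated subject, draws a pair of random model RDMs, measures
#' their similarity (`compare_rdms`), and the change in 2-model RCA (lag 0)
#' from before to after injecting the common input. Across subjects, the
#' change grows with model similarity: 2-model RCA with orthogonal or
#' negatively correlated models resists a common input, while positively
#' correlated models let it through.
#'
#' @param config a [sim_config()].
#' @param n_subjects number of subjects (default from config).
#' @param master_seed integer master seed.
#' @param k latent channels of the random models (default 30).
#' @return a `sensitivity_result`: per-subject `pairs` data.frame
#'   (`model_similarity`, `connectivity_change`), Pearson `r` and `p_value`
#'   across subjects, and the least-squares `slope` and `intercept`.
#' @export
noise_sensitivity_analysis <- function(config, n_subjects = config$n_subjects,
                                       master_seed = 1, k = 30) {
  validate_sim_config(config)
  sim <- numeric(n_subjects); chg <- numeric(n_subjects)
  for (i in seq_len(n_subjects)) {
    ds <- simulate_timeseries_subject(config, subject_seed(master_seed, i, .STREAM["timeseries"]))
    inj <- inject_common_input(ds, seed = subject_seed(master_seed, i, .STREAM["common_input"]))
    m1 <- random_model(nrow(config$design),
                       seed = subject_seed(master_seed, i, .STREAM["random_models"]),
                       k = k, condition_ids = rownames(config$design))
    m2 <- random_model(nrow(config$design),
                       seed = subject_seed(master_seed, i, .STREAM["random_models"] + 100L),
                       k = k, condition_ids = rownames(config$design))
    pre1 <- rdm_series(ds$roi1); pre2 <- rdm_series(ds$roi2)
    post1 <- rdm_series(inj$roi1); post2 <- rdm_series(inj$roi2)
    sim[i] <- compare_rdms(m1, m2)
    chg[i] <- two_model_rca(post1, post2, m1, m2, lag = 0) -
      two_model_rca(pre1, pre2, m1, m2, lag = 0)
  }
  ct <- stats::cor.test(sim, chg)
  fit <- stats::lm(chg ~ sim)
  structure(list(pairs = data.frame(subject = seq_len(n_subjects),
                                    model_similarity = sim,
                                    connectivity_change = chg),
                 r = unname(ct$estimate), p_value = ct$p.value,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n_subjects = n_subjects, master_seed = master_seed),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("Common-input sensitivity vs model similarity\n")
  cat(sprintf("  %d subjects: Pearson r = %.3f, p = %.3g, slope = %.3f\n",
              x$n_subjects, x$r, x$p_value, x$slope))
  invisible(x)
}

#' @export
plot.sensitivity_result <- function(x, ...) {
  graphics::plot(x$pairs$model_similarity, x$pairs$connectivity_change,
                 xlab = "model-to-model similarity (r)",
                 ylab = "change in 2-model RCA after common input",
                 main = sprintf("r = %.2f, p = %.3g", x$r, x$p_value), ...)
  graphics::abline(x$intercept, x$slope)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
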