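# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (stats::cor, vectorized ranking) so that
# agreement is informative.

# Pearson correlation from explicit sum formulas
pearson_bf <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x * x) - sx * sx) * (n * sum(y * y) - sy * sy))
}

# upper-triangle (row-major, i < j) of a square matrix by explicit loops
ut_bf <- function(m) {
  n <- nrow(m)
  out <- numeric(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) out <- c(out, m[i, j])
  out
}

# one-sided (greater) and two-sided signed-rank p by full 2^n enumeration
signed_rank_bf <- function(d, alternative = "greater") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  v_all <- apply(signs, 1, function(s) sum(r[unlist(s)]))
  p_ge <- mean(v_all >= v_obs - 1e-9)
  p_le <- mean(v_all <= v_obs + 1e-9)
  switch(alternative,
         greater = p_ge, less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

# correlation between two factor-model RDM vectors of a full-crossing
# two-factor design by explicit pair counting (closed-form oracle)
model_cor_counting <- function(l1, l2, which_a = "f1", which_b = "f2") {
  lev <- expand.grid(b = seq_len(l2), a = seq_len(l1))[, c("a", "b")]
  vecs <- list(f1 = numeric(0), f2 = numeric(0), int = numeric(0))
  n <- nrow(lev)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    da <- as.integer(lev$a[i] != lev$a[j])
    db <- as.integer(lev$b[i] != lev$b[j])
    vecs$f1 <- c(vecs$f1, da)
    vecs$f2 <- c(vecs$f2, db)
    vecs$int <- c(vecs$int, da + db)
  }
  pearson_bf(vecs[[which_a]], vecs[[which_b]])
}

# small, fast configuration for structural tests (not the study conditions)
small_config <- function(...) {
  defaults <- list(n_subjects = 6, n_time = 80, window_roi1 = c(15, 30),
                   base_delay = 10, jitter_range = c(0, 5), analysis_lag = 10)
  args <- utils::modifyList(defaults, list(...))
  if (!"window_roi1" %in% names(list(...)) && args$window_roi1[2] > args$n_time - 1)
    args$window_roi1 <- c(args$n_time %/% 4, args$n_time %/% 2)
  if (!"base_delay" %in% names(list(...)) &&
      args$window_roi1[1] - args$base_delay - args$jitter_range[2] < 0)
    args$base_delay <- max(0, args$window_roi1[1] - args$jitter_range[2])
  if (!"analysis_lag" %in% names(list(...)) && args$analysis_lag >= args$n_time)
    args$analysis_lag <- args$n_time %/% 4
  do.call(sim_config, args)
}

# the packaged study conditions
study_config <- function(...) sim_config(...)

# build an rdm_series from a list of pattern matrices shifted by `lag`
shifted_series <- function(samples, lag) {
  T <- length(samples)
  rdm_series(samples[c((lag + 1):T, seq_len(lag))])
}
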