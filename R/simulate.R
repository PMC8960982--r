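#' Simulation configuration for the two-ROI experiments
#'
#' Collects every tunable of the synthetic two-region generator. Defaults
#' reproduce the study conditions of the packaged experiments: 16 conditions
#' (4 positions x 4 semantic categories), 120 channels in ROI 1 (position
#' coding, "V2") and 150 in ROI 2 (category coding, "ITC"), Gaussian signal
#' and noise of per-channel variance 0.5 each, N = 20 subjects, 200 time
#' samples, common-input variance 7, information window samples 30--60 in
#' ROI 1, an inter-ROI delay of +/-20 samples jittered by 0--10 across
#' subjects, and a fixed analysis lag of 20.
#'
#' @param design a [factorial_design()]; default `position = 4, category = 4`.
#' @param n_subjects number of simulated subjects per group (default 20).
#' @param channels_roi1,channels_roi2 channel counts (default 120 and 150).
#' @param signal_variance per-channel variance of the level prototypes
#'   (default 0.5).
#' @param noise_variance per-channel variance of the additive i.i.d.
#'   Gaussian measurement noise (default 0.5).
#' @param n_time time samples for time-resolved simulations (default 200).
#' @param common_input_variance per-channel variance of the condition- and
#'   time-specific common input (default 7).
#' @param mixing how the common input is mapped into ROI 2:
#'   `"orthonormal"` (default) uses a random isometry scaled to preserve the
#'   per-channel variance, so the injected pattern geometry is carried over
#'   exactly; `"scaled"` uses an i.i.d. Gaussian matrix scaled by
#'   1/sqrt(channels_roi1); `"literal"` uses an unscaled i.i.d. Gaussian
#'   matrix.
#' @param window_roi1 inclusive sample window (0-based) in which ROI 1
#'   carries information in the windowed scenario (default `c(30, 60)`).
#' @param base_delay inter-ROI delay magnitude in samples (default 20).
#' @param jitter_range inclusive integer range of the per-subject delay
#'   jitter (default `c(0, 10)`); the realized ROI 2 onset is
#'   `onset1 + base_delay - j` (congruent) or `onset1 - base_delay - j`
#'   (incongruent) with `j` uniform on this range.
#' @param analysis_lag lag (samples) used by the lagged estimators
#'   (default 20); fixed across subjects.
#' @param roi1_factor,roi2_factor which design factor each ROI represents.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(design = factorial_design(position = 4, category = 4),
                       n_subjects = 20,
                       channels_roi1 = 120, channels_roi2 = 150,
                       signal_variance = 0.5, noise_variance = 0.5,
                       n_time = 200, common_input_variance = 7,
                       mixing = c("orthonormal", "scaled", "literal"),
                       window_roi1 = c(30, 60),
                       base_delay = 20, jitter_range = c(0, 10),
                       analysis_lag = 20,
                       roi1_factor = names(design)[1],
                       roi2_factor = names(design)[2]) {
  mixing <- match.arg(mixing)
  cfg <- list(design = design, n_subjects = as.integer(n_subjects),
              channels_roi1 = as.integer(channels_roi1),
              channels_roi2 = as.integer(channels_roi2),
              signal_variance = signal_variance, noise_variance = noise_variance,
              n_time = as.integer(n_time),
              common_input_variance = common_input_variance, mixing = mixing,
              window_roi1 = as.integer(window_roi1),
              base_delay = as.integer(base_delay),
              jitter_range = as.integer(jitter_range),
              analysis_lag = as.integer(analysis_lag),
              roi1_factor = roi1_factor, roi2_factor = roi2_factor)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Two-ROI simulation configuration\n")
  cat(sprintf("  conditions: %d (%s)\n", nrow(x$design),
              paste(names(x$design), vapply(x$design, max, 0L), sep = "=", collapse = " x ")))
  cat(sprintf("  channels: %d / %d   subjects: %d   time samples: %d\n",
              x$channels_roi1, x$channels_roi2, x$n_subjects, x$n_time))
  cat(sprintf("  variances: signal %.3g, noise %.3g, common input %.3g (%s mixing)\n",
              x$signal_variance, x$noise_variance, x$common_input_variance, x$mixing))
  cat(sprintf("  ROI1 window [%d, %d], delay %d, jitter [%d, %d], analysis lag %d\n",
              x$window_roi1[1], x$window_roi1[2], x$base_delay,
              x$jitter_range[1], x$jitter_range[2], x$analysis_lag))
  invisible(x)
}

#' @rdname sim_config
#' @param cfg a `sim_config` candidate list.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg$design, "condition_design"))
  if (cfg$signal_variance < 0 || cfg$noise_variance <= 0 || cfg$common_input_variance < 0)
    stop("variances must be positive (signal variance may be zero only for degenerate tests)")
  if (cfg$channels_roi1 < 2 || cfg$channels_roi2 < 2) stop("each ROI needs >= 2 channels")
  if (cfg$n_time < 1) stop("n_time must be >= 1")
  if (length(cfg$window_roi1) != 2 || cfg$window_roi1[1] > cfg$window_roi1[2])
    stop("window_roi1 must be an inclusive [start, end] pair")
  if (cfg$window_roi1[1] < 0 || cfg$window_roi1[2] > cfg$n_time - 1)
    stop("window_roi1 must fit inside [0, n_time - 1]")
  if (length(cfg$jitter_range) != 2 || cfg$jitter_range[1] > cfg$jitter_range[2] ||
      cfg$jitter_range[1] < 0)
    stop("jitter_range must be a non-negative inclusive pair")
  if (cfg$analysis_lag < 0 || cfg$analysis_lag >= cfg$n_time)
    stop("analysis_lag must lie in [0, n_time - 1]")
  for (f in c(cfg$roi1_factor, cfg$roi2_factor))
    if (!f %in% names(cfg$design)) stop("unknown ROI factor '", f, "'")
  invisible(cfg)
}

#' Derive per-subject child seeds from a master seed
#'
#' Deterministic counter scheme: the seed of subject `i` in stream `stream`
#' is `(master * 48271 + i * 1009 + stream) mod (2^31 - 1)`. Adding subjects
#' never perturbs the seeds of existing ones, and distinct streams (static
#' data, time series, common input, windowed data, random models) never
#' share a counter.
#'
#' @param master_seed integer master seed.
#' @param i subject index (scalar or vector).
#' @param stream integer stream id (default 0).
#' @return integer seed(s) in \[0, 2^31 - 2\].
#' @export
subject_seed <- function(master_seed, i, stream = 0) {
  m <- 2147483647
  as.integer((as.numeric(master_seed) %% m * 48271 + as.numeric(i) * 1009 + stream) %% m)
}

# internal stream ids
.STREAM <- c(static = 0L, timeseries = 1L, common_input = 2L,
             windowed_congruent = 3L, windowed_incongruent = 4L,
             random_models = 5L)

#' Per-level prototype patterns
#'
#' Draws one prototype activation pattern per level of a factor. Prototypes
#' are random directions made exactly orthonormal across levels (QR
#' decomposition of a Gaussian matrix), then standardized channel-wise to
#' mean 0 and variance `signal_variance`. Every condition with the same
#' level shares its level's prototype, so the noiseless RDM of the resulting
#' condition patterns equals the binary factor model exactly: same-level
#' pairs at dissimilarity 0 and different-level pairs at exactly 1.
#'
#' @param design a [factorial_design()].
#' @param factor factor whose levels get prototypes.
#' @param n_channels channels of the region.
#' @param signal_variance per-channel variance of each prototype.
#' @param seed integer seed.
#' @return a levels x channels matrix of prototypes.
#' @export
make_prototypes <- function(design, factor, n_channels, signal_variance, seed) {
  .check_factor(design, factor)
  k <- max(design[[factor]])
  if (n_channels < k + 1) stop("need more channels than factor levels")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  g <- matrix(stats::rnorm(n_channels * k), n_channels, k)
  g <- sweep(g, 2L, colMeans(g))          # each prototype exactly mean-centered
  q <- qr.Q(qr(g))                        # orthonormal within the centered subspace
  # rows of t(q) are centered, orthonormal and share norm 1, so a single
  # rescaling gives every prototype per-channel variance signal_variance
  # and exactly zero pairwise Pearson correlation
  p <- t(q) * sqrt(signal_variance * (n_channels - 1))
  rownames(p) <- paste0(factor, seq_len(k))
  p
}

.signal_matrix <- function(design, factor, prototypes) {
  s <- prototypes[design[[factor]], , drop = FALSE]
  rownames(s) <- rownames(design)
  s
}

.noise <- function(n, ch, variance) matrix(stats::rnorm(n * ch, 0, sqrt(variance)), n, ch)

#' Simulate one subject's static two-ROI dataset
#'
#' ROI 1 patterns are its factor's level prototypes plus i.i.d. Gaussian
#' noise; likewise ROI 2 with its own factor (and channel count). The
#' noiseless ground-truth RDMs (equal to the binary factor models by
#' construction) are stored alongside.
#'
#' @param config a [sim_config()].
#' @param seed integer subject seed (see [subject_seed()]).
#' @return a `subject_dataset` with `roi1`, `roi2` ([activity_patterns()]),
#'   `ground_truth` (list of two [rdm()]s) and provenance fields.
#' @export
simulate_static_subject <- function(config, seed) {
  validate_sim_config(config)
  n <- nrow(config$design)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  p1 <- make_prototypes(config$design, config$roi1_factor, config$channels_roi1,
                        config$signal_variance, seed = stats::runif(1) * 2^30)
  p2 <- make_prototypes(config$design, config$roi2_factor, config$channels_roi2,
                        config$signal_variance, seed = stats::runif(1) * 2^30)
  s1 <- .signal_matrix(config$design, config$roi1_factor, p1)
  s2 <- .signal_matrix(config$design, config$roi2_factor, p2)
  x1 <- s1 + .noise(n, config$channels_roi1, config$noise_variance)
  x2 <- s2 + .noise(n, config$channels_roi2, config$noise_variance)
  structure(list(
    roi1 = activity_patterns(x1, roi_name = "roi1"),
    roi2 = activity_patterns(x2, roi_name = "roi2"),
    signal = list(roi1 = s1, roi2 = s2),
    ground_truth = list(roi1 = compute_rdm(s1), roi2 = compute_rdm(s2)),
    config = config, seed = as.integer(seed), type = "static"
  ), class = "subject_dataset")
}

#' Simulate one subject's time-resolved two-ROI dataset
#'
#' The representational content is constant over time: each sample is the
#' subject's fixed signal (level prototypes) plus a fresh draw of i.i.d.
#' Gaussian noise.
#'
#' @inheritParams simulate_static_subject
#' @return a `subject_dataset` with `roi1`, `roi2` as
#'   `conditions x channels x time` arrays.
#' @export
simulate_timeseries_subject <- function(config, seed) {
  validate_sim_config(config)
  n <- nrow(config$design); T <- config$n_time
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  p1 <- make_prototypes(config$design, config$roi1_factor, config$channels_roi1,
                        config$signal_variance, seed = stats::runif(1) * 2^30)
  p2 <- make_prototypes(config$design, config$roi2_factor, config$channels_roi2,
                        config$signal_variance, seed = stats::runif(1) * 2^30)
  s1 <- .signal_matrix(config$design, config$roi1_factor, p1)
  s2 <- .signal_matrix(config$design, config$roi2_factor, p2)
  a1 <- array(s1, c(n, config$channels_roi1, T)) +
    array(stats::rnorm(n * config$channels_roi1 * T, 0, sqrt(config$noise_variance)),
          c(n, config$channels_roi1, T))
  a2 <- array(s2, c(n, config$channels_roi2, T)) +
    array(stats::rnorm(n * config$channels_roi2 * T, 0, sqrt(config$noise_variance)),
          c(n, config$channels_roi2, T))
  dimnames(a1)[[1]] <- rownames(config$design)
  dimnames(a2)[[1]] <- rownames(config$design)
  structure(list(
    roi1 = a1, roi2 = a2,
    signal = list(roi1 = s1, roi2 = s2),
    ground_truth = list(roi1 = compute_rdm(s1), roi2 = compute_rdm(s2)),
    config = config, seed = as.integer(seed), type = "timeseries"
  ), class = "subject_dataset")
}

#' Inject a common input into both ROIs of a time-resolved dataset
#'
#' At every time sample an independent conditions-by-channels Gaussian
#' pattern E of the given variance is added to ROI 1, and its image under a
#' fixed random mixing matrix is added to ROI 2, so the two regions' pattern
#' fluctuations covary at each time point without either region's own
#' representation changing. The input dataset is not modified; the stored
#' ground-truth RDMs (pre-injection signal) are carried over unchanged.
#'
#' @param dataset a time-resolved `subject_dataset`.
#' @param common_input_variance per-channel variance of the injected pattern
#'   (must be > 0); default from the dataset's config.
#' @param seed integer seed for the mixing matrix and the injected patterns.
#' @param mixing mixing-matrix convention; default from the dataset's
#'   config. See [sim_config()].
#' @return a new `subject_dataset` with the common input added.
#' @export
inject_common_input <- function(dataset, common_input_variance = NULL, seed,
                                mixing = NULL) {
  stopifnot(inherits(dataset, "subject_dataset"))
  if (dataset$type == "static")
    stop("common input injection needs a time-resolved dataset")
  cfg <- dataset$config
  if (is.null(common_input_variance)) common_input_variance <- cfg$common_input_variance
  if (is.null(mixing)) mixing <- cfg$mixing
  if (common_input_variance <= 0) stop("common_input_variance must be > 0")
  n <- dim(dataset$roi1)[1]; c1 <- dim(dataset$roi1)[2]
  c2 <- dim(dataset$roi2)[2]; T <- dim(dataset$roi1)[3]
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  M <- switch(mixing,
    orthonormal = qr.Q(qr(matrix(stats::rnorm(c2 * c1), c2, c1))) * sqrt(c2 / c1),
    scaled      = matrix(stats::rnorm(c2 * c1), c2, c1) / sqrt(c1),
    literal     = matrix(stats::rnorm(c2 * c1), c2, c1),
    stop("unknown mixing convention '", mixing, "'"))
  out <- dataset
  for (t in seq_len(T)) {
    e <- .noise(n, c1, common_input_variance)
    out$roi1[, , t] <- dataset$roi1[, , t] + e
    out$roi2[, , t] <- dataset$roi2[, , t] + e %*% t(M)
  }
  out$common_input <- list(variance = common_input_variance, mixing = mixing,
                           seed = as.integer(seed))
  out
}

#' Simulate one subject's time-windowed two-ROI dataset
#'
#' Information appears only inside a fixed window in each region: inside the
#' window a sample is prototype signal plus noise, outside it is pure noise.
#' ROI 1's window is `config$window_roi1`; ROI 2's window is shifted by
#' `+base_delay - j` (congruent: ROI 2 follows ROI 1) or `-base_delay - j`
#' (incongruent: ROI 2 leads), with the jitter `j` drawn once per subject,
#' uniformly on `jitter_range`.
#'
#' @inheritParams simulate_static_subject
#' @param congruent logical; direction of the inter-ROI delay.
#' @return a `subject_dataset` with additional `windows` (0-based inclusive
#'   sample windows per ROI) and `jitter` fields.
#' @export
simulate_windowed_subject <- function(config, congruent, seed) {
  validate_sim_config(config)
  n <- nrow(config$design); T <- config$n_time
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  j <- sample(seq(config$jitter_range[1], config$jitter_range[2]), 1)
  shift <- if (congruent) config$base_delay - j else -config$base_delay - j
  w1 <- config$window_roi1
  w2 <- w1 + shift
  if (w2[1] < 0 || w2[2] > T - 1)
    stop(sprintf("shifted ROI 2 window [%d, %d] falls outside [0, %d]", w2[1], w2[2], T - 1))
  p1 <- make_prototypes(config$design, config$roi1_factor, config$channels_roi1,
                        config$signal_variance, seed = stats::runif(1) * 2^30)
  p2 <- make_prototypes(config$design, config$roi2_factor, config$channels_roi2,
                        config$signal_variance, seed = stats::runif(1) * 2^30)
  s1 <- .signal_matrix(config$design, config$roi1_factor, p1)
  s2 <- .signal_matrix(config$design, config$roi2_factor, p2)
  a1 <- array(stats::rnorm(n * config$channels_roi1 * T, 0, sqrt(config$noise_variance)),
              c(n, config$channels_roi1, T))
  a2 <- array(stats::rnorm(n * config$channels_roi2 * T, 0, sqrt(config$noise_variance)),
              c(n, config$channels_roi2, T))
  for (t in (w1[1]:w1[2]) + 1L) a1[, , t] <- a1[, , t] + s1
  for (t in (w2[1]:w2[2]) + 1L) a2[, , t] <- a2[, , t] + s2
  dimnames(a1)[[1]] <- rownames(config$design)
  dimnames(a2)[[1]] <- rownames(config$design)
  structure(list(
    roi1 = a1, roi2 = a2,
    signal = list(roi1 = s1, roi2 = s2),
    ground_truth = list(roi1 = compute_rdm(s1), roi2 = compute_rdm(s2)),
    windows = list(roi1 = w1, roi2 = w2), jitter = j, congruent = congruent,
    config = config, seed = as.integer(seed), type = "windowed"
  ), class = "subject_dataset")
}

#' @export
print.subject_dataset <- function(x, ...) {
  dims <- function(a) paste(dim(a), collapse = " x ")
  cat(sprintf("Simulated subject (%s), seed %d\n", x$type, x$seed))
  cat(sprintf("  roi1: %s   roi2: %s\n", dims(as.array(unclass(x$roi1))),
              dims(as.array(unclass(x$roi2)))))
  if (!is.null(x$windows))
    cat(sprintf("  windows: roi1 [%d, %d], roi2 [%d, %d] (%s, jitter %d)\n",
                x$windows$roi1[1], x$windows$roi1[2], x$windows$roi2[1],
                x$windows$roi2[2], if (x$congruent) "congruent" else "incongruent",
                x$jitter))
  if (!is.null(x$common_input))
    cat(sprintf("  common input: variance %.3g, %s mixing\n",
                x$common_input$variance, x$common_input$mixing))
  invisible(x)
}
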