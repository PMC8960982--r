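# column-wise Pearson correlation between matched columns of two matrices
.colcor <- function(a, b) {
  a <- scale(a); b <- scale(b)
  colSums(a * b) / (nrow(a) - 1L)
}

.as_series <- function(x) {
  if (inherits(x, "rdm_series")) return(x)
  rdm_series(x)
}

.check_series_pair <- function(s1, s2) {
  if (!identical(s1$condition_ids, s2$condition_ids))
    stop("condition sets do not align across the two series")
  if (ncol(s1$vectors) != ncol(s2$vectors))
    stop("the two series must have the same number of time samples")
}

.check_lag <- function(lag, T) {
  if (lag < 0 || lag >= T)
    stop(sprintf("lag must lie in [0, %d); got %d", T, lag))
}

#' Static model-free representational connectivity
#'
#' The direct Pearson correlation between the two regions' neural RDMs
#' (upper triangles). A significantly positive value indicates that the two
#' regions share representational structure of some kind -- whether or not
#' that structure is of interest.
#'
#' @param rdm1,rdm2 the two regions' [rdm()]s over the same conditions.
#' @return a single correlation in \[-1, 1\].
#' @export
model_free_static <- function(rdm1, rdm2) compare_rdms(rdm1, rdm2)

#' Static model fit of a neural RDM
#'
#' Pearson correlation between a region's neural RDM and a model RDM; the
#' building block of model-based RCA.
#'
#' @param rdm a region's neural [rdm()].
#' @param model a [binary_factor_model()], [intermediate_model()],
#'   [random_model()] or any `rdm` used as a model.
#' @return a single correlation in \[-1, 1\].
#' @export
model_fit_static <- function(rdm, model) compare_rdms(rdm, model)

#' Lagged model-free representational connectivity
#'
#' Correlates the source region's RDM at time t with the destination
#' region's RDM at time t + lag, then averages over the valid range
#' t = 0 .. T-1-lag (no wraparound, no padding). `lag = 0` gives the
#' time-averaged model-free RCA of stationary designs.
#'
#' @param series1,series2 [rdm_series()] (source, destination) of equal
#'   length and condition set.
#' @param lag non-negative integer lag in samples.
#' @return the mean over valid t of the per-sample RDM correlations.
#' @export
model_free_lagged <- function(series1, series2, lag = 0) {
  s1 <- .as_series(series1); s2 <- .as_series(series2)
  .check_series_pair(s1, s2)
  T <- ncol(s1$vectors)
  .check_lag(lag, T)
  idx <- seq_len(T - lag)
  mean(.colcor(s1$vectors[, idx, drop = FALSE],
               s2$vectors[, idx + lag, drop = FALSE]))
}

#' Time course of model fit
#'
#' The fit course of a region: at every time sample, the Pearson
#' correlation between the region's RDM and a model RDM. Fit courses are
#' the substrate of 1-model and 2-model RCA.
#'
#' @param series an [rdm_series()].
#' @param model a model `rdm` over the same conditions.
#' @return a `fit_course`: numeric vector of length T with attributes
#'   `roi_name` and `model_name`.
#' @export
fit_course <- function(series, model) {
  s <- .as_series(series)
  if (!inherits(model, "rdm")) stop("'model' must be an rdm")
  if (!identical(s$condition_ids, rownames(model)))
    stop("condition sets do not align between series and model")
  mv <- .ut(unclass(model))
  if (stats::var(mv) == 0) stop("degenerate model RDM: zero variance upper triangle")
  v <- as.vector(stats::cor(s$vectors, mv))
  structure(v, roi_name = s$roi_name,
            model_name = attr(model, "model_name") %||% "model",
            class = "fit_course")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fit_course <- function(x, ...) {
  cat(sprintf("Fit course: ROI '%s' vs model '%s', %d samples (range %.3f .. %.3f)\n",
              attr(x, "roi_name"), attr(x, "model_name"), length(x),
              min(x), max(x)))
  invisible(x)
}

#' @export
plot.fit_course <- function(x, ...) {
  graphics::plot(seq_along(x) - 1L, as.numeric(x), type = "l",
                 xlab = "time sample", ylab = "RDM-model correlation",
                 main = sprintf("ROI '%s' vs model '%s'",
                                attr(x, "roi_name"), attr(x, "model_name")), ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

.course_cor <- function(c1, c2, lag) {
  T <- length(c1)
  .check_lag(lag, T)
  a <- c1[seq_len(T - lag)]
  b <- c2[seq_len(T - lag) + lag]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("degenerate fit course: zero variance over the analysis range")
  stats::cor(a, b)
}

#' 1-model representational connectivity
#'
#' Both regions' RDM series are projected onto one common model RDM, and
#' the two resulting fit courses are correlated (destination shifted by the
#' lag). Tests whether the strength of one hypothesized representational
#' content waxes and wanes together in the two regions.
#'
#' @inheritParams model_free_lagged
#' @param model the common model `rdm`.
#' @return Pearson correlation of the two fit courses over the valid range.
#' @export
one_model_rca <- function(series1, series2, model, lag = 0) {
  s1 <- .as_series(series1); s2 <- .as_series(series2)
  .check_series_pair(s1, s2)
  .course_cor(fit_course(s1, model), fit_course(s2, model), lag)
}

#' 2-model representational connectivity
#'
#' Each region's RDM series is projected onto its own region-specific model
#' RDM and the fit courses are correlated at the analysis lag. Because the
#' models may differ, 2-model RCA can detect connectivity when information
#' is transformed between the regions, provided the temporal dynamics are
#' congruent; and because negatively correlated models project a common
#' input with opposite sign, it resists common-input confounds that fool
#' model-free and 1-model RCA.
#'
#' @inheritParams model_free_lagged
#' @param model1,model2 region-specific model `rdm`s (source, destination).
#' @return Pearson correlation of the two fit courses over the valid range.
#' @export
two_model_rca <- function(series1, series2, model1, model2, lag = 0) {
  s1 <- .as_series(series1); s2 <- .as_series(series2)
  .check_series_pair(s1, s2)
  .course_cor(fit_course(s1, model1), fit_course(s2, model2), lag)
}
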