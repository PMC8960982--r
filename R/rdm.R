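#' repconn: model-free and model-based representational connectivity analysis
#'
#' Representational connectivity analysis (RCA) infers functional connectivity
#' between two brain regions from the statistical relationship of their
#' representational dissimilarity matrices (RDMs) rather than their raw
#' activations. This package implements the model-free, 1-model and 2-model
#' variants of RCA, a factorial model-RDM builder, a two-region pattern
#' simulator, and nonparametric group inference, plus three packaged
#' simulation experiments ([run_simulation_1()], [run_simulation_2()],
#' [run_simulation_3()]) that demonstrate where the variants disagree.
#'
#' @section Conventions:
#' Dissimilarity is 1 minus the Pearson correlation of two condition pattern
#' rows, so RDM entries lie in \[0, 2\]. All RDM comparisons operate on the
#' upper triangle excluding the diagonal, vectorized in row-major order
#' (pairs (1,2), (1,3), ..., (1,n), (2,3), ...). Only significantly positive
#' correlations are interpreted as connectivity.
#'
#' @name repconn-package
#' @keywords internal
"_PACKAGE"

# pairs (i, j), i < j, in row-major order
.ut_pairs <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  cbind(i = i, j = j)
}

# extract the row-major upper triangle of a square matrix
.ut <- function(m) t(m)[lower.tri(m)]

# fast internal path: upper-triangle RDM vector (1 - Pearson) of a
# conditions x channels matrix, no object construction
.rdm_vec <- function(x) {
  v <- .rowvar(x)
  if (any(v <= 0 | !is.finite(v))) {
    bad <- rownames(x)[v <= 0 | !is.finite(v)]
    if (is.null(bad)) bad <- which(v <= 0 | !is.finite(v))
    stop("degenerate activity pattern: zero variance across channels for condition(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  1 - .ut(stats::cor(t(x)))
}

.rowvar <- function(x) {
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (ncol(x) - 1L)
}

#' Construct an activity-pattern matrix
#'
#' Bundles a conditions-by-channels matrix of activations with condition
#' labels and a region name. One such matrix holds one time sample of one
#' region of interest (ROI); a region may have any number of channels
#' (voxels, vertices or sensors).
#'
#' @param values numeric matrix, conditions in rows, channels in columns.
#' @param condition_ids character vector of condition labels; defaults to
#'   existing rownames or `cond1..condn`.
#' @param roi_name single string naming the region.
#' @return an `activity_patterns` object (a matrix with attributes).
#' @examples
#' ap <- activity_patterns(matrix(rnorm(12), 3, 4), roi_name = "V2")
#' compute_rdm(ap)
#' @export
activity_patterns <- function(values, condition_ids = NULL, roi_name = "roi") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (conditions x channels)")
  if (is.null(condition_ids)) {
    condition_ids <- rownames(values)
    if (is.null(condition_ids)) condition_ids <- paste0("cond", seq_len(nrow(values)))
  }
  if (length(condition_ids) != nrow(values))
    stop("length of 'condition_ids' must equal the number of rows")
  rownames(values) <- condition_ids
  structure(values, roi_name = roi_name, class = c("activity_patterns", class(values)))
}

#' @export
print.activity_patterns <- function(x, ...) {
  cat(sprintf("Activity patterns for ROI '%s': %d conditions x %d channels\n",
              attr(x, "roi_name"), nrow(x), ncol(x)))
  invisible(x)
}

#' Construct a representational dissimilarity matrix object
#'
#' Wraps a symmetric dissimilarity matrix with zero diagonal. Entries are
#' expected in \[0, 2\] (the range of 1 minus a correlation). Validation is
#' strict: asymmetry, a non-zero diagonal, or out-of-range entries beyond a
#' 1e-12 numerical tolerance are errors, never silently repaired.
#'
#' @param values square numeric matrix of dissimilarities.
#' @param condition_ids condition labels (default: rownames or `cond<i>`).
#' @return an object of class `rdm`.
#' @seealso [compute_rdm()], [upper_vector()], [compare_rdms()]
#' @export
rdm <- function(values, condition_ids = NULL) {
  if (!is.matrix(values) || nrow(values) != ncol(values))
    stop("an RDM must be a square matrix")
  if (nrow(values) < 2) stop("an RDM needs at least 2 conditions")
  if (is.null(condition_ids)) {
    condition_ids <- rownames(values)
    if (is.null(condition_ids)) condition_ids <- paste0("cond", seq_len(nrow(values)))
  }
  dimnames(values) <- list(condition_ids, condition_ids)
  out <- structure(values, class = c("rdm", class(values)))
  validate_rdm(out)
  out
}

#' Validate RDM invariants
#'
#' Checks symmetry, an exactly zero diagonal, and entries in \[0, 2\] up to a
#' 1e-12 tolerance for numerical overshoot. Overshoot within the tolerance is
#' accepted as-is (never clamped); anything beyond it is an error.
#'
#' @param x an `rdm` object or square matrix.
#' @param tol numerical tolerance for symmetry and range checks.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_rdm <- function(x, tol = 1e-12) {
  if (!isSymmetric(unclass(x), tol = tol, check.attributes = FALSE))
    stop("invalid RDM: matrix is not symmetric")
  if (any(diag(x) != 0))
    stop("invalid RDM: diagonal must be exactly zero")
  if (any(x < -tol) || any(x > 2 + tol))
    stop("invalid RDM: entries outside [0, 2] beyond numerical tolerance")
  invisible(x)
}

#' @export
print.rdm <- function(x, ...) {
  nm <- attr(x, "model_name")
  what <- if (is.null(nm)) "RDM" else sprintf("Model RDM '%s'", nm)
  cat(sprintf("%s over %d conditions (%d upper-triangle dissimilarities)\n",
              what, nrow(x), nrow(x) * (nrow(x) - 1L) / 2L))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Compute an RDM from activity patterns
#'
#' Dissimilarity between conditions i and j is 1 minus the Pearson
#' correlation of their pattern rows across channels, giving a symmetric
#' matrix with zero diagonal and entries in \[0, 2\].
#'
#' @param patterns an [activity_patterns()] object or a conditions-by-channels
#'   numeric matrix (at least 3 conditions, 2 channels).
#' @return an [rdm()] object.
#' @details A condition row with zero variance across channels has no defined
#'   correlation; such degenerate rows raise an error naming the condition.
#' @examples
#' x <- rbind(a = c(1, 2, 3), b = c(3, 2, 1), c = c(1, 3, 2))
#' compute_rdm(x)  # d(a,b) = 2, d(a,c) = 0.5, d(b,c) = 1.5
#' @export
compute_rdm <- function(patterns) {
  x <- unclass(patterns)
  if (!is.matrix(x) || !is.numeric(x)) stop("'patterns' must be a numeric matrix")
  if (nrow(x) < 3) stop("need at least 3 conditions to build an RDM")
  if (ncol(x) < 2) stop("need at least 2 channels to build an RDM")
  ids <- rownames(x)
  if (is.null(ids)) ids <- paste0("cond", seq_len(nrow(x)))
  v <- .rowvar(x)
  if (any(v <= 0 | !is.finite(v)))
    stop("degenerate activity pattern: zero variance across channels for condition(s) ",
         paste(ids[v <= 0 | !is.finite(v)], collapse = ", "))
  d <- 1 - stats::cor(t(x))
  if (any(d < -1e-12) || any(d > 2 + 1e-12))
    stop("numerical overshoot: dissimilarities escaped [0, 2] beyond tolerance")
  diag(d) <- 0
  d <- (d + t(d)) / 2
  rdm(d, condition_ids = ids)
}

#' Vectorize the upper triangle of an RDM
#'
#' Returns the n(n-1)/2 dissimilarities above the diagonal in row-major
#' order: (1,2), (1,3), ..., (1,n), (2,3), .... This order is fixed so that
#' saved vectors are reproducible.
#'
#' @param x an `rdm` object (validated before extraction).
#' @return numeric vector of length n(n-1)/2, named `i:j` by condition pair.
#' @export
upper_vector <- function(x) {
  if (!inherits(x, "rdm")) {
    if (is.matrix(x)) x <- rdm(x) else stop("'x' must be an rdm")
  }
  validate_rdm(x)
  n <- nrow(x)
  v <- .ut(unclass(x))
  p <- .ut_pairs(n)
  names(v) <- paste(rownames(x)[p[, 1]], rownames(x)[p[, 2]], sep = ":")
  v
}

#' Compare two RDMs by Pearson correlation
#'
#' The unit of comparison is the upper-triangle vector (diagonal excluded).
#' Conditions are aligned by ordered label match: both RDMs must carry the
#' same condition labels in the same order, which catches accidental
#' reordering between datasets.
#'
#' @param rdm_a,rdm_b `rdm` objects over the same ordered condition set.
#' @return Pearson correlation of the two upper-triangle vectors, in \[-1, 1\].
#' @examples
#' d <- factorial_design(position = 4, category = 4)
#' compare_rdms(binary_factor_model(d, "position"),
#'              binary_factor_model(d, "category"))  # -0.25
#' @export
compare_rdms <- function(rdm_a, rdm_b) {
  if (!inherits(rdm_a, "rdm") || !inherits(rdm_b, "rdm"))
    stop("both arguments must be rdm objects")
  if (nrow(rdm_a) != nrow(rdm_b) || !identical(rownames(rdm_a), rownames(rdm_b)))
    stop("condition sets do not align: RDMs must share the same ordered condition labels")
  a <- .ut(unclass(rdm_a))
  b <- .ut(unclass(rdm_b))
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop("degenerate RDM comparison: an upper-triangle vector has zero variance")
  stats::cor(a, b)
}

#' Build an RDM series from time-resolved patterns
#'
#' Computes one RDM per time sample. Accepts either a list of
#' conditions-by-channels matrices (one per sample) or a 3-dimensional array
#' `conditions x channels x time`.
#'
#' @param patterns_over_time list of matrices or a 3-d array.
#' @param condition_ids optional condition labels (default from the first
#'   sample's rownames).
#' @param roi_name region label carried along for reporting.
#' @return an `rdm_series` object: the T upper-triangle vectors stored as an
#'   n(n-1)/2 x T matrix plus condition metadata.
#' @details Any degenerate sample (zero-variance condition row) raises an
#'   error reporting the offending time index.
#' @export
rdm_series <- function(patterns_over_time, condition_ids = NULL, roi_name = "roi") {
  if (is.array(patterns_over_time) && length(dim(patterns_over_time)) == 3) {
    a <- patterns_over_time
    if (is.null(condition_ids)) condition_ids <- dimnames(a)[[1]]
    if (!is.null(attr(patterns_over_time, "roi_name")) && missing(roi_name))
      roi_name <- attr(patterns_over_time, "roi_name")
    samples <- lapply(seq_len(dim(a)[3]), function(t) a[, , t])
  } else if (is.list(patterns_over_time)) {
    samples <- lapply(patterns_over_time, unclass)
    if (is.null(condition_ids)) condition_ids <- rownames(samples[[1]])
  } else stop("'patterns_over_time' must be a list of matrices or a 3-d array")
  if (length(samples) < 1) stop("need at least one time sample")
  n <- nrow(samples[[1]])
  if (n < 3) stop("need at least 3 conditions")
  if (is.null(condition_ids)) condition_ids <- paste0("cond", seq_len(n))
  if (any(vapply(samples, nrow, 0L) != n))
    stop("inconsistent condition count across time samples")
  m <- n * (n - 1L) / 2L
  vecs <- matrix(NA_real_, m, length(samples))
  for (t in seq_along(samples)) {
    vecs[, t] <- tryCatch(.rdm_vec(samples[[t]]),
                          error = function(e) stop("at time sample ", t, ": ",
                                                   conditionMessage(e), call. = FALSE))
  }
  structure(list(vectors = vecs, condition_ids = condition_ids, n = n,
                 roi_name = roi_name),
            class = "rdm_series")
}

#' @export
print.rdm_series <- function(x, ...) {
  cat(sprintf("RDM series for ROI '%s': %d conditions, %d time samples\n",
              x$roi_name, x$n, ncol(x$vectors)))
  invisible(x)
}

#' @export
length.rdm_series <- function(x) ncol(x$vectors)

#' Extract one RDM from an RDM series
#'
#' @param x an `rdm_series`.
#' @param t time index (1-based position in the series).
#' @return an [rdm()] object.
#' @export
series_rdm <- function(x, t) {
  stopifnot(inherits(x, "rdm_series"), t >= 1, t <= ncol(x$vectors))
  n <- x$n
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- 0  # filled below via transpose trick
  p <- .ut_pairs(n)
  m[cbind(p[, 1], p[, 2])] <- x$vectors[, t]
  m[cbind(p[, 2], p[, 1])] <- x$vectors[, t]
  rdm(m, condition_ids = x$condition_ids)
}
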