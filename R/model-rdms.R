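#' Build a full-crossing factorial condition design
#'
#' Creates the condition set as the full crossing of named factors. The
#' condition order is fixed and documented: the first factor is the outer
#' loop (varies slowest), the last factor the inner loop. The default
#' stimulus set of the packaged experiments is 4 positions x 4 semantic
#' categories = 16 conditions.
#'
#' @param ... named integer level counts, e.g. `position = 4, category = 4`;
#'   each factor needs at least 2 levels.
#' @return a `condition_design`: a data.frame with one factor per column
#'   (integer level codes), rownames giving condition ids such as
#'   `position1.category2`.
#' @examples
#' d <- factorial_design(position = 4, category = 4)
#' nrow(d)  # 16
#' @export
factorial_design <- function(...) {
  counts <- c(...)
  if (length(counts) == 0) stop("at least one factor is required")
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("all factors must be named")
  if (any(counts < 2)) stop("each factor needs at least 2 levels")
  # expand.grid varies the FIRST column fastest; reverse to make the first
  # factor the outer (slowest) loop, then restore column order
  g <- expand.grid(rev(lapply(counts, seq_len)), KEEP.OUT.ATTRS = FALSE)
  g <- g[, rev(seq_along(counts)), drop = FALSE]
  names(g) <- names(counts)
  ids <- apply(g, 1L, function(r) paste0(names(counts), r, collapse = "."))
  rownames(g) <- ids
  structure(g, class = c("condition_design", "data.frame"))
}

#' @export
print.condition_design <- function(x, ...) {
  cat(sprintf("Factorial condition design: %s (%d conditions)\n",
              paste(names(x), vapply(x, max, 0L), sep = "=", collapse = " x "),
              nrow(x)))
  invisible(x)
}

.check_factor <- function(design, factor) {
  if (!inherits(design, "condition_design")) stop("'design' must be a condition_design")
  if (!factor %in% names(design))
    stop("unknown factor '", factor, "'; design has: ", paste(names(design), collapse = ", "))
}

.model_rdm <- function(values, design, model_name, rule) {
  out <- rdm(values, condition_ids = rownames(design))
  attr(out, "model_name") <- model_name
  attr(out, "rule") <- rule
  class(out) <- c("model_rdm", class(out))
  out
}

#' Binary single-factor model RDM
#'
#' The model RDM hypothesizing that a region represents one factor only:
#' entry (i, j) is 0 when conditions i and j share the factor's level and 1
#' otherwise. For the 4 x 4 default design each factor model has 24 zeros
#' and 96 ones in its 120-element upper triangle, and the position and
#' category models correlate at exactly -0.25.
#'
#' @param design a [factorial_design()].
#' @param factor name of the factor the model represents.
#' @return a `model_rdm` (inherits from `rdm`).
#' @export
binary_factor_model <- function(design, factor) {
  .check_factor(design, factor)
  lev <- design[[factor]]
  m <- 1 * outer(lev, lev, "!=")
  .model_rdm(m, design, model_name = factor,
             rule = "0 if same level, 1 otherwise")
}

#' Intermediate (two-factor) model RDM
#'
#' A model RDM carrying components of both factors of a two-factor design:
#' entry (i, j) counts the factors on which conditions i and j differ (0, 1
#' or 2), which equals the elementwise sum of the two binary factor models.
#' Pairs differing in both factors are hypothesized maximally dissimilar.
#' By symmetry of the construction this model correlates identically with
#' each component model (~ 0.612 for the 4 x 4 design).
#'
#' @param design a two-factor [factorial_design()].
#' @return a `model_rdm` with entries in \{0, 1, 2\}.
#' @export
intermediate_model <- function(design) {
  if (!inherits(design, "condition_design")) stop("'design' must be a condition_design")
  if (length(design) != 2)
    stop("the intermediate model is defined for exactly two factors")
  m <- Reduce(`+`, lapply(names(design), function(f) {
    lev <- design[[f]]
    1 * outer(lev, lev, "!=")
  }))
  .model_rdm(m, design, model_name = "intermediate",
             rule = "count of factors on which the pair differs")
}

#' Random model RDM
#'
#' A geometrically valid random RDM, generated as the RDM of a random
#' Gaussian latent pattern matrix (n conditions x k latent channels). Used
#' to probe how model-to-model similarity relates to common-input
#' sensitivity. Deterministic given the seed.
#'
#' @param n_conditions number of conditions (>= 3).
#' @param seed integer seed making the model reproducible.
#' @param k number of latent channels (default 30).
#' @param condition_ids optional labels; default `cond<i>`.
#' @return a `model_rdm`.
#' @export
random_model <- function(n_conditions, seed, k = 30, condition_ids = NULL) {
  if (n_conditions < 3) stop("need at least 3 conditions")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  x <- matrix(stats::rnorm(n_conditions * k), n_conditions, k)
  if (!is.null(condition_ids)) rownames(x) <- condition_ids
  out <- compute_rdm(x)
  attr(out, "model_name") <- sprintf("random(seed=%d,k=%d)", as.integer(seed), k)
  attr(out, "rule") <- "RDM of a random Gaussian latent pattern matrix"
  class(out) <- c("model_rdm", class(out))
  out
}

# preserve the caller's RNG state around internally seeded draws
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
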