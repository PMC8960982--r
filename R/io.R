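#' Read and write RDMs as CSV matrices
#'
#' RDMs are stored as plain CSV: a header row of condition ids, one row per
#' condition. `write_rdm()` refuses invalid RDMs; `read_rdm()` validates on
#' the way in, so round-trips are loss-free up to numeric formatting.
#'
#' @param x an [rdm()].
#' @param file path to a CSV file.
#' @return `read_rdm()` returns an `rdm`; `write_rdm()` returns `file`
#'   invisibly.
#' @export
write_rdm <- function(x, file) {
  validate_rdm(x)
  utils::write.csv(as.data.frame(unclass(x)), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_rdm
#' @export
read_rdm <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE)
  m <- as.matrix(df)
  rownames(m) <- colnames(m)
  rdm(m)
}

#' Read and write RDM upper-triangle vectors as single-column CSV
#'
#' @param v a named numeric vector as returned by [upper_vector()].
#' @param file path to a CSV file.
#' @export
write_rdm_vector <- function(v, file) {
  utils::write.csv(data.frame(pair = names(v), dissimilarity = as.numeric(v)),
                   file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_rdm_vector
#' @export
read_rdm_vector <- function(file) {
  df <- utils::read.csv(file)
  stats::setNames(df$dissimilarity, df$pair)
}

#' Read and write activity patterns as CSV
#'
#' One time sample per file: conditions in rows (first column holds the
#' condition id), channels in columns.
#'
#' @param x an [activity_patterns()] object.
#' @param file path to a CSV file.
#' @param roi_name region label attached on reading.
#' @export
write_patterns <- function(x, file) {
  df <- data.frame(condition = rownames(x), unclass(x), check.names = FALSE,
                   row.names = NULL)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_patterns
#' @export
read_patterns <- function(file, roi_name = "roi") {
  df <- utils::read.csv(file, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  activity_patterns(m, condition_ids = as.character(df[[1]]), roi_name = roi_name)
}

#' Write a time-resolved subject dataset as a CSV bundle
#'
#' One CSV per ROI and time sample plus a JSON manifest carrying the
#' provenance (seed, config summary, windows and delays where present).
#'
#' @param dataset a `subject_dataset`.
#' @param dir output directory.
#' @return the manifest path, invisibly.
#' @export
write_subject_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "subject_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(type = dataset$type, seed = dataset$seed,
                   n_conditions = nrow(dataset$config$design),
                   channels = c(dataset$config$channels_roi1,
                                dataset$config$channels_roi2))
  for (roi in c("roi1", "roi2")) {
    a <- dataset[[roi]]
    if (dataset$type == "static") {
      f <- sprintf("%s.csv", roi)
      write_patterns(dataset[[roi]], file.path(dir, f))
      manifest[[roi]] <- f
    } else {
      T <- dim(a)[3]
      files <- sprintf("%s_t%03d.csv", roi, seq_len(T) - 1L)
      for (t in seq_len(T))
        write_patterns(activity_patterns(a[, , t], roi_name = roi),
                       file.path(dir, files[t]))
      manifest[[roi]] <- files
    }
  }
  if (!is.null(dataset$windows)) {
    manifest$windows <- dataset$windows
    manifest$jitter <- dataset$jitter
    manifest$congruent <- dataset$congruent
  }
  if (!is.null(dataset$common_input)) manifest$common_input <- dataset$common_input
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
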