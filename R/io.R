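# Format glue: 4D volumes as one multi-page TIFF stack per time step
# (zero-padded time index in the filename, one page per z slice), matrices
# as labelled CSV, and complete model specifications as JSON.

volume_files <- function(dir, prefix) {
  files <- list.files(dir, pattern = paste0("^", prefix, "_t\\d+\\.tif$"),
                      full.names = TRUE)
  if (!length(files))
    stop_io("no files matching %s_t*.tif found in %s", prefix, dir)
  sort(files)
}

#' Read and write 4D label volumes as per-timestep TIFF stacks
#'
#' Each time step is one multi-page TIFF (`<prefix>_t<index>.tif`, 0-based
#' zero-padded index) holding `Z` pages of `Y x X` images. Labels are stored
#' as 8-bit samples (class codes 0..255, exact round trip); confidences as
#' 32-bit float samples.
#'
#' @param labels integer `(T, Z, Y, X)` array.
#' @param dir directory for the stack files.
#' @param prefix filename prefix, default `"labels"`.
#' @return `write_*` return the written file paths invisibly; `read_*`
#'   return the assembled `(T, Z, Y, X)` array.
#' @rdname volume_io
#' @export
write_label_volume <- function(labels, dir, prefix = "labels") {
  check_volume4d(labels)
  if (any(labels < 0) || any(labels > 255))
    stop_io("labels must be in [0, 255] for 8-bit storage")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(labels)
  paths <- character(d[1])
  for (t in seq_len(d[1])) {
    pages <- lapply(seq_len(d[2]), function(z)
      matrix(labels[t, z, , ] / 255, d[3], d[4]))
    paths[t] <- file.path(dir, sprintf("%s_t%03d.tif", prefix, t - 1L))
    tiff::writeTIFF(pages, paths[t], bits.per.sample = 8L)
  }
  invisible(paths)
}

#' @rdname volume_io
#' @export
read_label_volume <- function(dir, prefix = "labels") {
  files <- volume_files(dir, prefix)
  stacks <- lapply(files, function(f) {
    pages <- tiff::readTIFF(f, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages
  })
  d <- c(length(files), length(stacks[[1]]), dim(stacks[[1]][[1]]))
  out <- array(0L, dim = d)
  for (t in seq_along(stacks)) for (z in seq_along(stacks[[t]]))
    out[t, z, , ] <- as.integer(round(stacks[[t]][[z]] * 255))
  out
}

#' @param conf numeric `(T, Z, Y, X)` confidence array.
#' @rdname volume_io
#' @export
write_confidence_volume <- function(conf, dir, prefix = "confidence") {
  check_volume4d(conf, what = "confidence")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(conf)
  paths <- character(d[1])
  for (t in seq_len(d[1])) {
    pages <- lapply(seq_len(d[2]), function(z) matrix(conf[t, z, , ], d[3], d[4]))
    paths[t] <- file.path(dir, sprintf("%s_t%03d.tif", prefix, t - 1L))
    tiff::writeTIFF(pages, paths[t], bits.per.sample = 32L)
  }
  invisible(paths)
}

#' @rdname volume_io
#' @export
read_confidence_volume <- function(dir, prefix = "confidence") {
  files <- volume_files(dir, prefix)
  stacks <- lapply(files, function(f) {
    pages <- tiff::readTIFF(f, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages
  })
  d <- c(length(files), length(stacks[[1]]), dim(stacks[[1]][[1]]))
  out <- array(0, dim = d)
  for (t in seq_along(stacks)) for (z in seq_along(stacks[[t]]))
    out[t, z, , ] <- stacks[[t]][[z]]
  out
}

#' Read and write probability/count matrices as labelled CSV
#'
#' Matrices are written with a header row of column labels and a leading
#' column of row labels, probabilities at full double precision.
#'
#' @param m matrix.
#' @param path CSV file path.
#' @param row_labels,col_labels identifier vectors; defaults taken from
#'   `dimnames` or generated.
#' @rdname matrix_io
#' @export
write_matrix_csv <- function(m, path, row_labels = rownames(m),
                             col_labels = colnames(m)) {
  m <- as.matrix(m)
  if (is.null(row_labels)) row_labels <- paste0("class", seq_len(nrow(m)) - 1L)
  if (is.null(col_labels)) col_labels <- paste0("obs", seq_len(ncol(m)) - 1L)
  df <- data.frame(label = row_labels,
                   format(m, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  names(df) <- c("label", col_labels)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname matrix_io
#' @export
read_matrix_csv <- function(path) {
  if (!file.exists(path)) stop_io("matrix file not found: %s", path)
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' Serialize a complete model specification to JSON
#'
#' The JSON document bundles `n_classes`, `n_bins`, class names, the
#' transition and emission matrices (row-major nested arrays with
#' self-describing column labels) and the starting vector, at full double
#' precision.
#'
#' @param spec an [hmm_spec()].
#' @param path JSON file path.
#' @rdname spec_io
#' @export
write_hmm_spec <- function(spec, path) {
  stopifnot(inherits(spec, "hmm_spec"))
  jsonlite::write_json(
    list(n_classes = spec$n_classes, n_bins = spec$n_bins,
         class_names = spec$class_names,
         observable_labels = observable_labels(spec$n_classes, spec$n_bins,
                                               spec$class_names),
         transition = spec$transition, emission = spec$emission,
         start = spec$start),
    path, auto_unbox = TRUE, digits = I(17), matrix = "rowmajor")
  invisible(path)
}

#' @rdname spec_io
#' @export
read_hmm_spec <- function(path) {
  if (!file.exists(path)) stop_io("spec file not found: %s", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cn <- x$class_names
  if (length(cn) == 0) cn <- NULL
  hmm_spec(transition = x$transition, emission = x$emission,
           start = x$start, n_bins = x$n_bins, class_names = cn)
}

# Stable content fingerprint of a spec for provenance reports.
spec_fingerprint <- function(spec) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  write_hmm_spec(spec, f)
  unname(tools::md5sum(f))
}
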