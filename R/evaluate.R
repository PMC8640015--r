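# Evaluation and baselines: per-class / mean intersection-over-union,
# confusion-matrix tallying (square and confidence-binned rectangular), and
# the 1D temporal median-filter baseline.

#' Per-class and mean intersection over union
#'
#' For each class `c`, IoU is `|pred==c & truth==c| / |pred==c | truth==c|`.
#' A class absent from both volumes has an undefined ratio; it is scored 1
#' and flagged in the `absent` field so the convention is visible. The mean
#' is unweighted across classes.
#'
#' @param pred,truth integer label arrays of identical shape.
#' @param n_classes number of classes.
#' @param n_images optional count of 2D slice images the comparison spans
#'   (reported, not used in the computation).
#' @return an `iou_report`: list with `per_class` (named numeric vector),
#'   `mean_iou`, `absent` (logical), `n_images`.
#' @examples
#' iou(c(0, 1, 1, 0), c(0, 1, 0, 0), n_classes = 2)
#' @export
iou <- function(pred, truth, n_classes, n_images = NA_integer_) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth))
    stop_config("pred and truth must have identical shape")
  if (any(pred < 0) || any(pred >= n_classes) ||
      any(truth < 0) || any(truth >= n_classes))
    stop_config("labels must lie in [0, %d]", n_classes - 1L)
  per <- numeric(n_classes)
  absent <- logical(n_classes)
  for (c in seq_len(n_classes) - 1L) {
    p <- pred == c
    t <- truth == c
    un <- sum(p | t)
    if (un == 0) {
      per[c + 1L] <- 1
      absent[c + 1L] <- TRUE
    } else {
      per[c + 1L] <- sum(p & t) / un
    }
  }
  names(per) <- paste0("class", seq_len(n_classes) - 1L)
  structure(list(per_class = per, mean_iou = mean(per), absent = absent,
                 n_images = n_images),
            class = "iou_report")
}

#' @export
print.iou_report <- function(x, ...) {
  cat("IoU per class:\n")
  print(round(x$per_class, 4))
  cat(sprintf("mean IoU: %.4f\n", x$mean_iou))
  if (any(x$absent))
    cat("absent from both volumes (scored 1):",
        paste(names(x$per_class)[x$absent], collapse = ", "), "\n")
  if (!is.na(x$n_images)) cat(sprintf("slices compared: %d\n", x$n_images))
  invisible(x)
}

#' Tally a confusion matrix from predictions and ground truth
#'
#' Counts `[truth class, observable]` occurrences over all toxels. With
#' `n_bins = 1` the observable is the predicted class (square matrix); with
#' `n_bins > 1` it is the class-by-confidence-bin composite, giving the
#' rectangular `N x (N * n_bins)` matrix a confidence-binned model needs.
#'
#' @param pred integer label array.
#' @param truth integer label array, same shape.
#' @param conf confidence array, required when `n_bins > 1`.
#' @param n_classes number of classes.
#' @param n_bins number of confidence bins (default 1).
#' @param class_names optional display names used for labels.
#' @return a [confusion_matrix()].
#' @export
tally_confusion <- function(pred, truth, conf = NULL, n_classes,
                            n_bins = 1L, class_names = NULL) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth))
    stop_config("pred and truth must have identical shape")
  n_bins <- as.integer(n_bins)
  if (n_bins > 1) {
    if (is.null(conf))
      stop_config("a confidence array is required when n_bins > 1")
    if (length(conf) != length(pred))
      stop_config("conf must have the same shape as pred")
    bins <- confidence_bin(as.vector(conf), n_classes, n_bins)
    obs <- composite_observable(as.vector(pred), bins, n_bins, n_classes)
  } else {
    obs <- as.integer(pred)
  }
  m <- n_classes * n_bins
  idx <- as.integer(truth) * m + obs + 1L
  counts <- matrix(tabulate(idx, nbins = n_classes * m),
                   nrow = n_classes, ncol = m, byrow = TRUE)
  confusion_matrix(counts, n_bins = n_bins,
                   row_labels = class_names,
                   col_labels = observable_labels(n_classes, n_bins, class_names))
}

#' Temporal 1D median filter baseline
#'
#' Replaces each toxel's label by the median of the integer labels in a
#' centred window along time (nearest-edge padding at the sequence ends).
#' The median is taken on the integer class codes, so for more than two
#' classes the result depends on the code ordering; this mirrors the usual
#' simplistic post-processing baseline literally.
#'
#' @param labels integer `(T, Z, Y, X)` array.
#' @param window odd window size in time steps, default 5.
#' @return filtered label array, same shape.
#' @export
median_filter_time <- function(labels, window = 5L) {
  check_volume4d(labels)
  window <- as.integer(window)
  if (window < 1 || window %% 2 == 0)
    stop_config("window must be an odd positive integer")
  dims <- dim(labels)
  mat <- matrix(as.integer(labels), nrow = dims[1])
  array(.median_time_cpp(mat, window), dim = dims)
}

#' Serialize an IoU report
#'
#' `write_iou_table()` writes one CSV row per method (columns: per-class IoU
#' then the mean); `write_iou_json()` writes a single report as JSON.
#'
#' @param reports named list of `iou_report` objects (names = method names).
#' @param path output file path.
#' @rdname iou_serialize
#' @export
write_iou_table <- function(reports, path) {
  if (inherits(reports, "iou_report")) reports <- list(result = reports)
  rows <- lapply(reports, function(r) c(r$per_class, mean = r$mean_iou))
  df <- as.data.frame(do.call(rbind, rows))
  df <- cbind(method = names(reports), df)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @param report a single `iou_report`.
#' @rdname iou_serialize
#' @export
write_iou_json <- function(report, path) {
  jsonlite::write_json(
    list(per_class = as.list(report$per_class),
         mean_iou = report$mean_iou,
         absent = names(report$per_class)[report$absent],
         n_images = report$n_images),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
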