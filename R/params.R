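# HMM parameter objects and builders. All class and observable indices are
# 0-based throughout the package, matching the integer values stored in label
# volumes.

ROW_TOL <- 1e-9

check_stochastic <- function(m, what) {
  if (any(!is.finite(m)) || any(m < 0) || any(m > 1))
    stop_config("%s must have entries in [0, 1]", what)
  rs <- if (is.matrix(m)) rowSums(m) else sum(m)
  if (any(abs(rs - 1) > ROW_TOL))
    stop_config("%s rows must sum to 1 (max deviation %.3g)", what,
                max(abs(rs - 1)))
  invisible(TRUE)
}

#' Bundle the complete parameter set of a label-refinement HMM
#'
#' An `hmm_spec` holds everything needed to decode a toxel sequence: the
#' row-stochastic transition matrix (entry `[i, j]` is the probability of
#' hidden class `i-1` becoming class `j-1` in the next time step), the
#' row-stochastic emission matrix (entry `[s, e]` is the probability that
#' hidden class `s-1` is observed as observable `e-1`), and the starting
#' probability vector over hidden classes at `t = 0`. For a plain
#' label-observation model (HMM-T) the emission matrix is square
#' (`n_bins = 1`); for a confidence-binned model (HMM-TC) it has
#' `n_classes * n_bins` columns, one per class-by-confidence-bin composite
#' observable (see [composite_observable()]).
#'
#' @param transition numeric `N x N` row-stochastic matrix.
#' @param emission numeric `N x (N * n_bins)` row-stochastic matrix.
#' @param start numeric length-`N` probability vector; defaults to uniform.
#' @param n_bins number of confidence bins encoded in the emission columns
#'   (1 for HMM-T).
#' @param class_names optional character vector of `N` display names.
#' @return An object of class `hmm_spec` with fields `n_classes`, `n_bins`,
#'   `transition`, `emission`, `start` and `class_names`.
#' @examples
#' spec <- hmm_spec(
#'   transition = build_transition_default(4),
#'   emission   = diag(4),
#'   start      = build_start_uniform(4)
#' )
#' spec
#' @export
hmm_spec <- function(transition, emission, start = NULL, n_bins = 1L,
                     class_names = NULL) {
  transition <- as.matrix(transition)
  emission <- as.matrix(emission)
  n <- nrow(transition)
  n_bins <- as.integer(n_bins)
  if (n < 1 || ncol(transition) != n)
    stop_config("transition must be a square matrix")
  if (is.null(start)) start <- build_start_uniform(n)
  if (n_bins < 1) stop_config("n_bins must be >= 1")
  if (nrow(emission) != n)
    stop_config("emission must have one row per hidden class (%d)", n)
  if (ncol(emission) != n * n_bins)
    stop_config("emission must have n_classes * n_bins = %d columns, found %d",
                n * n_bins, ncol(emission))
  if (length(start) != n)
    stop_config("start must have length n_classes (%d)", n)
  check_stochastic(transition, "transition")
  check_stochastic(emission, "emission")
  check_stochastic(start, "start")
  if (!is.null(class_names) && length(class_names) != n)
    stop_config("class_names must have length n_classes (%d)", n)
  structure(
    list(n_classes = as.integer(n), n_bins = n_bins,
         transition = unname(transition), emission = unname(emission),
         start = unname(as.numeric(start)),
         class_names = if (is.null(class_names)) NULL else as.character(class_names)),
    class = "hmm_spec")
}

#' @export
print.hmm_spec <- function(x, ...) {
  kind <- if (x$n_bins == 1L) "HMM-T (label observables)" else
    sprintf("HMM-TC (%d confidence bins)", x$n_bins)
  cat(sprintf("hmm_spec: %d hidden classes, %d observables [%s]\n",
              x$n_classes, ncol(x$emission), kind))
  if (!is.null(x$class_names))
    cat("classes:", paste(x$class_names, collapse = ", "), "\n")
  invisible(x)
}

#' Confusion-matrix tallies from a segmenter's testing
#'
#' Raw integer counts with ground-truth classes as rows and observable states
#' as columns: `N` columns for plain label observables, `N * n_bins` for
#' confidence-binned composites. Converted to an emission matrix by
#' [emission_from_confusion()].
#'
#' @param counts non-negative integer matrix.
#' @param n_bins number of confidence bins spanned by the columns.
#' @param row_labels,col_labels optional identifier vectors; defaults are
#'   derived from class indices and bin indices.
#' @return An object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(counts, n_bins = 1L, row_labels = NULL,
                             col_labels = NULL) {
  counts <- as.matrix(counts)
  n_bins <- as.integer(n_bins)
  n <- nrow(counts)
  if (n_bins < 1) stop_config("n_bins must be >= 1")
  if (ncol(counts) != n * n_bins)
    stop_config("counts must have n_classes * n_bins = %d columns, found %d",
                n * n_bins, ncol(counts))
  if (any(counts < 0) || any(counts != round(counts)))
    stop_config("counts must be non-negative integers")
  if (is.null(row_labels)) row_labels <- paste0("class", seq_len(n) - 1L)
  if (is.null(col_labels)) col_labels <- observable_labels(n, n_bins, row_labels)
  if (length(row_labels) != n || length(col_labels) != ncol(counts))
    stop_config("label lengths do not match the counts matrix")
  structure(list(counts = unname(counts), n_classes = as.integer(n),
                 n_bins = n_bins, row_labels = as.character(row_labels),
                 col_labels = as.character(col_labels)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion_matrix: %d classes x %d observables (%d bins)\n",
              x$n_classes, ncol(x$counts), x$n_bins))
  m <- x$counts
  dimnames(m) <- list(x$row_labels, x$col_labels)
  print(m)
  invisible(x)
}

# Column labels for composite observables, class-major so serialized files
# are self-describing about the ordering convention.
observable_labels <- function(n_classes, n_bins, class_names = NULL) {
  if (is.null(class_names)) class_names <- paste0("class", seq_len(n_classes) - 1L)
  if (n_bins == 1L) return(class_names)
  bins <- if (n_bins == 3L) c("low", "mid", "high") else paste0("bin", seq_len(n_bins) - 1L)
  as.vector(t(outer(class_names, bins, paste, sep = ".")))
}

#' Build the default (empirically motivated) transition matrix
#'
#' Encodes the expected physical behaviour of a slowly dissolving phase:
#' classes persist (diagonal dominance), the dissolving class converts to its
#' product with probability `p_convert` per time step (10% by default), and
#' all other ordered class pairs receive a small cross-term `eps` covering
#' rare events such as slight misalignment between time steps or thermal
#' expansion. Each diagonal entry absorbs the remainder so rows sum to 1.
#'
#' @param n_classes number of segmentation classes (>= 2).
#' @param dissolving,product 0-based indices of the dissolving class and the
#'   class it irreversibly converts into. Set `dissolving = NULL` to build a
#'   matrix with no conversion pair (cross-terms only).
#' @param p_convert per-step conversion probability, default 0.10.
#' @param eps cross-term probability for all other ordered pairs, default 1e-3.
#' @return `n_classes x n_classes` row-stochastic matrix.
#' @examples
#' round(build_transition_default(4), 4)
#' @export
build_transition_default <- function(n_classes = 4L, dissolving = 2L,
                                     product = 3L, p_convert = 0.10,
                                     eps = 1e-3) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 2) stop_config("n_classes must be >= 2")
  if (eps < 0 || p_convert < 0 || p_convert > 1)
    stop_config("p_convert must be in [0, 1] and eps >= 0")
  m <- matrix(eps, n_classes, n_classes)
  if (!is.null(dissolving)) {
    if (is.null(product)) stop_config("product class must be given with dissolving")
    dissolving <- as.integer(dissolving); product <- as.integer(product)
    if (dissolving < 0 || dissolving >= n_classes ||
        product < 0 || product >= n_classes)
      stop_config("dissolving/product class indices must be in [0, %d]", n_classes - 1L)
    if (dissolving == product)
      stop_config("dissolving and product classes must differ")
    m[dissolving + 1L, product + 1L] <- p_convert
  }
  diag(m) <- 0
  d <- 1 - rowSums(m)
  if (any(d < 0))
    stop_config("off-diagonal mass exceeds 1 in row %d; reduce eps or p_convert",
                which(d < 0)[1])
  diag(m) <- d
  m
}

#' Build the naive transition matrix (all transitions equally probable)
#'
#' Every entry is `1/N`: staying and moving to any other class are equally
#' likely. Under this matrix every label sequence is equally coherent, so
#' decoding reduces to a per-step emission argmax and refinement leaves
#' typical segmentations unchanged — the degenerate baseline.
#'
#' @param n_classes number of classes (>= 2).
#' @return constant `N x N` matrix with entries `1/N`.
#' @export
build_transition_naive <- function(n_classes) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 2) stop_config("n_classes must be >= 2")
  matrix(1 / n_classes, n_classes, n_classes)
}

#' Build the naive-stable transition matrix (50% chance of staying)
#'
#' Diagonal entries are 0.5; the remaining 50% mass in each row is spread
#' uniformly over the other `N - 1` classes.
#'
#' @param n_classes number of classes (>= 2).
#' @return `N x N` row-stochastic matrix.
#' @export
build_transition_naive_stable <- function(n_classes) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 2) stop_config("n_classes must be >= 2")
  m <- matrix(0.5 / (n_classes - 1), n_classes, n_classes)
  diag(m) <- 0.5
  m
}

#' Uniform starting probabilities
#'
#' No class is more plausible than another specifically at `t = 0` (class
#' imbalance holds at every time step, not just the first), so the starting
#' vector is uniform.
#'
#' @param n_classes number of classes (>= 1).
#' @return length-`N` vector of `1/N`.
#' @export
build_start_uniform <- function(n_classes) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 1) stop_config("n_classes must be >= 1")
  rep(1 / n_classes, n_classes)
}

#' Convert confusion-matrix counts to emission probabilities
#'
#' Each row of the counts is divided by its row sum, giving for every
#' ground-truth (hidden) class the empirical distribution over observables.
#' Square counts give the plain emission matrix; rectangular,
#' confidence-binned counts give the binned one.
#'
#' @param cm a [confusion_matrix()] or a plain non-negative matrix.
#' @return row-stochastic matrix with the shape of the counts.
#' @export
emission_from_confusion <- function(cm) {
  if (inherits(cm, "confusion_matrix")) {
    counts <- cm$counts
    labels <- cm$row_labels
  } else {
    counts <- as.matrix(cm)
    labels <- paste0("class", seq_len(nrow(counts)) - 1L)
  }
  if (any(counts < 0)) stop_config("confusion counts must be non-negative")
  rs <- rowSums(counts)
  if (any(rs == 0))
    stop_config(
      "confusion matrix row for %s has zero sum: the test set never contained that class, its emission row is undefined",
      labels[which(rs == 0)[1]])
  counts / rs
}

#' Quantize a leading-class probability into a confidence bin
#'
#' The leading-class probability of an `N`-class prediction lies in
#' `(1/N, 1]`; this range is split into `n_bins` equal-width intervals. Bin
#' `k` (0-based) covers `[1/N + k*w, 1/N + (k+1)*w)` with
#' `w = (1 - 1/N) / n_bins`; intervals are closed below and open above,
#' except the top bin which is closed at 1. Degenerate values `p <= 1/N`
#' (a fully uncertain prediction) clamp to bin 0. With `n_bins = 3` the bins
#' are referred to as low-, mid- and high-confidence.
#'
#' @param p numeric vector of probabilities in `(0, 1]`.
#' @param n_classes number of classes.
#' @param n_bins number of bins (>= 1).
#' @return integer vector of bin indices in `[0, n_bins)`.
#' @examples
#' confidence_bin(c(0.3, 0.6, 0.9), n_classes = 4, n_bins = 3)
#' @export
confidence_bin <- function(p, n_classes, n_bins) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 1) stop_config("n_bins must be >= 1")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop_config("confidence values must lie in (0, 1]")
  lo <- 1 / n_classes
  w <- (1 - lo) / n_bins
  k <- floor((p - lo) / w)
  k <- pmax(0, pmin(n_bins - 1L, k))
  as.integer(k)
}

#' Composite observable index for a (class, confidence-bin) pair
#'
#' Confidence-binned models expand each predicted class into `n_bins`
#' observables; the composite index is class-major:
#' `class * n_bins + bin`. With 4 classes and 3 bins this enumerates the 12
#' composite observables 0..11.
#'
#' @param pred_class 0-based predicted class index (vector allowed).
#' @param bin_index 0-based bin index (vector allowed).
#' @param n_bins number of bins.
#' @param n_classes optional; when given, `pred_class` is range-checked.
#' @return integer composite observable indices.
#' @export
composite_observable <- function(pred_class, bin_index, n_bins,
                                 n_classes = NULL) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 1) stop_config("n_bins must be >= 1")
  if (any(bin_index < 0) || any(bin_index >= n_bins))
    stop_config("bin_index must lie in [0, %d]", n_bins - 1L)
  if (any(pred_class < 0))
    stop_config("pred_class must be >= 0")
  if (!is.null(n_classes) && any(pred_class >= n_classes))
    stop_config("pred_class must lie in [0, %d]", n_classes - 1L)
  as.integer(pred_class) * n_bins + as.integer(bin_index)
}

#' Adjust a binned emission matrix so each observable is dominated by its own class
#'
#' Emission matrices derived from a testing confusion matrix can assign an
#' observable's highest emission probability to a foreign hidden class when
#' class populations are very unbalanced (a rare class's row is normalized by
#' a small denominator, so occasional misclassifications inflate its
#' off-class probabilities). This adjustment enforces the intuitive
#' requirement that every low/mid/high-confidence observable of class `c` is
#' most likely emitted by hidden class `c`: for each violating column the
#' same-title entry is raised multiplicatively just above the column maximum,
#' rows are renormalized, and the pass repeats until the property holds for
#' every column. The procedure is idempotent.
#'
#' @param emission row-stochastic `N x (N * n_bins)` matrix.
#' @param n_bins number of bins encoded in the columns.
#' @param boost factor applied to the current column maximum when raising the
#'   same-title entry; must be > 1. Default 1.001.
#' @param max_iter safety bound on renormalization passes.
#' @return row-stochastic matrix in which, for every column `e`,
#'   `which.max(emission[, e])` is the base class of `e`.
#' @export
adjust_emission_diagonal <- function(emission, n_bins = 1L, boost = 1.001,
                                     max_iter = 100L) {
  emission <- as.matrix(emission)
  n <- nrow(emission)
  n_bins <- as.integer(n_bins)
  if (ncol(emission) != n * n_bins)
    stop_config("emission must have n_classes * n_bins = %d columns", n * n_bins)
  if (boost <= 1) stop_config("boost must be > 1")
  check_stochastic(emission, "emission")
  zero_cols <- which(colSums(emission) == 0)
  if (length(zero_cols))
    stop_config("emission column %d is entirely zero; no class emits that observable",
                zero_cols[1] - 1L)
  base_class <- rep(seq_len(n), each = n_bins) # 1-based owner of each column
  for (iter in seq_len(max_iter)) {
    owners <- apply(emission, 2, which.max)
    viol <- which(owners != base_class)
    if (!length(viol)) return(emission)
    for (e in viol) {
      c1 <- base_class[e]
      emission[c1, e] <- boost * max(emission[, e])
    }
    emission <- emission / rowSums(emission)
  }
  stop_config("diagonal adjustment did not converge in %d passes", max_iter)
}

#' Convenience constructors for complete model specifications
#'
#' `make_hmm_t_spec()` assembles a plain-label model from a transition
#' builder output and a square emission matrix; `make_hmm_tc_spec()`
#' assembles a confidence-binned model from a rectangular confusion matrix,
#' optionally applying the diagonal adjustment.
#'
#' @param transition `N x N` row-stochastic matrix.
#' @param emission square row-stochastic matrix (HMM-T) .
#' @param confusion a rectangular [confusion_matrix()] (HMM-TC).
#' @param adjust apply [adjust_emission_diagonal()] to the derived emission.
#' @param class_names optional class display names.
#' @return an [hmm_spec()].
#' @rdname make_hmm_spec
#' @export
make_hmm_t_spec <- function(transition, emission, class_names = NULL) {
  hmm_spec(transition, emission, n_bins = 1L, class_names = class_names)
}

#' @rdname make_hmm_spec
#' @export
make_hmm_tc_spec <- function(transition, confusion, adjust = TRUE,
                             class_names = NULL) {
  if (!inherits(confusion, "confusion_matrix"))
    stop_config("confusion must be a confusion_matrix")
  if (confusion$n_bins < 2)
    stop_config("a confidence-binned model needs n_bins >= 2 in the confusion matrix")
  em <- emission_from_confusion(confusion)
  if (adjust) em <- adjust_emission_diagonal(em, n_bins = confusion$n_bins)
  hmm_spec(transition, em, n_bins = confusion$n_bins, class_names = class_names)
}
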