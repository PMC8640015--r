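# Per-sequence temporal inference: Viterbi decoding of one spatial site's
# observation sequence, plus the constant-observation shortcut.

log_spec <- function(spec) {
  # log(0) = -Inf marks forbidden transitions/emissions
  list(trans = suppressWarnings(log(spec$transition)),
       emis = suppressWarnings(log(spec$emission)),
       start = suppressWarnings(log(spec$start)))
}

check_observations <- function(obs, spec) {
  if (!length(obs)) stop_config("observation sequence must be non-empty")
  m <- ncol(spec$emission)
  if (any(obs < 0) || any(obs >= m))
    stop_config("observable indices must lie in [0, %d]", m - 1L)
  as.integer(obs)
}

#' Decode one toxel sequence with the Viterbi algorithm
#'
#' Returns the hidden-class path maximizing
#' `P(X_0) * O[X_0, E_0] * prod_t T[X_{t-1}, X_t] * O[X_t, E_t]` for the
#' observation sequence `E`. Computation is in log space with `-Inf` for
#' zero probabilities, so forbidden transitions are never traversed while a
#' feasible alternative exists. Ties are broken toward the lowest class
#' index at every backtrack step and at the final state.
#'
#' @param observations integer vector of 0-based observable indices (plain
#'   class labels for `n_bins = 1`, composite indices otherwise).
#' @param spec an [hmm_spec()].
#' @return integer vector of 0-based hidden class indices, same length.
#' @examples
#' spec <- hmm_spec(build_transition_default(4),
#'                  default_emission(4))
#' viterbi_decode(c(2, 2, 3, 2, 3, 3), spec)
#' @export
viterbi_decode <- function(observations, spec) {
  stopifnot(inherits(spec, "hmm_spec"))
  obs <- check_observations(observations, spec)
  lg <- log_spec(spec)
  .viterbi_path_cpp(obs, lg$trans, lg$emis, lg$start)
}

#' Constant-observation shortcut
#'
#' For a site whose observable never changes over time, the refined class is
#' taken as the hidden class that emits that observable with the highest
#' probability (the emission-column argmax; ties go to the lowest class
#' index), repeated for the whole sequence. This skips Viterbi decoding for
#' the typically vast static majority of a 4D volume.
#'
#' @param observable single 0-based observable index.
#' @param spec an [hmm_spec()].
#' @param len sequence length (>= 1).
#' @return integer vector of `len` copies of the argmax class.
#' @export
shortcut_constant <- function(observable, spec, len) {
  stopifnot(inherits(spec, "hmm_spec"))
  observable <- check_observations(observable, spec)
  if (length(observable) != 1) stop_config("observable must be a single index")
  if (len < 1) stop_config("len must be >= 1")
  col <- spec$emission[, observable + 1L]
  if (all(col == 0))
    stop_config("emission column %d is entirely zero; no class emits that observable",
                observable)
  rep(which.max(col) - 1L, len)
}

# Emission-column argmax for every observable; -1 flags all-zero columns
# (the shortcut is then undefined and full decoding is used instead).
shortcut_classes <- function(spec) {
  cls <- apply(spec$emission, 2, which.max) - 1L
  cls[colSums(spec$emission) == 0] <- -1L
  as.integer(cls)
}

#' Audit the constant-observation shortcut against full Viterbi decoding
#'
#' The shortcut is an approximation: the emission-column argmax need not
#' agree with the Viterbi path on a constant sequence for every parameter
#' set. This audit decodes the constant sequence for every observable and a
#' range of sequence lengths, and reports any disagreement. A warning is
#' emitted when the shortcut would alter results for the given spec.
#'
#' @param spec an [hmm_spec()].
#' @param lengths sequence lengths to audit (default 1 to 6).
#' @return data frame with one row per (observable, length) pair whose
#'   shortcut output differs from Viterbi (zero rows when they always
#'   agree), with columns `observable`, `len`, `shortcut_class` and
#'   `viterbi_classes` (comma-separated path).
#' @export
audit_shortcut <- function(spec, lengths = 1:6) {
  stopifnot(inherits(spec, "hmm_spec"))
  rows <- list()
  for (e in seq_len(ncol(spec$emission)) - 1L) {
    if (all(spec$emission[, e + 1L] == 0)) next
    for (len in lengths) {
      sc <- shortcut_constant(e, spec, len)
      vit <- viterbi_decode(rep(e, len), spec)
      if (!identical(as.integer(sc), as.integer(vit)))
        rows[[length(rows) + 1L]] <- data.frame(
          observable = e, len = len, shortcut_class = sc[1],
          viterbi_classes = paste(vit, collapse = ","))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(observable = integer(), len = integer(),
               shortcut_class = integer(), viterbi_classes = character())
  if (nrow(out))
    warning(sprintf(
      "constant-observation shortcut disagrees with Viterbi for %d (observable, length) pairs",
      nrow(out)), call. = FALSE)
  out
}
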