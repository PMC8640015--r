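# Whole-volume refinement: apply per-site temporal decoding across an
# aligned (T, Z, Y, X) label volume, with optional confidence volume,
# chunked site processing and the constant-observation shortcut.

check_volume4d <- function(labels, n_classes = NULL, what = "labels") {
  if (!is.array(labels) || length(dim(labels)) != 4)
    stop_config("%s must be a 4D array with dimensions (T, Z, Y, X)", what)
  if (!is.null(n_classes) &&
      (any(labels < 0) || any(labels >= n_classes)))
    stop_config("%s values must be integer class labels in [0, %d]",
                what, n_classes - 1L)
  invisible(TRUE)
}

check_confidence <- function(conf, labels) {
  if (!is.array(conf) || !identical(dim(conf), dim(labels)))
    stop_config("confidence volume must match the label volume's dimensions")
  if (any(!is.finite(conf)) || any(conf <= 0) || any(conf > 1))
    stop_config("confidence values must lie in (0, 1]")
  invisible(TRUE)
}

#' Map a label (and confidence) volume to composite observables
#'
#' For a plain model (`n_bins = 1`) this is the identity on labels. For a
#' confidence-binned model each toxel's label and leading-class probability
#' are combined into a composite observable index via [confidence_bin()] and
#' [composite_observable()].
#'
#' @param labels integer `(T, Z, Y, X)` array of class labels in
#'   `[0, n_classes)`.
#' @param conf numeric array of the same shape with leading-class
#'   probabilities in `(0, 1]`; required when `spec$n_bins > 1`.
#' @param spec an [hmm_spec()].
#' @return integer array of composite observable indices, same shape.
#' @export
observe_volume <- function(labels, conf = NULL, spec) {
  stopifnot(inherits(spec, "hmm_spec"))
  check_volume4d(labels, spec$n_classes)
  if (spec$n_bins == 1L) {
    storage.mode(labels) <- "integer"
    return(labels)
  }
  if (is.null(conf))
    stop_config("a confidence volume is required for a model with n_bins = %d",
                spec$n_bins)
  check_confidence(conf, labels)
  bins <- confidence_bin(as.vector(conf), spec$n_classes, spec$n_bins)
  obs <- composite_observable(as.vector(labels), bins, spec$n_bins,
                              spec$n_classes)
  array(obs, dim = dim(labels))
}

#' Refine a 4D label volume by per-site temporal HMM decoding
#'
#' Every spatial site's label sequence through time is decoded independently
#' with [viterbi_decode()] under `spec`; sites whose observable is constant
#' over time are assigned by the [shortcut_constant()] emission-column
#' argmax when `use_shortcut` is `TRUE`. Sites are processed in chunks of
#' `chunk_sites` columns; because sites are independent, any chunking yields
#' bit-identical output.
#'
#' @inheritParams observe_volume
#' @param use_shortcut use the constant-observation shortcut (default TRUE).
#' @param chunk_sites number of spatial sites decoded per chunk; `NULL`
#'   processes the whole volume at once.
#' @return integer array of refined labels, same shape as `labels`, with
#'   attribute `shortcut_hits` giving the number of sites assigned by the
#'   shortcut.
#' @examples
#' spec <- hmm_spec(build_transition_default(4), default_emission(4))
#' labs <- array(0L, dim = c(5, 2, 2, 2))
#' labs[3, 1, 1, 1] <- 1L # an isolated flicker
#' refined <- refine_volume(labs, spec = spec)
#' refined[, 1, 1, 1]
#' @export
refine_volume <- function(labels, conf = NULL, spec, use_shortcut = TRUE,
                          chunk_sites = NULL) {
  stopifnot(inherits(spec, "hmm_spec"))
  obs <- observe_volume(labels, conf, spec)
  dims <- dim(obs)
  tt <- dims[1]
  n_sites <- prod(dims[-1])
  mat <- matrix(as.integer(obs), nrow = tt)
  lg <- log_spec(spec)
  sc <- shortcut_classes(spec)
  if (is.null(chunk_sites) || chunk_sites >= n_sites) {
    res <- .refine_obs_matrix_cpp(mat, lg$trans, lg$emis, lg$start,
                                  use_shortcut, sc)
    refined <- res$refined
    hits <- res$n_shortcut
  } else {
    if (chunk_sites < 1) stop_config("chunk_sites must be >= 1")
    refined <- matrix(0L, nrow = tt, ncol = n_sites)
    hits <- 0
    starts <- seq(1L, n_sites, by = as.integer(chunk_sites))
    for (s0 in starts) {
      s1 <- min(s0 + chunk_sites - 1L, n_sites)
      res <- .refine_obs_matrix_cpp(mat[, s0:s1, drop = FALSE],
                                    lg$trans, lg$emis, lg$start,
                                    use_shortcut, sc)
      refined[, s0:s1] <- res$refined
      hits <- hits + res$n_shortcut
    }
  }
  out <- array(as.integer(refined), dim = dims)
  attr(out, "shortcut_hits") <- hits
  out
}

#' Count temporal label flips
#'
#' Total number of label changes between consecutive time steps, summed over
#' spatial sites; a direct measure of temporal incoherence. Optionally
#' restricted to a spatial site mask (e.g. boundary toxels).
#'
#' @param labels integer `(T, Z, Y, X)` array.
#' @param site_mask optional logical `(Z, Y, X)` array selecting sites.
#' @return flip count (numeric scalar).
#' @export
temporal_flips <- function(labels, site_mask = NULL) {
  check_volume4d(labels)
  dims <- dim(labels)
  mat <- matrix(as.integer(labels), nrow = dims[1])
  mask <- if (is.null(site_mask)) logical(0) else {
    if (!identical(dim(site_mask), dims[-1]))
      stop_config("site_mask must have the volume's spatial dimensions")
    as.logical(site_mask)
  }
  .temporal_flips_cpp(mat, mask)
}

#' Mark toxels adjacent to a spatial class boundary
#'
#' A toxel is a boundary toxel when any of its 6 spatial neighbours (within
#' the same time step) carries a different label. These sites are where
#' near-tied class probabilities make per-timepoint predictions flicker.
#'
#' @param labels integer `(T, Z, Y, X)` array.
#' @return logical array of the same shape.
#' @export
spatial_boundary_mask <- function(labels) {
  check_volume4d(labels)
  d <- dim(labels)
  out <- array(FALSE, dim = d)
  for (axis in 2:4) {
    n <- d[axis]
    if (n < 2) next
    idx_lo <- lapply(seq_along(d), function(i) seq_len(d[i]))
    idx_hi <- idx_lo
    idx_lo[[axis]] <- seq_len(n - 1L)
    idx_hi[[axis]] <- 2:n
    lo <- do.call(`[`, c(list(labels), idx_lo, list(drop = FALSE)))
    hi <- do.call(`[`, c(list(labels), idx_hi, list(drop = FALSE)))
    diff <- lo != hi
    out_lo <- do.call(`[`, c(list(out), idx_lo, list(drop = FALSE))) | diff
    out_hi <- do.call(`[`, c(list(out), idx_hi, list(drop = FALSE))) | diff
    out <- do.call(`[<-`, c(list(out), idx_lo, list(out_lo)))
    out <- do.call(`[<-`, c(list(out), idx_hi, list(out_hi)))
  }
  out
}
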