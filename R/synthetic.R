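# Synthetic 4D phantoms with known hidden truth: a static base-material
# region containing inclusions of a dissolving class that irreversibly
# convert to a product class over time, observed through a diagonal-dominant
# emission process with per-toxel confidences. Emulates the statistical
# structure of a per-timepoint CNN segmentation of a corrosion time-series;
# the geometry itself (cylinder plus spheres) is immaterial because decoding
# treats every spatial site independently.

#' Default diagonal-dominant emission matrix for the 4-class corrosion system
#'
#' A canonical square emission matrix emulating a per-timepoint segmenter
#' whose accuracy differs per class: the large, easy classes (air outside
#' the sample, base material) are predicted almost perfectly, while the
#' small dissolving-phase and gas-product classes are harder, with most of
#' their errors going to the base material and a small mutual confusion
#' between the two. For other class counts a generic diagonal-dominant
#' matrix (0.9 on the diagonal) is returned.
#'
#' @param n_classes number of classes (default 4).
#' @return `N x N` row-stochastic matrix with identity column argmax.
#' @export
default_emission <- function(n_classes = 4L) {
  n_classes <- as.integer(n_classes)
  if (n_classes == 4L) {
    m <- rbind(
      c(0.980, 0.015, 0.0025, 0.0025),
      c(0.010, 0.970, 0.010, 0.010),
      c(0.005, 0.145, 0.800, 0.050),
      c(0.005, 0.145, 0.050, 0.800))
    return(m)
  }
  if (n_classes < 2) stop_config("n_classes must be >= 2")
  m <- matrix(0.1 / (n_classes - 1), n_classes, n_classes)
  diag(m) <- 0.9
  m
}

#' Configuration for the synthetic 4D phantom
#'
#' Defaults describe the study conditions the package is exercised under: a
#' 21-step time series of 64^3 volumes with four classes (air, base,
#' dissolving, product), a 10% per-step irreversible dissolving-to-product
#' conversion, observation noise drawn from [default_emission()], label
#' flicker at spatial class boundaries where the segmenter's leading-class
#' probability is nearly tied, and informative confidences (high for correct
#' interior predictions, intermediate for confidently wrong interior
#' predictions, just above `1/N` at boundaries).
#'
#' @param shape integer vector `(T, Z, Y, X)`.
#' @param n_classes number of classes.
#' @param dissolving,product 0-based indices of the converting pair.
#' @param p_convert per-step hidden conversion probability.
#' @param n_inclusions number of spherical dissolving-phase inclusions.
#' @param radius_range sphere radius range in voxels.
#' @param cylinder_radius_frac base-material cylinder radius as a fraction
#'   of the smaller lateral dimension.
#' @param emission `N x N` row-stochastic observation-noise matrix.
#' @param boundary_flip probability that a boundary toxel's observation is
#'   replaced by a neighbouring class (near 50-50 tie).
#' @param conf_interior,conf_wrong,conf_boundary `(lo, hi)` uniform ranges
#'   for the confidence of correct interior, incorrect interior and boundary
#'   toxels; all must lie in `(1/N, 1]`.
#' @param seed RNG seed; generation is fully deterministic given the seed.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(shape = c(21L, 64L, 64L, 64L), n_classes = 4L,
                           dissolving = 2L, product = 3L, p_convert = 0.10,
                           n_inclusions = 8L, radius_range = c(3, 6),
                           cylinder_radius_frac = 0.42,
                           emission = default_emission(n_classes),
                           boundary_flip = 0.5,
                           conf_interior = c(0.85, 1),
                           conf_wrong = c(0.30, 0.80),
                           conf_boundary = c(0.26, 0.45),
                           seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 4 || any(shape < 1))
    stop_config("shape must be four positive integers (T, Z, Y, X)")
  emission <- as.matrix(emission)
  if (nrow(emission) != n_classes || ncol(emission) != n_classes)
    stop_config("emission must be %d x %d", n_classes, n_classes)
  check_stochastic(emission, "emission")
  if (dissolving < 0 || dissolving >= n_classes ||
      product < 0 || product >= n_classes || dissolving == product)
    stop_config("invalid dissolving/product class indices")
  structure(list(shape = shape, n_classes = as.integer(n_classes),
                 dissolving = as.integer(dissolving),
                 product = as.integer(product), p_convert = p_convert,
                 n_inclusions = as.integer(n_inclusions),
                 radius_range = radius_range,
                 cylinder_radius_frac = cylinder_radius_frac,
                 emission = emission, boundary_flip = boundary_flip,
                 conf_interior = conf_interior, conf_wrong = conf_wrong,
                 conf_boundary = conf_boundary, seed = as.integer(seed)),
            class = "phantom_config")
}

# Shift a (T, Z, Y, X) array by one voxel along a spatial axis with
# nearest-edge clamping.
shift_axis <- function(a, axis, dir) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  src <- pmin(pmax(idx[[axis]] - dir, 1L), d[axis])
  idx[[axis]] <- src
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

#' Generate a synthetic 4D phantom with known hidden truth
#'
#' Builds a hidden label time series (base-material cylinder in air, with
#' spherical dissolving-class inclusions converting irreversibly to the
#' product class at `p_convert` per step), then corrupts it into an observed
#' label volume by drawing each toxel from the emission row of its hidden
#' class, adds near-50-50 label flicker at spatial class boundaries, and
#' attaches a leading-class confidence per toxel. All randomness flows from
#' `cfg$seed`; regeneration is bit-identical.
#'
#' @param cfg a [phantom_config()].
#' @return list with integer arrays `hidden` and `observed`, numeric array
#'   `confidence` (all `(T, Z, Y, X)`), logical `boundary` mask of the same
#'   shape, and the `config` used.
#' @export
generate_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  with_seed(cfg$seed, {
    tt <- cfg$shape[1]; zz <- cfg$shape[2]; yy <- cfg$shape[3]; xx <- cfg$shape[4]
    n <- cfg$n_classes

    # static geometry: base cylinder along z, spherical inclusions inside it
    yc <- (yy + 1) / 2; xc <- (xx + 1) / 2
    r_cyl <- cfg$cylinder_radius_frac * min(yy, xx)
    d2 <- outer((seq_len(yy) - yc)^2, (seq_len(xx) - xc)^2, `+`)
    cyl <- d2 <= r_cyl^2 # (Y, X)
    state <- array(0L, dim = c(zz, yy, xx))
    state[rep(as.vector(cyl), each = zz)] <- 1L

    if (cfg$n_inclusions > 0) {
      zg <- array(rep(seq_len(zz), times = yy * xx), dim = c(zz, yy, xx))
      yg <- array(rep(rep(seq_len(yy), each = zz), times = xx), dim = c(zz, yy, xx))
      xg <- array(rep(seq_len(xx), each = zz * yy), dim = c(zz, yy, xx))
      for (k in seq_len(cfg$n_inclusions)) {
        rad <- runif(1, cfg$radius_range[1], cfg$radius_range[2])
        rad <- min(rad, (zz - 1) / 2) # fit shallow volumes
        ang <- runif(1, 0, 2 * pi)
        rr <- runif(1, 0, max(r_cyl - rad - 1, 1))
        cy <- yc + rr * cos(ang); cx <- xc + rr * sin(ang)
        z_lo <- min(1 + rad, (zz + 1) / 2)
        z_hi <- max(zz - rad, (zz + 1) / 2)
        cz <- runif(1, z_lo, z_hi)
        sph <- (zg - cz)^2 + (yg - cy)^2 + (xg - cx)^2 <= rad^2
        state[sph & state == 1L] <- cfg$dissolving
      }
    }

    # temporal evolution: irreversible dissolving -> product
    hidden <- array(0L, dim = cfg$shape)
    hidden[1, , , ] <- state
    for (t in seq_len(tt - 1L)) {
      idx <- which(state == cfg$dissolving)
      if (length(idx)) {
        conv <- idx[runif(length(idx)) < cfg$p_convert]
        state[conv] <- cfg$product
      }
      hidden[t + 1L, , , ] <- state
    }

    # observation noise: per-toxel draw from the hidden class's emission row
    observed <- array(0L, dim = cfg$shape)
    u <- runif(length(hidden))
    for (h in seq_len(n) - 1L) {
      idx <- which(hidden == h)
      if (!length(idx)) next
      cum <- cumsum(cfg$emission[h + 1L, ])
      observed[idx] <- findInterval(u[idx], cum[-length(cum)])
    }

    # boundary flicker: near-tied sites flip to a neighbouring class ~50-50
    boundary <- spatial_boundary_mask(hidden)
    nb <- hidden
    assigned <- array(FALSE, dim = cfg$shape)
    for (axis in 2:4) for (dir in c(1L, -1L)) {
      sh <- shift_axis(hidden, axis, dir)
      sel <- boundary & !assigned & sh != hidden
      nb[sel] <- sh[sel]
      assigned[sel] <- TRUE
    }
    bidx <- which(boundary)
    if (length(bidx)) {
      flip <- runif(length(bidx)) < cfg$boundary_flip
      observed[bidx[flip]] <- nb[bidx[flip]]
      observed[bidx[!flip]] <- hidden[bidx[!flip]]
    }

    # confidence model: high when correct in the interior, intermediate when
    # confidently wrong, near 1/N at boundaries
    confidence <- array(0, dim = cfg$shape)
    correct <- observed == hidden
    i1 <- which(!boundary & correct)
    i2 <- which(!boundary & !correct)
    confidence[i1] <- runif(length(i1), cfg$conf_interior[1], cfg$conf_interior[2])
    confidence[i2] <- runif(length(i2), cfg$conf_wrong[1], cfg$conf_wrong[2])
    confidence[bidx] <- runif(length(bidx), cfg$conf_boundary[1], cfg$conf_boundary[2])

    list(hidden = hidden, observed = observed, confidence = confidence,
         boundary = boundary, config = cfg)
  })
}

#' Behavioural scenario sequences for the converting class pair
#'
#' Builds the two behavioural observation sequences used to probe how a
#' model treats the irreversible dissolving-to-product direction. In the
#' `forward` scenario the observable converts from the dissolving class to
#' the product class at `t_transition`, with contrary (dissolving)
#' observations injected at `noise_steps`; a well-parameterized model should
#' override isolated contrary observations and keep the product class. In
#' the `reverse` scenario the observable is the product class throughout
#' except for contrary dissolving observations at `noise_steps`; a single
#' trailing contrary observation should not flip the state, while a
#' sustained run eventually should.
#'
#' @param direction `"forward"` or `"reverse"`.
#' @param noise_steps 0-based time indices receiving contrary observations
#'   (for `forward` they must be at or after `t_transition`).
#' @param t_transition 0-based first time step of the product phase in the
#'   forward scenario (default 8).
#' @param n_steps sequence length (default 21).
#' @param dissolving,product 0-based class indices (defaults 2 and 3).
#' @return integer observation sequence of length `n_steps`.
#' @export
scenario_behaviour <- function(direction = c("forward", "reverse"),
                                   noise_steps = integer(),
                                   t_transition = 8L, n_steps = 21L,
                                   dissolving = 2L, product = 3L) {
  direction <- match.arg(direction)
  noise_steps <- as.integer(noise_steps)
  if (any(noise_steps < 0) || any(noise_steps >= n_steps))
    stop_config("noise_steps must lie in [0, %d]", n_steps - 1L)
  if (direction == "forward") {
    if (t_transition < 1 || t_transition >= n_steps)
      stop_config("t_transition must lie in [1, %d]", n_steps - 1L)
    if (any(noise_steps < t_transition))
      stop_config("forward noise_steps must be at or after t_transition")
    obs <- c(rep(dissolving, t_transition), rep(product, n_steps - t_transition))
  } else {
    obs <- rep(product, n_steps)
  }
  obs[noise_steps + 1L] <- dissolving
  as.integer(obs)
}

#' Wipe a single time step of a label volume
#'
#' Replaces every label at time step `t` with `fill_class`, simulating the
#' loss of one time point's predictions; refinement should recover most of
#' the wiped information from the neighbouring time steps.
#'
#' @param observed integer `(T, Z, Y, X)` array.
#' @param t 0-based time index to wipe.
#' @param fill_class 0-based class written into the slice.
#' @return a copy of `observed` with slice `t` set to `fill_class`.
#' @export
scenario_timestep_wipe <- function(observed, t, fill_class) {
  check_volume4d(observed)
  tt <- dim(observed)[1]
  if (t < 0 || t >= tt)
    stop_config("t must lie in [0, %d]", tt - 1L)
  if (fill_class < 0) stop_config("fill_class must be a valid class index")
  out <- observed
  out[t + 1L, , , ] <- as.integer(fill_class)
  out
}
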