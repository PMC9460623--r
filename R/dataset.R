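# Training-set construction by superposition, and the masked-target input.
#
# Stage 1 (phases): unit voltages on all channels, integer free phases drawn
# uniformly from {0,...,359}; each sample is the min-max-normalized heating
# potential labelled with (sin, cos) of every free phase. Stage 2 (voltages):
# phases fixed at the stage-1 solution, integer voltages 0-9 per channel;
# labels are the voltages rescaled to [0,1] by /9. Default corpus sizes are
# 2000 samples for the linear applicator and 50,000 for the circular one,
# split 80/20 into training and validation.

#' Default training-corpus size for a scheme
#' @param scheme `"linear"` or `"circular"`.
#' @return 2000 (linear) or 50000 (circular).
#' @export
default_corpus_size <- function(scheme)
  switch(scheme, linear = 2000L, circular = 50000L,
         stop("scheme must be 'linear' or 'circular'"))

#' Sample integer free phases
#'
#' Draws `m` vectors of independent integer degrees, uniform on {0,...,359},
#' one entry per free phase (2 for the linear scheme, 6 for the circular).
#' Deterministic for a given seed.
#'
#' @param seed integer seed.
#' @param m number of samples.
#' @param scheme `"linear"` or `"circular"`.
#' @return an `m x n_free` integer matrix.
#' @export
sample_free_phases <- function(seed, m, scheme) {
  stopifnot(m >= 1)
  nf <- free_phase_count(scheme)
  set.seed(as.integer(seed))
  matrix(sample.int(360, m * nf, replace = TRUE) - 1L, nrow = m, ncol = nf)
}

#' Sample integer channel voltages
#'
#' Draws `m` vectors of independent integer voltages, uniform on {0,...,9},
#' one entry per channel. All-zero vectors (a degenerate excitation whose
#' heating potential cannot be normalized) are re-drawn.
#'
#' @param seed integer seed.
#' @param m number of samples.
#' @param scheme `"linear"` or `"circular"`.
#' @return an `m x n_channels` integer matrix with no all-zero row.
#' @export
sample_voltages <- function(seed, m, scheme) {
  stopifnot(m >= 1)
  n <- switch(scheme, linear = 4L, circular = 12L,
              stop("scheme must be 'linear' or 'circular'"))
  set.seed(as.integer(seed))
  v <- matrix(sample.int(10, m * n, replace = TRUE) - 1L, nrow = m, ncol = n)
  repeat {
    zero <- rowSums(v) == 0L
    if (!any(zero)) break
    v[zero, ] <- matrix(sample.int(10, sum(zero) * n, replace = TRUE) - 1L,
                        ncol = n)
  }
  v
}

#' Sine/cosine phase encoding
#'
#' `encode_phases()` maps angles (degrees) to interleaved `(sin, cos)` pairs;
#' `decode_phases()` inverts via the two-argument arctangent, projecting
#' off-circle pairs (raw regression outputs) radially onto the unit circle.
#'
#' @param phases angles in degrees.
#' @param sc numeric vector of interleaved `(sin, cos)` pairs.
#' @return `encode_phases()`: length `2 * length(phases)` vector;
#'   `decode_phases()`: angles in `(-180, 180]`.
#' @examples decode_phases(encode_phases(133.44))
#' @export
encode_phases <- function(phases) {
  rad <- phases * pi / 180
  as.vector(rbind(sin(rad), cos(rad)))
}

#' @rdname encode_phases
#' @export
decode_phases <- function(sc) {
  stopifnot(length(sc) %% 2 == 0)
  s <- sc[seq(1, length(sc), 2)]
  co <- sc[seq(2, length(sc), 2)]
  if (any(s^2 + co^2 < 1e-24))
    stop("(0, 0) sine/cosine pair: phase angle undefined")
  wrap_phase(atan2(s, co) * 180 / pi)
}

#' Square focus-target specification
#'
#' @param center target centre (x, y) in mm.
#' @param side_mm square side length in mm (default 10, matched to the
#'   10 mm tumor diameter).
#' @return a `target_spec`.
#' @export
target_spec <- function(center, side_mm = 10) {
  stopifnot(length(center) == 2, side_mm > 0)
  structure(list(center = as.numeric(center), side_mm = side_mm),
            class = "target_spec")
}

#' Binary masked-target input
#'
#' The mask stands in for the unknown ideal heating map: 1 on the square of
#' side `target$side_mm` centred at the target (pixels whose centres fall in
#' the half-open square), 0 elsewhere. With 1 mm pixels and the default
#' 10 mm side the mask has exactly 100 active pixels.
#'
#' @param target a [target_spec()].
#' @param grid a [grid_spec()].
#' @param phantom optional `phantom_grid`; when given, the mask must lie
#'   wholly inside the breast.
#' @return an `n_rows x n_cols` 0/1 matrix.
#' @export
build_mask <- function(target, grid, phantom = NULL) {
  stopifnot(inherits(target, "target_spec"), inherits(grid, "grid_spec"))
  co <- pixel_coords(grid)
  h <- target$side_mm / 2
  inx <- co$x >= target$center[1] - h & co$x < target$center[1] + h
  iny <- co$y >= target$center[2] - h & co$y < target$center[2] + h
  mask <- outer(iny, inx) * 1
  if (sum(mask) == 0) stop("target square contains no pixel centre")
  if (!is.null(phantom)) {
    if (!same_grid(grid, phantom$grid))
      stop("mask grid does not match the phantom grid")
    if (any(mask == 1 & !phantom$breast_mask))
      stop("target square crosses the breast boundary")
  }
  mask
}

# Heating-potential maps for a batch of excitations, as a (H, W, m) array of
# min-max-normalized maps. coeffs: n_channels x m complex matrix.
hp_batch <- function(fs, phantom, coeffs) {
  grid <- fs$grid
  hw <- grid$n_rows * grid$n_cols
  ncomp <- fs$n_components
  # field matrix: (ncomp*hw) x N
  fm <- vapply(fs$fields, function(f) as.vector(f),
               complex(ncomp * hw))
  sig <- as.vector(phantom$sigma)
  m <- ncol(coeffs)
  out <- array(NA_real_, c(grid$n_rows, grid$n_cols, m))
  step <- max(1L, floor(2e6 / (ncomp * hw)))
  for (s0 in seq(1, m, step)) {
    s1 <- min(m, s0 + step - 1L)
    e <- fm %*% coeffs[, s0:s1, drop = FALSE]       # (ncomp*hw) x b
    mag2 <- abs(e)^2
    dim(mag2) <- c(ncomp, hw, s1 - s0 + 1L)
    q <- 0.5 * sig * colSums(mag2)                   # hw x b
    for (j in seq_len(ncol(q))) {
      rng <- range(q[, j])
      if (diff(rng) <= 0)
        stop("sample ", s0 + j - 1L, " produced a constant heating map")
      out[, , s0 + j - 1L] <- (q[, j] - rng[1]) / diff(rng)
    }
  }
  out
}

make_split <- function(m, seed) {
  set.seed(as.integer(seed) + 1L)
  n_val <- max(1L, round(0.2 * m))
  val <- sort(sample.int(m, n_val))
  list(train = setdiff(seq_len(m), val), val = val)
}

training_set <- function(inputs, labels, kind, scheme, seed, grid) {
  split <- make_split(dim(inputs)[3], seed)
  structure(list(inputs = inputs, labels = labels, kind = kind,
                 scheme = scheme, seed = as.integer(seed), grid = grid,
                 train = split$train, val = split$val),
            class = "training_set")
}

#' Build the phase-stage training set
#'
#' For every row of `free_phases`: expand through the scheme constraint,
#' superpose the unit-voltage fields, compute and min-max normalize the
#' heating potential, and pair it with the interleaved `(sin, cos)` encoding
#' of the free phases (labels of length 4 linear / 12 circular).
#'
#' @param fs a `field_set` with a named scheme.
#' @param phantom the `phantom_grid` the fields were computed in.
#' @param free_phases `m x n_free` matrix of free phases in degrees
#'   (e.g. from [sample_free_phases()]).
#' @param seed seed for the 80/20 train/validation split.
#' @return a `training_set` with `inputs` `(n_rows, n_cols, m)` and
#'   `labels` `(m, 2 * n_free)`.
#' @export
build_phase_dataset <- function(fs, phantom, free_phases, seed = 0L) {
  stopifnot(inherits(fs, "field_set"), inherits(phantom, "phantom_grid"))
  if (!same_grid(fs$grid, phantom$grid))
    stop("field set and phantom must share one grid")
  free_phases <- as.matrix(free_phases)
  stopifnot(ncol(free_phases) == free_phase_count(fs$scheme))
  m <- nrow(free_phases)
  coeffs <- vapply(seq_len(m), function(i) {
    ph <- expand_free_phases(fs$scheme, free_phases[i, ])
    excitation_coefficients(rep(1, fs$n_channels), ph)
  }, complex(fs$n_channels))
  inputs <- hp_batch(fs, phantom, coeffs)
  labels <- t(apply(free_phases, 1, encode_phases))
  training_set(inputs, labels, "phase", fs$scheme, seed, fs$grid)
}

#' Build the voltage-stage training set
#'
#' For every row of `voltages`: superpose the fields with the fixed phases,
#' normalize the heating potential, and label with the voltages rescaled to
#' [0, 1] (by /9). Because the heating potential is homogeneous of degree 2
#' in the drive and then min-max scaled, uniformly rescaled voltage vectors
#' give identical inputs.
#'
#' @param fs a `field_set` with a named scheme.
#' @param phantom the matching `phantom_grid`.
#' @param fixed_phases full per-channel phase vector (degrees) satisfying the
#'   scheme constraint — normally the stage-1 solution.
#' @param voltages `m x n_channels` matrix (e.g. from [sample_voltages()]).
#' @param seed seed for the 80/20 split.
#' @return a `training_set` with labels `(m, n_channels)` in [0, 1].
#' @export
build_voltage_dataset <- function(fs, phantom, fixed_phases, voltages,
                                  seed = 0L) {
  stopifnot(inherits(fs, "field_set"), inherits(phantom, "phantom_grid"))
  if (!same_grid(fs$grid, phantom$grid))
    stop("field set and phantom must share one grid")
  fixed_phases <- wrap_phase(as.numeric(fixed_phases))
  stopifnot(length(fixed_phases) == fs$n_channels)
  check_phase_constraint(fs$scheme, fixed_phases)
  voltages <- as.matrix(voltages)
  stopifnot(ncol(voltages) == fs$n_channels)
  if (any(rowSums(voltages) == 0))
    stop("all-zero voltage rows are degenerate; re-draw them")
  coeffs <- vapply(seq_len(nrow(voltages)), function(i)
    excitation_coefficients(voltages[i, ], fixed_phases),
    complex(fs$n_channels))
  inputs <- hp_batch(fs, phantom, coeffs)
  training_set(inputs, voltages / 9, "voltage", fs$scheme, seed, fs$grid)
}

#' @export
print.training_set <- function(x, ...) {
  d <- dim(x$inputs)
  cat(sprintf(
    "<training_set> %s/%s: %d samples of %d x %d (train %d / val %d), %d labels\n",
    x$scheme, x$kind, d[3], d[1], d[2], length(x$train), length(x$val),
    ncol(x$labels)))
  invisible(x)
}
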