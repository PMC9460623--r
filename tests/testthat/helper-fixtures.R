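# Shared fixtures, built lazily and cached for the whole test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# Full-scale linear-applicator study conditions: seed-1 phantom on the
# 71 x 91 grid with the 12-antenna / 4-channel layout.
linear_fixture <- function() {
  fixture("linear", function() {
    phantom <- generate_phantom(1)
    layout <- make_layout("linear")
    fs <- simulate_unit_fields(phantom, layout)
    list(phantom = phantom, layout = layout, fs = fs,
         target = target_spec(c(26, 12)))
  })
}

# Small homogeneous phantom built directly (uniform material, optional
# all-false breast mask) for closed-form field and metric checks.
manual_phantom <- function(n_rows = 8, n_cols = 8, eps_r = 30, sigma = 1.4,
                           breast = FALSE, pixel_mm = 1) {
  grid <- grid_spec(n_rows, n_cols, pixel_mm)
  bm <- matrix(breast, n_rows, n_cols)
  structure(list(grid = grid,
                 eps_r = matrix(eps_r, n_rows, n_cols),
                 sigma = matrix(sigma, n_rows, n_cols),
                 breast_mask = bm, interior_mask = bm,
                 tumor = NULL, seed = NA_integer_,
                 heterogeneity = NA_real_,
                 semi_axes_mm = c(NA_real_, NA_real_), skin_mm = NA_real_),
            class = "phantom_grid")
}

# Random complex toy field set with a custom scheme.
toy_fieldset <- function(seed, n_channels = 2, n_rows = 8, n_cols = 8,
                         n_components = 2) {
  set.seed(seed)
  grid <- grid_spec(n_rows, n_cols)
  fields <- lapply(seq_len(n_channels), function(i) {
    array(complex(real = rnorm(n_components * n_rows * n_cols),
                  imaginary = rnorm(n_components * n_rows * n_cols)),
          c(n_components, n_rows, n_cols))
  })
  field_set(grid, fields, scheme = "custom")
}

# Single-antenna layout helper for field-model checks.
single_antenna_layout <- function(grid, x, y) {
  structure(list(scheme = "custom", grid = grid,
                 positions = cbind(x = x, y = y), n_antennas = length(x),
                 n_channels = length(x),
                 channel_of_antenna = seq_along(x)),
            class = "antenna_layout")
}

# Complex wavenumber of the wave model (for closed-form oracles).
medium_wavenumber <- function(eps_r, sigma, frequency = 2.45e9) {
  eps0 <- 8.8541878128e-12
  c0 <- 299792458
  w <- 2 * pi * frequency
  (w / c0) * sqrt(complex(real = eps_r, imaginary = -sigma / (w * eps0)))
}

# Naive per-pixel superposition + energy-fraction oracle used to check the
# coupling-matrix lookup path.
oracle_omega <- function(fs, phantom, region_mask, voltages, phases) {
  E <- array(0 + 0i, dim(fs$fields[[1]]))
  for (i in seq_len(fs$n_channels))
    E <- E + voltages[i] * exp(1i * phases[i] * pi / 180) * fs$fields[[i]]
  q0 <- 0.5 * phantom$sigma * apply(abs(E)^2, c(2, 3), sum)
  100 * sum(q0[(region_mask > 0) & phantom$breast_mask]) /
    sum(q0[phantom$breast_mask])
}

# Reference per-antenna phase sets of the linear / circular study cases,
# used by the phase-closure and metric-consistency checks.
linear_phase_rows <- function() {
  list(A = c(0.00, -48.46, -178.10, 133.44),
       B = c(0.00, -100.00, 138.00, 38.00),
       C = c(0.00, -43.10, 135.73, 92.63),
       D = c(0.00, -100.00, 140.00, 40.00))
}

circular_phase_rows <- function() {
  list(A = c(0.00, 98.57, -15.76, -114.3, 170.8, -74.84, -40.73, 34.11,
             -62.28, -96.39, -108.0, -11.60),
       B = c(0.00, 126.03, -61.00, 172.97, 97.59, -75.38, -94.68, -19.31,
             -59.18, -39.88, 96.33, 136.21),
       C = c(0.00, -31.33, 138.53, 169.86, 52.28, -117.6, 0.42, 118.0,
             29.80, -88.19, -157.3, -69.07))
}

# (omega_target, omega_hotspot, psi) triples of the eight linear study rows.
metric_triples <- function() {
  list(c(8.42, 10.78, 1.28), c(10.20, 9.04, 0.89),
       c(8.69, 16.64, 1.91), c(10.56, 12.71, 1.20),
       c(12.63, 11.44, 0.91), c(15.20, 10.08, 0.66),
       c(13.67, 16.05, 1.17), c(15.10, 10.24, 0.68))
}

# Half an ULP of a printed decimal value (0.005 for "12.34", 0.05 for "12.3").
printed_tol <- function(x) {
  vapply(x, function(z) {
    s <- format(z, trim = TRUE)
    dec <- if (grepl("\\.", s)) nchar(sub("^[^.]*\\.", "", s)) else 0
    0.5 * 10^(-dec)
  }, numeric(1))
}
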