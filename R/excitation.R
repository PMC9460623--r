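# Excitations, phase-constraint schemes, superposition and heating potential.
#
# Phases are kept in degrees throughout (radians appear only inside the
# complex exponential) and are reported wrapped to (-180, 180]. Channel 1 is
# the phase reference (phi_1 = 0). The linear applicator has two free phases
# (phi_2, phi_3) with phi_4 = phi_2 + phi_3; the circular applicator lets the
# six even-numbered antennas vary freely and assigns every odd antenna
# k in {3,5,...,11} the wrapped sum of its two neighbours.

#' Wrap an angle to (-180, 180] degrees
#'
#' @param deg finite angle(s) in degrees.
#' @return angle(s) congruent mod 360, in (-180, 180].
#' @examples wrap_phase(-226.56)  # 133.44
#' @export
wrap_phase <- function(deg) {
  if (any(!is.finite(deg))) stop("phase must be finite")
  out <- deg - 360 * floor(deg / 360)   # [0, 360)
  ifelse(out > 180, out - 360, out)
}

#' Linear-applicator phase vector from its two free phases
#'
#' @param phi2,phi3 free phases (degrees) of channels 2 and 3.
#' @return the four channel phases `(0, phi2, phi3, wrap(phi2 + phi3))`.
#' @examples linear_phase_vector(-48.46, -178.10)  # phi4 = 133.44
#' @export
linear_phase_vector <- function(phi2, phi3) {
  c(0, wrap_phase(phi2), wrap_phase(phi3), wrap_phase(phi2 + phi3))
}

#' Circular-applicator phase vector from its six even-antenna phases
#'
#' Antenna 1 is the 0-degree reference; each odd antenna k in {3,5,7,9,11}
#' gets the wrapped sum of its two neighbours' phases.
#'
#' @param even_phases length-6 phases (degrees) of antennas 2,4,6,8,10,12.
#' @return the twelve antenna phases, wrapped to (-180, 180].
#' @examples circular_phase_vector(c(0, 0, -74.84, 34.11, 0, 0))[7]  # -40.73
#' @export
circular_phase_vector <- function(even_phases) {
  stopifnot(length(even_phases) == 6)
  ph <- numeric(12)
  ph[seq(2, 12, 2)] <- wrap_phase(even_phases)
  for (k in c(3, 5, 7, 9, 11))
    ph[k] <- wrap_phase(ph[k - 1] + ph[k + 1])
  ph
}

free_phase_count <- function(scheme) {
  switch(scheme, linear = 2L, circular = 6L,
         stop("scheme must be 'linear' or 'circular'"))
}

expand_free_phases <- function(scheme, free) {
  if (scheme == "linear") {
    stopifnot(length(free) == 2)
    linear_phase_vector(free[1], free[2])
  } else {
    circular_phase_vector(free)
  }
}

#' Construct a per-channel excitation
#'
#' @param scheme `"linear"` (4 channels), `"circular"` (12), or `"custom"`
#'   (no phase constraint; any N).
#' @param voltages per-channel voltage amplitudes (V, non-negative).
#' @param phases per-channel phases in degrees; for the named schemes they
#'   must satisfy the scheme constraint (within `tol` degrees). Either
#'   `phases` or `free_phases` must be given for named schemes.
#' @param free_phases alternative: the free subset (length 2 linear /
#'   6 circular), expanded through the scheme constraint.
#' @param port_resistance port impedance, ohm.
#' @param tol constraint-check tolerance in degrees.
#' @return an `excitation`.
#' @export
excitation <- function(scheme, voltages, phases = NULL, free_phases = NULL,
                       port_resistance = MHF_PORT_OHM, tol = 1e-6) {
  n <- switch(scheme, linear = 4L, circular = 12L, custom = length(voltages),
              stop("unknown scheme: ", scheme))
  voltages <- as.numeric(voltages)
  if (length(voltages) != n)
    stop(sprintf("%s scheme needs %d voltages", scheme, n))
  if (any(!is.finite(voltages)) || any(voltages < 0))
    stop("voltages must be finite and >= 0")
  if (!is.null(free_phases)) {
    if (scheme == "custom") stop("free_phases only apply to named schemes")
    phases <- expand_free_phases(scheme, free_phases)
  }
  if (is.null(phases)) stop("phases (or free_phases) required")
  phases <- wrap_phase(as.numeric(phases))
  if (length(phases) != n)
    stop(sprintf("%s scheme needs %d phases", scheme, n))
  if (scheme != "custom")
    check_phase_constraint(scheme, phases, tol)
  structure(list(scheme = scheme, voltages = voltages, phases = phases,
                 n_channels = n, port_resistance = port_resistance),
            class = "excitation")
}

# Angular difference |a - b| on the circle.
ang_diff <- function(a, b) abs(wrap_phase(a - b))

check_phase_constraint <- function(scheme, phases, tol = 1e-6) {
  if (ang_diff(phases[1], 0) > tol)
    stop("channel 1 phase must be 0 (reference)")
  if (scheme == "linear") {
    if (ang_diff(phases[4], phases[2] + phases[3]) > tol)
      stop("linear constraint violated: phi4 != phi2 + phi3 (mod 360)")
  } else {
    for (k in c(3, 5, 7, 9, 11))
      if (ang_diff(phases[k], phases[k - 1] + phases[k + 1]) > tol)
        stop(sprintf(
          "circular constraint violated at antenna %d: phi%d != phi%d + phi%d",
          k, k, k - 1, k + 1))
  }
  invisible(TRUE)
}

#' @export
print.excitation <- function(x, ...) {
  cat(sprintf("<excitation> %s, %d channels (total %g W into %g ohm)\n",
              x$scheme, x$n_channels, total_input_power(x),
              x$port_resistance))
  cat("  V:  ", paste(sprintf("%6.3f", x$voltages), collapse = " "), "\n")
  cat("  deg:", paste(sprintf("%6.2f", x$phases), collapse = " "), "\n")
  invisible(x)
}

#' Port input power of a voltage drive
#'
#' Uses the lumped-port convention P = V^2 / R, which makes a 1 V drive into
#' a 50 ohm port 0.02 W.
#'
#' @param v drive voltage(s), V (>= 0).
#' @param resistance port resistance, ohm.
#' @return power(s) in W.
#' @export
port_power <- function(v, resistance = MHF_PORT_OHM) {
  if (any(!is.finite(v)) || any(v < 0)) stop("voltage must be finite and >= 0")
  v^2 / resistance
}

# Number of physical antennas carrying each channel's voltage.
antennas_per_channel <- function(exc) {
  if (exc$scheme == "linear") rep(3, exc$n_channels) else rep(1, exc$n_channels)
}

# Total input power summed over physical antennas (12 for both named schemes).
total_input_power <- function(exc) {
  sum(antennas_per_channel(exc) *
        port_power(exc$voltages, exc$port_resistance))
}

#' Scale an excitation to a fixed total input power
#'
#' Multiplies every voltage by a common factor so the per-antenna port powers
#' sum to `total_w` (default 6 W). For the linear scheme each channel's
#' voltage feeds its 3 physical antennas, so the budget counts 12 antennas in
#' both schemes. Phases are untouched; energy-fraction metrics are invariant
#' under this scaling while the average target power deposition is not.
#'
#' @param exc an `excitation` with at least one nonzero voltage.
#' @param total_w total input power in W.
#' @return the scaled `excitation`.
#' @export
scale_to_total_power <- function(exc, total_w = 6) {
  stopifnot(inherits(exc, "excitation"))
  p <- total_input_power(exc)
  if (p <= 0) stop("all-zero voltages: cannot scale a degenerate excitation")
  exc$voltages <- exc$voltages * sqrt(total_w / p)
  exc
}

# Complex channel coefficients a_i * exp(j * phi_i).
excitation_coefficients <- function(voltages, phases) {
  voltages * exp(1i * phases * pi / 180)
}

#' Superpose unit-excitation fields into a total field
#'
#' Forms the component-wise complex sum of the per-channel fields weighted by
#' the excitation coefficients a_i e^{j phi_i}.
#'
#' @param fs a `field_set`.
#' @param exc an `excitation` (or a bare `list(voltages=, phases=)` for toy
#'   inputs) with `fs$n_channels` entries.
#' @return a complex array `(n_components, n_rows, n_cols)`.
#' @export
superpose <- function(fs, exc) {
  stopifnot(inherits(fs, "field_set"))
  if (inherits(exc, "excitation") && exc$scheme != "custom" &&
      fs$scheme != "custom" && exc$scheme != fs$scheme)
    stop("excitation scheme does not match the field set")
  if (length(exc$voltages) != fs$n_channels ||
      length(exc$phases) != fs$n_channels)
    stop(sprintf("excitation has %d channels but field set has %d",
                 length(exc$voltages), fs$n_channels))
  cf <- excitation_coefficients(exc$voltages, exc$phases)
  out <- array(0 + 0i, dim(fs$fields[[1]]))
  for (i in seq_len(fs$n_channels))
    out <- out + cf[i] * fs$fields[[i]]
  out
}

#' Heating potential of a total field
#'
#' Q0(r) = 0.5 sigma(r) |E_tot(r)|^2 in W/m^3, where |.|^2 sums the squared
#' complex moduli of all field components (no real-field assumption).
#'
#' @param E_tot complex array `(n_components, n_rows, n_cols)`.
#' @param phantom a `phantom_grid` on the same grid.
#' @return an `hp_map` with elements `q0` and `grid`.
#' @export
heating_potential <- function(E_tot, phantom) {
  stopifnot(inherits(phantom, "phantom_grid"))
  d <- dim(E_tot)
  if (length(d) != 3 || d[2] != phantom$grid$n_rows ||
      d[3] != phantom$grid$n_cols)
    stop("E_tot must be (components, n_rows, n_cols) on the phantom grid")
  mag2 <- apply(abs(E_tot)^2, c(2, 3), sum)
  structure(list(grid = phantom$grid, q0 = 0.5 * phantom$sigma * mag2),
            class = "hp_map")
}

#' Min-max normalize a heating-potential map
#'
#' Rescales so the highest level is 1 and the lowest 0.
#'
#' @param hp an `hp_map` (or bare matrix).
#' @return the normalized object of the same type.
#' @export
normalize_hp <- function(hp) {
  m <- if (inherits(hp, "hp_map")) hp$q0 else hp
  rng <- range(m)
  if (diff(rng) <= 0)
    stop("constant heating-potential map cannot be normalized")
  mn <- (m - rng[1]) / diff(rng)
  if (inherits(hp, "hp_map")) { hp$q0 <- mn; hp } else mn
}

#' @export
print.hp_map <- function(x, ...) {
  cat(sprintf("<hp_map> %d x %d px, q0 range %.4g..%.4g W/m^3\n",
              x$grid$n_rows, x$grid$n_cols, min(x$q0), max(x$q0)))
  invisible(x)
}

#' @export
plot.hp_map <- function(x, ...) {
  co <- pixel_coords(x$grid)
  graphics::image(co$x, rev(co$y), t(x$q0[nrow(x$q0):1, ]),
                  xlab = "x (mm)", ylab = "y (mm)",
                  main = "heating potential", ...)
  invisible(x)
}

#' Write / read an excitation as YAML
#'
#' Scheme, per-channel voltages (V) and phases (deg); the round trip is
#' exact to better than 1e-9.
#'
#' @param exc an `excitation`.
#' @param path file path.
#' @return `read_excitation()` returns the `excitation`.
#' @export
write_excitation <- function(exc, path) {
  stopifnot(inherits(exc, "excitation"))
  yaml::write_yaml(list(scheme = exc$scheme,
                        port_resistance_ohm = exc$port_resistance,
                        voltage_v = exc$voltages,
                        phase_deg = exc$phases),
                   path, precision = 17)
  invisible(path)
}

#' @rdname write_excitation
#' @export
read_excitation <- function(path) {
  y <- yaml::read_yaml(path)
  excitation(y$scheme, voltages = as.numeric(y$voltage_v),
             phases = as.numeric(y$phase_deg),
             port_resistance = as.numeric(y$port_resistance_ohm))
}
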