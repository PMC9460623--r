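# Per-antenna unit-excitation fields on the phantom grid.
#
# The built-in model is a desk-scale stand-in for a full-wave solver: each
# antenna radiates a cylindrical wave whose complex wavenumber is averaged
# along the straight ray from antenna to pixel, so both phase accumulation
# and lossy attenuation through heterogeneous tissue are captured.
# Scattering and multipath are not modelled. Externally solved fields can be
# dropped in through the field-set container; everything downstream depends
# only on the field-set contract.

MHF_FREQUENCY_HZ <- 2.45e9
MHF_PORT_OHM <- 50
# cylindrical-wave amplitude for a 1 V drive: the free-space power flowing
# through a unit-height cylinder equals the 0.02 W port power,
# P = pi |A|^2 / eta0  =>  A = sqrt(P * eta0 / pi)
MHF_FIELD_AMP <- sqrt((1 / MHF_PORT_OHM) * 376.730313668 / pi)

#' Antenna layout for an applicator scheme
#'
#' Linear scheme: two rows of 6 antennas, 2 cm apart, on opposite sides of
#' the breast (antennas 1-6 above, 7-12 below); three successive antennas
#' form one driven channel, so N = 4 channels. Circular scheme: 12 antennas
#' at 30 degree separation on a circle concentric with the grid, each its own
#' channel (N = 12).
#'
#' @param scheme `"linear"` or `"circular"`.
#' @param grid a [grid_spec()]; default the scheme's [default_grid()].
#' @return an `antenna_layout` with `positions` (12 x 2 mm),
#'   `channel_of_antenna`, `n_channels`.
#' @export
make_layout <- function(scheme = c("linear", "circular"), grid = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(grid)) grid <- default_grid(scheme)
  co <- pixel_coords(grid)
  if (scheme == "linear") {
    xs <- (seq_len(6) - 3.5) * 20
    yrow <- max(abs(co$y)) - 1
    pos <- rbind(cbind(xs, yrow), cbind(xs, -yrow))
    chan <- rep(1:4, each = 3)
  } else {
    radius <- min(max(abs(co$x)), max(abs(co$y))) - 1.5
    ang <- (seq_len(12) - 1) * 30 * pi / 180
    pos <- cbind(radius * cos(ang), radius * sin(ang))
    chan <- 1:12
  }
  dimnames(pos) <- list(NULL, c("x", "y"))
  structure(list(scheme = scheme, grid = grid, positions = pos,
                 n_antennas = nrow(pos), n_channels = max(chan),
                 channel_of_antenna = chan),
            class = "antenna_layout")
}

#' @export
print.antenna_layout <- function(x, ...) {
  cat(sprintf("<antenna_layout> %s: %d antennas, %d channels\n",
              x$scheme, x$n_antennas, x$n_channels))
  invisible(x)
}

#' Construct a field set
#'
#' Container for N per-channel unit-excitation complex vector fields on a
#' grid. Normally produced by [simulate_unit_fields()] or [read_fieldset()];
#' exposed so toy and externally computed field sets can be built directly.
#'
#' @param grid a [grid_spec()].
#' @param fields list of N complex arrays, each `(n_components, n_rows,
#'   n_cols)` with 1-3 spatial components, in V/m per 1 V drive.
#' @param scheme `"linear"`, `"circular"`, or `"custom"`.
#' @param layout optional `antenna_layout` (required for the named schemes).
#' @param frequency operating frequency in Hz.
#' @param port_resistance port impedance in ohm.
#' @return a `field_set`.
#' @export
field_set <- function(grid, fields, scheme = "custom", layout = NULL,
                      frequency = MHF_FREQUENCY_HZ,
                      port_resistance = MHF_PORT_OHM) {
  stopifnot(inherits(grid, "grid_spec"), is.list(fields), length(fields) >= 1)
  nc_comp <- dim(fields[[1]])[1]
  for (f in fields) {
    d <- dim(f)
    if (length(d) != 3 || d[1] != nc_comp || d[2] != grid$n_rows ||
        d[3] != grid$n_cols)
      stop("every field must be a (components, n_rows, n_cols) array on the grid")
    if (!d[1] %in% 1:3) stop("fields must have 1-3 spatial components")
    if (any(!is.finite(Re(f))) || any(!is.finite(Im(f))))
      stop("fields must be finite everywhere")
  }
  if (!is.null(layout) && layout$n_channels != length(fields))
    stop(sprintf("layout has %d channels but %d fields supplied",
                 layout$n_channels, length(fields)))
  structure(list(grid = grid, scheme = scheme, layout = layout,
                 fields = fields, n_channels = length(fields),
                 n_components = nc_comp, frequency = frequency,
                 port_resistance = port_resistance),
            class = "field_set")
}

#' Simulate per-channel unit-excitation fields
#'
#' Drives each channel with 1 V (every physical antenna of a linear-scheme
#' channel) and records the resulting complex vector field on the grid,
#' using the ray-averaged cylindrical-wave model. A channel's field is the
#' sum of its member antennas' single-antenna waves (superposition at a
#' single frequency). A 1 V drive into the 50 ohm port corresponds to 0.02 W
#' input power; the wave amplitude is calibrated so that power flows through
#' a unit-height free-space cylinder around the antenna.
#'
#' @param phantom a `phantom_grid`.
#' @param layout an `antenna_layout` on the same grid.
#' @param frequency operating frequency in Hz (default 2.45 GHz).
#' @param d_min_mm source-singularity guard: amplitude saturates below this
#'   distance (default one pixel).
#' @return a `field_set` with `layout$n_channels` 2-component fields.
#' @export
simulate_unit_fields <- function(phantom, layout,
                                 frequency = MHF_FREQUENCY_HZ,
                                 d_min_mm = NULL) {
  stopifnot(inherits(phantom, "phantom_grid"),
            inherits(layout, "antenna_layout"))
  if (!same_grid(phantom$grid, layout$grid))
    stop("phantom and layout must share one grid")
  grid <- phantom$grid
  if (is.null(d_min_mm)) d_min_mm <- grid$pixel_mm
  px <- point_to_pixel(grid, layout$positions[, 1], layout$positions[, 2])
  on_grid <- !is.na(px[, 1]) & !is.na(px[, 2])
  inside <- rep(FALSE, nrow(px))
  if (any(on_grid))
    inside[on_grid] <- phantom$breast_mask[px[on_grid, , drop = FALSE]]
  if (any(inside))
    stop("antenna position(s) inside the breast: ",
         paste(which(inside), collapse = ", "))
  co <- pixel_coords(grid)
  raw <- cpp_unit_fields(phantom$eps_r, phantom$sigma, co$x, co$y,
                         layout$positions, grid$pixel_mm, frequency,
                         MHF_FIELD_AMP, d_min_mm)
  fields <- vector("list", layout$n_channels)
  for (ch in seq_len(layout$n_channels)) {
    ants <- which(layout$channel_of_antenna == ch)
    ex <- matrix(0 + 0i, grid$n_rows, grid$n_cols)
    ey <- ex
    for (a in ants) {
      ex <- ex + raw[, , 2 * a - 1]
      ey <- ey + raw[, , 2 * a]
    }
    f <- array(0 + 0i, c(2, grid$n_rows, grid$n_cols))
    f[1, , ] <- ex
    f[2, , ] <- ey
    fields[[ch]] <- f
  }
  field_set(grid, fields, scheme = layout$scheme, layout = layout,
            frequency = frequency, port_resistance = MHF_PORT_OHM)
}

#' @export
print.field_set <- function(x, ...) {
  cat(sprintf(
    "<field_set> %s: %d channels, %d components, %d x %d px, %.3g GHz\n",
    x$scheme, x$n_channels, x$n_components, x$grid$n_rows, x$grid$n_cols,
    x$frequency / 1e9))
  invisible(x)
}

#' Write / read a field-set container
#'
#' Plain-JSON array container with complex datasets `field_000` ...
#' `field_{N-1}` shaped `(components, n_rows, n_cols)`, attributes
#' `frequency_hz`, `port_resistance_ohm`, `pixel_mm`, `scheme`,
#' `n_channels`, and (when present) the antenna position table. Numbers are
#' written in full precision: a save -> load round trip is bit-identical,
#' and files written by an external solver honoring this layout load the
#' same way. Time convention e^{+j w t}: lossy-medium wavenumbers carry
#' Im(k) < 0.
#'
#' @param fs a `field_set`.
#' @param path file path.
#' @return `read_fieldset()` returns the `field_set`.
#' @export
write_fieldset <- function(fs, path) {
  stopifnot(inherits(fs, "field_set"))
  attrs <- list(frequency_hz = fs$frequency,
                port_resistance_ohm = fs$port_resistance,
                pixel_mm = fs$grid$pixel_mm,
                n_rows = fs$grid$n_rows, n_cols = fs$grid$n_cols,
                scheme = fs$scheme, n_channels = fs$n_channels,
                n_components = fs$n_components)
  ds <- stats::setNames(fs$fields,
                        sprintf("field_%03d", seq_len(fs$n_channels) - 1))
  if (!is.null(fs$layout)) {
    ds$antenna_positions <- fs$layout$positions
    ds$channel_of_antenna <- fs$layout$channel_of_antenna
  }
  write_container(path, "mhfocus_fieldset", attrs, ds)
}

#' @rdname write_fieldset
#' @export
read_fieldset <- function(path) {
  obj <- read_container(path, "mhfocus_fieldset")
  a <- obj$attrs
  grid <- grid_spec(a$n_rows, a$n_cols, a$pixel_mm)
  nm <- sprintf("field_%03d", seq_len(a$n_channels) - 1)
  missing <- setdiff(nm, names(obj$datasets))
  if (length(missing) > 0)
    stop("field-set container is missing dataset(s): ",
         paste(missing, collapse = ", "))
  extra <- grep("^field_[0-9]+$", names(obj$datasets), value = TRUE)
  if (length(extra) != a$n_channels)
    stop(sprintf("container holds %d fields but declares n_channels = %d",
                 length(extra), a$n_channels))
  fields <- lapply(nm, function(n) {
    f <- obj$datasets[[n]]
    if (length(dim(f)) != 3 || dim(f)[2] != grid$n_rows ||
        dim(f)[3] != grid$n_cols)
      stop("dataset ", n, " does not match the declared grid shape")
    f
  })
  layout <- NULL
  if (!is.null(obj$datasets$antenna_positions)) {
    pos <- obj$datasets$antenna_positions
    chan <- as.integer(obj$datasets$channel_of_antenna)
    layout <- structure(list(scheme = a$scheme, grid = grid, positions = pos,
                             n_antennas = nrow(pos),
                             n_channels = as.integer(a$n_channels),
                             channel_of_antenna = chan),
                        class = "antenna_layout")
  }
  field_set(grid, fields, scheme = a$scheme, layout = layout,
            frequency = a$frequency_hz,
            port_resistance = a$port_resistance_ohm)
}

#' Export per-channel field magnitudes as CSV
#'
#' Writes `|E_i|` (root of the component-wise squared moduli) of each channel
#' to `<stem>_chan<i>.csv` for inspection.
#'
#' @param fs a `field_set`.
#' @param stem path stem.
#' @export
write_field_magnitude_csv <- function(fs, stem) {
  for (i in seq_len(fs$n_channels)) {
    f <- fs$fields[[i]]
    mag <- sqrt(apply(abs(f)^2, c(2, 3), sum))
    write_map_csv(mag, sprintf("%s_chan%d.csv", stem, i))
  }
  invisible(stem)
}
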