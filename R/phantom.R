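#' Generate a synthetic heterogeneously dense breast phantom
#'
#' Builds a 2D dielectric map (relative permittivity and conductivity at
#' 2.45 GHz) emulating the central slice of a heterogeneously dense breast:
#' an elliptical breast region with a 2 mm skin rim and a smoothed
#' Gaussian-random-field glandular texture inside. The interior conductivity
#' is min-max rescaled to [1.00, 1.88] S/m and the permittivity co-varies over
#' [10, 55]; outside the breast the medium is free space (eps_r = 1,
#' sigma = 0), so out-of-breast pixels never enter energy sums.
#'
#' The texture is synthesized spectrally: white noise is low-pass filtered
#' with a Gaussian kernel of correlation length `heterogeneity` (mm). As
#' `heterogeneity` grows the interior becomes spatially constant, in which
#' case conductivity and permittivity are set to their range midpoints
#' (1.44 S/m, 32.5).
#'
#' @param seed integer seed; the phantom is bit-reproducible given
#'   `(seed, grid, heterogeneity, semi_axes_mm, skin_mm)`.
#' @param grid a [grid_spec()]; default the 71 x 91 linear-applicator grid.
#' @param heterogeneity correlation length of the glandular texture in mm
#'   (> 0); default 8 mm.
#' @param semi_axes_mm outer ellipse semi-axes (x, y) in mm, skin included.
#' @param skin_mm skin rim thickness in mm; skin pixels get eps_r = 38,
#'   sigma = 1.5 S/m.
#' @return an object of class `phantom_grid` with elements `grid`, `eps_r`,
#'   `sigma`, `breast_mask`, `interior_mask`, `tumor` (NULL until
#'   [insert_tumor()]), and the generation parameters.
#' @seealso [insert_tumor()], [write_phantom()]
#' @examples
#' ph <- generate_phantom(seed = 1)
#' range(ph$sigma[ph$interior_mask])
#' @export
generate_phantom <- function(seed, grid = default_grid("linear"),
                             heterogeneity = 8,
                             semi_axes_mm = c(42, 32), skin_mm = 2) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.finite(heterogeneity) || heterogeneity <= 0)
    stop("heterogeneity must be > 0")
  co <- pixel_coords(grid)
  half_x <- max(abs(co$x)) + grid$pixel_mm / 2
  half_y <- max(abs(co$y)) + grid$pixel_mm / 2
  if (semi_axes_mm[1] > half_x || semi_axes_mm[2] > half_y)
    stop("grid too small to contain the breast ellipse")

  ex <- outer(rep(1, grid$n_rows), co$x) / semi_axes_mm[1]
  ey <- outer(co$y, rep(1, grid$n_cols)) / semi_axes_mm[2]
  r2 <- ex^2 + ey^2
  breast_mask <- r2 <= 1
  exi <- outer(rep(1, grid$n_rows), co$x) / (semi_axes_mm[1] - skin_mm)
  eyi <- outer(co$y, rep(1, grid$n_cols)) / (semi_axes_mm[2] - skin_mm)
  interior_mask <- (exi^2 + eyi^2) <= 1

  field <- gaussian_random_field(seed, grid$n_rows, grid$n_cols,
                                 heterogeneity / grid$pixel_mm)
  f <- field[interior_mask]
  rng <- diff(range(f))
  if (rng <= 1e-12 * (abs(mean(f)) + 1)) {
    sig_in <- rep(1.44, sum(interior_mask))
    eps_in <- rep(32.5, sum(interior_mask))
  } else {
    u <- (f - min(f)) / rng
    sig_in <- 1.00 + u * (1.88 - 1.00)
    eps_in <- 10 + u * (55 - 10)
  }

  sigma <- matrix(0, grid$n_rows, grid$n_cols)
  eps_r <- matrix(1, grid$n_rows, grid$n_cols)
  skin <- breast_mask & !interior_mask
  sigma[skin] <- 1.5
  eps_r[skin] <- 38
  sigma[interior_mask] <- sig_in
  eps_r[interior_mask] <- eps_in

  structure(list(grid = grid, eps_r = eps_r, sigma = sigma,
                 breast_mask = breast_mask, interior_mask = interior_mask,
                 tumor = NULL, seed = as.integer(seed),
                 heterogeneity = heterogeneity,
                 semi_axes_mm = semi_axes_mm, skin_mm = skin_mm),
            class = "phantom_grid")
}

# Spectral synthesis of a smoothed Gaussian random field. The Gaussian
# low-pass e^{-(k*len)^2/2} kills every non-DC mode as len -> Inf, so the
# infinite-correlation limit is exactly constant (machine zero range).
gaussian_random_field <- function(seed, n_rows, n_cols, len_px) {
  set.seed(as.integer(seed))
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  kr <- 2 * pi * c(0:floor(n_rows / 2), -(ceiling(n_rows / 2) - 1):-1) / n_rows
  kc <- 2 * pi * c(0:floor(n_cols / 2), -(ceiling(n_cols / 2) - 1):-1) / n_cols
  k2 <- outer(kr^2, rep(1, n_cols)) + outer(rep(1, n_rows), kc^2)
  filt <- exp(-0.5 * k2 * len_px^2)
  Re(stats::fft(stats::fft(z) * filt, inverse = TRUE)) / (n_rows * n_cols)
}

#' Insert a tumor disc into a phantom
#'
#' Sets every pixel whose centre lies within `radius_mm` of `center` to the
#' tumor dielectric values eps_r = 40, sigma = 2.0 S/m (just above the 1.88
#' S/m background maximum, so the tumor is the most conductive tissue).
#' Idempotent: re-inserting the same tumor changes nothing.
#'
#' @param phantom a `phantom_grid`.
#' @param center tumor centre (x, y) in mm.
#' @param radius_mm tumor radius in mm (default 5, a 1 cm lesion).
#' @return the modified `phantom_grid` with a `tumor` record.
#' @export
insert_tumor <- function(phantom, center, radius_mm = 5) {
  stopifnot(inherits(phantom, "phantom_grid"))
  if (radius_mm < 0) stop("radius_mm must be >= 0")
  d <- pixel_distances(phantom$grid, center)
  disc <- d <= radius_mm
  if (any(disc & !phantom$breast_mask))
    stop("tumor extends outside the breast")
  phantom$eps_r[disc] <- 40
  phantom$sigma[disc] <- 2.0
  phantom$tumor <- list(center = center, radius_mm = radius_mm)
  phantom
}

#' @export
print.phantom_grid <- function(x, ...) {
  cat(sprintf("<phantom_grid> %d x %d px, breast %d px (interior %d px)\n",
              x$grid$n_rows, x$grid$n_cols,
              sum(x$breast_mask), sum(x$interior_mask)))
  s <- x$sigma[x$breast_mask]
  cat(sprintf("  sigma in breast: %.3f..%.3f S/m; eps_r: %.1f..%.1f\n",
              min(s), max(s), min(x$eps_r[x$breast_mask]),
              max(x$eps_r[x$breast_mask])))
  if (!is.null(x$tumor))
    cat(sprintf("  tumor: r = %g mm at (%g, %g) mm\n",
                x$tumor$radius_mm, x$tumor$center[1], x$tumor$center[2]))
  invisible(x)
}

#' @export
plot.phantom_grid <- function(x, what = c("sigma", "eps_r"), ...) {
  what <- match.arg(what)
  co <- pixel_coords(x$grid)
  m <- x[[what]]
  graphics::image(co$x, rev(co$y), t(m[nrow(m):1, ]),
                  xlab = "x (mm)", ylab = "y (mm)",
                  main = if (what == "sigma") "conductivity (S/m)"
                         else "relative permittivity", ...)
  invisible(x)
}
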