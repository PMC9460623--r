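# Focusing-quality metrics: target energy fraction, dominant hotspot,
# hotspot-to-target ratio, and average target power deposition at 6 W.

# Summed-area table with a zero top row / left column, so the sum over rows
# r0..r1, cols c0..c1 is S[r1+1,c1+1] - S[r0,c1+1] - S[r1+1,c0] + S[r0,c0].
sat <- function(m) {
  s <- apply(apply(m, 2, cumsum), 1, cumsum)  # t(cumsum rows then cols)
  rbind(0, cbind(0, t(s)))
}

sat_window <- function(s, r0, c0, k) {
  s[cbind(r0 + k, c0 + k)] - s[cbind(r0, c0 + k)] -
    s[cbind(r0 + k, c0)] + s[cbind(r0, c0)]
}

# Window sums for every placement: matrix indexed by (top row, left col).
sat_window_all <- function(s, r0s, c0s, k) {
  R0 <- rep(r0s, times = length(c0s))
  C0 <- rep(c0s, each = length(r0s))
  matrix(sat_window(s, R0, C0, k), length(r0s), length(c0s))
}

#' Energy fraction deposited in a region
#'
#' 100 * sum_region(sigma |E|^2) / sum_breast(sigma |E|^2), evaluated on the
#' heating potential (the 1/2 cancels). Pixels outside the breast mask have
#' sigma = 0 and contribute to neither sum; the region is intersected with
#' the breast.
#'
#' @param hp an `hp_map` (or bare q0 matrix).
#' @param phantom the `phantom_grid`.
#' @param region_mask logical/0-1 matrix selecting the region.
#' @return percentage in [0, 100].
#' @export
omega_region <- function(hp, phantom, region_mask) {
  q0 <- if (inherits(hp, "hp_map")) hp$q0 else hp
  stopifnot(all(dim(q0) == dim(phantom$sigma)),
            all(dim(region_mask) == dim(q0)))
  total <- sum(q0[phantom$breast_mask])
  if (total <= 0) stop("zero breast-wide deposited energy: metric undefined")
  100 * sum(q0[(region_mask > 0) & phantom$breast_mask]) / total
}

#' Dominant hotspot of a heating map
#'
#' Slides a window congruent to the target square over every in-grid
#' position that overlaps the breast and does not intersect the target
#' square, and returns the one maximizing the deposited energy. Ties are
#' broken by smallest row, then smallest column. Because the window matches
#' the target square, the hotspot-to-target ratio compares like-for-like
#' energy fractions.
#'
#' @param hp an `hp_map`.
#' @param phantom the `phantom_grid`.
#' @param target a [target_spec()] inside the breast.
#' @return list with `mask` (the hotspot window), `omega_hotspot` (percent),
#'   `center` (window centre, mm), `row`/`col` (top-left pixel).
#' @export
find_dominant_hotspot <- function(hp, phantom, target) {
  q0 <- if (inherits(hp, "hp_map")) hp$q0 else hp
  grid <- phantom$grid
  tmask <- build_mask(target, grid, phantom)
  k <- max(1L, round(target$side_mm / grid$pixel_mm))
  nr <- grid$n_rows; nc <- grid$n_cols
  if (nr < k || nc < k) stop("grid too small for the hotspot window")
  sq <- sat(q0)
  sb <- sat(phantom$breast_mask * 1)
  tr <- range(which(rowSums(tmask) > 0))
  tc <- range(which(colSums(tmask) > 0))
  r0s <- seq_len(nr - k + 1L)
  c0s <- seq_len(nc - k + 1L)
  score <- sat_window_all(sq, r0s, c0s, k)
  breast_px <- sat_window_all(sb, r0s, c0s, k)
  overlaps_t <- outer(r0s, c0s, function(r0, c0)
    (r0 <= tr[2] & r0 + k - 1L >= tr[1]) & (c0 <= tc[2] & c0 + k - 1L >= tc[1]))
  valid <- breast_px >= 1 & !overlaps_t
  if (!any(valid))
    stop("breast too small to host a hotspot window disjoint from the target")
  score[!valid] <- -Inf
  hits <- which(score == max(score), arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  r0 <- unname(hits[1, 1]); c0 <- unname(hits[1, 2])
  mask <- matrix(0, nr, nc)
  mask[r0:(r0 + k - 1L), c0:(c0 + k - 1L)] <- 1
  co <- pixel_coords(grid)
  center <- c(mean(co$x[c0:(c0 + k - 1L)]), mean(co$y[r0:(r0 + k - 1L)]))
  list(mask = mask, omega_hotspot = omega_region(q0, phantom, mask),
       center = center, row = r0, col = c0)
}

#' Hotspot-to-target ratio
#'
#' @param omega_hotspot,omega_target energy fractions in percent;
#'   `omega_target` must be positive.
#' @return the dimensionless quotient (lower is better).
#' @examples psi(10.78, 8.42)  # 1.28
#' @export
psi <- function(omega_hotspot, omega_target) {
  if (any(omega_target <= 0))
    stop("omega_target must be > 0 for the hotspot-to-target ratio")
  omega_hotspot / omega_target
}

#' Average power deposition over the target square
#'
#' Mean heating potential over the target pixels, reported in kW/m^3. Only
#' meaningful for an excitation already scaled to the 6 W total input power
#' (the quantity scales with drive power, unlike the energy fractions). With
#' `options(mhfocus.pav_printed_formula = TRUE)` the 1/2 of the heating
#' potential is dropped (sum of sigma |E|^2 over the target area).
#'
#' @param E_tot complex field array from [superpose()].
#' @param phantom the `phantom_grid`.
#' @param target a [target_spec()].
#' @return average deposition in kW/m^3.
#' @export
p_av <- function(E_tot, phantom, target) {
  hp <- heating_potential(E_tot, phantom)
  tmask <- build_mask(target, phantom$grid, phantom)
  val <- mean(hp$q0[tmask > 0])
  if (isTRUE(getOption("mhfocus.pav_printed_formula", FALSE))) val <- 2 * val
  val / 1000
}

#' Score an excitation against a target
#'
#' Runs the full evaluation protocol: scale the excitation to the 6 W total
#' input power, superpose the unit fields, form the heating potential, and
#' report the target energy fraction, the dominant-hotspot fraction, their
#' ratio, and the average target power deposition.
#'
#' @param exc an `excitation` (any overall drive level; a scaled copy is
#'   used, which leaves the energy fractions unchanged).
#' @param fs the `field_set`.
#' @param phantom the `phantom_grid`.
#' @param target a [target_spec()].
#' @param total_w total input power for reporting (default 6 W).
#' @return a `metrics_report` with `omega_target`, `omega_hotspot`, `psi`,
#'   `p_av_kw_m3`, `hotspot_center`, and the scaled `excitation`.
#' @export
evaluate_excitation <- function(exc, fs, phantom, target, total_w = 6) {
  stopifnot(inherits(exc, "excitation"))
  if (!same_grid(fs$grid, phantom$grid))
    stop("field set and phantom must share one grid")
  exc6 <- scale_to_total_power(exc, total_w)
  E <- superpose(fs, exc6)
  hp <- heating_potential(E, phantom)
  tmask <- build_mask(target, phantom$grid, phantom)
  om_t <- omega_region(hp, phantom, tmask)
  hs <- find_dominant_hotspot(hp, phantom, target)
  structure(list(omega_target = om_t, omega_hotspot = hs$omega_hotspot,
                 psi = psi(hs$omega_hotspot, om_t),
                 p_av_kw_m3 = p_av(E, phantom, target),
                 hotspot_center = hs$center, target = target,
                 excitation = exc6, total_w = total_w),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> target (%g, %g) mm, %g W total input\n",
              x$target$center[1], x$target$center[2], x$total_w))
  cat(sprintf(
    "  omega_target %6.2f %%   omega_hotspot %6.2f %%   psi %5.2f   P_av %7.2f kW/m^3\n",
    x$omega_target, x$omega_hotspot, x$psi, x$p_av_kw_m3))
  cat(sprintf("  hotspot at (%g, %g) mm\n",
              x$hotspot_center[1], x$hotspot_center[2]))
  invisible(x)
}

#' Flatten a metrics report to a one-row data frame
#'
#' Mirrors the per-case result tables: per-channel phases and per-antenna
#' powers followed by the four metrics.
#'
#' @param report a `metrics_report`.
#' @return a one-row data frame.
#' @export
report_row <- function(report) {
  exc <- report$excitation
  pw <- port_power(exc$voltages, exc$port_resistance)
  row <- c(stats::setNames(exc$phases,
                           paste0("phase_deg_", seq_along(exc$phases))),
           stats::setNames(pw, paste0("power_w_", seq_along(pw))),
           omega_target = report$omega_target,
           omega_hotspot = report$omega_hotspot,
           psi = report$psi, p_av_kw_m3 = report$p_av_kw_m3)
  as.data.frame(as.list(row))
}
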