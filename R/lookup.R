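# Brute-force look-up-table baselines: exhaustive integer-degree phase
# search and gridded voltage search, both scored by the target energy
# fraction only (hotspots are deliberately ignored — that asymmetry against
# the network planner is the point of the comparison).
#
# Each cell's objective is evaluated through per-region coupling matrices
# M_R[i, j] = sum_{r in R} sigma(r) E_i(r) . conj(E_j(r)): for channel
# coefficients c the deposited energy in R is c^H M_R c, so
# omega_target(c) = 100 * (c^H M_t c) / (c^H M_b c) — algebraically identical
# to superposing and summing per cell, at a fraction of the cost. Cells are
# processed in vectorized blocks.

# N x N Hermitian coupling matrix of a pixel region.
region_coupling <- function(fs, phantom, region_mask) {
  stopifnot(inherits(fs, "field_set"))
  sel <- which((region_mask > 0) & phantom$breast_mask)
  n <- fs$n_channels
  hw <- fs$grid$n_rows * fs$grid$n_cols
  # (ncomp*|R|) x N matrix of field values in the region
  fm <- vapply(fs$fields, function(f) {
    m <- matrix(f, fs$n_components, hw)
    as.vector(m[, sel, drop = FALSE])
  }, complex(fs$n_components * length(sel)))
  w <- rep(phantom$sigma[sel], each = fs$n_components)
  Conj(t(fm * w)) %*% fm
}

free_count_for_lookup <- function(fs) {
  switch(fs$scheme, linear = 2L, circular = 6L,
         custom = fs$n_channels - 1L)
}

# (N x m) full phase matrix from an (n_free x m) free-phase matrix.
free_to_full_phases <- function(scheme, free, n_channels) {
  m <- ncol(free)
  if (scheme == "linear") {
    rbind(0, free[1, ], free[2, ], free[1, ] + free[2, ])
  } else if (scheme == "circular") {
    full <- matrix(0, 12, m)
    full[seq(2, 12, 2), ] <- free
    for (k in c(3, 5, 7, 9, 11))
      full[k, ] <- full[k - 1, ] + full[k + 1, ]
    full
  } else {
    rbind(0, free)
  }
}

# All free-phase combinations in lexicographic order (first phase slowest),
# as an (n_free x m) matrix.
phase_grid <- function(vals, n_free) {
  g <- expand.grid(rev(replicate(n_free, vals, simplify = FALSE)))
  t(as.matrix(g[, rev(seq_len(n_free)), drop = FALSE]))
}

#' Exhaustive phase look-up table
#'
#' Enumerates every combination of integer-degree free phases (step
#' `step_deg`), scores each by the target energy fraction at unit voltages,
#' and returns the best cell (ties: first in lexicographic free-phase
#' order). The full 1-degree table for the linear scheme has
#' 360 x 360 = 129,600 cells; schemes with more free phases need a coarser
#' step to stay under `max_cells`.
#'
#' @param fs a `field_set`.
#' @param phantom the `phantom_grid`.
#' @param target a [target_spec()].
#' @param step_deg phase step in degrees (must divide 360).
#' @param top_k how many best cells to keep in the `top` table.
#' @param max_cells refusal threshold on the enumeration size.
#' @param block_size cells per vectorized block.
#' @return list with `free_phases`, `phases`, `omega_target`, `n_cells`,
#'   `step_deg`, and `top` (data frame of the `top_k` best cells).
#' @export
phase_lookup <- function(fs, phantom, target, step_deg = 1, top_k = 20,
                         max_cells = 1e7, block_size = 20000) {
  stopifnot(inherits(fs, "field_set"), inherits(phantom, "phantom_grid"))
  if (360 %% step_deg != 0) stop("step_deg must divide 360")
  nf <- free_count_for_lookup(fs)
  vals <- seq(0, 360 - step_deg, by = step_deg)
  n_cells <- length(vals)^nf
  if (n_cells > max_cells)
    stop(sprintf(
      "phase table would need %.3g cells (> %.3g); use a coarser step_deg",
      n_cells, max_cells))
  tmask <- build_mask(target, fs$grid, phantom)
  Mt <- region_coupling(fs, phantom, tmask)
  Mb <- region_coupling(fs, phantom, phantom$breast_mask)
  free <- phase_grid(vals, nf)
  omega <- numeric(n_cells)
  for (b0 in seq(1, n_cells, block_size)) {
    ix <- b0:min(n_cells, b0 + block_size - 1L)
    full <- free_to_full_phases(fs$scheme, free[, ix, drop = FALSE],
                                fs$n_channels)
    C <- exp(1i * full * pi / 180)
    num <- Re(colSums(Conj(C) * (Mt %*% C)))
    den <- Re(colSums(Conj(C) * (Mb %*% C)))
    omega[ix] <- 100 * num / den
  }
  best <- which.max(omega)
  ord <- order(-omega)[seq_len(min(top_k, n_cells))]
  top <- data.frame(t(free[, ord, drop = FALSE]))
  names(top) <- paste0("free_phase_", seq_len(nf))
  top$omega_target <- omega[ord]
  bf <- unname(free[, best])
  list(free_phases = wrap_phase(bf),
       phases = wrap_phase(free_to_full_phases(fs$scheme,
                                               matrix(bf, ncol = 1),
                                               fs$n_channels)[, 1]),
       omega_target = omega[best], n_cells = n_cells,
       step_deg = step_deg, top = top)
}

# Voltage combinations for channels ch..N in lexicographic order given a
# chunking over the first channel's level.
voltage_grid <- function(vals, n) {
  g <- expand.grid(rev(replicate(n, vals, simplify = FALSE)))
  t(as.matrix(g[, rev(seq_len(n)), drop = FALSE]))
}

#' Gridded voltage look-up table at fixed phases
#'
#' Enumerates per-channel voltages over `seq(v_min, v_max, v_step)` (41
#' levels per channel by default, 41^4 = 2,825,761 cells for four channels),
#' skips the degenerate all-zero cell, and maximizes the target energy
#' fraction. The winning voltages are also returned scaled to the 6 W total
#' input power (which leaves the energy fraction unchanged).
#'
#' @param fs a `field_set`.
#' @param phantom the `phantom_grid`.
#' @param target a [target_spec()].
#' @param fixed_phases full per-channel phase vector in degrees (normally
#'   the phase-table winner).
#' @param v_min,v_max,v_step voltage grid in V.
#' @param top_k best cells to keep.
#' @param max_cells refusal threshold on the enumeration size.
#' @return list with `voltages`, `voltages_6w`, `omega_target`, `n_cells`
#'   (the all-zero cell included in the count), and `top`.
#' @export
voltage_lookup <- function(fs, phantom, target, fixed_phases,
                           v_min = 0, v_max = 1, v_step = 0.025,
                           top_k = 20, max_cells = 1e7) {
  stopifnot(inherits(fs, "field_set"), inherits(phantom, "phantom_grid"))
  n <- fs$n_channels
  vals <- seq(v_min, v_max, by = v_step)
  n_cells <- length(vals)^n
  if (n_cells > max_cells)
    stop(sprintf(
      "voltage table would need %.3g cells (> %.3g); coarsen v_step",
      n_cells, max_cells))
  fixed_phases <- as.numeric(fixed_phases)
  stopifnot(length(fixed_phases) == n)
  tmask <- build_mask(target, fs$grid, phantom)
  c0 <- exp(1i * fixed_phases * pi / 180)
  # real symmetric forms: energy_R(v) = v' S_R v
  St <- Re(Conj(c0) * region_coupling(fs, phantom, tmask) *
             rep(c0, each = n))
  Sb <- Re(Conj(c0) * region_coupling(fs, phantom, phantom$breast_mask) *
             rep(c0, each = n))
  best <- list(omega = -Inf, v = NULL)
  top <- NULL
  for (lead in vals) {
    Vg <- voltage_grid(vals, n - 1L)
    V <- rbind(lead, Vg)
    keep <- colSums(V) > 0
    if (!any(keep)) next
    V <- V[, keep, drop = FALSE]
    num <- colSums(V * (St %*% V))
    den <- colSums(V * (Sb %*% V))
    om <- 100 * num / den
    ord <- order(-om)[seq_len(min(top_k, length(om)))]
    chunk <- data.frame(t(V[, ord, drop = FALSE]))
    names(chunk) <- paste0("v", seq_len(n))
    chunk$omega_target <- om[ord]
    top <- rbind(top, chunk)
    i <- which.max(om)
    if (om[i] > best$omega) best <- list(omega = om[i], v = V[, i])
  }
  top <- top[order(-top$omega_target), ][seq_len(min(top_k, nrow(top))), ]
  rownames(top) <- NULL
  exc6 <- scale_to_total_power(
    excitation(if (fs$scheme %in% c("linear", "circular")) fs$scheme
               else "custom",
               voltages = best$v, phases = fixed_phases), 6)
  list(voltages = unname(best$v), voltages_6w = exc6$voltages,
       omega_target = best$omega, n_cells = n_cells,
       v_step = v_step, top = top)
}

#' Write the top cells of a look-up table to CSV
#'
#' @param lut result of [phase_lookup()] or [voltage_lookup()].
#' @param path file path.
#' @export
write_lookup_csv <- function(lut, path) {
  utils::write.csv(lut$top, path, row.names = FALSE)
  invisible(path)
}
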