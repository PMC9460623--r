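# End-to-end planning protocol: phantom -> unit fields -> phase corpus ->
# stage-1 network -> voltage corpus at the predicted phases -> stage-2
# network -> masked-target predictions -> metrics (optionally with the
# look-up-table baselines on the same field set).

#' Pipeline configuration
#'
#' Defaults reproduce the study conditions: 71 x 91 (linear) or 91 x 91
#' (circular) grid at 1 mm, 2.45 GHz, corpus sizes 2000 / 50,000, batch
#' size 100 / 200, up to 100 epochs with early stopping (patience 10), a
#' 10 mm square target, and 6 W total input power. Stage seeds are derived
#' from `seed` by fixed offsets so every stage is reproducible in isolation.
#'
#' @param scheme `"linear"` or `"circular"`.
#' @param seed master seed.
#' @param target_center target (x, y) in mm.
#' @param with_tumor place a 5 mm tumor at the target centre.
#' @param heterogeneity phantom texture correlation length (mm).
#' @param m_phase,m_voltage corpus sizes (defaults per scheme).
#' @param epochs,patience training schedule.
#' @param batch_size minibatch size (default per scheme).
#' @param grid optional [grid_spec()] override.
#' @param semi_axes_mm breast outer ellipse semi-axes (mm).
#' @param run_lookup also run the phase/voltage look-up tables (linear
#'   scheme only at full grid).
#' @param lookup_step_deg phase-table step in degrees.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(scheme = c("linear", "circular"), seed = 1L,
                            target_center = c(26, 12), with_tumor = FALSE,
                            heterogeneity = 8,
                            m_phase = NULL, m_voltage = NULL,
                            epochs = 100, patience = 10,
                            batch_size = NULL, grid = NULL,
                            semi_axes_mm = c(42, 32),
                            run_lookup = FALSE, lookup_step_deg = 1) {
  scheme <- match.arg(scheme)
  if (is.null(grid)) grid <- default_grid(scheme)
  if (is.null(m_phase)) m_phase <- default_corpus_size(scheme)
  if (is.null(m_voltage)) m_voltage <- default_corpus_size(scheme)
  if (is.null(batch_size)) batch_size <- if (scheme == "linear") 100L else 200L
  structure(list(scheme = scheme, seed = as.integer(seed),
                 target_center = target_center, with_tumor = with_tumor,
                 heterogeneity = heterogeneity, m_phase = m_phase,
                 m_voltage = m_voltage, epochs = epochs, patience = patience,
                 batch_size = batch_size, grid = grid,
                 semi_axes_mm = semi_axes_mm, run_lookup = run_lookup,
                 lookup_step_deg = lookup_step_deg),
            class = "pipeline_config")
}

#' Run the full two-stage planning pipeline
#'
#' Executes every stage of the protocol and assembles a per-stage metrics
#' table. When `out_dir` is given, the phantom and field-set containers, the
#' trained models, training curves and a manifest (seeds, file checksums)
#' are written there; a rerun with an identical configuration reproduces
#' identical checksums.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional artifact directory.
#' @param verbose print stage progress to stderr.
#' @return list with `phantom`, `fieldset`, `cnn1`, `cnn2`, `phases`,
#'   `voltages`, `report_cnn1`, `report_cnn2`, `reports` (data frame),
#'   optionally `lookup_phase` / `lookup_voltage` rows, and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[3]
  stage <- function(name) say("[%6.1fs] %s", proc.time()[3] - t0, name)
  sd <- config$seed

  stage("phantom")
  phantom <- generate_phantom(sd, config$grid, config$heterogeneity,
                              config$semi_axes_mm)
  if (config$with_tumor)
    phantom <- insert_tumor(phantom, config$target_center, 5)
  target <- target_spec(config$target_center)

  stage("unit fields")
  layout <- make_layout(config$scheme, config$grid)
  fs <- simulate_unit_fields(phantom, layout)

  stage(sprintf("phase corpus (%d samples)", config$m_phase))
  free <- sample_free_phases(sd + 101L, config$m_phase, config$scheme)
  ds1 <- build_phase_dataset(fs, phantom, free, seed = sd + 1L)

  stage("stage-1 training")
  spec1 <- cnn_spec(output_dim = 2L * free_phase_count(config$scheme),
                    input_shape = c(config$grid$n_rows, config$grid$n_cols),
                    batch_size = config$batch_size, epochs = config$epochs,
                    patience = config$patience)
  cnn1 <- build_model(spec1, seed = sd + 11L)
  cnn1 <- train_cnn(cnn1, ds1, seed = sd + 21L, verbose = verbose)

  mask <- build_mask(target, config$grid, phantom)
  ph_pred <- predict_phases(cnn1, mask)
  say("  predicted phases: %s",
      paste(sprintf("%.2f", ph_pred$phases), collapse = " "))

  stage(sprintf("voltage corpus (%d samples)", config$m_voltage))
  volts <- sample_voltages(sd + 31L, config$m_voltage, config$scheme)
  ds2 <- build_voltage_dataset(fs, phantom, ph_pred$phases, volts,
                               seed = sd + 2L)

  stage("stage-2 training")
  spec2 <- cnn_spec(output_dim = fs$n_channels,
                    input_shape = c(config$grid$n_rows, config$grid$n_cols),
                    batch_size = config$batch_size, epochs = config$epochs,
                    patience = config$patience)
  cnn2 <- build_model(spec2, seed = sd + 12L)
  cnn2 <- train_cnn(cnn2, ds2, seed = sd + 22L, verbose = verbose)
  v_pred <- predict_voltages(cnn2, mask)

  stage("evaluation")
  exc1 <- excitation(config$scheme, rep(1, fs$n_channels),
                     phases = ph_pred$phases)
  rep1 <- evaluate_excitation(exc1, fs, phantom, target)
  exc2 <- excitation(config$scheme, v_pred, phases = ph_pred$phases)
  rep2 <- evaluate_excitation(exc2, fs, phantom, target)
  reports <- rbind(cbind(stage = "cnn_phase", report_row(rep1)),
                   cbind(stage = "cnn_voltage", report_row(rep2)))

  out <- list(phantom = phantom, fieldset = fs, target = target,
              cnn1 = cnn1, cnn2 = cnn2, phases = ph_pred$phases,
              voltages = v_pred, report_cnn1 = rep1, report_cnn2 = rep2)

  if (config$run_lookup) {
    stage("phase look-up table")
    lp <- phase_lookup(fs, phantom, target,
                       step_deg = config$lookup_step_deg)
    excp <- excitation(config$scheme, rep(1, fs$n_channels),
                       phases = lp$phases)
    repp <- evaluate_excitation(excp, fs, phantom, target)
    stage("voltage look-up table")
    lv <- voltage_lookup(fs, phantom, target, lp$phases)
    excv <- excitation(config$scheme, lv$voltages, phases = lp$phases)
    repv <- evaluate_excitation(excv, fs, phantom, target)
    reports <- rbind(reports,
                     cbind(stage = "lookup_phase", report_row(repp)),
                     cbind(stage = "lookup_voltage", report_row(repv)))
    out$lookup_phase <- lp
    out$lookup_voltage <- lv
    out$report_lookup_phase <- repp
    out$report_lookup_voltage <- repv
  }
  out$reports <- reports

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_phantom(phantom, file.path(out_dir, "phantom.json"))
    write_fieldset(fs, file.path(out_dir, "fieldset.json"))
    saveRDS(cnn1, file.path(out_dir, "cnn1.rds"))
    saveRDS(cnn2, file.path(out_dir, "cnn2.rds"))
    write_training_curve(cnn1, file.path(out_dir, "cnn1_curve.csv"))
    write_training_curve(cnn2, file.path(out_dir, "cnn2_curve.csv"))
    utils::write.csv(reports, file.path(out_dir, "reports.csv"),
                     row.names = FALSE)
    files <- c("phantom.json", "fieldset.json", "cnn1_curve.csv",
               "cnn2_curve.csv", "reports.csv")
    manifest <- list(
      config = unclass(config[setdiff(names(config), "grid")]),
      grid = c(config$grid$n_rows, config$grid$n_cols,
               config$grid$pixel_mm),
      seeds = list(master = sd, phase_sampling = sd + 101L,
                   voltage_sampling = sd + 31L,
                   init = c(sd + 11L, sd + 12L),
                   shuffle = c(sd + 21L, sd + 22L)),
      checksums = as.list(tools::md5sum(file.path(out_dir, files))))
    names(manifest$checksums) <- files
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$manifest <- manifest
  }
  stage("done")
  out
}
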