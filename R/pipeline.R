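#' Configuration-driven pipeline
#'
#' `run_pipeline()` executes the three-step reduced-model pipeline — (1)
#' oscillatory flow with the flow-rate controller, (2) mean Lagrangian
#' velocity with the Helmholtz projection, (3) reduced transport — or the
#' full oscillatory benchmark, from a single configuration, writing all
#' stage outputs and a run manifest. The pipeline contains no random
#' numbers: two runs of one configuration produce identical outputs, and any
#' stage can be re-run from the previous stage's serialized files.
#'
#' @section Configuration:
#' A named list (or YAML file read with [read_config()]) with blocks:
#' * `scenario`: name (free text).
#' * `geometry`: `obstructed`, `nx`, `ny`, `n_segments`.
#' * `waveform`: either `type: sine` with `stroke_volume_mL` (and optional
#'   `scale`), or `csv` with a file path.
#' * `fluid`: `rho_kg_m3`, `nu_m2_s`, `period_s`.
#' * `transport`: `schmidt` (or `kappa_m2_s`), `t_end_s`, `dt_s`, `scheme`.
#' * `variant`: one of `"lagrangian"`, `"eulerian_mean"`, `"diffusionless"`,
#'   `"full_dns"`.
#' * `output`: directory path.
#' * `bolus` (optional): `center_cm`, `width_cm2`; a default center outside
#'   the domain falls back to the domain midpoint.
#' * `tolerances` (optional): `tol_periodic`, `n_adjust_cycles`.
#'
#' @param config configuration list or path to a YAML file.
#' @param flow_series optional path to a stage-1 field series directory to
#'   resume from (stage isolation).
#' @return the run manifest (also written as `manifest.json`), invisibly the
#'   full result list.
#' @export
run_pipeline <- function(config, flow_series = NULL) {
  if (is.character(config)) config <- read_config(config)
  cfg <- validate_config(config)
  outdir <- cfg$output
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  geo <- cfg$geometry
  wf <- config_waveform(cfg)
  sc <- channel_scenario(
    obstructed = isTRUE(geo$obstructed), nx = geo$nx, ny = geo$ny,
    n_segments = geo$n_segments,
    period = cfg$fluid$period_s, nu = cfg$fluid$nu_m2_s,
    schmidt = cfg$transport$schmidt %||% 1000,
    t_end = cfg$transport$t_end_s)
  sc$waveform <- wf
  se <- stroke_volume_and_epsilon(wf, sc$V_seg)
  sc$V_s <- se$V_s; sc$epsilon <- se$epsilon
  if (!is.null(cfg$transport$kappa_m2_s)) {
    sc$transport <- transport_params(
      kappa = cfg$transport$kappa_m2_s, dt = sc$transport$dt,
      scheme = sc$transport$scheme, t_end = sc$transport$t_end,
      snapshot_every = sc$transport$snapshot_every)
  }

  # stage 1: flow
  if (is.null(flow_series)) {
    tol <- cfg$tolerances %||% list()
    fres <- solve_oscillatory_channel(
      sc$grid, wf, sc$fluid,
      tol_periodic = tol$tol_periodic %||% 1e-4,
      n_adjust_cycles = tol$n_adjust_cycles %||% 100L)
    field <- fres$field
    ctrl <- fres$controller
    write_field_series(field, file.path(outdir, "flow_series"))
    ctrl_sum <- list(cycles_run = ctrl$cycles_run,
                     final_residual = utils::tail(ctrl$residual_history, 1),
                     tracking_err = ctrl$flow_rate_tracking_err,
                     forcing_amplitude = max(abs(ctrl$force_per_phase)),
                     cycle_error_norms = ctrl$cycle_error_norms)
    utils::write.csv(data.frame(t_s = ctrl$phase_times,
                                force_cm_s2 = ctrl$force_per_phase),
                     file.path(outdir, "controller_force.csv"),
                     row.names = FALSE)
  } else {
    field <- read_field_series(flow_series)
    ctrl_sum <- list(resumed_from = flow_series)
  }

  # stage 2: drift (variant-dependent)
  variant <- cfg$variant
  drift_info <- NULL
  mean_field <- NULL
  if (variant == "lagrangian") {
    traj <- lagrangian_mean_from_trajectories(field)
    raw <- scatter_to_grid(traj$samples, field$grid)
    pr <- project_solenoidal(raw)
    mean_field <- pr$field
    write_field_vtr(raw, file.path(outdir, "drift_raw.vtr"))
    write_field_vtr(mean_field, file.path(outdir, "drift_solenoidal.vtr"))
    utils::write.csv(as.data.frame(traj$particles),
                     file.path(outdir, "particles.csv"), row.names = FALSE)
    drift_info <- c(pr$diagnostics,
                    list(particle_status = as.list(table(traj$particles$status))))
  } else if (variant == "eulerian_mean") {
    mean_field <- cycle_average(field)
    write_field_vtr(mean_field, file.path(outdir, "drift_eulerian.vtr"))
  }

  # stage 3: transport
  gt <- tile_grid(sc$grid)
  center <- cfg$bolus$center_cm %||% sc$bolus_center
  if (center <= gt$x0 || center >= gt$x0 + gt$Lx) {
    center <- gt$x0 + gt$Lx / 2       # short domains: release mid-domain
  }
  width <- cfg$bolus$width_cm2 %||% sc$bolus_width
  bolus <- gaussian_bolus(gt, center, width)
  params <- sc$transport
  hist <- switch(
    variant,
    full_dns = integrate_full_transport(field, bolus, params),
    diffusionless = {
      pd <- transport_params(kappa = 0, dt = params$dt, scheme = params$scheme,
                             t_end = params$t_end,
                             snapshot_every = params$snapshot_every)
      h <- integrate_full_transport(field, bolus, pd)
      h$variant <- "diffusionless_dns"
      h
    },
    lagrangian = ,
    eulerian_mean = integrate_reduced_transport(
      mean_field, bolus,
      transport_params(kappa = params$kappa, dt = 1, scheme = "upwind_2nd",
                       t_end = params$t_end,
                       snapshot_every = params$snapshot_every)))

  prof <- longitudinal_profile(hist)
  stats <- dispersion_stats(prof)
  kH <- hydrodynamic_diffusivity(stats)
  metrics <- cbind(stats, kappa_H = kH$kappa_H)
  write_metrics_csv(metrics, file.path(outdir, "metrics.csv"))
  utils::write.csv(data.frame(x_cm = prof$x,
                              C_final = prof$C[, ncol(prof$C)]),
                   file.path(outdir, "profile_final.csv"), row.names = FALSE)

  files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  checks <- as.list(tools::md5sum(sort(files)))
  names(checks) <- substring(names(checks), nchar(outdir) + 2)
  manifest <- list(
    scenario = cfg$scenario, variant = hist$variant,
    package_version = as.character(utils::packageVersion("csfdrift")),
    stroke_volume_mL = sc$V_s, epsilon = sc$epsilon,
    controller = ctrl_sum, drift = drift_info,
    transport = list(scheme = hist$params$scheme,
                     dt_requested_s = hist$params$dt_requested,
                     dt_used_s = hist$params$dt_used,
                     kappa_cm2_s = hist$params$kappa_cm2s,
                     mass_initial = hist$mass[1],
                     mass_final = utils::tail(hist$mass, 1),
                     outflow_final = utils::tail(hist$outflow, 1),
                     ledger_error = hist$ledger_error),
    results = list(sigma_end_cm = sqrt(utils::tail(stats$sigma2, 1)),
                   xbar_end_cm = utils::tail(stats$xbar, 1),
                   kappa_H_end_cm2_s = utils::tail(kH$kappa_H, 1)),
    checksums = checks)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, history = hist, metrics = metrics,
                 field = field, mean_field = mean_field))
}

validate_config <- function(config) {
  need <- c("geometry", "waveform", "fluid", "transport", "variant", "output")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("config is missing blocks: ", paste(miss, collapse = ", "))
  variant <- match.arg(config$variant,
                       c("lagrangian", "eulerian_mean", "diffusionless",
                         "full_dns"))
  config$variant <- variant
  g <- config$geometry
  config$geometry <- list(obstructed = isTRUE(g$obstructed),
                          nx = as.integer(g$nx %||% 64L),
                          ny = as.integer(g$ny %||% 64L),
                          n_segments = as.integer(g$n_segments %||% 5L))
  if (identical(config$waveform$type, "csv")) {
    if (!file.exists(config$waveform$csv))
      stop("waveform CSV does not exist: ", config$waveform$csv)
  }
  config$scenario <- config$scenario %||% "unnamed"
  config$fluid <- list(rho_kg_m3 = config$fluid$rho_kg_m3 %||% 1000,
                       nu_m2_s = config$fluid$nu_m2_s %||% 2e-6,
                       period_s = config$fluid$period_s %||% 1)
  config
}

config_waveform <- function(cfg) {
  w <- cfg$waveform
  if (identical(w$type, "csv")) return(read_waveform_csv(w$csv))
  Vs <- w$stroke_volume_mL %||% 0.823
  scale <- w$scale %||% 1
  harmonic_waveform(pi * Vs / cfg$fluid$period_s * scale, cfg$fluid$period_s)
}

#' Write ready-to-run fixture configurations and oracle fields
#'
#' @param kind one of `"manufactured"`, `"womersley"`, `"channel_patent"`,
#'   `"channel_obstructed"`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
make_fixtures <- function(kind = c("manufactured", "womersley",
                                   "channel_patent", "channel_obstructed"),
                          dir) {
  kind <- match.arg(kind)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  waveform_block <- list(type = "sine", stroke_volume_mL = 0.823)
  if (kind == "manufactured") {
    g <- structured_grid(96, 8, dx = 1 / 96, dy = 0.025, x0 = 0, y0 = -0.1,
                         periodic_x = TRUE, wall_y = FALSE)
    f <- make_manufactured_wave_flow(g, amplitude = 0.003, wavenumber = 2 * pi,
                                     period = 1, kind = "traveling")
    write_field_series(f, file.path(dir, "manufactured_series"))
    jsonlite::write_json(f$metadata[c("kind", "U", "k", "omega", "epsilon",
                                      "drift_u", "drift_v")],
                         file.path(dir, "manufactured_drift.json"),
                         auto_unbox = TRUE, digits = NA)
    paths <- c(paths, file.path(dir, "manufactured_series"),
               file.path(dir, "manufactured_drift.json"))
  } else if (kind == "womersley") {
    config <- list(
      scenario = "womersley_oracle",
      geometry = list(obstructed = FALSE, nx = 8L, ny = 64L, n_segments = 1L),
      waveform = list(type = "sine", stroke_volume_mL = 1 / pi),
      fluid = list(rho_kg_m3 = 1000, nu_m2_s = 5e-6, period_s = 1),
      transport = list(schmidt = 1000, t_end_s = 10, dt_s = 0.01,
                       scheme = "limited_upwind_3rd"),
      variant = "full_dns", output = file.path(dir, "womersley_out"))
    p <- file.path(dir, "womersley.yaml")
    write_config(config, p)
    paths <- c(paths, p)
  } else {
    obstructed <- kind == "channel_obstructed"
    config <- list(
      scenario = kind,
      geometry = list(obstructed = obstructed, nx = 64L, ny = 64L,
                      n_segments = 5L),
      waveform = waveform_block,
      fluid = list(rho_kg_m3 = 1000, nu_m2_s = 2e-6, period_s = 1),
      transport = list(schmidt = 1000, t_end_s = 60, dt_s = 0.01,
                       scheme = "limited_upwind_3rd"),
      variant = "full_dns", output = file.path(dir, paste0(kind, "_out")))
    p <- file.path(dir, paste0(kind, ".yaml"))
    write_config(config, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
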