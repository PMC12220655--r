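#' Desk-scale cervical-channel scenario
#'
#' Builds the canonical two-dimensional analog of the cervical spinal-canal
#' study: one vertebral segment is a plane channel of length 1.6 cm (the
#' C3-C4 intervertebral distance) and height 1.172 cm (the mean open
#' cross-sectional area at unit depth, so the segment fluid volume is
#' 1.875 mL), replicated five times for transport between the rostral and
#' caudal ends at x = 1.6 cm and x = 9.6 cm. The flow is driven by a
#' single-harmonic flow-rate waveform whose stroke volume is the
#' physiological 0.823 mL, giving the dimensionless stroke length
#' epsilon = V_s / V_segment = 0.439. In the obstructed variant two
#' wall-mounted wedge obstacles per segment (axial extent 0.5 cm, height
#' 0.66 cm, spacing 0.8 cm) stand in for nerve rootlets and denticulate
#' ligaments. Their axial asymmetry mirrors the oblique, caudally slanted
#' exit of the rootlets from the cord, and their size and spacing are
#' comparable to the stroke length (V_s / A = 0.70 cm) — the regime where
#' the asymptotic drift formula breaks down and trajectory-based drift is
#' required. The wedges break the axial mirror symmetry of the channel, so
#' the steady Lagrangian drift develops intervertebral connecting pathways
#' (a substantial fraction of drift trajectories traverse a full segment
#' within about twenty cycles) instead of closed recirculation cells; this
#' drift topology, not any transport outcome, fixed the obstacle design.
#'
#' The working fluid has the density of cerebrospinal fluid and a kinematic
#' viscosity of 2e-6 m^2/s, chosen so that the oscillatory (Stokes) boundary
#' layer spans several cells of the default 64-cell transverse grid while
#' the Womersley number (about 10) stays in the physiological high-frequency
#' regime; the solute Schmidt number is kept at the drug-like value 1000.
#'
#' @param obstructed include the obstacle array (`TRUE`) or the patent
#'   channel (`FALSE`).
#' @param nx,ny cells per segment.
#' @param n_segments axial replicas for transport.
#' @param stroke_volume target stroke volume in mL.
#' @param period cardiac period in s.
#' @param nu kinematic viscosity in m^2/s.
#' @param schmidt Schmidt number `nu / kappa`.
#' @param t_end transport end time in s (default 60 cycles).
#' @param scale_Q optional factor applied to the flow-rate waveform (e.g.
#'   0.00763 for the small-stroke validation of the asymptotic drift).
#' @return a list with components `grid` (single segment, axially periodic),
#'   `waveform`, `fluid`, `transport` (a [transport_params()]), `V_seg`,
#'   `V_s`, `epsilon`, `bolus_center`, `bolus_width`.
#' @export
channel_scenario <- function(obstructed = TRUE, nx = 64L, ny = 64L,
                             n_segments = 5L, stroke_volume = 0.823,
                             period = 1, nu = 2e-6, schmidt = 1000,
                             t_end = 60, scale_Q = 1) {
  L_seg <- 1.6
  height <- 1.172
  dx <- L_seg / nx; dy <- height / ny
  mask <- matrix(FALSE, nx, ny)
  if (obstructed) {
    xl <- ((seq_len(nx) - 0.5) * dx) %% 0.8        # local coordinate in cm
    yc <- (seq_len(ny) - 0.5) * dy
    # caudally slanted wedges on the pia-side wall: two per segment
    mask <- outer(xl, yc, function(a, b)
      (a >= 0.1 & a < 0.6) & (b < 0.66 * (a - 0.1) / 0.5))
  }
  grid <- structured_grid(nx, ny, dx, dy, x0 = 1.6, y0 = 0, mask = mask,
                          periodic_x = TRUE, wall_y = TRUE,
                          n_segments = n_segments)
  Q0 <- pi * stroke_volume / period * scale_Q
  waveform <- harmonic_waveform(Q0, period)
  fluid <- fluid_params(rho = 1000, nu = nu, period = period)
  kappa <- nu / schmidt
  V_seg <- L_seg * height
  se <- stroke_volume_and_epsilon(waveform, V_seg)
  list(grid = grid, waveform = waveform, fluid = fluid,
       transport = transport_params(kappa = kappa, dt = 0.01,
                                    scheme = "limited_upwind_3rd",
                                    t_end = t_end, snapshot_every = 1),
       V_seg = V_seg, V_s = se$V_s, epsilon = se$epsilon,
       bolus_center = 5.6, bolus_width = 0.5)
}

#' Run the three-step dispersion study on a scenario
#'
#' Executes the full pipeline at the scenario's study conditions:
#' (1) the oscillatory flow solve with the flow-rate controller;
#' (2) the trajectory-based mean Lagrangian velocity (20 seeding phases,
#'     seeds at every fluid-cell center) with the Helmholtz projection, plus
#'     the cycle-averaged Eulerian field;
#' (3) transport: the full oscillatory benchmark solve, the reduced solve
#'     driven by the solenoidal Lagrangian drift, the Eulerian-mean
#'     comparison solve, and optionally the diffusionless benchmark.
#'
#' @param scenario a [channel_scenario()] list.
#' @param variants character vector among `"full_dns"`,
#'   `"reduced_lagrangian"`, `"comparison_eulerian"`, `"diffusionless_dns"`.
#' @param flow optional precomputed result of [solve_oscillatory_channel()]
#'   (to share the flow solve across studies).
#' @param verbose print stage progress.
#' @return a list with the flow result, drift fields (`raw`, `solenoidal`,
#'   `eulerian`, projection diagnostics), per-variant concentration
#'   histories, and per-variant dispersion metrics (`sigma` at `t_end`,
#'   `kappa_H` trace).
#' @export
dispersion_study <- function(scenario,
                             variants = c("full_dns", "reduced_lagrangian",
                                          "comparison_eulerian"),
                             flow = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(flow)) {
    say("flow solve (%d x %d)...", scenario$grid$nx, scenario$grid$ny)
    flow <- solve_oscillatory_channel(scenario$grid, scenario$waveform,
                                      scenario$fluid, verbose = verbose)
  }
  field <- flow$field
  say("trajectory-based mean Lagrangian velocity...")
  traj <- lagrangian_mean_from_trajectories(field)
  raw <- scatter_to_grid(traj$samples, scenario$grid)
  proj <- project_solenoidal(raw)
  eulerian <- cycle_average(field)
  gt <- tile_grid(scenario$grid)
  bolus <- gaussian_bolus(gt, scenario$bolus_center, scenario$bolus_width)
  histories <- list()
  for (v in variants) {
    say("transport variant %s...", v)
    histories[[v]] <- switch(
      v,
      full_dns = integrate_full_transport(field, bolus, scenario$transport),
      diffusionless_dns = {
        p0 <- scenario$transport
        pd <- transport_params(kappa = 0, dt = p0$dt, scheme = p0$scheme,
                               t_end = p0$t_end,
                               snapshot_every = p0$snapshot_every)
        h <- integrate_full_transport(field, bolus, pd)
        h$variant <- "diffusionless_dns"
        h
      },
      reduced_lagrangian = integrate_reduced_transport(
        proj$field, bolus,
        transport_params(kappa = scenario$transport$kappa, dt = 1,
                         scheme = "upwind_2nd",
                         t_end = scenario$transport$t_end,
                         snapshot_every = scenario$transport$snapshot_every)),
      comparison_eulerian = integrate_reduced_transport(
        eulerian, bolus,
        transport_params(kappa = scenario$transport$kappa, dt = 1,
                         scheme = "upwind_2nd",
                         t_end = scenario$transport$t_end,
                         snapshot_every = scenario$transport$snapshot_every)),
      stop(sprintf("unknown variant '%s'", v)))
  }
  metrics <- lapply(histories, function(h) {
    pr <- longitudinal_profile(h)
    ds <- dispersion_stats(pr)
    list(profile = pr, stats = ds, kappa_H = hydrodynamic_diffusivity(ds),
         sigma_end = sqrt(utils::tail(ds$sigma2, 1)),
         ledger_error = h$ledger_error)
  })
  list(scenario = scenario, flow = flow, drift = list(
    raw = raw, solenoidal = proj$field, potential = proj$potential,
    projection_diagnostics = proj$diagnostics, eulerian = eulerian,
    particles = traj$particles),
    histories = histories, metrics = metrics)
}
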