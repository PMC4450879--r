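#' Linear-region Young's modulus of a stress-strain curve
#'
#' Least-squares slope of the loading branch over the window where stress
#' lies between `window[1]` and `window[2]` of the peak stress (default
#' 60-90%), the package's operational definition of the "linear region" of
#' a tensile test.
#'
#' @param strain Strain samples (dimensionless, monotone on the loading
#'   branch).
#' @param stress Stress samples (MPa).
#' @param window Lower/upper stress fractions of the peak delimiting the
#'   fitting window.
#' @return Modulus (MPa).
#' @export
compute_modulus <- function(strain, stress, window = c(0.6, 0.9)) {
  stopifnot(length(strain) == length(stress), length(window) == 2,
            window[1] < window[2])
  ipk <- which.max(stress)
  s <- stress[1:ipk]; e <- strain[1:ipk]
  pk <- stress[ipk]
  w <- which(s >= window[1] * pk & s <= window[2] * pk)
  if (length(w) < 3)
    stop("too few points (", length(w), ") in the ", window[1] * 100, "-",
         window[2] * 100, "% of peak-stress window; refine the curve")
  unname(coef(lm(s[w] ~ e[w]))[2])
}

#' Log-log relaxation rate of a stress-decay curve
#'
#' Slope of `log10(stress)` versus `log10(time since hold start)` over the
#' fitting window (default 1-100 s of the hold), returned as a positive
#' decay rate (decades of stress per decade of time).
#'
#' @param t_hold Time since the start of the hold (s).
#' @param stress Stress during the hold (MPa), positive.
#' @param window Time window (s) for the fit.
#' @return Positive relaxation rate (dimensionless).
#' @export
relaxation_rate <- function(t_hold, stress, window = c(1, 100)) {
  w <- which(t_hold >= window[1] & t_hold <= window[2] & stress > 0)
  if (length(w) < 3) stop("too few samples in the relaxation-rate window")
  -unname(coef(lm(log10(stress[w]) ~ log10(t_hold[w])))[2])
}

# time grid for a ramp of given duration (n steps, >= 2 rows incl. t = 0)
ramp_grid <- function(duration, n = 80) {
  seq(0, duration, length.out = max(3, n + 1))
}

# geometric hold grid after t0: steps grow by `grow` from dt0 up to dt_max
hold_grid <- function(t0, hold, dt0 = 0.2, grow = 1.25, dt_max = 20) {
  tt <- t0
  dt <- dt0
  while (tail(tt, 1) < t0 + hold) {
    tt <- c(tt, min(tail(tt, 1) + dt, t0 + hold))
    dt <- min(dt * grow, dt_max)
  }
  tt
}

#' Strain-stiffening test: displacement ramps at several rates
#'
#' Runs displacement-controlled tensile ramps at the requested rates, all to
#' the same displacement amplitude. By default the amplitude is the
#' displacement at which the 0.1 mm/s ramp reaches the 20 N cycle peak on
#' the given geometry (determined by within-step bisection), emulating a
#' ramp "to the first load peak". Stress is nominal (force / reference
#' area), strain is engineering (displacement / length).
#'
#' @param params A [material_params()] object.
#' @param geom A [tendon_geometry()].
#' @param rates Displacement rates (mm/s).
#' @param amplitude Displacement amplitude (mm); `NULL` to determine it from
#'   `F_peak` at `reference_rate`.
#' @param F_peak Target peak force defining the amplitude (N).
#' @param reference_rate Rate (mm/s) at which the amplitude is determined.
#' @param mesh Optional prebuilt mesh (default 4 x 16 on `geom`).
#' @param settings A [solver_settings()] object.
#' @param n_steps Number of time steps per ramp.
#' @param window Stress window for [compute_modulus()].
#' @return A list of class `strain_stiffening` with `curves` (named list of
#'   data frames `t`, `strain`, `stress`), `moduli` (MPa, named by rate) and
#'   `amplitude` (mm).
#' @export
strain_stiffening <- function(params, geom = average_geometry(),
                              rates = c(0.05, 0.1, 0.2, 0.4, 0.6, 1.0),
                              amplitude = NULL, F_peak = 20,
                              reference_rate = 0.1, mesh = NULL,
                              settings = solver_settings(), n_steps = 80,
                              window = c(0.6, 0.9)) {
  if (is.null(mesh)) mesh <- build_mesh(geom)
  if (is.null(amplitude)) {
    cyc <- run_cyclic(params, geom, mesh = mesh, rate = reference_rate,
                      F_max = F_peak, F_min = 1, n_cycles = 1,
                      settings = settings, stop_after_peak = TRUE)
    amplitude <- cyc$U_peak
  }
  curves <- list()
  moduli <- numeric(0)
  for (rate in rates) {
    tt <- ramp_grid(amplitude / rate, n_steps)
    prot <- data.frame(t = tt, U = rate * tt)
    resp <- tryCatch(
      run_protocol(prot, geom, params, mesh = mesh, settings = settings),
      error = function(e) stop("strain-stiffening run failed at rate ", rate,
                               " mm/s: ", conditionMessage(e)))
    cv <- data.frame(t = resp$trace$t, strain = resp$trace$U / geom$L,
                     stress = resp$trace$F / geom$A)
    key <- sprintf("%g", rate)
    curves[[key]] <- cv
    moduli[key] <- compute_modulus(cv$strain, cv$stress, window)
  }
  structure(list(curves = curves, moduli = moduli, amplitude = amplitude,
                 rates = rates), class = "strain_stiffening")
}

#' Stress-relaxation test: ramp-and-hold at several strain levels
#'
#' Applies each target strain as a displacement ramp at `rate`, then holds
#' the displacement for `hold` seconds on a geometrically growing time grid.
#' Reports the stress history and the log-log relaxation rate per strain.
#'
#' @inheritParams strain_stiffening
#' @param strains Target strains in percent of the length.
#' @param rate Ramp rate (mm/s).
#' @param hold Hold duration (s).
#' @param fibre_axis `"axial"` or `"radial"` (the latter gives the
#'   horizontal-fibre control test).
#' @param rate_window Hold-time window (s) for [relaxation_rate()].
#' @param record `"none"` or `"probe"` Gauss-point recording.
#' @return A list of class `stress_relaxation` with `curves` (per strain:
#'   `t`, `t_hold`, `strain`, `stress` in MPa), `rates` (relaxation rate per
#'   strain) and `fields` (probe recordings when requested).
#' @export
stress_relaxation <- function(params, geom = average_geometry(),
                              strains = c(2, 4, 6, 8, 10), rate = 0.1,
                              hold = 300, mesh = NULL,
                              settings = solver_settings(),
                              fibre_axis = "axial", n_steps = 60,
                              rate_window = c(1, 100),
                              record = c("none", "probe")) {
  record <- match.arg(record)
  if (is.null(mesh)) mesh <- build_mesh(geom)
  curves <- list(); rr <- numeric(0); flds <- list()
  for (s in strains) {
    U <- s / 100 * geom$L
    t_ramp <- U / rate
    tt <- c(ramp_grid(t_ramp, n_steps), hold_grid(t_ramp, hold)[-1])
    prot <- data.frame(t = tt, U = pmin(rate * tt, U))
    resp <- run_protocol(prot, geom, params, mesh = mesh,
                         settings = settings, fibre_axis = fibre_axis,
                         record = record)
    key <- sprintf("%g", s)
    curves[[key]] <- data.frame(
      t = tt, t_hold = tt - t_ramp, strain = prot$U / geom$L,
      stress = resp$trace$F / geom$A)
    hold_part <- curves[[key]][curves[[key]]$t_hold > 0, ]
    rr[key] <- relaxation_rate(hold_part$t_hold, hold_part$stress, rate_window)
    if (record == "probe") flds[[key]] <- resp$fields
  }
  structure(list(curves = curves, rates = rr, strains = strains,
                 fields = flds), class = "stress_relaxation")
}

#' Creep test: constant-traction hold and partial recovery
#'
#' Applies each axial traction with a short loading ramp, holds it for
#' `hold` seconds, then drops to `recovery_load` for another `hold` seconds.
#' Strain is the mean axial displacement of the top edge over the length.
#'
#' @inheritParams strain_stiffening
#' @param stresses Applied tractions (MPa).
#' @param hold Hold duration per phase (s).
#' @param recovery_load Traction during the recovery phase (MPa).
#' @param t_ramp Duration of each loading/unloading ramp (s).
#' @return A list of class `creep_test` with `curves` (per stress: `t`,
#'   `sigma`, `strain`).
#' @export
creep_test <- function(params, geom = average_geometry(),
                       stresses = c(1, 2, 3), hold = 500,
                       recovery_load = 0.2, t_ramp = 1, mesh = NULL,
                       settings = solver_settings()) {
  if (is.null(mesh)) mesh <- build_mesh(geom)
  curves <- list()
  for (s0 in stresses) {
    t1 <- c(ramp_grid(t_ramp, 10), hold_grid(t_ramp, hold)[-1])
    sg1 <- pmin(t1 / t_ramp, 1) * s0
    t2a <- tail(t1, 1) + ramp_grid(t_ramp, 10)[-1]
    sg2a <- s0 + (recovery_load - s0) * (t2a - tail(t1, 1)) / t_ramp
    t2b <- hold_grid(tail(t2a, 1), hold)[-1]
    tt <- c(t1, t2a, t2b)
    sg <- c(sg1, sg2a, rep(recovery_load, length(t2b)))
    prot <- data.frame(t = tt, sigma = sg)
    resp <- run_protocol(prot, geom, params, mesh = mesh, settings = settings)
    curves[[sprintf("%g", s0)]] <- data.frame(
      t = tt, sigma = sg, strain = resp$trace$U / geom$L)
  }
  structure(list(curves = curves, stresses = stresses, hold = hold,
                 recovery_load = recovery_load), class = "creep_test")
}

#' Horizontal-fibre control test
#'
#' Re-runs the stress-relaxation protocol with the collagen fibres oriented
#' radially so that axial stretch never puts them in tension: the response
#' is carried entirely by the non-fibrillar matrix and the fluid. Fibre
#' stresses vanish identically; the biphasic matrix still relaxes and the
#' pore pressure is negative under stretch.
#'
#' @inheritParams stress_relaxation
#' @return A `stress_relaxation` object (with probe fields recorded).
#' @export
horizontal_fibre_test <- function(params, geom = average_geometry(),
                                  strains = 4, rate = 0.1, hold = 300,
                                  mesh = NULL, settings = solver_settings(),
                                  n_steps = 60) {
  stress_relaxation(params, geom, strains = strains, rate = rate,
                    hold = hold, mesh = mesh, settings = settings,
                    fibre_axis = "radial", n_steps = n_steps,
                    record = "probe")
}

#' Displacement-controlled cyclic loading between force thresholds
#'
#' Drives the model at a constant displacement rate, reversing direction
#' when the computed reaction force crosses `F_max` (on loading) or `F_min`
#' (on unloading). The reversal point is located by bisection on the
#' sub-step so that each peak force matches the threshold to `tol_F`. This
#' reproduces the structure of the cyclic tensile experiment (1-20 N at
#' 0.1 mm/s).
#'
#' @inheritParams strain_stiffening
#' @param rate Displacement rate magnitude (mm/s).
#' @param F_max,F_min Reversal force thresholds (N).
#' @param n_cycles Number of load cycles (a cycle = reach `F_max`, return
#'   to `F_min`).
#' @param dt Nominal time step (s).
#' @param tol_F Bisection tolerance on the reversal force (N).
#' @param U_bound Abort if the displacement exceeds this bound before
#'   `F_max` is reached (default half the length).
#' @param record `"none"` or `"probe"`.
#' @param stop_after_peak Stop at the first `F_max` crossing (used to find
#'   the peak displacement).
#' @param fibre_axis Fibre orientation.
#' @param label Specimen label used in error messages.
#' @return A list with `trace` (data frame `t`, `U`, `F`), `U_peak` (mm,
#'   first `F_max` crossing), `peaks`/`valleys` (indices of reversals),
#'   and `fields` (per-step probe matrices when recorded).
#' @export
run_cyclic <- function(params, geom = average_geometry(), mesh = NULL,
                       rate = 0.1, F_max = 20, F_min = 1, n_cycles = 1,
                       dt = 0.25, settings = solver_settings(),
                       tol_F = 1e-3, U_bound = NULL,
                       record = c("none", "probe"), stop_after_peak = FALSE,
                       fibre_axis = "axial", probe_element = NULL,
                       label = "specimen") {
  record <- match.arg(record)
  if (is.null(mesh)) mesh <- build_mesh(geom)
  if (is.null(U_bound)) U_bound <- 0.5 * geom$L
  if (is.null(probe_element)) probe_element <- probe_element_index(mesh)
  bc <- boundary_spec(mesh, control = "displacement")
  fmode <- fibre_mode_code(fibre_axis)
  gp_rows <- (4L * (probe_element - 1L) + 1L):(4L * probe_element)
  state <- field_state(mesh)
  attr(state, "control") <- list(U = 0)
  tt <- 0; UU <- 0; FF <- 0
  fields <- if (record == "probe") list(NULL) else NULL
  dir <- 1
  U <- 0
  cycles_done <- 0
  peaks <- integer(0); valleys <- integer(0)
  U_peak <- NA_real_
  step_to <- function(st, U_new, dtt) {
    .advance(st, mesh, bc, params, attr(st, "control"), list(U = U_new),
             dtt, settings, fmode, 0L)
  }
  repeat {
    U_new <- U + dir * rate * dt
    st_new <- step_to(state, U_new, dt)
    F_new <- attr(st_new, "force")
    crossed <- (dir > 0 && F_new >= F_max) || (dir < 0 && F_new <= F_min)
    if (crossed) {
      thr <- if (dir > 0) F_max else F_min
      lo <- 0; hi <- dt
      st_hit <- st_new; F_hit <- F_new
      for (i in 1:40) {
        if (abs(F_hit - thr) <= tol_F) break
        mid <- (lo + hi) / 2
        st_mid <- step_to(state, U + dir * rate * mid, mid)
        F_mid <- attr(st_mid, "force")
        if ((dir > 0) == (F_mid >= thr)) {
          hi <- mid; st_hit <- st_mid; F_hit <- F_mid
        } else lo <- mid
      }
      st_new <- st_hit
      F_new <- F_hit
    }
    state <- st_new
    U <- attr(state, "control")$U
    tt <- c(tt, state$t); UU <- c(UU, U); FF <- c(FF, F_new)
    if (record == "probe")
      fields[[length(tt)]] <- attr(state, "gp")[gp_rows, , drop = FALSE]
    if (crossed && dir > 0) {
      peaks <- c(peaks, length(tt))
      if (is.na(U_peak)) U_peak <- U
      if (stop_after_peak) break
      dir <- -1
    } else if (crossed && dir < 0) {
      valleys <- c(valleys, length(tt))
      cycles_done <- cycles_done + 1
      if (cycles_done >= n_cycles) break
      dir <- 1
    }
    if (U > U_bound)
      stop("force never reached ", F_max, " N within the displacement bound ",
           "for ", label, " (U > ", U_bound, " mm)")
    if (length(tt) > 100000) stop("cyclic run exceeded the step limit")
  }
  list(trace = data.frame(t = tt, U = UU, F = FF), U_peak = U_peak,
       peaks = peaks, valleys = valleys, fields = fields,
       probe_element = probe_element, mesh = mesh)
}

#' Constituent stress decomposition and fluid velocity over one load cycle
#'
#' Runs one displacement-controlled load cycle (rate 0.1 mm/s, reversing at
#' the 20 N peak and the 1 N valley) and evaluates, at the probe element
#' (outer surface, mid-height): the percentage of the peak total axial
#' Cauchy stress carried by the non-fibrillar matrix, and the peak Darcy
#' flux magnitude over the cycle.
#'
#' @inheritParams run_cyclic
#' @return A list of class `cycle_decomposition` with `matrix_share_pct`,
#'   `fluid_velocity_um_s`, `trace`, and the per-step probe `fields`.
#' @export
cycle_decomposition <- function(params, geom = average_geometry(),
                                mesh = NULL, rate = 0.1, F_max = 20,
                                F_min = 1, dt = 0.25,
                                settings = solver_settings()) {
  cyc <- run_cyclic(params, geom, mesh = mesh, rate = rate, F_max = F_max,
                    F_min = F_min, n_cycles = 1, dt = dt,
                    settings = settings, record = "probe")
  ipk <- cyc$peaks[1]
  gp_pk <- cyc$fields[[ipk]]
  sm <- mean(gp_pk[, "sm_zz"])
  tot <- mean(gp_pk[, "sf_zz"] + gp_pk[, "sm_zz"] - gp_pk[, "p"])
  share <- 100 * sm / tot
  wmax <- 0
  for (f in cyc$fields) {
    if (is.null(f)) next
    wmax <- max(wmax, sqrt(f[, "wr"]^2 + f[, "wz"]^2))
  }
  structure(list(matrix_share_pct = share,
                 fluid_velocity_um_s = 1000 * wmax,
                 trace = cyc$trace, fields = cyc$fields,
                 peak_index = ipk, probe_element = cyc$probe_element),
            class = "cycle_decomposition")
}
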