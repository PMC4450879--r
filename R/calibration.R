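#' Segment a protocol into monotonic load steps
#'
#' Splits a displacement-controlled protocol at the reversals of the
#' prescribed displacement. A hysteresis guard suppresses spurious
#' reversals from measurement jitter: a direction change is only accepted
#' once the displacement has moved away from the running extremum by more
#' than `guard` times the displacement range. Three full load cycles yield
#' six segments (three loading, three unloading ramps).
#'
#' @param protocol Data frame with columns `t` and `U` (and usually
#'   `F_exp`).
#' @param guard Hysteresis guard as a fraction of the displacement range.
#' @param expect Expected number of segments (`NA` to skip the check).
#' @return The protocol with a `segments` attribute (list of index
#'   vectors partitioning the rows).
#' @export
segment_protocol <- function(protocol, guard = 0.02, expect = NA) {
  stopifnot(all(c("t", "U") %in% names(protocol)))
  U <- protocol$U
  n <- length(U)
  if (n < 3) stop("protocol too short to segment")
  rng <- diff(range(U))
  if (rng <= 0) stop("displacement is constant; nothing to segment")
  eps <- guard * rng
  breaks <- integer(0)
  dir <- 0
  ext <- U[1]; ext_i <- 1L
  for (i in 2:n) {
    if (dir == 0) {
      if (U[i] > ext + eps) dir <- 1
      else if (U[i] < ext - eps) dir <- -1
      if (U[i] * dir > ext * dir) { ext <- U[i]; ext_i <- i }
      next
    }
    if ((dir > 0 && U[i] > ext) || (dir < 0 && U[i] < ext)) {
      ext <- U[i]; ext_i <- i
    } else if ((dir > 0 && U[i] < ext - eps) ||
               (dir < 0 && U[i] > ext + eps)) {
      breaks <- c(breaks, ext_i)
      dir <- -dir
      ext <- U[i]; ext_i <- i
    }
  }
  bounds <- c(0L, breaks, n)
  segs <- list()
  for (k in seq_len(length(bounds) - 1L))
    segs[[k]] <- (bounds[k] + 1L):bounds[k + 1L]
  if (!is.na(expect) && length(segs) != expect)
    stop("detected ", length(segs), " monotonic segments, expected ", expect,
         "; reversal times: ",
         paste(signif(protocol$t[breaks], 6), collapse = ", "))
  attr(protocol, "segments") <- segs
  protocol
}

#' Calibration objective: segment-wise mean squared force error
#'
#' The misfit between the model reaction force and the measured force,
#' averaged per monotonic load step and then across the (by default six)
#' steps: `f = (1/6) sum_i (1/n_i) sum_j (F_mod - F_exp)^2` (N^2).
#'
#' @param F_mod Model force at the protocol's time samples (N).
#' @param protocol A protocol with `F_exp` and a `segments` attribute (see
#'   [segment_protocol()]).
#' @param expect_segments Required number of segments (default 6; pass the
#'   actual count to override).
#' @return A list with `f` (N^2), `RMS = sqrt(f)` (N) and `per_segment`.
#' @export
calibration_objective <- function(F_mod, protocol, expect_segments = 6) {
  segs <- attr(protocol, "segments")
  if (is.null(segs)) stop("protocol has no segments; run segment_protocol()")
  if (length(F_mod) != nrow(protocol))
    stop("F_mod must be sampled at the protocol time samples")
  if (!is.na(expect_segments) && length(segs) != expect_segments)
    stop("protocol has ", length(segs), " segments, expected ",
         expect_segments, " (override via expect_segments)")
  per <- vapply(segs, function(idx)
    mean((F_mod[idx] - protocol$F_exp[idx])^2), numeric(1))
  f <- mean(per)
  list(f = f, RMS = sqrt(f), per_segment = per)
}

#' Average several cyclic protocols in the phase domain
#'
#' Each requested load cycle of each protocol is interpolated onto a
#' uniform phase grid over `[0, 2 pi)`; displacement and force are averaged
#' pointwise across specimens and cycles, and the mean cycle is mapped back
#' to the time domain using the mean cycle duration. The averaged cycle is
#' tiled to the requested number of cycles so that a three-cycle average
#' again yields six monotonic segments.
#'
#' @param protocols List of protocols (data frames `t`, `U`, `F_exp`), each
#'   segmentable into full cycles.
#' @param cycles Integer vector of cycle indices to use (default `1:3`).
#' @param n_phase Phase samples per cycle (default 256).
#' @param guard Hysteresis guard passed to [segment_protocol()].
#' @return An averaged protocol (data frame `t`, `U`, `F_exp`) with a
#'   `segments` attribute.
#' @export
average_protocol <- function(protocols, cycles = 1:3, n_phase = 256,
                             guard = 0.02) {
  if (!length(protocols)) stop("no protocols given")
  phase <- seq(0, 2 * pi, length.out = n_phase + 1)[1:n_phase]
  Us <- NULL; Fs <- NULL; durs <- numeric(0)
  for (sp in seq_along(protocols)) {
    pr <- protocols[[sp]]
    pr <- segment_protocol(pr, guard = guard)
    segs <- attr(pr, "segments")
    # a cycle = an up segment followed by a down segment; segment 1 starts
    # the first cycle
    n_cyc <- length(segs) %/% 2
    for (cy in cycles) {
      if (cy > n_cyc)
        stop("protocol ", sp, " has only ", n_cyc,
             " full cycles; cycle ", cy, " requested")
      s1 <- segs[[2 * cy - 1]]
      # anchor phase 0 at the preceding reversal sample when one exists
      idx <- c(if (s1[1] > 1L) s1[1] - 1L, s1, segs[[2 * cy]])
      tt <- pr$t[idx]
      ph <- (tt - tt[1]) / (tt[length(tt)] - tt[1]) * 2 * pi
      Us <- rbind(Us, approx(ph, pr$U[idx], xout = phase, rule = 2)$y)
      Fs <- rbind(Fs, approx(ph, pr$F_exp[idx], xout = phase, rule = 2)$y)
      durs <- c(durs, tt[length(tt)] - tt[1])
    }
  }
  Um <- colMeans(Us); Fm <- colMeans(Fs); Tm <- mean(durs)
  t1 <- phase / (2 * pi) * Tm
  n_cycles_out <- length(cycles)
  tt <- numeric(0); UU <- numeric(0); FF <- numeric(0)
  for (k in seq_len(n_cycles_out)) {
    tt <- c(tt, (k - 1) * Tm + t1)
    UU <- c(UU, Um)
    FF <- c(FF, Fm)
  }
  out <- data.frame(t = tt, U = UU, F_exp = FF)
  segment_protocol(out, guard = guard)
}

#' Define an inverse-identification problem
#'
#' Bundles a segmented protocol, the specimen geometry, the set of free
#' parameters, the initial guess and the convergence tolerance. Positive
#' parameters are optimised on a log scale and the matrix Poisson's ratio
#' through a scaled logit onto (0, 0.499), so any simplex point maps to an
#' admissible parameter set.
#'
#' @param protocol A protocol with `F_exp` and segments.
#' @param geom A [tendon_geometry()].
#' @param init Initial [material_params()].
#' @param free Names of the parameters to optimise (default the nine
#'   constitutive constants).
#' @param tol Convergence threshold on the change of the objective between
#'   optimiser sweeps (N^2), default 1e-5.
#' @param max_evals Cap on objective evaluations.
#' @return An object of class `calibration_problem`.
#' @export
calibration_problem <- function(protocol, geom, init,
                                free = c("E1", "E2", "k1", "k2", "eta",
                                         "k0", "Mk", "Em", "num"),
                                tol = 1e-5, max_evals = 4000) {
  if (is.null(attr(protocol, "segments")))
    stop("protocol must be segmented (see segment_protocol)")
  validate_params(init)
  bad <- setdiff(free, c("E1", "E2", "k1", "k2", "eta", "k0", "Mk", "Em", "num"))
  if (length(bad)) stop("unknown free parameter(s): ", paste(bad, collapse = ", "))
  structure(list(protocol = protocol, geom = geom, init = init, free = free,
                 tol = tol, max_evals = max_evals),
            class = "calibration_problem")
}

num_cap <- 0.499

param_transform <- function(params, free) {
  th <- numeric(length(free))
  for (i in seq_along(free)) {
    v <- params[[free[i]]]
    th[i] <- if (free[i] == "num") stats::qlogis(v / num_cap) else log(v)
  }
  names(th) <- free
  th
}

param_untransform <- function(th, free, base) {
  p <- unclass(base)
  for (i in seq_along(free)) {
    p[[free[i]]] <- unname(if (free[i] == "num") num_cap * stats::plogis(th[i])
                           else exp(th[i]))
  }
  class(p) <- "tendon_params"
  p
}

#' Finite-element forward model for calibration
#'
#' Returns a function mapping a parameter set to the model reaction force
#' at the protocol's time samples. The solver marches on a coarsened time
#' grid (nominal step `dt`, always including the displacement reversals)
#' and the force is interpolated back onto the protocol grid.
#'
#' @param problem A [calibration_problem()].
#' @param mesh Forward-model mesh; default a coarse 2 x 8 grid, adequate
#'   for the nearly homogeneous tensile state.
#' @param dt Nominal solver step (s), or `NULL` (default) to march on the
#'   protocol's own time grid.
#' @param settings A [solver_settings()] object.
#' @return A function `params -> F_mod` (N).
#' @export
fe_forward_model <- function(problem, mesh = NULL, dt = NULL,
                             settings = solver_settings()) {
  geom <- problem$geom
  if (is.null(mesh)) mesh <- build_mesh(geom, 2, 8)
  prot <- problem$protocol
  segs <- attr(prot, "segments")
  rev_t <- prot$t[vapply(segs, function(s) s[length(s)], integer(1))]
  grid_t <- if (is.null(dt)) prot$t else
    sort(unique(c(seq(min(prot$t), max(prot$t), by = dt),
                  rev_t, max(prot$t))))
  grid_U <- approx(prot$t, prot$U, xout = grid_t, rule = 2)$y
  run_prot <- data.frame(t = grid_t, U = grid_U)
  if (abs(run_prot$U[1]) > 1e-12)
    stop("calibration protocol must start at U = 0")
  function(params) {
    resp <- run_protocol(run_prot, geom, params, mesh = mesh,
                         settings = settings)
    approx(grid_t, resp$trace$F, xout = prot$t, rule = 2)$y
  }
}

#' Fit the constitutive parameters to a force-displacement record
#'
#' Minimises the segment-wise mean-squared force error with Nelder-Mead in
#' transformed (log / logit) coordinates. The optimiser is run in sweeps;
#' convergence is declared when a sweep improves the objective by less than
#' `problem$tol` (default 1e-5). Forward-model failures at a candidate are
#' penalised with a large finite objective. Optional multi-start perturbs
#' the initial point in transformed coordinates.
#'
#' @param problem A [calibration_problem()].
#' @param forward A forward model `params -> F_mod` (see
#'   [fe_forward_model()]).
#' @param n_starts Number of starts (first start uses `problem$init`).
#' @param seed Seed for the multi-start perturbations.
#' @param start_sd Standard deviation of the transformed-coordinate
#'   perturbation for extra starts.
#' @param sweep_iters Nelder-Mead iterations per sweep.
#' @param expect_segments Passed to [calibration_objective()].
#' @param verbose Print sweep progress.
#' @return An object of class `tendon_fit`: `params_hat`, `f` (N^2),
#'   `RMS` (N), `n_evals`, `trace` (best objective per sweep), and
#'   `converged`.
#' @export
fit_calibration <- function(problem, forward = fe_forward_model(problem),
                            n_starts = 1, seed = 1, start_sd = 0.3,
                            sweep_iters = 150, expect_segments = 6,
                            verbose = FALSE) {
  stopifnot(inherits(problem, "calibration_problem"))
  free <- problem$free
  n_evals <- 0L
  fn <- function(th) {
    n_evals <<- n_evals + 1L
    p <- param_untransform(th, free, problem$init)
    F_mod <- tryCatch(forward(p), error = function(e) NULL)
    if (is.null(F_mod) || any(!is.finite(F_mod))) return(1e12)
    calibration_objective(F_mod, problem$protocol, expect_segments)$f
  }
  th0 <- param_transform(problem$init, free)
  best <- NULL
  set.seed(seed)
  starts <- list(th0)
  if (n_starts > 1)
    for (k in 2:n_starts)
      starts[[k]] <- th0 + rnorm(length(th0), 0, start_sd)
  for (st in starts) {
    par <- st
    f_prev <- fn(par)
    trace <- f_prev
    repeat {
      res <- optim(par, fn, method = "Nelder-Mead",
                   control = list(maxit = sweep_iters, reltol = 1e-12))
      trace <- c(trace, res$value)
      improved <- f_prev - res$value
      par <- res$par
      f_prev <- res$value
      if (verbose)
        message(sprintf("  sweep: f = %.6g (delta %.3g, %d evals)",
                        res$value, improved, n_evals))
      if (improved < problem$tol || n_evals >= problem$max_evals) break
    }
    cand <- list(par = par, f = f_prev, trace = trace)
    if (is.null(best) || cand$f < best$f) best <- cand
  }
  params_hat <- param_untransform(best$par, free, problem$init)
  structure(list(params_hat = params_hat, f = best$f, RMS = sqrt(best$f),
                 n_evals = n_evals, trace = best$trace,
                 converged = n_evals < problem$max_evals),
            class = "tendon_fit")
}

#' @export
print.tendon_fit <- function(x, ...) {
  cat(sprintf("Calibration fit: RMS = %.4g N (f = %.4g N^2), %d evaluations%s\n",
              x$RMS, x$f, x$n_evals,
              if (x$converged) "" else " [evaluation budget reached]"))
  print(x$params_hat)
  invisible(x)
}
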