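#' Settings for the implicit coupled solver
#'
#' @param dt Default time step (s).
#' @param newton_rtol Relative residual drop required for convergence.
#' @param atol_u Absolute tolerance on the momentum residual (N).
#' @param atol_p Absolute tolerance on the fluid-mass residual (mm^3/s).
#' @param max_newton Newton iteration cap per step.
#' @param jacobian_mode Jacobian construction; the graph-coloured
#'   finite-difference tangent (`"fd"`) is the implemented mode.
#' @param fd_h Relative finite-difference perturbation.
#' @param incr_tol Relative Newton-increment size below which the iterate is
#'   considered stationary (the residual has hit its roundoff floor).
#' @param max_halvings Maximum number of recursive time-step halvings when a
#'   step fails to converge.
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(dt = 0.1, newton_rtol = 1e-8, atol_u = 1e-9,
                            atol_p = 1e-12, max_newton = 30,
                            jacobian_mode = "fd", fd_h = 1e-6,
                            incr_tol = 1e-12, max_halvings = 8) {
  if (dt <= 0) stop("dt must be > 0")
  if (newton_rtol <= 0) stop("newton_rtol must be > 0")
  if (!identical(jacobian_mode, "fd"))
    stop("jacobian_mode '", jacobian_mode,
         "' not available; the coloured finite-difference tangent ('fd') is used")
  structure(list(dt = dt, newton_rtol = newton_rtol, atol_u = atol_u,
                 atol_p = atol_p, max_newton = as.integer(max_newton),
                 jacobian_mode = jacobian_mode, fd_h = fd_h,
                 incr_tol = incr_tol,
                 max_halvings = as.integer(max_halvings)),
            class = "solver_settings")
}

#' Initial (stress-free, drained) field state on a mesh
#'
#' Nodal displacements and pore pressures are zero, the per-Gauss-point
#' fibre history is stress free and the volume ratio is one.
#'
#' @param mesh A [build_mesh()] object.
#' @return An object of class `field_state` with elements `d` (dof vector,
#'   node-interleaved `u_r, u_z, p`), `hist` (per-point `Pf, P1, eps_f`),
#'   `Jgp` and `t`.
#' @export
field_state <- function(mesh) {
  structure(list(d = numeric(3L * mesh$nn),
                 hist = matrix(0, mesh$ngp, 3,
                               dimnames = list(NULL, c("Pf", "P1", "eps_f"))),
                 Jgp = rep(1, mesh$ngp), t = 0),
            class = "field_state")
}

gp_colnames <- c("r", "z", "R", "J", "p", "wr", "wz", "eps_f", "Pf", "P1",
                 "sf_rr", "sf_rz", "sf_zz", "sm_rr", "sm_rz", "sm_zz", "sm_hh")

fibre_mode_code <- function(fibre_axis) {
  switch(match.arg(fibre_axis, c("axial", "radial")), axial = 0L, radial = 1L)
}

#' Advance the coupled problem by one implicit time step
#'
#' Solves the quasi-static momentum balance of the total stress and the
#' backward-Euler fluid mass balance for the state at `t + dt` using Newton
#' iteration with a coloured finite-difference Jacobian. Fibre histories are
#' committed only on convergence. On non-convergence the step is split into
#' two half steps recursively, up to `settings$max_halvings` levels.
#'
#' @param state A converged [field_state()].
#' @param mesh A [build_mesh()] object.
#' @param bc A [boundary_spec()] object.
#' @param params A [material_params()] object.
#' @param control Named list with the control value at `t + dt`: `U` (top
#'   axial displacement, mm) for displacement control or `sigma` (axial
#'   nominal traction, MPa) for traction control.
#' @param dt Time step (s).
#' @param settings A [solver_settings()] object.
#' @param fibre_axis `"axial"` or `"radial"` reference fibre direction.
#' @return The new [field_state()], with attributes `force` (total axial
#'   reaction on the top edge, N), `gp` (Gauss-point field matrix) and
#'   `niter`.
#' @export
solve_step <- function(state, mesh, bc, params, control, dt,
                       settings = solver_settings(), fibre_axis = "axial") {
  ctrl_prev <- attr(state, "control")
  if (is.null(ctrl_prev))
    ctrl_prev <- if (bc$control == "displacement") list(U = 0) else list(sigma = 0)
  .advance(state, mesh, bc, params, ctrl_prev, control, dt, settings,
           fibre_mode_code(fibre_axis), depth = 0L)
}

.advance <- function(state, mesh, bc, params, ctrl0, ctrl1, dt, settings,
                     fmode, depth) {
  res <- .try_step(state, mesh, bc, params, ctrl1, dt, settings, fmode)
  if (!is.null(res)) return(res)
  if (depth >= settings$max_halvings)
    stop("solver failed to converge at t = ", state$t + dt,
         " s even after ", depth, " time-step halvings")
  mid <- if (bc$control == "displacement")
    list(U = (ctrl0$U + ctrl1$U) / 2) else list(sigma = (ctrl0$sigma + ctrl1$sigma) / 2)
  s1 <- .advance(state, mesh, bc, params, ctrl0, mid, dt / 2, settings, fmode,
                 depth + 1L)
  .advance(s1, mesh, bc, params, mid, ctrl1, dt / 2, settings, fmode,
           depth + 1L)
}

.try_step <- function(state, mesh, bc, params, ctrl, dt, settings, fmode) {
  if (bc$control == "displacement") {
    fixed <- c(bc$fixed_zero, bc$top_uz)
    fixed_vals <- c(numeric(length(bc$fixed_zero)),
                    rep(ctrl$U, length(bc$top_uz)))
    load_scale <- 0
  } else {
    fixed <- bc$fixed_zero
    fixed_vals <- numeric(length(fixed))
    load_scale <- ctrl$sigma
  }
  out <- cpp_solve_step(mesh$nodes, mesh$elems, state$d, state$hist,
                        state$Jgp, dt, unclass(params), fmode,
                        as.integer(fixed - 1L), fixed_vals,
                        bc$load_vec, load_scale,
                        mesh$groups, mesh$rows, unclass(settings))
  if (!isTRUE(out$converged)) return(NULL)
  gp <- out$gp
  colnames(gp) <- gp_colnames
  new <- structure(list(d = as.numeric(out$d), hist = out$hist,
                        Jgp = as.numeric(out$Jgp), t = state$t + dt),
                   class = "field_state")
  colnames(new$hist) <- c("Pf", "P1", "eps_f")
  attr(new, "force") <- sum(out$res_int[bc$reaction_dofs])
  attr(new, "res_int") <- as.numeric(out$res_int)
  attr(new, "gp") <- gp
  attr(new, "niter") <- out$niter
  attr(new, "control") <- ctrl
  new
}

#' Run a loading protocol through the finite-element model
#'
#' Marches the solver along the protocol's time grid (one implicit step per
#' sample; failed steps are subdivided automatically) and records the total
#' axial reaction force on the top edge. Gauss-point fields (pore pressure,
#' Darcy flux, constituent stresses, volume ratio) can be recorded at every
#' step or at selected times.
#'
#' @param protocol A data frame with column `t` (s, strictly increasing,
#'   starting at the reference state) and either `U` (top displacement, mm)
#'   or `sigma` (axial traction, MPa).
#' @param geom A [tendon_geometry()] (ignored when `mesh` is given).
#' @param params A [material_params()] object.
#' @param mesh Optional prebuilt [build_mesh()].
#' @param settings A [solver_settings()] object.
#' @param fibre_axis `"axial"` or `"radial"`.
#' @param bc Optional [boundary_spec()]; by default the standard tensile
#'   set-up matching the protocol's control column.
#' @param record `"none"`, `"probe"` (fields of one element), or `"all"`.
#' @param probe_element Element index for `record = "probe"`; defaults to
#'   the element nearest the outer surface at mid-height.
#' @param keep_states Optional logical vector over protocol rows; full
#'   [field_state()] objects are retained for the flagged rows (attribute
#'   `kept_states` of the result).
#' @return A list of class `tendon_response`: `trace` (data frame `t`, `U`
#'   or `sigma`, `F` in N), `state` (final [field_state()]), and `fields`
#'   (list of recorded Gauss-point matrices, one per step, when requested).
#' @export
run_protocol <- function(protocol, geom = average_geometry(), params,
                         mesh = NULL, settings = solver_settings(),
                         fibre_axis = "axial", bc = NULL,
                         record = c("none", "probe", "all"),
                         probe_element = NULL, keep_states = NULL) {
  record <- match.arg(record)
  stopifnot(is.data.frame(protocol), "t" %in% names(protocol))
  if (nrow(protocol) < 2 || any(diff(protocol$t) <= 0))
    stop("protocol must have strictly increasing time samples")
  control_col <- if ("U" %in% names(protocol)) "U" else
    if ("sigma" %in% names(protocol)) "sigma" else
      stop("protocol needs a 'U' (displacement) or 'sigma' (traction) column")
  if (is.null(mesh)) mesh <- build_mesh(geom)
  if (is.null(bc))
    bc <- boundary_spec(mesh, control = if (control_col == "U")
      "displacement" else "traction")
  if (is.null(probe_element)) probe_element <- probe_element_index(mesh)
  fmode <- fibre_mode_code(fibre_axis)
  state <- field_state(mesh)
  state$t <- protocol$t[1]
  n <- nrow(protocol)
  force <- numeric(n)
  fields <- if (record != "none") vector("list", n) else NULL
  v0 <- protocol[[control_col]][1]
  if (abs(v0) > 1e-12)
    stop("protocol must start from the reference state (", control_col, " = 0)")
  ctrl <- if (control_col == "U") list(U = 0) else list(sigma = 0)
  attr(state, "control") <- ctrl
  gp_rows <- if (record == "probe")
    (4L * (probe_element - 1L) + 1L):(4L * probe_element) else NULL
  kept <- if (!is.null(keep_states)) vector("list", sum(keep_states)) else NULL
  kk <- 0L
  Utop_dofs <- 3L * (mesh$sets$top - 1L) + 2L
  U_top <- numeric(n)
  for (i in 2:n) {
    ctrl1 <- if (control_col == "U") list(U = protocol$U[i])
             else list(sigma = protocol$sigma[i])
    state <- .advance(state, mesh, bc, params, ctrl, ctrl1,
                      protocol$t[i] - protocol$t[i - 1], settings, fmode, 0L)
    ctrl <- ctrl1
    force[i] <- attr(state, "force")
    U_top[i] <- mean(state$d[Utop_dofs])
    if (record == "all") fields[[i]] <- attr(state, "gp")
    if (record == "probe") fields[[i]] <- attr(state, "gp")[gp_rows, , drop = FALSE]
    if (!is.null(keep_states) && isTRUE(keep_states[i])) {
      kk <- kk + 1L
      kept[[kk]] <- state
    }
  }
  trace <- data.frame(t = protocol$t, force = force)
  trace[[control_col]] <- protocol[[control_col]]
  names(trace)[names(trace) == "force"] <- "F"
  trace <- trace[, c("t", control_col, "F")]
  if (control_col == "sigma") trace$U <- U_top
  out <- structure(list(trace = trace, state = state, fields = fields,
                        mesh = mesh, probe_element = probe_element),
                   class = "tendon_response")
  if (!is.null(keep_states)) attr(out, "kept_states") <- kept
  out
}

#' @export
print.tendon_response <- function(x, ...) {
  cat(sprintf("Tendon FE response: %d steps, t in [%g, %g] s, peak |F| = %.3f N\n",
              nrow(x$trace) - 1L, min(x$trace$t), max(x$trace$t),
              max(abs(x$trace$F))))
  invisible(x)
}

#' Element nearest the outer surface at mid-height
#'
#' The probe location used for fluid-velocity output (outermost element
#' column, element row containing z = L/2).
#'
#' @param mesh A [build_mesh()] object.
#' @return An element index.
#' @export
probe_element_index <- function(mesh) {
  jmid <- pmin(mesh$nz - 1L, as.integer(floor(mesh$nz / 2)))
  as.integer(jmid * mesh$nr + mesh$nr)  # last radial column of that row
}

# Pure-R residual assembly; reference implementation used to cross-check
# the compiled core on small meshes.
fem_residual_r <- function(mesh, d, hist, Jgp_prev, dt, params,
                           fibre_axis = "axial") {
  mod <- derive_moduli(params)
  fmode <- fibre_mode_code(fibre_axis)
  g <- 1 / sqrt(3)
  xi <- c(-g, g, g, -g); et <- c(-g, -g, g, g)
  res <- numeric(3L * mesh$nn)
  for (e in seq_len(mesh$ne)) {
    nd <- mesh$elems[e, ]
    X <- mesh$nodes[nd, , drop = FALSE]
    xr <- X[, 1] + d[3 * (nd - 1) + 1]
    xz <- X[, 2] + d[3 * (nd - 1) + 2]
    pe <- d[3 * (nd - 1) + 3]
    for (q in 1:4) {
      gpi <- 4L * (e - 1L) + q
      s <- xi[q]; tq <- et[q]
      N <- 0.25 * c((1 - s) * (1 - tq), (1 + s) * (1 - tq),
                    (1 + s) * (1 + tq), (1 - s) * (1 + tq))
      dNdxi <- 0.25 * cbind(
        c(-(1 - tq), (1 - tq), (1 + tq), -(1 + tq)),
        c(-(1 - s), -(1 + s), (1 + s), (1 - s)))
      Jm <- t(dNdxi) %*% X
      detJref <- det(Jm)
      dNdX <- dNdxi %*% solve(Jm)
      Rgp <- sum(N * X[, 1])
      F2 <- rbind(c(sum(xr * dNdX[, 1]), sum(xr * dNdX[, 2])),
                  c(sum(xz * dNdX[, 1]), sum(xz * dNdX[, 2])))
      rgp <- sum(N * xr)
      F33 <- rgp / Rgp
      J <- det(F2) * F33
      if (J <= 0) stop("inverted element in reference residual")
      dNdx <- dNdX %*% solve(F2)
      # embed axisymmetric F into 3x3 (order r, theta, z)
      Fful <- rbind(c(F2[1, 1], 0, F2[1, 2]),
                    c(0, F33, 0),
                    c(F2[2, 1], 0, F2[2, 2]))
      e0 <- if (fmode == 0L) c(0, 0, 1) else c(1, 0, 0)
      fd <- update_fibre_direction(Fful, e0)
      st <- fibre_state(Pf = hist[gpi, 1], P1 = hist[gpi, 2],
                        eps_f = hist[gpi, 3], e0 = e0)
      up <- fibre_update(st, fd$eps_f, dt, params)
      sf <- if (up$Pf > 0) fibre_cauchy(up$Pf, fd$lam, J, fd$ef_cur)
            else matrix(0, 3, 3)
      sm <- matrix_cauchy(kinematics(Fful), mod)
      pgp <- sum(N * pe)
      tot <- total_stress(sf, sm, pgp)$sig_total
      s_rr <- tot[1, 1]; s_hh <- tot[2, 2]; s_zz <- tot[3, 3]; s_rz <- tot[1, 3]
      w <- detJref * 2 * pi * Rgp * J
      dpdr <- sum(dNdx[, 1] * pe); dpdz <- sum(dNdx[, 2] * pe)
      mob <- params$k0 * J^params$Mk / params$gamma_w
      storage <- (J - Jgp_prev[gpi]) / (dt * J)
      idx <- 3 * (nd - 1)
      res[idx + 1] <- res[idx + 1] +
        (dNdx[, 1] * s_rr + dNdx[, 2] * s_rz + N / rgp * s_hh) * w
      res[idx + 2] <- res[idx + 2] + (dNdx[, 1] * s_rz + dNdx[, 2] * s_zz) * w
      res[idx + 3] <- res[idx + 3] +
        (N * storage + mob * (dNdx[, 1] * dpdr + dNdx[, 2] * dpdz)) * w
    }
  }
  res
}
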