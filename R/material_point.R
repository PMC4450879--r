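#' Drained uniaxial material-point response
#'
#' Integrates the constitutive model at a single material point under a
#' prescribed axial stretch history with zero pore pressure (fully drained)
#' and a stress-free lateral surface: at each step the lateral stretch is
#' found so that the total radial stress vanishes. This is the thin
#' homogeneous limit of the tensile test and serves as an independent oracle
#' for the finite-element solver.
#'
#' @param times Strictly increasing time samples (s), starting at the
#'   reference state.
#' @param lam_z Axial stretch at each time (same length as `times`),
#'   `lam_z[1]` normally 1.
#' @param params A [material_params()] object.
#' @param fibre_axis `"axial"` (default) or `"radial"` fibre orientation.
#' @return A data frame with one row per time sample: `t`, `lam_z`, `lam_r`,
#'   `J`, `eps_f`, `Pf`, true axial stress `sig_zz` (MPa), nominal axial
#'   stress `stress_nominal = force / reference area` (MPa).
#' @export
uniaxial_response <- function(times, lam_z, params, fibre_axis = c("axial", "radial")) {
  fibre_axis <- match.arg(fibre_axis)
  stopifnot(length(times) == length(lam_z), all(diff(times) > 0))
  mod <- derive_moduli(params)
  e0 <- if (fibre_axis == "axial") c(0, 0, 1) else c(1, 0, 0)
  st <- fibre_state(e0 = e0, t = times[1])
  n <- length(times)
  out <- data.frame(t = times, lam_z = lam_z, lam_r = NA_real_, J = NA_real_,
                    eps_f = NA_real_, Pf = NA_real_, sig_zz = NA_real_,
                    stress_nominal = NA_real_)
  lam_r <- 1
  for (i in seq_len(n)) {
    lz <- lam_z[i]
    dt <- if (i == 1) NA else times[i] - times[i - 1]
    # trial fibre stress as a function of lam_r (radial fibres depend on it)
    step_state <- function(lr) {
      F <- diag(c(lr, lr, lz))
      fd <- update_fibre_direction(F, e0)
      if (i == 1) {
        list(Pf = 0, st = st, fd = fd)  # reference state, stress-free
      } else {
        up <- fibre_update(st, fd$eps_f, dt, params)
        list(Pf = up$Pf, st = up$state, fd = fd)
      }
    }
    resid_rr <- function(lr) {
      F <- diag(c(lr, lr, lz))
      kin <- kinematics(F)
      sm <- matrix_cauchy(kin, mod)
      s <- step_state(lr)
      sf <- if (s$Pf > 0) fibre_cauchy(s$Pf, s$fd$lam, kin$J, s$fd$ef_cur)
            else matrix(0, 3, 3)
      sm[1, 1] + sf[1, 1]
    }
    # scalar Newton (secant) for the traction-free lateral condition
    lr <- lam_r
    f0 <- resid_rr(lr)
    h <- 1e-6
    for (it in 1:50) {
      if (abs(f0) < 1e-12 * max(1, params$Em)) break
      fp <- (resid_rr(lr + h) - f0) / h
      step <- f0 / fp
      step <- max(min(step, 0.2), -0.2)
      lr <- lr - step
      f0 <- resid_rr(lr)
    }
    lam_r <- lr
    s <- step_state(lr)
    if (i > 1) st <- s$st
    F <- diag(c(lr, lr, lz))
    kin <- kinematics(F)
    sm <- matrix_cauchy(kin, mod)
    sf <- if (s$Pf > 0) fibre_cauchy(s$Pf, s$fd$lam, kin$J, s$fd$ef_cur)
          else matrix(0, 3, 3)
    szz <- sm[3, 3] + sf[3, 3]
    out$lam_r[i] <- lr
    out$J[i] <- kin$J
    out$eps_f[i] <- s$fd$eps_f
    out$Pf[i] <- s$Pf
    out$sig_zz[i] <- szz
    out$stress_nominal[i] <- szz * lr^2  # force / A0 = sig * A_cur / A0
  }
  out
}
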