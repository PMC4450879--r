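#' Stress in the equilibrium fibre spring
#'
#' Exponential tension-only spring law for the collagen fibres:
#' `P1 = E1 (exp(k1 eps_f) - 1)` for `eps_f > 0`, zero otherwise
#' (fibres carry load only in tension). The exponent `k1 * eps_f` is capped
#' at 200 with a warning to keep optimiser exploration finite.
#'
#' @param eps_f Logarithmic fibre strain (dimensionless); may be a vector.
#' @param E1 Spring stiffness (MPa).
#' @param k1 Exponential coefficient (dimensionless).
#' @return First Piola-Kirchhoff stress (MPa).
#' @export
spring_stress <- function(eps_f, E1, k1) {
  if (any(!is.finite(eps_f))) stop("eps_f must be finite")
  x <- k1 * eps_f
  if (any(x > 200)) {
    warning("fibre spring exponent k1*eps_f capped at 200 (overflow guard)")
    x <- pmin(x, 200)
  }
  ifelse(eps_f > 0, E1 * (expm1(x)), 0)
}

#' Per-point state of the viscoelastic collagen fibre
#'
#' History carried by one integration point of the fibre model: total fibre
#' first Piola-Kirchhoff stress `Pf`, equilibrium-spring stress `P1`,
#' logarithmic fibre strain `eps_f`, the reference fibre direction `e0`, and
#' the time stamp `t`. The internal Maxwell quantities (dashpot and spring
#' strain) are analytically eliminated and never stored.
#'
#' @param Pf Total fibre stress (MPa).
#' @param P1 Equilibrium-spring stress (MPa).
#' @param eps_f Logarithmic fibre strain.
#' @param e0 Unit reference fibre direction (length-3 vector).
#' @param t Time of the state (s).
#' @return An object of class `fibre_state`.
#' @export
fibre_state <- function(Pf = 0, P1 = 0, eps_f = 0, e0 = c(0, 0, 1), t = 0) {
  e0 <- as.numeric(e0)
  if (length(e0) != 3 || abs(sqrt(sum(e0^2)) - 1) > 1e-10)
    stop("e0 must be a unit length-3 vector")
  if (Pf < 0 || P1 < 0) stop("fibre stresses must be non-negative")
  structure(list(Pf = Pf, P1 = P1, eps_f = eps_f, e0 = e0,
                 ef_cur = e0 * exp(eps_f), lam = exp(eps_f), t = t),
            class = "fibre_state")
}

# Backward-Euler quadratic coefficients for the fibre stress update.
# Derived from the standard-linear-solid balance
#   Pf = P1 + eta*(epsdot_f - (Pfdot - P1dot) / (k2 (Pf - P1 + E2)))
# with backward differences for all rates over dt. Returns c(b, c) of
# Pf^2 + b Pf + c = 0. Note the -a*Pf_old term in c: it is required for
# Pf = P1 to be a fixed point under zero rates.
fibre_quadratic_coeffs <- function(Pf_old, P1_old, eps_old, eps_new, dt, params) {
  P1_new <- spring_stress(eps_new, params$E1, params$k1)
  epsdot <- (eps_new - eps_old) / dt
  P1dot <- (P1_new - P1_old) / dt
  a <- params$eta / (params$k2 * dt)
  b <- params$E2 - 2 * P1_new - params$eta * epsdot + a
  cc <- -a * Pf_old - (P1_new + params$eta * epsdot) * (params$E2 - P1_new) -
    (params$eta / params$k2) * P1dot
  c(b = b, c = cc, P1_new = P1_new)
}

#' Backward-Euler update of the fibre stress
#'
#' Advances the viscoelastic collagen-fibre model (standard linear solid with
#' exponential springs) by one implicit time step. Time-discretising the
#' stress balance of the fibre turns it into a quadratic equation in the new
#' fibre stress; the positive root is taken. When the new fibre strain is
#' non-positive the fibre is slack: the stress is zero and the viscous
#' history is reset to the stress-free state.
#'
#' @param state A [fibre_state()] holding converged values at time `t`.
#' @param eps_f_new Logarithmic fibre strain at `t + dt`.
#' @param dt Time step (s), > 0.
#' @param params A [material_params()] object.
#' @return A list with `Pf` (the new fibre stress, MPa) and `state`
#'   (the updated [fibre_state()]).
#' @export
fibre_update <- function(state, eps_f_new, dt, params) {
  if (!inherits(state, "fibre_state")) stop("state must be a fibre_state")
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  if (eps_f_new <= 0) {
    new <- fibre_state(Pf = 0, P1 = 0, eps_f = 0, e0 = state$e0, t = state$t + dt)
    new$eps_f <- eps_f_new
    new$lam <- exp(eps_f_new)
    new$ef_cur <- state$e0 * new$lam
    return(list(Pf = 0, state = new))
  }
  q <- fibre_quadratic_coeffs(state$Pf, state$P1, state$eps_f, eps_f_new, dt, params)
  disc <- q[["b"]]^2 - 4 * q[["c"]]
  if (disc < 0)
    stop("fibre update failed: negative discriminant in the quadratic ",
         "stress equation; retry with a smaller time step dt")
  Pf_new <- max(0, (-q[["b"]] + sqrt(disc)) / 2)
  new <- state
  new$Pf <- Pf_new
  new$P1 <- q[["P1_new"]]
  new$eps_f <- eps_f_new
  new$lam <- exp(eps_f_new)
  new$ef_cur <- state$e0 * new$lam
  new$t <- state$t + dt
  list(Pf = Pf_new, state = new)
}

#' Push the current fibre direction through the deformation gradient
#'
#' `ef = F e0`; the fibre stretch is `lam = |ef|` and the logarithmic fibre
#' strain `eps_f = log(lam)`.
#'
#' @param F 3x3 deformation gradient.
#' @param e0 Unit reference fibre direction.
#' @return A list with `ef_cur`, `lam`, `eps_f`.
#' @export
update_fibre_direction <- function(F, e0) {
  e0 <- as.numeric(e0)
  if (abs(sqrt(sum(e0^2)) - 1) > 1e-10) stop("e0 must be a unit vector")
  ef <- as.numeric(F %*% e0)
  lam <- sqrt(sum(ef^2))
  list(ef_cur = ef, lam = lam, eps_f = log(lam))
}

#' Cauchy stress tensor of the collagen fibres
#'
#' Pushes the one-dimensional fibre stress forward to the current
#' configuration: `sigma_f = (lam / J) Pf (e x e)` with `e` the current unit
#' fibre direction. The result is rank one and symmetric.
#'
#' @param Pf Fibre first Piola-Kirchhoff stress (MPa).
#' @param lam Fibre stretch.
#' @param J Volume ratio det(F).
#' @param ef_cur Current (deformed) fibre vector; only its direction is used.
#' @return 3x3 Cauchy stress tensor (MPa).
#' @export
fibre_cauchy <- function(Pf, lam, J, ef_cur) {
  if (J <= 0) stop("J must be > 0")
  if (lam <= 0) stop("lam must be > 0")
  n <- sqrt(sum(ef_cur^2))
  if (n == 0) stop("zero-length fibre vector")
  e <- ef_cur / n
  (lam / J) * Pf * tcrossprod(e)
}
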