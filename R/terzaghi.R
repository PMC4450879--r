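#' One-dimensional consolidation benchmark
#'
#' Validates the coupled displacement/pore-pressure solver against the
#' classical consolidation problem: a laterally confined poroelastic column
#' loaded axially by a step traction, draining through the loaded end only.
#' The fibres are effectively disabled (vanishing stiffness), the
#' permeability exponent is zero, and the load is small so the neo-Hookean
#' matrix responds linearly with confined modulus `M = Km + 4 Gm / 3`. The
#' computed pore-pressure profiles are compared with the analytic series
#' solution at the requested dimensionless times `Tv = c_v t / H^2`,
#' where `c_v = k M / gamma_w`.
#'
#' @param nz Number of axial elements (default 32).
#' @param Tv_check Dimensionless times at which profiles are compared.
#' @param H Column height (mm).
#' @param k0 Hydraulic conductivity used for the benchmark (mm/s).
#' @param sigma0 Magnitude of the applied compressive traction (MPa);
#'   kept small so the response is linear.
#' @param n_steps Approximate number of (log-spaced) time steps to `Tv = 1`.
#' @param settings A [solver_settings()] object.
#' @return A list with `error` (max relative pore-pressure error over the
#'   profile and check times), `profiles` (data frame with `z`, `Tv`,
#'   `p_fe`, `p_exact`), and `c_v`.
#' @export
terzaghi_benchmark <- function(nz = 32, Tv_check = c(0.1, 0.5, 1.0),
                               H = 1, k0 = 1e-4, sigma0 = 1e-3,
                               n_steps = 80, settings = solver_settings()) {
  # near-zero fibre stiffness so only the matrix and fluid respond
  p <- material_params(E1 = 1e-9, E2 = 1e-9, k1 = 1, k2 = 1, eta = 1e-9,
                       k0 = k0, Mk = 0, Em = 0.77, num = 0.35)
  mod <- derive_moduli(p)
  M <- mod$Km + 4 * mod$Gm / 3
  c_v <- k0 * M / p$gamma_w
  t_char <- H^2 / c_v
  geom <- tendon_geometry(L = H, A = pi * 0.3^2)
  mesh <- build_mesh(geom, nr = 1, nz = nz)
  bc <- boundary_spec(mesh, control = "traction", drainage = "top",
                      confined = TRUE)
  tv <- sort(unique(c(exp(seq(log(1e-3), log(1), length.out = n_steps)),
                      Tv_check)))
  times <- c(0, tv * t_char)
  prot <- data.frame(t = times, sigma = c(0, rep(-sigma0, length(tv))))
  resp <- run_protocol(prot, geom, p, mesh = mesh, settings = settings,
                       bc = bc, record = "none",
                       keep_states = c(FALSE, tv %in% Tv_check))
  states <- attr(resp, "kept_states")
  axis_nodes <- mesh$sets$axis
  zz <- mesh$nodes[axis_nodes, 2]
  profs <- NULL
  for (k in seq_along(Tv_check)) {
    st <- states[[k]]
    p_fe <- st$d[3 * (axis_nodes - 1) + 3]
    p_ex <- terzaghi_series(zz, H, Tv_check[k]) * sigma0
    profs <- rbind(profs, data.frame(z = zz, Tv = Tv_check[k],
                                     p_fe = p_fe, p_exact = p_ex))
  }
  err <- max(abs(profs$p_fe - profs$p_exact)) / sigma0
  list(error = err, profiles = profs, c_v = c_v, M = M)
}

# analytic consolidation series: normalised excess pressure at height z
# (drainage at z = H, impermeable base), Tv the dimensionless time
terzaghi_series <- function(z, H, Tv, n_terms = 200) {
  zp <- (H - z) / H  # depth from the drained surface
  out <- numeric(length(z))
  for (m in 0:(n_terms - 1)) {
    M <- (2 * m + 1) * pi / 2
    out <- out + 2 / M * sin(M * zp) * exp(-M^2 * Tv)
  }
  out
}
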