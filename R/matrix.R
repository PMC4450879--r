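#' Kinematic quantities from a deformation gradient
#'
#' @param F 3x3 deformation gradient with det(F) > 0.
#' @return A list of class `kinematics` with `F`, `C = t(F) F`, and
#'   `J = det(F)`.
#' @export
kinematics <- function(F) {
  F <- as.matrix(F)
  if (!all(dim(F) == c(3, 3))) stop("F must be 3x3")
  J <- det(F)
  if (J <= 0) stop("det(F) <= 0: inverted state")
  structure(list(F = F, C = crossprod(F), J = J), class = "kinematics")
}

#' Strain-energy density of the non-fibrillar matrix
#'
#' Compressible neo-Hookean energy (Simo-Ortiz form):
#' `W = Km/2 (1/2 (J^2 - 1) - log J) + Gm/2 (tr(C) - 3 det(C)^{1/3})`.
#' Vanishes in the reference state and grows without bound as J -> 0.
#'
#' @param kin A [kinematics()] object (or a 3x3 deformation gradient).
#' @param mod Moduli list with `Km`, `Gm` from [derive_moduli()].
#' @return Energy density (MPa).
#' @export
strain_energy <- function(kin, mod) {
  if (is.matrix(kin)) kin <- kinematics(kin)
  J <- kin$J
  if (J <= 0) stop("J must be > 0")
  detC <- det(kin$C)
  mod$Km / 2 * (0.5 * (J^2 - 1) - log(J)) +
    mod$Gm / 2 * (sum(diag(kin$C)) - 3 * detC^(1 / 3))
}

#' Cauchy stress of the non-fibrillar matrix
#'
#' Closed form of `(2/J) F dW/dC t(F)` for the compressible neo-Hookean
#' energy: `sigma_m = Km/2 (J - 1/J) I + Gm/J (F t(F) - J^{2/3} I)`.
#'
#' @inheritParams strain_energy
#' @return 3x3 symmetric Cauchy stress tensor (MPa).
#' @export
matrix_cauchy <- function(kin, mod) {
  if (is.matrix(kin)) kin <- kinematics(kin)
  J <- kin$J
  if (J <= 0) stop("inverted element: J <= 0")
  B <- tcrossprod(kin$F)
  mod$Km / 2 * (J - 1 / J) * diag(3) + mod$Gm / J * (B - J^(2 / 3) * diag(3))
}

#' Total stress in the biphasic tissue
#'
#' Stress partition of the saturated mixture: the solid stress is the sum of
#' fibre and matrix contributions, and the total stress subtracts the pore
#' pressure, `sigma_total = sigma_f + sigma_m - p I`.
#'
#' @param sig_f Fibre Cauchy stress (3x3, MPa).
#' @param sig_m Matrix Cauchy stress (3x3, MPa).
#' @param p Pore pressure (MPa).
#' @return A list of class `stress_decomposition` with `sig_f`, `sig_m`,
#'   `sig_s = sig_f + sig_m` and `sig_total = sig_s - p I`.
#' @export
total_stress <- function(sig_f, sig_m, p) {
  stopifnot(all(dim(sig_f) == c(3, 3)), all(dim(sig_m) == c(3, 3)))
  sig_s <- sig_f + sig_m
  structure(list(sig_f = sig_f, sig_m = sig_m, sig_s = sig_s,
                 sig_total = sig_s - p * diag(3), p = p),
            class = "stress_decomposition")
}
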