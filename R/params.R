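#' Constitutive parameter set for the tendon material model
#'
#' Bundles the nine calibrated constants of the fibre-reinforced
#' poroviscoelastic model together with the fixed fluid/solid constants.
#' Units are fixed package-wide: mm, N, s, MPa, mm/s, N/mm^3.
#'
#' @param E1 Stiffness of the equilibrium fibre spring (MPa).
#' @param E2 Stiffness of the spring in the Maxwell element (MPa).
#' @param k1 Dimensionless exponential coefficient of the equilibrium spring.
#' @param k2 Dimensionless exponential coefficient of the Maxwell spring.
#' @param eta Dashpot damping constant (MPa s).
#' @param k0 Initial hydraulic conductivity (mm/s).
#' @param Mk Dimensionless permeability exponent (>= 0).
#' @param Em Young's modulus of the non-fibrillar matrix (MPa).
#' @param num Poisson's ratio of the non-fibrillar matrix, in (0, 0.5).
#' @param rho_s Solid tissue density (g/ml). Default 1.4.
#' @param nfm Water mass fraction of the tissue, in (0, 1). Default 0.70.
#' @param gamma_w Specific weight of the pore fluid (N/mm^3), used to convert
#'   hydraulic conductivity to Darcy flux under a pressure gradient.
#'   Default 9.81e-6 (water).
#' @return An object of class `tendon_params` (a validated named list).
#' @examples
#' p <- material_params(E1 = 0.023, E2 = 0.443, k1 = 40, k2 = 31.06,
#'                      eta = 609.34, k0 = 1.19e-7, Mk = 0.96,
#'                      Em = 0.77, num = 0.35)
#' derive_moduli(p)
#' @export
material_params <- function(E1, E2, k1, k2, eta, k0, Mk, Em, num,
                            rho_s = 1.4, nfm = 0.70, gamma_w = 9.81e-6) {
  p <- list(E1 = E1, E2 = E2, k1 = k1, k2 = k2, eta = eta,
            k0 = k0, Mk = Mk, Em = Em, num = num,
            rho_s = rho_s, nfm = nfm, gamma_w = gamma_w)
  p <- lapply(p, as.numeric)
  class(p) <- "tendon_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(inherits(p, "tendon_params"))
  num_ok <- function(x) length(x) == 1L && is.finite(x)
  for (nm in names(p)) {
    if (!num_ok(p[[nm]])) stop("parameter '", nm, "' must be a finite scalar")
  }
  pos <- c("E1", "E2", "k1", "k2", "eta", "k0", "Em", "rho_s", "gamma_w")
  for (nm in pos) {
    if (p[[nm]] <= 0) stop("parameter '", nm, "' must be > 0, got ", p[[nm]])
  }
  if (p$Mk < 0) stop("parameter 'Mk' must be >= 0, got ", p$Mk)
  if (p$num <= 0 || p$num >= 0.5)
    stop("matrix Poisson's ratio 'num' must lie in (0, 0.5), got ", p$num,
         if (p$num >= 0.5) " (incompressibility violation)" else "")
  if (p$nfm <= 0 || p$nfm >= 1)
    stop("water mass fraction 'nfm' must lie in (0, 1), got ", p$nfm)
  invisible(p)
}

#' @export
print.tendon_params <- function(x, ...) {
  cat("Tendon material parameters (fibre-reinforced poroviscoelastic model)\n")
  cat(sprintf("  fibres : E1 = %g MPa, E2 = %g MPa, k1 = %g, k2 = %g, eta = %g MPa s\n",
              x$E1, x$E2, x$k1, x$k2, x$eta))
  cat(sprintf("  matrix : Em = %g MPa, num = %g\n", x$Em, x$num))
  cat(sprintf("  fluid  : k0 = %g mm/s, Mk = %g, nfm = %g, rho_s = %g g/ml\n",
              x$k0, x$Mk, x$nfm, x$rho_s))
  invisible(x)
}

#' Bulk and shear modulus of the non-fibrillar matrix
#'
#' Converts the matrix Young's modulus and Poisson's ratio into the bulk
#' (`Km`) and shear (`Gm`) moduli used by the compressible neo-Hookean law:
#' `Km = Em / (3 (1 - 2 num))`, `Gm = Em / (2 (1 + num))`.
#'
#' @param Em Matrix Young's modulus (MPa), or a [material_params()] object
#'   (in which case `num` is ignored).
#' @param num Matrix Poisson's ratio, in (0, 0.5).
#' @return A list with elements `Km` and `Gm` (MPa).
#' @export
derive_moduli <- function(Em, num = NULL) {
  if (inherits(Em, "tendon_params")) {
    num <- Em$num
    Em <- Em$Em
  }
  if (!is.finite(Em) || Em <= 0) stop("Em must be a positive finite number")
  if (!is.finite(num) || num < 0) stop("num must be finite and non-negative")
  if (num >= 0.5)
    stop("num >= 0.5: incompressibility violation (bulk modulus diverges)")
  list(Km = Em / (3 * (1 - 2 * num)), Gm = Em / (2 * (1 + num)))
}

#' Fluid volume fraction and initial void ratio from the water mass fraction
#'
#' Assuming a fully saturated mixture, the fluid volume fraction follows from
#' the water mass fraction `nfm` and the solid tissue density `rho_s` (fluid
#' density 1 g/ml): `nf = rho_s nfm / (1 - nfm + nfm rho_s)`. The initial
#' void ratio is `e0 = nf / (1 - nf)`.
#'
#' @param nfm Water mass fraction, in (0, 1).
#' @param rho_s Solid tissue density (g/ml).
#' @return A list with elements `nf` and `e0_void`.
#' @export
fluid_fraction <- function(nfm, rho_s = 1.4) {
  if (!is.finite(nfm) || nfm <= 0 || nfm >= 1)
    stop("nfm must lie in (0, 1)")
  if (!is.finite(rho_s) || rho_s <= 0) stop("rho_s must be > 0")
  nf <- rho_s * nfm / (1 - nfm + nfm * rho_s)
  list(nf = nf, e0_void = nf / (1 - nf))
}

#' Void-ratio-dependent hydraulic conductivity
#'
#' `k = k0 ((1 + e) / (1 + e0))^Mk`. Because the solid constituent is
#' intrinsically incompressible, `(1 + e)/(1 + e0)` equals the volume ratio
#' `J`, so permeability grows as the tissue dilates.
#'
#' @param e_void Current void ratio (> -1).
#' @param e0_void Initial void ratio (> 0).
#' @param k0 Initial hydraulic conductivity (mm/s).
#' @param Mk Permeability exponent (>= 0).
#' @return Hydraulic conductivity (mm/s).
#' @export
permeability <- function(e_void, e0_void, k0, Mk) {
  if (any(1 + e_void <= 0)) stop("void ratio must satisfy 1 + e > 0")
  if (e0_void <= 0) stop("initial void ratio must be > 0")
  if (k0 <= 0) stop("k0 must be > 0")
  k0 * ((1 + e_void) / (1 + e0_void))^Mk
}

#' Read a material parameter set from JSON
#'
#' The file is flat JSON keyed by the model's symbol names
#' (`E1, E2, k1, k2, eta, k0, Mk, Em, num`) plus optional constants
#' (`rho_s`, `nfm`, `gamma_w`), which default to 1.4 g/ml, 0.70 and
#' 9.81e-6 N/mm^3 when absent.
#'
#' @param path Path to a JSON file.
#' @return A [material_params()] object.
#' @export
load_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  x <- jsonlite::fromJSON(path)
  required <- c("E1", "E2", "k1", "k2", "eta", "k0", "Mk", "Em", "num")
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop("parameter file ", path, " is missing required key(s): ",
         paste(missing, collapse = ", "))
  do.call(material_params, x[intersect(names(x), c(required, "rho_s", "nfm", "gamma_w"))])
}

#' Write a material parameter set to JSON
#'
#' @param params A [material_params()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_params <- function(params, path) {
  validate_params(params)
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Parameter sets shipped with the package
#'
#' Calibrated parameter sets for the average rat Achilles tendon model
#' (load cycles 1-3 and 10-12) and the nine specimen-specific models,
#' stored as JSON fixtures under `inst/extdata`.
#'
#' @param which `"average"` for the average-tendon sets or `"specimens"`
#'   for the per-specimen table.
#' @param row For `"average"`: `"1-3"` (default) or `"10-12"`. For
#'   `"specimens"`: specimen number 1-9, or `"mean"`, `"SD"`, `"CV"`.
#' @param as_params Return a validated [material_params()] object (default)
#'   rather than the raw named list (use `FALSE` for the SD/CV rows, which
#'   are not themselves valid parameter sets).
#' @return A [material_params()] object or a named list.
#' @export
reference_params <- function(which = c("average", "specimens"), row = "1-3",
                             as_params = TRUE) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   if (which == "average") "params_average_tendon.json"
                   else "params_specimens.json",
                   package = "tendonpve", mustWork = TRUE)
  tab <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  row <- as.character(row)
  if (!row %in% names(tab))
    stop("no row '", row, "'; available: ", paste(names(tab), collapse = ", "))
  x <- tab[[row]]
  x$RMS <- NULL
  if (!as_params) return(lapply(x, as.numeric))
  do.call(material_params, x)
}
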