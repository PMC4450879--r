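#' Specification of a synthetic test cohort
#'
#' Describes a cohort of virtual specimens emulating the cyclic tensile
#' experiment on rat Achilles tendons: 9 specimens, cyclic loading between
#' 1 N and 20 N at 0.1 mm/s repeated 20 times, mean geometry 8.4 mm length
#' and 1.63 mm^2 cross-section. Inter-specimen variability draws the
#' positive constitutive parameters log-normally with the coefficients of
#' variation of the specimen-specific fits; the matrix Poisson's ratio uses
#' a truncated normal on (0.05, 0.49) and the geometry a truncated normal.
#' Measurement noise is additive white noise on the force.
#'
#' @param n_specimens Number of specimens (default 9).
#' @param geom_mean Named vector `c(L = , A = )`, mm and mm^2.
#' @param geom_cv Coefficient of variation of L and A (default 0.1).
#' @param param_means A [material_params()] object with the population
#'   means (default the average-tendon cycle 1-3 set).
#' @param param_cvs Named per-parameter CVs (default the CV row of the
#'   specimen table).
#' @param noise_sd Force noise standard deviation (N), default 0.1
#'   (about 0.5% of the 20 N peak).
#' @param n_cycles Load cycles per specimen (default 20).
#' @param rate Displacement rate (mm/s).
#' @param F_max,F_min Reversal force thresholds (N).
#' @param seed Integer seed; the cohort is bitwise reproducible given the
#'   seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_specimens = 9,
                        geom_mean = c(L = 8.4, A = 1.63), geom_cv = 0.1,
                        param_means = reference_params("average", "1-3"),
                        param_cvs = NULL, noise_sd = 0.1, n_cycles = 20,
                        rate = 0.1, F_max = 20, F_min = 1, seed = 1) {
  if (is.null(param_cvs)) {
    cv <- reference_params("specimens", "CV", as_params = FALSE)
    param_cvs <- unlist(cv)
  }
  validate_params(param_means)
  stopifnot(all(param_cvs >= 0), n_specimens >= 1, noise_sd >= 0,
            geom_cv >= 0)
  structure(list(n_specimens = as.integer(n_specimens),
                 geom_mean = geom_mean, geom_cv = geom_cv,
                 param_means = param_means, param_cvs = param_cvs,
                 noise_sd = noise_sd, n_cycles = as.integer(n_cycles),
                 rate = rate, F_max = F_max, F_min = F_min,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

specimen_seed <- function(seed, index, salt = 0L) {
  (as.integer(seed) * 10007L + as.integer(index) * 101L + as.integer(salt)) %%
    2147483647L
}

# log-normal draw with arithmetic mean m and coefficient of variation cv
rlnorm_mean_cv <- function(n, m, cv) {
  if (cv == 0) return(rep(m, n))
  s2 <- log(1 + cv^2)
  rlnorm(n, meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

rtrunc_norm <- function(n, m, s, lo, hi) {
  if (s == 0) return(rep(min(max(m, lo), hi), n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (k in 1:1000) {
      x <- rnorm(1, m, s)
      if (x > lo && x < hi) { out[i] <- x; break }
      if (k == 1000) out[i] <- min(max(m, lo), hi)
    }
  }
  out
}

#' Draw one specimen (geometry + parameters) from a cohort specification
#'
#' Deterministic given `(spec$seed, index)`.
#'
#' @param spec A [cohort_spec()].
#' @param index Specimen index (1-based).
#' @return A list with `geom` ([tendon_geometry()]) and `params`
#'   ([material_params()]).
#' @export
sample_specimen <- function(spec, index) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(specimen_seed(spec$seed, index))
  m <- spec$param_means
  cv <- spec$param_cvs
  draw <- list()
  for (nm in c("E1", "E2", "k1", "k2", "eta", "k0", "Mk", "Em")) {
    cvi <- if (nm %in% names(cv)) cv[[nm]] else 0
    draw[[nm]] <- rlnorm_mean_cv(1, m[[nm]], cvi)
  }
  cvn <- if ("num" %in% names(cv)) cv[["num"]] else 0
  draw$num <- rtrunc_norm(1, m$num, cvn * m$num, 0.05, 0.49)
  L <- rtrunc_norm(1, spec$geom_mean[["L"]], spec$geom_cv * spec$geom_mean[["L"]],
                   1e-3, Inf)
  A <- rtrunc_norm(1, spec$geom_mean[["A"]], spec$geom_cv * spec$geom_mean[["A"]],
                   1e-6, Inf)
  params <- do.call(material_params,
                    c(draw, list(rho_s = m$rho_s, nfm = m$nfm,
                                 gamma_w = m$gamma_w)))
  list(geom = tendon_geometry(L, A), params = params)
}

#' Simulate a cyclic force-displacement protocol for one specimen
#'
#' Runs the forward model under displacement control at `spec$rate`,
#' reversing by within-step bisection when the force crosses `spec$F_max`
#' (loading) or `spec$F_min` (unloading), for `spec$n_cycles` cycles.
#' Additive Gaussian measurement noise (sd `spec$noise_sd`) is applied to
#' the force channel; the noise-free force is kept alongside.
#'
#' @param geom A [tendon_geometry()].
#' @param params A [material_params()] object.
#' @param spec A [cohort_spec()].
#' @param index Specimen index (fixes the noise stream).
#' @param mesh Optional forward mesh (default 4 x 16).
#' @param dt Nominal step (s).
#' @param settings A [solver_settings()] object.
#' @param U_bound Displacement bound passed to [run_cyclic()]; exceeding it
#'   before `F_max` is reached raises an error naming the specimen.
#' @return A protocol data frame `t`, `U`, `F_exp` (noisy) with attributes
#'   `F_clean`, `peaks`, `valleys`.
#' @export
generate_protocol <- function(geom, params, spec, index = 1, mesh = NULL,
                              dt = 0.25, settings = solver_settings(),
                              U_bound = NULL) {
  cyc <- run_cyclic(params, geom, mesh = mesh, rate = spec$rate,
                    F_max = spec$F_max, F_min = spec$F_min,
                    n_cycles = spec$n_cycles, dt = dt, settings = settings,
                    U_bound = U_bound,
                    label = paste0("specimen ", index))
  set.seed(specimen_seed(spec$seed, index, salt = 7L))
  F_clean <- cyc$trace$F
  noise <- if (spec$noise_sd > 0)
    rnorm(length(F_clean), 0, spec$noise_sd) else numeric(length(F_clean))
  out <- data.frame(t = cyc$trace$t, U = cyc$trace$U,
                    F_exp = F_clean + noise)
  attr(out, "F_clean") <- F_clean
  attr(out, "peaks") <- cyc$peaks
  attr(out, "valleys") <- cyc$valleys
  out
}

#' Generate a full synthetic cohort with its truth ledger
#'
#' Draws `spec$n_specimens` specimens, simulates each cyclic protocol, and
#' (optionally) writes per-specimen protocol CSVs plus a JSON truth file of
#' the generating geometry and parameters for parameter-recovery studies.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Output directory (`NULL` to skip writing).
#' @param mesh,dt,settings Forward-model controls, see
#'   [generate_protocol()].
#' @return A list of class `tendon_cohort`: `specimens` (list with `geom`,
#'   `params`, `protocol`) and `truth` (list of generating values).
#' @export
generate_cohort <- function(spec, out_dir = NULL, mesh = NULL, dt = 0.25,
                            settings = solver_settings()) {
  stopifnot(inherits(spec, "cohort_spec"))
  specimens <- vector("list", spec$n_specimens)
  truth <- vector("list", spec$n_specimens)
  for (i in seq_len(spec$n_specimens)) {
    sp <- sample_specimen(spec, i)
    prot <- generate_protocol(sp$geom, sp$params, spec, index = i,
                              mesh = mesh, dt = dt, settings = settings)
    specimens[[i]] <- list(geom = sp$geom, params = sp$params,
                           protocol = prot)
    truth[[i]] <- list(L = sp$geom$L, A = sp$geom$A,
                       params = unclass(sp$params))
  }
  names(specimens) <- names(truth) <- paste0("specimen_", seq_len(spec$n_specimens))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(spec$n_specimens)) {
      write_protocol(specimens[[i]]$protocol,
                     file.path(out_dir, sprintf("specimen_%02d.csv", i)))
    }
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(specimens = specimens, truth = truth, spec = spec),
            class = "tendon_cohort")
}
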