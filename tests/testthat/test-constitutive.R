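test_that("matrix moduli follow from Em and num, with the incompressible limit", {
  m <- derive_moduli(0.77, 0.35)
  expect_equal(m$Km, 0.77 / (3 * 0.3), tolerance = 1e-12)
  expect_equal(m$Km, 0.85556, tolerance = 1e-4)
  expect_equal(m$Gm, 0.28519, tolerance = 1e-4)
  m0 <- derive_moduli(1, 0)
  expect_equal(m0$Km, 1 / 3)
  expect_equal(m0$Gm, 1 / 2)
  # Km grows monotonically without bound as num -> 0.5
  Kms <- vapply(c(0.4, 0.45, 0.49, 0.499), function(v) derive_moduli(1, v)$Km,
                numeric(1))
  expect_true(all(diff(Kms) > 0))
  expect_error(derive_moduli(1, 0.5), "incompressibility")
  expect_error(derive_moduli(-1, 0.3))
})

test_that("the equilibrium fibre spring is exponential and tension-only", {
  expect_equal(spring_stress(0.05, 0.023, 40), 0.023 * expm1(2),
               tolerance = 1e-12)
  expect_equal(spring_stress(0.05, 0.023, 40), 0.146948, tolerance = 1e-5)
  expect_identical(spring_stress(0, 0.023, 40), 0)
  expect_identical(spring_stress(-0.01, 0.023, 40), 0)
  expect_warning(spring_stress(10, 0.023, 40), "capped")
  expect_error(spring_stress(NaN, 0.023, 40))
})

test_that("fluid fraction and initial void ratio follow from the water mass fraction", {
  ff <- fluid_fraction(0.7, 1.4)
  expect_equal(ff$nf, 0.765625, tolerance = 1e-9)
  expect_equal(ff$e0_void, 3.26667, tolerance = 1e-5)
  expect_equal(fluid_fraction(0.7, 1.0)$nf, 0.7, tolerance = 1e-12)
  expect_equal(fluid_fraction(1 - 1e-9, 1.4)$nf, 1, tolerance = 1e-6)
  expect_error(fluid_fraction(1.2))
})

test_that("permeability is void-ratio dependent with exponent Mk", {
  expect_equal(permeability(3.26667, 3.26667, 1.19e-7, 0.96), 1.19e-7)
  expect_equal(permeability(5.0, 3.26667, 1.19e-7, 0.96), 1.6509e-7,
               tolerance = 1e-4)
  expect_equal(permeability(7, 3.26667, 2e-7, 0), 2e-7)
  expect_error(permeability(-1.5, 3.26667, 1e-7, 1))
})

test_that("fibre update has the equilibrium fixed point and quadratic root", {
  p <- avg_params()
  P1 <- spring_stress(0.05, p$E1, p$k1)
  for (dt in c(1e-3, 0.1, 10, 1e6)) {
    st <- fibre_state(Pf = P1, P1 = P1, eps_f = 0.05)
    up <- fibre_update(st, 0.05, dt, p)
    expect_equal(up$Pf, P1, tolerance = 1e-10)
  }
  # quadratic-root identity along a random strain path
  set.seed(7)
  st <- fibre_state()
  eps <- 0.02
  for (i in 1:60) {
    eps <- max(1e-4, eps + rnorm(1, 0, 0.01))
    q <- tendonpve:::fibre_quadratic_coeffs(st$Pf, st$P1, st$eps_f, eps, 0.1, p)
    up <- fibre_update(st, eps, 0.1, p)
    resid <- up$Pf^2 + q[["b"]] * up$Pf + q[["c"]]
    scale <- max(up$Pf^2, abs(q[["c"]]), 1e-30)
    expect_lt(abs(resid) / scale, 1e-9)
    st <- up$state
  }
})

test_that("the Maxwell branch relaxes monotonically toward the equilibrium spring", {
  p <- avg_params()
  P1 <- spring_stress(0.05, p$E1, p$k1)
  st <- fibre_state(Pf = 3 * P1, P1 = P1, eps_f = 0.05)
  prev <- st$Pf
  for (i in 1:400) {
    up <- fibre_update(st, 0.05, 2, p)
    expect_lte(up$Pf, prev + 1e-12)
    prev <- up$Pf
    st <- up$state
  }
  expect_equal(prev, P1, tolerance = 1e-3)
})

test_that("an infinitely slow step recovers the rate-independent equilibrium response", {
  p <- avg_params()
  st <- fibre_state(Pf = 0.5, P1 = 0.2, eps_f = 0.03)
  up <- fibre_update(st, 0.08, 1e6, p)
  expect_equal(up$Pf, spring_stress(0.08, p$E1, p$k1), tolerance = 1e-4)
})

test_that("compression zeroes the fibre stress and resets the viscous history", {
  p <- avg_params()
  st <- fibre_state(Pf = 1, P1 = 0.5, eps_f = 0.06)
  up <- fibre_update(st, -0.02, 0.1, p)
  expect_identical(up$Pf, 0)
  expect_identical(up$state$Pf, 0)
  expect_identical(up$state$P1, 0)
  # reloading from the reset state starts from the stress-free configuration
  up2 <- fibre_update(up$state, 0.01, 0.1, p)
  expect_gte(up2$Pf, 0)
  expect_error(fibre_update(st, 0.05, 0, p), "dt")
})

test_that("dissipated fibre work over a closed strain cycle is non-negative", {
  p <- avg_params()
  set.seed(11)
  for (rep in 1:5) {
    amp <- runif(1, 0.02, 0.1)
    period <- runif(1, 2, 30)
    nstep <- 120
    tt <- seq(0, period, length.out = nstep + 1)
    eps <- amp * (1 - cos(2 * pi * tt / period)) / 2  # closed cycle 0 -> amp -> 0
    st <- fibre_state()
    W <- 0
    Pf_prev <- 0
    for (i in 2:length(tt)) {
      up <- fibre_update(st, eps[i], tt[i] - tt[i - 1], p)
      W <- W + 0.5 * (up$Pf + Pf_prev) * (eps[i] - eps[i - 1])
      Pf_prev <- up$Pf
      st <- up$state
    }
    expect_gte(W, -1e-10)
  }
})

test_that("fibre direction updates through the deformation gradient", {
  upd <- update_fibre_direction(diag(3), c(0, 0, 1))
  expect_equal(upd$ef_cur, c(0, 0, 1))
  expect_equal(upd$lam, 1)
  expect_equal(upd$eps_f, 0)
  th <- 0.4
  Rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  upd <- update_fibre_direction(Rot, c(1, 0, 0))
  expect_equal(upd$lam, 1, tolerance = 1e-12)
  expect_equal(upd$eps_f, 0, tolerance = 1e-12)
  upd <- update_fibre_direction(diag(c(1, 1, 1.1)), c(0, 0, 1))
  expect_equal(upd$lam, 1.1)
  expect_equal(upd$eps_f, 0.095310, tolerance = 1e-5)
})

test_that("fibre Cauchy stress is the rank-one push-forward of the fibre stress", {
  expect_equal(fibre_cauchy(0, 1.1, 1, c(0, 0, 1.1)), matrix(0, 3, 3))
  s <- fibre_cauchy(1, 1.1, 1.0, c(0, 0, 1.1))
  expect_equal(s[3, 3], 1.1, tolerance = 1e-12)
  expect_equal(sum(abs(s)) - abs(s[3, 3]), 0)
  # congruent rotation of the fibre direction rotates the tensor
  th <- 0.7
  Rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  e <- c(1, 0, 0)
  s1 <- fibre_cauchy(2, 1.2, 1.1, Rot %*% e * 1.2)
  s0 <- fibre_cauchy(2, 1.2, 1.1, e * 1.2)
  expect_equal(s1, Rot %*% s0 %*% t(Rot), tolerance = 1e-12)
  expect_error(fibre_cauchy(1, 1, 1, c(0, 0, 0)), "zero-length")
})

test_that("neo-Hookean matrix stress matches its closed form and limits", {
  mod <- derive_moduli(0.77, 0.35)
  expect_equal(matrix_cauchy(kinematics(diag(3)), mod), matrix(0, 3, 3))
  # pure dilatation: deviatoric part vanishes, sigma = Km/2 (J - 1/J) I
  J <- 1.2
  s <- matrix_cauchy(kinematics(J^(1 / 3) * diag(3)), mod)
  expect_equal(s, mod$Km / 2 * (J - 1 / J) * diag(3), tolerance = 1e-12)
  expect_equal(s[1, 1], 0.156852, tolerance = 1e-5)
  # small simple shear: shear stress -> Gm * gamma
  gam <- 1e-5
  F <- diag(3); F[1, 3] <- gam
  s <- matrix_cauchy(kinematics(F), mod)
  expect_equal(s[1, 3] / gam, mod$Gm, tolerance = 1e-3)
  expect_error(matrix_cauchy(kinematics(diag(c(-1, 1, 1))), mod))
})

test_that("matrix stress equals the numerical push-forward of the strain energy", {
  mod <- derive_moduli(0.77, 0.35)
  set.seed(3)
  for (i in 1:100) {
    F <- random_F()
    s_closed <- matrix_cauchy(kinematics(F), mod)
    s_fd <- fd_cauchy_from_energy(F, mod)
    expect_equal(s_fd, s_closed, tolerance = 1e-5)
  }
})

test_that("strain energy vanishes at identity and blows up on compression to a point", {
  mod <- derive_moduli(0.77, 0.35)
  expect_equal(strain_energy(kinematics(diag(3)), mod), 0)
  W <- vapply(c(0.5, 0.1, 0.02, 0.005),
              function(J) strain_energy(kinematics(J^(1 / 3) * diag(3)), mod),
              numeric(1))
  expect_true(all(diff(W) > 0))  # unbounded growth, driven by -log(J)
  expect_gt(W[4], 10 * W[1])
})

test_that("the stress partition is exact", {
  sf <- matrix(0, 3, 3); sf[3, 3] <- 10
  sm <- matrix(0, 3, 3)
  ts <- total_stress(sf, sm, -0.1)
  expect_identical(ts$sig_total[3, 3], 10.1)
  expect_identical(ts$sig_total[1, 1], 0.1)
  expect_identical(ts$sig_s, sf + sm)
  set.seed(5)
  A <- matrix(rnorm(9), 3, 3); A <- A + t(A)
  B <- matrix(rnorm(9), 3, 3); B <- B + t(B)
  p <- rnorm(1)
  ts <- total_stress(A, B, p)
  expect_identical(ts$sig_total, A + B - p * diag(3))
  expect_equal(sum(diag(ts$sig_total)), sum(diag(ts$sig_s)) - 3 * p)
})

test_that("parameter sets validate their invariants and round-trip through JSON", {
  expect_error(material_params(E1 = 0.02, E2 = 0.4, k1 = 40, k2 = 31,
                               eta = 600, k0 = 1e-7, Mk = 1, Em = 0.8,
                               num = 0.6), "num")
  expect_error(material_params(E1 = -1, E2 = 0.4, k1 = 40, k2 = 31,
                               eta = 600, k0 = 1e-7, Mk = 1, Em = 0.8,
                               num = 0.3), "E1")
  p <- reference_params("average", "1-3")
  expect_equal(p$E1, 0.023)
  expect_equal(p$eta, 609.34)
  expect_equal(p$Mk, 0.96)
  f <- tempfile(fileext = ".json")
  save_params(p, f)
  p2 <- load_params(f)
  expect_equal(unclass(p2), unclass(p), tolerance = 1e-12)
})
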