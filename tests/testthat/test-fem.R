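cpp_res <- function(mesh, d, hist, Jprev, dt, params, fmode = 0L, ...) {
  tendonpve:::cpp_residual(mesh$nodes, mesh$elems, d, hist, Jprev, dt,
                           unclass(params), fmode, ...)
}

random_state <- function(mesh, seed = 1) {
  set.seed(seed)
  d <- numeric(3 * mesh$nn)
  d[seq(1, length(d), 3)] <- rnorm(mesh$nn, 0, 0.005)
  d[seq(2, length(d), 3)] <- rnorm(mesh$nn, 0, 0.02)
  d[seq(3, length(d), 3)] <- rnorm(mesh$nn, 0, 0.01)
  hist <- matrix(0, mesh$ngp, 3)
  hist[, 1] <- abs(rnorm(mesh$ngp, 0.05, 0.02))
  hist[, 2] <- hist[, 1] * 0.8
  hist[, 3] <- abs(rnorm(mesh$ngp, 0.01, 0.005))
  list(d = d, hist = hist, Jprev = rep(1, mesh$ngp))
}

test_that("the structured mesh has the right counts and exact meridian area", {
  geom <- avg_geom()
  mesh <- build_mesh(geom, 4, 16)
  expect_equal(mesh$ne, 64)
  expect_equal(mesh$nn, 85)
  expect_equal(tendonpve:::mesh_meridian_area(mesh), geom$R * geom$L,
               tolerance = 1e-12)
  m1 <- build_mesh(geom, 1, 1)
  expect_equal(m1$ne, 1)
  expect_equal(m1$nn, 4)
  expect_error(build_mesh(tendon_geometry(-1, 1)))
  expect_error(build_mesh(geom, 0, 4))
})

test_that("compiled and reference residuals agree and vanish in the reference state", {
  p <- avg_params()
  mesh <- build_mesh(avg_geom(), 2, 2)
  st <- random_state(mesh)
  rc <- cpp_res(mesh, st$d, st$hist, st$Jprev, 0.1, p)
  expect_true(rc$ok)
  rr <- tendonpve:::fem_residual_r(mesh, st$d, st$hist, st$Jprev, 0.1, p)
  expect_equal(rc$res, rr, tolerance = 1e-12)
  d0 <- numeric(3 * mesh$nn)
  r0 <- cpp_res(mesh, d0, matrix(0, mesh$ngp, 3), st$Jprev, 0.1, p)
  expect_lt(max(abs(r0$res)), 1e-12)
})

test_that("the coloured finite-difference Jacobian matches a naive dense one", {
  p <- avg_params()
  mesh <- build_mesh(avg_geom(), 2, 2)
  st <- random_state(mesh, seed = 4)
  dt <- 0.1
  h0 <- 1e-6
  ndof <- 3 * mesh$nn
  R0 <- cpp_res(mesh, st$d, st$hist, st$Jprev, dt, p)$res
  # naive: one residual evaluation per dof
  K_naive <- matrix(0, ndof, ndof)
  for (j in seq_len(ndof)) {
    h <- h0 * max(1, abs(st$d[j]))
    dp <- st$d; dp[j] <- dp[j] + h
    K_naive[, j] <- (cpp_res(mesh, dp, st$hist, st$Jprev, dt, p)$res - R0) / h
  }
  # coloured: simultaneous perturbation of non-interacting dofs, scattered
  # through the precomputed adjacency rows (same tables the solver uses)
  K_col <- matrix(0, ndof, ndof)
  for (grp in mesh$groups) {
    if (!length(grp)) next
    dp <- st$d
    hs <- h0 * pmax(1, abs(st$d[grp + 1]))
    dp[grp + 1] <- dp[grp + 1] + hs
    Rp <- cpp_res(mesh, dp, st$hist, st$Jprev, dt, p)$res
    for (k in seq_along(grp)) {
      jj <- grp[k] + 1
      rows <- mesh$rows[[jj]] + 1
      K_col[rows, jj] <- (Rp[rows] - R0[rows]) / hs[k]
    }
  }
  expect_lt(max(abs(K_col - K_naive)) / max(abs(K_naive)), 1e-7)
})

test_that("a homogeneous drained stretch reproduces the material point (patch test)", {
  p <- avg_params()
  geom <- avg_geom()
  m1 <- build_mesh(geom, 1, 1)
  lz <- 1.05; lr <- 0.98; dt <- 0.5
  d <- numeric(3 * m1$nn)
  d[seq(1, length(d), 3)] <- (lr - 1) * m1$nodes[, 1]
  d[seq(2, length(d), 3)] <- (lz - 1) * m1$nodes[, 2]
  out <- cpp_res(m1, d, matrix(0, m1$ngp, 3), rep(1, m1$ngp), dt, p,
                 commit = TRUE)
  F_fe <- sum(out$res[3 * (m1$sets$top - 1) + 2])
  kin <- kinematics(diag(c(lr, lr, lz)))
  up <- fibre_update(fibre_state(), log(lz), dt, p)
  s_zz <- fibre_cauchy(up$Pf, lz, kin$J, c(0, 0, lz))[3, 3] +
    matrix_cauchy(kin, derive_moduli(p))[3, 3]
  F_mp <- s_zz * pi * (geom$R * lr)^2
  expect_equal(F_fe, F_mp, tolerance = 1e-6)
  # committed Gauss-point fields are homogeneous and consistent
  expect_equal(unname(out$gp[, 4]), rep(kin$J, 4), tolerance = 1e-12)
})

test_that("a zero increment converges immediately; small ramps converge fast", {
  p <- avg_params()
  mesh <- coarse_mesh()
  bc <- boundary_spec(mesh)
  st <- field_state(mesh)
  s1 <- solve_step(st, mesh, bc, p, list(U = 0), dt = 0.1)
  expect_lte(attr(s1, "niter"), 1)
  expect_equal(attr(s1, "force"), 0, tolerance = 1e-8)
  s2 <- solve_step(s1, mesh, bc, p, list(U = 0.05), dt = 0.5)
  expect_lte(attr(s2, "niter"), 8)
  expect_gt(attr(s2, "force"), 0)
})

test_that("halving the time step changes the reaction force by < 1% at protocol rates", {
  p <- avg_params()
  geom <- avg_geom()
  mesh <- coarse_mesh(geom)
  run <- function(dt) {
    tt <- seq(0, 6, by = dt)
    prot <- data.frame(t = tt, U = 0.1 * tt)
    run_protocol(prot, geom, p, mesh = mesh)$trace
  }
  a <- run(0.1); b <- run(0.05)
  Fb <- approx(b$t, b$F, xout = a$t)$y
  expect_lt(max(abs(a$F - Fb)) / max(a$F), 0.01)
})

test_that("fluid content change balances the boundary flux (global conservation)", {
  p <- avg_params()
  geom <- avg_geom()
  mesh <- coarse_mesh(geom)
  strict <- solver_settings(newton_rtol = 1e-12, atol_p = 1e-15,
                            incr_tol = 1e-15, max_newton = 60)
  bc <- boundary_spec(mesh)
  st <- field_state(mesh)
  attr(st, "control") <- list(U = 0)
  dr <- geom$R / mesh$nr; dz <- geom$L / mesh$nz
  w_ref <- dr * dz / 4 * 2 * pi  # times R_gp below
  U <- 0
  for (k in 1:3) {
    U <- U + 0.05
    st_new <- solve_step(st, mesh, bc, p, list(U = U), dt = 0.5,
                         settings = strict)
    gp <- attr(st_new, "gp")
    dV <- sum((st_new$Jgp - st$Jgp) * w_ref * gp[, "R"])
    p_rows <- 3 * (mesh$sets$outer - 1) + 3
    Q_out <- sum(attr(st_new, "res_int")[p_rows])
    expect_equal(dV / 0.5, Q_out, tolerance = 1e-8)
    st <- st_new
  }
})

test_that("tension dilates the tissue, drops the pore pressure and sucks fluid in", {
  p <- avg_params()
  geom <- avg_geom()
  mesh <- coarse_mesh(geom)
  tt <- seq(0, 8, by = 0.5)
  prot <- data.frame(t = tt, U = 0.1 * tt)
  resp <- run_protocol(prot, geom, p, mesh = mesh, record = "all")
  gp <- resp$fields[[length(tt)]]
  expect_true(all(gp[, "J"] > 1))
  interior <- gp[, "r"] < 0.8 * geom$R
  expect_true(all(gp[interior, "p"] < 0))
  # radial Darcy flux in the outermost Gauss points is inward (negative)
  outer_gp <- gp[, "R"] > 0.8 * geom$R
  expect_true(all(gp[outer_gp, "wr"] < 0))
})

test_that("the reaction-force trace is mesh-converged at 4 x 16", {
  p <- avg_params()
  geom <- avg_geom()
  tt <- seq(0, 12.8, by = 0.4)
  U <- pmin(0.1 * tt, 2 * 1.27 - 0.1 * tt)  # ramp to ~U20 and back down
  prot <- data.frame(t = tt, U = U)
  f1 <- run_protocol(prot, geom, p, mesh = build_mesh(geom, 4, 16))$trace$F
  f2 <- run_protocol(prot, geom, p, mesh = build_mesh(geom, 8, 32))$trace$F
  keep <- abs(f1) > 0.5
  expect_lt(max(abs(f1[keep] - f2[keep]) / abs(f1[keep])), 0.02)
})

test_that("the consolidation benchmark matches the analytic series within 2%", {
  tz <- terzaghi_benchmark()
  expect_lt(tz$error, 0.02)
  # early and late limits of the profile
  early <- terzaghi_benchmark(Tv_check = 0.01, n_steps = 60)
  base_p <- early$profiles[early$profiles$z < 0.2, ]
  expect_true(all(base_p$p_fe > 0.9 * 1e-3))  # undrained far from the drain
  late <- terzaghi_benchmark(Tv_check = 3, n_steps = 60)
  expect_true(all(abs(late$profiles$p_fe) < 0.05 * 1e-3))  # fully drained
})
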