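test_that("the objective is the segment-averaged mean squared force error", {
  prot <- triangle_protocol(3)
  prot <- segment_protocol(prot, expect = 6)
  n <- nrow(prot)
  ob <- calibration_objective(prot$F_exp, prot)
  expect_equal(ob$f, 0)
  ob <- calibration_objective(prot$F_exp + 0.3, prot)
  expect_equal(ob$f, 0.09, tolerance = 1e-12)
  expect_equal(ob$RMS, 0.3, tolerance = 1e-12)
  # hand-evaluated two-segment case: n = (2, 1), errors (1, 1) and (2)
  toy <- data.frame(t = 1:3, U = c(0, 1, 0.5), F_exp = c(0, 0, 0))
  attr(toy, "segments") <- list(1:2, 3L)
  ob <- calibration_objective(c(1, 1, 2), toy, expect_segments = 2)
  expect_equal(ob$f, 0.5 * (1 + 4))
  expect_equal(ob$per_segment, c(1, 4))
  expect_error(calibration_objective(c(1, 1, 2), toy), "expected 6")
})

test_that("the objective is invariant to segment order and within-segment resampling", {
  prot <- triangle_protocol(3)
  prot <- segment_protocol(prot)
  F_mod <- prot$F_exp + seq(-0.5, 0.5, length.out = nrow(prot))
  f1 <- calibration_objective(F_mod, prot)$f
  prot2 <- prot
  attr(prot2, "segments") <- rev(attr(prot, "segments"))
  expect_equal(calibration_objective(F_mod, prot2)$f, f1)
})

test_that("protocols segment at displacement reversals, robust to jitter", {
  expect_length(attr(segment_protocol(triangle_protocol(3)), "segments"), 6)
  ramp <- data.frame(t = 0:50, U = seq(0, 1, length.out = 51), F_exp = 0)
  expect_length(attr(segment_protocol(ramp), "segments"), 1)
  noisy <- triangle_protocol(3, jitter = 0.01)
  expect_length(attr(segment_protocol(noisy), "segments"), 6)
  segs <- attr(segment_protocol(noisy), "segments")
  expect_identical(sort(unlist(segs)), seq_len(nrow(noisy)))  # a partition
  expect_error(segment_protocol(triangle_protocol(2), expect = 6),
               "expected 6")
})

test_that("phase-domain averaging reproduces identities", {
  pr <- triangle_protocol(3, amp = 1, period = 10)
  # identical inputs: the average equals any input after resampling
  av <- average_protocol(list(pr, pr), cycles = 1:3)
  Ui <- approx(pr$t, pr$U, xout = av$t[av$t <= 10], rule = 2)$y
  expect_lt(max(abs(av$U[av$t <= 10] - Ui)), 0.02)
  expect_length(attr(av, "segments"), 6)
  # mirrored forces cancel
  pr2 <- pr; pr2$F_exp <- -pr2$F_exp
  av2 <- average_protocol(list(pr, pr2), cycles = 1:3)
  expect_equal(max(abs(av2$F_exp)), 0)
  # mean cycle duration: periods 2 s and 4 s average to 3 s
  pa <- triangle_protocol(1, period = 2, n_per_cycle = 50)
  pb <- triangle_protocol(1, period = 4, n_per_cycle = 50)
  av3 <- average_protocol(list(pa, pb), cycles = 1)
  expect_equal(max(av3$t) - min(av3$t), 3, tolerance = 0.02)
  expect_error(average_protocol(list(pa), cycles = 1:2), "cycle")
})

test_that("parameter transforms keep every candidate admissible", {
  p <- avg_params()
  free <- c("E1", "E2", "k1", "k2", "eta", "k0", "Mk", "Em", "num")
  th <- tendonpve:::param_transform(p, free)
  back <- tendonpve:::param_untransform(th, free, p)
  expect_equal(unclass(back)[free], unclass(p)[free], tolerance = 1e-12)
  set.seed(2)
  for (i in 1:50) {
    cand <- tendonpve:::param_untransform(th + rnorm(9, 0, 3), free, p)
    expect_silent(tendonpve:::validate_params(cand))
    expect_true(cand$num > 0 && cand$num < 0.5)
  }
})

test_that("with white force noise the optimal objective approaches the noise variance", {
  set.seed(9)
  s <- 0.25
  pr <- triangle_protocol(3, n_per_cycle = 2000)
  F_true <- pr$F_exp
  pr$F_exp <- F_true + rnorm(nrow(pr), 0, s)
  pr <- segment_protocol(pr)
  f <- calibration_objective(F_true, pr)$f
  expect_equal(f, s^2, tolerance = 0.05)
})

test_that("the Nelder-Mead loop recovers parameters of an analytic forward model", {
  # toy forward model: exponential force-displacement law in E1 and k1
  geom <- avg_geom()
  pr <- triangle_protocol(2, amp = 0.12, period = 2.4)
  truth <- avg_params()
  toy_forward <- function(params)
    params$E1 * expm1(pmin(params$k1 * pr$U, 200)) * geom$A
  pr$F_exp <- toy_forward(truth)
  pr <- segment_protocol(pr, expect = 4)
  init <- truth
  init$E1 <- truth$E1 * 3
  init$k1 <- truth$k1 / 2
  class(init) <- "tendon_params"
  prob <- calibration_problem(pr, geom, init, free = c("E1", "k1"),
                              tol = 1e-12)
  fit <- fit_calibration(prob, toy_forward, expect_segments = 4)
  expect_lt(fit$f, 1e-8)
  expect_equal(fit$params_hat$E1, truth$E1, tolerance = 1e-3)
  expect_equal(fit$params_hat$k1, truth$k1, tolerance = 1e-3)
  expect_true(all(diff(fit$trace) <= 0))
})

test_that("the fluid parameters are weakly identified by uniaxial tension", {
  # a tenfold change in k0 barely moves the objective of a tensile protocol
  p_true <- avg_params()
  geom <- avg_geom()
  mesh <- coarse_mesh(geom)
  zero_cvs <- setNames(rep(0, 9),
                       c("E1", "E2", "k1", "k2", "eta", "k0", "Mk", "Em", "num"))
  spec <- cohort_spec(n_specimens = 1, geom_cv = 0, param_cvs = zero_cvs,
                      noise_sd = 0, n_cycles = 1)
  prot <- generate_protocol(geom, p_true, spec, mesh = mesh, dt = 0.5)
  prot <- segment_protocol(prot, expect = 2)
  prob <- calibration_problem(prot, geom, p_true)
  fwd <- fe_forward_model(prob, mesh = mesh)
  p_k0 <- p_true
  p_k0$k0 <- 10 * p_true$k0
  class(p_k0) <- "tendon_params"
  f_true <- calibration_objective(fwd(p_true), prot, 2)$f
  f_k0 <- calibration_objective(fwd(p_k0), prot, 2)$f
  expect_lt(f_true, 1e-20)           # same grid, same solver: exact replay
  expect_lt(sqrt(f_k0), 0.05)        # RMS shift < 0.05 N on a 1-20 N signal
  # a fibre parameter of the same relative change moves the objective
  # orders of magnitude more
  p_E1 <- p_true
  p_E1$E1 <- 10 * p_true$E1
  class(p_E1) <- "tendon_params"
  f_E1 <- calibration_objective(fwd(p_E1), prot, 2)$f
  expect_gt(f_E1, 1e4 * max(f_k0, 1e-12))
})

test_that("forward-model failures are penalised, not fatal", {
  geom <- avg_geom()
  pr <- segment_protocol(triangle_protocol(3))
  init <- avg_params()
  prob <- calibration_problem(pr, geom, init, free = c("E1", "Em"),
                              tol = 1e-3, max_evals = 40)
  bad_forward <- function(params) stop("solver blew up")
  fit <- fit_calibration(prob, bad_forward)
  expect_equal(fit$f, 1e12)
})
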