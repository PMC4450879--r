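# shared fixtures: the average-tendon cycle 1-3 parameter set, small meshes,
# and synthetic protocols built in code

avg_params <- function() reference_params("average", "1-3")

avg_geom <- function() average_geometry()

coarse_mesh <- function(geom = avg_geom()) build_mesh(geom, 2, 8)

# triangle-wave displacement protocol (n_cycles periods), optional jitter
triangle_protocol <- function(n_cycles = 3, amp = 1, period = 10,
                              n_per_cycle = 40, jitter = 0, seed = 42) {
  tt <- seq(0, n_cycles * period, length.out = n_cycles * n_per_cycle + 1)
  ph <- (tt %% period) / period
  U <- amp * (2 * pmin(ph, 1 - ph))
  if (jitter > 0) {
    set.seed(seed)
    U <- U + rnorm(length(U), 0, jitter * amp)
  }
  data.frame(t = tt, U = U, F_exp = 10 * U)
}

# independent numerical push-forward of the strain energy:
# sigma = (1/J) dW/dF F^T, with dW/dF by central differences
fd_cauchy_from_energy <- function(F, mod, h = 1e-6) {
  P <- matrix(0, 3, 3)
  for (i in 1:3) {
    for (j in 1:3) {
      Fp <- F; Fm <- F
      Fp[i, j] <- Fp[i, j] + h
      Fm[i, j] <- Fm[i, j] - h
      P[i, j] <- (strain_energy(kinematics(Fp), mod) -
                  strain_energy(kinematics(Fm), mod)) / (2 * h)
    }
  }
  (P %*% t(F)) / det(F)
}

# random deformation gradient with J > 0, bounded distortion
random_F <- function() {
  repeat {
    F <- diag(3) + matrix(rnorm(9, 0, 0.15), 3, 3)
    if (det(F) > 0.3) return(F)
  }
}
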