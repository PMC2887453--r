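test_that("single-spring spectrum is five zeros and one mode at 2", {
  sp <- compute_modes(enm_hessian(spring_net()))
  expect_equal(sp$n_zero, 5L)
  expect_equal(sp$values, c(rep(0, 5), 2), tolerance = 1e-10)
})

test_that("a straight chain has extra zero modes from transverse bending", {
  # 3 beads, 2 springs: the 9x9 linearization leaves transverse bending
  # at zero stiffness, so 7 eigenvalues vanish; the two longitudinal
  # modes of the open chain sit at 1 and 3
  chain <- suppressWarnings(build_network(cbind(c(0, 3.8, 7.6), 0, 0),
                                          cutoff = 5))
  sp <- compute_modes(enm_hessian(chain))
  expect_equal(count_zero_modes(sp), 7L)
  expect_equal(sp$values[8:9], c(1, 3), tolerance = 1e-10)
})

test_that("an isolated particle contributes three extra zero modes", {
  pts <- rbind(coords(make_toy_chain(4, kind = "helix")), c(100, 100, 100))
  net <- suppressWarnings(build_network(pts, cutoff = 6))
  sp <- compute_modes(enm_hessian(net))
  expect_equal(count_zero_modes(sp), 9L)
})

test_that("mode spectra are orthonormal, complete and residual-free", {
  net <- oracle_networks()$hinge
  H <- enm_hessian(net)
  sp <- compute_modes(H)
  V <- sp$vectors
  expect_equal(sp$n_zero, 6L)
  expect_lt(max(abs(crossprod(V) - diag(ncol(V)))), 1e-8)
  expect_lt(max(abs(tcrossprod(V) - diag(nrow(V)))), 1e-8)
  expect_lt(max(abs(H %*% V - V %*% diag(sp$values))), 1e-8)
})

test_that("zero modes span exactly the rigid translations and rotations", {
  net <- oracle_networks()$two_valley
  sp <- compute_modes(enm_hessian(net))
  n <- net$n_particles
  cen <- sweep(net$R0, 2, colMeans(net$R0))
  rigid <- cbind(
    as.numeric(t(cbind(rep(1, n), 0, 0))),
    as.numeric(t(cbind(0, rep(1, n), 0))),
    as.numeric(t(cbind(0, 0, rep(1, n)))),
    as.numeric(t(cbind(0, -cen[, 3], cen[, 2]))),   # infinitesimal rotations
    as.numeric(t(cbind(cen[, 3], 0, -cen[, 1]))),
    as.numeric(t(cbind(-cen[, 2], cen[, 1], 0)))
  )
  Z <- sp$vectors[, seq_len(sp$n_zero), drop = FALSE]
  # every rigid motion lies in the zero subspace ...
  resid <- rigid - Z %*% crossprod(Z, rigid)
  expect_lt(max(abs(resid)) / max(abs(rigid)), 1e-7)
  # ... and the two subspaces have equal dimension, hence coincide
  expect_equal(qr(rigid)$rank, 6L)
  expect_equal(sp$n_zero, 6L)
})

test_that("single-mode deviations decay exponentially at their eigenvalue", {
  net <- oracle_networks()$hinge
  sp <- compute_modes(enm_hessian(net))
  alpha <- sp$n_zero + 3L
  lam <- sp$values[alpha]
  c0 <- 0.05
  dev <- c0 * matrix(sp$vectors[, alpha], net$n_particles, 3, byrow = TRUE)
  times <- seq(0, 5, length.out = 11)
  tr <- linear_mode_relaxation(sp, net, dev, times)
  amp <- vapply(tr$frames, function(fr) sqrt(sum((fr - net$R0)^2)),
                numeric(1))
  expect_equal(amp, c0 * exp(-lam * times), tolerance = 1e-10)
  # t -> infinity returns the reference
  far <- linear_mode_relaxation(sp, net, dev, c(0, 1e6))
  expect_lt(max(abs(far$frames[[2]] - net$R0)), 1e-12)
})

test_that("linear and nonlinear relaxation agree to second order in amplitude", {
  net <- oracle_networks()$hinge
  sp <- compute_modes(enm_hessian(net))
  times <- c(0, 1, 5, 10, 20)
  err_at <- function(amp) {
    set.seed(31)
    dev <- matrix(rnorm(3 * net$n_particles), ncol = 3)
    # project out rigid motions, scale to the requested RMSD
    v <- as.numeric(t(dev))
    Z <- sp$vectors[, seq_len(sp$n_zero)]
    v <- v - Z %*% crossprod(Z, v)
    dev <- matrix(v, net$n_particles, 3, byrow = TRUE)
    dev <- dev * amp / sqrt(mean(rowSums(dev^2)))
    lin <- linear_mode_relaxation(sp, net, dev, times)
    non <- relax(net, net$R0 + dev, t_max = max(times), n_frames = 21,
                 schedule = "linear", force_tol = 1e-12)
    max(vapply(seq_along(times), function(k) {
      kk <- which.min(abs(non$times - times[k]))
      stopifnot(abs(non$times[kk] - times[k]) < 1e-9)
      max(abs(lin$frames[[k]] - non$frames[[kk]]))
    }, numeric(1)))
  }
  e_small <- err_at(0.005)
  e_large <- err_at(0.010)
  expect_lt(e_small, 1e-4)
  # quadratic scaling: doubling the amplitude quadruples the error
  expect_gt(e_large / e_small, 3)
  expect_lt(e_large / e_small, 5)
})

test_that("soft-mode energy is quadratic in its amplitude", {
  net <- oracle_networks()$hinge
  sp <- compute_modes(enm_hessian(net))
  lam1 <- sp$values[sp$n_zero + 1L]
  e1 <- matrix(sp$vectors[, sp$n_zero + 1L], net$n_particles, 3, byrow = TRUE)
  for (c0 in c(0.01, 0.05)) {
    E <- elastic_energy(net, net$R0 + c0 * e1)
    expect_equal(E, 0.5 * lam1 * c0^2, tolerance = 0.01)
  }
})

test_that("soft-mode direction reflects first-order label distance changes", {
  # hand-built geometry: particle A moves directly away from B; C far, still
  pts <- rbind(c(0, 0, 0), c(4, 0, 0), c(4, 4, 0), c(0, 4, 0))
  net <- suppressWarnings(build_network(pts, cutoff = 6))
  fake_vec <- matrix(0, 12, 12)
  mode <- rbind(c(-1, 0, 0), c(0, 0, 0), c(0, 0, 0), c(0, 0, 0))
  fake_vec[, 7] <- as.numeric(t(mode)) # slot 7 = first "nonzero" mode
  fake <- structure(list(values = c(rep(0, 6), 1, rep(10, 5)),
                         vectors = fake_vec, zero_tol = 1e-8, n_zero = 6L),
                    class = "mode_spectrum")
  dir1 <- soft_mode_distance_direction(fake, net, c(1, 2, 3))
  expect_equal(abs(dir1), c(1, 0), tolerance = 1e-12)

  # mode perpendicular to both monitored bonds: degenerate direction
  mode2 <- rbind(c(0, 0, 1), c(0, 0, 0), c(0, 0, 0), c(0, 0, 0))
  fake$vectors[, 7] <- as.numeric(t(mode2))
  expect_warning(dir2 <- soft_mode_distance_direction(fake, net, c(1, 2, 3)),
                 "unchanged")
  expect_equal(dir2, c(0, 0))
})

test_that("a near-degenerate soft mode triggers a warning", {
  net <- suppressWarnings(build_network(rbind(c(0, 0, 0), c(4, 0, 0),
                                              c(4, 4, 0), c(0, 4, 0)),
                                        cutoff = 6))
  fake_vec <- matrix(0, 12, 12)
  mode <- rbind(c(-1, 0, 0), c(0, 0, 0), c(0, 0, 0), c(0, 0, 0))
  fake_vec[, 7] <- as.numeric(t(mode))
  fake <- structure(list(values = c(rep(0, 6), 1, 1.01, rep(10, 4)),
                         vectors = fake_vec, zero_tol = 1e-8, n_zero = 6L),
                    class = "mode_spectrum")
  expect_warning(soft_mode_distance_direction(fake, net, c(1, 2, 3)),
                 "degenerate")
})
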