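test_that("label distances are plain Euclidean distances per frame", {
  fr <- rbind(c(0, 0, 0), c(3, 4, 0), c(3, 4, 12))
  traj <- structure(list(times = 0, frames = list(fr), energies = 0,
                         converged = TRUE, force_tol = 1e-8),
                    class = "relax_trajectory")
  tr <- label_distance_series(traj, c(1, 2, 3))
  expect_equal(tr$l_AB, 5)
  expect_equal(tr$l_BC, 12)
})

test_that("the spring's monitored distance decreases monotonically to d0", {
  net <- spring_net()
  traj <- relax(net, spring_conf(1.5), t_max = 20, n_frames = 80)
  # a 2-particle system: monitor the spring itself via duplicated-endpoint
  d <- vapply(traj$frames, function(fr) sqrt(sum((fr[1, ] - fr[2, ])^2)),
              numeric(1))
  expect_true(all(diff(d) < 0))
  expect_equal(d[length(d)], 1, tolerance = 1e-7)
})

test_that("the mechanical coordinate reproduces the spring's closed form", {
  net <- spring_net()
  traj <- relax(net, spring_conf(1.5), t_max = 25, n_frames = 200)
  prof <- mechanical_coordinate(traj)
  # single soft mode at lambda = 2: E(s) = (lambda/2) s^2 = s^2
  expect_lt(max(abs(prof$E - prof$s^2)), 1e-6)
  expect_true(all(diff(prof$s) <= 0))
  expect_gte(min(prof$s), 0)
  expect_lt(prof$s[length(prof$s)], 1e-6)

  # starting at the reference the profile is the single point (0, 0)
  p0 <- mechanical_coordinate(relax(net, net$R0, t_max = 5))
  expect_equal(nrow(p0), 1L)
  expect_equal(p0$s, 0)
  expect_equal(p0$E, 0)
})

test_that("arc-length and energy-flux estimators of s agree", {
  net <- oracle_networks()$helix
  set.seed(8)
  start <- net$R0 + matrix(rnorm(3 * net$n_particles, sd = 0.2), ncol = 3)
  traj <- relax(net, start, t_max = 2000, n_frames = 600)
  s_arc <- mechanical_coordinate(traj)$s
  s_flux <- mechanical_coordinate(traj, net, method = "energy-flux")$s
  expect_lt(max(abs(s_arc - s_flux)) / max(s_arc), 1e-3)
})

test_that("s is insensitive to the sampling density", {
  net <- oracle_networks()$helix
  set.seed(9)
  start <- net$R0 + matrix(rnorm(3 * net$n_particles, sd = 0.2), ncol = 3)
  dense <- relax(net, start, t_max = 2000, n_frames = 800)
  coarse <- relax(net, start, t_max = 2000, n_frames = 400)
  s_d <- mechanical_coordinate(dense)
  s_c <- mechanical_coordinate(coarse)
  expect_lt(abs(max(s_d$s) - max(s_c$s)) / max(s_d$s), 1e-3)
})

test_that("nonconverged trajectories have no defined mechanical coordinate", {
  hx <- make_two_domain_hinge(n = 16, angle = 20)
  net <- suppressWarnings(build_network(hx$reference, cutoff = 10))
  short <- relax(net, coords(hx$deformed), t_max = 0.5)
  expect_error(mechanical_coordinate(short), "converge")
})

test_that("quadratic well fits recover known curvatures", {
  # exact parabola
  prof <- structure(data.frame(time = 0:50, s = seq(1, 0, length.out = 51),
                               E = 3 * seq(1, 0, length.out = 51)^2),
                    class = c("energy_profile", "data.frame"))
  fit <- fit_quadratic_well(prof, s_window = 2)
  expect_equal(fit$k, 3, tolerance = 1e-12)
  expect_equal(fit$harmonic_radius, 1)

  # single spring: k = lambda1 / 2 = 1
  net <- spring_net()
  traj <- relax(net, spring_conf(1.5), t_max = 25, n_frames = 200)
  fitsp <- fit_quadratic_well(mechanical_coordinate(traj), s_window = 0.3)
  expect_equal(fitsp$k, 1, tolerance = 1e-4)

  expect_error(fit_quadratic_well(prof, s_window = 1e-9), "at least 5")
})

test_that("the fitted well curvature matches the soft mode on the hinge", {
  hx <- make_two_domain_hinge(n = 40, angle = 25)
  net <- suppressWarnings(build_network(hx$reference, cutoff = 10))
  sp <- compute_modes(enm_hessian(net))
  lam1 <- sp$values[sp$n_zero + 1L]
  traj <- relax(net, coords(hx$deformed), t_max = 2000, n_frames = 200)
  prof <- mechanical_coordinate(traj)
  fit <- fit_quadratic_well(prof, s_window = 0.3 * max(prof$s))
  expect_equal(fit$k, lam1 / 2, tolerance = 0.05)

  # the late-time trace tangent aligns with the soft-mode direction
  dir1 <- soft_mode_distance_direction(sp, net, hx$labels)
  tr <- label_distance_series(traj, hx$labels)
  n <- nrow(tr)
  tang <- c(tr$l_AB[n - 8] - tr$l_AB[n], tr$l_BC[n - 8] - tr$l_BC[n])
  tang <- tang / sqrt(sum(tang^2))
  angle <- acos(min(1, abs(sum(tang * dir1)))) * 180 / pi
  expect_lt(angle, 5)
})

test_that("identical traces give zero dispersion and no branching", {
  tr <- structure(data.frame(time = 0:20,
                             l_AB = seq(10, 5, length.out = 21),
                             l_BC = seq(3, 8, length.out = 21)),
                  class = c("distance_trace", "data.frame"))
  bd <- bundle_dispersion(list(tr, tr, tr, tr))
  expect_true(all(bd$dispersion == 0))
  expect_false(bd$branched)

  far <- tr
  far$l_AB <- far$l_AB + 10
  expect_error(bundle_dispersion(list(tr, far)), "endpoint")
})

test_that("the two-valley fixture branches and merges near the endpoint", {
  tv <- make_two_valley_network()
  net <- suppressWarnings(build_network(tv$structure, tv$cutoff))
  starts <- c(
    lapply(1:8, function(k) random_rms_displacement(tv$near_start, 0.25,
                                                    seed = 800 + k)),
    lapply(1:8, function(k) random_rms_displacement(tv$side_start, 0.25,
                                                    seed = 900 + k))
  )
  trajs <- lapply(starts, function(st) relax(net, st, t_max = 500))
  classes <- vapply(trajs, classify_endpoint, character(1), net = net)
  expect_true(all(classes == "reference"))
  traces <- lapply(trajs, label_distance_series, labels = tv$labels)
  bd <- bundle_dispersion(traces)
  expect_true(bd$branched)
  expect_lte(bd$merge_progress, 0.25)
})
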