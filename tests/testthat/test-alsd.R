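test_that("config validation enforces the lambda range contract", {
  expect_error(alsd_config(lambda_min = 1.1, lambda_max = 1.2), "lambda",
               class = "alsdyn_config_error")
  expect_error(alsd_config(m_lambda = 0), "m_lambda",
               class = "alsdyn_config_error")
  expect_true(alsd_config(lambda_min = 1, lambda_max = 1)$fix_lambda)
  expect_false(alsd_config()$fix_lambda)
})

test_that("Hamiltonian potential follows the lambda-scaled arithmetic", {
  cfg <- alsd_config()
  b0 <- zero_bias(cfg)
  d <- structure(list(e_tail = 2, e_tail_rest = 3, e_rest = 5),
                 class = "energy_decomposition")
  # identity at lambda = 1, zero bias, inside the walls
  expect_equal(hamiltonian_potential(d, 1, b0, cfg), 10)
  # the stated worked value at lambda = 0.6
  expect_equal(hamiltonian_potential(d, 0.6, b0, cfg), 7.52)
  # gauge: a constant added to ln_p shifts the potential by RT * const
  bc <- bias_estimate(b0$lambda_grid, b0$ln_p + 2.5)
  for (lam in c(0.65, 0.9, 1.02))
    expect_equal(hamiltonian_potential(d, lam, bc, cfg) -
                   hamiltonian_potential(d, lam, b0, cfg),
                 rt_energy(cfg) * 2.5, tolerance = 1e-12)
  # far outside the walls is an integration blow-up signal
  expect_error(hamiltonian_potential(d, 2.0, b0, cfg),
               class = "alsdyn_numerical_error")
})

test_that("lambda force matches a finite difference of the potential", {
  cfg <- alsd_config()
  set.seed(1)
  b <- bias_estimate(zero_bias(cfg)$lambda_grid,
                     cumsum(rnorm(cfg$n_bins, sd = 0.3)))
  d <- structure(list(e_tail = 4.2, e_tail_rest = -7.7, e_rest = 1),
                 class = "energy_decomposition")
  h <- 1e-6
  for (lam in c(0.62, 0.8, 0.97, 1.045)) {  # interior, knot region, wall
    fd <- -(hamiltonian_potential(d, lam + h, b, cfg) -
              hamiltonian_potential(d, lam - h, b, cfg)) / (2 * h)
    expect_equal(lambda_force(d, lam, b, cfg), fd, tolerance = 1e-6)
  }
  # zero when nothing couples to lambda
  d0 <- structure(list(e_tail = 0, e_tail_rest = 0, e_rest = 9),
                  class = "energy_decomposition")
  expect_equal(lambda_force(d0, 0.8, zero_bias(cfg), cfg), 0)
  # positive e_tail pushes lambda down
  dpos <- structure(list(e_tail = 3, e_tail_rest = 0, e_rest = 0),
                    class = "energy_decomposition")
  expect_lt(lambda_force(dpos, 0.9, zero_bias(cfg), cfg), 0)
})

test_that("bias estimates are validated and interpolate smoothly", {
  expect_error(bias_estimate(c(1, 0.9)), "increasing",
               class = "alsdyn_config_error")
  expect_error(bias_estimate(c(0.6, 1), c(0, NaN)), "finite",
               class = "alsdyn_config_error")
  b <- bias_estimate(seq(0.6, 1.03, length.out = 10),
                     sin(seq(0, 3, length.out = 10)))
  # interpolant passes through the knots; derivative is finite everywhere
  at <- bias_at(b, b$lambda_grid)
  expect_equal(at$value, b$ln_p, tolerance = 1e-12)
  dense <- bias_at(b, seq(0.55, 1.08, length.out = 400))
  expect_true(all(is.finite(dense$value)) && all(is.finite(dense$deriv)))
  # value/derivative continuity across a knot
  eps <- 1e-9
  k <- b$lambda_grid[5]
  expect_equal(bias_at(b, k - eps)$value, bias_at(b, k + eps)$value,
               tolerance = 1e-6)
  expect_equal(bias_at(b, k - eps)$deriv, bias_at(b, k + eps)$deriv,
               tolerance = 1e-4)
})

test_that("stepping is deterministic and damps toward minima without noise", {
  sys <- small_toy()
  cfg <- alsd_config(n_steps = 200L, save_interval = 50L)
  b <- zero_bias(cfg)
  set.seed(42); s1 <- init_state(sys, cfg)
  s1 <- step_langevin(s1, sys, b, cfg, n_steps = 200)
  set.seed(42); s2 <- init_state(sys, cfg)
  s2 <- step_langevin(s2, sys, b, cfg, n_steps = 200)
  expect_identical(s1$positions, s2$positions)
  expect_identical(s1$lambda, s2$lambda)
  # high friction + zero noise: potential energy decreases from a strained start
  cfg0 <- alsd_config(noise_scale = 0, friction = 5, lambda_min = 1,
                      lambda_max = 1)
  set.seed(1)
  pos <- sys$positions
  ti <- tail_indices(sys)
  pos[ti, ] <- pos[ti, ] + matrix(rnorm(length(ti) * 3, sd = 0.6), length(ti))
  e0 <- total_energy(energy_decomposition(sys, pos))
  st <- init_state(sys, cfg0, positions = pos)
  st$velocities[] <- 0
  st <- step_langevin(st, sys, zero_bias(cfg0), cfg0, n_steps = 400)
  e1 <- total_energy(energy_decomposition(sys, st$positions))
  expect_lt(e1, e0)
})

test_that("an uncoupled harmonic bead equilibrates to RT/k", {
  hs <- harmonic_test_system(k = 2)
  cfg <- alsd_config(lambda_min = 1, lambda_max = 1, timestep = 0.02,
                     n_steps = 400000L, save_interval = 40L)
  tr <- run_production(hs, cfg, zero_bias(cfg), seed = 5, n_equil = 5000)
  expect_equal(var(tr$frames[, 1]), rt_energy(cfg) / 2, tolerance = 0.05)
})

test_that("adaptation returns a flat bias for a flat target", {
  fb <- free_bead_system()
  cfg <- alsd_config(timestep = 0.02)
  b <- adapt_bias(fb, cfg, n_iterations = 8, steps_per_iteration = 50000,
                  seed = 9, flatness_threshold = 0.9)
  expect_lt(max(b$ln_p) - min(b$ln_p), 0.35)
  expect_gte(utils::tail(b$flatness, 1), 0.5)
})

test_that("adaptation recovers -ln lambda on the 1-D harmonic system", {
  hs <- harmonic_test_system(k = 2)
  cfg <- alsd_config(timestep = 0.02)
  b <- adapt_bias(hs, cfg, n_iterations = 12, steps_per_iteration = 100000,
                  seed = 11, flatness_threshold = 0.85)
  target <- -log(b$lambda_grid)
  resid <- (b$ln_p - mean(b$ln_p)) - (target - mean(target))
  expect_lt(sqrt(mean(resid^2)), 0.1)
  # flatness improves in expectation: late iterations beat the first
  expect_gt(mean(utils::tail(b$flatness, 2)), b$flatness[1])
})

test_that("adaptation diagnoses an immobile lambda walker", {
  hs <- harmonic_test_system(k = 2)
  # an absurdly heavy lambda cannot leave its starting bin in a short run
  cfg <- alsd_config(m_lambda = 1e8)
  expect_error(adapt_bias(hs, cfg, n_iterations = 2,
                          steps_per_iteration = 200, seed = 1),
               "one histogram bin", class = "alsdyn_numerical_error")
})

test_that("production trajectories are self-consistent and seeded", {
  sys <- small_toy()
  cfg <- alsd_config(n_steps = 0L)
  tr0 <- run_production(sys, cfg, zero_bias(cfg), seed = 1)
  expect_equal(n_frames(tr0), 1)
  cfg <- alsd_config(n_steps = 3000L, save_interval = 300L)
  b <- zero_bias(cfg)
  tr <- run_production(sys, cfg, b, seed = 8)
  expect_equal(n_frames(tr), 11)
  # stored energies recompute from stored positions
  for (i in c(1, 5, 11)) {
    d <- energy_decomposition(sys, frame_positions(tr, i))
    expect_equal(d$e_tail, tr$e_tail[i], tolerance = 1e-8)
    expect_equal(d$e_tail_rest, tr$e_tail_rest[i], tolerance = 1e-8)
  }
  # metadata carries the bias hash and seed
  expect_identical(tr$meta$bias_hash, b$hash)
  expect_identical(tr$meta$seed, 8L)
  expect_identical(run_production(sys, cfg, b, seed = 8)$frames, tr$frames)
})

test_that("identical trajectories under a gauge-shifted bias", {
  # the bias enters the dynamics only through its derivative, so adding a
  # constant must reproduce the run bit for bit; reweighting against each
  # run's own bias then yields identical weights
  sys <- small_toy()
  cfg <- alsd_config(n_steps = 2000L, save_interval = 200L)
  b1 <- zero_bias(cfg)
  b2 <- bias_estimate(b1$lambda_grid, b1$ln_p + 4.2)
  t1 <- run_production(sys, cfg, b1, seed = 3)
  t2 <- run_production(sys, cfg, b2, seed = 3)
  expect_identical(t1$frames, t2$frames)
  w1 <- reweight(t1, b1, cfg)$weights
  w2 <- reweight(t2, b2, cfg)$weights
  expect_equal(w1, w2, tolerance = 1e-12)
})

test_that("TTP runs are independent, seeded, and preserve failures", {
  sys <- small_toy()
  cfg <- alsd_config(n_steps = 2000L, save_interval = 200L)
  b <- zero_bias(cfg)
  expect_error(run_ttp(sys, cfg, b, n_runs = 1), "n_runs",
               class = "alsdyn_config_error")
  a <- run_ttp(sys, cfg, b, n_runs = 4, base_seed = 5)
  bb <- run_ttp(sys, cfg, b, n_runs = 4, base_seed = 5)
  expect_identical(lapply(a, `[[`, "frames"), lapply(bb, `[[`, "frames"))
  seeds <- vapply(a, function(t) t$meta$seed, integer(1))
  expect_equal(length(unique(seeds)), 4)
  # distinct initial conformations
  first_frames <- lapply(a, frame_positions, i = 1)
  for (i in 1:3) expect_gt(sqrt(mean((first_frames[[i + 1]] -
                                        first_frames[[1]])^2)), 0)
  # per-run means differ (nonzero between-run variance)
  ti <- tail_indices(sys)
  rg <- vapply(a, function(t) mean(vapply(seq_len(n_frames(t)), function(i)
    radius_of_gyration(frame_positions(t, i)[ti, ]), numeric(1))), numeric(1))
  expect_gt(sd(rg), 0)
})
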