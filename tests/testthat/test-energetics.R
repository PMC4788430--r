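test_that("Debye length matches an SI closed-form evaluation", {
  # independent route: kappa^-1 = sqrt(eps0 epsr kB T / (2 NA e^2 I)), SI
  eps0 <- 8.8541878128e-12; kB <- 1.380649e-23; NA_ <- 6.02214076e23
  e <- 1.602176634e-19
  si <- function(I, T, epsr)
    sqrt(eps0 * epsr * kB * T / (2 * NA_ * e^2 * I * 1000)) * 1e10
  expect_equal(debye_length(0.153, 300, 80), si(0.153, 300, 80),
               tolerance = 1e-4)
  expect_equal(debye_length(0.153, 300, 80), 7.875, tolerance = 0.01)
  # quadrupling the ionic strength halves the screening length
  expect_equal(debye_length(0.153 * 4, 300, 80),
               debye_length(0.153, 300, 80) / 2, tolerance = 1e-12)
  expect_identical(debye_length(0.1, 310, 78), debye_length(0.1, 310, 78))
  expect_error(debye_length(-1), class = "alsdyn_config_error")
})

test_that("relaxed, uncharged, separated configurations have zero energy", {
  cfg <- small_toy_config(charge_pattern = 2L)
  sys <- build_tail_scaffold_system(cfg)
  sys$charges[] <- 0
  # the built default conformation: straight tail at rest bond lengths,
  # pointing away from the scaffold
  d <- energy_decomposition(sys)
  expect_equal(d$e_tail, 0, tolerance = 1e-10)
  # only the tether bond could contribute; it is at rest length too
  expect_equal(d$e_tail_rest, 0, tolerance = 1e-10)
})

test_that("screened-Coulomb pair term matches the hand closed form", {
  par <- forcefield_params()
  s2 <- pair_system(q = c(1, -1), region = c("TAIL", "REST"), sep = 10)
  d <- energy_decomposition(s2, params = par)
  kq <- par$coulomb_constant / par$dielectric
  expected <- kq * (-1) * (exp(-par$kappa * 10) / 10 -
                             exp(-par$kappa * par$cutoff) / par$cutoff)
  expect_equal(d$e_tail_rest, expected, tolerance = 1e-12)
  expect_equal(d$e_tail, 0)
  expect_equal(d$e_rest, 0)
})

test_that("decomposition matches the brute-force oracle and sums to total", {
  set.seed(7)
  cfg <- toy_system_config(n_tail_beads = 6, charge_pattern = c(2, 4, 6),
                           n_scaffold = 4, scaffold_geometry = "straight")
  sys <- build_tail_scaffold_system(cfg)
  par <- forcefield_params()
  for (rep in 1:3) {
    pos <- sys$positions + matrix(rnorm(length(sys$positions), sd = 0.4),
                                  nrow(sys$positions))
    d <- energy_decomposition(sys, pos, par)
    o <- oracle_decomp(sys, pos, par)
    expect_equal(d$e_tail, o$et, tolerance = 1e-10)
    expect_equal(d$e_tail_rest, o$etr, tolerance = 1e-10)
    expect_equal(d$e_rest, o$er, tolerance = 1e-10)
    expect_equal(total_energy(d), o$et + o$etr + o$er, tolerance = 1e-10)
  }
})

test_that("coincident beads raise an error", {
  s2 <- pair_system(sep = 5)
  pos <- s2$positions
  pos[2, ] <- pos[1, ]
  expect_error(energy_decomposition(s2, pos), "coincident")
})

test_that("forces are the negative gradient of the scaled potential", {
  set.seed(21)
  cfg <- toy_system_config(n_tail_beads = 6, charge_pattern = c(2, 4, 6),
                           n_scaffold = 4, scaffold_geometry = "straight")
  sys <- build_tail_scaffold_system(cfg)
  par <- forcefield_params()
  pos <- sys$positions + matrix(rnorm(length(sys$positions), sd = 0.15),
                                nrow(sys$positions))
  h <- 1e-5
  for (lam in c(1, 0.72)) {
    f <- cg_forces(sys, pos, lam, par)
    scaled <- function(p) {
      d <- energy_decomposition(sys, p, par)
      lam^2 * d$e_tail + lam * d$e_tail_rest + d$e_rest
    }
    num <- matrix(0, nrow(pos), 3)
    for (i in which(sys$mobile)) for (k in 1:3) {
      pp <- pos; pp[i, k] <- pp[i, k] + h
      pm <- pos; pm[i, k] <- pm[i, k] - h
      num[i, k] <- -(scaled(pp) - scaled(pm)) / (2 * h)
    }
    scale <- max(abs(num))
    expect_lt(max(abs(num - f$forces)) / scale, 1e-5)
    # immobile beads carry zero force
    expect_true(all(f$forces[!sys$mobile, ] == 0))
  }
})

test_that("tail-internal pair force scales as lambda squared", {
  par <- forcefield_params()
  s2 <- pair_system(q = c(1, 1), sep = 6)   # TAIL-TAIL, electrostatics only
  f1 <- cg_forces(s2, lambda = 1, params = par)$forces
  f06 <- cg_forces(s2, lambda = 0.6, params = par)$forces
  expect_equal(f06, 0.36 * f1, tolerance = 1e-12)
  # cross pair scales as lambda
  sx <- pair_system(q = c(1, -1), region = c("TAIL", "REST"), sep = 6)
  sx$mobile <- c(TRUE, TRUE)
  fx1 <- cg_forces(sx, lambda = 1, params = par)$forces
  fx06 <- cg_forces(sx, lambda = 0.6, params = par)$forces
  expect_equal(fx06, 0.6 * fx1, tolerance = 1e-12)
})

test_that("Newton's third law holds for every interaction term", {
  par <- forcefield_params()
  cases <- list(pair_system(q = c(1, 1), sep = 6),              # Coulomb
                pair_system(sep = 3.5),                         # WCA overlap
                pair_system(bonded = TRUE, sep = 5, r0 = 4))    # stretched bond
  for (s2 in cases) {
    f <- cg_forces(s2, params = par)$forces
    expect_equal(colSums(f), c(0, 0, 0), tolerance = 1e-12)
    expect_gt(max(abs(f)), 0)  # the case actually exercises a force
  }
})

test_that("energy is invariant under rigid motions and e_rest under tail moves", {
  set.seed(5)
  sys <- small_toy()
  par <- forcefield_params()
  pos <- sys$positions + matrix(rnorm(length(sys$positions), sd = 0.2),
                                nrow(sys$positions))
  e0 <- total_energy(energy_decomposition(sys, pos, par))
  # translation
  e1 <- total_energy(energy_decomposition(sys, pos + 13.7, par))
  expect_equal(e1, e0, tolerance = 1e-9)
  # rotation about z by 40 degrees
  th <- 40 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  e2 <- total_energy(energy_decomposition(sys, pos %*% t(R), par))
  expect_equal(e2, e0, tolerance = 1e-9)
  # e_rest constant when only TAIL beads move
  er0 <- energy_decomposition(sys, pos, par)$e_rest
  pos2 <- pos
  pos2[tail_indices(sys), ] <- pos2[tail_indices(sys), ] +
    matrix(rnorm(3 * sys$n_tail), sys$n_tail)
  expect_equal(energy_decomposition(sys, pos2, par)$e_rest, er0)
})
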