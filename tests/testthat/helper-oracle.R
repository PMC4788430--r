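# Independent oracles, deliberately coded apart from the package's
# compiled path: a plain-R brute-force energy decomposition, an R force
# routine, and a pure-R BAOAB Langevin integrator at lambda = 1.

oracle_pair_energy <- function(qi, qj, ri, rj, d, params) {
  e <- 0
  s <- ri + rj
  if (d < s * 2^(1 / 6)) {
    sr6 <- (s / d)^6
    e <- e + 4 * params$wca_epsilon * (sr6^2 - sr6) + params$wca_epsilon
  }
  if (qi * qj != 0 && d < params$cutoff) {
    kq <- params$coulomb_constant / params$dielectric
    e <- e + kq * qi * qj * (exp(-params$kappa * d) / d -
                               exp(-params$kappa * params$cutoff) / params$cutoff)
  }
  e
}

oracle_decomp <- function(system, pos, params) {
  n <- nrow(pos)
  bonded <- paste(pmin(system$bond_i, system$bond_j),
                  pmax(system$bond_i, system$bond_j))
  et <- etr <- er <- 0
  add <- function(acc, i, j, e) {
    cls <- sum(system$region[c(i, j)] == "REST")
    if (cls == 0) acc$et <- acc$et + e
    else if (cls == 1) acc$etr <- acc$etr + e
    else acc$er <- acc$er + e
    acc
  }
  acc <- list(et = 0, etr = 0, er = 0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (paste(i, j) %in% bonded) next
    d <- sqrt(sum((pos[i, ] - pos[j, ])^2))
    e <- oracle_pair_energy(system$charges[i], system$charges[j],
                            system$radii[i], system$radii[j], d, params)
    acc <- add(acc, i, j, e)
  }
  for (b in seq_along(system$bond_i)) {
    i <- system$bond_i[b]; j <- system$bond_j[b]
    d <- sqrt(sum((pos[i, ] - pos[j, ])^2))
    acc <- add(acc, i, j, 0.5 * params$bond_k * (d - system$bond_r0[b])^2)
  }
  for (r in seq_along(system$restraint_bead)) {
    i <- system$restraint_bead[r]
    dv <- pos[i, system$restraint_dim[r]] - system$restraint_x0[r]
    e <- 0.5 * system$restraint_k[r] * dv^2
    if (system$region[i] == "TAIL") acc$et <- acc$et + e else acc$er <- acc$er + e
  }
  acc
}

# vectorized R forces at lambda = 1 (for the plain-MD oracle)
oracle_forces_l1 <- function(system, pos, params) {
  n <- nrow(pos)
  f <- matrix(0, n, 3)
  kq <- params$coulomb_constant / params$dielectric
  d2 <- as.matrix(dist(pos))^2
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (any(system$bond_i == i & system$bond_j == j) ||
        any(system$bond_i == j & system$bond_j == i)) next
    d <- sqrt(d2[i, j])
    dEdr <- 0
    s <- system$radii[i] + system$radii[j]
    if (d < s * 2^(1 / 6)) {
      sr6 <- (s / d)^6
      dEdr <- dEdr + 4 * params$wca_epsilon * (-12 * sr6^2 + 6 * sr6) / d
    }
    qq <- system$charges[i] * system$charges[j]
    if (qq != 0 && d < params$cutoff) {
      ed <- kq * qq * exp(-params$kappa * d) / d
      dEdr <- dEdr - ed * (params$kappa + 1 / d)
    }
    if (dEdr != 0) {
      g <- -dEdr / d * (pos[i, ] - pos[j, ])
      f[i, ] <- f[i, ] + g
      f[j, ] <- f[j, ] - g
    }
  }
  for (b in seq_along(system$bond_i)) {
    i <- system$bond_i[b]; j <- system$bond_j[b]
    dvec <- pos[i, ] - pos[j, ]
    d <- sqrt(sum(dvec^2))
    g <- -params$bond_k * (d - system$bond_r0[b]) / d * dvec
    f[i, ] <- f[i, ] + g
    f[j, ] <- f[j, ] - g
  }
  for (r in seq_along(system$restraint_bead)) {
    i <- system$restraint_bead[r]; dd <- system$restraint_dim[r]
    f[i, dd] <- f[i, dd] - system$restraint_k[r] *
      (pos[i, dd] - system$restraint_x0[r])
  }
  f[!system$mobile, ] <- 0
  f
}

# pure-R BAOAB at fixed lambda = 1; returns per-saved-frame total potential
oracle_md_l1 <- function(system, params, n_steps, dt = 0.01, gamma = 0.1,
                         temperature = 300, save_interval = 100,
                         n_equil = 0) {
  kT <- 1.98720e-3 * temperature
  n <- nrow(system$positions)
  pos <- system$positions
  mob <- system$mobile
  vel <- matrix(rnorm(3 * n, sd = sqrt(kT)), n, 3)
  vel[!mob, ] <- 0
  c1 <- exp(-gamma * dt)
  c2 <- sqrt(1 - c1^2)
  f <- oracle_forces_l1(system, pos, params)
  e_saved <- numeric(0)
  for (step in seq_len(n_steps + n_equil)) {
    vel[mob, ] <- vel[mob, ] + 0.5 * dt * f[mob, ]
    pos[mob, ] <- pos[mob, ] + 0.5 * dt * vel[mob, ]
    vel[mob, ] <- c1 * vel[mob, ] +
      c2 * sqrt(kT) * matrix(rnorm(3 * sum(mob)), sum(mob), 3)
    pos[mob, ] <- pos[mob, ] + 0.5 * dt * vel[mob, ]
    f <- oracle_forces_l1(system, pos, params)
    vel[mob, ] <- vel[mob, ] + 0.5 * dt * f[mob, ]
    if (step > n_equil && (step - n_equil) %% save_interval == 0) {
      d <- oracle_decomp(system, pos, params)
      e_saved <- c(e_saved, d$et + d$etr + d$er)
    }
  }
  e_saved
}

# closed-form accessible area of each of two equal expanded spheres of
# radius R whose centers are d apart (d < 2R): 4 pi R^2 - 2 pi R h with
# cap height h = R - d/2
two_sphere_area <- function(R, d) 4 * pi * R^2 - 2 * pi * R * (R - d / 2)
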