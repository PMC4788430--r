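# The two-sphere closed form used throughout: two equal expanded spheres of
# radius R at center distance d < 2R each lose a spherical cap of height
# R - d/2, so the accessible area per sphere is 4 pi R^2 - 2 pi R (R - d/2).

test_that("isolated spheres recover the analytic sphere area exactly", {
  p <- sasa_params()
  a1 <- sasa(matrix(0, 1, 3), 1.7, p)
  expect_equal(a1, 4 * pi * (1.7 + 1.4)^2, tolerance = 1e-12)
  expect_equal(a1, 120.76, tolerance = 1e-4)
  # two carbons 100 Angstrom apart: no burial
  a2 <- sasa(rbind(c(0, 0, 0), c(100, 0, 0)), c(1.7, 1.7), p)
  expect_equal(a2, rep(4 * pi * 3.1^2, 2), tolerance = 1e-12)
})

test_that("two-sphere burial matches the spherical-cap closed form", {
  R <- 1.7 + 1.4
  for (d in c(2.0, 3.5, 5.0)) {
    a <- sasa(rbind(c(0, 0, 0), c(d, 0, 0)), c(1.7, 1.7),
              sasa_params(n_sphere_points = 3840L))
    expect_equal(a[1], two_sphere_area(R, d), tolerance = 5e-3)
    expect_equal(a[2], two_sphere_area(R, d), tolerance = 5e-3)
  }
})

test_that("point-count convergence: 960 vs 3840", {
  set.seed(42)
  n <- 20
  xyz <- matrix(runif(3 * n, 0, 12), n, 3)
  el <- sample(c("C", "N", "O", "P"), n, replace = TRUE)
  radmap <- c(C = 1.70, N = 1.625, O = 1.48, P = 1.87)
  a960 <- sasa(xyz, radmap[el], sasa_params(n_sphere_points = 960L))
  a3840 <- sasa(xyz, radmap[el], sasa_params(n_sphere_points = 3840L))
  expect_lt(max(abs(a960 - a3840) / pmax(a3840, 1)), 0.02)
  # two-sphere case tighter than 0.5%
  t960 <- sasa(rbind(c(0, 0, 0), c(3.5, 0, 0)), c(1.7, 1.7),
               sasa_params(n_sphere_points = 960L))
  t3840 <- sasa(rbind(c(0, 0, 0), c(3.5, 0, 0)), c(1.7, 1.7),
                sasa_params(n_sphere_points = 3840L))
  expect_lt(max(abs(t960 - t3840) / t3840), 0.005)
})

test_that("SASA agrees with an independent Shrake-Rupley implementation", {
  # expected values computed once with biotite (Python) at 5000 points on
  # the same coordinates, radii and probe; frozen here
  set.seed(42)
  n <- 20
  xyz <- matrix(runif(3 * n, 0, 12), n, 3)
  el <- sample(c("C", "N", "O", "P"), n, replace = TRUE)
  radmap <- c(C = 1.70, N = 1.625, O = 1.48, P = 1.87)
  biotite <- c(70.2115, 39.7176, 90.9342, 80.8381, 79.1362, 51.7456,
               75.7852, 79.6529, 27.7356, 35.2869, 40.2696, 18.6990,
               77.9173, 66.8553, 97.3507, 63.2618, 87.0217, 110.4980,
               45.3344, 31.0398)
  ours <- sasa(xyz, radmap[el], sasa_params(n_sphere_points = 3840L))
  expect_equal(sum(ours), sum(biotite), tolerance = 2e-3)
  expect_lt(max(abs(ours - biotite) / biotite), 0.01)
})

test_that("CSA behaves as DNA surface loss caused by the tail", {
  p <- sasa_params(n_sphere_points = 960L)
  # a tail sphere 200 Angstrom away buries nothing
  coords <- rbind(c(200, 0, 0), c(0, 0, 0), c(4, 0, 0))
  expect_equal(csa(coords, c(2, 2, 2), 1, 2:3, p), 0, tolerance = 1e-9)
  # one tail sphere contacting one DNA sphere: the cap closed form
  R <- 2 + 1.4
  d <- 4
  coords2 <- rbind(c(d, 0, 0), c(0, 0, 0))
  v <- csa(coords2, c(2, 2), 1, 2, p)
  expect_equal(v, 4 * pi * R^2 - two_sphere_area(R, d), tolerance = 0.02)
  # definitional identity: burial equals total SASA loss of the DNA set
  without_tail <- sasa(coords2[2, , drop = FALSE], 2, p)
  with_tail <- sasa(coords2, c(2, 2), p)[2]
  expect_equal(v, without_tail - with_tail, tolerance = 1e-12)
  expect_gte(v, 0)
  expect_error(csa(coords2, c(2, 2), integer(0), 2, p), "empty",
               class = "alsdyn_config_error")
  expect_error(csa(coords2, c(2, 2), 1, 1, p), "disjoint",
               class = "alsdyn_config_error")
})

test_that("csa_structure handles selections, hydrogens and both contexts", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0, "C"),
    pdb_line(2, "HA", "ALA", "A", 1, 1, 0, 0, "H"),
    pdb_line(3, "P", "DA", "D", 1, 3.2, 0, 0, "P"),
    pdb_line(4, "O5'", "DA", "D", 1, 6.0, 0.5, 0, "O"),
    pdb_line(5, "CB", "GLY", "B", 9, 0, 8, 0, "C"),
    "END"), p)
  s <- read_pdb(p)
  v_all <- csa_structure(s, "chain A", "nucleic and heavy")
  # hydrogens excluded: the H at (1,0,0) must not shield the phosphate
  expect_gt(v_all, 0)
  v_pair <- csa_structure(s, "chain A", "nucleic and heavy", context = "pair")
  # chain B far away: both conventions agree here
  expect_equal(v_all, v_pair, tolerance = 0.5)
  expect_error(csa_structure(s, "resid 99", "nucleic"), "empty",
               class = "alsdyn_config_error")
})

test_that("radius of gyration closed forms", {
  expect_equal(radius_of_gyration(matrix(c(3, 4, 5), 1, 3)), 0)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0))), 1)
  sq <- rbind(c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0))
  expect_equal(radius_of_gyration(sq), sqrt(2), tolerance = 1e-12)
  # mass weighting moves the centroid
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0)),
                                  masses = c(3, 1)),
               sqrt((3 * 0.5^2 + 1 * 1.5^2) / 4), tolerance = 1e-12)
  expect_error(radius_of_gyration(sq, masses = rep(0, 4)), "mass",
               class = "alsdyn_config_error")
})

test_that("Kabsch superposition recovers constructed rigid transforms", {
  set.seed(9)
  cloud <- matrix(rnorm(30), 10, 3)
  # identity
  sr <- kabsch_superpose(cloud, cloud)
  expect_equal(sr$rmsd, 0, tolerance = 1e-10)
  expect_equal(sr$rotation, diag(3), tolerance = 1e-8)
  # pure translation
  sr_t <- kabsch_superpose(cloud, cloud + rep(c(3, -1, 7), each = 10))
  expect_equal(sr_t$rmsd, 0, tolerance = 1e-10)
  expect_equal(sr_t$rotation, diag(3), tolerance = 1e-8)
  expect_equal(sr_t$translation, c(3, -1, 7), tolerance = 1e-8)
  # known 30-degree rotation about z
  th <- 30 * pi / 180
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  ref <- cloud %*% t(Rz)
  sr_r <- kabsch_superpose(cloud, ref)
  expect_equal(sr_r$rotation, Rz, tolerance = 1e-8)
  expect_equal(sr_r$rmsd, 0, tolerance = 1e-8)
  expect_equal(det(sr_r$rotation), 1, tolerance = 1e-10)
  expect_equal(apply_superposition(sr_r, cloud), ref, tolerance = 1e-8)
  # invariance of the rmsd under a global pre-rotation of both sets
  noisy <- ref + matrix(rnorm(30, sd = 0.3), 10, 3)
  r1 <- kabsch_superpose(cloud, noisy)$rmsd
  r2 <- kabsch_superpose(cloud %*% t(Rz), noisy %*% t(Rz))$rmsd
  expect_equal(r1, r2, tolerance = 1e-9)
  # degenerate collinear sets refuse
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear",
               class = "alsdyn_config_error")
})

test_that("per-position contact matches a brute-force recount", {
  sys <- small_toy()
  ti <- tail_indices(sys)
  ri <- rest_indices(sys)
  groups <- list(`0` = ri[1:2], `1` = ri[3:4], `2` = ri[5:6])
  set.seed(31)
  frames <- lapply(1:5, function(i) {
    pos <- sys$positions
    pos[ti, ] <- pos[ti, ] + matrix(rnorm(length(ti) * 3, sd = 3), length(ti))
    pos
  })
  w <- c(0.4, 0.1, 0.2, 0.2, 0.1)
  we <- fake_ensemble(frames, w)
  res <- per_position_contact(we, sys, ti, groups, pad = 2.8)
  # brute force
  brute <- vapply(groups, function(g) {
    sum(w * vapply(frames, function(pos) {
      hit <- FALSE
      for (a in ti) for (b in g) {
        cut <- sys$radii[a] + sys$radii[b] + 2.8
        if (sum((pos[a, ] - pos[b, ])^2) <= cut^2) hit <- TRUE
      }
      as.numeric(hit)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(res$mean, unname(brute), tolerance = 1e-12)
  # far away: all zero
  far <- lapply(frames, function(pos) { pos[ti, 2] <- pos[ti, 2] + 200; pos })
  res_far <- per_position_contact(fake_ensemble(far, w), sys, ti, groups)
  expect_equal(res_far$mean, rep(0, 3))
  # permanent contact at position 0 only
  expect_equal(res$position, c("0", "1", "2"))
  expect_error(per_position_contact(we, sys, ti, list(g = integer(0))),
               "empty", class = "alsdyn_config_error")
})

test_that("contact ratio flags burial against the scaffold", {
  sys <- small_toy()
  ti <- tail_indices(sys)
  ri <- rest_indices(sys)
  p <- sasa_params(n_sphere_points = 240L)
  # frame A: tail in its built position touching nothing; frame B: first
  # tail bead wedged against a scaffold bead
  posA <- sys$positions
  posA[ti, 2] <- posA[ti, 2] + 100
  posB <- sys$positions
  posB[ti[1], ] <- sys$positions[ri[1], ] + c(0, sum(sys$radii[c(ti[1], ri[1])]) * 0.9, 0)
  we <- fake_ensemble(list(posA, posB), c(0.5, 0.5))
  res <- contact_ratio(we, sys, ti[1], ri, p, threshold = 0.1)
  expect_equal(res$mean, 0.5, tolerance = 1e-12)
  # always far: 0; always wedged: 1
  expect_equal(contact_ratio(fake_ensemble(list(posA)), sys, ti[1], ri, p)$mean, 0)
  expect_equal(contact_ratio(fake_ensemble(list(posB)), sys, ti[1], ri, p)$mean, 1)
  # frame-by-frame recount with the burial definition
  keep <- setdiff(seq_len(nrow(posB)), ri)
  a_without <- sasa(posB[keep, , drop = FALSE], sys$radii[keep], p)[match(ti[1], keep)]
  a_with <- sasa(posB, sys$radii, p)[ti[1]]
  expect_gt(a_without - a_with, 0.1)
})

test_that("exposure ratio is relative to the extended reference", {
  sys <- small_toy()
  ti <- tail_indices(sys)
  p <- sasa_params(n_sphere_points = 960L)
  # isolated bead: ratio 1 against the isolated-sphere reference
  pos_iso <- sys$positions
  pos_iso[ti, ] <- pos_iso[ti, ] + 500  # whole tail far away; bead 1 isolated?
  pos_iso[ti[1], ] <- c(1000, 1000, 1000)
  we <- fake_ensemble(list(pos_iso))
  res <- exposure_ratio(we, sys, ti[1], params = p)
  expect_equal(res$mean, 1, tolerance = 1e-9)
  expect_false(res$flagged)
  # half-buried two-sphere construction equals the cap form over 4 pi R^2
  d <- 3
  R <- sys$radii[ti[1]] + p$probe_radius
  pos_half <- pos_iso
  pos_half[ti[2], ] <- pos_half[ti[1], ] + c(d, 0, 0)
  res_half <- exposure_ratio(fake_ensemble(list(pos_half)), sys, ti[1],
                             params = p)
  expect_equal(res_half$mean, two_sphere_area(R, d) / (4 * pi * R^2),
               tolerance = 5e-3)
  expect_error(exposure_ratio(we, sys, ti[1], reference_sasa = 0, params = p),
               class = "alsdyn_config_error")
})

test_that("density grids count weighted occupancy and subtract cleanly", {
  sys <- small_toy()
  origin <- c(-1, -1, -1)
  frames <- list(matrix(c(0, 0, 0), 1, 3), matrix(c(2.5, 0, 0), 1, 3),
                 matrix(c(0, 2.5, 0), 1, 3))
  mk <- function(w) fake_ensemble(frames, w)
  g <- density_grid(mk(c(1, 0, 0)), 1, origin, spacing = 2, dims = c(3, 3, 3))
  expect_equal(g$counts[1, 1, 1], 1)
  expect_equal(sum(g$counts), 1)
  # linearity in the weights
  g2 <- density_grid(mk(c(2, 0, 0)), 1, origin, spacing = 2, dims = c(3, 3, 3))
  expect_equal(g2$counts, 2 * g$counts)
  # brute-force tally over three weighted frames
  w <- c(0.2, 0.3, 0.5)
  g3 <- density_grid(mk(w), 1, origin, spacing = 2, dims = c(3, 3, 3))
  expect_equal(g3$counts[1, 1, 1], 0.2)
  expect_equal(g3$counts[2, 1, 1], 0.3)
  expect_equal(g3$counts[1, 2, 1], 0.5)
  expect_equal(sum(g3$counts), sum(w))
  # out-of-grid atoms go to the overflow bin with a warning
  expect_warning(
    go <- density_grid(mk(c(0, 0, 1)), 1, origin, spacing = 2,
                       dims = c(1, 1, 1)),
    "overflow")
  expect_equal(go$overflow, 1)
  # differences: self-zero, conservation, antisymmetry
  d0 <- density_difference(g3, g3)
  expect_true(all(d0$counts == 0))
  gb <- density_grid(mk(c(0.6, 0.2, 0.2)), 1, origin, 2, c(3, 3, 3))
  dd <- density_difference(g3, gb)
  expect_equal(sum(dd$counts), 0, tolerance = 1e-12)
  expect_equal(dd$counts, -density_difference(gb, g3)$counts)
  bad <- density_grid(mk(c(1, 0, 0)), 1, origin, 2, c(2, 2, 2))
  expect_error(density_difference(g3, bad), "shape",
               class = "alsdyn_config_error")
  # text export round-trip of the nonzero voxels
  path <- withr::local_tempfile(fileext = ".txt")
  write_density_grid(g3, path, dx_path = withr::local_tempfile(fileext = ".dx"))
  tab <- read.table(path, header = TRUE, comment.char = "#")
  expect_equal(sum(tab$value), sum(g3$counts), tolerance = 1e-9)
})

test_that("backbone dihedrals recover constructed geometry", {
  n <- 8
  helix <- build_backbone(rep(-60, n), rep(-45, n))
  dh <- backbone_dihedrals(helix)
  expect_true(all(abs(dh$phi[2:n] - (-60)) < 0.1))
  expect_true(all(abs(dh$psi[1:(n - 1)] - (-45)) < 0.1))
  # terminal angles undefined
  expect_true(is.na(dh$phi[1]))
  expect_true(is.na(dh$psi[n]))
  # mirroring negates the dihedrals
  mirror <- helix
  mirror$models[[1]][, 3] <- -mirror$models[[1]][, 3]
  dhm <- backbone_dihedrals(mirror)
  expect_equal(dhm$phi[2:n], -dh$phi[2:n], tolerance = 1e-8)
  expect_equal(dhm$psi[1:(n - 1)], -dh$psi[1:(n - 1)], tolerance = 1e-8)
})

test_that("helix content applies the window and run-length rule", {
  n <- 10
  helix <- build_backbone(rep(-60, n), rep(-45, n))
  strand <- build_backbone(rep(-120, n), rep(120, n))
  run1 <- list(structures = list(helix), weights = 1)
  hc <- helix_content(run1)
  # interior residues of an ideal helix are fully helical
  expect_true(all(hc$mean[3:(n - 2)] == 1))
  hc_s <- helix_content(list(structures = list(strand), weights = 1))
  expect_true(all(hc_s$mean == 0))
  # a 3-residue helical stretch flanked by strand fails the run rule
  phi <- c(rep(-120, 3), rep(-60, 3), rep(-120, 4))
  psi <- c(rep(120, 3), rep(-45, 3), rep(120, 4))
  mixed <- build_backbone(phi, psi)
  hc_m <- helix_content(list(structures = list(mixed), weights = 1))
  expect_true(all(hc_m$mean == 0))
  # weighted average over frames, SE across runs
  runs <- list(list(structures = list(helix, strand), weights = c(0.75, 0.25)),
               list(structures = list(helix, strand), weights = c(0.25, 0.75)))
  hc2 <- helix_content(runs)
  expect_equal(hc2$mean[5], 0.5, tolerance = 1e-12)
  expect_equal(hc2$n_runs[1], 2)
})

test_that("pair distance distributions match per-frame recomputation", {
  sys <- small_toy()
  posA <- sys$positions
  posB <- sys$positions
  posB[1, ] <- posB[1, ] + c(4, 0, 0)
  # static ensemble at a fixed 10 Angstrom separation
  st <- sys$positions
  st[1, ] <- st[2, ] + c(10, 0, 0)
  res_static <- pair_distance_distribution(
    list(fake_ensemble(list(st)), fake_ensemble(list(st))),
    site_pairs = list(c(1, 2)))
  expect_equal(res_static[[1]]$summary[["mean"]], 10, tolerance = 1e-9)
  expect_equal(res_static[[1]]$summary[["se"]], 0, tolerance = 1e-12)
  # two equally weighted frames at 8 and 12
  f8 <- sys$positions; f8[1, ] <- f8[2, ] + c(8, 0, 0)
  f12 <- sys$positions; f12[1, ] <- f12[2, ] + c(12, 0, 0)
  res <- pair_distance_distribution(fake_ensemble(list(f8, f12)),
                                    site_pairs = list(c(1, 2)))
  expect_equal(res[[1]]$summary[["mean"]], 10, tolerance = 1e-9)
  # brute-force check on 5 random frames
  set.seed(4)
  frames <- lapply(1:5, function(i)
    sys$positions + matrix(rnorm(length(sys$positions)), nrow(sys$positions)))
  w <- runif(5); w <- w / sum(w)
  res5 <- pair_distance_distribution(fake_ensemble(frames, w),
                                     site_pairs = list(c(3, 17)))
  brute <- sum(w * vapply(frames, function(p)
    sqrt(sum((p[3, ] - p[17, ])^2)), numeric(1)))
  expect_equal(res5[[1]]$summary[["mean"]], brute, tolerance = 1e-12)
  expect_equal(sum(res5[[1]]$histogram$mass), 1)
})
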