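# Synthetic coarse-grained tail-on-scaffold systems: a flexible cationic
# chain (the histone-tail stand-in) tethered to a rigid anionic scaffold
# (the DNA stand-in), plus the acetylation perturbation and self-avoiding
# initial-conformation generation for TTP runs.

#' Configuration for the synthetic tail-on-scaffold system
#'
#' The defaults describe a 40-bead tail (one bead per residue of an H3
#' N-terminal tail) carrying +1 charges at the lysine/arginine-like
#' positions 2, 4, 8, 9, 14, 17, 18, 23, 26, 27, 36, 37 and 40, tethered to
#' a rigid scaffold of two parallel strands of phosphate-like -1 beads laid
#' out along an arc with a 3.4 Angstrom axial rise per position (a wrapped
#' double-helix backbone at bead resolution).
#'
#' @param n_tail_beads number of tail beads (>= 2)
#' @param charge_pattern integer positions (1-based, 1 = free N-terminal end)
#'   of the +1 tail beads
#' @param n_scaffold total number of scaffold beads across both strands
#' @param scaffold_geometry `"arc"` (wrapped) or `"straight"` (rod; simpler
#'   geometry for tests)
#' @param scaffold_charge per-bead scaffold charge in elementary units
#' @param bead_radius tail bead radius (Angstrom)
#' @param scaffold_radius scaffold bead radius (Angstrom)
#' @param bond_length tail bond rest length (Angstrom)
#' @param arc_radius radius of the scaffold arc (Angstrom)
#' @param axial_rise spacing between scaffold positions along the arc/rod
#' @param strand_offset half-distance between the two strands (Angstrom)
#' @param tether_index scaffold bead (1-based within the scaffold) to which
#'   tail bead `n_tail_beads` is anchored; default the middle of strand one
#' @param seed integer seed recorded with the system
#' @return an object of class `toy_system_config`
#' @export
toy_system_config <- function(n_tail_beads = 40L,
                              charge_pattern = c(2L, 4L, 8L, 9L, 14L, 17L, 18L,
                                                 23L, 26L, 27L, 36L, 37L, 40L),
                              n_scaffold = 60L,
                              scaffold_geometry = c("arc", "straight"),
                              scaffold_charge = -1,
                              bead_radius = 2.0,
                              scaffold_radius = 2.5,
                              bond_length = 3.8,
                              arc_radius = 41.5,
                              axial_rise = 3.4,
                              strand_offset = 5.0,
                              tether_index = NULL,
                              seed = 1L) {
  scaffold_geometry <- match.arg(scaffold_geometry)
  if (!is.numeric(n_tail_beads) || n_tail_beads < 2)
    abort_config("n_tail_beads must be >= 2", "n_tail_beads")
  if (!is.numeric(n_scaffold) || n_scaffold < 1)
    abort_config("scaffold bead count must be >= 1", "n_scaffold")
  if (bead_radius <= 0) abort_config("bead_radius must be > 0", "bead_radius")
  if (scaffold_radius <= 0) abort_config("scaffold_radius must be > 0", "scaffold_radius")
  if (bond_length <= 0) abort_config("bond_length must be > 0", "bond_length")
  if (any(charge_pattern < 1 | charge_pattern > n_tail_beads))
    abort_config("charge_pattern positions out of tail range", "charge_pattern")
  n_pos <- ceiling(n_scaffold / 2)
  if (is.null(tether_index)) tether_index <- as.integer(ceiling(n_pos / 2))
  if (tether_index < 1 || tether_index > n_scaffold)
    abort_config("tether_index out of scaffold range", "tether_index")
  structure(list(
    n_tail_beads = as.integer(n_tail_beads),
    charge_pattern = as.integer(sort(unique(charge_pattern))),
    n_scaffold = as.integer(n_scaffold),
    scaffold_geometry = scaffold_geometry,
    scaffold_charge = as.numeric(scaffold_charge),
    bead_radius = as.numeric(bead_radius),
    scaffold_radius = as.numeric(scaffold_radius),
    bond_length = as.numeric(bond_length),
    arc_radius = as.numeric(arc_radius),
    axial_rise = as.numeric(axial_rise),
    strand_offset = as.numeric(strand_offset),
    tether_index = as.integer(tether_index),
    seed = as.integer(seed)), class = "toy_system_config")
}

scaffold_coords <- function(config) {
  n <- config$n_scaffold
  n_pos <- ceiling(n / 2)
  pos_idx <- c(seq_len(n_pos), seq_len(n - n_pos))       # strand A then B
  strand  <- rep(c(1, -1), c(n_pos, n - n_pos))
  centered <- pos_idx - (n_pos + 1) / 2
  if (config$scaffold_geometry == "arc") {
    theta <- centered * config$axial_rise / config$arc_radius
    cbind(config$arc_radius * cos(theta),
          config$arc_radius * sin(theta),
          strand * config$strand_offset)
  } else {
    cbind(centered * config$axial_rise,
          rep(0, n),
          strand * config$strand_offset)
  }
}

#' Build the synthetic tail-on-scaffold system
#'
#' The tail (region TAIL, mobile) is a flexible chain whose last bead is
#' bonded to one scaffold bead; the scaffold (region REST) is rigid,
#' immobile and uniformly charged.  The returned default conformation is a
#' straight tail pointing away from the scaffold; use
#' [initial_conformations()] for diverse starting points.
#'
#' @param config a [toy_system_config()]
#' @return an object of class `cg_system` with fields `positions` (N x 3),
#'   `charges`, `radii`, `region` ("TAIL"/"REST"), `mobile`, bond and
#'   restraint tables, and `n_tail`
#' @export
build_tail_scaffold_system <- function(config = toy_system_config()) {
  if (!inherits(config, "toy_system_config"))
    abort_config("config must be a toy_system_config")
  nt <- config$n_tail_beads
  ns <- config$n_scaffold
  scaf <- scaffold_coords(config)
  tether_global <- nt + config$tether_index
  tp <- scaf[config$tether_index, ]
  # outward direction: radially away from the arc center; perpendicular to
  # the rod for the straight geometry
  if (config$scaffold_geometry == "arc") {
    ctr <- colMeans(scaf)
    u <- c(tp[1] - ctr[1], tp[2] - ctr[2], 0)
    nu <- sqrt(sum(u^2))
    u <- if (nu < 1e-8) c(0, 1, 0) else u / nu
  } else {
    u <- c(0, 1, 0)
  }
  tail <- t(vapply(seq_len(nt), function(k) {
    tp + u * ((nt - k + 1) * config$bond_length)
  }, numeric(3)))
  positions <- rbind(tail, scaf)
  charges <- c(ifelse(seq_len(nt) %in% config$charge_pattern, 1, 0),
               rep(config$scaffold_charge, ns))
  radii <- c(rep(config$bead_radius, nt), rep(config$scaffold_radius, ns))
  region <- c(rep("TAIL", nt), rep("REST", ns))
  mobile <- c(rep(TRUE, nt), rep(FALSE, ns))
  bond_i <- c(seq_len(nt - 1L), nt)
  bond_j <- c(seq_len(nt - 1L) + 1L, tether_global)
  bond_r0 <- rep(config$bond_length, nt)
  new_cg_system(positions, charges, radii, region, mobile,
                bond_i, bond_j, bond_r0, n_tail = nt, config = config)
}

new_cg_system <- function(positions, charges, radii, region, mobile,
                          bond_i = integer(0), bond_j = integer(0),
                          bond_r0 = numeric(0),
                          restraints = data.frame(bead = integer(0),
                                                  dim = integer(0),
                                                  k = numeric(0),
                                                  x0 = numeric(0)),
                          n_tail = sum(region == "TAIL"), config = NULL) {
  n <- nrow(positions)
  stopifnot(length(charges) == n, length(radii) == n, length(region) == n,
            length(mobile) == n, length(bond_i) == length(bond_j),
            length(bond_i) == length(bond_r0))
  if (length(bond_i)) {
    if (any(bond_i == bond_j) || any(c(bond_i, bond_j) < 1) ||
        any(c(bond_i, bond_j) > n))
      abort_config("bonds must connect two distinct in-range beads", "bonds")
  }
  if (any(radii <= 0)) abort_config("all radii must be > 0", "radii")
  if (!all(region %in% c("TAIL", "REST")))
    abort_config("region labels must be TAIL or REST", "region")
  structure(list(
    positions = unname(as.matrix(positions)),
    charges = as.numeric(charges),
    radii = as.numeric(radii),
    region = region,
    region_code = ifelse(region == "TAIL", 0L, 1L),
    mobile = as.logical(mobile),
    bond_i = as.integer(bond_i), bond_j = as.integer(bond_j),
    bond_r0 = as.numeric(bond_r0),
    restraint_bead = as.integer(restraints$bead),
    restraint_dim = as.integer(restraints$dim),
    restraint_k = as.numeric(restraints$k),
    restraint_x0 = as.numeric(restraints$x0),
    n_tail = as.integer(n_tail),
    config = config), class = "cg_system")
}

#' @export
print.cg_system <- function(x, ...) {
  cat(sprintf("<cg_system> %d beads (%d TAIL, %d REST), %d bonds, total charge %+g\n",
              nrow(x$positions), sum(x$region == "TAIL"),
              sum(x$region == "REST"), length(x$bond_i), sum(x$charges)))
  invisible(x)
}

#' Indices of the tail beads of a system
#' @param system a `cg_system`
#' @return integer vector
#' @export
tail_indices <- function(system) which(system$region == "TAIL")

#' Indices of the scaffold (REST) beads of a system
#' @param system a `cg_system`
#' @return integer vector
#' @export
rest_indices <- function(system) which(system$region == "REST")

#' Neutralize tail bead charges (the acetylation perturbation)
#'
#' Lysine acetylation removes the side-chain positive charge; here the
#' listed tail beads get charge 0 (and optionally a slightly larger radius
#' for the added acetyl group).  Idempotent; the input is not modified.
#'
#' @param system a `cg_system`
#' @param bead_indices tail bead indices to neutralize (may be empty)
#' @param radius_increment added to the radius of each listed bead
#' @return the perturbed `cg_system`
#' @export
apply_acetylation <- function(system, bead_indices, radius_increment = 0) {
  if (!inherits(system, "cg_system")) abort_config("system must be a cg_system")
  bead_indices <- as.integer(bead_indices)
  if (length(bead_indices) == 0) return(system)
  if (any(bead_indices < 1 | bead_indices > nrow(system$positions)) ||
      any(system$region[bead_indices] != "TAIL"))
    abort_config("bead_indices must all be TAIL beads", "bead_indices")
  out <- system
  already <- out$charges[bead_indices] == 0
  out$charges[bead_indices] <- 0
  out$radii[bead_indices[!already]] <-
    out$radii[bead_indices[!already]] + radius_increment
  out
}

#' One-bead harmonic test system
#'
#' A single mobile TAIL bead in a one-dimensional harmonic well
#' \eqn{E_{tail} = k x^2 / 2} (y and z are free and carry no potential).
#' Under ALSD the canonical marginal of \eqn{\lambda} for this system is
#' proportional to \eqn{1/\lambda}, and the converged umbrella bias is
#' \eqn{\ln P(\lambda) = -\ln\lambda + const}; at fixed \eqn{\lambda = 1},
#' equipartition gives \eqn{\langle x^2\rangle = RT/k}.  These closed forms
#' anchor the sampler's validation suite.
#'
#' @param k harmonic force constant (kcal/mol/Angstrom^2)
#' @param x0 well center (Angstrom)
#' @return a `cg_system`
#' @export
harmonic_test_system <- function(k = 2.0, x0 = 0) {
  if (k <= 0) abort_config("k must be > 0", "k")
  new_cg_system(positions = matrix(c(x0, 0, 0), 1, 3),
                charges = 0, radii = 1, region = "TAIL", mobile = TRUE,
                restraints = data.frame(bead = 1L, dim = 1L, k = k, x0 = x0))
}

#' Generate diverse self-avoiding initial tail conformations
#'
#' Regrows the tail from its scaffold anchor as a self-avoiding random walk
#' with fixed bond length (minimum separation 0.95 of contact distance),
#' leaving the scaffold untouched.  Reproducible from `seed`.
#'
#' @param system a `cg_system` with a tethered tail
#' @param n number of conformations (>= 1)
#' @param seed integer seed
#' @param max_restarts placement restarts per conformation before erroring
#' @return a list of `n` full N x 3 coordinate matrices
#' @export
initial_conformations <- function(system, n, seed = 1L, max_restarts = 200L) {
  if (!inherits(system, "cg_system")) abort_config("system must be a cg_system")
  if (n < 1) abort_config("n must be >= 1", "n")
  nt <- system$n_tail
  tail_idx <- tail_indices(system)
  if (length(tail_idx) < 1) abort_config("system has no TAIL beads")
  bl <- if (length(system$bond_r0)) system$bond_r0[1] else 3.8
  # the anchor: the non-tail partner of the tether bond, if there is one
  cross <- which(xor(system$region[system$bond_i] == "TAIL",
                     system$region[system$bond_j] == "TAIL"))
  anchor <- NA_integer_
  if (length(cross)) {
    tb <- cross[1]
    anchor <- if (system$region[system$bond_i[tb]] == "TAIL")
      system$bond_j[tb] else system$bond_i[tb]
    anchor_pos <- system$positions[anchor, ]
  } else {
    anchor_pos <- system$positions[tail_idx[nt], ] + c(bl, 0, 0)
  }
  fixed_idx <- which(!system$mobile)
  fixed_pos <- system$positions[fixed_idx, , drop = FALSE]
  fixed_rad <- system$radii[fixed_idx]
  tail_rad <- system$radii[tail_idx]
  set.seed(as.integer(seed))
  lapply(seq_len(n), function(run) {
    for (attempt in seq_len(max_restarts)) {
      placed <- matrix(NA_real_, nt, 3)
      prev <- anchor_pos
      ok <- TRUE
      for (k in rev(seq_len(nt))) {       # grow from the anchored end outward
        good <- FALSE
        for (try in 1:60) {
          u <- rnorm(3); u <- u / sqrt(sum(u^2))
          cand <- prev + u * bl
          clash <- FALSE
          if (nrow(fixed_pos)) {
            keep <- if (k == nt && !is.na(anchor)) fixed_idx != anchor
                    else rep(TRUE, nrow(fixed_pos))
            if (any(keep)) {
              d2 <- colSums((t(fixed_pos[keep, , drop = FALSE]) - cand)^2)
              lim <- 0.95 * (fixed_rad[keep] + tail_rad[k])
              if (any(d2 < lim^2)) clash <- TRUE
            }
          }
          if (!clash && k + 2 <= nt) {
            prior <- placed[(k + 2):nt, , drop = FALSE]
            d2 <- colSums((t(prior) - cand)^2)
            lim <- 0.95 * (tail_rad[(k + 2):nt] + tail_rad[k])
            if (any(d2 < lim^2)) clash <- TRUE
          }
          if (!clash) { good <- TRUE; break }
        }
        if (!good) { ok <- FALSE; break }
        placed[k, ] <- cand
        prev <- cand
      }
      if (ok) {
        pos <- system$positions
        pos[tail_idx, ] <- placed
        return(pos)
      }
    }
    abort_numerical(sprintf(
      "self-avoiding placement failed after %d restarts (conformation %d)",
      max_restarts, run))
  })
}

# -- structured-text serialization -------------------------------------------

#' Write a `cg_system` to a structured text file
#'
#' Versioned plain-text format: a header, a bead table, a bond table and a
#' restraint table.  Round-trips with [read_cg_system()].
#'
#' @param system a `cg_system`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_cg_system <- function(system, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# alsdyn cg_system",
               "format_version: 1",
               sprintf("n_beads: %d", nrow(system$positions)),
               sprintf("n_tail: %d", system$n_tail),
               "beads: idx x y z charge radius region mobile"), con)
  for (i in seq_len(nrow(system$positions)))
    writeLines(sprintf("%d %.8f %.8f %.8f %.8f %.8f %s %d", i,
                       system$positions[i, 1], system$positions[i, 2],
                       system$positions[i, 3], system$charges[i],
                       system$radii[i], system$region[i],
                       as.integer(system$mobile[i])), con)
  writeLines("bonds: i j r0", con)
  for (b in seq_along(system$bond_i))
    writeLines(sprintf("%d %d %.8f", system$bond_i[b], system$bond_j[b],
                       system$bond_r0[b]), con)
  writeLines("restraints: bead dim k x0", con)
  for (r in seq_along(system$restraint_bead))
    writeLines(sprintf("%d %d %.8f %.8f", system$restraint_bead[r],
                       system$restraint_dim[r], system$restraint_k[r],
                       system$restraint_x0[r]), con)
  invisible(path)
}

#' Read a `cg_system` written by [write_cg_system()]
#' @param path input path
#' @return a `cg_system`
#' @export
read_cg_system <- function(path) {
  ln <- readLines(path)
  if (length(ln) < 5 || !grepl("^# alsdyn cg_system", ln[1]))
    abort_config(sprintf("%s is not an alsdyn cg_system file", path))
  ver <- sub("^format_version:\\s*", "", ln[2])
  if (ver != "1") abort_config(sprintf("unsupported format_version %s", ver))
  nb <- as.integer(sub("^n_beads:\\s*", "", ln[3]))
  nt <- as.integer(sub("^n_tail:\\s*", "", ln[4]))
  bead_rows <- ln[6:(5 + nb)]
  f <- do.call(rbind, strsplit(bead_rows, " "))
  positions <- matrix(as.numeric(f[, 2:4]), nb, 3)
  i0 <- 5 + nb + 1
  stopifnot(grepl("^bonds:", ln[i0]))
  rest_at <- grep("^restraints:", ln)[1]
  bond_rows <- if (rest_at > i0 + 1) ln[(i0 + 1):(rest_at - 1)] else character(0)
  bonds <- if (length(bond_rows))
    do.call(rbind, strsplit(bond_rows, " ")) else matrix(character(0), 0, 3)
  res_rows <- if (rest_at < length(ln)) ln[(rest_at + 1):length(ln)] else character(0)
  res <- if (length(res_rows))
    do.call(rbind, strsplit(res_rows, " ")) else matrix(character(0), 0, 4)
  new_cg_system(positions,
                charges = as.numeric(f[, 5]), radii = as.numeric(f[, 6]),
                region = f[, 7], mobile = as.logical(as.integer(f[, 8])),
                bond_i = as.integer(bonds[, 1]), bond_j = as.integer(bonds[, 2]),
                bond_r0 = as.numeric(bonds[, 3]),
                restraints = data.frame(bead = as.integer(res[, 1]),
                                        dim = as.integer(res[, 2]),
                                        k = as.numeric(res[, 3]),
                                        x0 = as.numeric(res[, 4])),
                n_tail = nt)
}
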