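# Ensemble statistics: Shrake-Rupley SASA and the tail-DNA contact surface
# area (CSA), radius of gyration, per-position contact probabilities,
# terminal-atom contact/exposure ratios, Kabsch superposition, 3D occupancy
# and difference grids, backbone dihedrals with a dihedral-window helix
# assignment, and site-site distance distributions.  All weighted-ensemble
# statistics are combined across runs TTP-style (run-level means, SE across
# runs).

#' SASA parameters
#'
#' The element radii are the values conventionally used for nucleosome
#' surface analysis: C 1.7, N 1.625, O 1.48, P 1.87 Angstrom, probe
#' (water) 1.4 Angstrom; hydrogens excluded.  S 1.8 is supplied for
#' completeness on protein structures.
#'
#' @param radii named element-to-radius map (Angstrom)
#' @param probe_radius probe sphere radius (Angstrom)
#' @param n_sphere_points deterministic golden-spiral point count
#' @param exclude_hydrogens drop H/D atoms from the calculation entirely
#' @return an object of class `sasa_params`
#' @export
sasa_params <- function(radii = c(C = 1.70, N = 1.625, O = 1.48, P = 1.87,
                                  S = 1.80),
                        probe_radius = 1.4, n_sphere_points = 960L,
                        exclude_hydrogens = TRUE) {
  radii <- unlist(radii)
  if (any(radii <= 0)) abort_config("radii must be positive", "radii")
  if (is.null(names(radii)) || any(!nzchar(names(radii))))
    abort_config("radii must be a named element->radius map", "radii")
  if (n_sphere_points < 1) abort_config("n_sphere_points must be >= 1",
                                        "n_sphere_points")
  structure(list(radii = setNames(as.numeric(radii), names(radii)),
                 probe_radius = as.numeric(probe_radius),
                 n_sphere_points = as.integer(n_sphere_points),
                 exclude_hydrogens = isTRUE(exclude_hydrogens)),
            class = "sasa_params")
}

#' Shrake-Rupley solvent accessible surface area
#'
#' @param coords N x 3 coordinates (Angstrom)
#' @param radii per-atom radii (Angstrom)
#' @param params a [sasa_params()] (probe radius and point count are used)
#' @return per-atom accessible areas (Angstrom^2)
#' @export
sasa <- function(coords, radii, params = sasa_params()) {
  coords <- unname(as.matrix(coords))
  if (!all(is.finite(coords))) abort_numerical("non-finite coordinates")
  if (length(radii) != nrow(coords)) abort_config("radii/coords mismatch")
  sasa_cpp(coords, as.numeric(radii), params$probe_radius,
           params$n_sphere_points)
}

# resolve element-based radii for a structure's atoms; errors listing any
# atom whose element is missing from the map
atom_radii <- function(structure, indices, params) {
  el <- structure$atoms$element[indices]
  r <- params$radii[el]
  bad <- which(is.na(r))
  if (length(bad))
    abort_config(sprintf(
      "no radius for element(s) %s (atoms %s); extend sasa_params radii",
      paste(unique(el[bad]), collapse = ", "),
      paste(structure$atoms$serial[indices][bad][seq_len(min(5, length(bad)))],
            collapse = ", ")))
  unname(r)
}

#' Per-atom SASA of a PDB structure
#'
#' Hydrogens are removed before the calculation when
#' `params$exclude_hydrogens` (the returned vector covers the atoms that
#' entered, with their indices in the `indices` attribute).
#'
#' @param structure a `pdb_structure`
#' @param params a [sasa_params()]
#' @param indices optional subset of atom indices forming the context
#' @return per-atom areas with attribute `indices`
#' @export
sasa_structure <- function(structure, params = sasa_params(), indices = NULL) {
  idx <- indices %||% seq_len(nrow(structure$atoms))
  if (params$exclude_hydrogens)
    idx <- idx[!(structure$atoms$element[idx] %in% c("H", "D"))]
  if (!length(idx)) abort_config("empty atom set for SASA")
  a <- sasa(structure_coords(structure)[idx, , drop = FALSE],
            atom_radii(structure, idx, params), params)
  attr(a, "indices") <- idx
  a
}

#' Contact surface area between a tail and DNA, generic coordinates
#'
#' CSA = (SASA of the DNA atoms with the tail absent) minus (SASA of the
#' DNA atoms with the tail present); every other supplied atom is part of
#' the context in both evaluations.
#'
#' @param coords N x 3 coordinates of the full context
#' @param radii per-atom radii
#' @param tail_idx,dna_idx disjoint index sets into the rows of `coords`
#' @param params a [sasa_params()]
#' @return the contact surface area (Angstrom^2)
#' @export
csa <- function(coords, radii, tail_idx, dna_idx, params = sasa_params()) {
  if (!length(tail_idx) || !length(dna_idx))
    abort_config("empty tail or DNA selection")
  if (length(intersect(tail_idx, dna_idx)))
    abort_config("tail and DNA selections must be disjoint")
  coords <- unname(as.matrix(coords))
  keep <- setdiff(seq_len(nrow(coords)), tail_idx)
  a_without <- sasa(coords[keep, , drop = FALSE], radii[keep], params)
  s_without <- sum(a_without[match(dna_idx, keep)])
  a_with <- sasa(coords, radii, params)
  s_with <- sum(a_with[dna_idx])
  s_without - s_with
}

#' CSA between two selections of a PDB structure
#'
#' @param structure a `pdb_structure`
#' @param tail_selection,dna_selection `atom_selection`s or selection
#'   expression strings
#' @param params a [sasa_params()]
#' @param context `"all"` keeps every other atom (e.g. the histone core)
#'   present in both SASA evaluations; `"pair"` restricts the context to
#'   the two selections only (both conventions are reported by validation
#'   code because the printed reference values do not state one)
#' @return the contact surface area (Angstrom^2)
#' @export
csa_structure <- function(structure, tail_selection, dna_selection,
                          params = sasa_params(), context = c("all", "pair")) {
  context <- match.arg(context)
  sel <- function(s) if (is.character(s)) select_atoms(structure, s)$indices
    else s$indices
  tail_idx <- sel(tail_selection)
  dna_idx <- sel(dna_selection)
  if (!length(tail_idx) || !length(dna_idx))
    abort_config("empty tail or DNA selection")
  ctx <- if (context == "all") seq_len(nrow(structure$atoms))
    else sort(union(tail_idx, dna_idx))
  if (params$exclude_hydrogens)
    ctx <- ctx[!(structure$atoms$element[ctx] %in% c("H", "D"))]
  tail_local <- match(intersect(tail_idx, ctx), ctx)
  dna_local <- match(intersect(dna_idx, ctx), ctx)
  csa(structure_coords(structure)[ctx, , drop = FALSE],
      atom_radii(structure, ctx, params), tail_local, dna_local, params)
}

#' CSA from a PDB file (the deposited-structure validation path)
#'
#' @param path PDB file
#' @param tail_expression,dna_expression selection expressions; defaults
#'   select an H3 tail (chain A residues 1-40) against all nucleotide
#'   heavy atoms
#' @param params a [sasa_params()]
#' @param model_index model to analyze
#' @param context see [csa_structure()]
#' @return the contact surface area (Angstrom^2)
#' @export
csa_pdb <- function(path, tail_expression = "chain A and resid 1-40 and heavy",
                    dna_expression = "nucleic and heavy",
                    params = sasa_params(), model_index = 1L,
                    context = "all") {
  s <- read_pdb(path, model_index)
  csa_structure(s, tail_expression, dna_expression, params, context)
}

#' Radius of gyration
#'
#' Mass-weighted RMS distance from the mass-weighted centroid.
#'
#' @param coords N x 3 coordinates
#' @param masses per-point masses (default unit)
#' @return Angstrom
#' @export
radius_of_gyration <- function(coords, masses = NULL) {
  coords <- unname(as.matrix(coords))
  n <- nrow(coords)
  if (n < 1) abort_config("need at least one point")
  if (is.null(masses)) masses <- rep(1, n)
  if (sum(masses) <= 0) abort_config("zero total mass")
  ctr <- colSums(coords * masses) / sum(masses)
  sqrt(sum(masses * rowSums(sweep(coords, 2, ctr)^2)) / sum(masses))
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the (weighted)
#' RMSD of `mobile` onto `reference`.
#'
#' @param mobile,reference equal-size M x 3 point sets (M >= 3)
#' @param weights optional per-point weights
#' @return an object of class `superposition_result`: `rotation` (3 x 3,
#'   det +1), `translation`, `rmsd`; apply with [apply_superposition()]
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- unname(as.matrix(mobile)); reference <- unname(as.matrix(reference))
  m <- nrow(mobile)
  if (m < 3 || nrow(reference) != m)
    abort_config("need equal point counts >= 3")
  w <- weights %||% rep(1, m)
  w <- w / sum(w)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  H <- t(A * w) %*% B
  sv <- svd(H)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-300))
    abort_config("degenerate (collinear) point sets")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  aligned <- sweep(A %*% t(R), 2, cr, `+`)
  rmsd <- sqrt(sum(w * rowSums((aligned - reference)^2)))
  structure(list(rotation = R, translation = cr - as.vector(R %*% cm),
                 rmsd = rmsd), class = "superposition_result")
}

#' Apply a superposition to coordinates
#' @param sr a `superposition_result`
#' @param coords N x 3 matrix
#' @return transformed N x 3 matrix
#' @export
apply_superposition <- function(sr, coords) {
  sweep(unname(as.matrix(coords)) %*% t(sr$rotation), 2, sr$translation, `+`)
}

# -- weighted-ensemble machinery for CG observables --------------------------

as_ensemble_list <- function(ensembles) {
  if (inherits(ensembles, "weighted_ensemble")) list(ensembles) else ensembles
}

# per-run weighted means -> mean / SE data; SE is NA for a single run
runs_summary <- function(per_run) {
  if (length(per_run) >= 2) {
    s <- ttp_summary(per_run)
    c(mean = s$mean, se = s$se, n_runs = s$n_runs)
  } else c(mean = per_run[[1]], se = NA_real_, n_runs = 1)
}

#' Per-position contact probability of the tail along the scaffold
#'
#' For each scaffold position group (indexed by its signed offset in
#' "base-pair" positions from the tail root: positive toward the dyad,
#' negative toward the DNA end), the weighted fraction of frames in which
#' any tail bead lies within `r_i + r_j + pad` of any bead of the group;
#' SE across runs.
#'
#' @param ensembles a `weighted_ensemble` or a list of them (one per run)
#' @param system the `cg_system` the trajectories sampled
#' @param tail_idx tail bead indices
#' @param position_groups named list of bead index vectors, names being
#'   the signed offsets
#' @param pad added to the sum of radii to define contact (default 2.8
#'   Angstrom, one water diameter)
#' @return a data.frame: position, mean, se, n_runs
#' @export
per_position_contact <- function(ensembles, system, tail_idx, position_groups,
                                 pad = 2.8) {
  if (!length(position_groups) || any(!lengths(position_groups)))
    abort_config("empty position group")
  ensembles <- as_ensemble_list(ensembles)
  per_run <- lapply(ensembles, function(we) {
    contact <- matrix(0, length(we$frame_index), length(position_groups))
    for (fi in seq_along(we$frame_index)) {
      pos <- frame_positions(we$trajectory, we$frame_index[fi])
      tp <- pos[tail_idx, , drop = FALSE]
      for (g in seq_along(position_groups)) {
        gi <- position_groups[[g]]
        gp <- pos[gi, , drop = FALSE]
        cut2 <- outer(system$radii[tail_idx], system$radii[gi], `+`) + pad
        d2 <- outer(rowSums(tp^2), rowSums(gp^2), `+`) - 2 * tp %*% t(gp)
        contact[fi, g] <- as.numeric(any(d2 <= cut2^2))
      }
    }
    colSums(contact * we$weights)
  })
  res <- t(vapply(seq_along(position_groups), function(g)
    runs_summary(vapply(per_run, `[`, numeric(1), g)), numeric(3)))
  data.frame(position = names(position_groups), mean = res[, 1],
             se = res[, 2], n_runs = res[, 3], row.names = NULL)
}

#' DNA contact ratio of terminal beads/atoms
#'
#' A terminal atom counts as in contact in a frame when its SASA computed
#' without the DNA present exceeds its SASA with the DNA present by more
#' than `threshold` (buried-against-DNA area above the discretization
#' noise floor).  Weighted fraction of frames per terminal atom, TTP mean
#' and SE across runs.
#'
#' @param ensembles a `weighted_ensemble` or list of them
#' @param system the `cg_system`
#' @param terminal_idx indices of the terminal beads
#' @param dna_idx indices of the DNA/scaffold beads
#' @param params a [sasa_params()]
#' @param threshold buried-area contact threshold (Angstrom^2)
#' @return a data.frame: bead, mean, se, n_runs
#' @export
contact_ratio <- function(ensembles, system, terminal_idx, dna_idx,
                          params = sasa_params(), threshold = 0.1) {
  ensembles <- as_ensemble_list(ensembles)
  n_all <- nrow(system$positions)
  keep <- setdiff(seq_len(n_all), dna_idx)
  term_in_keep <- match(terminal_idx, keep)
  per_run <- lapply(ensembles, function(we) {
    hits <- matrix(0, length(we$frame_index), length(terminal_idx))
    for (fi in seq_along(we$frame_index)) {
      pos <- frame_positions(we$trajectory, we$frame_index[fi])
      a_with <- sasa(pos, system$radii, params)[terminal_idx]
      a_without <- sasa(pos[keep, , drop = FALSE], system$radii[keep],
                        params)[term_in_keep]
      hits[fi, ] <- as.numeric(a_without - a_with > threshold)
    }
    colSums(hits * we$weights)
  })
  res <- t(vapply(seq_along(terminal_idx), function(t)
    runs_summary(vapply(per_run, `[`, numeric(1), t)), numeric(3)))
  data.frame(bead = terminal_idx, mean = res[, 1], se = res[, 2],
             n_runs = res[, 3], row.names = NULL)
}

#' Solvent exposure ratio of terminal beads/atoms
#'
#' Weighted mean over frames of (terminal-atom SASA in the frame) /
#' (terminal-atom SASA in the fully extended reference).  Ratios above 1
#' are reported as-is and flagged via the `flagged` column, never
#' truncated.
#'
#' @param ensembles a `weighted_ensemble` or list of them
#' @param system the `cg_system`
#' @param terminal_idx indices of the terminal beads
#' @param reference_sasa per-terminal-atom reference areas; default the
#'   isolated-sphere area \eqn{4\pi(r + probe)^2}
#' @param params a [sasa_params()]
#' @return a data.frame: bead, mean, se, n_runs, flagged
#' @export
exposure_ratio <- function(ensembles, system, terminal_idx,
                           reference_sasa = NULL, params = sasa_params()) {
  ensembles <- as_ensemble_list(ensembles)
  if (is.null(reference_sasa))
    reference_sasa <- 4 * pi * (system$radii[terminal_idx] +
                                  params$probe_radius)^2
  if (any(reference_sasa <= 0)) abort_config("reference SASA must be > 0")
  flagged <- rep(FALSE, length(terminal_idx))
  per_run <- lapply(ensembles, function(we) {
    ratio <- matrix(0, length(we$frame_index), length(terminal_idx))
    for (fi in seq_along(we$frame_index)) {
      pos <- frame_positions(we$trajectory, we$frame_index[fi])
      ratio[fi, ] <- sasa(pos, system$radii, params)[terminal_idx] /
        reference_sasa
    }
    flagged <<- flagged | apply(ratio > 1 + 1e-9, 2, any)
    colSums(ratio * we$weights)
  })
  res <- t(vapply(seq_along(terminal_idx), function(t)
    runs_summary(vapply(per_run, `[`, numeric(1), t)), numeric(3)))
  data.frame(bead = terminal_idx, mean = res[, 1], se = res[, 2],
             n_runs = res[, 3], flagged = flagged, row.names = NULL)
}

# -- density grids -----------------------------------------------------------

#' Weighted 3D occupancy grid of a selection over an ensemble
#'
#' Counts, per voxel, the weighted frequency with which the selected
#' beads/atoms appear there; atoms outside the grid go to an overflow
#' count with a warning.  Frames can be rigid-body aligned first.
#'
#' @param ensembles a `weighted_ensemble` or list of them (weights of each
#'   run scaled by 1/n_runs so the total is one frame-weight unit per atom)
#' @param selection bead/atom indices
#' @param origin grid origin (corner), 3-vector
#' @param spacing voxel edge (Angstrom)
#' @param dims integer 3-vector of voxel counts
#' @param align optional `list(reference = matrix, core = indices)`: each
#'   frame is Kabsch-aligned on `core` to `reference` before counting
#' @return an object of class `density_grid`: `origin`, `spacing`,
#'   `counts` (3D array), `overflow`
#' @export
density_grid <- function(ensembles, selection, origin, spacing, dims,
                         align = NULL) {
  if (spacing <= 0) abort_config("spacing must be > 0", "spacing")
  ensembles <- as_ensemble_list(ensembles)
  counts <- array(0, dim = dims)
  overflow <- 0
  nr <- length(ensembles)
  for (we in ensembles) {
    for (fi in seq_along(we$frame_index)) {
      pos <- frame_positions(we$trajectory, we$frame_index[fi])
      if (!is.null(align)) {
        sr <- kabsch_superpose(pos[align$core, , drop = FALSE],
                               align$reference)
        pos <- apply_superposition(sr, pos)
      }
      p <- pos[selection, , drop = FALSE]
      v <- floor(sweep(p, 2, origin) / spacing) + 1
      inside <- v[, 1] >= 1 & v[, 1] <= dims[1] &
        v[, 2] >= 1 & v[, 2] <= dims[2] & v[, 3] >= 1 & v[, 3] <= dims[3]
      w <- we$weights[fi] / nr
      if (any(!inside)) overflow <- overflow + sum(!inside) * w
      vi <- v[inside, , drop = FALSE]
      for (k in seq_len(nrow(vi)))
        counts[vi[k, 1], vi[k, 2], vi[k, 3]] <-
          counts[vi[k, 1], vi[k, 2], vi[k, 3]] + w
    }
  }
  if (overflow > 0)
    warning(sprintf("weighted count %.4g fell outside the grid (overflow bin)",
                    overflow))
  structure(list(origin = origin, spacing = spacing, counts = counts,
                 overflow = overflow), class = "density_grid")
}

#' Difference of two unit-normalized density grids
#'
#' Each input is normalized to unit total first; positive voxels mark
#' regions preferred in `grid_a`.
#'
#' @param grid_a,grid_b `density_grid`s on identical lattices
#' @return a `density_grid` whose counts sum to 0
#' @export
density_difference <- function(grid_a, grid_b) {
  if (!identical(dim(grid_a$counts), dim(grid_b$counts)) ||
      !isTRUE(all.equal(grid_a$origin, grid_b$origin)) ||
      !isTRUE(all.equal(grid_a$spacing, grid_b$spacing)))
    abort_config("grids must share origin, spacing and shape")
  na <- grid_a$counts / sum(grid_a$counts)
  nb <- grid_b$counts / sum(grid_b$counts)
  structure(list(origin = grid_a$origin, spacing = grid_a$spacing,
                 counts = na - nb, overflow = 0), class = "density_grid")
}

#' Write a density grid as a text voxel map (and optionally OpenDX)
#'
#' @param grid a `density_grid`
#' @param path output path for the tabular voxel map (i j k x y z value)
#' @param dx_path optional path for an OpenDX volumetric export
#' @return `path`, invisibly
#' @export
write_density_grid <- function(grid, path, dx_path = NULL) {
  d <- dim(grid$counts)
  idx <- which(grid$counts != 0, arr.ind = TRUE)
  con <- file(path, "w")
  writeLines(c("# alsdyn density_grid format 1",
               sprintf("# origin: %g %g %g", grid$origin[1], grid$origin[2],
                       grid$origin[3]),
               sprintf("# spacing: %g", grid$spacing),
               sprintf("# dims: %d %d %d", d[1], d[2], d[3]),
               "i j k x y z value"), con)
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    xyz <- grid$origin + (v - 0.5) * grid$spacing
    writeLines(sprintf("%d %d %d %.4f %.4f %.4f %.8g", v[1], v[2], v[3],
                       xyz[1], xyz[2], xyz[3],
                       grid$counts[v[1], v[2], v[3]]), con)
  }
  close(con)
  if (!is.null(dx_path)) {
    vals <- as.vector(aperm(grid$counts, c(3, 2, 1)))  # z fastest in DX
    hdr <- c(sprintf("object 1 class gridpositions counts %d %d %d",
                     d[1], d[2], d[3]),
             sprintf("origin %g %g %g", grid$origin[1], grid$origin[2],
                     grid$origin[3]),
             sprintf("delta %g 0 0", grid$spacing),
             sprintf("delta 0 %g 0", grid$spacing),
             sprintf("delta 0 0 %g", grid$spacing),
             sprintf("object 2 class gridconnections counts %d %d %d",
                     d[1], d[2], d[3]),
             sprintf("object 3 class array type double rank 0 items %d data follows",
                     length(vals)))
    body <- apply(matrix(c(vals, rep(0, (3 - length(vals) %% 3) %% 3)),
                         ncol = 3, byrow = TRUE), 1,
                  function(r) paste(sprintf("%.6g", r), collapse = " "))
    writeLines(c(hdr, body, "object \"density\" class field"), dx_path)
  }
  invisible(path)
}

# -- dihedrals and helix content ---------------------------------------------

#' Dihedral angle of four points (degrees, in (-180, 180])
#' @param p1,p2,p3,p4 3-vectors
#' @return degrees
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- n1 / sqrt(sum(n1^2))
  m2 <- n2 / sqrt(sum(n2^2))
  b2u <- b2 / sqrt(sum(b2^2))
  x <- sum(m1 * m2)
  y <- sum(c(m1[2] * b2u[3] - m1[3] * b2u[2],
             m1[3] * b2u[1] - m1[1] * b2u[3],
             m1[1] * b2u[2] - m1[2] * b2u[1]) * m2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

#' Backbone phi/psi dihedrals of a chain segment
#'
#' Standard definitions: phi(i) = C(i-1)-N(i)-CA(i)-C(i), psi(i) =
#' N(i)-CA(i)-C(i)-N(i+1).  Terminal or incomplete residues carry NA
#' (flagged, not an error).
#'
#' @param structure a `pdb_structure`
#' @param chain chain identifier
#' @param residue_range integer vector of residue numbers (default all in
#'   the chain)
#' @return a data.frame: resid, phi, psi (degrees)
#' @export
backbone_dihedrals <- function(structure, chain = "A", residue_range = NULL) {
  a <- structure$atoms
  xyz <- structure_coords(structure)
  in_chain <- a$chain == chain
  resids <- sort(unique(a$resid[in_chain]))
  if (!is.null(residue_range)) resids <- intersect(resids, residue_range)
  get_atom <- function(rid, nm) {
    i <- which(in_chain & a$resid == rid & a$name == nm)
    if (length(i) != 1) return(NULL)
    xyz[i, ]
  }
  res <- data.frame(resid = resids, phi = NA_real_, psi = NA_real_)
  for (r in seq_along(resids)) {
    rid <- resids[r]
    N <- get_atom(rid, "N"); CA <- get_atom(rid, "CA"); C <- get_atom(rid, "C")
    if (is.null(N) || is.null(CA) || is.null(C)) next
    Cm <- get_atom(rid - 1, "C")
    if (!is.null(Cm)) res$phi[r] <- dihedral_angle(Cm, N, CA, C)
    Np <- get_atom(rid + 1, "N")
    if (!is.null(Np)) res$psi[r] <- dihedral_angle(N, CA, C, Np)
  }
  res
}

#' Build an ideal peptide backbone from phi/psi angles
#'
#' Internal-coordinate (NeRF) chain construction with standard bond
#' lengths and angles (N-CA 1.458, CA-C 1.525, C-N 1.329 Angstrom; N-CA-C
#' 111.2, CA-C-N 116.2, C-N-CA 121.7 degrees), trans peptide bonds.  A
#' fixture generator for the dihedral and helix-assignment analyses.
#'
#' @param phi,psi per-residue dihedrals in degrees (phi of residue 1 and
#'   psi of the last residue are ignored)
#' @param chain chain identifier for the returned structure
#' @return a `pdb_structure` with N, CA, C atoms per residue
#' @export
build_backbone <- function(phi, psi, chain = "A") {
  n <- length(phi)
  if (length(psi) != n) abort_config("phi and psi must have equal length")
  place <- function(a, b, c, bond, angle, torsion) {
    ang <- angle * pi / 180; tor <- torsion * pi / 180
    bc <- c - b; bc <- bc / sqrt(sum(bc^2))
    ab <- b - a
    nrm <- c(ab[2] * bc[3] - ab[3] * bc[2], ab[3] * bc[1] - ab[1] * bc[3],
             ab[1] * bc[2] - ab[2] * bc[1])
    nrm <- nrm / sqrt(sum(nrm^2))
    m <- c(nrm[2] * bc[3] - nrm[3] * bc[2], nrm[3] * bc[1] - nrm[1] * bc[3],
           nrm[1] * bc[2] - nrm[2] * bc[1])
    # the out-of-plane component is negated so that the placed atom's
    # dihedral (IUPAC sign convention, as measured by dihedral_angle)
    # equals `torsion`
    d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
           -bond * sin(ang) * sin(tor))
    c + d[1] * bc + d[2] * m + d[3] * nrm
  }
  coords <- matrix(NA_real_, 3 * n, 3)
  coords[1, ] <- c(0, 0, 0)                              # N1
  coords[2, ] <- c(1.458, 0, 0)                          # CA1
  a_nac <- 111.2 * pi / 180
  coords[3, ] <- coords[2, ] + 1.525 * c(-cos(a_nac), sin(a_nac), 0)  # C1
  for (i in seq_len(n - 1)) {
    Ni <- coords[3 * i - 2, ]; CAi <- coords[3 * i - 1, ]; Ci <- coords[3 * i, ]
    Nn <- place(Ni, CAi, Ci, 1.329, 116.2, psi[i])
    CAn <- place(CAi, Ci, Nn, 1.458, 121.7, 180)
    Cn <- place(Ci, Nn, CAn, 1.525, 111.2, phi[i + 1])
    coords[3 * i + 1, ] <- Nn
    coords[3 * i + 2, ] <- CAn
    coords[3 * i + 3, ] <- Cn
  }
  atoms <- data.frame(
    serial = seq_len(3 * n),
    name = rep(c("N", "CA", "C"), n),
    altloc = " ",
    resname = "ALA",
    chain = chain,
    resid = rep(seq_len(n), each = 3),
    occupancy = 1,
    element = rep(c("N", "C", "C"), n),
    stringsAsFactors = FALSE)
  structure(list(atoms = atoms, models = list(coords), model_index = 1L),
            class = "pdb_structure")
}

#' Helical-residue assignment by dihedral window
#'
#' A residue is helical in a frame when its (phi, psi) falls inside the
#' helical window AND it belongs to a run of at least `min_run`
#' consecutive in-window residues (a dihedral-window stand-in for
#' hydrogen-bond based assignment, validated on ideal geometries).
#'
#' @param structure a `pdb_structure`
#' @param chain chain id
#' @param residue_range residues to assess
#' @param phi_window,psi_window degrees, defaults phi in \[-100, -30\],
#'   psi in \[-80, -5\]
#' @param min_run minimum consecutive in-window run length (default 4)
#' @return named logical vector per residue
#' @export
helix_assign <- function(structure, chain = "A", residue_range = NULL,
                         phi_window = c(-100, -30), psi_window = c(-80, -5),
                         min_run = 4L) {
  dh <- backbone_dihedrals(structure, chain, residue_range)
  inw <- !is.na(dh$phi) & !is.na(dh$psi) &
    dh$phi >= phi_window[1] & dh$phi <= phi_window[2] &
    dh$psi >= psi_window[1] & dh$psi <= psi_window[2]
  r <- rle(inw)
  r$values <- r$values & r$lengths >= min_run
  out <- inverse.rle(r)
  names(out) <- dh$resid
  out
}

#' Weighted per-residue helix content of a structural ensemble
#'
#' @param runs one run or a list of runs; each run is a list with
#'   `structures` (list of `pdb_structure`) and `weights` (normalized
#'   within the run)
#' @param chain chain id
#' @param residue_range residues to report
#' @param ... passed to [helix_assign()]
#' @return a data.frame: resid, mean, se, n_runs
#' @export
helix_content <- function(runs, chain = "A", residue_range = NULL, ...) {
  if (!is.null(runs$structures)) runs <- list(runs)
  per_run <- lapply(runs, function(run) {
    w <- run$weights / sum(run$weights)
    h <- vapply(seq_along(run$structures), function(i)
      as.numeric(helix_assign(run$structures[[i]], chain, residue_range, ...)),
      numeric(length(helix_assign(run$structures[[1]], chain,
                                  residue_range, ...))))
    as.vector(h %*% w)
  })
  rid <- as.integer(names(helix_assign(runs[[1]]$structures[[1]], chain,
                                       residue_range, ...)))
  res <- t(vapply(seq_along(rid), function(r)
    runs_summary(vapply(per_run, `[`, numeric(1), r)), numeric(3)))
  data.frame(resid = rid, mean = res[, 1], se = res[, 2],
             n_runs = res[, 3], row.names = NULL)
}

#' Weighted site-site distance distributions over an ensemble
#'
#' @param ensembles a `weighted_ensemble` or list of them
#' @param site_pairs list of 2-vectors of bead/atom indices
#' @param breaks histogram bin edges (default spans the observed range)
#' @return a list per pair: `pair`, `summary` (TTP mean +/- SE),
#'   `histogram` (normalized, pooled with run-equal weighting)
#' @export
pair_distance_distribution <- function(ensembles, site_pairs, breaks = NULL) {
  ensembles <- as_ensemble_list(ensembles)
  lapply(site_pairs, function(pr) {
    per_run_vals <- lapply(ensembles, function(we) {
      vapply(seq_along(we$frame_index), function(fi) {
        pos <- frame_positions(we$trajectory, we$frame_index[fi])
        sqrt(sum((pos[pr[1], ] - pos[pr[2], ])^2))
      }, numeric(1))
    })
    per_run_means <- vapply(seq_along(ensembles), function(r)
      sum(ensembles[[r]]$weights * per_run_vals[[r]]), numeric(1))
    allv <- unlist(per_run_vals)
    allw <- unlist(lapply(ensembles, function(we) we$weights /
                            length(ensembles)))
    br <- breaks %||% seq(min(allv) - 1e-9, max(allv) + 1e-9, length.out = 31)
    list(pair = pr, summary = runs_summary(per_run_means),
         histogram = weighted_histogram(allv, allw, br))
  })
}
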