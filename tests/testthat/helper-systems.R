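# Small systems and fixtures shared across tests.

small_toy_config <- function(...) {
  args <- list(n_tail_beads = 8L, charge_pattern = c(2L, 4L, 6L, 8L),
               n_scaffold = 12L, scaffold_geometry = "straight")
  over <- list(...)
  args[names(over)] <- over
  do.call(toy_system_config, args)
}

small_toy <- function(...) build_tail_scaffold_system(small_toy_config(...))

# a free mobile bead with no potential at all (flat lambda target)
free_bead_system <- function() {
  alsdyn:::new_cg_system(positions = matrix(0, 1, 3), charges = 0, radii = 1,
                         region = "TAIL", mobile = TRUE)
}

# bare two-bead systems for single-term force checks
pair_system <- function(q = c(0, 0), region = c("TAIL", "TAIL"), sep = 5,
                        radii = c(2, 2), bonded = FALSE, r0 = sep) {
  alsdyn:::new_cg_system(
    positions = rbind(c(0, 0, 0), c(sep, 0, 0)), charges = q, radii = radii,
    region = region, mobile = c(TRUE, TRUE),
    bond_i = if (bonded) 1L else integer(0),
    bond_j = if (bonded) 2L else integer(0),
    bond_r0 = if (bonded) r0 else numeric(0))
}

# hand-written PDB fixtures -------------------------------------------------

pdb_line <- function(serial, name, resname, chain, resid, x, y, z,
                     element = substr(name, 1, 1)) {
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
          resname, chain, resid, x, y, z, 1.0, 0.0, element)
}

write_three_atom_pdb <- function(path) {
  writeLines(c(
    pdb_line(1, "N", "GLY", "A", 1, 1.234, 2.345, 3.456),
    pdb_line(2, "CA", "GLY", "A", 1, 2.000, 3.000, 4.000, "C"),
    pdb_line(3, "C", "GLY", "A", 1, 3.500, 3.250, 4.750, "C"),
    "END"), path)
  path
}

write_lysine_pdb <- function(path) {
  # coarse lysine-like sidechain geometry; coordinates are arbitrary but fixed
  writeLines(c(
    pdb_line(1, "N", "LYS", "A", 14, 0, 0, 0),
    pdb_line(2, "CA", "LYS", "A", 14, 1.5, 0, 0, "C"),
    pdb_line(3, "C", "LYS", "A", 14, 2.2, 1.3, 0, "C"),
    pdb_line(4, "CB", "LYS", "A", 14, 2.1, -1.2, 0.5, "C"),
    pdb_line(5, "NZ", "LYS", "A", 14, 5.4, -2.8, 1.9),
    pdb_line(6, "HZ1", "LYS", "A", 14, 5.9, -3.2, 2.4, "H"),
    "END"), path)
  path
}

write_arginine_pdb <- function(path) {
  writeLines(c(
    pdb_line(1, "N", "ARG", "B", 2, 0, 0, 0),
    pdb_line(2, "CA", "ARG", "B", 2, 1.5, 0, 0, "C"),
    pdb_line(3, "CZ", "ARG", "B", 2, 4.9, -1.0, 0.8, "C"),
    pdb_line(4, "NH1", "ARG", "B", 2, 5.8, -0.1, 1.1),
    pdb_line(5, "NH2", "ARG", "B", 2, 5.2, -2.3, 0.9),
    "END"), path)
  path
}

write_two_model_pdb <- function(path) {
  writeLines(c(
    "MODEL        1",
    pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0, "C"),
    pdb_line(2, "CA", "ALA", "A", 2, 3.8, 0, 0, "C"),
    "ENDMDL",
    "MODEL        2",
    pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 1, "C"),
    pdb_line(2, "CA", "ALA", "A", 2, 3.8, 0, 1, "C"),
    "ENDMDL",
    "END"), path)
  path
}

# craft a minimal weighted_ensemble around an explicit frame list, for
# analysis-function unit tests (weights need not come from a sampler)
fake_ensemble <- function(frames, weights = NULL, lambda = NULL) {
  nf <- length(frames)
  n <- nrow(frames[[1]])
  fr <- do.call(rbind, lapply(frames, function(m) as.vector(t(m))))
  w <- weights %||% rep(1 / nf, nf)
  traj <- structure(list(
    frames = fr, lambda = lambda %||% rep(1, nf),
    e_tail = rep(0, nf), e_tail_rest = rep(0, nf), e_rest = rep(0, nf),
    step = seq_len(nf), lambda_hist = numeric(0),
    meta = list(config_hash = "fixture", bias_hash = "fixture",
                seed = 0L, n_beads = n)), class = "alsd_trajectory")
  structure(list(trajectory = traj, frame_index = seq_len(nf),
                 weights = w, log_weights = log(pmax(w, 1e-300)),
                 ess = 1 / sum(w^2), target_lambda = 1),
            class = "weighted_ensemble")
}
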