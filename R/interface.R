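# Staged command-line pipeline: build -> adapt -> sample -> reweight ->
# analyze.  Each stage writes its outputs plus a manifest (config hash,
# input hashes, seeds, package version); downstream stages refuse to run on
# hash mismatches (stale-input guard).  Exit codes: 0 success, 2 config
# error, 3 stale input, 4 numerical failure.

#' Assemble a full run configuration
#'
#' @param toy a [toy_system_config()]
#' @param forcefield a [forcefield_params()]
#' @param alsd an [alsd_config()]
#' @param sasa a [sasa_params()]
#' @param acetylate tail bead indices whose charge is neutralized at build
#'   time (empty for the unmodified system)
#' @param n_runs TTP runs for the sample stage
#' @param n_iterations adaptation iterations
#' @param adapt_steps steps per adaptation iteration
#' @param n_equil per-run equilibration steps before production
#' @param contact_pad,contact_threshold analysis thresholds (Angstrom /
#'   Angstrom^2)
#' @param grid_spacing density grid voxel edge for the coarse-grained
#'   system (Angstrom)
#' @param seed master seed
#' @return an object of class `run_config`
#' @export
run_config <- function(toy = toy_system_config(),
                       forcefield = forcefield_params(),
                       alsd = alsd_config(),
                       sasa = sasa_params(),
                       acetylate = integer(0),
                       n_runs = 8L, n_iterations = 20L,
                       adapt_steps = alsd$n_steps,
                       n_equil = 2000L,
                       contact_pad = 2.8, contact_threshold = 0.1,
                       grid_spacing = 2.0, seed = 1L) {
  structure(list(toy = toy, forcefield = forcefield, alsd = alsd,
                 sasa = sasa, acetylate = as.integer(acetylate),
                 n_runs = as.integer(n_runs),
                 n_iterations = as.integer(n_iterations),
                 adapt_steps = as.integer(adapt_steps),
                 n_equil = as.integer(n_equil),
                 contact_pad = as.numeric(contact_pad),
                 contact_threshold = as.numeric(contact_threshold),
                 grid_spacing = as.numeric(grid_spacing),
                 seed = as.integer(seed)), class = "run_config")
}

#' Write a run configuration to JSON
#' @param config a `run_config`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_run_config <- function(config, path) {
  j <- lapply(unclass(config), unclass)
  # named atomic vectors serialize as arrays; keep the element names
  j$sasa$radii <- as.list(j$sasa$radii)
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a run configuration from JSON (validated through the constructors)
#' @param path JSON path
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("config file not found: %s", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  toy <- do.call(toy_system_config,
                 j$toy[intersect(names(j$toy), names(formals(toy_system_config)))])
  ff <- do.call(forcefield_params,
                j$forcefield[intersect(names(j$forcefield),
                                       names(formals(forcefield_params)))])
  al <- do.call(alsd_config,
                j$alsd[intersect(names(j$alsd), names(formals(alsd_config)))])
  sp_args <- j$sasa[intersect(names(j$sasa), names(formals(sasa_params)))]
  if (!is.null(sp_args$radii)) sp_args$radii <- unlist(sp_args$radii)
  sp <- do.call(sasa_params, sp_args)
  run_config(toy = toy, forcefield = ff, alsd = al, sasa = sp,
             acetylate = j$acetylate %||% integer(0),
             n_runs = j$n_runs %||% 8L,
             n_iterations = j$n_iterations %||% 20L,
             adapt_steps = j$adapt_steps %||% al$n_steps,
             n_equil = j$n_equil %||% 2000L,
             contact_pad = j$contact_pad %||% 2.8,
             contact_threshold = j$contact_threshold %||% 0.1,
             grid_spacing = j$grid_spacing %||% 2.0,
             seed = j$seed %||% 1L)
}

config_hash <- function(config) hash_object(unclass(config))

write_manifest <- function(outdir, stage, config, inputs = list(),
                           outputs = character(0), extra = list()) {
  man <- c(list(stage = stage,
                package_version = as.character(utils::packageVersion("alsdyn")),
                config_hash = config_hash(config),
                seed = config$seed,
                inputs = inputs,
                outputs = lapply(setNames(outputs, basename(outputs)),
                                 hash_file)),
           extra)
  jsonlite::write_json(man, file.path(outdir, sprintf("manifest_%s.json", stage)),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(man)
}

read_manifest <- function(outdir, stage) {
  p <- file.path(outdir, sprintf("manifest_%s.json", stage))
  if (!file.exists(p))
    abort_stale(sprintf("missing %s manifest; run the %s stage first", stage, stage))
  jsonlite::read_json(p, simplifyVector = TRUE)
}

check_upstream <- function(outdir, stage, config) {
  man <- read_manifest(outdir, stage)
  if (!identical(man$config_hash, config_hash(config)))
    abort_stale(sprintf(
      "config hash mismatch with the %s stage output (stale input)", stage))
  for (f in names(man$outputs)) {
    p <- file.path(outdir, f)
    if (!file.exists(p))
      abort_stale(sprintf("%s output %s has been deleted", stage, f))
    if (!identical(hash_file(p), man$outputs[[f]]))
      abort_stale(sprintf("%s output %s has been modified (hash mismatch)",
                          stage, f))
  }
  man
}

log_msg <- function(outdir, ...) {
  msg <- sprintf(...)
  message(msg)
  cat(msg, "\n", file = file.path(outdir, "alsdyn.log"), append = TRUE)
}

# tabular output with a parameter header block (no silent defaults)
write_table_with_header <- function(df, path, header) {
  con <- file(path, "w")
  writeLines(sprintf("# %s: %s", names(header),
                     vapply(header, function(v) paste(format(v), collapse = " "),
                            character(1))), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  close(con)
  invisible(path)
}

#' Build stage: system + initial conformations
#'
#' @param config a `run_config` or path to its JSON
#' @param outdir output directory (created)
#' @return `outdir`, invisibly
#' @export
cli_build <- function(config, outdir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  system <- build_tail_scaffold_system(config$toy)
  if (length(config$acetylate))
    system <- apply_acetylation(system, config$acetylate)
  sys_path <- file.path(outdir, "system.cg")
  write_cg_system(system, sys_path)
  confs <- initial_conformations(system, config$n_runs, seed = config$seed)
  conf_path <- file.path(outdir, "initial_conformations.tsv")
  df <- do.call(rbind, lapply(seq_along(confs), function(i)
    data.frame(conformation = i, bead = seq_len(nrow(confs[[i]])),
               x = confs[[i]][, 1], y = confs[[i]][, 2], z = confs[[i]][, 3])))
  write_table_with_header(df, conf_path,
                          list(seed = config$seed, n_conformations = length(confs)))
  write_manifest(outdir, "build", config,
                 outputs = c(sys_path, conf_path))
  ff <- config$forcefield
  log_msg(outdir, paste("[build] forcefield: bond_k %g wca_epsilon %g",
                        "dielectric %g ionic_strength %g M (debye %.2f A)",
                        "temperature %g K"),
          ff$bond_k, ff$wca_epsilon, ff$dielectric, ff$ionic_strength,
          ff$debye, ff$temperature)
  log_msg(outdir, "[build] %d beads, %d initial conformations, seed %d",
          nrow(system$positions), length(confs), config$seed)
  invisible(outdir)
}

#' Adapt stage: estimate the umbrella bias
#' @inheritParams cli_build
#' @return `outdir`, invisibly
#' @export
cli_adapt <- function(config, outdir) {
  if (is.character(config)) config <- read_run_config(config)
  check_upstream(outdir, "build", config)
  system <- read_cg_system(file.path(outdir, "system.cg"))
  bias <- adapt_bias(system, config$alsd, n_iterations = config$n_iterations,
                     steps_per_iteration = config$adapt_steps,
                     seed = config$seed)
  bias_path <- file.path(outdir, "bias.tsv")
  write_table_with_header(
    data.frame(lambda = bias$lambda_grid, ln_p = bias$ln_p),
    bias_path,
    list(flatness = bias$flatness, n_iterations = length(bias$flatness),
         temperature = config$alsd$temperature, seed = config$seed))
  write_manifest(outdir, "adapt", config, outputs = bias_path,
                 extra = list(bias_hash = bias$hash,
                              flatness = bias$flatness))
  log_msg(outdir, "[adapt] %d iterations, final flatness %.3f",
          length(bias$flatness), bias$flatness[length(bias$flatness)])
  invisible(outdir)
}

read_bias <- function(outdir) {
  man <- read_manifest(outdir, "adapt")
  tab <- read.table(file.path(outdir, "bias.tsv"), header = TRUE,
                    comment.char = "#")
  bias_estimate(tab$lambda, tab$ln_p, flatness = as.numeric(man$flatness))
}

#' Sample stage: TTP production runs under the frozen bias
#' @inheritParams cli_build
#' @return `outdir`, invisibly
#' @export
cli_sample <- function(config, outdir) {
  if (is.character(config)) config <- read_run_config(config)
  check_upstream(outdir, "build", config)
  check_upstream(outdir, "adapt", config)
  system <- read_cg_system(file.path(outdir, "system.cg"))
  bias <- read_bias(outdir)
  trajs <- run_ttp(system, config$alsd, bias, n_runs = config$n_runs,
                   base_seed = config$seed, n_equil = config$n_equil)
  paths <- vapply(seq_along(trajs), function(r) {
    p <- file.path(outdir, sprintf("trajectory_%03d.tsv", r))
    write_trajectory(trajs[[r]], p)
    p
  }, character(1))
  write_manifest(outdir, "sample", config, outputs = paths,
                 extra = list(bias_hash = bias$hash,
                              seeds = vapply(trajs, function(t) t$meta$seed, 1L)))
  log_msg(outdir, "[sample] %d runs x %d frames", length(trajs),
          n_frames(trajs[[1]]))
  invisible(outdir)
}

#' Export a trajectory as a headered TSV (one row per frame)
#' @param trajectory an `alsd_trajectory`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_trajectory <- function(trajectory, path) {
  n <- trajectory$meta$n_beads
  df <- data.frame(step = trajectory$step, lambda = trajectory$lambda,
                   e_tail = trajectory$e_tail,
                   e_tail_rest = trajectory$e_tail_rest,
                   e_rest = trajectory$e_rest)
  pos <- as.data.frame(trajectory$frames)
  names(pos) <- paste0(rep(c("x", "y", "z"), n), rep(seq_len(n), each = 3))
  write_table_with_header(
    cbind(df, pos), path,
    list(format = "alsdyn trajectory 1", n_beads = n,
         seed = trajectory$meta$seed,
         config_hash = trajectory$meta$config_hash,
         bias_hash = trajectory$meta$bias_hash,
         lambda_hist = trajectory$lambda_hist))
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#' @param path TSV path
#' @return an `alsd_trajectory`
#' @export
read_trajectory <- function(path) {
  hdr <- character(0)
  con <- file(path, "r")
  repeat {
    l <- readLines(con, 1)
    if (!length(l) || !startsWith(l, "#")) break
    hdr <- c(hdr, l)
  }
  close(con)
  hval <- function(key) {
    h <- hdr[startsWith(hdr, sprintf("# %s:", key))]
    if (!length(h)) return(NULL)
    trimws(sub(sprintf("^# %s:", key), "", h[1]))
  }
  tab <- read.table(path, header = TRUE, comment.char = "#")
  n <- as.integer(hval("n_beads"))
  structure(list(
    frames = unname(as.matrix(tab[, -(1:5), drop = FALSE])),
    lambda = tab$lambda, e_tail = tab$e_tail,
    e_tail_rest = tab$e_tail_rest, e_rest = tab$e_rest,
    step = tab$step,
    lambda_hist = as.numeric(strsplit(hval("lambda_hist"), "\\s+")[[1]]),
    meta = list(config_hash = hval("config_hash"),
                bias_hash = hval("bias_hash"),
                seed = as.integer(hval("seed")), n_beads = n)),
    class = "alsd_trajectory")
}

#' Reweight stage: canonical weights at lambda = 1 for every run
#' @inheritParams cli_build
#' @return `outdir`, invisibly
#' @export
cli_reweight <- function(config, outdir) {
  if (is.character(config)) config <- read_run_config(config)
  man <- check_upstream(outdir, "sample", config)
  check_upstream(outdir, "adapt", config)
  bias <- read_bias(outdir)
  paths <- character(0)
  ess <- numeric(0)
  for (f in names(man$outputs)) {
    tr <- read_trajectory(file.path(outdir, f))
    we <- reweight(tr, bias, config$alsd)
    p <- file.path(outdir, sub("^trajectory", "weights", f))
    write_table_with_header(
      data.frame(frame = we$frame_index, lambda = tr$lambda[we$frame_index],
                 weight = we$weights),
      p, list(ess = we$ess, bias_hash = bias$hash,
              temperature = config$alsd$temperature))
    paths <- c(paths, p)
    ess <- c(ess, we$ess)
  }
  write_manifest(outdir, "reweight", config, outputs = paths,
                 extra = list(ess = ess))
  log_msg(outdir, "[reweight] mean ESS %.1f over %d runs", mean(ess),
          length(ess))
  invisible(outdir)
}

load_ensembles <- function(config, outdir) {
  man <- read_manifest(outdir, "sample")
  bias <- read_bias(outdir)
  lapply(names(man$outputs), function(f)
    reweight(read_trajectory(file.path(outdir, f)), bias, config$alsd))
}

#' Analyze stage: the full table suite for a sampled toy system
#'
#' Emits: CSA summary and per-run table, Rg summary and histogram,
#' per-position contact probabilities, terminal-bead contact and exposure
#' ratios, the tail density grid, and site-site distance distributions.
#' Every table's header records the parameters used.
#'
#' @inheritParams cli_build
#' @param reference_outdir optional second (e.g. unacetylated) pipeline
#'   directory; when given, the tail density difference grid
#'   (reference - this) is also written
#' @return `outdir`, invisibly
#' @export
cli_analyze <- function(config, outdir, reference_outdir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  check_upstream(outdir, "sample", config)
  system <- read_cg_system(file.path(outdir, "system.cg"))
  ensembles <- load_ensembles(config, outdir)
  tail_idx <- tail_indices(system)
  dna_idx <- rest_indices(system)
  hdr_common <- list(probe_radius = config$sasa$probe_radius,
                     n_sphere_points = config$sasa$n_sphere_points,
                     seed = config$seed)

  csa_fun <- function(pos) csa(pos, system$radii, tail_idx, dna_idx,
                               config$sasa)
  per_run_csa <- vapply(ensembles, function(we) ensemble_mean(we, csa_fun),
                        numeric(1))
  rg_fun <- function(pos) radius_of_gyration(pos[tail_idx, , drop = FALSE])
  per_run_rg <- vapply(ensembles, function(we) ensemble_mean(we, rg_fun),
                       numeric(1))
  s_csa <- ttp_summary(per_run_csa)
  s_rg <- ttp_summary(per_run_rg)
  write_table_with_header(
    data.frame(observable = c("csa", "rg"),
               mean = c(s_csa$mean, s_rg$mean),
               se = c(s_csa$se, s_rg$se),
               n_runs = c(s_csa$n_runs, s_rg$n_runs)),
    file.path(outdir, "summary.tsv"), hdr_common)
  write_table_with_header(
    data.frame(run = seq_along(ensembles), csa = per_run_csa,
               rg = per_run_rg,
               ess = vapply(ensembles, function(we) we$ess, numeric(1))),
    file.path(outdir, "per_run.tsv"), hdr_common)

  # Rg histogram (pooled, run-equal weighting)
  allrg <- unlist(lapply(ensembles, function(we) frame_values(we, rg_fun)))
  allw <- unlist(lapply(ensembles, function(we)
    we$weights / length(ensembles)))
  br <- seq(min(allrg) - 1e-6, max(allrg) + 1e-6, length.out = 31)
  h <- weighted_histogram(allrg, allw, br)
  write_table_with_header(data.frame(rg_mid = h$mids, mass = h$mass),
                          file.path(outdir, "rg_histogram.tsv"), hdr_common)

  # per-position contact: group scaffold beads by axial position
  n_pos <- ceiling(config$toy$n_scaffold / 2)
  tether <- config$toy$tether_index
  groups <- lapply(seq_len(n_pos), function(p) {
    g <- dna_idx[c(p, p + n_pos)]
    g[!is.na(g)]
  })
  names(groups) <- seq_len(n_pos) - tether
  ppc <- per_position_contact(ensembles, system, tail_idx, groups,
                              pad = config$contact_pad)
  write_table_with_header(ppc, file.path(outdir, "position_contact.tsv"),
                          c(hdr_common, list(pad = config$contact_pad)))

  # charged (lysine/arginine-like) tail positions, including any that were
  # neutralized at build time
  term_idx <- tail_idx[config$toy$charge_pattern]
  cr <- contact_ratio(ensembles, system, term_idx, dna_idx, config$sasa,
                      threshold = config$contact_threshold)
  write_table_with_header(cr, file.path(outdir, "contact_ratio.tsv"),
                          c(hdr_common,
                            list(threshold = config$contact_threshold)))
  er <- exposure_ratio(ensembles, system, term_idx, params = config$sasa)
  write_table_with_header(er, file.path(outdir, "exposure_ratio.tsv"),
                          hdr_common)

  # tail density grid around the scaffold
  scaf <- system$positions[dna_idx, , drop = FALSE]
  lo <- apply(scaf, 2, min) - 40
  hi <- apply(scaf, 2, max) + 40
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / config$grid_spacing)))
  dg <- density_grid(ensembles, tail_idx, origin = lo,
                     spacing = config$grid_spacing, dims = dims)
  write_density_grid(dg, file.path(outdir, "tail_density.txt"),
                     dx_path = file.path(outdir, "tail_density.dx"))
  if (!is.null(reference_outdir)) {
    ref_ens <- tryCatch(load_ensembles(config, reference_outdir),
                        error = function(e) abort_stale(conditionMessage(e)))
    ref_sys <- read_cg_system(file.path(reference_outdir, "system.cg"))
    dg_ref <- density_grid(ref_ens, tail_indices(ref_sys), origin = lo,
                           spacing = config$grid_spacing, dims = dims)
    dd <- density_difference(dg_ref, dg)
    write_density_grid(dd, file.path(outdir, "tail_density_difference.txt"))
  }

  # distances: free tail end to tether scaffold bead, and tail midpoint
  tether_global <- dna_idx[tether]
  pairs <- list(c(tail_idx[1], tether_global),
                c(tail_idx[ceiling(length(tail_idx) / 2)], tether_global))
  pdd <- pair_distance_distribution(ensembles, pairs)
  dist_df <- do.call(rbind, lapply(pdd, function(p)
    data.frame(i = p$pair[1], j = p$pair[2], mean = p$summary["mean"],
               se = p$summary["se"], n_runs = p$summary["n_runs"])))
  write_table_with_header(dist_df, file.path(outdir, "distances.tsv"),
                          hdr_common)

  write_manifest(outdir, "analyze", config,
                 outputs = file.path(outdir, c("summary.tsv", "per_run.tsv",
                                               "rg_histogram.tsv",
                                               "position_contact.tsv",
                                               "contact_ratio.tsv",
                                               "exposure_ratio.tsv",
                                               "tail_density.txt",
                                               "distances.tsv")))
  log_msg(outdir, "[analyze] CSA %.2f +/- %.2f A^2, Rg %.2f +/- %.2f A",
          s_csa$mean, s_csa$se, s_rg$mean, s_rg$se)
  invisible(outdir)
}

#' Command-line entry point
#'
#' `alsdyn_main(c("build", "--config", "cfg.json", "--out", "dir"))` etc.;
#' stages: build, adapt, sample, reweight, analyze, csa-pdb.  Returns the
#' exit code (0 success, 2 config error, 3 stale input, 4 numerical
#' failure) rather than calling [quit()], so it is testable in-process.
#'
#' @param args character vector of command-line arguments
#' @return integer exit code, invisibly
#' @export
alsdyn_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  get_opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (!length(i)) return(default)
    if (i[1] + 1 > length(args)) return(default)
    args[i[1] + 1]
  }
  code <- tryCatch({
    if (!length(args)) abort_config(
      "usage: alsdyn <build|adapt|sample|reweight|analyze|csa-pdb> ...")
    stage <- args[1]
    if (stage == "csa-pdb") {
      pdb <- get_opt("--pdb")
      if (is.null(pdb)) abort_config("csa-pdb needs --pdb <file>")
      tail_expr <- get_opt("--tail", "chain A and resid 1-40 and heavy")
      dna_expr <- get_opt("--dna", "nucleic and heavy")
      p <- sasa_params()
      v <- csa_pdb(pdb, tail_expr, dna_expr, p,
                   context = get_opt("--context", "all"))
      cat(sprintf(
        "csa: %.2f A^2\n# tail: %s\n# dna: %s\n# radii: %s\n# probe: %.2f n_points: %d\n",
        v, tail_expr, dna_expr,
        paste(names(p$radii), p$radii, sep = "=", collapse = " "),
        p$probe_radius, p$n_sphere_points))
      return(invisible(0L))
    }
    cfg_path <- get_opt("--config")
    outdir <- get_opt("--out")
    if (is.null(cfg_path) || is.null(outdir))
      abort_config(sprintf("%s needs --config <json> and --out <dir>", stage))
    config <- read_run_config(cfg_path)
    acet <- get_opt("--acetylate")
    if (!is.null(acet))
      config$acetylate <- as.integer(strsplit(acet, ",")[[1]])
    switch(stage,
           build = cli_build(config, outdir),
           adapt = cli_adapt(config, outdir),
           sample = cli_sample(config, outdir),
           reweight = cli_reweight(config, outdir),
           analyze = cli_analyze(config, outdir,
                                 reference_outdir = get_opt("--reference")),
           abort_config(sprintf("unknown stage '%s'", stage)))
    0L
  },
  alsdyn_config_error = function(e) { message("config error: ",
                                              conditionMessage(e)); 2L },
  alsdyn_stale_input = function(e) { message("stale input: ",
                                             conditionMessage(e)); 3L },
  alsdyn_numerical_error = function(e) { message("numerical failure: ",
                                                 conditionMessage(e)); 4L },
  error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(code)
}
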