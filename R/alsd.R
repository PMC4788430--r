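# The ALSD sampler: extended-ensemble Langevin dynamics in (coordinates,
# lambda), adaptive estimation of the umbrella bias RT ln P(lambda, T), and
# orchestration of independent TTP runs.

#' ALSD sampler configuration
#'
#' `lambda` ranges over `[lambda_min, lambda_max]` (default 0.6 to 1.03),
#' confined by half-harmonic walls; `m_lambda` is the fictitious mass of
#' lambda.  The special case `lambda_min == lambda_max` disables the lambda
#' dynamics entirely, reducing the sampler to plain canonical Langevin MD
#' (the equivalence oracle).  Bead masses and the time unit are reduced
#' (mass 1); only equilibrium ensembles are targeted.
#'
#' @param temperature K
#' @param lambda_min,lambda_max coupling range; must satisfy
#'   `lambda_min < 1 <= lambda_max` unless equal
#' @param m_lambda fictitious mass of lambda (kcal/mol * time^2)
#' @param wall_k half-harmonic wall constant outside the lambda range
#' @param timestep integration step (reduced time)
#' @param friction Langevin friction (1/time); the default 0.1 is weak
#'   coupling, chosen because conformational diffusion of the chain (and
#'   hence lambda round-trip mixing) slows linearly with friction while
#'   the sampled ensemble is friction-independent
#' @param mass bead mass (reduced)
#' @param n_steps,save_interval default production length and frame stride
#' @param n_bins lambda histogram bins (also the bias knot count)
#' @param noise_scale multiplier on the Langevin noise (0 disables noise;
#'   testing hook for the overdamped limit)
#' @param seed default seed recorded in run metadata
#' @return an object of class `alsd_config`
#' @export
alsd_config <- function(temperature = 300,
                        lambda_min = 0.6, lambda_max = 1.03,
                        m_lambda = 1.0, wall_k = 1000,
                        timestep = 0.01, friction = 0.1, mass = 1.0,
                        n_steps = 20000L, save_interval = 100L,
                        n_bins = 30L, noise_scale = 1.0, seed = 1L) {
  if (lambda_min != lambda_max && !(lambda_min < 1 && 1 <= lambda_max))
    abort_config("need lambda_min < 1 <= lambda_max (or equal, to fix lambda)",
                 "lambda_min")
  for (nm in c("m_lambda", "wall_k", "timestep", "friction", "mass"))
    if (get(nm) <= 0) abort_config(sprintf("%s must be > 0", nm), nm)
  if (n_steps < 0) abort_config("n_steps must be >= 0", "n_steps")
  if (save_interval < 1) abort_config("save_interval must be >= 1", "save_interval")
  structure(list(temperature = as.numeric(temperature),
                 lambda_min = as.numeric(lambda_min),
                 lambda_max = as.numeric(lambda_max),
                 m_lambda = as.numeric(m_lambda),
                 wall_k = as.numeric(wall_k),
                 timestep = as.numeric(timestep),
                 friction = as.numeric(friction),
                 mass = as.numeric(mass),
                 n_steps = as.integer(n_steps),
                 save_interval = as.integer(save_interval),
                 n_bins = as.integer(n_bins),
                 noise_scale = as.numeric(noise_scale),
                 fix_lambda = lambda_min == lambda_max,
                 seed = as.integer(seed)), class = "alsd_config")
}

#' RT in kcal/mol at the configured temperature
#' @param config an `alsd_config` (or anything with `$temperature`)
#' @return numeric
#' @export
rt_energy <- function(config) GAS_CONSTANT * config$temperature

# -- bias --------------------------------------------------------------------

#' Construct an umbrella bias estimate on a lambda grid
#'
#' Tabulates \eqn{\ln P(\lambda, T)} at strictly increasing knots; between
#' knots the value and first derivative come from monotone cubic
#' (Fritsch-Carlson) interpolation, linearly extrapolated with the end
#' slopes outside the grid.
#'
#' @param lambda_grid strictly increasing knots spanning the lambda range
#' @param ln_p log-probability estimate at the knots (finite)
#' @param flatness per-iteration min/max histogram ratios (diagnostics)
#' @return an object of class `bias_estimate` (with a content `hash` used
#'   by the stale-input guard)
#' @export
bias_estimate <- function(lambda_grid, ln_p = rep(0, length(lambda_grid)),
                          flatness = numeric(0)) {
  if (length(lambda_grid) < 1 || any(diff(lambda_grid) <= 0))
    abort_config("lambda_grid must be strictly increasing", "lambda_grid")
  if (length(ln_p) != length(lambda_grid) || !all(is.finite(ln_p)))
    abort_config("ln_p must be finite and match lambda_grid", "ln_p")
  b <- list(lambda_grid = as.numeric(lambda_grid), ln_p = as.numeric(ln_p),
            flatness = flatness)
  b$hash <- hash_object(b[c("lambda_grid", "ln_p")])
  structure(b, class = "bias_estimate")
}

#' Zero (flat) bias on the config's lambda range
#' @param config an `alsd_config`
#' @return a `bias_estimate`
#' @export
zero_bias <- function(config = alsd_config()) {
  bias_estimate(bias_knots(config))
}

bias_knots <- function(config) {
  n <- config$n_bins
  if (config$fix_lambda)
    return(config$lambda_min + c(-0.01, 0.01))
  w <- (config$lambda_max - config$lambda_min) / n
  config$lambda_min + (seq_len(n) - 0.5) * w
}

#' Evaluate a bias (value and derivative) at arbitrary lambda
#' @param bias a `bias_estimate`
#' @param lambda numeric vector
#' @return list with `value` and `deriv`
#' @export
bias_at <- function(bias, lambda) {
  pchip_eval_cpp(bias$lambda_grid, bias$ln_p, as.numeric(lambda))
}

# -- Hamiltonian pieces ------------------------------------------------------

wall_energy <- function(lambda, config) {
  if (lambda > config$lambda_max)
    0.5 * config$wall_k * (lambda - config$lambda_max)^2
  else if (lambda < config$lambda_min)
    0.5 * config$wall_k * (lambda - config$lambda_min)^2
  else 0
}

check_lambda_range <- function(lambda, config) {
  if (lambda < config$lambda_min - 0.5 || lambda > config$lambda_max + 0.5)
    abort_numerical(sprintf(
      "lambda = %g is far outside the walls [%g, %g]: integration blow-up",
      lambda, config$lambda_min, config$lambda_max))
}

#' Potential part of the ALSD Hamiltonian
#'
#' \eqn{\lambda^2 E_{tail} + \lambda E_{tail-rest} + E_{rest} +
#' RT \ln P(\lambda) + wall(\lambda)}; the wall is zero inside the range.
#'
#' @param decomp an `energy_decomposition`
#' @param lambda coupling value
#' @param bias a `bias_estimate`
#' @param config an `alsd_config`
#' @return kcal/mol
#' @export
hamiltonian_potential <- function(decomp, lambda, bias, config = alsd_config()) {
  check_lambda_range(lambda, config)
  lambda^2 * decomp$e_tail + lambda * decomp$e_tail_rest + decomp$e_rest +
    rt_energy(config) * bias_at(bias, lambda)$value +
    wall_energy(lambda, config)
}

#' Generalized force on lambda
#'
#' \eqn{-\partial H/\partial\lambda = -(2\lambda E_{tail} + E_{tail-rest} +
#' RT\,\partial \ln P/\partial\lambda + \partial wall/\partial\lambda)}.
#'
#' @inheritParams hamiltonian_potential
#' @return scalar force
#' @export
lambda_force <- function(decomp, lambda, bias, config = alsd_config()) {
  check_lambda_range(lambda, config)
  dwall <- if (lambda > config$lambda_max)
    config$wall_k * (lambda - config$lambda_max)
  else if (lambda < config$lambda_min)
    config$wall_k * (lambda - config$lambda_min)
  else 0
  -(2 * lambda * decomp$e_tail + decomp$e_tail_rest +
      rt_energy(config) * bias_at(bias, lambda)$deriv + dwall)
}

# -- state and stepping ------------------------------------------------------

#' Initialize an ALSD dynamical state
#'
#' Maxwell-Boltzmann velocities for the mobile beads and for lambda-dot
#' (drawn from the current RNG stream), lambda starting at 1 (clamped into
#' range).
#'
#' @param system a `cg_system`
#' @param config an `alsd_config`
#' @param positions starting coordinates (default: the system's)
#' @param lambda starting coupling value
#' @return an object of class `alsd_state`
#' @export
init_state <- function(system, config = alsd_config(),
                       positions = system$positions, lambda = 1) {
  n <- nrow(system$positions)
  kT <- rt_energy(config)
  vel <- matrix(rnorm(3 * n, sd = sqrt(kT / config$mass)), n, 3)
  vel[!system$mobile, ] <- 0
  lambda <- min(max(lambda, config$lambda_min), config$lambda_max)
  lv <- if (config$fix_lambda) 0 else rnorm(1, sd = sqrt(kT / config$m_lambda))
  structure(list(positions = unname(as.matrix(positions)), velocities = vel,
                 lambda = lambda, lambda_velocity = lv, step = 0L),
            class = "alsd_state")
}

langevin_cfg <- function(config) {
  list(timestep = config$timestep, friction = config$friction,
       temperature = config$temperature, mass = config$mass,
       m_lambda = config$m_lambda, wall_k = config$wall_k,
       lambda_min = config$lambda_min, lambda_max = config$lambda_max,
       fix_lambda = config$fix_lambda, noise_scale = config$noise_scale)
}

run_chunk <- function(state, system, bias, config, params, n_steps,
                      save_interval = config$save_interval) {
  run_langevin_cpp(system, params, langevin_cfg(config),
                   state$positions, state$velocities,
                   state$lambda, state$lambda_velocity,
                   bias$lambda_grid, bias$ln_p,
                   as.integer(n_steps), as.integer(save_interval),
                   config$n_bins)
}

advance_state <- function(state, res, n_steps) {
  structure(list(positions = res$final_positions,
                 velocities = res$final_velocities,
                 lambda = res$final_lambda,
                 lambda_velocity = res$final_lambda_velocity,
                 step = state$step + as.integer(n_steps)),
            class = "alsd_state")
}

#' Advance the joint (coordinates, lambda) Langevin dynamics
#'
#' BAOAB splitting: deterministic half-kicks and drifts around an exact
#' Ornstein-Uhlenbeck friction/noise update, applied to the mobile beads
#' and to lambda with its fictitious mass.  Deterministic given the R RNG
#' state (seed with [set.seed()]).
#'
#' @param state an `alsd_state`
#' @param system a `cg_system`
#' @param bias a `bias_estimate`
#' @param config an `alsd_config`
#' @param params a [forcefield_params()]
#' @param n_steps number of steps to take (default 1)
#' @return the advanced `alsd_state`
#' @export
step_langevin <- function(state, system, bias, config = alsd_config(),
                          params = forcefield_params(), n_steps = 1L) {
  res <- run_chunk(state, system, bias, config, params, n_steps,
                   save_interval = max(1L, as.integer(n_steps)))
  advance_state(state, res, n_steps)
}

# -- adaptive bias estimation ------------------------------------------------

# Conditional thermodynamic-integration estimate of ln P(lambda) from the
# pooled lambda-binned samples of all iterations.  Because the umbrella
# bias depends on lambda alone, the conditional coordinate distribution at
# fixed lambda is canonical at that lambda under ANY bias, so the binned
# average of dH0/dlambda = 2*lambda*E_tail + E_tail-rest estimates
# F'(lambda) without bias-dependent corrections; integrating with the
# trapezoid rule and dividing by -kT gives ln P up to a constant.  Per
# sample this derivative carries far less variance than bin occupancy, and
# up-sweep/down-sweep hysteresis cancels to first order in the pooled
# conditional mean.  Bins never visited inherit the nearest estimated
# derivative (flat continuation) until later iterations cover them.
ti_lnp <- function(counts, dhdl_sum, knots, kT) {
  m <- ifelse(counts > 0, dhdl_sum / pmax(counts, 1), NA_real_)
  if (all(is.na(m))) return(rep(0, length(knots)))
  filled <- which(!is.na(m))
  for (j in which(is.na(m)))
    m[j] <- m[filled[which.min(abs(filled - j))]]
  dF <- diff(knots) * (m[-1] + m[-length(m)]) / 2
  F <- c(0, cumsum(dF))
  lp <- -F / kT
  lp - mean(lp)
}

#' Adaptively estimate the umbrella bias RT ln P(lambda, T)
#'
#' Iteratively runs the sampler under the current bias and re-estimates
#' \eqn{\ln P(\lambda)} from the lambda-binned free-energy derivative
#' pooled over all iterations so far (conditional thermodynamic
#' integration: the binned mean of \eqn{2\lambda E_{tail} +
#' E_{tail-rest}} is \eqn{F'(\lambda)} under any lambda-only bias); the
#' new estimate becomes the next iteration's bias.  Pooling all
#' iterations, rather than adding each iteration's log-histogram to the
#' running bias, keeps the update stable when conformational relaxation
#' is slower than a single iteration.  Stops early once the flatness
#' criterion `min(hist)/max(hist) >= flatness_threshold` holds for an
#' iteration's own histogram.
#'
#' @param system a `cg_system`
#' @param config an `alsd_config`
#' @param n_iterations maximum bias-update iterations (>= 1); ignored when
#'   `steps_per_iteration` is a vector
#' @param steps_per_iteration sampler steps per iteration; a vector gives
#'   an explicit schedule (short exploration iterations followed by long
#'   refinement iterations work well when conformational relaxation is
#'   slow)
#' @param seed integer seed
#' @param flatness_threshold early-stop histogram flatness (default 0.7)
#' @param n_walkers number of independent walkers advanced each iteration
#'   (TTP-style).  Walkers start from distinct self-avoiding initial
#'   conformations and keep their own dynamical state across iterations;
#'   their binned samples are pooled.  Independent walkers decorrelate the
#'   slow conformational modes that dominate the estimator noise on
#'   chain-like systems; 1 (the default) is fine for small systems
#' @param n_equil per-walker burn-in steps at lambda = 1 before any sample
#'   enters the pooled estimate (relaxes the synthetic starting
#'   conformations)
#' @param start_positions optional starting coordinates (single walker)
#' @return a `bias_estimate` whose `flatness` field holds the
#'   per-iteration diagnostics (pooled over walkers)
#' @export
adapt_bias <- function(system, config = alsd_config(), n_iterations = 20L,
                       steps_per_iteration = config$n_steps, seed = 1L,
                       flatness_threshold = 0.7, n_walkers = 1L,
                       n_equil = 0L, start_positions = NULL) {
  if (n_iterations < 1) abort_config("n_iterations must be >= 1", "n_iterations")
  if (config$fix_lambda)
    abort_config("cannot adapt a bias with lambda fixed", "lambda_min")
  sched <- if (length(steps_per_iteration) > 1) as.integer(steps_per_iteration)
    else rep(as.integer(steps_per_iteration), n_iterations)
  set.seed(as.integer(seed))
  bias <- zero_bias(config)
  starts <- if (n_walkers > 1) {
    initial_conformations(system, n_walkers, seed = seed)
  } else {
    list(start_positions %||% system$positions)
  }
  states <- lapply(starts, function(p) init_state(system, config, positions = p))
  params <- forcefield_params(temperature = config$temperature)
  if (n_equil > 0) {
    # burn each walker in at lambda = 1 before any sample is pooled: the
    # self-avoiding starting conformations are not equilibrium draws, and
    # their shared transient would otherwise tilt the pooled estimate in a
    # common direction
    eq_cfg <- config
    eq_cfg$lambda_min <- eq_cfg$lambda_max <- 1
    eq_cfg$fix_lambda <- TRUE
    for (w in seq_along(states)) {
      states[[w]]$lambda <- 1
      res <- run_chunk(states[[w]], system, zero_bias(eq_cfg), eq_cfg, params,
                       n_equil, save_interval = n_equil)
      states[[w]] <- advance_state(states[[w]], res, n_equil)
    }
  }
  flat <- numeric(0)
  counts <- rep(0, config$n_bins)
  dhdl <- rep(0, config$n_bins)
  for (iter in seq_along(sched)) {
    steps_this <- sched[iter]
    h_iter <- rep(0, config$n_bins)
    for (w in seq_along(states)) {
      res <- run_chunk(states[[w]], system, bias, config, params, steps_this,
                       save_interval = steps_this)
      states[[w]] <- advance_state(states[[w]], res, steps_this)
      h_iter <- h_iter + as.numeric(res$lambda_hist)
      dhdl <- dhdl + as.numeric(res$dhdl_sum)
    }
    if (sum(h_iter > 0) <= 1)
      abort_numerical(paste(
        "lambda never left one histogram bin during an iteration;",
        "increase lambda mobility (smaller m_lambda / longer iterations)"))
    counts <- counts + h_iter
    lp <- ti_lnp(counts, dhdl, bias$lambda_grid, rt_energy(config))
    flat <- c(flat, min(h_iter) / max(h_iter))
    bias <- bias_estimate(bias$lambda_grid, lp, flatness = flat)
    if (flat[iter] >= flatness_threshold && iter > 1) break
  }
  bias
}

# -- production and TTP ------------------------------------------------------

#' Fixed-bias production run
#'
#' Runs the sampler under a frozen bias, saving a frame (positions, lambda,
#' three-term energy decomposition) every `save_interval` steps; the
#' full-resolution lambda histogram over the run is recorded for the
#' flatness check.
#'
#' @param system a `cg_system`
#' @param config an `alsd_config`
#' @param bias the adapted `bias_estimate`
#' @param seed integer seed
#' @param positions optional starting coordinates
#' @param n_equil equilibration steps discarded before saving begins
#' @return an object of class `alsd_trajectory`: `frames` (n_frames x 3N
#'   row-per-frame coordinates), `lambda`, `e_tail`, `e_tail_rest`,
#'   `e_rest`, `step`, `lambda_hist` and `meta` (config hash, bias hash,
#'   seed)
#' @export
run_production <- function(system, config = alsd_config(), bias = zero_bias(config),
                           seed = config$seed, positions = NULL,
                           n_equil = 0L) {
  set.seed(as.integer(seed))
  params <- forcefield_params(temperature = config$temperature)
  state <- init_state(system, config, positions = positions %||% system$positions)
  if (n_equil > 0) {
    res <- run_chunk(state, system, bias, config, params, n_equil,
                     save_interval = n_equil)
    state <- advance_state(state, res, n_equil)
  }
  res <- run_chunk(state, system, bias, config, params, config$n_steps)
  ns <- res$n_saved
  structure(list(
    frames = res$frames[seq_len(ns), , drop = FALSE],
    lambda = res$lambda[seq_len(ns)],
    e_tail = res$e_tail[seq_len(ns)],
    e_tail_rest = res$e_tail_rest[seq_len(ns)],
    e_rest = res$e_rest[seq_len(ns)],
    step = res$step[seq_len(ns)],
    lambda_hist = as.numeric(res$lambda_hist),
    meta = list(config_hash = hash_object(unclass(config)),
                bias_hash = bias$hash, seed = as.integer(seed),
                n_beads = nrow(system$positions))),
    class = "alsd_trajectory")
}

#' Number of frames in a trajectory
#' @param trajectory an `alsd_trajectory`
#' @return integer
#' @export
n_frames <- function(trajectory) nrow(trajectory$frames)

#' Coordinates of one saved frame
#' @param trajectory an `alsd_trajectory`
#' @param i frame index
#' @return an N x 3 matrix
#' @export
frame_positions <- function(trajectory, i) {
  matrix(trajectory$frames[i, ], ncol = 3, byrow = TRUE)
}

#' Independent TTP production runs
#'
#' Trivial trajectory parallelization: `n_runs` independent productions
#' from distinct self-avoiding initial conformations, each with its own
#' seed derived from `(base_seed, run index)`.  Results are independent of
#' execution order.  Failed runs are reported with their index; completed
#' runs are preserved.
#'
#' @param system a `cg_system`
#' @param config an `alsd_config`
#' @param bias the adapted `bias_estimate`
#' @param n_runs number of runs (>= 2)
#' @param base_seed integer seed
#' @param n_equil per-run equilibration steps
#' @return a list of `alsd_trajectory` (failures dropped, recorded in the
#'   `failures` attribute)
#' @export
run_ttp <- function(system, config = alsd_config(), bias = zero_bias(config),
                    n_runs = 8L, base_seed = 1L, n_equil = 0L) {
  if (n_runs < 2) abort_config("n_runs must be >= 2", "n_runs")
  confs <- initial_conformations(system, n_runs, seed = base_seed)
  seeds <- (as.integer(base_seed) + 7919L * seq_len(n_runs)) %% 2147483647L
  out <- vector("list", n_runs)
  failures <- list()
  for (r in seq_len(n_runs)) {
    out[[r]] <- tryCatch(
      run_production(system, config, bias, seed = seeds[r],
                     positions = confs[[r]], n_equil = n_equil),
      error = function(e) {
        failures[[length(failures) + 1]] <<- list(run = r,
                                                  message = conditionMessage(e))
        NULL
      })
    if (!is.null(out[[r]])) out[[r]]$meta$run_index <- r
  }
  if (length(failures) == n_runs)
    abort_numerical(sprintf("all %d TTP runs failed; first error: %s",
                            n_runs, failures[[1]]$message))
  if (length(failures))
    warning(sprintf("%d of %d TTP runs failed (indices %s)", length(failures),
                    n_runs, paste(unlist(lapply(failures, `[[`, "run")),
                                  collapse = ", ")))
  out <- out[!vapply(out, is.null, TRUE)]
  attr(out, "failures") <- failures
  out
}
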