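# Canonical-ensemble reconstruction at lambda = 1 by importance
# reweighting, and TTP-style run-level statistics.  Weights are normalized
# within each run; cross-run combination always goes through run-level
# means (never frame pooling), matching the TTP estimate "mean +/- SE over
# independent runs".

#' Reweight an ALSD trajectory to the canonical ensemble at lambda = 1
#'
#' Per-frame log-weight
#' \deqn{\ln w = -\beta[(1-\lambda^2) E_{tail} + (1-\lambda) E_{tail-rest}]
#'   + \ln P(\lambda),}
#' normalized within the run by log-sum-exp.  The bias must be the one the
#' production run used (checked via its content hash, guarding against
#' silent misweighting).
#'
#' @param trajectory an `alsd_trajectory`
#' @param bias the production `bias_estimate`
#' @param config the production `alsd_config`
#' @param lambda_window optional `c(lo, hi)`: restrict to frames with
#'   lambda inside the window (sensitivity analysis; default all frames)
#' @return an object of class `weighted_ensemble`: the trajectory, frame
#'   `weights` (nonnegative, summing to 1), `log_weights`, `ess` (Kish
#'   effective sample size) and `target_lambda = 1`
#' @export
reweight <- function(trajectory, bias, config = alsd_config(),
                     lambda_window = NULL) {
  if (!identical(trajectory$meta$bias_hash, bias$hash))
    abort_stale(paste(
      "bias hash does not match the trajectory metadata;",
      "refusing to reweight with a bias the production run did not use"))
  keep <- seq_along(trajectory$lambda)
  if (!is.null(lambda_window)) {
    keep <- which(trajectory$lambda >= lambda_window[1] &
                    trajectory$lambda <= lambda_window[2])
    if (!length(keep)) abort_numerical("no frames inside lambda_window")
  }
  lam <- trajectory$lambda[keep]
  beta <- 1 / rt_energy(config)
  lw <- -beta * ((1 - lam^2) * trajectory$e_tail[keep] +
                   (1 - lam) * trajectory$e_tail_rest[keep]) +
    bias_at(bias, lam)$value
  w <- exp(lw - lse(lw))
  structure(list(trajectory = trajectory, frame_index = keep,
                 weights = w, log_weights = lw,
                 ess = 1 / sum(w^2), target_lambda = 1),
            class = "weighted_ensemble")
}

#' Weighted ensemble average of a per-frame observable
#'
#' @param ensemble a `weighted_ensemble`
#' @param values per-frame values (full trajectory length or one per kept
#'   frame), or a function applied to each frame's N x 3 coordinates
#' @return the weighted mean
#' @export
ensemble_mean <- function(ensemble, values) {
  v <- frame_values(ensemble, values)
  sum(ensemble$weights * v)
}

# resolve `values` to one number per kept frame
frame_values <- function(ensemble, values) {
  if (is.function(values)) {
    vapply(ensemble$frame_index, function(i)
      values(frame_positions(ensemble$trajectory, i)), numeric(1))
  } else if (length(values) == n_frames(ensemble$trajectory)) {
    values[ensemble$frame_index]
  } else if (length(values) == length(ensemble$frame_index)) {
    values
  } else abort_config("values length matches neither trajectory nor ensemble")
}

#' TTP summary: mean and standard error over run-level values
#'
#' The TTP estimate: the mean of per-run (reweighted) means, with the
#' standard error computed across runs -- never across pooled frames.
#'
#' @param per_run_values one value per independent run (>= 2 runs)
#' @return an object of class `summary_stat` with `mean`, `se`, `n_runs`
#' @export
ttp_summary <- function(per_run_values) {
  v <- as.numeric(per_run_values)
  if (length(v) < 2) abort_config("need >= 2 runs for a TTP summary")
  structure(list(mean = mean(v), se = sd(v) / sqrt(length(v)),
                 n_runs = length(v)), class = "summary_stat")
}

#' @export
print.summary_stat <- function(x, ...) {
  cat(sprintf("%.6g +/- %.3g (SE over %d runs)\n", x$mean, x$se, x$n_runs))
  invisible(x)
}

#' Normalized weighted histogram
#'
#' Bin masses sum to 1.  With `condition`/`condition_breaks` the histogram
#' is computed per condition slice (e.g. the CSA distribution per lambda
#' bin), each slice normalized separately.
#'
#' @param values observable values
#' @param weights nonnegative weights (default uniform); must not be all
#'   zero
#' @param breaks bin edges covering the values
#' @param condition optional per-value conditioning variable
#' @param condition_breaks bin edges for `condition`
#' @return a list: `breaks`, `mass` (sums to 1), `mids`; or, conditioned, a
#'   matrix of masses (rows = value bins, columns = condition bins)
#' @export
weighted_histogram <- function(values, weights = NULL, breaks,
                               condition = NULL, condition_breaks = NULL) {
  n <- length(values)
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n) abort_config("weights/values length mismatch")
  if (all(weights == 0)) abort_config("all-zero weights")
  if (is.null(condition)) {
    bin <- cut(values, breaks, include.lowest = TRUE, labels = FALSE)
    if (anyNA(bin)) abort_config("values fall outside breaks")
    mass <- vapply(seq_len(length(breaks) - 1),
                   function(b) sum(weights[bin == b]), numeric(1))
    mass <- mass / sum(mass)
    list(breaks = breaks, mass = mass,
         mids = (breaks[-1] + breaks[-length(breaks)]) / 2)
  } else {
    cb <- cut(condition, condition_breaks, include.lowest = TRUE, labels = FALSE)
    m <- sapply(seq_len(length(condition_breaks) - 1), function(s) {
      sel <- which(cb == s)
      if (!length(sel) || sum(weights[sel]) == 0)
        return(rep(NA_real_, length(breaks) - 1))
      weighted_histogram(values[sel], weights[sel], breaks)$mass
    })
    rownames(m) <- sprintf("[%g,%g)", breaks[-length(breaks)], breaks[-1])
    colnames(m) <- sprintf("[%g,%g)", condition_breaks[-length(condition_breaks)],
                           condition_breaks[-1])
    m
  }
}

#' Reweighted TTP summary of an observable over several runs
#'
#' Convenience wrapper: per-run weighted means, then [ttp_summary()].
#'
#' @param ensembles a list of `weighted_ensemble`, one per run
#' @param values per-frame observable (vector per run, or a function of
#'   frame coordinates)
#' @return a `summary_stat`
#' @export
ttp_observable <- function(ensembles, values) {
  per_run <- vapply(seq_along(ensembles), function(r) {
    v <- if (is.list(values) && !is.function(values)) values[[r]] else values
    ensemble_mean(ensembles[[r]], v)
  }, numeric(1))
  ttp_summary(per_run)
}
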