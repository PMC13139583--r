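#' Solver configuration
#'
#' The models are integrated with a fixed-step classical Runge-Kutta scheme.
#' The step is `grid_step / velocity` divided into substeps so that it never
#' exceeds `max_step`; the default maximum step of 0.01 s (0.5 cm at
#' 50 cm/s) guarantees that no 1 cm cue window is skipped.
#'
#' @param max_step Maximum integration step (s). Default 0.01.
#' @param grid_step Output grid spacing (cm). Default 0.1.
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(max_step = 0.01, grid_step = 0.1) {
  stopifnot(max_step > 0, grid_step > 0)
  structure(list(max_step = max_step, grid_step = grid_step),
            class = "solver_config")
}

#' Fixed-step RK4 integration of a generic right-hand side
#'
#' A small deterministic integrator used for cross-checks and custom
#' dynamics; the circuit models use the compiled equivalent.
#'
#' @param rhs Function `rhs(t, state)` returning the derivative.
#' @param init Initial state vector.
#' @param times Monotone vector of output times; integration substeps never
#'   exceed `max_step`.
#' @param max_step Maximum step (s).
#' @param project Optional function applied to the state after every step
#'   (e.g. `function(s) pmax(s, 0)` for rectified rate dynamics, matching
#'   the compiled simulators).
#' @return Matrix `length(init) x length(times)`; first column is `init`.
#' @export
integrate_ode <- function(rhs, init, times, max_step = 0.01,
                          project = NULL) {
  stopifnot(all(is.finite(init)), !is.unsorted(times))
  out <- matrix(NA_real_, length(init), length(times))
  out[, 1] <- s <- init
  for (g in seq_along(times)[-1]) {
    dt <- times[g] - times[g - 1]
    nsub <- max(1L, ceiling(dt / max_step - 1e-12))
    h <- dt / nsub
    t <- times[g - 1]
    for (sub in seq_len(nsub)) {
      k1 <- rhs(t, s)
      k2 <- rhs(t + h / 2, s + h / 2 * k1)
      k3 <- rhs(t + h / 2, s + h / 2 * k2)
      k4 <- rhs(t + h, s + h * k3)
      s <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (!is.null(project)) s <- project(s)
      t <- t + h
    }
    if (any(!is.finite(s)))
      stop("non-finite state at t = ", signif(t, 6))
    out[, g] <- s
  }
  out
}

#' Simulate a set of trials with one model
#'
#' Runs the chosen simulator on each trial and collects the choices; full
#' rate trajectories can be kept, reduced, or discarded.
#'
#' @param trials List of `evseq_trial` objects.
#' @param model `"mutual"`, `"uncoupled"`, `"unstable"`, `"bump"`,
#'   `"trad_accum"` or `"trad_bump"`.
#' @param params Optional [chain_params()] / [bump_params()] overriding the
#'   model default.
#' @param gate Optional `evseq_gate`.
#' @param geometry,solver Geometry and solver configuration.
#' @param reduce Function applied to each `evseq_sim` before storing (e.g.
#'   a binning step); `NULL` stores choices only.
#' @return A list of class `evseq_session`: `choices` data.frame
#'   (`trial_id`, `delta`, `choice`) and, if requested, `results`.
#' @export
simulate_trials <- function(trials,
                            model = c("mutual", "uncoupled", "unstable",
                                      "bump", "trad_accum", "trad_bump"),
                            params = NULL, gate = NULL,
                            geometry = maze_geometry(),
                            solver = solver_config(), reduce = NULL) {
  model <- match.arg(model)
  sim_fun <- model_sim_fun(model, params, gate, geometry, solver)
  results <- if (!is.null(reduce)) vector("list", length(trials)) else NULL
  choices <- character(length(trials))
  delta <- integer(length(trials))
  for (k in seq_along(trials)) {
    res <- sim_fun(trials[[k]])
    choices[k] <- res$choice
    delta[k] <- final_evidence(trials[[k]])
    if (!is.null(reduce)) results[[k]] <- reduce(res)
  }
  structure(list(choices = data.frame(
    trial_id = vapply(trials, function(tr) tr$trial_id, double(1)),
    delta = delta, choice = choices),
    results = results, model = model),
    class = "evseq_session")
}

#' Single-trial simulator closure for a named model
#'
#' Returns a function mapping an `evseq_trial` to an `evseq_sim`, wiring in
#' parameters, gate, geometry and solver; used to stream simulations through
#' analyses such as [model_tuning_curves()] and [bin_model_session()].
#'
#' @inheritParams simulate_trials
#' @return A function of one trial.
#' @export
model_sim_fun <- function(model, params = NULL, gate = NULL,
                          geometry = maze_geometry(),
                          solver = solver_config()) {
  switch(model,
    mutual = ,
    uncoupled = ,
    unstable = {
      if (is.null(params)) params <- chain_params(variant = model)
      function(tr) simulate_chain_trial(tr, params, gate, geometry, solver)
    },
    bump = {
      if (is.null(params)) params <- bump_params()
      function(tr) simulate_bump_trial(tr, params, gate, geometry, solver)
    },
    trad_accum = function(tr)
      simulate_traditional_accumulator(tr, geometry = geometry,
                                       solver = solver),
    trad_bump = {
      if (is.null(params)) params <- bump_params()
      function(tr) simulate_traditional_bump(tr, params, geometry, solver)
    })
}

#' Run the input-noise session protocol
#'
#' Draws `trials_per_session` trials per session without replacement from a
#' trial pool, thins each trial's cues to `keep_prob` (the animal perceiving
#' only a third of the towers), simulates the model on the reduced cue sets,
#' and records the choice against the ORIGINAL cue counts for
#' psychometrics.
#'
#' @param trial_pool List of trials (at least `trials_per_session`).
#' @param model Model name as in [simulate_trials()].
#' @param cfg A [noise_config()].
#' @inheritParams simulate_trials
#' @return Data frame with columns `session`, `trial_id`, `delta`
#'   (original), `delta_perceived`, `choice`.
#' @export
run_noise_sessions <- function(trial_pool, model = "mutual",
                               cfg = noise_config(), params = NULL,
                               gate = NULL, geometry = maze_geometry(),
                               solver = solver_config()) {
  if (length(trial_pool) < cfg$trials_per_session)
    stop("trial pool smaller than trials_per_session")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  sim_fun <- model_sim_fun(model, params, gate, geometry, solver)
  out <- vector("list", cfg$n_sessions)
  for (s in seq_len(cfg$n_sessions)) {
    idx <- sample.int(length(trial_pool), cfg$trials_per_session)
    rows <- lapply(idx, function(k) {
      tr <- trial_pool[[k]]
      noisy <- apply_input_noise(tr, cfg$keep_prob)
      res <- sim_fun(noisy)
      data.frame(session = s, trial_id = tr$trial_id,
                 delta = final_evidence(tr),
                 delta_perceived = final_evidence(noisy),
                 choice = res$choice)
    })
    out[[s]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}

#' Psychometric curve
#'
#' Fraction of left choices as a function of the final cue-count difference
#' `delta = #right - #left`, binned with width 3 towers over -14..14 (bin
#' centers 0, +/-3, ..., +/-12; the outermost bins absorb |delta| = 13, 14).
#' The s.e.m. is computed across sessions when a `session` column is
#' present, else binomially per bin.
#'
#' @param choices Data frame with columns `delta` and `choice` (and
#'   optionally `session`).
#' @return Data frame with `delta_bin` (center), `n`, `frac_left`, `sem`;
#'   empty bins are flagged with `n = 0` and `NA` fractions.
#' @export
psychometric_curve <- function(choices) {
  centers <- seq(-12, 12, by = 3)
  bin_of <- function(d) pmax(-12, pmin(12, round(d / 3) * 3))
  keep <- abs(choices$delta) <= 14
  df <- choices[keep, , drop = FALSE]
  df$bin <- bin_of(df$delta)
  per_bin <- function(b) {
    sub <- df[df$bin == b, , drop = FALSE]
    n <- nrow(sub)
    if (n == 0)
      return(data.frame(delta_bin = b, n = 0L, frac_left = NA_real_,
                        sem = NA_real_))
    fl <- mean(sub$choice == "left")
    sem <- if (!is.null(sub$session) && length(unique(sub$session)) > 1) {
      per_sess <- tapply(sub$choice == "left", sub$session, mean)
      stats::sd(per_sess) / sqrt(length(per_sess))
    } else {
      sqrt(fl * (1 - fl) / n)
    }
    data.frame(delta_bin = b, n = n, frac_left = fl, sem = sem)
  }
  do.call(rbind, lapply(centers, per_bin))
}

#' Evidence tuning curves of model neurons
#'
#' For each simulated unit, bins activity by position (the 0.1 cm grid) and
#' accumulated evidence (1-tower bins over `evidence_range`), drops bins
#' with fewer than `min_samples` samples, finds the position of maximal mean
#' firing (averaged across evidence), and returns the mean rate versus
#' evidence at that position.
#'
#' Because full bump-model trajectories are large, trials are simulated
#' twice in a streaming fashion (the integrator is deterministic): once to
#' locate each unit's peak position and once to collect rates there.
#'
#' @param trials List of trials to simulate.
#' @param sim_fun Function mapping a trial to an `evseq_sim` (see
#'   [model_sim_fun()] via [simulate_trials()]), or a list of precomputed
#'   `evseq_sim` objects for the same trials.
#' @param evidence_range Integer range of evidence bins. Default -15..15.
#' @param min_samples Minimum samples per (position, evidence) bin. Default 2.
#' @return A list with `peak_position` (per unit, cm) and `curves`, a data
#'   frame (`unit`, `evidence`, `rate`, `n`).
#' @export
model_tuning_curves <- function(trials, sim_fun, evidence_range = c(-15, 15),
                                min_samples = 2) {
  precomputed <- is.list(sim_fun)
  get_res <- function(k) if (precomputed) sim_fun[[k]] else
    sim_fun(trials[[k]])
  # pass 1: mean rate per grid column
  res1 <- get_res(1)
  sums <- res1$rates
  grid <- res1$grid
  for (k in seq_along(trials)[-1]) sums <- sums + get_res(k)$rates
  mean_rates <- sums / length(trials)
  peak_col <- apply(mean_rates, 1, which.max)
  # pass 2: rate and evidence at each unit's peak column per trial
  nu <- nrow(mean_rates)
  rate_at_peak <- matrix(NA_real_, length(trials), nu)
  ev_at_peak <- matrix(NA_integer_, length(trials), nu)
  for (k in seq_along(trials)) {
    res <- get_res(k)
    rate_at_peak[k, ] <- res$rates[cbind(seq_len(nu), peak_col)]
    ev_cols <- evidence_before(trials[[k]], grid[unique(peak_col)])
    ev_at_peak[k, ] <- ev_cols[match(peak_col, unique(peak_col))]
  }
  levels <- seq(evidence_range[1], evidence_range[2])
  rows <- lapply(seq_len(nu), function(u) {
    e <- ev_at_peak[, u]
    r <- rate_at_peak[, u]
    keep <- e >= evidence_range[1] & e <= evidence_range[2]
    tab <- table(factor(e[keep], levels = levels))
    means <- tapply(r[keep], factor(e[keep], levels = levels), mean)
    ok <- !is.na(means) & tab >= min_samples
    if (!any(ok)) return(NULL)
    data.frame(unit = u, evidence = as.integer(levels[ok]),
               rate = as.numeric(means[ok]), n = as.integer(tab[ok]))
  })
  list(peak_position = grid[peak_col],
       curves = do.call(rbind, rows))
}

#' Simulated single-neuron optogenetic perturbation
#'
#' Simulates a cue-free trial with and without a subthreshold excitatory
#' drive `O` added inside the rectification (chains) or inside `F` (bump)
#' of one unit, and returns the per-unit, per-position rate difference.
#' Default magnitudes: 25 Hz/s (mutual/unstable chains), 12.5 Hz/s
#' (uncoupled chains), 0.2 Hz/s (bump).
#'
#' @param params A [chain_params()] or [bump_params()].
#' @param target For chains: `list(side = "left"|"right", index = i)`
#'   (1-based unit). For the bump: `list(position = i, evidence = j)`
#'   (1-based layer, integer evidence level).
#' @param magnitude Perturbation drive (Hz/s); `NULL` picks the model
#'   default.
#' @param gate,geometry,solver Passed to the simulator.
#' @return List with `delta` (perturbed - control rates, units x grid),
#'   `control`, `perturbed` (both `evseq_sim`) and `grid`.
#' @export
run_perturbation <- function(params, target, magnitude = NULL, gate = NULL,
                             geometry = maze_geometry(),
                             solver = solver_config()) {
  no_cue <- trial(trial_id = 0, geometry = geometry)
  if (inherits(params, "chain_params")) {
    if (is.null(magnitude))
      magnitude <- if (params$variant == "uncoupled") 12.5 else 25
    n <- params$n_positions
    oL <- numeric(n); oR <- numeric(n)
    if (target$side == "left") oL[target$index] <- magnitude
    else oR[target$index] <- magnitude
    ctrl <- simulate_chain_trial(no_cue, params, gate, geometry, solver)
    pert <- simulate_chain_trial(no_cue, params, gate, geometry, solver,
                                 perturb = list(o_left = oL, o_right = oR))
  } else if (inherits(params, "bump_params")) {
    if (is.null(magnitude)) magnitude <- 0.2
    O <- matrix(0, params$n_positions, params$n_evidence)
    j <- match(target$evidence, evidence_levels(params))
    if (is.na(j)) stop("target evidence level not represented")
    O[target$position, j] <- magnitude
    ctrl <- simulate_bump_trial(no_cue, params, gate, geometry, solver)
    pert <- simulate_bump_trial(no_cue, params, gate, geometry, solver,
                                perturb = O)
  } else stop("params must be chain_params or bump_params")
  list(delta = pert$rates - ctrl$rates, control = ctrl, perturbed = pert,
       grid = ctrl$grid)
}
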