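#' Configuration of a synthetic neural session
#'
#' Synthetic sessions provide ground-truth-known inputs for every analysis
#' stage. Two families are available:
#'
#' * `"parametric"`: neurons are drawn from known tuning fields
#'   `FR(p, e) = A * P(p) * E(e) + base`, with `P` Gaussian in position and
#'   `E` Gaussian in evidence (`tuning = "gaussian"`), logistic in evidence
#'   (`"logistic"`), choice-only (`"choice"`, a binary preferred-choice
#'   gain) or absent (`"null"`, pure position tuning).
#' * `"model"`: neurons are units of a simulated circuit model (see
#'   [bin_model_session()] for the binned equivalent).
#'
#' Behavioral choices follow the majority side, flipped by a lapse
#' probability `plogis(-lapse_beta * |delta|)` that is 0.5 on zero-evidence
#' trials and decays with the cue-count difference, so incorrect trials
#' exist (needed to separate evidence from choice coding).
#'
#' @param n_neurons Number of neurons (parametric family).
#' @param n_trials Number of trials.
#' @param tuning `"gaussian"`, `"logistic"`, `"choice"` or `"null"`.
#' @param noise `"none"`, `"gaussian"` or `"poisson"`.
#' @param noise_sd Additive noise sd (Hz) when `noise = "gaussian"`.
#' @param frame_rate Samples per second. Default 30.
#' @param lapse_beta Lapse steepness (per tower). Default 0.4.
#' @param mean_low,mean_high Poisson cue-count means (see
#'   [generate_trials()]).
#' @param geometry A [maze_geometry()].
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_neurons = 40, n_trials = 150,
                         tuning = c("gaussian", "logistic", "choice",
                                    "null"),
                         noise = c("gaussian", "none", "poisson"),
                         noise_sd = 0.5, frame_rate = 30, lapse_beta = 0.4,
                         mean_low = 2.3, mean_high = 7.7,
                         geometry = maze_geometry()) {
  structure(list(n_neurons = n_neurons, n_trials = n_trials,
                 tuning = match.arg(tuning), noise = match.arg(noise),
                 noise_sd = noise_sd, frame_rate = frame_rate,
                 lapse_beta = lapse_beta, mean_low = mean_low,
                 mean_high = mean_high, geometry = geometry),
            class = "synth_config")
}

#' Generate a synthetic neural session
#'
#' Samples trials, per-neuron ground-truth tuning parameters, frame-rate
#' position traces (constant velocity) and firing rates, plus lapse-model
#' choices. Uses R's global RNG.
#'
#' @param cfg A [synth_config()].
#' @return List of class `evseq_synth_session`: `rates` (neurons x
#'   samples), `positions`, `trial_index`, `trials`, `choices`,
#'   `ground_truth` (data frame of generating parameters), `cfg`.
#' @export
generate_session <- function(cfg = synth_config()) {
  g <- cfg$geometry
  trials <- generate_trials(cfg$n_trials, cfg$mean_low, cfg$mean_high,
                            geometry = g)
  dt_pos <- g$velocity / cfg$frame_rate
  pos1 <- seq(g$precue_start, g$maze_end - 1e-9, by = dt_pos)
  positions <- rep(pos1, cfg$n_trials)
  trial_index <- rep(seq_len(cfg$n_trials), each = length(pos1))
  delta <- vapply(trials, final_evidence, integer(1))
  # lapse-model choices: correct side flipped with prob plogis(-beta |delta|)
  p_err <- stats::plogis(-cfg$lapse_beta * abs(delta))
  err <- stats::runif(cfg$n_trials) < p_err
  correct_side <- ifelse(delta > 0, "right", ifelse(delta < 0, "left",
                         sample(c("left", "right"), cfg$n_trials, TRUE)))
  other <- function(x) ifelse(x == "left", "right", "left")
  choices <- ifelse(err, other(correct_side), correct_side)
  gt <- data.frame(
    neuron = seq_len(cfg$n_neurons),
    mu_p = stats::runif(cfg$n_neurons, -20, 290),
    sigma_p = stats::runif(cfg$n_neurons, 20, 45),
    mu_e = stats::runif(cfg$n_neurons, -8, 8),
    sigma_e = stats::runif(cfg$n_neurons, 2, 8),
    k = stats::runif(cfg$n_neurons, 0.3, 0.9) *
      sample(c(-1, 1), cfg$n_neurons, TRUE),
    amp = stats::runif(cfg$n_neurons, 3, 8),
    base = stats::runif(cfg$n_neurons, 0.2, 1),
    pref = sample(c("left", "right"), cfg$n_neurons, TRUE))
  ev <- unlist(lapply(trials, function(tr) evidence_before(tr, pos1)))
  rates <- matrix(0, cfg$n_neurons, length(positions))
  choice_per_sample <- choices[trial_index]
  for (i in seq_len(cfg$n_neurons)) {
    P <- exp(-(positions - gt$mu_p[i])^2 / (2 * gt$sigma_p[i]^2))
    Efield <- switch(cfg$tuning,
      gaussian = exp(-(ev - gt$mu_e[i])^2 / (2 * gt$sigma_e[i]^2)),
      logistic = 1 / (1 + exp(-gt$k[i] * (ev - 0))),
      choice = as.numeric(choice_per_sample == gt$pref[i]),
      null = 1)
    rates[i, ] <- gt$amp[i] * P * Efield + gt$base[i]
  }
  if (cfg$noise == "gaussian") {
    rates <- rates + matrix(stats::rnorm(length(rates), 0, cfg$noise_sd),
                            nrow(rates))
    rates[rates < 0] <- 0
  } else if (cfg$noise == "poisson") {
    spikes <- matrix(stats::rpois(length(rates), rates / cfg$frame_rate),
                     nrow(rates))
    rates <- t(apply(spikes, 1, smooth_rates, kernel = "gaussian",
                     frame_rate = cfg$frame_rate)) * cfg$frame_rate
  }
  structure(list(rates = rates, positions = positions,
                 trial_index = trial_index, trials = trials,
                 choices = choices, ground_truth = gt, cfg = cfg),
            class = "evseq_synth_session")
}

#' Bin a synthetic session
#' @param session An `evseq_synth_session`.
#' @param ... Passed to [bin_session()].
#' @return An `evseq_binned`.
#' @export
bin_synth_session <- function(session, ...) {
  bin_session(session$rates, session$positions, session$trial_index,
              session$trials, session$choices, ...)
}

#' Smooth a spike train or rate trace
#'
#' Convolution with a unit-mass Gaussian window (length 1 s, sd 0.25 s) or
#' its causal half (zero weight on future samples), at the given frame
#' rate. Edges are zero-padded.
#'
#' @param x Numeric vector (one neuron's samples).
#' @param kernel `"gaussian"` or `"causal"`.
#' @param frame_rate Samples per second. Default 30.
#' @param window Window length (s). Default 1.
#' @param sd Kernel standard deviation (s). Default 0.25.
#' @return Smoothed vector of the same length.
#' @export
smooth_rates <- function(x, kernel = c("gaussian", "causal"),
                         frame_rate = 30, window = 1, sd = 0.25) {
  kernel <- match.arg(kernel)
  half <- round(window * frame_rate / 2)
  lags <- (-half):half
  w <- exp(-(lags / (sd * frame_rate))^2 / 2)
  if (kernel == "causal") w[lags < 0] <- 0
  w <- w / sum(w)
  n <- length(x)
  out <- numeric(n)
  for (k in seq_along(lags)) {
    lag <- lags[k]
    src <- seq_len(n) - lag
    ok <- src >= 1 & src <= n
    out[ok] <- out[ok] + w[k] * x[src[ok]]
  }
  out
}
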