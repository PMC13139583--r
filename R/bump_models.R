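#' Parameters of the position-gated bump attractor
#'
#' Layers of ring-connected neurons, one layer per position section, with
#' each neuron in a layer tuned to one integer evidence level. The rate of
#' the neuron at position `i` and evidence level `j` obeys
#' \deqn{dr_{i,j}/dt = -a r_{i,j} + F(\sum_k W_{j,k} r_{i,k} + b r_{i-1,j}
#'   + c (I_{i,j+1,L} + I_{i,j-1,R}) + P_i(t) - T)}
#' with output nonlinearity `F(x) = q (1 + tanh(gamma x)) / 2`, cosine
#' recurrent weights `W`, feedforward weight `b` between equal evidence
#' levels of neighboring layers, and shifter-neuron inputs (Eqs. for
#' `I_{i,j,L/R}`) that move the bump one evidence level per cue.
#'
#' Defaults (a=55, b=0.088, c=0.2, T=300, X=0.04, q=1250, gamma=1,
#' omega0=0.12, omega1=-1) with 17 position layers and 35 evidence levels
#' (-17..17) give 595 neurons in total.
#'
#' @param a Decay rate (1/s).
#' @param b Feedforward weight between layers (1/s).
#' @param c_shift Shifter synaptic weight (1/s).
#' @param T_thresh Soft threshold inside `F` (Hz/s).
#' @param X External drive above threshold at the active layer (Hz/s).
#' @param q Maximal output of `F` (Hz/s).
#' @param gamma Gain of the tanh nonlinearity (s/Hz).
#' @param omega0,omega1 Cosine weight profile parameters
#'   (`W_jk = omega0 (cos(theta_j - theta_k) + omega1)`).
#' @param n_evidence Number of evidence levels (odd, so 0 is a level).
#' @param n_positions Number of position layers.
#' @return An object of class `bump_params`.
#' @export
bump_params <- function(a = 55, b = 0.088, c_shift = 0.2, T_thresh = 300,
                        X = 0.04, q = 1250, gamma = 1, omega0 = 0.12,
                        omega1 = -1.0, n_evidence = 35, n_positions = 17) {
  stopifnot(n_evidence %% 2 == 1, n_evidence >= 3, q > 0, gamma > 0)
  structure(list(a = a, b = b, c_shift = c_shift, T_thresh = T_thresh,
                 X = X, q = q, gamma = gamma, omega0 = omega0,
                 omega1 = omega1, n_evidence = as.integer(n_evidence),
                 n_positions = as.integer(n_positions)),
            class = "bump_params")
}

#' Evidence levels represented by a bump model
#' @param params A [bump_params()].
#' @return Integer vector, e.g. -17..17 for the defaults.
#' @export
evidence_levels <- function(params) {
  half <- (params$n_evidence - 1) / 2
  as.integer(seq(-half, half))
}

#' Cosine recurrent weight matrix
#'
#' Each evidence level is assigned an angle, evenly spaced on `[0, 2*pi)`,
#' and `W_jk = omega0 * (cos(theta_j - theta_k) + omega1)`: local (near-zero)
#' coupling between neighbors and long-range inhibition. The matrix is
#' symmetric and circulant.
#'
#' @param params A [bump_params()].
#' @return An `n_evidence x n_evidence` matrix (1/s).
#' @export
cosine_weights <- function(params) {
  nev <- params$n_evidence
  theta <- 2 * pi * (seq_len(nev) - 1) / nev
  params$omega0 * (cos(outer(theta, theta, "-")) + params$omega1)
}

#' Neuronal output nonlinearity
#'
#' `F(x) = q * (1 + tanh(gamma * x)) / 2`: strictly increasing with range
#' `(0, q)`.
#'
#' @param x Net input (Hz/s), vectorized.
#' @param params A [bump_params()].
#' @return Output drive (Hz/s).
#' @export
output_nonlinearity <- function(x, params = bump_params()) {
  params$q * (1 + tanh(params$gamma * x)) / 2
}

#' Shifter-neuron rates
#'
#' The shifter neurons multiplicatively gate the global cue signal by the
#' local bump activity: `I_{i,j,L} = r_{i,j} * 1_left(t)` and
#' `I_{i,j,R} = r_{i,j} * 1_right(t)`.
#'
#' @param state Rate matrix (`n_positions x n_evidence`, Hz).
#' @param trial An `evseq_trial`.
#' @param p Position (cm).
#' @return List with matrices `left` and `right`.
#' @export
shifter_rates <- function(state, trial, p) {
  list(left = state * cue_indicator(trial, p, "left"),
       right = state * cue_indicator(trial, p, "right"))
}

#' Position-gated bump attractor right-hand side (reference implementation)
#'
#' Derivative of the full rate field at position `p`; evidence levels at the
#' boundaries lack the out-of-range shifter term (the nominal periodic seam
#' is severed). Mirrors the compiled integrator used by
#' [simulate_bump_trial()].
#'
#' @param state Rate matrix (`n_positions x n_evidence`, Hz).
#' @param p Position (cm).
#' @param params A [bump_params()].
#' @param trial An `evseq_trial`.
#' @param gate An `evseq_gate`; default square gate with the bump threshold.
#' @param perturb Optional matrix (same shape as `state`) of subthreshold
#'   drives added inside `F`.
#' @return Derivative matrix (Hz/s).
#' @export
bump_rhs <- function(state, p, params, trial, gate = NULL, perturb = NULL) {
  npos <- params$n_positions
  nev <- params$n_evidence
  if (!all(dim(state) == c(npos, nev))) stop("state shape mismatch")
  if (is.null(gate)) gate <- default_bump_gate(params)
  spec <- gate_cpp_spec(gate, npos)
  P <- gate_values_from_spec(spec, p, npos)
  iL <- cue_indicator(trial, p, "left")
  iR <- cue_indicator(trial, p, "right")
  O <- if (is.null(perturb)) matrix(0, npos, nev) else perturb
  W <- cosine_weights(params)
  acc <- state %*% t(W)
  acc <- acc + params$b * rbind(0, state[-npos, , drop = FALSE])
  shiftL <- cbind(state[, -1, drop = FALSE], 0) * iL   # from level j + 1
  shiftR <- cbind(0, state[, -nev, drop = FALSE]) * iR # from level j - 1
  acc <- acc + params$c_shift * (shiftL + shiftR) +
    matrix(P, npos, nev) - params$T_thresh + O
  -params$a * state + output_nonlinearity(acc, params)
}

# square gate matching the bump parameterization
default_bump_gate <- function(params, geometry = maze_geometry()) {
  square_gate(P0 = 20, T_thresh = params$T_thresh, X = params$X,
              geometry = geometry)
}

#' Initial condition of the bump models
#'
#' Neurons at evidence levels -1, 0 and +1 of the first layer start at 15,
#' 17.5 and 15 Hz; all others at 0 Hz.
#' @param params A [bump_params()].
#' @return Rate matrix (`n_positions x n_evidence`).
#' @export
bump_initial_state <- function(params = bump_params()) {
  lev <- evidence_levels(params)
  init <- matrix(0, params$n_positions, params$n_evidence)
  init[1, match(c(-1, 0, 1), lev)] <- c(15, 17.5, 15)
  init
}

#' Simulate a position-gated bump attractor trial
#'
#' Integrates the full `n_positions x n_evidence` rate field over the maze
#' (fixed-step RK4, sampled on the 0.1 cm grid).
#'
#' @param trial An `evseq_trial`.
#' @param params A [bump_params()].
#' @param gate An `evseq_gate`; default square gate implied by `params`.
#' @param geometry A [maze_geometry()].
#' @param solver A [solver_config()]; the default uses a 0.5 ms maximum step
#'   because the shifter pulses during layer handoffs need a finer fixed
#'   step than the chains model (see the methods vignette).
#' @param perturb Optional perturbation matrix (`n_positions x n_evidence`,
#'   Hz/s) added inside `F`.
#' @param init Initial rate matrix; default [bump_initial_state()].
#' @return An `evseq_sim` with `rates` (neurons x grid), neuron metadata in
#'   `$neurons` (`neuron_id`, `position_index`, `evidence_level`, `side`),
#'   and the model `choice`.
#' @export
simulate_bump_trial <- function(trial, params = bump_params(), gate = NULL,
                                geometry = maze_geometry(),
                                solver = solver_config(max_step = 5e-4),
                                perturb = NULL, init = NULL) {
  npos <- params$n_positions
  nev <- params$n_evidence
  if (is.null(gate)) gate <- default_bump_gate(params, geometry)
  spec <- gate_cpp_spec(gate, npos)
  if (is.null(init)) init <- bump_initial_state(params)
  O <- if (is.null(perturb)) matrix(0, npos, nev) else perturb
  stopifnot(all(dim(init) == c(npos, nev)), all(dim(O) == c(npos, nev)))
  # flat layout: index i * nev + j (position-major)
  rates <- sim_bump_cpp(trial$left_cues, trial$right_cues, params$a,
                        params$b, params$c_shift, params$T_thresh, params$q,
                        params$gamma, cosine_weights(params), npos, nev, spec,
                        as.numeric(t(O)), as.numeric(t(init)),
                        geometry$precue_start, geometry$maze_end,
                        geometry$velocity, solver$grid_step, solver$max_step,
                        cosine_fast = TRUE, omega0 = params$omega0,
                        omega1 = params$omega1)
  grid <- seq(geometry$precue_start, geometry$maze_end, by = solver$grid_step)
  lev <- evidence_levels(params)
  meta <- data.frame(neuron_id = seq_len(npos * nev),
                     position_index = rep(seq_len(npos), each = nev),
                     evidence_level = rep(lev, npos))
  meta$side <- ifelse(meta$evidence_level < 0, "left",
                      ifelse(meta$evidence_level > 0, "right", "none"))
  rownames(rates) <- sprintf("p%02d_e%+03d", meta$position_index,
                             meta$evidence_level)
  res <- structure(list(rates = rates, grid = grid, trial = trial,
                        model = "bump", params = params, neurons = meta,
                        geometry = geometry),
                   class = "evseq_sim")
  res$choice <- readout_choice_bump(res)
  res
}

#' Choice readout of a bump simulation
#'
#' The choice is read from the evidence label of the most active neuron in
#' the final position layer at the end of the maze: negative label means
#' left, positive right, and a peak exactly at evidence 0 is resolved at
#' random with equal probability.
#'
#' @param result An `evseq_sim` from [simulate_bump_trial()].
#' @return `"left"` or `"right"`.
#' @export
readout_choice_bump <- function(result) {
  params <- result$params
  nev <- params$n_evidence
  npos <- params$n_positions
  last_layer <- result$rates[(npos - 1) * nev + seq_len(nev), ncol(result$rates)]
  lev <- evidence_levels(params)[which.max(last_layer)]
  if (lev < 0) "left" else if (lev > 0) "right"
  else if (stats::runif(1) < 0.5) "left" else "right"
}

#' Traditional (ungated) bump attractor baseline
#'
#' A single ring of 35 evidence-tuned neurons with no position gating:
#' `dr_j/dt = -a r_j + F(sum_k W_jk r_k + c (I_{j+1,L} + I_{j-1,R}) + X)`.
#' The bump persists at a fixed evidence location when no cues arrive, so
#' the model integrates evidence but produces no positional sequence.
#'
#' @param state Numeric vector of 35 rates (Hz).
#' @param p Position (cm) for the cue indicators.
#' @param trial An `evseq_trial`.
#' @param params A [bump_params()]; `T_thresh` is ignored (no gate) and `b`
#'   unused.
#' @return `traditional_bump_rhs`: derivative vector (Hz/s).
#' @export
traditional_bump_rhs <- function(state, p, trial, params = bump_params()) {
  st <- matrix(state, 1, params$n_evidence)
  p1 <- params
  p1$n_positions <- 1L
  p1$b <- 0
  p1$T_thresh <- 0
  gate <- structure(list(type = "always"), class = "evseq_gate")
  # reuse bump_rhs with an always-on zero-threshold gate: P - T = X
  spec <- always_on_gate(p1$X)
  P <- p1$X
  iL <- cue_indicator(trial, p, "left")
  iR <- cue_indicator(trial, p, "right")
  W <- cosine_weights(p1)
  nev <- p1$n_evidence
  acc <- as.numeric(st %*% t(W)) +
    p1$c_shift * (c(state[-1], 0) * iL + c(0, state[-nev]) * iR) + P
  -p1$a * state + output_nonlinearity(acc, p1)
}

#' @rdname traditional_bump_rhs
#' @param geometry A [maze_geometry()].
#' @param solver A [solver_config()].
#' @return `simulate_traditional_bump`: an `evseq_sim` with 35 rows.
#' @export
simulate_traditional_bump <- function(trial, params = bump_params(),
                                      geometry = maze_geometry(),
                                      solver = solver_config(max_step = 5e-4)) {
  nev <- params$n_evidence
  lev <- evidence_levels(params)
  init <- numeric(nev)
  init[match(c(-1, 0, 1), lev)] <- c(15, 17.5, 15)
  rates <- sim_bump_cpp(trial$left_cues, trial$right_cues, params$a, 0,
                        params$c_shift, 0, params$q, params$gamma,
                        cosine_weights(params), 1L, nev,
                        always_on_gate(params$X), numeric(nev), init,
                        geometry$precue_start, geometry$maze_end,
                        geometry$velocity, solver$grid_step, solver$max_step,
                        cosine_fast = TRUE, omega0 = params$omega0,
                        omega1 = params$omega1)
  grid <- seq(geometry$precue_start, geometry$maze_end, by = solver$grid_step)
  rownames(rates) <- sprintf("e%+03d", lev)
  res <- structure(list(rates = rates, grid = grid, trial = trial,
                        model = "traditional_bump", params = params,
                        geometry = geometry),
                   class = "evseq_sim")
  lev_peak <- lev[which.max(rates[, ncol(rates)])]
  res$choice <- if (lev_peak < 0) "left" else if (lev_peak > 0) "right"
  else if (stats::runif(1) < 0.5) "left" else "right"
  res
}
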