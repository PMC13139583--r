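#' Parameters of the competing-chains models
#'
#' Two chains of position-gated units (left and right) accumulate evidence in
#' the relative amplitude of the active pair. The firing rate of unit `i` in
#' the left chain obeys
#' \deqn{dr_{i,L}/dt = -a r_{i,L} + [b r_{i,L} + c r_{i-1,L} - e r_{i,R}
#'   + f 1_{left}(t) + P_i(t) - T]^+}
#' with the analogous equation for the right chain. `a` is the decay rate,
#' `b` self-excitation, `c` the feedforward weight from the previous unit,
#' `e` mutual inhibition from the opposite chain, `f` the cue input weight,
#' `P_i` the position gate and `T` the firing threshold.
#'
#' Variants:
#' * `"mutual"`: as above (defaults a=50, b=10, c=50, e=40, f=100, T=15000,
#'   X=500; perfect integration of the rate difference since -a+b+e = 0).
#' * `"uncoupled"`: no cross-inhibition; cues enter push-pull
#'   (`+f 1_left - f 1_right` for the left chain). Accumulation is then
#'   per-unit temporal integration, which requires `b = a` and an exactly
#'   threshold-matched gate (`X = 0`, so `P_i = T` when active); these
#'   substitutions are applied automatically.
#' * `"unstable"`: self-excitation grows along the chain,
#'   `b_i = b0 + delta * i` with `delta = 0.5` by default, so the integrator
#'   becomes increasingly unstable at later positions.
#'
#' @param a Decay rate (1/s).
#' @param b Self-excitation (1/s); for `"unstable"` this is `b0`.
#' @param c_ff Feedforward weight (1/s).
#' @param e_inh Cross-inhibition weight (1/s).
#' @param f Cue input weight (Hz/s).
#' @param T_thresh Firing threshold (Hz/s).
#' @param X Common external drive (Hz/s).
#' @param n_positions Units per chain. Default 17.
#' @param variant `"mutual"`, `"uncoupled"` or `"unstable"`.
#' @param delta Instability increment (1/s), `"unstable"` only.
#' @return An object of class `chain_params`.
#' @export
chain_params <- function(a = 50, b = 10, c_ff = 50, e_inh = 40, f = 100,
                         T_thresh = 15000, X = 500, n_positions = 17,
                         variant = c("mutual", "uncoupled", "unstable"),
                         delta = 0.5) {
  variant <- match.arg(variant)
  stopifnot(a >= 0, b >= 0, c_ff >= 0, e_inh >= 0, f >= 0, n_positions >= 1)
  if (variant == "uncoupled") {
    # push-pull integration: per-unit perfect integrator with threshold-
    # matched gate (see vignette)
    b <- a
    e_inh <- 0
    X <- 0
  }
  bvec <- if (variant == "unstable") {
    unstable_self_excitation(0:(n_positions - 1), b0 = b, delta = delta)
  } else rep(b, n_positions)
  structure(list(a = a, b = b, bvec = bvec, c_ff = c_ff, e_inh = e_inh,
                 f = f, T_thresh = T_thresh, X = X,
                 n_positions = as.integer(n_positions), variant = variant,
                 delta = delta),
            class = "chain_params")
}

#' Position-dependent self-excitation of the unstable chains variant
#'
#' `b_i = b0 + delta * i` for 0-based position index `i`.
#'
#' @param i Position index (0-based), vectorized.
#' @param b0 Baseline self-excitation (1/s). Default 10, the perfect
#'   integrator value.
#' @param delta Increment per position (1/s). Default 0.5.
#' @return Self-excitation rate(s) (1/s).
#' @export
unstable_self_excitation <- function(i, b0 = 10, delta = 0.5) {
  stopifnot(all(i >= 0))
  b0 + delta * i
}

#' Competing-chains right-hand side (reference implementation)
#'
#' Derivative of the chain state at position `p`. This R implementation
#' mirrors the compiled integrator and is used for direct inspection and
#' cross-checking; simulations use [simulate_chain_trial()].
#'
#' @param state List with numeric vectors `r_L` and `r_R` (one rate per
#'   position unit, Hz).
#' @param p Position (cm).
#' @param params A [chain_params()].
#' @param trial An `evseq_trial`.
#' @param gate An `evseq_gate` (defaults to the square gate implied by
#'   `params`).
#' @param perturb Optional list with vectors `o_left`, `o_right` of
#'   subthreshold drives (Hz/s) added inside the rectification.
#' @return List with `r_L` and `r_R` derivatives (Hz/s).
#' @export
chain_rhs <- function(state, p, params, trial, gate = NULL, perturb = NULL) {
  n <- params$n_positions
  if (length(state$r_L) != n || length(state$r_R) != n)
    stop("state size does not match params$n_positions")
  if (is.null(gate)) gate <- default_chain_gate(params)
  spec <- gate_cpp_spec(gate, n)
  P <- gate_values_from_spec(spec, p, n)
  iL <- cue_indicator(trial, p, "left")
  iR <- cue_indicator(trial, p, "right")
  oL <- if (is.null(perturb)) numeric(n) else perturb$o_left
  oR <- if (is.null(perturb)) numeric(n) else perturb$o_right
  prevL <- c(0, state$r_L[-n])
  prevR <- c(0, state$r_R[-n])
  if (params$variant == "uncoupled") {
    brL <- params$bvec * state$r_L + params$c_ff * prevL +
      params$f * (iL - iR) + P - params$T_thresh + oL
    brR <- params$bvec * state$r_R + params$c_ff * prevR +
      params$f * (iR - iL) + P - params$T_thresh + oR
  } else {
    brL <- params$bvec * state$r_L + params$c_ff * prevL -
      params$e_inh * state$r_R + params$f * iL + P - params$T_thresh + oL
    brR <- params$bvec * state$r_R + params$c_ff * prevR -
      params$e_inh * state$r_L + params$f * iR + P - params$T_thresh + oR
  }
  list(r_L = -params$a * state$r_L + pmax(brL, 0),
       r_R = -params$a * state$r_R + pmax(brR, 0))
}

# square gate matching the chain parameterization
default_chain_gate <- function(params, geometry = maze_geometry()) {
  square_gate(P0 = 20, T_thresh = params$T_thresh, X = params$X,
              geometry = geometry)
}

# evaluate a C++ gate spec in R (used by the reference rhs implementations)
gate_values_from_spec <- function(spec, p, n) {
  if (spec$type == "piecewise") {
    b <- spec$boundaries
    ifelse(b[seq_len(n)] <= p & p < b[seq_len(n) + 1], spec$drive, 0)
  } else {
    spec$alpha * exp(-(p - spec$centers)^2 / spec$beta)
  }
}

#' Simulate a competing-chains trial
#'
#' Integrates the chain equations over the maze with a fixed-step RK4 scheme
#' (step `grid_step / velocity`, below the 0.01 s maximum-step requirement)
#' and samples all `2 * n_positions` units on the 0.1 cm position grid.
#'
#' @param trial An `evseq_trial`.
#' @param params A [chain_params()].
#' @param gate An `evseq_gate`; default is the square gate implied by
#'   `params`.
#' @param geometry A [maze_geometry()].
#' @param solver A [solver_config()].
#' @param perturb Optional perturbation list (`o_left`, `o_right`), see
#'   [run_perturbation()].
#' @return An `evseq_sim` object: `rates` (units x grid positions, rows
#'   `L1..Ln, R1..Rn`), `grid`, `trial`, `choice` and metadata.
#' @export
simulate_chain_trial <- function(trial, params = chain_params(), gate = NULL,
                                 geometry = maze_geometry(),
                                 solver = solver_config(), perturb = NULL) {
  n <- params$n_positions
  if (is.null(gate)) gate <- default_chain_gate(params, geometry)
  spec <- gate_cpp_spec(gate, n)
  oL <- if (is.null(perturb)) numeric(n) else as.numeric(perturb$o_left)
  oR <- if (is.null(perturb)) numeric(n) else as.numeric(perturb$o_right)
  stopifnot(length(oL) == n, length(oR) == n)
  rates <- sim_chain_cpp(trial$left_cues, trial$right_cues, params$a,
                         params$bvec, params$c_ff, params$e_inh, params$f,
                         params$T_thresh, spec,
                         as.integer(params$variant == "uncoupled"), oL, oR,
                         geometry$precue_start, geometry$maze_end,
                         geometry$velocity, solver$grid_step, solver$max_step)
  grid <- seq(geometry$precue_start, geometry$maze_end, by = solver$grid_step)
  rownames(rates) <- c(paste0("L", seq_len(n)), paste0("R", seq_len(n)))
  res <- structure(list(rates = rates, grid = grid, trial = trial,
                        model = paste0("chain_", params$variant),
                        params = params, geometry = geometry),
                   class = "evseq_sim")
  res$choice <- readout_choice_chains(res)
  res
}

#' Choice readout of a chains simulation
#'
#' Left if the final unit of the left chain ends the maze with higher
#' activity than the final unit of the right chain, right if lower; exact
#' ties are broken at random with equal probability.
#'
#' @param result An `evseq_sim` from [simulate_chain_trial()].
#' @return `"left"` or `"right"`.
#' @export
readout_choice_chains <- function(result) {
  n <- result$params$n_positions
  last <- ncol(result$rates)
  dL <- result$rates[n, last] - result$rates[2 * n, last]
  if (dL > 0) "left" else if (dL < 0) "right"
  else if (stats::runif(1) < 0.5) "left" else "right"
}

#' Choice-readout cell parameters
#'
#' A population of binary readout cells at each position compares the two
#' chains: `r_readout = alpha * (sgn(r_L - r_R + xi) + 1)` with
#' `xi ~ N(0, noise_sd^2)` drawn independently per cell and sample, and `i`
#' readout cells per choice at position `i` (so later positions have more
#' choice cells).
#'
#' @param alpha Readout amplitude (Hz). Default 5, so rates are 0 or 10 Hz.
#' @param noise_sd Noise standard deviation (Hz). Default 2.
#' @return A list of class `readout_params`.
#' @export
readout_params <- function(alpha = 5, noise_sd = 2) {
  structure(list(alpha = alpha, noise_sd = noise_sd),
            class = "readout_params")
}

#' Choice-readout population rates for a chains simulation
#'
#' Evaluates the binary choice-readout cells at every grid sample of a
#' simulated trial. Each readout cell responds only while its position gate
#' is active (elsewhere 0).
#'
#' @param result An `evseq_sim` from [simulate_chain_trial()].
#' @param rp A [readout_params()].
#' @param gate Gate used to restrict each cell to its active position;
#'   default the square gate implied by the chain parameters.
#' @return List with matrices `left` and `right` (cells x grid) and a
#'   data.frame `cells` (`position_index` 1-based per cell).
#' @export
choice_readout_rates <- function(result, rp = readout_params(), gate = NULL) {
  params <- result$params
  n <- params$n_positions
  if (is.null(gate)) gate <- default_chain_gate(params, result$geometry)
  spec <- gate_cpp_spec(gate, n)
  ngrid <- length(result$grid)
  pos_idx <- rep(seq_len(n), seq_len(n)) # i cells per choice at position i
  ncells <- length(pos_idx)
  d <- result$rates[seq_len(n), , drop = FALSE] -
    result$rates[n + seq_len(n), , drop = FALSE]
  active <- vapply(result$grid, function(p)
    gate_values_from_spec(spec, p, n) > 0, logical(n))
  out_L <- matrix(0, ncells, ngrid)
  out_R <- matrix(0, ncells, ngrid)
  for (k in seq_len(ncells)) {
    i <- pos_idx[k]
    on <- active[i, ]
    xi <- stats::rnorm(sum(on), 0, rp$noise_sd)
    out_L[k, on] <- rp$alpha * (sign(d[i, on] + xi) + 1)
    xi <- stats::rnorm(sum(on), 0, rp$noise_sd)
    out_R[k, on] <- rp$alpha * (sign(-d[i, on] + xi) + 1)
  }
  list(left = out_L, right = out_R,
       cells = data.frame(position_index = pos_idx))
}

#' Traditional competing-accumulator baseline
#'
#' The classic two-population mutual-inhibition integrator:
#' \deqn{dr_L/dt = -a r_L + [b r_L - e r_R + f 1_{left}(t) + X]^+}
#' with defaults a=50, b=10, e=40, f=100, X=500 and no position gating, so
#' activity ramps persistently rather than sequentially.
#'
#' @param state Numeric length-2 vector `c(r_L, r_R)` (Hz).
#' @param p Position (cm) at which to evaluate the cue indicators.
#' @param trial An `evseq_trial`.
#' @param a,b,e_inh,f,X Model parameters.
#' @return `traditional_accumulator_rhs`: length-2 derivative.
#' @export
traditional_accumulator_rhs <- function(state, p, trial, a = 50, b = 10,
                                        e_inh = 40, f = 100, X = 500) {
  iL <- cue_indicator(trial, p, "left")
  iR <- cue_indicator(trial, p, "right")
  brL <- b * state[1] - e_inh * state[2] + f * iL + X
  brR <- b * state[2] - e_inh * state[1] + f * iR + X
  c(-a * state[1] + max(brL, 0), -a * state[2] + max(brR, 0))
}

#' @rdname traditional_accumulator_rhs
#' @param geometry A [maze_geometry()].
#' @param solver A [solver_config()].
#' @return `simulate_traditional_accumulator`: an `evseq_sim` with two rows
#'   (`L1`, `R1`).
#' @export
simulate_traditional_accumulator <- function(trial, a = 50, b = 10,
                                             e_inh = 40, f = 100, X = 500,
                                             geometry = maze_geometry(),
                                             solver = solver_config()) {
  rates <- sim_chain_cpp(trial$left_cues, trial$right_cues, a, b, 0, e_inh,
                         f, 0, always_on_gate(X), 0L, 0, 0,
                         geometry$precue_start, geometry$maze_end,
                         geometry$velocity, solver$grid_step, solver$max_step)
  grid <- seq(geometry$precue_start, geometry$maze_end, by = solver$grid_step)
  rownames(rates) <- c("L1", "R1")
  res <- structure(list(rates = rates, grid = grid, trial = trial,
                        model = "traditional_accumulator",
                        params = list(n_positions = 1L), geometry = geometry),
                   class = "evseq_sim")
  res$choice <- {
    d <- rates[1, ncol(rates)] - rates[2, ncol(rates)]
    if (d > 0) "left" else if (d < 0) "right"
    else if (stats::runif(1) < 0.5) "left" else "right"
  }
  res
}

#' @export
print.evseq_sim <- function(x, ...) {
  cat(sprintf("%s simulation: %d units x %d grid points, choice %s\n",
              x$model, nrow(x$rates), ncol(x$rates), x$choice))
  invisible(x)
}
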