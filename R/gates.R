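#' Position-gating signals
#'
#' The position gate `P_i(t)` lifts only the units encoding the current
#' position above the firing threshold `T`, so that activity progresses
#' along the sequence as the animal runs. Three forms are supported:
#'
#' * `square_gate()`: `P_i = T + X` while `i <= p / P0 < i + 1`, else 0.
#'   With `P0 = 20` cm the 330 cm maze is divided into 17 sections of active
#'   positions.
#' * `gaussian_gate()`: a smooth gate
#'   `P_i(p) = alpha * exp(-(p - mu_i)^2 / beta)` with centers
#'   `mu_i = 20 i - 10` cm; all gates are simultaneously nonzero. This
#'   variant is paired with a lower firing threshold (`T = 1100` Hz/s) in the
#'   chain model.
#' * `heterogeneous_gate()`: a square gate with randomly drawn transition
#'   points (widths >= 5 cm).
#'
#' Gate indices run from -2 (first active section, starting at -30 cm for the
#' defaults) to 14; they map onto unit indices `0..(n-1)` by adding
#' `index_offset = 2` so that chains are 0-indexed from the maze start.
#'
#' @param P0 Gate width (cm).
#' @param T_thresh Firing threshold (Hz/s) supplied to the active drive.
#' @param X Common external drive (Hz/s); the active gate value is
#'   `T_thresh + X`.
#' @param geometry A [maze_geometry()].
#' @return An object of class `evseq_gate`.
#' @export
square_gate <- function(P0 = 20, T_thresh = 15000, X = 500,
                        geometry = maze_geometry()) {
  stopifnot(P0 > 0)
  lo <- floor(geometry$precue_start / P0)
  hi <- floor((geometry$maze_end - 1e-9) / P0)
  structure(list(type = "square", P0 = P0, T_thresh = T_thresh, X = X,
                 geometry = geometry, index_offset = -lo,
                 n_gates = hi - lo + 1L),
            class = "evseq_gate")
}

#' @rdname square_gate
#' @param alpha Gaussian gate amplitude (Hz/s). Default 60.
#' @param beta Gaussian gate squared width (cm^2). Default 1250.
#' @param n_gates Number of gates (same index map as the square gate).
#' @export
gaussian_gate <- function(alpha = 60, beta = 1250, n_gates = 17,
                          geometry = maze_geometry()) {
  stopifnot(alpha > 0, beta > 0)
  structure(list(type = "gaussian", alpha = alpha, beta = beta,
                 geometry = geometry, index_offset = 2L,
                 n_gates = as.integer(n_gates)),
            class = "evseq_gate")
}

#' @rdname square_gate
#' @param transition_points Sorted gate boundaries (cm); gate `i` is active on
#'   `[rho_i, rho_{i+1})` and the last gate extends to `maze_end`.
#' @export
heterogeneous_gate <- function(transition_points, T_thresh = 15000, X = 500,
                               geometry = maze_geometry()) {
  rho <- as.numeric(transition_points)
  stopifnot(length(rho) >= 1, !is.unsorted(rho))
  if (any(rho > geometry$maze_end))
    stop("transition points exceed maze_end")
  structure(list(type = "heterogeneous", rho = rho, T_thresh = T_thresh,
                 X = X, geometry = geometry, index_offset = 0L,
                 n_gates = length(rho)),
            class = "evseq_gate")
}

#' Draw a heterogeneous-width position gate
#'
#' Transition points are drawn uniformly between `precue_start` and
#' `maze_end`, sorted, and adjusted left-to-right: whenever consecutive
#' points are closer than `min_gap`, the later point is incremented by
#' `min_gap` cm and subsequent gaps re-checked.
#'
#' @param n Number of gates (one unit per gate).
#' @param geometry A [maze_geometry()].
#' @param min_gap Minimal gate width (cm). Default 5.
#' @inheritParams square_gate
#' @return An `evseq_gate` of type `heterogeneous`.
#' @export
draw_heterogeneous_gates <- function(n, geometry = maze_geometry(),
                                     min_gap = 5, T_thresh = 15000, X = 500) {
  stopifnot(n >= 1)
  rho <- sort(stats::runif(n, geometry$precue_start, geometry$maze_end))
  rho <- adjust_transition_points(rho, min_gap)
  if (any(rho > geometry$maze_end))
    stop("adjusted transition points exceed maze_end")
  heterogeneous_gate(rho, T_thresh = T_thresh, X = X, geometry = geometry)
}

# left-to-right minimum-gap adjustment: increment the later point by min_gap
# whenever a gap is too small, then re-check subsequent gaps
adjust_transition_points <- function(rho, min_gap = 5) {
  if (length(rho) < 2) return(rho)
  for (i in seq_len(length(rho) - 1)) {
    if (rho[i + 1] - rho[i] < min_gap) rho[i + 1] <- rho[i + 1] + min_gap
  }
  rho
}

#' Gate index at a position
#'
#' The unique integer `i` with `i <= p / P0 < i + 1` for square gates; for
#' heterogeneous gates, the index of the interval containing `p` (0-based),
#' or `NA` before the first transition point.
#'
#' @param gate An `evseq_gate`.
#' @param p Position(s) (cm); vectorized.
#' @return Integer gate index (square: can be negative).
#' @export
gate_index <- function(gate, p) {
  switch(gate$type,
    square = as.integer(floor(p / gate$P0)),
    heterogeneous = {
      idx <- findInterval(p, gate$rho) - 1L
      idx[idx < 0] <- NA_integer_
      idx
    },
    stop("gate_index is defined for square and heterogeneous gates"))
}

#' Gate drive value
#'
#' Value of the position-gating signal of gate index `i` at position `p`:
#' `T + X` inside the active section for square/heterogeneous gates,
#' `alpha * exp(-(p - mu_i)^2 / beta)` for Gaussian gates.
#'
#' @param gate An `evseq_gate`.
#' @param p Position (cm).
#' @param i Gate index (square gates: maze-section index, e.g. -2..14 for
#'   defaults; heterogeneous/gaussian handled on their own index ranges).
#' @return Drive in Hz/s.
#' @export
gate_value <- function(gate, p, i) {
  switch(gate$type,
    square = ifelse(i <= p / gate$P0 & p / gate$P0 < i + 1,
                    gate$T_thresh + gate$X, 0),
    heterogeneous = {
      hi <- c(gate$rho[-1], gate$geometry$maze_end)
      ifelse(gate$rho[i + 1] <= p & p < hi[i + 1],
             gate$T_thresh + gate$X, 0)
    },
    gaussian = {
      mu <- 20 * i - 10
      gate$alpha * exp(-(p - mu)^2 / gate$beta)
    })
}

#' @export
print.evseq_gate <- function(x, ...) {
  cat(sprintf("%s position gate, %d sections\n", x$type, x$n_gates))
  invisible(x)
}

# convert a gate into the list consumed by the C++ simulators: unit k
# (0-based) is gate index k - index_offset
gate_cpp_spec <- function(gate, n_units) {
  g <- gate$geometry
  switch(gate$type,
    square = list(type = "piecewise",
                  boundaries = gate$P0 * (0:n_units - gate$index_offset),
                  drive = gate$T_thresh + gate$X),
    heterogeneous = {
      stopifnot(n_units == length(gate$rho))
      list(type = "piecewise", boundaries = c(gate$rho, g$maze_end),
           drive = gate$T_thresh + gate$X)
    },
    gaussian = list(type = "gaussian",
                    centers = 20 * (0:(n_units - 1) - gate$index_offset) - 10,
                    alpha = gate$alpha, beta = gate$beta))
}

# an always-on gate used by the traditional (ungated) baseline models
always_on_gate <- function(drive) {
  list(type = "piecewise", boundaries = c(-1e9, 1e9), drive = drive)
}
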