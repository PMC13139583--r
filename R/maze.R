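#' Maze geometry for the accumulating-towers task
#'
#' The virtual T-maze consists of a 30 cm precue region, a 200 cm cue region
#' in which towers appear on either side, and a 100 cm delay region with no
#' cues. The animal is assumed to traverse the maze at constant velocity so
#' that time and position are interchangeable via
#' `p(t) = velocity * t + precue_start`.
#'
#' @param precue_start Start of the maze (cm). Default -30.
#' @param cue_start Start of the cue region (cm). Default 0.
#' @param cue_end End of the cue region (cm). Default 200.
#' @param maze_end End of the delay region (cm). Default 300.
#' @param velocity Running speed (cm/s). Default 50.
#' @return An object of class `maze_geometry`.
#' @examples
#' geom <- maze_geometry()
#' geom$maze_end - geom$precue_start # 330 cm of maze
#' @export
maze_geometry <- function(precue_start = -30, cue_start = 0, cue_end = 200,
                          maze_end = 300, velocity = 50) {
  stopifnot(precue_start < cue_start, cue_start < cue_end, cue_end < maze_end,
            velocity > 0)
  structure(list(precue_start = precue_start, cue_start = cue_start,
                 cue_end = cue_end, maze_end = maze_end, velocity = velocity),
            class = "maze_geometry")
}

#' Construct a single trial
#'
#' A trial is the atomic behavioral input to every simulator and analysis:
#' the ordered positions (cm) of the left and right cues within the cue
#' region.
#'
#' @param left_cues,right_cues Numeric vectors of cue positions (cm).
#' @param trial_id Identifier attached to the trial.
#' @param geometry A [maze_geometry()]; cues must lie in
#'   `[cue_start, cue_end)`.
#' @return An object of class `evseq_trial` with sorted cue positions.
#' @export
trial <- function(left_cues = numeric(0), right_cues = numeric(0),
                  trial_id = NA_integer_, geometry = maze_geometry()) {
  left_cues <- sort(as.numeric(left_cues))
  right_cues <- sort(as.numeric(right_cues))
  ok <- function(x) all(x >= geometry$cue_start & x < geometry$cue_end)
  if (!ok(left_cues) || !ok(right_cues))
    stop("cue positions must lie within [cue_start, cue_end)")
  structure(list(left_cues = left_cues, right_cues = right_cues,
                 trial_id = trial_id),
            class = "evseq_trial")
}

#' @export
print.evseq_trial <- function(x, ...) {
  cat(sprintf("trial %s: %d left, %d right cues (evidence %+d)\n",
              as.character(x$trial_id), length(x$left_cues),
              length(x$right_cues), final_evidence(x)))
  invisible(x)
}

# draw cue positions uniformly in the cue region conditioned on a minimal
# within-side spacing, by the exact order-statistics construction: n sorted
# uniforms on the slack interval plus the mandatory gaps. This is the same
# law that whole-set rejection sampling targets, but never fails, so the
# Poisson count marginals are preserved exactly (counts above the packing
# bound, < 0.2% of draws at the default rates, are truncated to it).
draw_spaced_positions <- function(n, geometry, min_spacing) {
  if (n == 0) return(numeric(0))
  span <- geometry$cue_end - geometry$cue_start
  if (min_spacing > 0) n <- min(n, floor(span / min_spacing) + 1)
  slack <- span - (n - 1) * min_spacing
  u <- sort(stats::runif(n, 0, slack))
  pmin(geometry$cue_start + u + min_spacing * (seq_len(n) - 1),
       geometry$cue_end - 1e-9)
}

#' Generate a synthetic accumulating-towers trial
#'
#' Cue counts on each side are Poisson with the given means; positions are
#' uniform in the cue region with an enforced minimal within-side spacing.
#' Uses R's global random number generator (call `set.seed()` for
#' reproducibility).
#'
#' @param mean_left,mean_right Poisson means for left/right cue counts.
#' @param geometry A [maze_geometry()].
#' @param min_spacing Minimal distance between consecutive same-side cues
#'   (cm). Default 12.
#' @param trial_id Identifier for the generated trial.
#' @return An `evseq_trial`.
#' @export
generate_trial <- function(mean_left, mean_right, geometry = maze_geometry(),
                           min_spacing = 12, trial_id = NA_integer_) {
  if (mean_left < 0 || mean_right < 0) stop("Poisson means must be >= 0")
  stopifnot(min_spacing >= 0)
  nl <- stats::rpois(1, mean_left)
  nr <- stats::rpois(1, mean_right)
  trial(draw_spaced_positions(nl, geometry, min_spacing),
        draw_spaced_positions(nr, geometry, min_spacing),
        trial_id = trial_id, geometry = geometry)
}

#' Generate a pool of trials with randomized majority side
#'
#' Each trial assigns the higher Poisson rate to the left or right side with
#' equal probability, emulating the task's randomized rewarded side.
#'
#' @param n Number of trials.
#' @param mean_low,mean_high Poisson means of the minority/majority side.
#'   Defaults 2.3 and 7.7.
#' @inheritParams generate_trial
#' @return A list of `evseq_trial` objects with ids `1:n`.
#' @export
generate_trials <- function(n, mean_low = 2.3, mean_high = 7.7,
                            geometry = maze_geometry(), min_spacing = 12) {
  lapply(seq_len(n), function(i) {
    if (stats::runif(1) < 0.5) {
      generate_trial(mean_high, mean_low, geometry, min_spacing, trial_id = i)
    } else {
      generate_trial(mean_low, mean_high, geometry, min_spacing, trial_id = i)
    }
  })
}

#' Cue indicator signal
#'
#' Returns 1 iff any cue on the given side lies strictly within 0.5 cm of
#' position `p`; this is the brief input pulse integrated by the circuit
#' models.
#'
#' @param trial An `evseq_trial`.
#' @param p Position(s) (cm); vectorized.
#' @param side `"left"` or `"right"`.
#' @return Integer vector of 0/1 values, one per position.
#' @export
cue_indicator <- function(trial, p, side = c("left", "right")) {
  side <- match.arg(side)
  cues <- if (side == "left") trial$left_cues else trial$right_cues
  if (length(cues) == 0) return(integer(length(p)))
  vapply(p, function(pp) as.integer(min(abs(pp - cues)) < 0.5), integer(1))
}

#' Final signed evidence of a trial
#'
#' Number of right minus number of left cues.
#' @param trial An `evseq_trial`.
#' @return Integer.
#' @export
final_evidence <- function(trial) {
  length(trial$right_cues) - length(trial$left_cues)
}

#' Accumulated evidence before a position
#'
#' Signed count (right minus left) of cues strictly before position `p`;
#' this is the cumulative-evidence convention used when binning sessions.
#'
#' @param trial An `evseq_trial`.
#' @param p Position(s) (cm); vectorized.
#' @return Integer vector.
#' @export
evidence_before <- function(trial, p) {
  vapply(p, function(pp) {
    sum(trial$right_cues < pp) - sum(trial$left_cues < pp)
  }, numeric(1)) |> as.integer()
}

#' Input-noise configuration
#'
#' The sensory-noise protocol retains each cue independently with probability
#' `keep_prob` (default 0.33, i.e. 67% of cues ignored), applied to 25
#' sessions of 150 trials each by default.
#'
#' @param keep_prob Per-cue retention probability in `[0, 1]`.
#' @param n_sessions,trials_per_session Session layout of the protocol.
#' @param seed Optional integer seed.
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(keep_prob = 0.33, n_sessions = 25,
                         trials_per_session = 150, seed = NULL) {
  stopifnot(keep_prob >= 0, keep_prob <= 1, n_sessions >= 1,
            trials_per_session >= 1)
  structure(list(keep_prob = keep_prob, n_sessions = n_sessions,
                 trials_per_session = trials_per_session, seed = seed),
            class = "noise_config")
}

#' Apply sensory input noise to a trial
#'
#' Each cue is independently retained with probability `keep_prob`; the
#' original trial is unchanged. The returned trial carries the reduced cue
#' sets that drive the simulation, while psychometrics are computed against
#' the original counts.
#'
#' @param trial An `evseq_trial`.
#' @param keep_prob Retention probability, or a [noise_config()].
#' @return A new `evseq_trial` with thinned cue sets.
#' @export
apply_input_noise <- function(trial, keep_prob = 0.33) {
  if (inherits(keep_prob, "noise_config")) keep_prob <- keep_prob$keep_prob
  thin <- function(x) x[stats::runif(length(x)) < keep_prob]
  out <- trial
  out$left_cues <- thin(trial$left_cues)
  out$right_cues <- thin(trial$right_cues)
  out
}

#' Write / read trials as CSV
#'
#' One row per cue with columns `trial_id`, `side` (`L`/`R`) and
#' `cue_position_cm`; trials without cues appear with side `NA`. The
#' round-trip is exact.
#'
#' @param trials List of `evseq_trial` objects.
#' @param path File path.
#' @return `write_trials_csv` returns `path` invisibly; `read_trials_csv`
#'   returns a list of trials.
#' @export
write_trials_csv <- function(trials, path) {
  rows <- lapply(trials, function(tr) {
    nl <- length(tr$left_cues); nr <- length(tr$right_cues)
    if (nl + nr == 0) {
      data.frame(trial_id = tr$trial_id, side = NA_character_,
                 cue_position_cm = NA_real_)
    } else {
      data.frame(trial_id = tr$trial_id,
                 side = c(rep("L", nl), rep("R", nr)),
                 cue_position_cm = c(tr$left_cues, tr$right_cues))
    }
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @param geometry A [maze_geometry()] used to validate cue positions.
#' @export
read_trials_csv <- function(path, geometry = maze_geometry()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ids <- unique(df$trial_id)
  lapply(ids, function(id) {
    sub <- df[df$trial_id == id & !is.na(df$side), , drop = FALSE]
    trial(sub$cue_position_cm[sub$side == "L"],
          sub$cue_position_cm[sub$side == "R"],
          trial_id = id, geometry = geometry)
  })
}

# mirror a trial (swap sides); used by symmetry tests and mirrored analyses
#' Swap the left and right cue sets of a trial
#' @param trial An `evseq_trial`.
#' @return The mirrored trial.
#' @export
mirror_trial <- function(trial) {
  out <- trial
  out$left_cues <- trial$right_cues
  out$right_cues <- trial$left_cues
  out
}
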