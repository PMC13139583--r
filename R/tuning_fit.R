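#' Joint position-by-evidence Gaussian tuning fit
#'
#' Fits the firing-rate model
#' \deqn{FR(p, e) = a \exp(-(p - \mu_p)^2 / 2\sigma_p^2)
#'                    \exp(-(e - \mu_e)^2 / 2\sigma_e^2) + b}
#' to one neuron's position-binned observations (normalized to `[0, 1]`) by
#' alternating bounded nonlinear least squares over the position block
#' (`mu_p, sigma_p, a, b`) and the evidence block (`mu_e, sigma_e, a, b`),
#' ending on a position update. Box bounds: `-50 <= mu_p <= 350`,
#' `0 <= sigma_p <= 200`, `e_low - 1 <= mu_e <= e_high + 1` (recomputed each
#' iteration from the evidence levels observed within 5 cm of the current
#' `mu_p`), `0 <= sigma_e <= 30`, `0 <= a <= 10`, `0 <= b <= 1`. Because the
#' evidence Gaussian may extend beyond the observed range, the fit
#' accommodates both unimodal and monotonic tuning (a monotonic neuron fits
#' with `mu_e` near the extreme of its observed range).
#'
#' @param p Position of each observation (cm; bin centers).
#' @param e Accumulated evidence of each observation (towers).
#' @param y Firing rate of each observation (Hz); normalized internally.
#' @param n_alternations Number of position-block updates (default 3: the
#'   sequence position, evidence, position, evidence, position).
#' @param tol Early-stop threshold on the parameter change. Default 1e-3.
#' @return An object of class `evseq_tuning_fit`: `mu_p`, `sigma_p`,
#'   `mu_e`, `sigma_e`, `a`, `b`, `mse` (on normalized rates), `e_low`,
#'   `e_high`, `eligible` (final `mu_e` within its bounds) and `preference`
#'   (`"right"` if `mu_e > 0`, `"left"` if `mu_e < 0`).
#' @export
joint_fit <- function(p, e, y, n_alternations = 3, tol = 1e-3) {
  keep <- is.finite(p) & is.finite(e) & is.finite(y)
  p <- p[keep]; e <- e[keep]; y <- y[keep]
  if (length(y) < 4) stop("too few observations for a joint fit")
  rng <- range(y)
  yn <- if (diff(rng) > 0) (y - rng[1]) / diff(rng) else y * 0
  if (diff(rng) == 0) {
    # degenerate constant neuron: amplitude ~ 0, offset at the constant
    fit <- list(mu_p = mean(p), sigma_p = 30, mu_e = 0, sigma_e = 5, a = 0,
                b = 0, mse = 0, e_low = min(e), e_high = max(e),
                eligible = TRUE, preference = "none", n_obs = length(y))
    return(structure(fit, class = "evseq_tuning_fit"))
  }
  # initialization: peak bin, broad position width, rate-weighted evidence
  peak_bin <- p[which.max(yn)]
  near <- abs(p - peak_bin) <= 2.5
  mu_e0 <- if (sum(yn[near]) > 0) sum(e[near] * yn[near]) / sum(yn[near]) else 0
  theta <- c(mu_p = peak_bin, sigma_p = 30, mu_e = mu_e0, sigma_e = 5,
             a = diff(range(yn)), b = min(yn))
  ebounds <- evidence_bounds(p, e, theta[["mu_p"]])
  theta[["mu_e"]] <- min(max(theta[["mu_e"]], ebounds[1]), ebounds[2])
  gaussf <- function(x, mu, sig) exp(-(x - mu)^2 / (2 * sig^2))
  for (it in seq_len(n_alternations)) {
    old <- theta
    theta <- fit_block(theta, p, e, yn, "position", ebounds)
    ebounds <- evidence_bounds(p, e, theta[["mu_p"]])
    if (it < n_alternations) {
      theta[["mu_e"]] <- min(max(theta[["mu_e"]], ebounds[1]), ebounds[2])
      theta <- fit_block(theta, p, e, yn, "evidence", ebounds)
    }
    if (max(abs(theta - old)) < tol) break
  }
  pred <- theta[["a"]] * gaussf(p, theta[["mu_p"]], theta[["sigma_p"]]) *
    gaussf(e, theta[["mu_e"]], theta[["sigma_e"]]) + theta[["b"]]
  ebounds <- evidence_bounds(p, e, theta[["mu_p"]])
  eligible <- theta[["mu_e"]] >= ebounds[1] && theta[["mu_e"]] <= ebounds[2]
  structure(list(mu_p = theta[["mu_p"]], sigma_p = theta[["sigma_p"]],
                 mu_e = theta[["mu_e"]], sigma_e = theta[["sigma_e"]],
                 a = theta[["a"]], b = theta[["b"]],
                 mse = mean((pred - yn)^2),
                 e_low = ebounds[1] + 1, e_high = ebounds[2] - 1,
                 eligible = eligible,
                 preference = if (theta[["mu_e"]] > 0) "right"
                 else if (theta[["mu_e"]] < 0) "left" else "none",
                 n_obs = length(yn)),
            class = "evseq_tuning_fit")
}

# mu_e bounds (e_low - 1, e_high + 1) from evidence observed within 5 cm
# (one bin) of the current mu_p; falls back to the full evidence range when
# mu_p sits outside the sampled positions
evidence_bounds <- function(p, e, mu_p) {
  near <- abs(p - mu_p) <= 5
  ee <- if (any(near)) e[near] else e
  c(min(ee) - 1, max(ee) + 1)
}

# one bounded least-squares block update (L-BFGS-B, analytic gradient)
fit_block <- function(theta, p, e, yn, block = c("position", "evidence"),
                      ebounds) {
  block <- match.arg(block)
  sig_min <- 1e-2
  if (block == "position") {
    Efix <- exp(-(e - theta[["mu_e"]])^2 / (2 * theta[["sigma_e"]]^2))
    par0 <- theta[c("mu_p", "sigma_p", "a", "b")]
    lower <- c(-50, sig_min, 0, 0); upper <- c(350, 200, 10, 1)
    x <- p; fix <- Efix
  } else {
    Pfix <- exp(-(p - theta[["mu_p"]])^2 / (2 * theta[["sigma_p"]]^2))
    par0 <- theta[c("mu_e", "sigma_e", "a", "b")]
    lower <- c(ebounds[1], sig_min, 0, 0); upper <- c(ebounds[2], 30, 10, 1)
    x <- e; fix <- Pfix
  }
  par0 <- pmin(pmax(par0, lower), upper)
  fn <- function(par) {
    g <- exp(-(x - par[1])^2 / (2 * par[2]^2))
    sum((par[3] * g * fix + par[4] - yn)^2)
  }
  gr <- function(par) {
    g <- exp(-(x - par[1])^2 / (2 * par[2]^2))
    r <- par[3] * g * fix + par[4] - yn
    ag <- par[3] * g * fix
    c(2 * sum(r * ag * (x - par[1]) / par[2]^2),
      2 * sum(r * ag * (x - par[1])^2 / par[2]^3),
      2 * sum(r * g * fix),
      2 * sum(r))
  }
  opt <- stats::optim(par0, fn, gr, method = "L-BFGS-B", lower = lower,
                      upper = upper, control = list(maxit = 100))
  if (block == "position") {
    theta[c("mu_p", "sigma_p", "a", "b")] <- opt$par
  } else {
    theta[c("mu_e", "sigma_e", "a", "b")] <- opt$par
  }
  theta
}

#' Fit position-evidence tuning for all neurons of a binned session
#'
#' Applies [joint_fit()] to each neuron using correct trials only (the
#' incorrect and zero-evidence trials are excluded, matching the tuning
#' characterization protocol).
#'
#' @param binned An `evseq_binned`.
#' @param neurons Optional subset of neuron indices.
#' @param correct_only Use only correct trials (default TRUE; if
#'   correctness is unknown all trials are used).
#' @param ... Passed to [joint_fit()].
#' @return Data frame, one row per neuron, with the fit fields plus
#'   `mu_e_norm` and `sigma_e_norm` from [normalize_evidence_params()].
#' @export
fit_tuning <- function(binned, neurons = NULL, correct_only = TRUE, ...) {
  n_neur <- dim(binned$rates)[1]
  if (is.null(neurons)) neurons <- seq_len(n_neur)
  tr_keep <- trial_filter(binned, correct_only)
  dat <- binned_observations(binned, tr_keep)
  rows <- lapply(neurons, function(i) {
    y <- as.numeric(binned$rates[i, tr_keep, ])
    fit <- joint_fit(dat$p, dat$e, y, ...)
    nn <- normalize_evidence_params(fit, observed_evidence(binned, fit$mu_p,
                                                          tr_keep))
    data.frame(neuron = i, mu_p = fit$mu_p, sigma_p = fit$sigma_p,
               mu_e = fit$mu_e, sigma_e = fit$sigma_e, a = fit$a, b = fit$b,
               mse = fit$mse, eligible = fit$eligible,
               preference = fit$preference,
               mu_e_norm = nn[1], sigma_e_norm = nn[2])
  })
  do.call(rbind, rows)
}

trial_filter <- function(binned, correct_only) {
  if (correct_only && !all(is.na(binned$correct))) {
    which(!is.na(binned$correct) & binned$correct)
  } else seq_along(binned$trials)
}

# long vectors of bin-center position and evidence matching
# as.numeric(rates[i, tr_keep, ])
binned_observations <- function(binned, tr_keep) {
  n_bin <- length(binned$bin_centers)
  list(p = rep(binned$bin_centers, each = length(tr_keep)),
       e = as.numeric(binned$evidence[tr_keep, , drop = FALSE]))
}

# evidence levels observed within 5 cm of mu_p across the kept trials
observed_evidence <- function(binned, mu_p, tr_keep = NULL) {
  if (is.null(tr_keep)) tr_keep <- seq_along(binned$trials)
  near <- abs(binned$bin_centers - mu_p) <= 5
  if (!any(near)) near <- rep(TRUE, length(binned$bin_centers))
  as.numeric(binned$evidence[tr_keep, near, drop = FALSE])
}

#' Normalized evidence-tuning parameters
#'
#' Rescales the fitted evidence mean and width by the evidence range
#' observed near the neuron's peak position, so tuning can be compared
#' across positions: `mu_e < 0` divides by the largest observed magnitude
#' of negative evidence, `mu_e > 0` by the largest positive evidence, and
#' `mu_e = 0` maps to 0; `sigma_e` divides by the observed evidence range.
#' Normalized means near +/-1 indicate monotonic-like tuning.
#'
#' @param fit An `evseq_tuning_fit` (or a list with `mu_e`, `sigma_e`).
#' @param evidence Evidence values observed within 5 cm of `mu_p`.
#' @return Numeric vector `c(mu_e_norm, sigma_e_norm)` (NA when the needed
#'   branch of the evidence set is empty or the range is zero).
#' @export
normalize_evidence_params <- function(fit, evidence) {
  evidence <- evidence[is.finite(evidence)]
  if (length(evidence) == 0) return(c(NA_real_, NA_real_))
  epos <- evidence[evidence > 0]
  eneg <- evidence[evidence < 0]
  mu_n <- if (fit$mu_e > 0) {
    if (length(epos)) fit$mu_e / max(epos) else NA_real_
  } else if (fit$mu_e < 0) {
    if (length(eneg)) fit$mu_e / max(abs(eneg)) else NA_real_
  } else 0
  rng <- max(evidence) - min(evidence)
  sig_n <- if (rng > 0) fit$sigma_e / rng else NA_real_
  c(mu_n, sig_n)
}

#' Pseudosession significance test of evidence tuning
#'
#' Refits each neuron against surrogate evidence from `n_pseudo`
#' pseudosessions (the same firing rates paired with cue sequences from
#' freshly generated trials), and compares the true-session mean squared
#' error to the null MSE distribution. The default comparison is the
#' one-sample t-test of the null MSEs against the observed MSE (one-sided:
#' fit better than null); `method = "empirical"` instead uses the
#' percentile of the observed MSE in the null distribution, which is
#' exactly calibrated (see the methods vignette for the distinction).
#'
#' @param binned An `evseq_binned`.
#' @param fits Data frame from [fit_tuning()] (its rows determine which
#'   neurons are tested; must carry `neuron` and `mse`).
#' @param n_pseudo Number of pseudosessions. Default 50.
#' @param alpha Significance level. Default 0.05.
#' @param trial_generator Function `n -> list of trials` supplying surrogate
#'   cue sequences; default [generate_trials()].
#' @param method `"t"` (as in the original protocol) or `"empirical"`.
#' @param ... Passed to [joint_fit()].
#' @return `fits` with columns `p_pseudo` and `significant` added.
#' @export
pseudosession_test <- function(binned, fits, n_pseudo = 50, alpha = 0.05,
                               trial_generator = NULL,
                               method = c("t", "empirical"), ...) {
  method <- match.arg(method)
  if (n_pseudo < 1) stop("n_pseudo must be >= 1")
  if (is.null(trial_generator)) trial_generator <- generate_trials
  tr_keep <- trial_filter(binned, TRUE)
  dat <- binned_observations(binned, tr_keep)
  n_bin <- length(binned$bin_centers)
  edges <- binned$bin_edges[-length(binned$bin_edges)]
  null_mse <- matrix(NA_real_, nrow(fits), n_pseudo)
  for (s in seq_len(n_pseudo)) {
    pseudo <- trial_generator(length(binned$trials))
    ev <- t(vapply(pseudo, function(tr) evidence_before(tr, edges),
                   integer(n_bin)))
    e_s <- as.numeric(ev[tr_keep, , drop = FALSE])
    for (k in seq_len(nrow(fits))) {
      y <- as.numeric(binned$rates[fits$neuron[k], tr_keep, ])
      null_mse[k, s] <- joint_fit(dat$p, e_s, y, ...)$mse
    }
  }
  pvals <- vapply(seq_len(nrow(fits)), function(k) {
    nulls <- null_mse[k, ]
    obs <- fits$mse[k]
    if (method == "t") {
      # an (essentially) constant null collapses the t-test; fall back to a
      # direct comparison with the observed MSE
      if (stats::sd(nulls) < 1e-10 * max(1, abs(mean(nulls))))
        return(as.numeric(mean(nulls) <= obs))
      stats::t.test(nulls, mu = obs, alternative = "greater")$p.value
    } else {
      (sum(nulls <= obs) + 1) / (length(nulls) + 1)
    }
  }, numeric(1))
  fits$p_pseudo <- pvals
  fits$significant <- pvals < alpha
  fits
}

#' One-dimensional evidence tuning curve around the most active position
#'
#' Restricts a neuron's (normalized) observations to positions within
#' `0.5 * sigma_p` of `mu_p` (clipped to 0-300 cm), averages the rates at
#' each observed evidence level, and fits both a Gaussian
#' `a exp(-(e - mu)^2 / sigma^2) + c` and a logistic
#' `a / (1 + exp(-k (e - x0))) + c` to the averages, returning the better
#' fit by mean squared error (both forms have four parameters, so no
#' complexity correction is needed).
#'
#' @param binned An `evseq_binned`.
#' @param neuron Neuron index.
#' @param fit The neuron's `evseq_tuning_fit` (or row of [fit_tuning()]).
#' @param correct_only Use correct trials only. Default TRUE.
#' @return List with `means` (data frame `evidence`, `rate`, `n`), `best`
#'   (`"gaussian"` or `"logistic"`), `gaussian`, `logistic` (parameter
#'   vectors with `mse`).
#' @export
tuning_curve_1d <- function(binned, neuron, fit, correct_only = TRUE) {
  tr_keep <- trial_filter(binned, correct_only)
  y <- matrix(binned$rates[neuron, tr_keep, ], nrow = length(tr_keep))
  rngy <- range(y, na.rm = TRUE)
  yn <- if (diff(rngy) > 0) (y - rngy[1]) / diff(rngy) else y * 0
  half <- 0.5 * fit$sigma_p
  win <- abs(binned$bin_centers - fit$mu_p) <= half &
    binned$bin_centers >= 0 & binned$bin_centers <= 300
  if (!any(win)) stop("no position bins within the tuning window")
  e <- as.numeric(binned$evidence[tr_keep, win, drop = FALSE])
  v <- as.numeric(yn[, win])
  keep <- is.finite(v)
  e <- e[keep]; v <- v[keep]
  lev <- sort(unique(e))
  means <- vapply(lev, function(l) mean(v[e == l]), numeric(1))
  ns <- vapply(lev, function(l) sum(e == l), integer(1))
  m <- min(lev); M <- max(lev)
  gauss_fn <- function(par) par[3] * exp(-(lev - par[1])^2 / par[2]^2) + par[4]
  logis_fn <- function(par) par[3] / (1 + exp(-par[1] * (lev - par[2]))) + par[4]
  sse <- function(pred) mean((pred - means)^2)
  og <- stats::optim(c(lev[which.max(means)],
                       max((M - m) / 2, 0.5), max(diff(range(means)), 1e-3),
                       min(means)),
                     function(par) sse(gauss_fn(par)), method = "L-BFGS-B",
                     lower = c(m, 1e-2, 0, 0), upper = c(M, 30, 10, 1))
  slope0 <- if (stats::cor(lev, means) >= 0 || is.na(stats::cor(lev, means)))
    0.25 else -0.25
  ol <- stats::optim(c(slope0, 0, max(diff(range(means)), 1e-3), min(means)),
                     function(par) sse(logis_fn(par)), method = "L-BFGS-B",
                     lower = c(-1, -15, 0, 0), upper = c(1, 15, 10, 1))
  best <- if (og$value <= ol$value) "gaussian" else "logistic"
  list(means = data.frame(evidence = lev, rate = means, n = ns),
       best = best,
       gaussian = c(mu = og$par[1], sigma = og$par[2], a = og$par[3],
                    c = og$par[4], mse = og$value),
       logistic = c(k = ol$par[1], x0 = ol$par[2], a = ol$par[3],
                    c = ol$par[4], mse = ol$value))
}

#' Choice-selective sequence matrices
#'
#' Trial-averaged, peak-normalized position profiles of the significantly
#' evidence-tuned neurons, split by correct-left and correct-right trials,
#' with rows sorted by evidence preference (right-preferring: mean evidence
#' tuning greater than 0) and then by position mean.
#'
#' @param binned An `evseq_binned`.
#' @param fits Data frame from [fit_tuning()] /[pseudosession_test()]; only
#'   rows with `significant == TRUE` (if present) are used.
#' @return List with matrices `left` and `right` (neurons x position bins,
#'   each row normalized to its peak across both matrices) and the row
#'   `order` data frame.
#' @export
sequence_matrix <- function(binned, fits) {
  if (!is.null(fits$significant)) fits <- fits[fits$significant, , drop = FALSE]
  if (nrow(fits) == 0) stop("no significant neurons")
  ord <- order(fits$preference != "right", fits$mu_p)
  fits <- fits[ord, , drop = FALSE]
  corr <- !is.na(binned$correct) & binned$correct
  left_tr <- which(corr & binned$choices == "left")
  right_tr <- which(corr & binned$choices == "right")
  prof <- function(i, tr) {
    if (length(tr) == 0) return(rep(NA_real_, dim(binned$rates)[3]))
    m <- matrix(binned$rates[i, tr, ], nrow = length(tr))
    colMeans(m, na.rm = TRUE)
  }
  L <- t(vapply(fits$neuron, prof, numeric(dim(binned$rates)[3]),
                tr = left_tr))
  R <- t(vapply(fits$neuron, prof, numeric(dim(binned$rates)[3]),
                tr = right_tr))
  pk <- pmax(apply(L, 1, max, na.rm = TRUE), apply(R, 1, max, na.rm = TRUE))
  pk[pk == 0 | !is.finite(pk)] <- 1
  list(left = L / pk, right = R / pk, order = fits)
}
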