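#' Difference between right- and left-preferring population activity
#'
#' Mean activity of the significantly evidence-tuned right-preferring
#' neurons minus that of the left-preferring neurons at every sample,
#' optionally after causal half-Gaussian filtering (window 1 s, sd 0.25 s)
#' applied per trial so that cue responses are purely causal.
#'
#' @param rates Matrix neurons x samples (Hz).
#' @param fits Data frame from [fit_tuning()] (with `significant` if
#'   available); preferences define the two populations.
#' @param trial_index Optional per-sample trial index; required when
#'   `filter = "causal"` so filtering restarts at trial boundaries.
#' @param filter `"none"` or `"causal"`.
#' @param frame_rate Samples per second for the filter. Default 30.
#' @return Numeric vector, one value per sample.
#' @export
population_difference_trace <- function(rates, fits, trial_index = NULL,
                                        filter = c("none", "causal"),
                                        frame_rate = 30) {
  filter <- match.arg(filter)
  if (!is.null(fits$significant)) fits <- fits[fits$significant, , drop = FALSE]
  rp <- fits$neuron[fits$preference == "right"]
  lp <- fits$neuron[fits$preference == "left"]
  if (length(rp) == 0 || length(lp) == 0)
    stop("need at least one neuron of each preference")
  if (filter == "causal") {
    if (is.null(trial_index)) stop("trial_index required for causal filtering")
    for (tr in unique(trial_index)) {
      idx <- which(trial_index == tr)
      rates[, idx] <- t(apply(rates[, idx, drop = FALSE], 1, smooth_rates,
                              kernel = "causal", frame_rate = frame_rate))
    }
  }
  colMeans(rates[rp, , drop = FALSE]) - colMeans(rates[lp, , drop = FALSE])
}

#' Cubic spline basis for cue response kernels
#'
#' Basis with `df` degrees of freedom on the kernel lag grid `0..width`: a
#' constant column plus a natural cubic spline basis with `df - 1` degrees
#' of freedom (interior knots at evenly spaced quantiles of the uniform lag
#' grid). Including the constant lets the basis represent sustained,
#' step-like integrator responses exactly.
#'
#' @param width Kernel width (cm).
#' @param df Degrees of freedom. Default 7.
#' @param step Lag grid step (cm).
#' @return Matrix (lags x df).
#' @export
cue_spline_basis <- function(width, df = 7, step = 5) {
  lags <- seq(0, width, by = step)
  cbind(1, unclass(splines::ns(lags, df = df - 1)))
}

#' Fit cue response kernels by spline-basis ridge regression
#'
#' Models the right-minus-left population difference trace as a sum of
#' causal responses to individual cues: binary cue-onset vectors (onset =
#' the position at which the cue becomes visible, `onset_lead` cm before the
#' cue) are convolved with each spline basis function, separately per side,
#' and a ridge regression (regularization strength `lambda`, intercept
#' unpenalized) recovers the kernel shapes. Optionally fits separate
#' kernels per prior-evidence magnitude (`split = "evidence"`: low |e| <= 1
#' width 300 cm, medium 2 <= |e| <= 4 width 200 cm, high |e| >= 5 width
#' 200 cm) or per cue position (`split = "position"`: early < 70 cm width
#' 300 cm, middle 70-140 cm width 230 cm, late > 140 cm width 160 cm).
#'
#' @param trace Numeric vector: the population difference at every sample.
#' @param trials List of trials.
#' @param positions Per-sample positions (cm).
#' @param trial_index Per-sample 1-based trial indices.
#' @param width Kernel width (cm) for the unsplit fit. Default 300.
#' @param df Spline degrees of freedom. Default 7.
#' @param lambda Ridge strength. Default 1.
#' @param onset_lead Visibility lead of a cue (cm). Default 10.
#' @param split `NULL`, `"evidence"` or `"position"`.
#' @return List of class `evseq_kernel_fit`: `kernels` data frame
#'   (`side`, `category`, `lag`, `value`), `coef`, `intercept`, `r2`,
#'   `lambda`.
#' @export
fit_cue_kernels <- function(trace, trials, positions, trial_index,
                            width = 300, df = 7, lambda = 1,
                            onset_lead = 10, split = NULL) {
  step <- stats::median(diff(positions[trial_index == trial_index[1]]))
  categories <- kernel_categories(split, width)
  design_cols <- list()
  for (ci in seq_len(nrow(categories))) {
    B <- cue_spline_basis(categories$width[ci], df, step)
    for (side in c("L", "R")) {
      ons <- onset_vector(trials, positions, trial_index, side, onset_lead,
                          categories$name[ci], split)
      conv <- causal_convolve_trials(ons, B, trial_index)
      colnames(conv) <- paste(side, categories$name[ci], seq_len(df),
                              sep = "_")
      design_cols[[length(design_cols) + 1]] <- conv
    }
  }
  X <- do.call(cbind, design_cols)
  xm <- colMeans(X); ym <- mean(trace)
  Xc <- sweep(X, 2, xm)
  beta <- solve(crossprod(Xc) + lambda * diag(ncol(Xc)),
                crossprod(Xc, trace - ym))
  pred <- as.numeric(Xc %*% beta) + ym
  r2 <- 1 - sum((trace - pred)^2) / sum((trace - ym)^2)
  kern <- list()
  for (ci in seq_len(nrow(categories))) {
    B <- cue_spline_basis(categories$width[ci], df, step)
    lags <- seq(0, categories$width[ci], by = step)
    for (side in c("L", "R")) {
      cols <- paste(side, categories$name[ci], seq_len(df), sep = "_")
      kern[[length(kern) + 1]] <- data.frame(
        side = side, category = categories$name[ci], lag = lags,
        value = as.numeric(B %*% beta[cols, 1]))
    }
  }
  structure(list(kernels = do.call(rbind, kern),
                 coef = beta[, 1], intercept = ym - sum(xm * beta[, 1]),
                 r2 = r2, lambda = lambda),
            class = "evseq_kernel_fit")
}

kernel_categories <- function(split, width) {
  if (is.null(split)) {
    data.frame(name = "all", width = width)
  } else if (split == "evidence") {
    data.frame(name = c("low", "medium", "high"), width = c(300, 200, 200))
  } else if (split == "position") {
    data.frame(name = c("early", "middle", "late"), width = c(300, 230, 160))
  } else stop("unknown split")
}

# binary onset vector: 1 at the sample where a cue of the given side (and
# category, if splitting) becomes visible
onset_vector <- function(trials, positions, trial_index, side, onset_lead,
                         category, split) {
  ons <- numeric(length(positions))
  for (k in seq_along(trials)) {
    tr <- trials[[k]]
    cues <- if (side == "L") tr$left_cues else tr$right_cues
    if (length(cues) == 0) next
    if (!is.null(split)) {
      keepc <- vapply(cues, function(cp) {
        if (split == "evidence") {
          e <- abs(evidence_before(tr, cp))
          switch(category, low = e <= 1, medium = e >= 2 && e <= 4,
                 high = e >= 5)
        } else {
          switch(category, early = cp < 70, middle = cp >= 70 && cp <= 140,
                 late = cp > 140)
        }
      }, logical(1))
      cues <- cues[keepc]
      if (length(cues) == 0) next
    }
    idx <- which(trial_index == k)
    for (cp in cues) {
      target <- cp - onset_lead
      j <- idx[which.min(abs(positions[idx] - target))]
      ons[j] <- ons[j] + 1
    }
  }
  ons
}

# convolve an onset vector with each basis column, independently per trial
causal_convolve_trials <- function(ons, B, trial_index) {
  out <- matrix(0, length(ons), ncol(B))
  nb <- nrow(B)
  for (k in unique(trial_index)) {
    idx <- which(trial_index == k)
    o <- ons[idx]
    hits <- which(o > 0)
    if (length(hits) == 0) next
    seg <- matrix(0, length(idx), ncol(B))
    for (h in hits) {
      span <- h:min(length(idx), h + nb - 1)
      seg[span, ] <- seg[span, ] + o[h] * B[seq_along(span), ]
    }
    out[idx, ] <- seg
  }
  out
}

#' Single-neuron evidence vs. choice encoding regression
#'
#' At each position bin, fits `FR = b0 + b1 * e + b2 * c` per neuron by
#' ordinary least squares over both correct and incorrect trials (`c` coded
#' 0 = left, 1 = right), computes the partial F-statistic of each
#' coefficient and flags significance by the one-sided F-test at
#' `alpha = 0.01`. A neuron counts as active at a bin when
#' `|p - mu_p| < sigma_p` from its joint tuning fit.
#'
#' @param binned An `evseq_binned` with `choices`.
#' @param fits Data frame from [fit_tuning()].
#' @param alpha Significance level. Default 0.01.
#' @return List of class `evseq_encoding`: `table` (neuron x bin rows with
#'   coefficients, F, p, significance, active flag) and `fractions`
#'   (per-bin fraction of active neurons significant for evidence and
#'   choice).
#' @export
evidence_choice_regression <- function(binned, fits, alpha = 0.01) {
  if (is.null(binned$choices)) stop("binned session lacks choices")
  cvec <- as.numeric(binned$choices == "right")
  if (length(unique(cvec)) < 2) stop("both choices must be present")
  n_bin <- length(binned$bin_centers)
  rows <- vector("list", nrow(fits) * n_bin)
  ri <- 0
  for (k in seq_len(nrow(fits))) {
    i <- fits$neuron[k]
    active_bins <- which(abs(binned$bin_centers - fits$mu_p[k]) <
                           fits$sigma_p[k])
    for (bn in seq_len(n_bin)) {
      y <- binned$rates[i, , bn]
      e <- binned$evidence[, bn]
      keep <- is.finite(y)
      if (sum(keep) < 5) next
      ft <- ols_partial_f(y[keep], cbind(e = e[keep], c = cvec[keep]))
      if (is.null(ft)) next
      ri <- ri + 1
      rows[[ri]] <- data.frame(neuron = i, bin = bn,
                               position = binned$bin_centers[bn],
                               beta_e = ft$beta[1], beta_c = ft$beta[2],
                               F_e = ft$F[1], F_c = ft$F[2],
                               p_e = ft$p[1], p_c = ft$p[2],
                               sig_e = ft$p[1] < alpha,
                               sig_c = ft$p[2] < alpha,
                               active = bn %in% active_bins)
    }
  }
  tab <- do.call(rbind, rows[seq_len(ri)])
  fr <- do.call(rbind, lapply(seq_len(n_bin), function(bn) {
    sub <- tab[tab$bin == bn & tab$active, , drop = FALSE]
    data.frame(bin = bn, position = binned$bin_centers[bn],
               n_active = nrow(sub),
               frac_evidence = if (nrow(sub)) mean(sub$sig_e) else NA_real_,
               frac_choice = if (nrow(sub)) mean(sub$sig_c) else NA_real_)
  }))
  structure(list(table = tab, fractions = fr, alpha = alpha),
            class = "evseq_encoding")
}

#' Per-coefficient partial F-test for a small OLS fit
#'
#' Fits `y ~ X` with intercept by least squares and returns each
#' coefficient's estimate, partial F statistic (the squared t statistic)
#' and one-sided F-test p-value. Degenerate designs (collinear or constant
#' predictors) return `NULL`.
#'
#' @param y Response vector.
#' @param X Predictor matrix (without intercept column).
#' @return List with `beta`, `F`, `p`, or `NULL` if the design is
#'   rank-deficient.
#' @export
ols_partial_f <- function(y, X) {
  Z <- cbind(1, X)
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) return(NULL)
  beta <- qr.coef(qz, y)
  res <- y - Z %*% beta
  df2 <- length(y) - ncol(Z)
  if (df2 <= 0) return(NULL)
  s2 <- sum(res^2) / df2
  XtXinv <- chol2inv(qr.R(qz))
  se <- sqrt(s2 * diag(XtXinv))
  tt <- beta / se
  Fst <- tt[-1]^2
  list(beta = beta[-1], F = Fst,
       p = stats::pf(Fst, 1, df2, lower.tail = FALSE))
}

#' Linear evidence decoding with nested cross-validation
#'
#' At each position bin, fits ridge decoders predicting the accumulated
#' evidence from the active neurons' rates on correct trials, separately
#' for the non-negative and non-positive evidence branches (so correlations
#' cannot arise just from decoding the choice); the strict branches
#' (`e > 0` / `e < 0`) additionally control for sign-of-evidence coding.
#' Nested five-fold cross-validation selects the regularization strength
#' from `lambda_grid` in the inner loop; decoders are scored by the Pearson
#' correlation between predicted and actual evidence on the outer test
#' folds. Shuffle controls permute evidence across trials of the same sign
#' (`shuffle_repeats` times).
#'
#' @param binned An `evseq_binned`.
#' @param fits Data frame from [fit_tuning()].
#' @param branches Subset of `c("nonneg", "nonpos", "pos", "neg")`.
#' @param lambda_grid Ridge strengths. Default
#'   `10^seq(-4, 3)`.
#' @param n_folds Folds in both loops. Default 5.
#' @param shuffle_repeats Shuffle-control repeats. Default 5.
#' @param min_trials,min_neurons Minimal problem size per bin (smaller bins
#'   are reported as `NA`).
#' @return Data frame of class rows: `bin`, `position`, `branch`,
#'   `n_trials`, `n_neurons`, `cor`, `cor_shuffle`.
#' @export
linear_evidence_decoder <- function(binned, fits,
                                    branches = c("nonneg", "nonpos"),
                                    lambda_grid = c(1e-4, 1e-3, 1e-2, 1e-1,
                                                    1, 10, 100, 1000),
                                    n_folds = 5, shuffle_repeats = 5,
                                    min_trials = 15, min_neurons = 2) {
  corr_tr <- trial_filter(binned, TRUE)
  n_bin <- length(binned$bin_centers)
  out <- list()
  for (bn in seq_len(n_bin)) {
    pos <- binned$bin_centers[bn]
    act <- fits$neuron[abs(pos - fits$mu_p) < fits$sigma_p]
    for (br in branches) {
      e <- binned$evidence[corr_tr, bn]
      sel <- switch(br, nonneg = e >= 0, nonpos = e <= 0, pos = e > 0,
                    neg = e < 0)
      tr <- corr_tr[sel]
      X <- t(matrix(binned$rates[act, tr, bn], nrow = length(act)))
      keep <- apply(is.finite(X), 1, all)
      X <- X[keep, , drop = FALSE]
      yv <- binned$evidence[tr[keep], bn]
      res_row <- data.frame(bin = bn, position = pos, branch = br,
                            n_trials = nrow(X), n_neurons = length(act),
                            cor = NA_real_, cor_shuffle = NA_real_)
      if (length(act) >= min_neurons && nrow(X) >= min_trials &&
          stats::sd(yv) > 0) {
        res_row$cor <- nested_ridge_cor(X, yv, lambda_grid, n_folds)
        if (shuffle_repeats > 0) {
          sh <- vapply(seq_len(shuffle_repeats), function(r)
            nested_ridge_cor(X, sample(yv), lambda_grid, n_folds),
            numeric(1))
          res_row$cor_shuffle <- mean(sh, na.rm = TRUE)
        }
      }
      out[[length(out) + 1]] <- res_row
    }
  }
  do.call(rbind, out)
}

# nested k-fold CV ridge; returns mean outer-fold Pearson correlation
nested_ridge_cor <- function(X, y, lambda_grid, n_folds) {
  n <- nrow(X)
  folds <- sample(rep(seq_len(n_folds), length.out = n))
  cors <- rep(NA_real_, n_folds)
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    if (sum(tr) < 3 || stats::sd(y[tr]) == 0) next
    lam <- pick_lambda(X[tr, , drop = FALSE], y[tr], lambda_grid, n_folds)
    pred <- ridge_predict(X[tr, , drop = FALSE], y[tr],
                          X[!tr, , drop = FALSE], lam)
    if (stats::sd(pred) > 0 && stats::sd(y[!tr]) > 0)
      cors[f] <- stats::cor(pred, y[!tr])
  }
  mean(cors, na.rm = TRUE)
}

pick_lambda <- function(X, y, lambda_grid, n_folds) {
  n <- nrow(X)
  folds <- sample(rep(seq_len(n_folds), length.out = n))
  score <- vapply(lambda_grid, function(lam) {
    cs <- rep(NA_real_, n_folds)
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      if (sum(tr) < 3 || sum(!tr) < 2 || stats::sd(y[tr]) == 0) next
      pred <- ridge_predict(X[tr, , drop = FALSE], y[tr],
                            X[!tr, , drop = FALSE], lam)
      if (stats::sd(pred) > 0 && stats::sd(y[!tr]) > 0)
        cs[f] <- stats::cor(pred, y[!tr])
    }
    mean(cs, na.rm = TRUE)
  }, numeric(1))
  if (all(is.na(score))) return(lambda_grid[length(lambda_grid) %/% 2])
  lambda_grid[which.max(score)]
}

ridge_predict <- function(Xtr, ytr, Xte, lambda) {
  xm <- colMeans(Xtr); ym <- mean(ytr)
  Xc <- sweep(Xtr, 2, xm)
  beta <- tryCatch(
    solve(crossprod(Xc) + lambda * diag(ncol(Xc)), crossprod(Xc, ytr - ym)),
    error = function(e) matrix(0, ncol(Xc), 1))
  as.numeric(sweep(Xte, 2, xm) %*% beta) + ym
}

#' Population-averaged preferred-evidence map
#'
#' Averages firing across significantly evidence-tuned neurons in bins of
#' position by preferred evidence (each neuron's evidence axis is reflected
#' so its fitted evidence mean is positive). Per neuron, a bin requires at
#' least `min_obs` observations; with multiple sessions, bins sampled
#' sufficiently in fewer than `min_session_frac` of sessions are masked.
#'
#' @param binned An `evseq_binned` or list of them (sessions).
#' @param fits Matching data frame (or list) from [fit_tuning()] /
#'   [pseudosession_test()].
#' @param evidence_range Integer range of the preferred-evidence axis.
#' @param min_obs Minimal observations per neuron-bin. Default 3.
#' @param min_session_frac Session coverage threshold. Default 0.1.
#' @param cross_sections Positions (cm) at which cross-sections are
#'   extracted. Default `c(50, 100, 150, 200, 250)`.
#' @return List: `map` (position bins x preferred-evidence levels),
#'   `n` (contributing neurons per bin), `mask`, `cross_sections` data
#'   frame.
#' @export
population_average_map <- function(binned, fits, evidence_range = c(-15, 15),
                                   min_obs = 3, min_session_frac = 0.1,
                                   cross_sections = c(50, 100, 150, 200, 250)) {
  if (inherits(binned, "evseq_binned")) {
    binned <- list(binned); fits <- list(fits)
  }
  lev <- seq(evidence_range[1], evidence_range[2])
  n_bin <- length(binned[[1]]$bin_centers)
  centers <- binned[[1]]$bin_centers
  sum_map <- matrix(0, n_bin, length(lev))
  n_map <- matrix(0L, n_bin, length(lev))
  sess_cov <- matrix(0L, n_bin, length(lev))
  for (s in seq_along(binned)) {
    bs <- binned[[s]]
    fs <- fits[[s]]
    if (!is.null(fs$significant)) fs <- fs[fs$significant, , drop = FALSE]
    fs <- fs[fs$preference %in% c("left", "right"), , drop = FALSE]
    covered <- matrix(FALSE, n_bin, length(lev))
    for (k in seq_len(nrow(fs))) {
      i <- fs$neuron[k]
      flip <- if (fs$preference[k] == "left") -1 else 1
      for (bn in seq_len(n_bin)) {
        y <- bs$rates[i, , bn]
        pe <- flip * bs$evidence[, bn]
        keep <- is.finite(y) & pe >= evidence_range[1] & pe <= evidence_range[2]
        if (!any(keep)) next
        tb <- tapply(y[keep], factor(pe[keep], levels = lev), mean)
        cnt <- table(factor(pe[keep], levels = lev))
        ok <- !is.na(tb) & cnt >= min_obs
        sum_map[bn, ok] <- sum_map[bn, ok] + tb[ok]
        n_map[bn, ok] <- n_map[bn, ok] + 1L
        covered[bn, ok] <- covered[bn, ok] | (cnt[ok] >= min_obs)
      }
    }
    sess_cov <- sess_cov + covered
  }
  map <- ifelse(n_map > 0, sum_map / n_map, NA_real_)
  mask <- sess_cov < ceiling(min_session_frac * length(binned))
  map[mask] <- NA_real_
  cs <- do.call(rbind, lapply(cross_sections, function(pp) {
    bn <- which.min(abs(centers - pp))
    data.frame(position = pp, preferred_evidence = lev, rate = map[bn, ])
  }))
  list(map = map, n = n_map, mask = mask, positions = centers,
       preferred_evidence = lev, cross_sections = cs)
}

#' Population difference traces by final-evidence band
#'
#' For correct trials grouped by final evidence (low 1-3, medium 4-6, high
#' >= 7 towers, separately for left and right trials), computes the
#' difference between the mean rates of the right- and left-preferring
#' populations at each position bin. Neurons contribute at a bin when they
#' are active there (`|p - mu_p| < sigma_p`) and carry a significant
#' evidence coefficient at any position bin of the encoding regression.
#'
#' @param binned An `evseq_binned`.
#' @param fits Data frame from [fit_tuning()].
#' @param encoding An `evseq_encoding` from [evidence_choice_regression()].
#' @return Data frame: `band`, `side`, `bin`, `position`, `difference`,
#'   `n_trials` (empty bands yield `NA` differences).
#' @export
population_response_by_final_evidence <- function(binned, fits, encoding) {
  sig_any <- unique(encoding$table$neuron[encoding$table$sig_e])
  fs <- fits[fits$neuron %in% sig_any &
               fits$preference %in% c("left", "right"), , drop = FALSE]
  corr <- which(!is.na(binned$correct) & binned$correct)
  bands <- list(low = c(1, 3), medium = c(4, 6), high = c(7, Inf))
  n_bin <- length(binned$bin_centers)
  out <- list()
  for (bname in names(bands)) {
    for (side in c("left", "right")) {
      dl <- abs(binned$delta)
      sgn <- if (side == "right") binned$delta > 0 else binned$delta < 0
      tr <- corr[dl[corr] >= bands[[bname]][1] &
                   dl[corr] <= bands[[bname]][2] & sgn[corr]]
      for (bn in seq_len(n_bin)) {
        act <- fs[abs(binned$bin_centers[bn] - fs$mu_p) < fs$sigma_p, ,
                  drop = FALSE]
        dv <- NA_real_
        if (length(tr) > 0 && any(act$preference == "right") &&
            any(act$preference == "left")) {
          m <- function(pref) {
            ids <- act$neuron[act$preference == pref]
            mean(binned$rates[ids, tr, bn], na.rm = TRUE)
          }
          dv <- m("right") - m("left")
        }
        out[[length(out) + 1]] <- data.frame(
          band = bname, side = side, bin = bn,
          position = binned$bin_centers[bn], difference = dv,
          n_trials = length(tr))
      }
    }
  }
  do.call(rbind, out)
}
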