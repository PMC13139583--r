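test_that("population difference traces mirror and cancel correctly", {
  rates <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  fits <- data.frame(neuron = 1:2, preference = c("right", "left"))
  expect_equal(population_difference_trace(rates, fits), rep(0, 4))
  rates2 <- rbind(c(2, 4, 1, 0), c(1, 1, 1, 1))
  tr1 <- population_difference_trace(rates2, fits)
  fits_m <- data.frame(neuron = 1:2, preference = c("left", "right"))
  expect_equal(population_difference_trace(rates2, fits_m), -tr1)
  expect_error(population_difference_trace(rates2,
    data.frame(neuron = 1, preference = "right")), "each preference")
})

test_that("the chains population difference tracks accumulated evidence", {
  set.seed(40)
  trs <- generate_trials(25)
  n <- 17
  fits <- data.frame(neuron = 1:34,
                     preference = rep(c("left", "right"), each = 17))
  gains <- numeric(0)
  for (k in seq_along(trs)) {
    res <- simulate_chain_trial(trs[[k]])
    tr_fit <- population_difference_trace(res$rates, fits)
    # mid-gate samples of the late delay period
    j <- which.min(abs(res$grid - 290))
    ev <- final_evidence(trs[[k]])
    if (abs(ev) >= 1 && abs(ev) <= 5)
      gains <- c(gains, tr_fit[j] / ev)
  }
  # right-minus-left population mean difference = 2 * evidence / 17 units
  expect_gt(length(gains), 5)
  expect_lt(max(abs(gains - 2 / 17)), 0.25 * 2 / 17)
})

test_that("cue kernels are recovered by the spline ridge regression", {
  set.seed(41)
  trs <- generate_trials(60)
  pos1 <- seq(-30, 300, by = 5)
  positions <- rep(pos1, length(trs))
  trial_index <- rep(seq_along(trs), each = length(pos1))
  # zero trace: ridge shrinks kernels to (essentially) zero
  k0 <- fit_cue_kernels(numeric(length(positions)), trs, positions,
                        trial_index)
  expect_lt(max(abs(k0$kernels$value)), 1e-8)

  # perfect-integrator trace: +g step after right cues, -g after left
  g <- 2
  trace <- numeric(length(positions))
  for (k in seq_along(trs)) {
    idx <- which(trial_index == k)
    seg <- numeric(length(pos1))
    for (cp in trs[[k]]$right_cues) seg <- seg + g * (pos1 >= cp - 10)
    for (cp in trs[[k]]$left_cues) seg <- seg - g * (pos1 >= cp - 10)
    trace[idx] <- seg
  }
  kf <- fit_cue_kernels(trace, trs, positions, trial_index)
  KR <- kf$kernels$value[kf$kernels$side == "R"]
  KL <- kf$kernels$value[kf$kernels$side == "L"]
  expect_lt(sqrt(sum((KR - g)^2) / sum(rep(g, length(KR))^2)), 0.15)
  expect_lt(sqrt(sum((KL + g)^2) / (g^2 * length(KL))), 0.15)
  expect_gt(kf$r2, 0.95)
  # symmetric generator: recovered kernels mirror each other
  expect_lt(max(abs(KR + KL)), 0.2)

  # split fits return one kernel pair per category at the stated widths
  ks <- fit_cue_kernels(trace, trs, positions, trial_index,
                        split = "evidence")
  widths <- tapply(ks$kernels$lag, ks$kernels$category, max)
  expect_equal(as.numeric(widths[c("low", "medium", "high")]),
               c(300, 200, 200))
  kp <- fit_cue_kernels(trace, trs, positions, trial_index,
                        split = "position")
  widths <- tapply(kp$kernels$lag, kp$kernels$category, max)
  expect_equal(as.numeric(widths[c("early", "middle", "late")]),
               c(300, 230, 160))
})

test_that("evidence and choice coding are separable per neuron", {
  set.seed(42)
  sess <- generate_session(synth_config(n_neurons = 4, n_trials = 200,
                                        tuning = "choice",
                                        noise = "gaussian", noise_sd = 0.4,
                                        lapse_beta = 0.25))
  ev <- unlist(lapply(seq_along(sess$trials), function(k)
    evidence_before(sess$trials[[k]],
                    sess$positions[sess$trial_index == k])))
  # neurons 1-2 become pure evidence coders, 3-4 stay pure choice coders
  sess$rates[1, ] <- 3 + 0.8 * ev + stats::rnorm(length(ev), 0, 0.4)
  sess$rates[2, ] <- 3 - 0.5 * ev + stats::rnorm(length(ev), 0, 0.4)
  binned <- bin_synth_session(sess)
  fits <- fit_tuning(binned)
  # activity windows: rewritten evidence coders respond everywhere; the
  # choice coders only within their generating position field
  gt <- sess$ground_truth
  fits$mu_p <- c(150, 150, gt$mu_p[3:4])
  fits$sigma_p <- c(160, 160, gt$sigma_p[3:4])
  enc <- evidence_choice_regression(binned, fits)
  tab <- enc$table[enc$table$active, ]
  frac <- aggregate(cbind(sig_e, sig_c) ~ neuron, tab, mean)
  expect_true(all(frac$sig_e[1:2] > 0.8))
  expect_true(all(frac$sig_c[1:2] < 0.2))
  expect_true(all(frac$sig_e[3:4] < 0.2))
  expect_true(all(frac$sig_c[3:4] > 0.8))
  expect_equal(nrow(enc$fractions), 66)
})

test_that("the encoding F-test is calibrated on null neurons", {
  set.seed(43)
  n_tr <- 150
  e <- sample(-8:8, n_tr, replace = TRUE)
  ch <- as.numeric(stats::runif(n_tr) < 0.5)
  n_null <- 800
  p_e <- p_c <- numeric(n_null)
  for (i in seq_len(n_null)) {
    ft <- ols_partial_f(stats::rnorm(n_tr, 5, 1), cbind(e = e, c = ch))
    p_e[i] <- ft$p[1]; p_c[i] <- ft$p[2]
  }
  se <- sqrt(0.01 * 0.99 / n_null)
  expect_lt(abs(mean(p_e < 0.01) - 0.01), 2 * se + 1e-9)
  expect_lt(abs(mean(p_c < 0.01) - 0.01), 2 * se + 1e-9)
  # degenerate design is reported as NULL, not an error
  expect_null(ols_partial_f(stats::rnorm(10), cbind(rep(1, 10), rep(2, 10))))
})

test_that("the evidence decoder is honest about what it can decode", {
  set.seed(44)
  sess <- generate_session(synth_config(n_neurons = 12, n_trials = 160,
                                        tuning = "null", noise = "gaussian",
                                        noise_sd = 0.2))
  ev <- unlist(lapply(seq_along(sess$trials), function(k)
    evidence_before(sess$trials[[k]],
                    sess$positions[sess$trial_index == k])))
  for (i in 1:12)
    sess$rates[i, ] <- 5 + (0.4 + 0.05 * i) * ev +
      stats::rnorm(length(ev), 0, 0.3)
  binned <- bin_synth_session(sess)
  fits <- data.frame(neuron = 1:12, mu_p = 150, sigma_p = 160)
  dec <- linear_evidence_decoder(binned, fits, shuffle_repeats = 2)
  mid <- dec$position > 90 & dec$position < 210
  expect_gt(mean(dec$cor[mid], na.rm = TRUE), 0.95)
  expect_lt(abs(mean(dec$cor_shuffle[mid], na.rm = TRUE)), 0.15)

  # population coding only the sign of evidence: strict branches decode ~ 0
  for (i in 1:12)
    sess$rates[i, ] <- 5 + 2 * sign(ev) + stats::rnorm(length(ev), 0, 0.3)
  b2 <- bin_synth_session(sess)
  dec2 <- linear_evidence_decoder(b2, fits, branches = c("pos", "neg"),
                                  shuffle_repeats = 0)
  m2 <- dec2$position > 90 & dec2$position < 210
  expect_lt(abs(mean(dec2$cor[m2], na.rm = TRUE)), 0.2)

  # a single constant neuron cannot decode anything: flagged as NA
  b3 <- binned
  b3$rates <- binned$rates[1, , , drop = FALSE] * 0 + 4
  dec3 <- linear_evidence_decoder(b3, fits[1, ], shuffle_repeats = 0)
  expect_true(all(is.na(dec3$cor) | abs(dec3$cor) < 0.3))
})

test_that("population maps reflect preferred evidence and masking rules", {
  # three identical left-preferring neurons with a known mid-maze field:
  # the map equals the single field on the reflected evidence axis
  set.seed(45)
  fx <- fixture_parametric_binned(n_neurons = 1, n_trials = 150,
                                  tuning = "null", noise = "none",
                                  seed = 45)
  sess <- fx$session
  ev <- unlist(lapply(seq_along(sess$trials), function(k)
    evidence_before(sess$trials[[k]],
                    sess$positions[sess$trial_index == k])))
  mu_e <- -3; sig_e <- 3
  sess$rates[1, ] <- 4 * exp(-(sess$positions - 150)^2 / (2 * 40^2)) *
    exp(-(ev - mu_e)^2 / (2 * sig_e^2)) + 0.2
  b <- bin_synth_session(sess)
  b$rates <- array(rep(b$rates[1, , ], each = 3), c(3, dim(b$rates)[2:3]))
  fits <- data.frame(neuron = 1:3, preference = "left", mu_p = 150,
                     sigma_p = 40)
  pm <- population_average_map(b, fits, min_session_frac = 0)
  bn <- which.min(abs(pm$positions - 150))
  row <- pm$map[bn, ]
  pe <- pm$preferred_evidence
  ok <- !is.na(row)
  expect_gt(sum(ok), 5)
  expect_gt(stats::cor(row[ok],
                       exp(-(-pe[ok] - mu_e)^2 / (2 * sig_e^2))), 0.95)
  expect_equal(dim(pm$map), c(66, 31))
  expect_equal(nrow(pm$cross_sections), 5 * 31)
  # under-sampled bins are masked
  expect_true(any(is.na(pm$map)))
})

test_that("banded population responses mirror and order with evidence", {
  set.seed(46)
  sess <- generate_session(synth_config(n_neurons = 10, n_trials = 200,
                                        tuning = "logistic",
                                        noise = "gaussian", noise_sd = 0.3))
  binned <- bin_synth_session(sess)
  fits <- fit_tuning(binned)
  fits$significant <- TRUE
  enc <- evidence_choice_regression(binned, fits)
  bands <- population_response_by_final_evidence(binned, fits, enc)
  expect_setequal(unique(bands$band), c("low", "medium", "high"))
  # right trials: higher bands give larger right-minus-left differences in
  # the late cue period
  late <- bands$position > 120 & bands$position < 200 &
    bands$side == "right"
  m <- tapply(bands$difference[late], bands$band[late],
              function(x) mean(x, na.rm = TRUE))
  expect_true(m[["low"]] < m[["high"]])
})
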