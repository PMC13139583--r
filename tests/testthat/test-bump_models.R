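test_that("cosine weights and output nonlinearity follow the printed forms", {
  params <- bump_params()
  W <- cosine_weights(params)
  expect_equal(dim(W), c(35, 35))
  expect_equal(diag(W), rep(0.12 * (1 - 1), 35)) # omega0 (1 + omega1) = 0
  expect_equal(W, t(W))
  # circulant: every row is a rotation of the first
  expect_equal(W[2, 2:35], W[1, 1:34])
  # most distant pair approaches omega0 (cos(pi) + omega1) = -0.24
  th <- 2 * pi * 17 / 35
  expect_equal(min(W), 0.12 * (cos(th) - 1))
  expect_lt(min(W), -0.239)

  expect_equal(output_nonlinearity(0, params), 625)
  expect_equal(output_nonlinearity(1e3, params), 1250)
  x <- seq(-3, 3, by = 0.5)
  expect_true(all(diff(output_nonlinearity(x, params)) > 0))
  expect_equal(output_nonlinearity(x, params) +
                 output_nonlinearity(-x, params), rep(1250, length(x)))
})

test_that("shifter neurons multiplicatively gate the cue signal", {
  params <- bump_params()
  st <- matrix(stats::runif(17 * 35), 17, 35)
  tr <- trial(left_cues = 50)
  off <- shifter_rates(st, tr, 120)
  expect_equal(off$left, st * 0)
  expect_equal(off$right, st * 0)
  on <- shifter_rates(st, tr, 50.2)
  expect_equal(on$left, st)
  expect_equal(on$right, st * 0)
})

test_that("bump right-hand side matches the compiled integrator", {
  params <- bump_params()
  tr <- trial(right_cues = 35.03)
  # silent neurons behind a closed gate have exactly zero drive
  st0 <- matrix(0, 17, 35)
  d0 <- bump_rhs(st0, 310, params, tr)
  expect_equal(max(abs(d0)), 0)
  # left-right symmetry of the derivative for a symmetric state, no cue
  st <- bump_initial_state(params)
  ds <- bump_rhs(st, -25, params, trial())
  expect_equal(ds, ds[, 35:1])

  # short-horizon trajectory cross-check (R reference vs C++)
  res <- simulate_bump_trial(tr)
  rhs_flat <- function(t, s) {
    p <- -30 + 50 * t
    as.numeric(t(bump_rhs(matrix(s, 17, 35, byrow = TRUE), p, params, tr)))
  }
  cols <- 1:140 # spans the first layer handoff at p = -20
  times <- (res$grid[cols] + 30) / 50
  init <- as.numeric(t(bump_initial_state(params)))
  ref <- integrate_ode(rhs_flat, init, times, max_step = 5e-4,
                       project = function(s) pmax(s, 0))
  expect_lt(max(abs(ref - res$rates[, cols])), 1e-5)
  # and a segment spanning the cue, so the shifter pathway is cross-checked
  cols2 <- 640:680 # p in [33.9, 37.9], cue window (34.53, 35.53)
  ref2 <- integrate_ode(rhs_flat, res$rates[, cols2[1]],
                        (res$grid[cols2] + 30) / 50, max_step = 5e-4,
                        project = function(s) pmax(s, 0))
  expect_lt(max(abs(ref2 - res$rates[, cols2])), 1e-5)
})

test_that("bump simulation counts, transfers and decides correctly", {
  params <- bump_params()
  res0 <- simulate_bump_trial(trial())
  expect_equal(nrow(res0$rates), 595)
  nev <- 35
  lev <- evidence_levels(params)
  peak_at <- function(res, layer, p) {
    j <- which.min(abs(res$grid - p))
    lev[which.max(res$rates[(layer - 1) * nev + 1:nev, j])]
  }
  # no cues: the bump stays at evidence 0 in every active layer
  # (layer l is gated on [20 l - 60, 20 l - 40); probe 5 cm before its end)
  for (l in c(1, 5, 9, 13, 17))
    expect_identical(peak_at(res0, l, 20 * l - 45), 0L)

  # net evidence +3 with well-separated mid-gate cues ends at level +3
  res3 <- simulate_bump_trial(trial(right_cues = c(50, 110, 170)))
  expect_identical(peak_at(res3, 17, 295), 3L)
  expect_identical(res3$choice, "right")

  # conservation across handoffs on cue-free segments
  resc <- simulate_bump_trial(trial(right_cues = 50))
  for (l in 6:17)
    expect_identical(peak_at(resc, l, 20 * l - 45), 1L)

  # bump shape stereotypy: peak-normalized profiles agree across layers
  profs <- sapply(2:16, function(l) {
    j <- which.min(abs(res0$grid - (20 * l - 40.2))) # just before handoff
    r <- res0$rates[(l - 1) * nev + 1:nev, j]
    r / max(r)
  })
  rms <- apply(profs, 2, function(x) sqrt(mean((x - profs[, 8])^2)))
  expect_lt(max(rms), 0.05)

  # unimodality away from the boundary levels
  prof <- profs[, 8]
  interior <- prof[4:32]
  expect_equal(sum(diff(sign(diff(interior))) < 0), 1)

  # mirror equivariance: reflected cue sets give reflected fields
  tr <- trial(left_cues = c(30, 90), right_cues = c(50, 130, 170))
  r1 <- simulate_bump_trial(tr)$rates
  r2 <- simulate_bump_trial(mirror_trial(tr))$rates
  refl <- r2[as.vector(sapply(0:16, function(i) i * nev + 35:1)), ]
  expect_lt(max(abs(r1 - refl)), 1e-9)
})

test_that("bump choice readout uses the final-layer argmax with random ties", {
  params <- bump_params()
  mk <- function(peak_level) {
    rates <- matrix(0, 595, 2)
    lev <- evidence_levels(params)
    rates[16 * 35 + match(peak_level, lev), 2] <- 9
    structure(list(rates = rates, params = params, grid = c(-30, 300)),
              class = "evseq_sim")
  }
  expect_identical(readout_choice_bump(mk(-4)), "left")
  expect_identical(readout_choice_bump(mk(1)), "right")
  set.seed(11)
  ties <- replicate(200, readout_choice_bump(mk(0)))
  expect_gt(mean(ties == "left"), 0.35)
  expect_lt(mean(ties == "left"), 0.65)
})

test_that("traditional bump attractor integrates without sequences", {
  params <- bump_params()
  res0 <- simulate_traditional_bump(trial())
  lev <- evidence_levels(params)
  # bump persists at evidence 0 across the whole maze
  for (p in c(0, 100, 200, 299))
    expect_identical(lev[which.max(res0$rates[, which.min(abs(res0$grid - p))])],
                     0L)
  expect_true(all(res0$rates <= 1250 / 55 + 1e-9)) # F <= q bounds rates
  # a single right cue moves the peak up one level, persistently
  res1 <- simulate_traditional_bump(trial(right_cues = 50))
  expect_identical(lev[which.max(res1$rates[, ncol(res1$rates)])], 1L)
  # rhs reference agrees with the compiled path over a short horizon
  rhs_flat <- function(t, s)
    traditional_bump_rhs(s, -30 + 50 * t, trial(), params)
  times <- (res0$grid[1:60] + 30) / 50
  init <- numeric(35)
  init[match(c(-1, 0, 1), lev)] <- c(15, 17.5, 15)
  ref <- integrate_ode(rhs_flat, init, times, max_step = 5e-4,
                       project = function(s) pmax(s, 0))
  expect_lt(max(abs(ref - res0$rates[, 1:60])), 1e-5)
})

test_that("bump perturbations are causal, sparse and bidirectional", {
  params <- bump_params()
  pert <- run_perturbation(params, list(position = 5, evidence = 3))
  nev <- 35
  lev <- evidence_levels(params)
  # earlier layers untouched (exact zeros)
  expect_equal(max(abs(pert$delta[1:(4 * nev), ])), 0)
  # at a later layer: increase near the stimulated level, decrease near 0
  j <- which.min(abs(pert$grid - 150))
  d10 <- pert$delta[9 * nev + 1:nev, j]
  expect_gt(d10[match(3, lev)], 1)
  expect_lt(d10[match(0, lev)], -1)
  # sparse: most neurons essentially unchanged
  expect_lt(mean(abs(d10) > 0.5), 0.5)
})
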