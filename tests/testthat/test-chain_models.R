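test_that("chain right-hand side matches hand evaluation", {
  params <- chain_params()
  n <- params$n_positions
  zero <- list(r_L = numeric(n), r_R = numeric(n))
  tr <- trial()
  # beyond maze_end every gate is off and all terms vanish
  d0 <- chain_rhs(zero, 310, params, tr)
  expect_equal(d0$r_L, numeric(n))
  expect_equal(d0$r_R, numeric(n))

  # symmetric state, no cues: both chains evolve identically
  st <- list(r_L = rep(2, n), r_R = rep(2, n))
  ds <- chain_rhs(st, 50, params, tr)
  expect_equal(ds$r_L, ds$r_R)

  # hand evaluation at the active neuron (p = 50 -> unit index 5, 1-based 5)
  i <- 5
  st <- list(r_L = numeric(n), r_R = numeric(n))
  st$r_L[i] <- 4; st$r_R[i] <- 4; st$r_L[i - 1] <- 2
  d <- chain_rhs(st, 50, params, tr)
  bracket_L <- 10 * 4 + 50 * 2 - 40 * 4 + 500
  expect_equal(d$r_L[i], -50 * 4 + max(bracket_L, 0))
  bracket_R <- 10 * 4 + 0 - 40 * 4 + 500
  expect_equal(d$r_R[i], -50 * 4 + max(bracket_R, 0))

  expect_error(chain_rhs(list(r_L = 1, r_R = 1), 50, params, tr), "size")
})

test_that("compiled simulator agrees with the R reference dynamics", {
  params <- chain_params()
  # cue window edges chosen off the RK4 stage grid (multiples of 0.05 cm) so
  # both integrators see identical indicator values at every stage
  tr <- trial(left_cues = 45.03, right_cues = c(65.03, 125.03))
  res <- simulate_chain_trial(tr)
  n <- params$n_positions
  rhs_flat <- function(t, s) {
    p <- -30 + 50 * t
    d <- chain_rhs(list(r_L = s[1:n], r_R = s[n + 1:n]), p, params, tr)
    c(d$r_L, d$r_R)
  }
  grid <- res$grid[1:900] # up to p = 59.9 cm, spans the left cue at 45 cm
  times <- (grid + 30) / 50
  ref <- integrate_ode(rhs_flat, numeric(2 * n), times, max_step = 0.002,
                       project = function(s) pmax(s, 0))
  expect_lt(max(abs(ref - res$rates[, 1:900])), 1e-6)
})

test_that("noise-free chains integrate evidence faithfully and decide correctly", {
  # no cues: exact left/right symmetry
  res0 <- simulate_chain_trial(trial())
  n <- 17
  expect_equal(unname(res0$rates[1:n, ]), unname(res0$rates[n + 1:n, ]))

  # single right cue: difference appears and persists down the chain
  res1 <- simulate_chain_trial(trial(right_cues = 50))
  d <- res1$rates[1:n, ] - res1$rates[n + 1:n, ]
  probes <- seq(65, 295, by = 10) # mid-gate samples after the cue
  active_d <- sapply(probes, function(p) {
    j <- which.min(abs(res1$grid - p))
    d[floor(p / 20) + 3, j]
  })
  expect_true(all(active_d < -1))

  # faithful transfer: active-pair difference ~ 2 Hz per net cue (5% rel tol)
  tr <- fixture_trial() # evidence profile known, cues well separated
  res <- simulate_chain_trial(tr)
  d <- res$rates[1:n, ] - res$rates[n + 1:n, ]
  for (p in c(39, 79, 139, 199, 259, 299)) {
    j <- which.min(abs(res$grid - p))
    unit <- floor(p / 20) + 3
    ev <- evidence_before(tr, p)
    expect_equal(unname(d[unit, j]), -2 * ev, tolerance = 0.05 + 1e-8)
  }

  # decisions follow the majority side on all nonzero-evidence trials
  set.seed(7)
  trs <- generate_trials(40)
  sess <- simulate_trials(trs, "mutual")
  nz <- sess$choices$delta != 0
  expect_true(all(ifelse(sess$choices$delta[nz] > 0, "right", "left") ==
                    sess$choices$choice[nz]))
})

test_that("rates stay non-negative and mirror equivariance is exact", {
  set.seed(8)
  for (k in 1:3) {
    tr <- generate_trial(2.3, 7.7, trial_id = k)
    res <- simulate_chain_trial(tr)
    expect_true(all(res$rates >= 0))
    resm <- simulate_chain_trial(mirror_trial(tr))
    n <- 17
    expect_equal(unname(res$rates[1:n, ]), unname(resm$rates[n + 1:n, ]),
                 tolerance = 1e-12)
  }
})

test_that("saturation is governed by the common drive X", {
  # strong one-sided evidence saturates the difference at X / (a - b)
  tr <- trial(right_cues = seq(10, 190, by = 20)) # 10 right cues
  res <- simulate_chain_trial(tr)
  n <- 17
  j <- which.min(abs(res$grid - 250))
  unit <- floor(250 / 20) + 3
  dL <- res$rates[unit, j]; dR <- res$rates[n + unit, j]
  expect_lt(unname(dL), 0.01)                           # nondominant chain silenced
  expect_equal(unname(dR), 500 / 40, tolerance = 0.01)  # dominant pinned at X/(a-b)
  # doubling X doubles the linear range: same trial no longer saturates
  res2 <- simulate_chain_trial(tr, chain_params(X = 1000),
                               gate = square_gate(X = 1000))
  d2 <- unname(res2$rates[n + unit, j] - res2$rates[unit, j])
  expect_gt(d2, 19) # ~ 2 Hz x 10 cues, unsaturated
  expect_gt(unname(res2$rates[unit, j]), 0.5)
})

test_that("chain variants implement their stated structure", {
  pu <- chain_params(variant = "uncoupled")
  expect_equal(pu$e_inh, 0)
  expect_equal(pu$b, pu$a) # per-unit perfect integrator
  expect_equal(pu$X, 0)    # threshold-matched gate
  ru <- simulate_chain_trial(trial(right_cues = c(50, 90)), pu)
  n <- 17
  j <- ncol(ru$rates)
  expect_equal(unname(ru$rates[2 * n, j] - ru$rates[n, j]), 4,
               tolerance = 0.01)

  expect_equal(unstable_self_excitation(0), 10)
  expect_equal(unstable_self_excitation(10), 15)
  expect_true(all(diff(unstable_self_excitation(0:16)) > 0))
  ps <- chain_params(variant = "unstable")
  expect_equal(ps$bvec, 10 + 0.5 * (0:16))
  rs <- simulate_chain_trial(trial(right_cues = c(50, 90)), ps)
  # instability amplifies the difference beyond the perfect-integrator value
  expect_gt(rs$rates[2 * n, ncol(rs$rates)] - rs$rates[n, ncol(rs$rates)], 4)
})

test_that("choice readout compares the last units and breaks ties at random", {
  expect_identical(readout_choice_chains(fake_chain_result(5, 3)), "left")
  expect_identical(readout_choice_chains(fake_chain_result(3, 5)), "right")
  set.seed(9)
  ties <- replicate(200, readout_choice_chains(fake_chain_result(0, 0)))
  expect_gt(mean(ties == "left"), 0.35)
  expect_lt(mean(ties == "left"), 0.65)
})

test_that("choice-readout cells are binary, counted and saturated correctly", {
  res <- simulate_chain_trial(trial(right_cues = c(50, 70, 90, 110)))
  set.seed(10)
  ro <- choice_readout_rates(res)
  n <- 17
  expect_equal(nrow(ro$left), n * (n + 1) / 2)
  expect_equal(sum(ro$cells$position_index == 3), 3)
  expect_true(all(ro$left %in% c(0, 10) | abs(ro$left) < 1e-12 |
                    abs(ro$left - 10) < 1e-12))
  # strong right evidence: right readouts at the last position fire at 2 alpha
  late <- ro$cells$position_index == 17 # active on [280, 300)
  j <- which.min(abs(res$grid - 285))
  expect_true(all(ro$right[late, j] == 10))
  expect_true(all(ro$left[late, j] == 0))
  # balanced chains: readouts fire with ~ 0.5 probability while active
  res0 <- simulate_chain_trial(trial())
  ro0 <- choice_readout_rates(res0)
  act <- ro0$left[late, res0$grid >= 280 & res0$grid < 300]
  expect_gt(mean(act == 10), 0.3)
  expect_lt(mean(act == 10), 0.7)
})

test_that("traditional accumulator ramps persistently without gating", {
  # symmetric no-cue evolution settles at X / (a - b + e)
  res0 <- simulate_traditional_accumulator(trial())
  expect_equal(unname(res0$rates[1, ]), unname(res0$rates[2, ]))
  expect_equal(unname(res0$rates[1, ncol(res0$rates)]), 500 / 80,
               tolerance = 1e-4)
  # a left cue biases the difference persistently
  res <- simulate_traditional_accumulator(trial(left_cues = 50))
  d <- res$rates[1, ] - res$rates[2, ]
  expect_true(all(d[res$grid > 60] > 1))
  expect_identical(res$choice, "left")
  # rhs cross-check against the closed form at a probe state
  dv <- traditional_accumulator_rhs(c(4, 3), 50, trial(left_cues = 50))
  expect_equal(dv[1], -50 * 4 + (10 * 4 - 40 * 3 + 100 + 500))
  expect_equal(dv[2], -50 * 3 + (10 * 3 - 40 * 4 + 500))
})

test_that("single-unit perturbations respect the causal chain structure", {
  pert <- run_perturbation(chain_params(), list(side = "left", index = 5))
  n <- 17
  earlier <- pert$delta[c(1:4, n + 1:4), ]
  expect_true(all(earlier == 0)) # exact zeros upstream
  later_same <- pert$delta[6:n, ]
  expect_true(all(apply(later_same, 1, max) > 1))
  later_opp <- pert$delta[n + 6:n, ]
  expect_true(all(later_opp <= 1e-9))
  expect_true(all(apply(later_opp, 1, min) < -1))

  pu <- run_perturbation(chain_params(variant = "uncoupled"),
                         list(side = "left", index = 5))
  expect_true(all(pu$delta[n + 1:n, ] == 0)) # opposite chain untouched
  expect_true(all(apply(pu$delta[6:n, ], 1, max) > 1))

  # stimulating the last unit has no downstream units to affect: only the
  # stimulated unit (and, through same-position mutual inhibition, its
  # partner) changes
  plast <- run_perturbation(chain_params(), list(side = "left", index = n))
  expect_true(all(plast$delta[-c(n, 2 * n), ] == 0))
  expect_gt(max(plast$delta[n, ]), 0)
  expect_lt(min(plast$delta[2 * n, ]), 0)
  plast_u <- run_perturbation(chain_params(variant = "uncoupled"),
                              list(side = "left", index = n))
  expect_true(all(plast_u$delta[-n, ] == 0))
})
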