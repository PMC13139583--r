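# evseq

Circuit models of evidence accumulation through choice-selective neural
sequences, with the analysis pipeline that distinguishes their
evidence-coding signatures.

## The problem

In the accumulating-towers task a mouse runs down a virtual T-maze (30 cm
precue, 200 cm cue region, 100 cm delay, constant 50 cm/s) while brief
visual cues appear on the left and right; reward follows a turn to the
majority side, so the animal must integrate the signed cue count
*e* = #R − #L and remember it through the delay. Imaging across cortical
and subcortical regions during this task shows *choice-selective
sequences* — neurons fire transiently at specific positions, with distinct
neuron sets active depending on the upcoming choice — which traditional
persistent-activity accumulator circuits cannot produce.

`evseq` is for computational neuroscientists who want to simulate and
analyze the two circuit-model classes that reconcile accumulation with
sequences:

* **Mutually inhibiting competing chains** — two position-gated chains
  obeying
  `dr_iL/dt = -a r_iL + [b r_iL + c r_{i-1,L} - e r_iR + f 1_left(t) + P_i(t) - T]+`,
  with uncoupled (push–pull) and unstable (`b_i = b0 + 0.5 i`) variants and
  binary choice-readout cells. Evidence lives in the *rate difference* of
  the active pair: monotonic (graded, saturating) evidence tuning.
* **Position-gated bump attractor** — 17 layers × 35 evidence levels of
  ring-connected neurons,
  `dr_ij/dt = -a r_ij + F(Σ_k W_jk r_ik + b r_{i-1,j} + c (I_{i,j+1,L} + I_{i,j-1,R}) + P_i(t) - T)`,
  whose shifter neurons move a stereotyped activity bump one evidence level
  per cue: narrow, unimodal tuning tiling the evidence axis.

Around the models: task-trial generation, the 67%-cue-loss input-noise
protocol with psychometric curves, simulated single-neuron optogenetic
perturbations, and the full analysis pipeline for position-binned firing
rates — joint position×evidence Gaussian tuning fits with pseudosession
significance, normalized evidence parameters, 1-D tuning curves
(Gaussian vs. logistic), choice-selective sequence matrices, spline-basis
cue-kernel encoding, single-neuron evidence-vs-choice regression, linear
evidence decoding with nested cross-validation, and population-averaged
preferred-evidence maps — all testable end to end on synthetic sessions
with known ground truth.

## Worked example

```r
library(evseq)
set.seed(1)

tr <- generate_trial(2.3, 7.7, trial_id = 1)
tr
#> trial 1: 1 left, 7 right cues (evidence +6)

res <- simulate_chain_trial(tr)
res
#> chain_mutual simulation: 34 units x 3301 grid points, choice right

n <- 17
d <- res$rates[1:n, ] - res$rates[n + 1:n, ]
j <- which.min(abs(res$grid - 290))
d[17, j]
#> -12  (Hz; left-minus-right of the active pair = -2 Hz per cue of net
#>       right evidence, saturating at X/(a-b) = 12.5 Hz)

trs <- generate_trials(100)
sess <- simulate_trials(trs, "mutual")
psychometric_curve(sess$choices)[4:7, ]
#>  delta_bin  n frac_left       sem
#>         -3 17     1.000 0.0000000
#>          0  8     0.875 0.1169268
#>          3 13     0.000 0.0000000
#>          6 20     0.000 0.0000000
```

Noise-free, the model chooses the majority side on every trial with
nonzero evidence (the Δ = 0 bin is decided by the random tie rule). The
same surface runs the bump model (`simulate_bump_trial`,
`simulate_trials(trs, "bump")`), the input-noise protocol
(`run_noise_sessions`), perturbations (`run_perturbation`) and the
analyses (`bin_session` / `bin_model_session`, `fit_tuning`,
`pseudosession_test`, `fit_cue_kernels`, `evidence_choice_regression`,
`linear_evidence_decoder`, `population_average_map`). A thin command-line
front end over these functions is installed at
`inst/cli/evseq-cli.R`. See the methods vignette
(`vignettes/evseq-methods.Rmd`) for the models, fitting procedures,
numerical choices and limitations.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch with the installed package, the false-positive
percentage of the single-neuron evidence-vs-choice encoding F-test on 2000
synthetic null neurons (activity independent of evidence and choice across
150 generated task trials at one position bin, tested at the 1% level) and
writes it as JSON.
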