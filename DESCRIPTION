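Package: evseq
Title: Circuit Models of Evidence Accumulation Through Choice-Selective
    Neural Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Rate-model simulators and analysis tools for evidence
    accumulation through position-gated neural sequences in the
    accumulating-towers task. Implements two circuit model classes --
    mutually inhibiting competing chains (with uncoupled and unstable
    variants and choice-readout cells) and a position-gated bump
    attractor -- together with traditional competing-accumulator and
    bump-attractor baselines, an input-noise psychometric protocol, and
    simulated single-neuron optogenetic perturbations. Provides the
    accompanying analysis pipeline for position-binned firing rates:
    joint position-by-evidence Gaussian tuning fits with pseudosession
    significance testing, one-dimensional evidence tuning curves,
    choice-selective sequence matrices, spline-basis cue-kernel encoding
    models, single-neuron evidence-versus-choice regression, linear
    evidence decoding with nested cross-validation, and
    population-averaged preferred-evidence maps, all testable end to end
    on synthetic neural sessions with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    splines,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
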