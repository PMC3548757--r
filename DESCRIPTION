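Package: probeForest
Title: Physical Modelling of Oligonucleotide Microarray Hybridization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end physical model of probe intensities on
    short-oligonucleotide (Affymetrix-style) DNA microarrays. Duplex
    stability is computed with nearest-neighbor thermodynamics for every
    fragment of the target at every alignment offset on every probe,
    including mismatched and cross-hybridizing complexes; target
    fragmentation is modelled as a uniform (geometric fragment length)
    cutting process; probe synthesis failure is modelled through per-base
    truncation and abasic-site rates; the post-hybridization wash is an
    equilibrium-constant threshold; and scanner response follows a Gompertz
    curve between the background and linear-cutoff intensities. The package
    fits per-chip parameters (eight synthesis rates, per-segment target
    concentrations, fragmentation and wash stringency) to observed probe
    intensities with a Powell-type direction-set minimizer, provides a
    synthetic-chip simulator for validation, and reproduces model-driven
    analyses of mismatch position effects and forward/reverse strand
    intensity ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    S4Vectors,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
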