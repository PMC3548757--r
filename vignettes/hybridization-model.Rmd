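---
title: "A physical model of probe intensities on short-oligonucleotide arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A physical model of probe intensities on short-oligonucleotide arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probeForest)
```

## The model

probeForest predicts the fluorescent intensity of every probe spot on a
short-oligonucleotide (Affymetrix-style) DNA microarray from first
principles, assuming that hybridization on the chip surface obeys the
same equilibrium thermodynamics as hybridization in solution, and that
the apparent differences — forward/reverse strand asymmetries, the
position dependence of mismatch effects, batch effects — arise from the
experimental details around the binding reaction. Five ingredients are
modelled explicitly and composed into one forward function.

**Duplex thermodynamics.** The free energy of a gapless probe/fragment
duplex is the nearest-neighbor sum $\Delta G = \sum_i (\Delta H_i - T
\Delta S_i)$ over dinucleotide stacking steps, plus helix-initiation
terms for the terminal pairs and a salt correction per phosphate pair,
and the equilibrium constant is $K_{eq} = e^{-\Delta G / RT}$. The
bundled table carries the unified Watson–Crick oligonucleotide
parameters, the 51 published internal-mismatch values (including the
tandem G·T contexts), and the two initiation terms, in J/mol as loaded
by `readNNParams()`. Terminal mismatches are scored with the internal
mismatch values, and the initiation class of a terminal pair is G/C
when either of its bases is G or C — the standard classification for
Watson–Crick ends, extended symmetrically to mismatched ends so a
duplex scores identically from both strands. Dangling ends,
terminal-mismatch stabilization and
loop energetics are not modelled. Steps with two mismatched pairs and
no published value contribute zero energy and are counted in
`pfDiagnostics()`.

**Fragmentation.** The labelled target is cut uniformly at random:
every junction is cut independently with probability $p = 1/\mu$, where
$\mu$ is the mean fragment length in bases, so fragment lengths are
geometric. A fragment of length $j$ with both ends created by cuts has
concentration $C p^2 q^{j-1}$ ($q = 1-p$); a fragment end lying on the
segment boundary is a molecule end and carries factor $1$ instead of
$p$. For fragments running past the probe, the marginal over all
unseen extensions is available in closed form ($C p q^{j}$ for one open
end), and the implementation uses exactly that identity to group
fragments that share a duplex energy window — the grouped fast path and
the fragment-by-fragment enumeration agree to $10^{-10}$ in the test
suite, and both agree with Monte-Carlo fragmentation.

**Exhaustive cross-hybridization.** Every subsequence of every target
segment of length $\ge 2$, on both strands, is allowed to bind at every
offset of the probe that leaves at least two paired bases, including
offsets where the fragment overhangs either probe end (overhanging
bases are unpaired and contribute no energy). The washed, competitive
fraction of bound probes for one spot is the Langmuir occupancy

$$\alpha \;=\; \frac{\sum' C\,K_{eq}}{\sum C\,K_{eq} + 1},$$

where the denominator sums every complex formed during hybridization
and the primed numerator keeps only complexes with $K_{eq}$ at or above
the wash threshold $K_{eqW}$ — the wash is modelled as a threshold
below which duplexes dissociate, applied to the numerator only, as the
occupancy formula is written. Competition is per spot; target is
assumed in excess of probe.

**Synthesis errors.** Probe synthesis proceeds from the 3' end; each
base fails to incorporate with a base-specific probability (truncating
the probe) and each incorporated base later loses its base (abasic
site) with another base-specific probability. A spot is a forest of
full-length probes, all one-error variants and a residual of probes
with two or more errors, which are assumed not to bind. The spot
occupancy is the probability-weighted mix $\alpha = p_F \alpha_F +
\sum_x p_x \alpha_x$. The abasic-variant probability is computed as a
direct product (equivalent to the ratio form $p_F (1-B)/B$ whenever
$B > 0$, and well defined when $B = 0$). An abasic position is treated
as a nick: the duplex splits into two sub-helices that each carry their
own initiation terms, a single stranded-off pair contributes nothing.
This nick model is the package's reading of "backbone present, base
absent"; it is conservative and is exercised directly by the
brute-force equivalence tests.

**Scanner response.** Occupancy maps to expected intensity through a
Gompertz curve $I(\alpha) = \mathrm{MAX} \cdot \exp(\ln(\mathrm{MIN} /
\mathrm{MAX}) \cdot e^{-\alpha \cdot \mathrm{GOMP}})$ with natural
logarithms — the choice that makes $I(0) = \mathrm{MIN}$ exactly. MIN
and MAX are protocol settings (defaults 100 and 65536), never fitted;
GOMP defaults to 7.

## Parameters, units, defaults

| Parameter | Meaning | Unit | Default |
|---|---|---|---|
| `temperature_c` | hybridization temperature | °C | 42 |
| `na_molar` | sodium concentration | M | 1 |
| `mu` | mean fragment length | bases | 50 |
| `keqThreshold` | wash stringency $K_{eqW}$ | — | protocol/grid |
| `incorporation` (A,C,G,T) | per-base synthesis success | prob. | fitted |
| `retention` (A,C,G,T) | per-base base retention | prob. | fitted |
| `concentrations` | per-segment target amount | arbitrary | fitted |
| `scanner` MIN/MAX/GOMP | response curve | scanner units / — | 100 / 65536 / 7 |

Temperatures are configured in °C and converted to kelvin internally;
all energies are J/mol. The salt correction is the entropic
unified-parameter form, $-477 \cdot (\text{pairs}-1) \cdot
\ln[\mathrm{Na^+}]$ J/mol per helix; it vanishes at the 1 M reference
concentration, which also gave the original analyses their best fits.

Concentrations are relative: only the products $C \cdot K_{eq}$ are
identified. Because a 25-mer perfect duplex has $K_{eq} \sim 10^{19}$
at 42 °C, matching concentrations are numerically tiny ($\sim
10^{-17}$) in these arbitrary units.

## Fitting

`fitChip()` estimates, per chip, the eight synthesis rates (logit
scale) and one concentration per segment (log scale) by minimizing the
summed squared difference between observed and expected intensities,
for every combination of a mean-fragment-size grid and a wash grid; the
grid point with the highest Pearson correlation wins, with ties broken
towards the smaller wash threshold and then the smaller $\mu$. Raw
intensities are the default objective scale (a log-scale flag exists).
Missing observations are skipped, never imputed.

The minimizer runs, from each starting point, a bounded quasi-Newton
descent (L-BFGS-B on the unconstrained scale) followed by a Powell-type
direction-set refinement pass. The design was genuinely open here: a
pure direction-set search is the historical choice for this model, but
on desk-scale designs it reliably stalls in — and can terminate inside
— the curved valley that couples incorporation, retention and
concentration (per-base incorporation and retention enter the
full-length probability only through their product, so the objective is
nearly flat along one diagonal per base and the valley floor is
curved). On noiseless synthetic chips the quasi-Newton stage reaches
the generating parameters (objective numerically zero) from neutral
starts where the pure direction-set search stalls at a large residual;
the direction-set pass then serves as a derivative-free verification
and polish. Restart starting points are one neutral start (all rates
0.97, concentration anchored by a one-dimensional intensity match) plus
seeded jitter; fits are bit-reproducible given the seed.

`nnOneDSearch()` holds the fitted (or true) parameters fixed, scales
one nearest-neighbor step's $\Delta H$ over a ratio grid, and reports
the mean observed/expected correlation across chips normalized to the
ratio-1 value — the self-consistency check that the solution-phase
table is also the best table for the simulated chips.

## The synthetic-chip generator

Real chip data for the original designs are not packaged, so
`makeDesign()`/`simulateChip()` emulate them: random target segments
tiled by forward/reverse 25-mer probe pairs at sampled loci, optional
replicated spots, intensities produced by the forward model at known
parameters, and multiplicative lognormal spot noise clamped to the
scanner range. Generator defaults are the study conditions: 42 °C, 1 M
Na⁺, scanner 100/65536/7, mean fragment size 50 nt, wash threshold
$10^{10}$, and resequencing-chip-like synthesis rates (incorporation A 0.967, C
0.944, G 0.908, T 0.950; retention A 0.959, C 0.941, G 0.953, T 0.962).
Concentrations are placed by `calibrateConcentrations()` so the median
spot occupancy is 0.15 — mid-range of the scanner response, and safely
below the occupancy ceiling imposed by the synthesis-error mass (with
these rates a 25-mer spot cannot exceed $\alpha \approx 0.28$ because
probes with $\ge 2$ errors bind nothing). The noise level is not a free
dial: `calibrateNoiseSigma()` solves the lognormal algebra for the one
anchor the original data provide, a replicate-spot correlation of
0.906, and the suite verifies the simulated replicate correlation
across 62 chips against that number.

What the generator does **not** emulate: spatial artifacts (bubbles,
scratches), feature bleed-through, G-stack effects, probe surface
density, secondary structure, genetic variation relative to the
reference, or position-dependent synthesis efficiency. Passing
recovery tests therefore demonstrates internal consistency of model
and fitter under the stated noise model — not that real chips are free
of those unmodelled effects.

## Numerical choices

* **Problem sizes.** The suite uses 2000-probe chips over two 60-base
  segments for parameter recovery (144 distinct probe sequences, each
  with 51 synthesis variants; aggregated duplex tables are cached per
  variant sequence), 40-base single-segment designs for the mismatch
  and enthalpy-search scans, and segments ≤ 30 bases with probes ≤ 12
  for the brute-force equivalence sweep. These sizes make every check
  reproducible on one desk CPU while exercising every code path.
* **Exhaustive vs grouped enumeration.** `buildKeqTable(prune = 0)` is
  the reference per-fragment enumeration; prediction and fitting use
  the aggregated path grouped by duplex window, with the geometric-tail
  identities supplying exact marginal weights. Equality to $10^{-10}$
  between the two (and an independent brute force) is asserted in the
  tests.
* **Overflow.** $K_{eq}$ exponents are clamped at $\pm 700$ (the
  double-precision limit), counted in `pfDiagnostics()`.
* **Degenerate inputs.** $\mu = 1$ cuts every junction: all fragments
  are single bases, nothing can bind, $\alpha = 0$. Truncation variants
  shorter than two bases bind nothing. A wash threshold above every
  $K_{eq}$ empties the numerator.
* **Pruning.** `buildKeqTable()` drops entries below `prune` relative
  to the largest $K_{eq}$ (default $10^{-12}$); all oracle tests run at
  `prune = 0`.
* **Tie-breaks.** Grid selection ties (correlation differences below
  $10^{-12}$) resolve towards the smaller wash threshold, then the
  smaller $\mu$.

## Coordinate and orientation conventions

Probes are 5'→3'. The reverse strand of a segment is its reverse
complement, and fragment start coordinates are 1-based on the strand's
own sequence. In a `KeqTable`, `k` is the probe-frame position of the
fragment's 5' end (it exceeds the probe length when the fragment
overhangs the probe's 3' side), and `tail_class` records which fragment
ends lie on the segment boundary. Fragments may overhang the probe's
5' end (a flag disables this). Synthesis-error positions count from
the 3' end, where synthesis starts; mismatch-scan positions count from
the 5' end. All file formats use 1-based inclusive coordinates.

## Known limitations

The wash threshold is nearly unidentifiable in the simulated regime:
at concentrations placing spots mid-range, sub-threshold complexes
contribute negligibly to the occupancy either way, so wash grid points
tie and the tie-break picks the smallest. Only relative concentrations
are meaningful. Incorporation and retention separate only through
one-error variants, so their individual recovery degrades faster with
noise than their product. The per-spot Langmuir treatment ignores
probe surface density and non-equilibrium wash kinetics; two-or-more
error probes are assumed dark, which matters more for probes longer
than 25-mers.

## A small worked example

```{r example, eval = FALSE}
synth <- synthesisModel(c(A = 0.967, C = 0.944, G = 0.908, T = 0.950),
                        c(A = 0.959, C = 0.941, G = 0.953, T = 0.962))
design <- makeDesign(nLoci = 50, segmentLengths = c(60L, 60L),
                     nReplicateSpots = 10, seed = 1)
frag <- fragmentationModel(50)
wash <- washModel(1e10)
conc <- calibrateConcentrations(design, synth, frag, wash)
sim <- simulateChip(design, synth, conc, frag, wash,
                    noise = noiseModel("lognormal_multiplicative", 0.11),
                    seed = 1)
fit <- fitChip(design, setNames(sim$intensity, sim$probe_id),
               fitConfig(washGrid = 1e10, fragGrid = 50, seed = 1))
fit
```
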