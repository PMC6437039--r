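---
title: "Distributed multicellular logic: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distributed multicellular logic: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(platelogic)
```

# The architecture

A conventional genetic logic circuit wires regulators inside one cell; the
architecture modeled here distributes the computation over a population
instead. Each of the n input bits is physically realized as a pair of
mutually exclusive antibiotics — one drug per bit is always present, the
ZERO form or the ONE form — so an input word is a cocktail of n drugs. An
*E. coli* strain transformed with one resistance marker per bit survives
exactly one of the 2^n cocktails. That makes the 2^n-strain library a
one-hot decoder, and any m-output Boolean function becomes a plate layout
by canonical sum-of-minterms: one well per output, mixed from the one-hot
strains of that output's minterms. Under input w the well grows iff it
contains the strain for w; after development each well is yellow (growth,
binary 1) or blue (no growth, binary 0).

Three consequences shape the package:

* **Compilation is purely combinatorial.** `compile_function()` never
  minimizes the truth table. Minimization (Karnaugh/Quine–McCluskey) would
  merge minterms into cubes, but a strain responds to exactly one word, so
  the canonical form is not a simplification target — it *is* the device
  semantics. The compiler's only degrees of freedom are layout.
* **Correctness is an endpoint property.** The wet system is read once,
  after development; accordingly `verify_device()` compares binary
  endpoints, never trajectories, against the truth table for all 2^n
  words.
* **The growth model is a stand-in for a binary phenotype.** The assay
  reports live/dead per well, so any dynamics that cleanly separate
  "resistant strains reach high density" from "sensitive strains die"
  reproduces the logic. We chose the simplest such mechanism (below) and
  kept it behind one contract (`simulate_well()`) so a richer model can be
  dropped in.

# Bit-encoding conventions

The word string is written MSB first: `"110"` has bit 1 = 1, bit 2 = 1,
bit 3 = 0 and decimal value 6, which is also the digit the display device
renders for that input. The reference encoding
(`default_encoding()`) assigns, in bit order, Am/Ch, Tc/Km and Gm/Sm as
the ZERO/ONE drug pairs, with the bench concentrations and marker plasmids
attached as metadata. This position-based assignment reproduces every
published input→cocktail example bit-exactly (101 → Ch/Tc/Sm, 000 →
Am/Tc/Gm, 110 → Ch/Km/Gm) and the strain↔word correspondences (CTS ↔ 101,
ATG ↔ 000). Strain labels concatenate marker initials in bit order; for
two-bit libraries the bench convention of naming double-resistant strains
later-marker-first (KA, TA, KC, TC) is kept as a display alias.

Encodings are ordinary objects: any arity and any drug alphabet validate,
as long as all 2n abbreviations are distinct. Relabeling which drug pair
is "bit 1" is a permutation of positions, not a new mechanism, and is
expressed with `subset_encoding()` / custom `bit_encoding()` objects.

# The well model

Let B_i(t) be the biomass of strain i in a well of carrying capacity K,
and let S be the set of strains resistant to every drug present. Then

* dB_i/dt = mu_i · B_i · (1 − ΣB/K)  for i in S (logistic growth, shared
  capacity — co-cultured survivors compete for the same resources),
* dB_i/dt = −delta · B_i            otherwise (first-order killing),

with B_i(0) = f0 · K per strain. The well reads 1 iff total biomass at the
development time t_read is at least theta · K.

Antibiotic action is binary and concentration-independent: the assay never
titrates, it selects. Cross-resistance, resource competition beyond the
shared capacity, plasmid loss and pharmacokinetics are out of scope.

## Parameters, units and defaults

| parameter | default | unit | rationale |
|---|---|---|---|
| `mu` | 0.383 | 1/h | sets the response time (below) |
| `K` | 1.0 | biomass | arbitrary normalization |
| `inoculum_fraction` f0 | 0.01 | — | the 1:100 inoculation |
| `delta` | 0.5 | 1/h | sensitive biomass falls > 99.9% by 18 h |
| `theta` | 0.5 | — | halfway threshold; any value in (f0, 1) gives the same logic |
| `t_read` | 18 | h | development time of the assay |
| `dt` | 0.05 | h | integration step (see below) |

For a single surviving strain the logistic solution crosses theta·K at

t\* = ln( (theta / (1 − theta)) · (1 − f0) / f0 ) / mu = ln(99) / mu,

so `mu = 0.383`/h places t\* ≈ 12.0 h — the observed response time of the
assay — while reading at 18 h leaves ≈ 6 h of saturation margin against
false negatives, and delta = 0.5/h leaves sensitive wells at < 10⁻³ of
their inoculum, far below threshold, against false positives. All
parameters are overridable per call or via a flat YAML config
(`read_params()`).

## Numerical choices

Integration is fixed-step classical RK4. A fixed step (rather than an
adaptive solver) makes runs bit-for-bit deterministic and lets the
Monte-Carlo layer integrate thousands of replicate wells as one vectorized
system. At `dt = 0.05` h the single-strain endpoint agrees with the
analytic logistic to better than 1e-6·K, halving `dt` moves endpoints by
< 1e-6·K, and the trajectory matches an independent RK4 implementation
(deSolve) to ~1e-10 — all asserted in the test suite. Threshold-crossing
times are linearly interpolated within the bracketing step. A positivity
guard clips negative biomass (which RK4 could otherwise produce for decay
steps far stiffer than the defaults).

Degenerate inputs are defined, not accidental: an empty mixture is a
constant-0 well (zero biomass throughout); an empty drug cocktail is
survived by every strain; a well whose on-set is all 2^n words holds the
whole library and reads constant 1.

# The display device

The display compiles a digit font instead of a truth table: 15 wells on a
5-row × 3-column grid ("3 × 5 matrix" read as 3 columns × 5 rows, portrait
digits, row-major, top-left origin), where pixel (r,c) has on-set
{w : glyph(value(w)) lights (r,c)}. The published glyphs exist only as
plate photographs, so the package ships its own canonical 3×5
calculator-style font as a versioned JSON file; compiler and decoder are
both font-parameterized, and any 8 pairwise-distinct 5×3 masks validate.
With this font every pixel is lit by at least one digit, so the compiled
display has no empty wells.

Decoding is exact-match by policy: a readout that is not precisely one
glyph raises an error carrying the nearest digit and its Hamming distance,
because a faulty plate should be reported, never silently guessed.
Nearest-glyph decoding exists (`nearest = TRUE`) for robustness studies;
ties remain errors.

# Noise model and fault tolerance

The wet system's claim to robustness is population redundancy. The noise
model keeps that analysis tractable by acting *outside* the integrator:

* `leak_prob` — a sensitive strain nonetheless grows (resistance leakage,
  drug degradation): Bernoulli per strain/well/replicate;
* `dropout_prob` — a resistant strain fails to grow (plasmid loss, bad
  inoculum);
* `mu_cv`, `inoculum_cv` — log-normal jitter (mean preserved) on growth
  rate and starting biomass.

Because flips act on the survival decision, closed forms stay available:
for the 3-bit one-hot array under leak probability p, a fully correct
readout needs all 7 sensitive wells quiet, probability (1−p)^7; with
per-well accuracy q > 1/2, a 3-replicate majority vote reads a well
correctly with probability q³ + 3q²(1−q). The Monte-Carlo estimator is
checked against both closed forms within three standard errors in the
acceptance tests (2000 trials; the binomial standard-error tolerance
3·sqrt(p̂(1−p̂)/n) is the stochastic-test policy throughout). Runs with the
same seed are bit-for-bit identical, and runs differing only in
leak/dropout probabilities share their underlying uniform draws, so
reliability curves across noise levels are matched comparisons.

The quantitative reliability numbers are properties of this simulator and
its noise model — the wet-lab source asserts fault tolerance only
qualitatively.

# What the simulations do and do not show

The synthetic layer emulates the *study conditions*: binary antibiotic
selection, 1:100 inoculation, an 18 h endpoint, and a yellow/blue
threshold readout. Passing tests therefore demonstrate that the
compilation rule is logically sound (plate readout ≡ truth table, checked
exhaustively for the shipped devices and for 100 random 3-bit functions)
and that the kinetic defaults reproduce the observed response time. They
do not demonstrate robustness of real cultures to phenomena the model
excludes: concentration-dependent killing, cross-resistance, growth-rate
disparities between marker combinations (per-strain `mu` overrides exist,
but defaults are uniform for lack of published per-strain rates), plasmid
instability, or pH/indicator kinetics of the colorimetric development.

# Problem sizes

Everything is desk-scale by construction (n ≤ 3 for all shipped devices):
exhaustive verification is 8 words × ≤ 2 wells, the random-function
equivalence sweep uses 100 functions × 8 words, and the Monte-Carlo
acceptance runs use 2000 trials per word — sizes at which the binomial
standard errors above are decisive while the whole suite stays fast.
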