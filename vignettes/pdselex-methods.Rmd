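---
title: "Models and methods behind pdselex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pdselex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pdselex` models library-vs-library in vitro selection: an RNA pool and a
phage-displayed protein pool are mixed, RNA-protein complexes are enriched
by a two-step affinity purification, and both pools are amplified and
carried into the next round. After several rounds the surviving sequences
are read out by deep sequencing, candidate pairs are deconvoluted by
re-selecting a focused RNA library against individual proteins, and the
discovered pairs are characterized by surface plasmon resonance (SPR). The
package provides each of those stages as tested, seeded code: a stochastic
campaign simulator, the sequencing analysis, the deconvolution statistics,
and 1:1 Langmuir kinetics fitting.

## The selection model

One round has two purification steps. In step 1 the phage pool is
immobilized on beads and the RNA pool binds to it; in step 2 the
RNA-phage complexes are recaptured through a docking sequence in the
RNA's 3' fixed flank, so only RNAs *and* phage that traveled as a complex
survive. The simulator reduces this to per-molecule retention
probabilities:

* An RNA survives step 1 with probability
  `p = e1 * B + b1 * (1 - w)^n_washes`, where `B` is its equilibrium bound
  fraction against the abundance-weighted protein mixture at a single
  effective protein concentration, `e1` is the capture efficiency and `b1`
  the nonspecific background. `B` sums `w_j * C / (C + Kd_app(i, j))` over
  the landscape; pairs absent from the sparse `kd_landscape` contribute
  nothing (no specific binding).
* A phage survives step 2 with probability
  `p = e2 * B' + b2 * s * (1 - B')`, where `B'` is its bound fraction
  against the *captured* RNA mixture and `s < 1` is the background
  reduction from RNase H elution, which releases only genuine RNA-DNA
  hybrids.

Two phenomenological multipliers act on the intrinsic `K_D`. Avidity:
each virion displays about ten protein copies, so the apparent `K_D` is
divided by `copies^exponent` (defaults 10 and 1). Urea: a denaturant added
in late rounds multiplies the apparent `K_D` by `urea_penalty`
(default 5) *and* divides the nonspecific background by the same factor.
The second half is a deliberate modeling choice: a denaturant suppresses
nonspecific adsorption at least as strongly as a folded specific complex.
It is also what makes the intuitive monotonicity property provable —
raising stringency (more washes, urea, lower backgrounds) can never
decrease the cognate pair's expected enrichment factor, because the EF is
monotone in the specific-to-background capture ratio and
`5 C / (C + 5 Kd) >= C / (C + Kd)`.

Counts are thinned binomially per species, bottlenecked by a multinomial
draw at the configured carrying capacity, and amplified back to the next
round's input with mean-one lognormal per-species amplification bias.
Every random draw has an expectation-mode twin that substitutes its mean,
so mixture arithmetic (for example the two-component enrichment formula
`f' = f p_b / (f p_b + (1 - f) p_n)`) is reproduced to machine precision
and serves as an oracle in the tests. An all-zero captured pool is a
*selection crash*, reported as an outcome with the crashing round index,
not an error.

What the simulator does not model: phage mutation during amplification,
PCR chimeras, bead mass-transport kinetics, or indel sequencing errors
(substitution-only; the variable regions are short and flank-anchored).
Passing tests therefore demonstrate the analysis logic on data with the
assumed statistical structure, not robustness to those artifacts.

## Sequencing analysis

Reads are demultiplexed by 5' barcode (unique within `max_mismatch`;
barcode sets must keep pairwise Hamming distance above twice the
tolerance, otherwise they are rejected). RNA variable regions are located
by anchoring on the last 12 nt of the 5' flank and the first 12 nt of the
3' flank, each tolerating one substitution by default; protein reads are
translated in frame from scaffold codon 34, and variants containing stop
codons are excluded from abundance tables by default (they cannot be
displayed), with a flag to retain them.

Counting is exact — no clustering or error correction — matching the
choice to count exact variable regions; the simulator's substitution-error
knob is the place to study how much that blurs abundances. Abundances are
relative frequencies per pool and round, which makes the enrichment
factor `EF = abundance_after / abundance_before` robust to unequal
sequencing depth. A species unseen in the earlier round has an *undefined*
EF, which is distinct from `EF = 0` (present before, gone after); the
monotonic filter (both consecutive EFs defined and >= 1.0, boundary
inclusive) therefore drops late arrivals by construction. Ranked outputs
order by count descending with lexicographic tie-break, so all rankings
are deterministic.

Diversity profiles separate species seen exactly once (singletons) from
multi-copy bins; the default edges 2, 10, 1e2, 1e3, 1e4, 1e5, Inf give six
multi-copy bins. The edges are a package convention (no standard exists)
and are configurable. Note that singleton fractions depend strongly on
reads-per-species: a pool sequenced much deeper than its richness will
show few singletons even when fully diverse.

Consensus readouts are abundance-weighted motif fractions under IUPAC
matching (`S` = C/G and the rest of the standard code, case-insensitive,
T read as U). An exhaustive k-mer scan with single-position IUPAC
collapsing is included as a convenience for motif discovery; it is a
package extension, not a reimplementation of any published discovery
procedure.

## Deconvolution

Sequencing alone cannot say which RNA binds which protein. The
re-selection stage takes the most abundant post-selection RNAs (plus
labeled control RNAs), synthesizes them at uniform abundance, and selects
the library against each candidate protein individually on monovalent
beads (`avidity_copies = 1`). Per-RNA EFs are summarized over motif
subsets by box statistics: median and quartiles by linear interpolation
(`stats::quantile` type 7), whiskers at 1.5 IQR clamped to the data range.
A subset is called *cognate* for a protein when its median EF >= 1.0
(inclusive), *depleted* below 0.5, *neutral* between; both thresholds are
arguments and are recorded in the output. Two pairs are proposed as
mutually orthogonal when each protein is cognate for its own subset and
depleted for the other's.

Box plots carry no named significance test, so none is invented: subset
medians are reported with a seeded percentile bootstrap interval
(10^4 resamples by default) as the uncertainty measure.

The depletion reading deserves a note: a protein that binds *nothing* in
the library leaves all abundances unchanged and every EF near 1, which the
inclusive boundary would call cognate. Discrimination requires that each
tested protein enriches something. The synthetic scenario therefore gives
every non-planted protein one weak decoy binder (K_D exactly at the 1 uM
off-target floor), which is also the realistic reading of a selection
output: every variant that survived six rounds binds *something*.

## Synthetic study scenario

`planted_pair_scenario()` fixes the study conditions used by the
acceptance checks: 1e4 RNA loops (20 nt, hairpin design) by 100 displayed
protein variants (NNK-sampled 8-mers), three rounds, 1e5 reads per pool
per round at a 1e-3 substitution rate. One cognate pair is planted at
K_D = 10 pM (k_on 1e7 1/(M s), k_off 1e-4 1/s); binding is
motif-determined — every loop containing the consensus motif binds the
planted protein — and all other specific interactions sit at the 1 uM
decoy floor. Backgrounds (`b1 = 3e-3`, `b2 = 1e-3`, RNase H factor 0.3)
were chosen so that co-enrichment is gradual over three rounds (planted
RNA fraction roughly 1e-4 to 1.5e-3 to 0.12 to ~1) rather than fixating
in one round; a fixated pool makes round-to-round EFs degenerate at 1.0,
a regime the filter is not meant to distinguish. The default six-round
schedule mirrors the campaign structure: negative selection in rounds
1-2, urea in rounds 5-6, decreasing inputs and increasing washes; the
per-round numeric values are package defaults, all overridable.

## Binding kinetics

The SPR model is strict 1:1 Langmuir. Association:
`R(t) = R_max C k_on / (C k_on + k_off) (1 - exp(-(C k_on + k_off) t))`;
dissociation: `R(t) = R0 exp(-k_off (t - t0))`; `K_D = k_off / k_on`,
always the quotient of the same fit's rates. Sensorgrams are corrected by
double referencing — subtracting both the reference flow cell and a
blank buffer injection — which removes any signal common to sample and
reference, including linear drift.

Fitting is global: one `(k_on, k_off, R_max)` is shared across all
concentrations and both phases, minimized by Levenberg-Marquardt on
log10-scale parameters with box bounds `k_on` in [1e3, 1e10],
`k_off` in [1e-6, 1], and relative tolerance 1e-10. Whether instrument
software fits phases jointly or sequentially is not documented anywhere
authoritative; the joint fit is this package's documented choice, and a
per-curve mode can be had by fitting single-concentration subsets.
Initialization takes `k_off` from a log-linear regression of the
dissociation tails and `k_on` from the slope of `k_obs` versus
concentration; because amplitude-compensated local minima exist (noticed
at picomolar-K_D corners of the parameter grid, where 100 s association
curves are nearly linear), the optimizer is multi-started over log-spaced
`k_on` values and the lowest-RSS solution kept.

Two protocol lengths are used, as in practice: 100 s association / 420 s
dissociation, or 200 s / 1500 s for slow dissociation. The long protocol
matters: at `k_off = 1.4e-4` 1/s a 420 s window decays only 5.6%, and
with 1% noise the global optimum can sit tens of percent away from the
generating `k_off` — verified directly by comparing RSS at truth against
the fitted optimum. Recovery studies therefore use the extended window
for `k_off < 1e-3` 1/s.

No-binding calls compare the signal estimate against
`max(3 * noise_sd, 1% of fitted R_max)`, with noise estimated from the
10 s pre-injection baseline. The signal estimate is the largest
association-plateau mean (last quarter of each association phase) rather
than a raw pointwise maximum, because the expected maximum of ~1600
Gaussian noise points already exceeds 3 standard deviations.

Replicate aggregation reports per-parameter means and standard deviations
over >= 2 fits, and aggregates K_D as the mean of per-replicate ratios —
not the ratio of mean rates, which is a genuinely different number
whenever replicates vary (the package's tests construct duplicate
measurements where the two differ by ~9%). Selectivity is the off-target
to cognate K_D ratio at three significant figures; the orthogonality
matrix orients every ratio off-target/cognate, floors no-binding entries
at a concentration-limit K_D bound (default 1 uM) with a censoring flag,
and proposes mutually orthogonal pairs above a fold threshold
(default 4000).

## Numerical conventions

* Diversity arithmetic (`alphabet^positions`, library products) is plain
  double-precision integer arithmetic, exact below 2^53 and flagged with a
  warning beyond; all shipped designs are exact.
* Sequence coordinates are 0-based half-open internally; user-facing
  residue numbers use 1-based scaffold numbering (the randomized residues
  are 34, 37, 40, 88-92).
* One master seed fans out to per-round, per-stage streams via
  `stage_seed()` (`(seed + 7919 r + 131 s) mod (2^31 - 1)`), so any stage
  can be re-run in isolation; same seed, byte-identical FASTQ.
* Binomial thinning switches to a normal approximation only above 1e8
  expected successes, where `rbinom`'s integer return would overflow.
* The preset RNA flanks and the 95-residue protein scaffold are synthetic
  stand-ins with the documented architecture (the docking sequence is the
  reverse complement of the capture oligo `CGTTCTGTGTCTTTCGTCGAT`); both
  are data presets, replaceable by real sequences without code changes.

## Problem sizes in the tests

The shipped test suite and acceptance script run the full planted-pair
scenario at its stated size (1e4 x 100 species, 3 rounds, 1e5 reads per
pool per round; about half a minute), a 4 x 4 noiseless kinetics recovery
grid, and a 50-seed 1%-noise Monte-Carlo recovery study. Expectation-mode
oracles use two-species mixtures where closed forms are exact.

## Known limitations

Binding is single-site and equilibrium (no kinetics of capture, no
mass-transport limitation); avidity and urea are scalar multipliers, not
mechanistic models; sequencing errors are substitutions only; exact
counting does not merge error variants, so deep sequencing of a fixated
pool inflates low-count satellite species around the winner (visible as
the motif-bearing error cloud in the scenario, and handled there by
motif-level, not species-level, readouts).
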