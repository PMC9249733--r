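---
title: "Methods: projection models and Pareto design from sorted-library deep sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: projection models and Pareto design from sorted-library deep sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Overview

`abpareto` turns replicated sort-and-sequence experiments on antibody CDR
libraries into continuous, jointly optimizable metrics of antigen binding
(affinity) and non-specific binding (specificity), and uses those metrics to
identify Pareto-optimal library variants and to design novel single mutants.
This vignette records the modeling assumptions, the tunable parameters and
why their defaults are what they are, the numerical choices, and the known
limitations — in particular, what passing the synthetic end-to-end tests
does and does not establish about real data.

## Label assignment from presence/absence

The experiment supplies twelve sequenced samples: for each of two sort
replicates, an input library, an antigen-positive gate, and positive and
negative gates for two polyspecificity probes (a soluble membrane-protein
mixture and ovalbumin). Labels are pure functions of per-sample presence
(count ≥ 1):

* **Antigen:** positive when present in both antigen-positive samples;
  discarded when present in exactly one (an irreproducible observation);
  negative when present in neither but found in an input sample.
* **Specificity:** positive when present in at least three of the four
  non-specific-binding positive samples and in none of the negatives;
  negative under the mirrored rule; otherwise unlabeled.

Presence means `count >= 1` with no abundance threshold: the gates already
select on signal, and read counts in a sorted pool confound abundance with
gate occupancy, so we deliberately do not re-threshold. A `min_count`
argument is not exposed; robustness studies can pre-filter the count table.

Two "frequency" notions coexist and both are implemented, because they
answer different questions. The *occurrence* mode — the fraction of samples
in which a variant appears — is the ranking statistic used to select the
master dataset. The *relative abundance* mode — `count / total_reads` per
sample — is the only reading under which the enrichment ratio
`ER = log2(f_out / f_in)`, averaged over replicates where defined, is
well-defined. A pseudocount (conventionally 0.5 reads, added to the count
and its sample total) is off by default: silently regularizing absent
variants changes the set of defined enrichment values, which should be a
visible analysis decision.

The master-dataset selection keeps `n` variants (default 4000) split evenly
between specificity-positive and specificity-negative strata; within each
stratum antigen-positive variants are kept first (they are the scarcer
label) and remaining slots are filled by descending occurrence frequency,
with ties broken by variant id. The even split and positive-first rule are
one defensible codification of a selection that, in practice, involves
judgment; the tie-break makes it reproducible. Under the default synthetic
conditions the specificity strata are unbalanced (the bottom-10% gates admit
far fewer variants than the top-25% gates), so the pipeline's label stage
keeps all labeled variants unless a master size is requested explicitly.

## Feature encodings

* **One-hot.** Per position, one indicator column per residue *observed at
  that position in the fitting set*. Encoding an unseen residue is an error
  by design: a one-hot model has no representation for novel mutations, which
  is exactly why the design scan refuses one-hot encoders.
* **PhysChem (26 features).** Counts of the twenty residues (alphabetical
  one-letter order — the order is a convention, fixed here once), counts of
  hydrophobic (A,I,L,F,V), amphipathic (W,Y,M), polar (Q,N,S,T,C,M) and
  charged (K,R,D,E,H) residues — methionine genuinely belongs to two sets —
  the isoelectric point, and the mean Kyte–Doolittle hydropathy. The pI is
  the root of the Henderson–Hasselbalch net-charge function with
  Bjellqvist/ExPASy-style pKa constants (N-term 7.50, C-term 3.55, K 10.0,
  R 12.0, H 5.98, D 4.05, E 4.45, C 9.0, Y 10.0), found by bisection on
  pH ∈ [0, 14] to |charge| < 1e-4. Different published pKa sets shift pI by
  a roughly constant offset across VH variants; since the models consume
  the feature only through learned scalings, such an offset is immaterial.
* **Embeddings.** A single-layer 64-unit multiplicative LSTM over one-hot
  residue inputs; the sequence representation is the mean hidden state over
  positions. The cell is a pluggable, weight-file-defined parameterization:
  pretrained weights can be loaded from JSON, while the test suite uses
  seeded random weights and asserts only structural properties (64
  dimensions, determinism, order sensitivity). Nothing in this package
  trains the embedder.

## Projection models

The central idea is that a two-class discriminant trained on binary sort
labels carries more than the class boundary: its one-dimensional projection
`p(x) = w·x` orders variants *within* each class, serving as a continuous
surrogate for the underlying property.

**LDA.** The direction is the two-class Fisher discriminant
`w ∝ Sw⁻¹ (μ⁺ − μ⁻)` with `Sw` the pooled within-class covariance. One-hot
matrices are rank-deficient (per-position indicator blocks sum to one, and
invariant positions are constant), so `Sw` is inverted through the SVD of
the within-class-centered data with singular values below `1e-8 · σ_max`
dropped — a pseudo-inverse restricted to the data's span. The threshold sits
where the two Gaussian class scores are equal,
`w·(μ⁺ + μ⁻)/2 + log(π⁻/π⁺)`; it absorbs the class priors, which is why
fitted cutoffs are close to, but not exactly, the projection midpoint. The
sign convention (positive class mean projects higher) is guaranteed by
construction. Degenerate inputs fail loudly: a single class, or data with no
within-class variance at all, is an error rather than a fit.

**Neural projector.** Two ReLU hidden layers (defaults 32 and 8 — unstated
in the source experiment; chosen small because the decision surface is
near-linear and the training sets are thousands of rows), a single *linear*
projection node, and a 2-way softmax prediction layer, trained with
categorical cross-entropy, ADAM (lr 1e-3), batch size 50, and 50 epochs by
default (250 is the convention for embedding features, which converge more
slowly). All randomness (initialization, batch order) derives from one seed,
and refitting with the same data and seed reproduces parameters bit for bit.
After training, the projection sign is flipped if necessary so that the
positive-class logit increases with the projection; the threshold is the
projection value where the two logits are equal.

**kNN baseline.** Euclidean metric, majority vote, ties broken toward the
smaller label index, evaluated as mean test accuracy over 5-fold CV for
k = 1…25. It exists to show how much of the classification accuracy is
attributable to local similarity alone.

**Cross-validation** uses plain shuffled (unstratified) folds — with
n = 4000 and 5 folds, 3200/800 splits. Stratification was a genuinely open
choice; plain shuffling was chosen because the quoted fold sizes are exact
and the master dataset is already specificity-balanced by construction.
After confirming train/test agreement, final models are refit on all rows.

## Pareto design

Both metrics are kept in a fixed orientation: affinity is maximized and the
non-specificity metric (positive class = high non-specific binding, so
higher = worse) is minimized. The frontier is the set of non-dominated
points; duplicates of a frontier point are all retained. `near_frontier`
ranks non-frontier points by Euclidean distance to the nearest frontier
point in z-scored metric space (the two projections have incomparable
scales), tie-broken by id. The published analyses chose "at or near the
frontier" and allocated designs by hand; these functions are deterministic
stand-ins that log their parameters rather than attempts to reproduce that
judgment.

The single-mutant scan enumerates, for each base clone and each HCDR2/HCDR3
position, every residue other than the current one, excluding cysteine
(free thiols are a manufacturability liability) and — with the default
filter — any substitution with BLOSUM62 score < 0. HCDR1 is excluded from
the default regions because first-generation libraries of this design carry
almost no HCDR1 variation for the models to learn from. Candidates are
scored by both models into property points; `select_designs` takes
non-dominated candidates first, then spreads the selection by greedy max-min
distance in z-scored space. When the library models are one-hot, the scan
refits physchem models and rebuilds the reference frontier in *that*
projection space — projections from different models are not on a common
scale and must never be mixed in one dominance comparison.

## Statistics

Spearman's ρ uses average ranks and the t approximation
`t = ρ√((n−2)/(1−ρ²))` with two-sided p from t(n−2) — the same convention as
the upstream analyses — rather than the exact permutation null. Pearson's r
is reported only when both variables pass a Shapiro–Wilk normality test at
α = 0.05 (and n is within the test's 3–5000 validity range); Spearman is
always reported. Group comparisons use Welch's unequal-variance two-sided
t-test ("independent two-sided t-test" leaves the variance assumption open;
Welch is the safer default), with p = 1 by convention when both groups are
constant and equal. p-values are clamped to the smallest positive double so
that reported values are always in (0, 1]. No multiple-testing correction is
applied; callers comparing many correlations should correct downstream.

The leave-one-residue-out analysis trains on all variants lacking a given
residue at a given site and tests on exactly the variants carrying it. It is
the package's generalization probe: one-hot models cannot score the held-out
residue at all (the encoder raises), while physchem and embedding models can.

## The simulator: what it emulates, and what it does not

`make_truth` draws an (affinity, non-specificity) effect pair per site and
non-parent residue from a bivariate normal with correlation 0.6 — high
enough that affinity-enhancing residues usually carry a non-specificity
penalty (the tradeoff that makes co-optimization hard), low enough that
co-optimal variants exist. Parent residues are the zero reference. A
variant's latent property is the sum of its site effects plus N(0, 0.5)
variant noise; the additive truth means a linear model *can* represent it,
which is what makes the end-to-end recovery test an implementation check
rather than a model-adequacy claim.

`simulate_sort` draws 5,000 distinct variants (sparse sampling of the
1,679,616-variant space, as real sequencing is), log-normal abundances
(meanlog 0, sdlog 1), and for each sample adds N(0, 0.5) display noise to
the relevant latent, then keeps the abundance-weighted top 50% (antigen),
top 25% (non-specific positive) or bottom 10% (non-specific negative) of
cells. The two polyspecificity probes share the latent non-specificity with
an independent N(0, 0.25) per-variant reagent offset, so the 3-of-4 labeling
rule is exercised meaningfully. Sequencing draws multinomial counts at depth
1e5 per sample; zero depth is a valid degenerate sample. Magnetic
pre-enrichment rounds are not simulated (labeling consumes only the FACS
round plus input), and there is no sequencing-error, PCR-bias, or chimera
model.

Consequences: passing the synthetic recovery bars (held-out Spearman ≥ 0.8
for affinity and ≥ 0.7 for non-specificity, ≥ 60% latent-frontier recovery
at seed 7; repo-defined bars, not published values) shows the pipeline is
internally consistent — labels reflect the gates, projections recover an
additive landscape, the frontier machinery finds the true tradeoff surface.
It does not show that real antibody landscapes are additive, that real
display noise is Gaussian, or that published correlation levels will be
reproduced; those are properties of the deposited experimental data, which
this repository does not ship.

## Problem sizes and numerical choices

The test suite and the acceptance script run the simulator at its default
size (5,000 variants, 12 samples at depth 1e5), which yields roughly 4,500
antigen-labeled and 1,500 specificity-labeled variants and trains in seconds;
oracle-based property tests use a few hundred rows per instance. Key
numerical constants: SVD cutoff `1e-8 · σ_max` (LDA pseudo-inverse), pI
bisection tolerance 1e-4 charge units, ADAM (0.9, 0.999, 1e-8), and
deterministic tie-breaks (frequency then id for selection; id for frontier
distance ranks; smaller label index for kNN votes). Every stochastic step —
truth draw, library draw, gates, sequencing, fold shuffles, network
initialization — flows from explicit integer seeds, and fixtures regenerate
byte-identically from their manifests.

## Replication mode

`read_emi_csv` / `read_binding_csv` parse the deposited-supplement CSV
dialects (binary 1/0 label columns keyed by `sequence`; per-clone normalized
binding measurements), and the same encode → LDA → 5-fold CV → correlation
flow applies unchanged. The deposited files are not redistributable within
this package, so the bundled tests exercise replication mode on synthetic
data written in the identical dialect; users with the downloaded supplements
can wire them directly into `read_emi_csv` and `cross_validate`.

## Known limitations

* Labels use presence/absence only; very deep sequencing will label
  singletons with the same confidence as thousand-read variants.
* The projection is a unitless metric: it orders variants but is not
  calibrated to physical binding constants.
* The design scan is exhaustive over single mutants only; combinatorial
  design and generative models are out of scope.
* The command-line surface is the R API plus `scripts/acceptance.R`; the
  pipeline stages are library functions (`run_pipeline()`), not a standalone
  binary.
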