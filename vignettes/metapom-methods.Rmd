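---
title: "Methods: linking metabolic networks to molecular embedding distances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking metabolic networks to molecular embedding distances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metapom)
```

# The analysis

`metapom` quantifies how well a molecular representation — an embedding
such as a principal odor map (POM), or a structure fingerprint —
reflects the organization of metabolism. The package implements four
statistics over a species' metabolic network (a directed graph of
metabolites connected by documented reactions) plus an evaluation
harness, and a synthetic-data module that generates statistically
realistic inputs for all of them.

1. **Metabolic-distance correlation.** The metabolic distance
   `d_met(a, b)` is the length of the shortest *directed* path from `a`
   to `b` — the minimum number of reactions converting one odorant into
   the other. Because sparse networks contain far more short-distance
   pairs than long-distance ones, pairs are resampled so that each
   distance stratum `d = 1..12` contributes equally (50 pairs by
   default); the statistic is the Pearson correlation between `d_met`
   and the representation distance over the sampled pairs.
2. **Pathway smoothness.** Representations are projected to a common
   64-dimensional PCA space (a shared dimensionality avoids a
   dimensionality bias between representations). For a pathway
   `A → … → Z` and intermediate `B`, the smoothness
   `d(A, Z) / (d(A, B) + d(B, Z))` is 1 exactly when `B` lies on the
   straight segment between the endpoints and decreases as the
   trajectory bends; representations are compared by a paired t-test
   over intermediates.
3. **Co-occurrence rank shift.** Over all unordered pairs of molecules
   appearing in a set of natural substances (essential oils), distances
   are ranked from small to large with average ranks on ties; the
   statistic is the mean rank of co-occurring pairs minus the expected
   rank `(P+1)/2` of a random pair. Average-rank ties make the
   group-weighted shifts cancel exactly, which the tests assert.
4. **Performance index.** Cross-validated random-forest prediction of
   dataset targets from representation vectors, rescaled so 0 is random
   and 100 is perfect; and a correlation-based variant for neural
   population data in which per-condition odorant-pair correlation
   distances of neural activity are correlated with the corresponding
   molecular distances.

# Conventions and parameter choices

**Standardization.** A molecule is rejected for the *first* failing
rule, in order: unparseable, mixture (more than one disconnected
fragment), single atom, disallowed element, heavier than 500 Da.
"Single atom" is read against the heavy-atom graph (exactly one
non-hydrogen atom), since SMILES carry implicit hydrogens. Molecular
weight uses standard average atomic weights including implicit
hydrogens, and the threshold is a strict inequality: a molecule at
exactly 500 Da is kept. Allowed elements default to H, C, N, O, S.

**Fingerprints.** Circular (Morgan-style) fingerprints are computed
in-package over the heavy-atom graph: each atom contributes one hashed
environment identifier per radius `0..r` (default radius 2), folded
into 2048 buckets. Identical environments are *not* deduplicated, so
the counts of a molecule always sum to `heavy_atoms × (r + 1)`; the bit
fingerprint is the support indicator of the count vector at equal
width. Atom invariants are (atomic number, heavy degree, implicit
hydrogen count), with implicit hydrogens assigned from default valences
— sufficient for the HCNOS molecules the standardization filter admits.
Charged or exotic-valence atoms are outside this convention's scope.

**Distances.** Correlation distance is computed after centering every
dimension across the *population under analysis* — the union of
sampled pair members for the correlation stage, all oil compounds for
the co-occurrence stage. The same pair can therefore legitimately get
different distances under different populations, and the tests pin this
population dependence down explicitly. Tanimoto distance of two empty
bit fingerprints is defined as 0 (identical objects); the case cannot
occur for standardized molecules but keeps the function total.

**Sampling.** Ordered pairs are sampled: `(a, b)` and `(b, a)` are
distinct strata members because the graph is directed. Under-filled
strata keep all available pairs and warn (or error with
`strict = TRUE`). The network-size filter is inclusive
(`≥ 100` metabolites) and configurable. No currency-metabolite
exclusion is applied by default; real reaction tables should consider
excluding water/ATP-like hubs, which can shortcut paths.

**Smoothness.** The default `endpoint` mode scores each intermediate
against the pathway's start and end; `consecutive` mode scores rolling
triplets of consecutive members instead. Endpoint mode is the default
because the defining formula anchors both distances at the pathway
endpoints; both readings are available.

**Paired t-test.** Closed form, `t = mean(d) / (sd(d)/√n)` with `n − 1`
degrees of freedom, two-sided by default; a sd of the differences
within `1e-12` of zero (relative to the mean difference) is treated as
degenerate and rejected.

**Performance index.** The anchors — 0 for random, 100 for perfect —
are taken as definitional. For classification the centered AUROC is
therefore rescaled by 200 (`(AUROC − 0.5)/0.5 × 100`); a factor of 100
would put a perfect classifier at 50, contradicting the anchors.
Regression uses `R² × 100`, which already satisfies both anchors.
Protocol: leave-one-out with per-seed jackknife resampling for
`N ≤ 200`, fivefold cross-validation with bootstrap resampling
otherwise. Held-out predictions are pooled per seed before the metric
is computed (stable for LOO, where each split yields one prediction),
then rescaled, averaged over targets, and summarized across seeds.

A subtlety worth knowing: under LOO classification, deleting a *random*
training point leaves the training class prior shifted against the
held-out class; pooled over splits this biases the null AUROC far below
0.5 (index ≈ −35 on uninformative data). The jackknife deletion is
therefore stratified — the deleted point is drawn from the class
*opposite* the held-out sample, making training class counts identical
whichever class is held out. With this choice the harness is calibrated:
uninformative features score a seed-averaged index near 0, and a
noiseless single-feature rule scores ≥ 90. The learner is a ranger
random forest (200 trees by default) behind a pluggable fit/predict
interface and a configurable hyperparameter grid; the best grid entry
by mean index is reported.

**Neural extraction.** Traces are smoothed with a centered
moving-average window of 5 frames, truncated at the trace edges
(trailing mode is selectable); baseline mean and SD come from the 30
frames immediately before odor onset, with the population (divide-by-n)
SD; a trial responds when the smoothed post-onset maximum (30 frames)
strictly exceeds `μ + 3σ`. The baseline statistics are computed on the
**raw** trace by default: computing `σ` on the smoothed trace shrinks
it by roughly `√window` and inflates the false-positive rate to ~16%
under white noise, which would defeat the threshold's purpose; the raw
baseline gives a near-zero false-positive rate while keeping full
sensitivity at signal-to-noise 5. The smoothed-baseline reading remains
available via `neural_config(baseline_on = "smoothed")`. For glomerular
dF/F tables the implemented reading is: median-subtract per glomerulus,
take negative deflections as the odor-evoked signal, and normalize by
the glomerulus's mean squared deviation from zero (RMS selectable); the
underlying description is ambiguous and this reading is isolated in one
function.

# What the synthetic generators emulate

The generators produce inputs with the statistical structure each stage
assumes, so every pipeline path is exercised and tested without MetaCyc,
Pyrfume, or a trained network. They are pure functions of their
configuration: same seed, same bytes.

* `make_metabolome()` grows a directed tree of (by default) 250
  metabolites from a root, extending a random current leaf with
  probability 0.85 and branching from a random node otherwise — the low
  branching rate produces the long reaction chains needed to populate
  distance strata up to 12 with ≥ 50 ordered pairs. Each product's
  count fingerprint is its parent's with some coordinates moved by one
  unit. Step sizes follow a two-point mixture: a small edit (5
  coordinates) with probability 0.8, a structural cliff (30
  coordinates) with probability 0.2 — mean exactly `edit_rate = 10`.
  The cliffs matter: with constant-size steps, fingerprint distance
  tracks metabolic distance almost perfectly (r ≈ 0.998), leaving an
  embedding no room to dominate structure metrics the way real data
  shows; occasional drastic structural change per reaction is exactly
  the regime where an odor-map embedding outperforms fingerprints.
* `make_embedding_table()` builds a clean embedding whose Gram matrix
  is exactly `C = exp(−D/6)` over the undirected skeleton (tree metrics
  are of negative type, so `C` is positive semi-definite; with
  `n ≤ embed_dim` it is realized exactly as `C^{1/2} Q` with
  orthonormal-row `Q`), then mixes in independent Gaussian noise at an
  angle calibrated by root-finding so the *measured* pair-level
  correlation between metabolic distance and embedding
  correlation-distance equals the target `ρ`. The noise-free ceiling is
  about 0.95 (the exp nonlinearity over `d = 1..12` caps the ideal at
  ~0.97 and population centering costs ~0.02), so targets up to ~0.9
  are recovered accurately and `ρ = 0` yields pure noise.
* `make_oils()` draws each oil as the metabolites within graph radius 2
  of a random anchor (303 oils by default), appending oils anchored at
  any uncovered metabolite so the oil universe spans the metabolome, as
  a compound list compiled from the oils would.
* `make_neural()` plants ramp-to-plateau responses on Gaussian
  baseline noise; `make_eval_dataset()` builds feature tables with
  thresholded/linear targets (informative) or independent labels
  (uninformative).

What they do *not* emulate: chemical realism (the fingerprint walk is a
statistical stand-in, not reaction chemistry), reversible or
many-to-many reactions (the tree has single parents; the network code
itself supports arbitrary digraphs and is tested against a BFS oracle
on random ones), correlated or drifting neural noise, and distribution
shift between training and evaluation molecules. Green tests on
synthetic data therefore certify the *statistical machinery* — not that
any particular real embedding tracks any particular real metabolome.

# Numerical choices and problem sizes

Distances on unweighted digraphs use breadth-first search via igraph;
unreachable pairs are `NA` and never sampled. PCA uses `prcomp` with
effective dimensionality `min(64, n_keys − 1, width)`. Ranks use
average ties. The Gram eigen-decomposition clips eigenvalues below
`1e-9` at zero. Randomized rounding keeps non-integer mixture means
exact in expectation. All random draws run under an isolated RNG state
(seed in, caller's state untouched).

The shipped tests and demo run at desk scale by design: metabolomes of
80–250 nodes (1001 for the edit-rate check), 600 sampled pairs per
correlation run, 10 seeds per recovery point, oil universes of ~150–250
molecules (~31k pairs), 400 neural trials, and LOO evaluations at
`N = 100` with 5 seeds. A full-size analysis (thousands of metabolites,
`N`-seed LOO) uses the same code paths with larger configuration
values.

# Known limitations

* OpenBabel (via ChemmineR) is the single SMILES authority; molecules
  it parses leniently or kekulizes unusually follow its conventions.
  Tautomer/charge normalization and stereochemistry policy beyond the
  toolkit default are out of scope.
* The "odorous" predicate is pluggable and defaults to the
  standardization filter; transport-based odor-probability rules are
  not re-derived.
* The co-occurrence t-test pairs over molecule pairs (not over oils),
  matching the pair-level statistic; oil-level pairing would need a
  different variance model.
* Whether real analyses should pool sampled pairs across species
  networks or correlate per network first is data-dependent;
  `run_correlation_stage()` works per network and
  `correlation_over_seeds()` reports the sampling stability, leaving
  pooling to the caller.
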