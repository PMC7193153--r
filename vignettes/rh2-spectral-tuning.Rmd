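---
title: "Ancestral reconstruction and spectral tuning of green-sensitive opsins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestral reconstruction and spectral tuning of green-sensitive opsins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opsinshift)
```

## The problem

Green-sensitive (RH2) cone opsins let non-mammalian vertebrates discriminate
wavelengths in the blue-green band that dominates twilight and clear water.
The quantitative phenotype is the pigment's wavelength of maximal absorption,
λmax, in nanometres. Understanding how λmax evolved requires three linked
computations that this package implements end to end:

1. **Ancestral sequence reconstruction.** Given an amino-acid alignment of
   present-day opsins and a fixed, outgroup-rooted composite topology, infer
   the ancestral sequence at each internal node by maximum likelihood under
   an empirical substitution model (JTT, WAG or Dayhoff), with a per-site
   posterior probability (PP) for every ancestral state.
2. **Spectral-shift bookkeeping.** Given λmax values measured for ancestral
   (resurrected) and present-day pigments, census the per-branch shifts
   Δλmax = λ(descendant) − λ(ancestor), flag significant (|Δλmax| ≥ 10 nm)
   and large (|Δλmax| ≥ 30 nm) shifts, and ask whether site-directed
   mutagenesis of the ancestral pigment reproduces the descendant's λmax.
3. **Lineage rates.** Compare amino-acid substitution rates between lineages
   with and without gene duplications, by sequentially averaging branch
   lengths from the tips up to a focal ancestor and dividing by the
   lineage's origin time.

## Models and algorithms

### Substitution models and transition probabilities

An empirical model is a symmetric exchangeability matrix $S$ and equilibrium
frequencies $\pi$; the rate matrix is $Q_{ij} = S_{ij}\pi_j$ ($i \ne j$) with
the diagonal set so rows sum to zero, rescaled so the mean rate
$-\sum_i \pi_i Q_{ii} = 1$ — branch lengths are then expected substitutions
per site. The three shipped models are read from plain-text data files in
the de-facto lower-triangle-plus-frequencies interchange layout, with an md5
manifest checked on load. State order is fixed everywhere to the canonical
A R N D C Q E G H I L K M F P S T W Y V of the original model publications
(`aa_states()`), which is the single defence against silent index bugs.

$P(t) = e^{Qt}$ is computed through the symmetrized eigendecomposition that
reversibility guarantees ($D^{1/2} Q D^{-1/2}$ is symmetric, $D =
\mathrm{diag}(\pi)$); the decomposition is cached per rate matrix, so a
$P(t)$ evaluation is two small matrix products. Round-off negatives of
magnitude ≤ 1e-12 are clipped. The test suite checks $P(t)$ against a
truncated series, Chapman–Kolmogorov composition, detailed balance, and
`Matrix::expm`'s independent scaling-and-squaring path.

**Frequencies.** Which frequencies the original analyses used (model or
alignment-empirical) is not recoverable, so the package defaults to each
model's published frequencies and exposes `+F` empirical frequencies as an
explicit argument (`build_rate_matrix(model, frequencies =
empirical_frequencies(aln))`). A small pseudocount (0.5 per residue) keeps
`+F` frequencies strictly positive, as a stationary distribution requires.

### Likelihood and branch lengths

Site likelihoods use Felsenstein pruning with per-node rescaling of partial
likelihood vectors, so 40-taxon × 281-site problems stay comfortably finite.
Gaps and `X` are missing data — their partial vector is all ones — matching
the convention of restricting analysis to the well-aligned window rather
than treating gaps as a 21st state. User-facing site numbers are 1-based
positions of a reference sequence (bovine RH1 by convention; sites 122, 207
and 292 are the tuning-critical ones), and the analysis window defaults to
reference positions 31..311, which leaves 281 comparable sites for a
full-length reference.

Branch lengths on the fixed topology are maximized by deterministic
coordinate ascent: each branch in turn is optimized by a bounded scalar
search in [1e-8, 10] using the exact conditional decomposition of the
likelihood at that branch (the product of the "above" and "below" partials
across it), with fresh partials recomputed after every accepted update, so
the log-likelihood never decreases. There are no stochastic restarts: the
likelihood in branch lengths on a fixed topology at these problem sizes is
well behaved, and reproducibility matters more than escaping hypothetical
multimodality. Convergence is declared when a full sweep improves the
log-likelihood by less than `tol` (default 1e-6, 200-sweep cap). A
bifurcating root makes its two child edges only jointly identifiable (the
pulley principle); every quantity consumed downstream (tree likelihood,
posteriors, sequentially averaged depth) depends only on their sum.

### Marginal reconstruction

The reported quantity is the *marginal* posterior: for node $k$, site $s$
and state $a$, $\mathrm{PP}(a) \propto L(\text{data} \mid x_k = a)$
normalized over the 20 states. It is computed with one post-order and one
pre-order pass per site (outside–inside), which is algebraically the
clamp-and-renormalize definition; the tests verify that equivalence to
1e-9 against exhaustive enumeration on ≤4-taxon trees. MAP ties are broken
by canonical alphabet order and flagged — they are measure-zero but must be
reproducible. Competing reconstructions (different models or taxon sets)
are compared per site at a node by binning the smaller of the two PPs at
0.95 and 0.70, the thresholds conventional in this literature.

### Shifts, explanations, substitution traces

Δλmax is signed descendant-minus-ancestor, so positive is a red shift;
significance uses |Δλmax| ≥ 10 nm. The absolute-value reading is the only
one consistent with blue shifts being counted among the significant ones.
A mutagenesis assay "fully explains" its branch when the engineered
ancestral pigment's λmax lands within 4 nm of the descendant's. The percent
of a shift explained is $100 \cdot (\lambda_{mutant} -
\lambda_{anc})/(\lambda_{desc} - \lambda_{anc})$, rounded
half-away-from-zero to the nearest integer — the rounding rule that maps
15/35 to 43%. λmax values are integer nm throughout; no interpolation.

### Lineage rates

Depth of a focal ancestor is the recursive unweighted mean over its two or
three children of (child branch length + child depth), tips having depth 0;
on a clock tree this is exactly the root-to-tip path length. Rate =
depth / origin time, with origin times configuration constants
(615, 230 and 413 Myr for the vertebrate, tetrapod and Clupeocephala
lineages; `rh2_lineage_origins()`). The source analyses report SEs without
a derivation, so this package adopts a nonparametric bootstrap over
alignment columns — resample columns with replacement, re-optimize branch
lengths on the fixed topology, recompute depth and rate; SE = SD of the
bootstrap rates (default 100 replicates, seeded). Two rates are compared
with the pooled-SE statistic $Z = |r_1 - r_2| / \sqrt{se_1^2 + se_2^2}$.
Applied to the printed rates and SEs of the original study this formula
gives ≈4.6 and ≈3.7 rather than the printed 4.0 and 3.6; the original Z
construction is unstated, so the package documents its own formula and does
not claim to reproduce those two printed values.

## The packaged fixtures

`rh2_annotated_tree()` returns the composite RH2 phylogeny restricted to
λmax-annotated pigments: the 13 engineered ancestral stages (AncAgnatha
through AncSquamata, λmax 503–524 nm), a 14th internal node for the
previously published cypriniform ancestor (474 nm), and 22 present-day
pigments, with critical-site states, thick-branch (significant-shift) and
duplication flags. Values stated in the study's running text and
mutagenesis table are transcribed verbatim. A few placements and states are
recoverable only indirectly and are *reconstructed* — chosen once to be
consistent with every stated constraint (the 16-significant/3-large census,
the substitution counts E122Q×3, Q122E×4, M207L×2, A292S×1, and the
telescoping of λmax along paths) — and are flagged
`provenance = "reconstructed"` in the annotation table: the goldfish
pigment's placement and λmax, the two basal zebrafish paralogs, and the
loosejaw site-207 state (its assay tests M207L, but the stated
twice-occurred count for M207L excludes it, and the count is authoritative
for the trace). These rows should be treated as synthetic scaffolding, not
as measurements.

`rh2_mutation_assays()` is the 16-row mutagenesis table (ancestor λmax,
substitutions introduced, mutant λmax, descendant λmax). One label in the
source prints a truncated site name for the nine-site mutant; the packaged
table uses the full form (T209V) printed in the running text.

## The synthetic-data generators

`simulate_alignment()` evolves sequences site-independently down the tree —
root drawn from $\pi$, each branch sampling from the parent state's row of
$P(t)$ — recording every internal state, which is exactly the generative
model the reconstruction assumes. That is deliberate: it validates the
inference machinery (posterior calibration, branch-length recovery), not
the model's adequacy for real opsins. Real alignments violate the
simulator's assumptions in known ways — site-specific rates and
constraints, correlated sites in the retinal binding pocket, compositional
drift — so passing calibration tests here says the algorithms are correct,
not that PP = 0.95 means 95% on real data. `simulate_annotated_tree()`
plants λmax shifts (magnitude uniform in [10, 35] nm by default, probability
0.15 per branch) on a Yule-style random tree over an integer-nm jitter floor
(sd 1 nm), so shift detection can be scored against known truth. Generator
defaults mirror the study's conditions: 281 sites, ~40 taxa, root λmax
503 nm, shift sizes spanning the observed 10–35 nm range.

## Problem sizes and numerical choices

The test suite and analysis scripts use: 40 taxa × 281 sites for
reconstruction calibration (≥10,000 high-PP decisions per run); 5,000 sites
on 6 taxa for branch-length recovery (±20% or ±0.02); 150-site clock
alignments with 50-replicate bootstraps, 50 simulation replicates for the
rate-coverage property (true rate within ±3 SE in ≥90%); and exhaustive
oracles on trees of ≤4 taxa, where 20² internal-state enumeration is exact.
These sizes were chosen as the smallest at which each property is a sharp
test of correctness rather than of sampling noise. Scalar branch
optimization uses `stats::optimize` with interval [1e-8, 10]; bootstrap
replicates re-optimize from the point estimate with a looser sweep
tolerance (1e-4), which is ample because the rate is a smooth functional of
branch lengths.

## Known limitations

- No among-site rate heterogeneity (no gamma) or invariant sites — matching
  the original analyses' description; adding gamma would change absolute
  PPs.
- Marginal, not joint, reconstruction; no sampling of ancestral sequences.
- Topology is always user-supplied; no tree search, no rooting inference.
- The bootstrap SE is this package's documented choice, comparable across
  runs of this package but not asserted identical to the original study's
  unexplained SEs; likewise the pooled-SE Z.
- The real 37-sequence GenBank alignment is not packaged; real-data
  headline numbers (e.g. 241/281 concordance at the vertebrate root) are
  covered by method-level equivalence tests, not reproduced numerically.
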