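# opsinshift

Ancestral-sequence reconstruction and spectral-tuning analysis for
green-sensitive (RH2) visual pigments.

RH2 cone opsins let non-mammalian vertebrates discriminate the blue-green
wavelengths that dominate twilight and clear water. Their phenotype is the
wavelength of maximal absorption, λmax (nm), and its evolution is studied by
a three-stage computation that this package implements as a tested R
package plus a small analysis workflow:

1. **Ancestral inference** — maximum-likelihood marginal reconstruction of
   ancestral amino-acid sequences on a fixed rooted topology under the
   empirical JTT / WAG / Dayhoff models: rate matrix
   `Q[i,j] = S[i,j]·π[j]` normalized to mean rate 1, transition
   probabilities `P(t) = exp(Qt)` via the symmetrized eigendecomposition,
   Felsenstein-pruning likelihoods with underflow-safe rescaling, ML branch
   lengths by deterministic coordinate ascent, and per-node × per-site
   posterior probabilities `PP(a) ∝ L(data | node = a)`.
2. **Spectral shifts** — per-branch `Δλmax = λ(descendant) − λ(ancestor)`
   over an annotated phylogeny, with significance (`|Δλmax| ≥ 10` nm) and
   large-shift (`≥ 30` nm) flags; classification of site-directed
   mutagenesis assays as *fully explaining* a branch when the engineered
   mutant lands within 4 nm of the descendant; percent-of-shift-explained
   `100·(λ_mutant − λ_anc)/(λ_desc − λ_anc)` (half-away-from-zero integer
   rounding); and substitution tracing at the tuning-critical sites 122,
   207 and 292 (bovine-RH1 numbering).
3. **Lineage rates** — tips-to-ancestor sequential branch averaging,
   substitutions/site/year against configured origin times, bootstrap
   standard errors over alignment columns, and pooled-SE Z comparisons
   between duplication-rich and duplication-free lineages.

Seeded simulators (`simulate_alignment()`, `simulate_annotated_tree()`)
generate sequence alignments with recorded ancestral truth and
λmax-annotated trees with planted shifts, so every stage is validated
against known truth without external downloads. The composite RH2 tree
(36 annotated nodes) and the 16-row mutagenesis assay table ship as
plain-text fixtures (`rh2_annotated_tree()`, `rh2_mutation_assays()`).

## Worked example

```r
library(opsinshift)

# shift census on the packaged composite tree
fx <- rh2_annotated_tree()
census <- count_shifts(branch_shifts(fx$tree))
census$n_significant   # 16
census$n_large         # 3

# which mutations recur at the critical sites?
trace_site_substitutions(fx$tree, fx$critical_states)$counts
#> A292S E122Q M207L Q122E
#>     1     3     2     4

# do the engineered mutants reproduce their descendants?
classify_explained(rh2_mutation_assays())$n_explained   # 8 (of 16)
fraction_explained(489, 504, 524)
#> $contribution_nm  15
#> $percent          43
```

The analysis workflow (`analysis/01_simulate.R` … `04_rates.R`) is a set of
thin drivers over the same functions; each states what it found and writes
its tables under `results/`. The reconstruction step, for example, prints:

```
JTT: 99.8% of 10404 PP>=0.95 calls match the simulated truth
concordance at node 'N1' over 281 sites:
  identical, min PP >= 0.95: 251
  identical, 0.7 <= min PP < 0.95: 21
  identical, min PP < 0.7: 9
  different: 0
```

i.e. on a 40-taxon, 281-site simulation the JTT and WAG reconstructions of
the root agree at almost every site and the posterior probabilities are
well calibrated against the recorded truth. The rate step detects a planted
two-fold rate difference (Z = 4.0, P < 0.01) while the equal-rate
comparison stays non-significant (Z = 0.9).

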