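---
title: "Methods: expression-weighted network propagation for drug MoA inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression-weighted network propagation for drug MoA inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moanet)
```

## The model

`moanet` treats a drug's mechanism of action as a diffusion problem on a
cell-state-specific protein–protein interaction (PPI) network. The
assumptions, in order of application:

1. **Only expressed proteins participate.** The generic PPI network is
   intersected with genes whose FPKM exceeds 0.1 in the control *or* the
   treated condition. The published description of the filter does not say
   which condition it applies to; we use either-condition, so a gene
   switched on (or not yet fully off) by the drug still participates in the
   treated-state network. Nodes isolated by the intersection are dropped so
   the walk's transition operator is defined everywhere.

2. **Co-regulated interactions matter more.** An edge A–B is evidence of
   concerted activity; if both endpoints change expression under treatment,
   the interaction is more relevant to the drug response. The published
   weight equation is only available as a typeset image, so the package
   adopts the simplest form satisfying every verbal constraint the text
   states (symmetry; baseline weight 1 when either endpoint is unregulated;
   augmentation only when both are regulated):

   $$w_{AB} = 1 + \min(|\log_2 fC_A|,\ |\log_2 fC_B|)$$

   with $fC$ the treated/control fold change after a 0.1 pseudocount on
   both FPKM values. Absolute log fold change is used deliberately —
   regulation in either direction counts, as the co-regulation reading
   requires. `weight_edges(weight_fun = "geom_mean_log2")` provides the
   geometric-mean alternative $1 + \sqrt{|\log_2 fC_A| \cdot |\log_2
   fC_B|}$, which shares all three properties; conclusions that survive the
   swap do not depend on the unknown exact form.

3. **Proximity to the target profile is measured by a random walk with
   restart.** Targets identified by chemical proteomics are seeds with
   restart mass proportional to their spectral-count interaction strength,
   $\mathrm{strength} = sc_\mathrm{immobilized} / (sc_\mathrm{competition}
   + 1)$; the pseudocount keeps fully-competed proteins finite. The walk
   iterates $p \leftarrow (1-\alpha)\,T p + \alpha\,p_0$ with restart
   probability $\alpha = 0.3$ and the column-stochastic operator
   $T_{BA} = w_{AB} / \sum_C w_{AC}$, to convergence in L1 ($10^{-10}$).
   Because $I - (1-\alpha)T$ is strictly diagonally dominant for
   $\alpha > 0$, the fixed point is unique; `rwr_direct()` solves the
   linear system by sparse LU and serves as the independent reference the
   test suite compares the iteration against.

## Significance machinery

**Node null.** The diffusion is repeated for 100 uniformly drawn target
sets of the same size, reusing the true strength multiset, and all node
probabilities are pooled. Per-node empirical p-values use the add-one
estimator $(1 + \#\{null \ge obs\})/(1 + n)$, standard permutation-test
practice that never reports zero. Two flags are computed separately, since
the published workflow quotes both: membership in the top 5% of the pooled
null, and empirical $P < 0.005$ (the perturbed-subnetwork cutoff). Whether
the original random targets were restricted to some compartment (kinases,
say) is unstated; we sample uniformly over network nodes.

**Gene-set scores.** Node probabilities below their 95th percentile are set
to zero (noise suppression; ties at the threshold survive) and each term
scores the sum over its members. The permutation null redraws each term's
membership uniformly from *network nodes* — not from an annotation
universe — because the scores live on network nodes; 1,000 draws per term,
add-one p-values, Benjamini–Hochberg step-up, selection at FDR 5%.

A structural consequence worth stating plainly: with 1,000 permutations the
smallest achievable p-value is $1/1001 \approx 10^{-3}$, while BH selection
of a *lone* true term among $m = 201$ requires $p \le 0.05/201 \approx
2.5\times10^{-4}$. A single planted term therefore attains the minimal
p-value and the best rank but cannot clear FDR 5% by itself. Real GO
collections behave differently because annotation is redundant — dozens of
nested terms share a true signal and pass the step-up threshold together.
The synthetic benchmark plants exactly one term by design, so the package's
recovery claims are stated in terms of minimal-p attainment and rank; the
pipeline falls back to scoring target impact on all terms when the
FDR-selected set is empty.

**Leave-one-target-out impact.** Each target is dropped in turn, remaining
restart mass renormalized, terms rescored, and the matrix entry is
$\log_{10}((s_{-t} + \varepsilon)/(s_\mathrm{full} + \varepsilon))$ with
$\varepsilon = 10^{-12}$ guarding empty scores (both-below-$\varepsilon$
entries are set to 0). A zero-strength target leaves the seed profile
unchanged, so its row is exactly zero. Negative entries mark targets whose
removal disconnects the drug from a process — potentially essential
targets.

## Companion analyses

**Screen triage.** Every physical plate (plate × replicate) is divided by
the median of its negative-control wells; compounds *and* controls are then
averaged across the two replicate plates, and z-scores reference the mean
and sd of the pooled replicate-averaged negative controls. Averaging the
reference controls at the same level as the compounds is what makes the
null z-score standard normal — referencing single-well controls would
shrink null z by $\sqrt2$ and miscalibrate the $z < -2.12$ threshold. The
threshold itself is an input with the published default; how it was
originally derived from the control distributions is not specified.
Positive controls feed only an informational Z'-style separation statistic.
Hit fingerprints are clustered on Jaccard distance with average linkage
(the published dendrogram does not annotate its linkage; the method is an
argument), cut at a user-chosen distance; families of two or more compounds
are flagged as scaffolds.

**Bliss synergy.** Viabilities are normalized to the untreated well,
replicates averaged first (the original collapse rule for triplicates is
unstated), effects $E = 1 - v$ clamped to $[0,1]$ (raw values kept in an
attribute), and each interior dose pair compared with $E_x + E_y - E_xE_y$.
Positive deviation is synergy.

## What the synthetic data emulates — and what it does not

The generators reproduce the statistical *structure* the analysis assumes:
scale-free topology (preferential attachment, largest component kept, since
PPI degree distributions are heavy-tailed and diffusion needs
connectivity); log-normal expression above the 0.1 floor; a co-regulated
module of configurable size planted as the breadth-first neighborhood of
the future seed genes, with |log2 fold change| centered on the effect size
and random per-gene sign; spectral-count pairs with ratios in a set range,
the largest ratios assigned to the module-anchoring genes — the planted
co-regulation must surround the drug's *strongest* binders for the
generated data to be internally consistent with its own truth labels;
decoy gene sets drawn uniformly; Hill-curve dose–response surfaces with an
additive planted interaction; duplicate screen plates with Normal negative
controls, near-zero positive controls and hits shifted by a multiple of
the control sd; and cluster-prototype fingerprints with independent bit
flips.

They do **not** emulate: mass-spectrometry noise and shared-peptide
artifacts, annotation redundancy (see the BH note above), batch or edge
effects on plates, real chemical scaffolds (fingerprints are abstract bit
vectors), or database-specific PPI biases. Passing tests therefore
demonstrate correctness of the computations and recoverability of planted
signal under the stated noise model — not performance on any particular
real dataset.

## Parameters, defaults, sizes

| parameter | default | meaning |
|---|---|---|
| `fpkm_min` | 0.1 | expression floor (FPKM), either condition |
| `alpha` | 0.3 | restart probability of the walk |
| `tol`, `max_iter` | 1e-10, 10000 | L1 convergence control |
| `n_random_nodes` | 100 | random target sets for the node null |
| `top_fraction`, `p_cut` | 0.05, 0.005 | node flags |
| `percentile` | 95 | probability-threshold percentile |
| `n_random_go` | 1000 | permutations per gene set |
| `fdr` | 0.05 | BH selection level |
| screen `threshold` | −2.12 | z-score hit cutoff |
| `pseudocount` | 1 | on competition spectral counts |

Workflow defaults are the published values; everything else (generator
effect sizes, noise levels, plate layouts) is an artifact choice documented
at the generator signatures. The bundled study runs on a 500-node network
with a 50-gene module, 11 targets (3 anchoring the module), 200 decoy
terms, ~10⁴-compound screens for calibration checks, and 104 fingerprints
in 8 clusters — sizes at which every stage's behavior is measurable in
seconds while preserving the size ratios of the original study
(≈9,000-node networks, 11 targets, thousands of GO terms). The
one-root-seed design (`child_seed()` offsets per stage) keeps any stage
bit-reproducible in isolation.

## Numerical and degenerate-input choices

- Self-loops dropped, duplicate edges collapsed on input; isolated nodes
  dropped after the expression filter; seeds outside the kept network are
  dropped with a warning and the remaining mass renormalized; a seed set
  with no surviving positive-mass member is an error.
- Score ties at the 95th-percentile threshold are kept (≥, not >); a
  $10^{-12}$ tolerance absorbs float jitter when comparing permutation
  scores to the observed score.
- `quantile()` type 7 (R default) defines percentiles throughout.
- Average-linkage trees are cut with `cutree()` at a height, making cluster
  assignment deterministic and invariant to compound order.
- Dose–response matrices must carry a dose-0 row and column; single-agent
  vectors alone are rejected.

## Command-line surface

The package is organized as an analysis workflow: the numbered scripts
under `analysis/` are the runnable entry points (simulate, build network,
diffuse + significance, gene-set scores + impact, screen triage, synergy),
each a thin narrative driver over exported functions, and `run_moa()`
orchestrates the MoA stages programmatically. No separate shell wrapper is
shipped.

## Known limitations

- The exact published edge-weight equation is unrecoverable from the
  source text; the default here satisfies its stated properties but is not
  guaranteed identical.
- Gene sets are flat; no ontology-graph propagation of annotations.
- The network is undirected and unsigned; activating vs. inhibiting edges
  are not distinguished.
- Continuous-time diffusion kernels and directed walks are out of scope.
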