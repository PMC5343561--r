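---
title: "Ego-network modules from differential co-expression: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ego-network modules from differential co-expression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`egonetr` identifies small subnetworks of a protein–protein interaction
network whose genes jointly separate two phenotype groups (typically disease
vs normal) in expression data. The pipeline has six stages, orchestrated by
`egonet()`:

1. **Background PPIN.** The interaction network is restricted to genes
   present in the expression matrix; edge weights are preserved.
2. **Differential expression network (DEN).** Every background edge
   $(i, j)$ is scored by the pooled-sample Pearson correlation $r_{ij}$ of
   the two genes, and by a one-sided two-sample t-test on per-sample
   co-expression contributions (below). Edges with $|r_{ij}| \ge 0.8$ and
   $p < 0.05$ form the DEN, reweighted by $|r_{ij}|$.
3. **Ego genes.** DEN nodes are scored by
   $f_i = \sum_{j \in N(i)} A_{ij}\, s_j$, where
   $A = D^{-1/2} W D^{-1/2}$ is the symmetrically normalized weighted
   adjacency ($W$ the $|r|$-weighted adjacency, $D$ the diagonal of its row
   sums) and $s_j$ is the absolute Welch t-statistic of differential
   expression of gene $j$. Scores are standardized to z-scores over the DEN
   and the top 5% (at least one) become ego genes.
4. **Ego modules.** One candidate module is grown per ego gene by greedy
   expansion: at each step every DEN neighbour of the module is evaluated by
   the module classifier AUC and the best neighbour is added; growth stops
   when every neighbour strictly drops the AUC. Candidates with
   AUC $\ge 0.8$ and at least 4 genes are retained.
5. **Significance.** Each retained module is assessed by permuting sample
   labels ($B = 1000$ by default), recomputing the AUC each time, and
   forming the add-one Monte-Carlo p-value $(b + 1)/(B + 1)$ with $b$ the
   number of permuted AUCs at or above the observed one. P-values are
   Benjamini–Hochberg adjusted across modules; adjusted $p < 0.05$ (strict)
   is called significant.
6. **Ego pathways.** Pathways are first intersected with the background
   PPIN gene universe and kept when the intersection has 5–100 genes
   (inclusive). Per module, each background pathway is tested by the
   one-sided Fisher's exact test (hypergeometric upper tail
   $P(X \ge k)$ for overlap $k$, module size $m$, pathway size $K$,
   universe size $N$), adjusted by Benjamini–Hochberg *within* the module;
   adjusted $p < 0.05$ flags an ego pathway.

The module classifier is a linear support-vector machine (cost 1, no
hyperparameter search) evaluated by leave-one-out cross-validation:
features are standardized with training-fold statistics, the held-out
decision values are pooled across folds, oriented so that larger means more
case-like, and scored with the rank-sum (Mann–Whitney) AUC. This makes the
AUC deterministic for a fixed input — there is no fold-assignment
randomness to seed.

# The edge-level test

The co-expression "score" of an edge is a single pooled Pearson
correlation, but the edge filter also asks whether the co-expression signal
is associated with the phenotype. We decompose the correlation into
per-sample contributions
$c_s = \tilde z_i(s)\, \tilde z_j(s)$, where $\tilde z$ is the gene's
expression standardized over **all** samples (so
$\sum_s c_s = (n-1)\, r_{ij}$), and compare case against control
contributions with a one-sided two-sample t-test (pooled-variance by
default; Welch via `var_equal = FALSE`; a Fisher-z differential-correlation
test via `method = "fisherz"`).

The direction of the one-sided alternative deserves care. For a module that
is both co-expressed and *shifted* between groups, pooled standardization
places the minority group far from the pooled mean, so that group's
products carry the correlation mass: with a case-majority design
(e.g., 19 cases vs 6 controls) the signature of a disease-coherent edge is
*control-enriched* contributions. The default is therefore
`direction = "control"`; the case side and a two-sided variant are
available. With balanced designs the choice matters much less; for pure
differential correlation (no mean shift) use `method = "fisherz"`.

The pooled-variance Student test is the default because, under the null
(verified by simulation in the test suite), its p-values are closer to
uniform than Welch's on the skewed product distribution with a small
minority group, and it has substantially higher power for planted modules.
Under label exchangeability the pooled test is exact in size at the
permutation level, which is what the downstream calibration checks assess.

# The expansion stop rule

The greedy acceptance rule reads: add the neighbour with the largest AUC
change $\Delta A$; stop when every neighbour *strictly drops* the AUC
(`allow_plateau = TRUE`, the default). The stricter alternative — accept
only $\Delta A > 0$ — is available via `allow_plateau = FALSE`. The default
matters with few samples: the cross-validated AUC of 19-vs-6 designs lives
on a grid of $19 \times 6 = 114$ case–control pairs and saturates quickly
(a single strong gene often reaches AUC 1.0), so strict improvement halts
modules at one or two genes. Accepting AUC-neutral additions lets a
saturated module absorb the rest of its tightly co-expressed neighbourhood,
which matches the intended behaviour of growing a module "until the
accuracy drops" and produces modules of the size one expects from such an
analysis (4–6 genes) rather than singletons. The size cap (default 30)
bounds growth in pathological plateaus.

A consequence worth knowing: when the AUC saturates *below* 1.0 at a small
module, any further addition usually perturbs the cross-validated AUC
downward by one pair-swap and the expansion stops early. Recovery of a
planted module is therefore high but not perfect even at large effect
sizes; the AUC-greedy objective has no reason to absorb genes that add no
discriminative value.

# Tie-breaking and determinism

All stochastic stages consume explicit seeds; a single pipeline seed is
fanned out to per-module permutation streams by a fixed arithmetic rule, so
end-to-end and stage-wise (CLI) runs agree byte for byte. Deterministic
tie-breaks: at the ego-gene cut, equal z-scores break by higher weighted
degree, then lexicographic gene id; in expansion, equal AUC gains break by
higher z-score, then gene id. Boundary semantics follow the thresholds'
definitions verbatim: $|r| \ge 0.8$ inclusive, $p < 0.05$ strict, module
AUC $\ge 0.8$ and size $\ge 4$ inclusive, pathway sizes 5–100 inclusive,
significance calls strict.

Degenerate inputs are handled conservatively: a zero-variance gene
contributes $r = 0$, $p = 1$ edges (with a warning); an all-equal topology
score vector yields all-zero z-scores (with a warning); an empty DEN
terminates the pipeline gracefully with the stage counts collected so far;
a module whose AUC cannot be defined (one class absent) is an error.

# The synthetic benchmark generator

`simulate_egonet_data()` emulates the statistical structure the pipeline
assumes, with planted ground truth for recovery tests:

* **Graph**: scale-free background via preferential attachment ($m = 2$),
  reflecting the heavy-tailed degree distributions of interaction networks
  and exercising the degree normalization; an Erdős–Rényi alternative is
  available. The planted module is embedded as a star on the hub plus
  chords between consecutive satellites — connected and hub-centred.
* **Expression**: planted genes follow
  $x = \sigma\left(\sqrt{\rho}\, z + \sqrt{1-\rho}\,\varepsilon\right) + \sigma\,\delta\,\mathbf{1}(\text{case})$,
  with a latent factor $z$ shared across the module within each sample, so
  the expected within-group correlation of two planted genes is exactly
  $\rho$; every other gene is independent noise. $\delta$ is the
  standardized group shift per gene.
* **Pathways**: random gene sets drawn from the non-planted genes, plus one
  planted pathway (size 10) overlapping the planted module.

Defaults mirror a small case/control microarray design at desk scale:
19 cases, 6 controls, 300 genes, a 6-gene planted module with
$\delta = 3$, $\rho = 0.9$, $\sigma = 1$, 50 pathways with a 5-gene planted
overlap. These are the conditions under which the package's statistical
claims are tested.

What the generator does **not** emulate: probe-level artifacts, batch
effects, platform normalization, correlated background co-expression
(non-planted genes are independent), missing values, and biological
identifier semantics (gene symbols are synthetic; the nameable hub id
carries no biological claim). Passing recovery tests therefore demonstrate
correctness of the algorithms under the stated generative model, not
performance on real microarray data.

# Problem sizes used by the test suite

The suite checks calibration and recovery by simulation at sizes chosen to
give stable Monte-Carlo estimates at desk scale: null edge-test size over
100 generated datasets; edge-p uniformity over roughly a thousand null
edges; permutation-p uniformity over 200 null modules at $B = 19$;
module-level false-positive rate over 100 null modules at $B = 49$;
hub recovery over 100 seeds; expansion recovery over 50 seeds; planted
pathway recovery over 50 seeds with a 500-gene universe. Oracle
equivalences (pair-counting AUC, hypergeometric tail sums, brute-force
neighbour summation, hand step-up BH) are exact to stated tolerances.

# Known limitations

* The edge test's one-sided direction is design-dependent (see above); with
  unusual designs users should choose `direction` deliberately.
* Only the binary two-group outcome is implemented; continuous, multiclass
  and survival outcomes are out of scope.
* Identifier matching is exact-string; no alias or probe resolution.
* Fisher enrichment uses the background-PPIN universe, not the genome, and
  adjusts within module; cross-module adjustment is not applied.
* The permutation null permutes labels, not network structure; it tests
  group association of the module's expression, not topology.
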