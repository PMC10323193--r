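---
title: "Methods: qPCR fold-regulation statistics and CrossBoruta network inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: qPCR fold-regulation statistics and CrossBoruta network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This package implements the gene-expression analysis arm of a four-group rat
cardiac-graft ischemia/reperfusion study design: threshold-cycle (Ct) data
from a pathway-focused 88-gene qPCR array are quantified with the
delta-delta-Ct model, screened with significance and quality filters, and
then explored with non-linear machine-learning tools — all-relevant Boruta
feature selection iterated gene-by-gene into CrossBoruta gene–gene
networks, stress-majorization network geometry, and gain-ratio decision
trees. A seeded synthetic Ct generator reproduces the study design (groups
"1h ischemia" n=7, "1h ischemia+AAT" n=7, "5h ischemia" n=7,
"5h ischemia+AAT" n=9) so that every stage can be validated against
planted ground truth without any external data.

## Quantification model

For sample $s$ and gene $g$, with $R$ the set of reference genes,

$$\Delta Ct(s,g) = Ct(s,g) - \tfrac{1}{|R|}\sum_{r \in R} Ct(s,r), \qquad
  E(s,g) = 2^{-\Delta Ct(s,g)}.$$

Averaging reference genes on the Ct scale is the geometric mean of their
linear expression — the standard multi-reference normalization. The five
default reference genes are Rplp1, ACTB, B2m, Hprt1 and Ldha.

The fold change of a test group over a control group is
$FC = 2^{-\Delta\Delta Ct}$ with
$\Delta\Delta Ct = \overline{\Delta Ct}_{test} - \overline{\Delta Ct}_{ctrl}$,
i.e. the ratio of geometric means of the linear replicates. We chose this
(the convention of the commercial array-analysis tooling) over the ratio of
arithmetic means because it is the exact inverse of the planted Ct-shift
model, is unbiased on the log2 scale, and commutes with group swapping
($FC \mapsto 1/FC$ exactly). Fold regulation is $FR = FC$ when
$FC \ge 1$ and $-1/FC$ otherwise, so $|FR| \ge 1$ always and up/down
regulation are symmetric.

Per-gene p-values come from a two-sided pooled-variance Student's t-test on
the linear $2^{-\Delta Ct}$ replicates — deliberately not Welch's test, and
with no multiple-testing correction, because the reference tables this
package mirrors report raw per-gene t-test p-values. The significance
filter is strict: $p < 0.05$ and $FR > 2$ (up) or $FR < -2$ (down), with
ties at exactly 2.0 excluded.

Two quality categories are assigned from group-mean raw Ct: "A" when
exactly one group mean exceeds 30 cycles, "B" when both do. The category-B
definition deliberately ignores any p-value clause: flags describe
detectability of the transcript, not test outcome, and the reference
tables themselves contain B-flagged rows with small p-values. Wells
reported as undetermined are set to the panel Ct ceiling (35 cycles,
configurable) and logged; a gene undetermined in more than half of either
group's wells is dropped from that comparison with a warning. The data
this design mirrors published no missing-data rule, so this one is ours.

## Boruta in regression mode

Boruta asks, for a target $y$, which features carry *any* information
about it. Each iteration appends a row-permuted "shadow" copy of every
feature, fits a randomized regression forest, and credits a feature with a
hit when its importance exceeds the maximum shadow importance. After each
iteration every undecided feature's hit count is tested against
$\mathrm{Binomial}(k, 1/2)$ (two-sided, $\alpha = 0.01$, Bonferroni over
the panel): significantly above chance confirms, significantly below
rejects. Left-over Tentative features are resolved by comparing their
median importance with the median of the per-iteration shadow maxima (the
usual rough fix), or can be left Tentative.

Design notes:

* **Regression, not classification.** Targets are continuous expression
  values; with 7–9 samples per group a per-group classification over ~90
  features is hopeless, while pooled regression is workable.
* **Importance.** Variance-reduction (impurity) importance from a
  200-tree `ranger` forest by default — fast and adequate for the
  structural questions asked here; out-of-bag permutation importance is a
  flag away.
* **Shadow-pool floor.** The shadow pool is padded to at least five
  shadow attributes (extra permuted copies of existing columns), as in
  the reference implementation of the algorithm. Without the floor, a
  two-gene panel would test each feature against a single shadow, and the
  max-shadow hit threshold would be far too low.
* **Seeding.** A master seed expands into per-target, per-iteration
  sub-seeds (a Lehmer-style integer recurrence), so CrossBoruta runs are
  reproducible and independent of gene column order at the seed level.

## CrossBoruta networks

Every gene is taken in turn as the Boruta target against all remaining
genes. A confirmed feature $j$ for target $i$ is a directed candidate
$i \leftarrow j$; undirected edges keep either direction (`union`, the
default) or demand both (`intersection`). Edge weight is the mean of the
confirming directions' median importances, min–max normalized per network.
Each edge is annotated with the Spearman correlation of its two genes over
the pooled samples (Pearson on mid-ranks; p from the t approximation on
$n-2$ df) and colored positive/negative when significant at 0.05, grey
otherwise — grey edges are genuine forest patterns without a monotone
correlate and are retained, not dropped.

Network summaries report edge counts by color, degree-0 genes, and a
*homogeneity* score $1 - \mathrm{sd}(\rho_{edges})$ — the spread of edge
correlations relative to its maximal scale. The score is 1 for fewer than
two edges, and for exactly two edges of opposite extreme sign it can drop
slightly below 0 (the sample s.d. of two points in $[-1,1]$ can reach
$\sqrt 2$); we report the raw value rather than clamping, and export the
full $\rho$ distribution so alternative definitions can be recomputed.
Networks are built per study arm (vehicle pool vs. treated pool, 1 h and
5 h times pooled) by default; pool membership is configurable.

The machine-learning stages run on raw Ct by default (configurable to
$\Delta Ct$ or linear scale): decision-tree thresholds in the 20–24 range
only make sense on the Ct-like scale, and correlations of Ct values carry
the same sign as correlations of log-expression.

## Stress-majorization layout

Strongly associated genes should sit close together, so an adjacent pair
with normalized weight $w$ receives target distance $1/(w + 0.05)$;
non-adjacent pairs get the shortest-path distance over those edge lengths,
and nodes in different components are separated by 1.5 times the largest
finite distance. The published figures this mirrors show disconnected
genes drawn apart from the main cluster but state no rule; the padding
factor is ours and exposed. The embedding minimizes raw (unweighted)
stress $\sum_{i<j}(\lVert x_i - x_j\rVert - D_{ij})^2$ by iterated Guttman
transforms from seeded random starts (5 restarts, keep lowest stress;
coincident initializations are re-drawn). Stress is non-increasing by
construction; the run stops at a relative decrease below `tol` (default
1e-6; the exactness tests use 1e-14). Only inter-point distances are the
contract — coordinates are arbitrary up to rotation, translation and
reflection.

## Gain-ratio decision trees

Inter-group classification uses a C4.5-style tree: at each node, every
feature's candidate thresholds (midpoints of consecutive distinct sorted
values) are scored by information gain ratio, ties broken toward the
smaller threshold and then by panel order; values equal to a threshold
route left ("$\le$"). Leaves record the full set of labels present — the
published tree this package ships as `reference_tree()` has multi-group
leaves, so no majority-vote collapse is applied. Boosting, winnowing and
pruning are intentionally absent: the tree is a display of split criteria,
not a production classifier, so criterion fidelity rather than
bit-compatibility with proprietary C5.0 internals is the contract.
`reference_tree()` encodes the published splits verbatim (Flt1 at 23.029,
Gpx3 at 20.448, Cflar at 21.651, Bcl2 at 21.798 expression units on the
array's Ct-like scale).

## The synthetic generator

`simulate_study()` draws
$Ct(s,g) = \beta_g + \delta\text{-shift} + \lambda\,f_s + \varepsilon$:
per-gene baselines $\beta_g \sim U(18, 28)$ cycles; a planted log2 fold
change of $\delta$ lowers the affected group's Ct by $\delta$ cycles (so
planted truth maps exactly onto the $\Delta\Delta Ct$ pipeline); each
correlation module adds a shared per-sample standard-normal factor $f_s$
times a loading (two genes with loading $a$ and noise s.d. $\sigma$ have
expected correlation $a^2/(a^2+\sigma^2)$, i.e. ≈0.8 at the defaults
$a = 1$, $\sigma = 0.5$); reference genes carry tighter noise
(s.d. 0.15 cycles) and no effects; "silent" genes get baselines of 31–34
cycles, above the 30-cycle QC threshold. Gaussian noise on the Ct scale is
the standard qPCR error model (multiplicative log-normal on the linear
scale); amplification efficiency, plate effects and heavy-tailed errors
are not modeled, so passing recovery tests demonstrates correctness of the
computation chain, not robustness to those real-data artifacts.

`study_preset()` plants the qualitative structure of the study findings:
the six genes regulated by prolonged ischemia at their reported fold
regulations (e.g. Ccl2 $2^{1.97} = 3.92$, Tlr4 $-5.85$), planted in both
the vehicle and treated arms so the treated-vs-vehicle contrast at 5 h
stays null for them; Ccl11 up and Vcam1 down in the treated 5 h group; a
coherent positive module in the treated pool against a mixed-sign module
in the vehicle pool; silent genes Il9, Gpx5, Gpx6; and a Tlr4 baseline of
28.5 cycles so its down-regulation pushes the 5 h arms past 30 cycles.

## Problem sizes and validation scope

The test and acceptance suites use: the packaged reference tables (28, 4,
3 and 5 rows) for exact filter outcomes; 100 null Boruta runs and 5
planted runs at $n = 40$, $m = 10$; module recovery on a 14-gene panel
(two 4-gene modules, four noise genes, two silent genes) at 32 pooled
samples over 10 seeds; arm contrasts on an 8-gene panel at 15 samples per
arm over 10 seeds; layout exactness up to 10 nodes; tree validation on
1,000 random fixture samples and 10 planted-topology inductions at 8
samples per group; and 200 simulated two-group studies for fold-change
recovery. End-to-end pipeline tests run a compact 8-gene four-group
configuration.

## Known limitations

* **All-relevant selection at small n flags in-sample correlates.** With
  40 samples and 10 features of pure noise, the most correlated noise
  feature reaches $|r| \approx 0.35$ in a typical realization, and its
  forest importance then beats the max-shadow threshold persistently —
  across importance measures (impurity, raw or Z-scored permutation) and
  forest implementations. Because the data are fixed across iterations,
  hits are persistent rather than independent, and the binomial test
  eventually confirms such features in a substantial fraction of null
  datasets. Consequently a genuinely unconnected (silent) gene often
  acquires at least one spurious edge per network at these sample sizes.
  The intersection edge rule roughly halves spurious edges at a small
  recall cost; treat network edges at $n \approx 30$ as candidate
  associations, not detections.
* **Homogeneity** is our operationalization (no published definition
  exists); see above for its small-edge-count behavior.
* **Exact reproduction of the published networks and tree thresholds is
  out of scope**: the underlying animal Ct data are unpublished, so the
  validation surface is planted-structure recovery on synthetic data plus
  the packaged worked examples.
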