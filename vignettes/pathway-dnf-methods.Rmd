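---
title: "Pathway-centric drug network fusion: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-centric drug network fusion: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Statins inhibit HMGCR, the rate-limiting enzyme of the mevalonate (MVA)
pathway, and show anticancer activity — but sterol depletion triggers an
SREBP2-mediated feedback that re-induces MVA genes and blunts the effect.
Compounds that block this feedback (dipyridamole is the prototype)
potentiate statin-induced cancer cell death. Finding more such compounds by
wet-lab screening is slow; `pathdnf` implements the computational
alternative: ask, across a large drug panel, *which compounds resemble a
reference drug specifically with respect to a pathway of interest*.

A drug is profiled on three layers:

1. **Structure** — extended-connectivity fingerprints; similarity is the
   Tanimoto coefficient $T(A,B) = |A \cap B| / |A \cup B|$ over on-bit sets.
2. **Sensitivity** — z-scored drug response across a cell-line panel;
   similarity is the Pearson correlation of profiles.
3. **Perturbation** — per-drug standardized regression coefficients of drug
   effect on gene expression, *restricted to the pathway gene set* (for the
   MVA application, the six landmark genes ACLY, ACAT2, HMGCS1, HMGCR,
   FDFT1, INSIG1, shipped as `mva_gene_set()`); similarity is again Pearson
   correlation. The restriction is what makes the fused network
   pathway-centric.

## Similarity network fusion

Each similarity matrix $S$ is turned into a distance $d = 1 - s$ and then
into a locally scaled affinity
$$W(i,j) = \exp\!\left(-\frac{d^2(i,j)}{\mu\,\varepsilon(i,j)}\right),
\qquad
\varepsilon(i,j) = \frac{\bar d_K(i) + \bar d_K(j) + d(i,j)}{3},$$
where $\bar d_K(i)$ is the mean distance from $i$ to its $K$ nearest
non-self neighbours. Coincident points ($\varepsilon = 0$) get affinity 1.

Fusion cross-diffuses the layers. Per layer $v$, a full kernel
$P^{(v)}(i,j) = W(i,j) / (2\sum_{k\neq i} W(i,k))$ for $j \neq i$ with
$P(i,i) = 1/2$, and a sparse kernel $S^{(v)}$: each row of $W$ restricted to
its $K$ nearest non-self neighbours and row-normalized. Then for $t$
iterations
$$P^{(v)} \leftarrow S^{(v)} \left(\tfrac{1}{m-1}\sum_{u \neq v}
P^{(u)}\right) S^{(v)\top},$$
followed by re-normalization and symmetrization; the fused network is the
element-wise mean of the $P^{(v)}$. With one layer the cross-layer mean is
the layer itself, and iteration settles to a stable matrix.

Defaults are $K = 20$, $t = 20$, $\mu = 0.5$, the conventional settings of
the fusion algorithm's reference implementation; all are exposed and
recorded in every run manifest. Ties in the $K$-nearest-neighbour selection
are broken by position in the lexicographically sorted drug index, so runs
are deterministic. The vectorized implementation is tested element-wise
against an independent, loop-based implementation of the same update
equations.

## The permutation specificity screen

Ranking drugs by fused similarity to the reference mixes two sources of
closeness: generic similarity (structure, sensitivity — independent of the
gene set) and pathway-specific similarity. The permutation screen isolates
the second. The fused network is rebuilt `n_perm` times (999 in typical
use), each time with the perturbation layer restricted to a random gene set
of the same size $k$ drawn from all genes of the perturbation matrix; the
structure and sensitivity affinities do not depend on the gene set and are
computed exactly once. For each drug the observed statistic is compared to
its null distribution:
$$z = \frac{x_{\text{obs}} - \overline{x}_{\text{null}}}
{\mathrm{sd}(x_{\text{null}})}, \qquad p = \Phi(z),$$
with $\Phi$ the standard normal lower-tail CDF. Hits satisfy $p < 0.05$ and
$z < -1.8$; since $p = \Phi(z)$ and $\Phi(-1.8) \approx 0.036$, the z cutoff
is the binding constraint. No multiple-testing correction is applied — the
selection rule is deliberately a raw-threshold rule, and this is documented
rather than corrected.

**Choice of the permuted statistic.** The statistic $x$ is the *negated
fused similarity* of the drug to the reference (smaller = closer), not the
drug's rank. The rank was considered and rejected: when the two
gene-set-independent layers already place a drug near the top of every null
network — exactly the situation for a tight drug community — its null rank
distribution is concentrated just above 1 (e.g. mean 2.1, sd 1.0), and the
best achievable z, $(1 - 2.1)/1.0 \approx -1.1$, can never cross $-1.8$: the
rank statistic saturates and is blind to pathway-specific gains for the very
drugs the screen is meant to find. The continuous similarity statistic has
no such floor. The rank variant remains available
(`statistic = "rank"`).

A degenerate null (sd = 0, e.g. when the gene universe equals the pathway
set so every draw reproduces the observed layer) yields the conservative
sentinel $z = 0$, $p = 1$, with a flag. The empirical permutation p-value
$(1 + \#\{x_{\text{null}} \le x_{\text{obs}}\})/(n_{\text{perm}} + 1)$ is
reported alongside for diagnostics.

Downstream, `layer_contribution()` decomposes each hit's affinity to the
reference into per-layer percentages (the radar-plot decomposition),
`build_hit_network()` re-screens with each hit as reference and keeps edges
at $p < 0.05$, and `reciprocal_screen()` checks whether screens seeded at
different community members converge on the same hits.

## Perturbation signatures

When only raw expression is available, `signatures_for_panel()` computes the
perturbation layer. Per drug and gene, ordinary least squares of expression
on an intercept, the drug concentration (0 for controls), and one-hot
contrasts for cell line, batch and duration (reference level = first
lexicographic; aliased columns dropped and reported). The signature entry is
the standardized coefficient $\beta^* = \hat\beta / \mathrm{SE}(\hat\beta)$
of the concentration term — a t-like, scale-free quantity: rescaling a
gene's expression by a positive constant multiplies $\hat\beta$ and its SE
equally and leaves $\beta^*$ unchanged (asserted in the tests). Perfect fits
(SE = 0, detected at machine-level relative tolerance) are capped at
$\pm 10^6$ rather than propagating infinities. Concentration enters
untransformed by default; `log_concentration = TRUE` switches to
$\log_{10}(c + 1)$. A single concentration slope is fit per drug rather than
per-dose effects.

## The synthetic panel generator

`simulate_panel()` emulates the joint structure of a pharmacogenomic panel
with one planted drug community of size $m$ containing the designated
reference:

* **Sensitivity**: community drugs share a common factor,
  $x_i = \sqrt{\rho}\, z + \sqrt{1-\rho}\, e_i$ over cell lines; background
  drugs are independent standard normal.
* **Perturbation**: all coefficients are $N(0, \sigma^2)$; community drugs'
  pathway-gene columns are shifted by one shared template with entries of
  fixed magnitude $\delta\sigma$ and random signs, so the expected
  within-community pathway correlation is $\delta^2 / (\delta^2 + 1)$
  deterministically (a Gaussian-scaled template would make the community
  signal depend on the template draw).
* **Fingerprints**: community drugs share $c$ core on-bits, each lost
  independently with probability $q$, plus background bits; background drugs
  are uniformly random at the matched expected density, so shared structure
  — not bit count — separates the community.

Defaults are the study conditions used throughout the tests: 60 drugs,
community of 5, $\rho = 0.8$, $\delta = 3$, $q = 0.05$, $\sigma = 1$, 6
pathway genes among 300, 30 cell lines, 512-bit fingerprints with 64 core
bits at background density 0.1. The gene universe (300) is a deliberate
scale-down of a landmark-gene transcriptomic panel (~1000 genes): it leaves
the $k/n_{\text{genes}}$ ratio small, which is what the permutation null
cares about, at a fraction of the runtime. The generator is a pure function
of its spec and seed.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: realistic chemistry (bits are abstract, not hashed
substructures of real molecules), dose–response structure, missing-data
patterns of real screens, correlated gene–gene backgrounds (real pathway
genes co-vary even untreated), and multiple overlapping communities.

## Calibration and recovery, measured

Three properties are exercised end to end at the default study conditions
(n_perm = 199, which keeps a full calibration run in minutes; the screens
themselves default to 999):

* **Null calibration** — on pure-null panels ($\delta = 0$, $\rho = 0$, $q =
  0.5$), p-values pooled over 20 reference draws are approximately uniform;
  the fraction below 0.05 and the KS statistic are recomputed by
  `scripts/acceptance.R`. The normal approximation $p = \Phi(z)$ and the
  network-level coupling between drugs in one screen leave the pooled
  distribution slightly anticonservative; this is a property of the
  approximation, not of the permutation machinery.
* **Planted recovery** — at the strong-signal defaults, the community
  occupies the top ranks and recall of `select_hits()` against truth is
  high. Precision is structurally bounded: with 55 background drugs and the
  $z < -1.8$ rule, a perfectly calibrated screen still admits
  $\approx 55 \times \Phi(-1.8) \approx 2$ false hits per panel in
  expectation — chance 6-gene correlations are real correlations — so
  hit lists should be read as enriched candidate sets, exactly as
  prioritized hit lists are used in practice.
* **Reciprocity** — screens seeded at two different community members each
  recover the other among their hits.

## Numerical choices and degenerate inputs

* Pairwise-complete Pearson pairs with fewer than `min_overlap` (default 3)
  mutually defined features, or zero variance over the complete features,
  get similarity 0 — not `NA` — keeping the affinity kernel total.
* A drug missing an entire layer is dropped at assembly; assembly intersects
  the drug universes of the three layers and sorts lexicographically, so
  every downstream matrix has one deterministic index.
* Matrix I/O writes 17 significant digits; write-then-read round-trips are
  exact for doubles.
* All randomness funnels through explicit integer seeds; screens are
  bit-reproducible given `(seed, n_perm, inputs)`, and derived seeds (hit
  network, reciprocal screens) are small offsets of the configured seed.

## Known limitations

* The normal-approximation p-value is slightly anticonservative in the
  extreme tails; the empirical permutation p-value is reported for
  diagnostics but is resolution-limited at small `n_perm`.
* Fusion hyperparameters $K$, $t$, $\mu$ are conventional defaults, not
  tuned to any dataset; they are recorded in every manifest.
* The screen quantifies association with the reference, not mechanism; hits
  require orthogonal validation.
* Raw L1000-style binary formats are out of scope: users export labeled
  matrices first.
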