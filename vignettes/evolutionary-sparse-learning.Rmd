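---
title: "Evolutionary sparse learning with sparseclade: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary sparse learning with sparseclade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparseclade)
```

## The problem

Evolutionary sparse learning (ESL) asks which alignment positions and which
genomic loci carry the signal for a phylogenetic hypothesis — typically
membership in a focal clade. The hypothesis is a binary response over taxa
(+1 inside the clade, −1 outside); the predictors are the character states of
a multiple sequence alignment, one-hot encoded so that every (position,
residue) pair becomes a binary feature. A sparse group lasso logistic
regression then selects a small set of positions, grouped by locus, that
discriminate the two classes. Loci and positions with large aggregate
coefficient magnitude are the concentrated evidence for the clade; a clade
member whose predicted membership probability is low despite the model is a
candidate *fragile* placement worth scrutiny.

## The model

Writing $x_i$ for taxon $i$'s one-hot feature row, $y_i \in \{+1,-1\}$ for
its class, and $w_i$ for its sample weight (normalized to sum to 1), the
package minimizes

$$
L(\beta, c) \;=\; \sum_i w_i \,\log\!\big(1 + e^{-y_i (x_i^\top \beta + c)}\big)
\;+\; \lambda_1 \lVert \beta \rVert_1
\;+\; \lambda_2 \sum_{g=1}^{G} w_g \lVert \beta_g \rVert_2 ,
$$

where $\beta_g$ is the coefficient block of group (locus) $g$ and
$w_g = \sqrt{p_g}$ by default ($p_g$ = number of bit-columns in $g$; a
two-column weight file can override this). The $\lambda_1$ term drives
within-group sparsity at the level of individual bit-columns; the $\lambda_2$
term zeroes entire loci. The intercept $c$ is included and never penalized:
without it, class imbalance would bias every prediction, and with weighted
balancing the unpenalized optimum at $\beta = 0$ is exactly the weighted
class log-odds.

### Penalty scaling

Users give `lambda1` and `lambda2` on a $[0,1]$ scale. Internally each is
multiplied by a data-derived maximum computed at $\beta = 0$ with the
intercept at its null optimum $c^\* = \log(W_+/W_-)$:
$\lambda_1^{\max} = \max_j |\nabla_j \ell|$ (the smallest L1 penalty whose
solution is all-zero when $\lambda_2 = 0$) and
$\lambda_2^{\max} = \max_g \lVert \nabla_g \ell \rVert_2 / w_g$ (the smallest
group penalty zeroing every group when $\lambda_1 = 0$). The two maxima are
computed **independently** rather than jointly (i.e. $\lambda_2^{\max}$ is
not recomputed after soft-thresholding at the chosen $\lambda_1$). This was a
genuinely open design point; the independent convention was chosen because
under a joint convention $\beta = 0$ is never optimal for any
$\lambda_2 < \lambda_2^{\max}(\lambda_1)$ — the group attaining the maximum
always enters — so no setting short of the endpoint could return an empty
model, and "strong penalties select nothing on pure-noise data" would be
unattainable by construction. Under the independent convention both endpoint
identities hold exactly (`lambda1 = 1` gives $\beta = 0$; `lambda1 = 0,
lambda2 = 1` zeroes every group), and on noise-only simulations
$\lambda_1 = \lambda_2 = 0.5$ reliably selects zero groups. The cost is that
coefficient *values* (not selections) are not directly comparable with
implementations that scale jointly; `lambda1_abs`/`lambda2_abs` are recorded
on every model so any convention can be recovered.

## Encoding and filtering

Each FASTA file is one group; the file stem is the group name. At every
position, each distinct valid character observed among the selected taxa
becomes a bit-column; gap (`-`) and missing (`?`) characters never do.
Validity is set by `data_type_policy()`: `nucleotide` = A/T/C/G/U
case-insensitive, `protein` = the 20 unambiguous IUPAC amino acids
case-insensitive, `molecular` = their union, `default` = all letters
(case-sensitive) and digits, so presence/absence codes, methylation states
and other coded characters can be analyzed. Ambiguity codes (N, X, B, Z, J)
are missing data in the three molecular modes. Column order is groups in
input order, positions ascending, states in ASCII order, so feature indices
are reproducible; the canonical feature ID is `group|position|state`.

Three filters discard provably uninformative columns before fitting:

* **monomorphic** — every row with a valid state at the position carries
  this state. The test compares the column's carrier count against the
  position's valid-row count *recorded at encoding time*, not against the
  surviving column set; this makes filtering idempotent (removing a
  singleton A-column must not make the G-column of an (A,G,G,G) position
  look monomorphic on a second pass).
* **singleton** — exactly one carrier; such a column can only fit one taxon.
* **bit_ct** — fewer than `bit_ct` carriers, when a positive `bit_ct` is
  given; a pragmatic lever for very large matrices.

Counts are taken over the taxa actually fed to the solver, so balancing by
down-sampling changes what is filtered, and cross-validation re-derives the
filters inside each training fold (see below).

## Class balancing

`balance_classes()` offers four strategies. `up` duplicates randomly chosen
minority taxa until sizes match (duplication is literal: rows and weights are
repeated); `down` removes randomly chosen majority taxa; both are seeded and
bit-reproducible. `weighted` keeps every taxon and assigns weight
$1/(2 n_{\text{class}})$ so each class contributes total weight $1/2$ to the
loss. `phylo` is tree-aware: the −1 class is assembled from progressively
more distant sister clades of the focal clade (first cousins, then second
cousins, ...) until it is at least as large as the focal clade, after which
the taxon with the shortest terminal branch in the *larger* class is pruned
repeatedly until sizes match — retaining the most divergent outgroup taxa.
Ties on branch length are broken by postorder position, a deterministic rule
that needs no randomness. The scan stops as soon as the −1 count reaches the
+1 count (no pruning needed in that case), and pruning applies to whichever
class is larger, focal included — but the focal clade can only shrink after
the outside class has already overtaken it, never before.

## Solver

The objective is minimized by accelerated proximal gradient (FISTA). The
smooth logistic term contributes the gradient step; both penalties enter
through their closed-form proximal operator, evaluated per group as
soft-thresholding at $\lambda_1$ followed by group-norm shrinkage by
$\lambda_2 w_g$ (the group zeroes when its thresholded norm falls below that
level). Step sizes come from a halving backtracking line search, so no
Lipschitz constant is ever computed on the full matrix. When the accelerated
point overshoots — FISTA is not monotone — the step is retaken from the
previous iterate with momentum reset, which restores guaranteed descent; the
recorded objective history is non-increasing by construction.

Convergence is declared when the relative objective change drops below
`tol`. The default is `tol = 1e-9` with at most 2000 iterations: on the test
problems this leaves subgradient-optimality (KKT) residuals near $10^{-5}$,
whereas a looser $10^{-6}$ tolerance leaves residuals near $10^{-3}$, large
enough to perturb which features count as selected. Coefficients below
$10^{-10}$ in magnitude are zeroed on output so "number of selected
features" is exact rather than a thresholding artifact. Non-convergence is a
warning plus `converged = FALSE` on the model, never a silent success.

## Scores and predictions

Sparsity scores aggregate coefficient magnitudes:
$\mathrm{PSS}(\text{position}) = \sum |\beta|$ over the position's
bit-columns, $\mathrm{GSS}(g) = \sum \mathrm{PSS}$ over the group's
positions (reported raw and normalized by the maximum GSS), and
$\mathrm{HSS} = \sum_g \mathrm{GSS}(g) = \lVert\beta\rVert_1$. These additive
definitions are a documented compatibility assumption — other aggregation
conventions exist — and because the raw sums are always emitted alongside
the normalization, either convention is recoverable. Zero-score rows are
omitted from the tables.

Per taxon, $\mathrm{SPS} = x^\top\beta + c$ and
$\mathrm{SPP} = 1/(1+e^{-\mathrm{SPS}})$; classification is +1 iff
$\mathrm{SPS} > 0$, with the measure-zero tie at exactly 0 assigned to −1.
`drphylo_grid()` splits each taxon's SPS into per-group additive
contributions (row sums plus intercept reproduce SPS to machine precision),
which localizes the gene–species combinations responsible for a low SPP.

Cross-validation (`kfold_cv`) uses seeded stratified folds; each fold refits
from the *unfiltered* encoding of its training taxa, re-deriving the
monomorphic/singleton/`bit_ct` filters on training data only, so no
information about held-out taxa leaks through the feature-selection step.
Each class must have at least $k$ members; smaller focal clades are a hard
error rather than a silently unreliable estimate. The grid search iterates
$\lambda$ values ascending and, within each $\lambda_2$ row, skips the
remaining larger $\lambda_1$ cells once a model selects fewer than
`min_group_ct` groups — $\lambda_1$ dominates model size, and a stricter
penalty in the same row can only be sparser. Early stopping is deliberately
per-row, not global: other $\lambda_2$ rows may still contain useful models.

Saved models are versioned tab-separated text (nonzero coefficients keyed by
`group|position|state`, plus intercept, penalties, data type and per-group
alignment lengths), so they diff cleanly and can be applied to newly aligned
taxa: unseen states and gaps contribute 0, an all-gap taxon scores exactly
the intercept, and an alignment-length mismatch is an error.

## The synthetic-data generator

`make_fixture()` simulates the study conditions used throughout the test
suite: 16 taxa on a random rooted bifurcating tree, 5 genes of 50 sites, and
3 *planted* sites in gene `g3` that carry state A inside a focal clade
(chosen as the internal node closest to half the taxa) and C outside —
perfect diagnostics whose encoded bit-columns equal the class labels
exactly. Background sites draw an ancestral state uniformly from A/C/G/T,
substitute it per taxon with probability 0.3 (a realistic level of
clade-independent variation for moderately divergent sequences), and gap
characters appear with probability 0.02. Planted sites are deterministic and
never gapped, so encoder and solver tests have exact expectations; the
generator makes no attempt at model-based sequence evolution (no rate
heterogeneity, no correlated substitutions along the tree). Passing tests on
these fixtures therefore demonstrate correct mechanics and recoverability of
a clean signal — they do not certify power on real data, where diagnostic
sites are noisy, homoplasy correlates features with the tree, and missing
data is structured.

Problem sizes in the test suite and the acceptance workflow were chosen to
exercise every code path while keeping a full run in seconds-to-minutes on a
single core: 16-taxon fixtures (about 600 bit-columns after filtering),
20-replicate recovery and null-selection checks, and oracle comparisons
(numerical prox minimization, bisection for $\lambda_1^{\max}$, a
bound-constrained split-variable minimizer for the L1-only objective) on
instances of dimension 20–30.

## Known limitations

* Logistic loss only; continuous responses (least-squares loss) are out of
  scope, as are overlapping or tree-structured group penalties.
* Fractional penalties use the independent-scaling convention above;
  coefficient values are not directly comparable across conventions, though
  selections are stable in our experience.
* Polytomies are accepted as-is; in phylo balancing "sister" means all other
  children of the parent node. Unrooted trees are not rooted automatically.
* The dense in-memory sparse-matrix pipeline targets desk-scale problems
  (up to a few million bit-columns); no out-of-core path is provided.
* `default` data mode treats every letter and digit as a state; with
  free-form annotation characters this can create many columns — the
  `bit_ct` filter is the intended safety valve.
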