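---
title: "Denoising image-based spatial transcriptomics with per-cell Poisson mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Denoising image-based spatial transcriptomics with per-cell Poisson mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model and its assumptions

Image-based spatial transcriptomics assigns decoded transcript molecules to
segmented cells, and segmentation errors move molecules into the wrong
cells. `istclean` treats each segmented cell independently and asks, gene by
gene, whether the observed count is endogenous expression or contamination.

For cell $i$ and gene $j$, with observed count $x_{ij}$:

$$
x_{ij} \sim \begin{cases}
\mathrm{Poisson}(x^+_{ij} + \lambda^e_i) & Z_{ij} = 1 \\
\mathrm{Poisson}(x^+_{ij} + \lambda^c_i) & Z_{ij} = 0
\end{cases}
\qquad Z_{ij} \sim \mathrm{Bernoulli}(\pi_i),
$$

where $\pi_i$ is the proportion of panel genes the cell truly expresses,
$\lambda^e_i \ge \lambda^c_i$ are the cell's endogenous and contamination
rates, and $x^+_{ij}$ is the *contamination context*: the sum of gene $j$'s
counts over all cells with centroids within radius $d$ of cell $i$, plus a
global ambient term $x_{jb}$. The posterior
$\alpha_{ij} = P(Z_{ij}=1 \mid x_{ij})$ decides the filter: counts with
$\alpha_{ij} \le$ the cutoff are set to zero, all others are kept whole, so
the output stays integer.

Two strong assumptions are built in, and both matter for interpretation:

1. **All-or-nothing genes.** A gene in a cell is either entirely endogenous
   or entirely contamination. This is defensible for today's targeted
   panels, whose genes are mostly cell-type-specific markers, and it breaks
   down as panels approach the whole transcriptome.
2. **A single endogenous rate per cell.** All truly expressed genes in a
   cell share one Poisson mean. Real expression spans orders of magnitude;
   the assumption works because the endogenous/contamination gap is much
   larger than within-cell expression variation at the low dynamic range of
   current assays.

Both components carry the *same* offset $x^+_{ij}$, so the likelihood ratio
for a gene depends on how far its count stands out above its own local
context. A consequence worth knowing: in a neighbourhood dominated by cells
of the same type, a cell's program genes have $x_{ij} \approx$ a fraction of
$x^+_{ij}$ and carry little residual signal, so the mixture degenerates
toward $\lambda^e = \lambda^c$ and the posterior collapses to $\pi_i$. The
method is therefore most informative where local neighbourhoods are
heterogeneous; sparse same-type tissue is a documented limitation, not a
bug, and sharing information across cells of a type is deliberately out of
scope here.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `radius_um` | 50 | µm | neighbourhood radius $d$; distance-based rather than k-nearest so that denser tissue gets larger contexts |
| `n_hexbins` | 200 | bins | target hexagon count for ambient estimation |
| `alpha_cutoff` | 0.75 | — | posterior filter threshold; the boundary $\alpha = 0.75$ is filtered (inclusive) |
| `n_restarts` | 10 | — | EM restarts, $\pi_0 \sim \mathrm{Unif}(0, 0.5)$ — a cell is unlikely to express more than half of a targeted panel |
| `offset_mode` | `"additive"` | — | component mean $x^+ + \lambda$; see below |
| `min_nonzero_genes` | 3 | genes | skip rule: a 3-parameter mixture on fewer than 3 informative observations is unidentifiable, so such cells pass through unchanged and are flagged |
| `seed` | 0 | — | master seed; every cell gets its own stream derived from (seed, cell index) |

**Offset mode.** The component mean could plausibly be additive
($x^+ + \lambda$) or multiplicative ($x^+ \cdot \lambda$, reading
$\lambda^c$ as a spillover *fraction* that is 0 in clean data). The additive
form is the default and is what the posterior, the M-step and all tests
target; the multiplicative form is implemented behind
`offset_mode = "multiplicative"` (its M-step has the closed form
$\lambda = \sum w x / \sum w x^+$) for users who want the
proportional-contamination reading. The two agree on which genes stand out;
they differ in how strongly a large context penalises moderate counts.

## Global ambient background

Transcript molecules (cell-assigned or not) are binned into flat-top regular
hexagons anchored at the bounding-box minimum corner. The circumradius is
$r = \sqrt{2\,\mathrm{area}/(3\sqrt3\,n)}$ so that the hexagon area
$A = \tfrac{3\sqrt3}{2} r^2$ times the target bin count matches the bounding
box; molecules are assigned by cube-rounding in axial hex coordinates, which
is exact nearest-centre assignment. Bins whose centre falls in the bounding
box are part of the grid even when empty — empty bins are evidence of
background.

Per-bin totals $C_k$ are modelled as a two-component univariate Gaussian
mixture fitted by EM: initialisation splits the bins at the median total and
takes moments of each half (deterministic, so the fit needs no seed);
variances are floored at $10^{-6}\,\mathrm{var}(C)$ with a warning if the
floor binds; convergence is a relative log-likelihood change below
$10^{-8}$, capped at 500 iterations. Each bin is hard-assigned to the
component with the larger posterior responsibility, and the lower-mean
component is background. The per-gene ambient level is the mean count over
background bins scaled from bin area to neighbourhood-disc area,
$x_{jb} = (\pi d^2 / A)\cdot\overline{x}_{jB}$ — when $A = \pi d^2$ the
scale factor is exactly 1, a property the tests exploit.

When no transcript table is supplied the global term is zero (with a
warning): cell-assigned counts alone cannot populate extracellular bins
faithfully. The estimator also degenerates on data with *no* ambient signal
at all — its "background" component is then forced onto the dimmest tissue
bins — so for contamination-free data the background should simply stay
off. No transcript quality filter is applied by default (an optional
quality column/threshold is exposed in the reader).

## EM numerics

- **Rate floor** $\lambda \ge 10^{-6}$: a zero-mean Poisson would force
  $\alpha \in \{0, 1\}$ pathologically for any positive count.
- **Mixing clamp** $\pi \in [10^{-4}, 1-10^{-4}]$ keeps both components
  alive.
- **Initialisation from $\pi_0$** (the model is silent on rates): genes are
  ranked by residual $x_j - x^+_j$; the top $\lceil \pi_0 G \rceil$ genes
  seed $\lambda^e$ as their mean residual (at least 1), the rest seed
  $\lambda^c$ (at least the floor).
- **M-step**: $\pi$ is the clamped mean responsibility; each rate solves
  the weighted score $\sum_j w_j\,(x_j/(x^+_j+\lambda) - 1) = 0$, which is
  strictly decreasing and convex in $\lambda$, by safeguarded Newton on
  $[\lambda_{\min}, \max_j x_j + 1]$ (bracketed bisection fallback). With
  constant offsets this reproduces the closed form
  $\sum w x/\sum w - c$, which the tests verify, along with a
  grid-search check that the root maximises the expected complete-data
  log-likelihood.
- **Identifiability**: after each M-step components are re-ordered so
  $\lambda^e \ge \lambda^c$, flipping $\alpha$ and $\pi$ with them; the
  mixture likelihood is invariant under the swap.
- **Convergence**: relative log-likelihood change below $10^{-6}$, at most
  200 iterations per restart; the restart with the highest final
  log-likelihood is reported, with per-restart diagnostics in the fit
  object. Within every restart the log-likelihood trace is non-decreasing
  (asserted in tests).
- Zero-count genes stay in the likelihood — they carry information about
  $\pi$ and $\lambda^c$ — and are unaffected by the filter.
- The per-cell hot loop is compiled (Rcpp); all random draws happen in R
  from per-cell streams derived from the master seed and the cell index, so
  results are reproducible and independent of the order in which cells are
  processed. Re-running `denoise` on its own output is *not* a no-op in
  general (zeroing counts changes every neighbour's context); idempotence
  is not claimed.

## Evaluation statistics

**MECR** for a pair $(g_1, g_2)$ is
$\#\{x_{g_1}>0 \wedge x_{g_2}>0\} / \#\{x_{g_1}>0 \vee x_{g_2}>0\}$.
Real-valued inputs (from tools returning weighted counts) are rounded
half-up first, so $x \ge 0.5$ counts as positive. A pair expressed nowhere
is 0/0 and reported as `NA` with a warning rather than invented.

**PMP** for cell $i$ with marker set $M$ is
$\sum_{m \in M} x_{im} / \sum_j x_{ij}$; the summary takes within-type means
first and then averages across types, so rare types weigh equally.
Zero-total cells are excluded from means with a warning.

**Marker/pair derivation** from a labelled reference: per gene and type, the
mean over other types of the pairwise mid-rank two-sample AUC, the in-type
detection rate and the pooled out-of-type detection rate. The detection
filters (≥ 50 % in type, ≤ 5 % outside) are applied first and the top-30 %
AUC quantile (ceiling, descending, index tie-break) is taken within the
surviving pool — a quantile over an already-specific pool is stabler than
one over the whole panel. Pairs are all cross-type combinations of the
surviving genes, unordered and de-duplicated. Cell-type labels are accepted
as input (synthetic truth or user annotations); label transfer from a
reference is out of scope.

## The synthetic generator

`simulate_dataset()` plants full ground truth: endogenous counts are
Poisson($\lambda_{\mathrm{true}}$) on each cell's disjoint type program;
spillover duplicates each within-radius neighbour's realised endogenous
counts into the cell by binomial thinning at `spill_rate` (thinning realised
counts, not rates, keeps the bookkeeping exact); ambient counts are Poisson
at `ambient_rate` everywhere. Molecules are placed uniformly in a 10 µm disc
around the owning cell, with extracellular ambient molecules (expected count
`ambient_rate`·G·N) scattered uniformly over the extent — placement only
feeds the hexbinning, so this is a free design choice.

The default layout is *interleaved pairs*: cross-type cell pairs (25 µm
separation) on a jittered grid confined to a central tissue block covering
half the 7,000 µm extent. This was chosen a priori from the model's score
equations: the mixture identifies contamination from the residual between a
cell's counts and its context, so the planted truth is recoverable exactly
when neighbourhoods are cross-type dominated, and the surrounding cell-free
area gives the background estimator genuine ambient-only bins. A
`"uniform"` layout (uniform positions, random types) is available for
stress-testing the mis-specified regime. Default rates — expression mean 10,
spillover 0.15, ambient 0.02 per cell per gene, radius 50 µm, 2 types × 50
program genes + 20 unexpressed panel genes in 2,000 cells — describe a
moderately contaminated targeted-panel assay.

What the generator does *not* emulate: cell morphology and segmentation
polygons (spillover is distance-triggered, not boundary-driven), gene-level
expression heterogeneity within a program, z-axis effects, and
between-sample batch structure. Passing tests therefore demonstrate
correctness of the inference machinery under the model's own generative
assumptions, not performance on any particular real assay.

## Problem sizes used in the checks

The test suite fits single cells with 100–300 genes, runs the full pipeline
on simulations of 30–2,000 cells, and compares against independent oracles:
a closed-form textbook Poisson-mixture EM and a $10^4$-point grid-search MLE
(agreement within $10^{-6}$ log-likelihood at zero offsets), an exhaustive
bipartition oracle for the background mixture, and brute-force triple-loop
offsets. `scripts/acceptance.R` averages three full 2,000-cell denoising
runs and a 500-cell × 300-gene parameter-recovery study; these sizes give
stable estimates (ground-truth entry counts near $1.8\times10^5$ per run)
at desk-scale runtime.

## Known limitations

- Same-type-dominated neighbourhoods carry little identifying signal (see
  above); healthy sparse tissue of one type is the hardest case, and
  differential adjustment across samples could itself introduce batch
  effects in multi-sample studies.
- Per-cell independent fitting scales linearly in cells but repeats work
  that could be shared within cell types.
- The all-or-nothing and shared-rate assumptions limit applicability to
  large (whole-transcriptome) panels.
- Transcript-level (sub-gene) reassignment and non-integer corrected counts
  are non-goals by design.
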