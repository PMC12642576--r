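# istclean

Per-cell Poisson mixture denoising for image-based spatial transcriptomics
(IST) count matrices.

## The problem

Optical in-situ assays (10x Xenium, Vizgen MERSCOPE, NanoString CosMx)
localise individual transcript molecules in tissue and assign them to
segmented cells. Cell segmentation in 2D projections of 3D tissue is
imperfect, so transcripts routinely end up in the wrong cell — either
spilling over from a neighbour or as diffuse ambient signal. The result is
biologically implausible expression profiles: mutually exclusive lineage
markers co-expressed in one cell, spurious "hybrid" cell types, and
contamination levels that confound between-sample comparisons.

`istclean` removes this contamination at the (cell, gene) level while
keeping counts integer-valued: each gene's count in each cell is either
kept whole or set to zero.

## The model

For cell *i* with gene counts *x<sub>ij</sub>*, a two-component Poisson
mixture with a contamination offset:

```
x_ij ~ Poisson(x+_ij + lambda_e_i)   if Z_ij = 1   (endogenous)
x_ij ~ Poisson(x+_ij + lambda_c_i)   if Z_ij = 0   (contaminated)
Z_ij ~ Bernoulli(pi_i)
```

The offset *x⁺<sub>ij</sub>* is the **local context** — gene *j*'s counts
summed over all cells whose centroids lie within *d* = 50 µm of cell *i* —
plus a **global ambient** term *x<sub>jb</sub>* estimated by binning the
transcript molecules into ~200 hexagons, separating low-count background
bins from tissue bins with a two-component Gaussian mixture, and scaling
the mean background expression from the hexagon area *A* to the
neighbourhood disc: *x<sub>jb</sub> = (πd²/A) · mean over background
bins*.

Each cell's three parameters (π<sub>i</sub>, λ<sup>e</sup><sub>i</sub>,
λ<sup>c</sup><sub>i</sub>) are estimated by EM with 10 random restarts
(π₀ ~ Unif(0, 0.5); best final log-likelihood wins). The posterior
probability α<sub>ij</sub> = P(Z<sub>ij</sub> = 1 | x<sub>ij</sub>) then
drives the filter: counts with α<sub>ij</sub> ≤ 0.75 are zeroed.

A gene count is therefore kept when it is high *relative to its own
neighbourhood* — 25 transcripts mean little if the surroundings are
flooded with the same species, while 2 transcripts matter if they are the
only ones nearby.

The package also implements the matching evaluation statistics:

- **MECR** (mutually exclusive co-expression rate): for a gene pair known
  to be mutually exclusive, the fraction of cells expressing both among
  cells expressing either — a false-positive proxy.
- **PMP** (positive marker purity): the fraction of a cell's counts
  falling in its cell type's marker set — a true-positive proxy, averaged
  within cell types first.
- Reference-based derivation of type-specific genes and exclusive pairs
  (mean pairwise AUC, in-type detection ≥ 50 %, out-of-type detection
  ≤ 5 %, top 30 % by AUC).

A synthetic tissue generator with planted per-entry ground truth
(endogenous / contaminated) makes the whole pipeline testable without any
external download.

## Worked example

```r
library(istclean)

sim <- simulate_dataset(sim_config(n_cells = 400, seed = 1))
sim
#> <synthetic_dataset> 400 cells x 120 genes, 232758 molecules (949 extracellular), 2 types, seed 1

res <- denoise(sim$counts, sim$cells, sim$transcripts, seed = 1)
res
#> <denoise_result> 400 cells x 120 genes; 0 skipped; counts 231809 -> 196043 (15.4% removed)

evaluate_against_truth(res, sim)
#> <truth_eval> sensitivity 0.955, specificity 1.000
#>   MECR 0.7780 -> 0.0000; mean PMP 0.8678 -> 1.0000
```

15 % of the counts are removed; against the planted truth, 95.5 % of truly
endogenous entries survive and essentially all spillover/ambient entries
are gone. Cross-type co-expression of the planted mutually exclusive
program genes (MECR 0.78 in the raw counts — every cell sits next to an
opposite-type cell in this simulation) collapses to 0, while marker purity
rises from 0.87 to 1.0. `tidy(res)` returns the per-cell fit table
(π̂, λ̂ᵉ, λ̂ᶜ, log-likelihood, convergence); `autoplot(res)` maps the kept
fraction in space.

The same pipeline is available from the shell:

```sh
Rscript inst/cli/istclean simulate --out sim/ --seed 1
Rscript inst/cli/istclean run --counts sim/counts.mtx --cells sim/cells.tsv \
    --transcripts sim/transcripts.csv --out denoised/
Rscript inst/cli/istclean markers derive --ref ref/counts.mtx \
    --labels ref/labels.tsv --out markers/
Rscript inst/cli/istclean metrics mecr --counts denoised/adjusted.mtx \
    --pairs markers/pairs.tsv --out mecr.tsv
```

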