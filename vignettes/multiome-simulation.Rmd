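---
title: "Simulating coupled single-cell multi-omics data with full ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating coupled single-cell multi-omics data with full ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multiomeSim)
```

## The model

multiomeSim generates coupled single-cell datasets — true and observed
scRNA-seq, scATAC-seq, spliced/unspliced counts with RNA velocity, and
spatially placed cells with ligand–receptor signaling — from a single
latent model, and exports every generative ground truth so that
downstream inference methods can be benchmarked against what is actually
in the data.

The backbone is a factor model. Every cell carries a **cell identity
factor** (CIF) vector per kinetic parameter, laid out in four segments:

* **non-diff**: i.i.d. Gaussian(1, $\sigma_{cif}$) heterogeneity shared
  by all cells regardless of state;
* **diff**: the cell's position on a user-supplied differentiation tree,
  encoded by a Brownian walk along the tree;
* **tf**: the (normalized) expression of the transcription factors in the
  preceding cell, which is how a gene regulatory network (GRN) feeds
  back into expression;
* **lig**: the normalized ligand expression of spatially neighboring
  cells, which is how cell–cell interactions (CCIs) enter.

Each gene has a matching **gene identity vector** (GIV) weighting those
factors. The product CIF × GIV gives a cell × gene surface for each of
the three kinetic parameters of the classic two-state promoter model —
activation rate $k_{on}$, deactivation rate $k_{off}$, synthesis rate
$s$ (degradation $d$ is fixed at 1). Surfaces are carried to realistic
scales by **rank-based scaling**: the values are replaced by an ordered
sample from a reference distribution, preserving ranks exactly. True
counts are then drawn by the Beta–Poisson equivalent of the promoter
model,

$$y \sim \mathrm{Beta}(k_{on}, k_{off}), \qquad
  x \sim \mathrm{Poisson}(y\,s),$$

interpolated toward the noiseless mean $s\,k_{on}/(k_{on}+k_{off})$ by
the intrinsic-noise weight $\sigma_i$.

Chromatin accessibility is generated *first*, from the $k_{on}$ CIF and
a **region identity vector** matrix, rank-scaled to an accessibility
reference; each gene is controlled by 1–3 consecutive abstract regions.
Accessibility then gates expression: the ATAC-effect weight $E_a$ blends
the accessibility of a gene's regions into the rank source of $k_{on}$,
which is what couples the two modalities. The TF-motif-by-region and
region-by-gene maps factorize the GRN (`support(Mtr %*% Mrg)` covers
`support(Mtg)`), mirroring how GRNs are assembled from multiome data in
practice.

## Trees, populations and pseudotime

The minimal input is a rooted differentiation tree (Newick text or the
built-ins `Phyla1`/`Phyla3`/`Phyla5` with 1/3/5 leaves; the stock
topologies are balanced with unit branch lengths and are stand-ins, as
only their leaf counts are fixed by convention). In **continuous** mode
cells are spread over root-to-leaf lineages proportionally to lineage
length at stratified-uniform positions; each diff-CIF coordinate is a
Brownian motion over the tree whose scale is the tree distance itself:
per-step increments are $\mathcal N(0, \Delta d)$, so the variance at
path distance $D$ is $D$, and cells sharing a branch share the walk up
to their divergence. Two aspects of this scaling are deliberate. The
$\sqrt{\Delta d}$ step size (true Brownian motion) makes the accumulated
variance depend on tree distance rather than on how finely the path is
discretized by cell positions. And $\sigma_{cif}$ does not enter the
walk: it scales the non-diff heterogeneity against this fixed-scale
signal, so a larger $\sigma_{cif}$ yields noisier, looser structures.
Were the walk itself scaled by $\sigma_{cif}$, the trajectory signal at
$\sigma_{cif} = 0.1$ would be an order of magnitude smaller than the
between-gene spread, per-gene expression would be dominated by promoter
sampling noise, and the regulatory signatures the simulator exists to
produce (TF-target correlation, gene-module structure, the
neighbor-interaction correlation) would vanish.

In **discrete** mode only the leaves are used. Each leaf type receives a
mean vector from the same unit-rate walk evaluated at the leaves, and
cells scatter around it with sd $\sigma_{cif}$ — the within-type spread
follows $\sigma_{cif}$ while the separation is set by branch lengths, so
smaller $\sigma_{cif}$ gives crisper clusters. A consequence worth
knowing: with the stock unit-branch trees, clusters remain linearly
separable even at $\sigma_{cif} = 0.5$, so cluster-recovery ARI
saturates at 1 for both 0.1 and 0.5; the $\sigma_{cif}$ effect shows in
cluster tightness rather than in ARI at these sizes.

## GRN feedback in two sweeps

The GRN enters twice: the effect matrix sits in the tf segment of the
$s$-GIV (regulation raises synthesis), and the diff segment of regulated
genes inherits their regulators' identity (each TF gene gets two fixed
small entries, 0.2 by default; targets get the TF-block product with
their effect-matrix column; TF-and-target genes average the two).

The feedback chain — cell $t$'s TF expression entering cell $t+1$'s
factors — cannot be resolved strictly online, because rank scaling is a
global operation over the whole matrix. The package therefore runs two
sweeps: sweep one draws tf factors from the identity-factor Gaussian and
realizes expression; sweep two rebuilds each cell's tf factors from the
sweep-one expression of its predecessor *on its own lineage* (chaining
across lineages would pair unrelated branches), re-derives the
parameters, and resamples. The spatial simulator, which is stepwise
anyway, instead updates the chain every step.

## Spatial simulation and cell–cell interactions

Cells live on a $k \times k$ grid sized to hold 250% of the cell count
by default. At each step a new cell is born and placed — with
probability $p_n$ next to a same-type cell ("default" layout; "layers"
and "islands" pre-layouts are available, with 5% of positions
re-randomized for noise) — and every live cell advances along a random
root-to-leaf path by (tree depth)/$n_{cell}$ per step, so the final
snapshot contains all developmental stages. Neighborhoods are the up to
4 cardinally adjacent cells (radius adjustable). Interactions are
sampled per cell-type pair from the ligand–receptor database (3 to $m$
rows per pair, same-type pairs excluded by default), and the single-cell
truth keeps a uniform 80% of the implied neighbor edges. A cell's lig
segment holds, per neighbor slot and database row, the sender's
normalized ligand expression masked by that truth; the matching lig-GIV
entries carry the interaction effects into the receptor's synthesis
rate. Types used for placement affinity and truth sampling are the
snapshot (final-step) types, and a cell keeps one diff-CIF — drawn at
its final tree position — throughout, so the trajectory survives into
the output; intermediate steps exist to propagate the TF and ligand
chains, with `tc = 10` settling steps after the last birth.

Ligand–receptor effects default to 3, the midpoint of the 1–5 range used
for GRN effects, so a single interaction is comparable to an average
regulatory edge.

## Velocity, noise, batches

With `velocity = TRUE` the full kinetic model is stepped instead of the
Beta–Poisson shortcut: per cell and gene, the simulated span is
$L = \eta_L (1/k_{on} + 1/k_{off})$ split into $m = L / \min(1/k_{on},
1/k_{off})$ steps (capped at 100 for numerical thrift), switching
probabilities $p_{on} = k_{on} L/m$, $p_{off} = k_{off} L/m$ — the only
reading that keeps both in $[0,1]$ — and Euler updates for spliced and
unspliced counts, which stay real-valued during stepping and are rounded
only at output. A cell starts from its lineage predecessor's state; the
first cell of a lineage starts at the steady state
$x_s = s\,k_{on}\beta/(k_{on}+k_{off})$,
$x_u = s\,k_{on}d/(k_{on}+k_{off})$, whose velocity
$v = \beta x_u - d x_s$ is identically zero. (That initial state is
taken exactly as conventionally printed even though it is not the ODE
fixed point of the update rules — it is the unique state satisfying the
zero-initial-velocity identity, which benchmarks rely on.) Per-gene
$\beta, d \sim \mathcal N(1, 0.1)$ truncated at 0.1. Velocity smoothing
uses a Gaussian-kernel kNN average with $k = n_{cell}/50$ in the top-10
principal directions of the true counts, then per-cell norm
normalization. The cycle-length factor defaults to $\eta_L = 0.2$: the
ground-truth velocity is informative exactly when cells are still in
transit toward their own steady state, and a full cycle per cell
($\eta_L = 1$) lets them equilibrate, collapsing velocity into
steady-state noise with no net direction along the trajectory.

Observed RNA counts are produced molecule-by-molecule: binomial capture
at per-cell efficiency $\alpha \sim \mathcal N(0.1, 0.02)$, 8
amplification rounds with per-round success 0.7, multinomial allocation
of a per-cell depth $\sim \mathcal N(10^5, 3000)$ over amplicons, and
UMI collapse or (default) non-UMI read counting. Batch effects multiply
counts by $e^{shift}$ with $shift \sim \mathrm{Unif}(\mu_j - e_b,
\mu_j + e_b)$, $\mu_j \sim \mathcal N(0,1)$ per gene. ATAC observation
keeps each entry with probability 0.3 by default.

## Reference distributions

Rank scaling needs reference samples. The bundled kinetic references are
parametric log-normals ($\log_{10} k_{on}, \log_{10} k_{off} \sim
\mathcal N(-0.3, 0.6)$; $\log_{10} s \sim \mathcal N(1.2, 0.4)$; $10^4$
draws at a fixed fixture seed); the bundled ATAC reference is a
zero-inflated exponential (zero mass 0.7, rate set by `atac_density`).
These are stand-ins chosen to give count distributions with realistic
sparsity and dynamic range; any empirical sample can be substituted via
single-column text files (`read_reference_file()`), which is the route
for matching a specific real dataset. The bundled 100-gene GRN
(`grn_100()`) is likewise a seeded synthetic network — 9 TF modules over
100 genes, effects uniform on [1, 5] — reproducing the shape of the
classic benchmark network, not its edges.

## What the generator does and does not emulate

Passing tests on these synthetic data show that the *mechanisms* are
wired correctly — tree structure appears in both modalities, regulation
and signaling leave the intended correlation signatures, noise behaves
as constructed. They do not show that any particular real dataset is
matched: real data have empirical kinetic distributions, non-convex
cluster shapes, batch structure beyond multiplicative shifts, and
fragment-level ATAC noise, none of which are claimed here. The
summary-statistic helpers (`summary_stats()`) exist precisely to compare
a simulation against a real count matrix when that is the question.

## Numerical and design choices

* `n_diff = round(rd * ncif)`; the diff-to-nondiff ratio `rd` defaults
  to 0.8 so population structure dominates by default.
* The TF/ligand normalization $x_i/(x_i + \bar x)$ returns 0 for
  all-zero expression (zero expression exerts zero regulation) and is
  bounded in $[0, 1)$.
* Zero entries of the accessibility-by-region-map product are replaced
  by the raw surface values rescaled below the smallest nonzero entry
  (globally), so closed chromatin still ranks below open chromatin
  without collapsing ties.
* The bimodality factor divides both switching rates by $10^B$, making
  $B$ dimensionless with $B = 0$ the identity.
* Rank scaling breaks ties by position deterministically; reference
  draws are with replacement, so exact zeros in a reference reappear as
  exact zeros.
* Every stage draws from a child RNG stream derived from the single
  global seed (`derive_seed(seed, key)`), so enabling velocity or noise
  never perturbs the expression stage — two runs with the same seed are
  byte-identical, and the config echo written by `write_bundle()`
  reproduces the run.
* Problem sizes in the test suite follow the study conditions the
  quantities are defined at (e.g. 500 cells × 200 genes for the
  coupling readout, 500 × 500 for the spatial correlation run), with
  Monte-Carlo sizes chosen so the assertion tolerances are several
  standard errors wide.

## A worked example

```{r example, eval = FALSE}
grn <- grn_100()
cfg <- sim_config(ncell = 500, ngene = 200, tree = "Phyla5",
                  mode = "continuous", grn = load_grn(grn$edges, 200),
                  ea = 0.5, seed = 1)
res <- sim_true_counts(cfg)
atac_rna_coupling(res)$mean_cor   # expression-accessibility coupling
obs <- add_rna_technical_noise(res$counts, noise_config())
write_bundle(res, "bundle_out", observed = list(counts = obs))
```

## Known limitations

* Regions are abstract indices: no genomic coordinates, peak widths or
  fragment model.
* Cells do not move after placement; the grid is square with hard
  capacity.
* The cluster-separation scale is set by tree branch lengths; with the
  stock unit-branch trees, cluster-recovery ARI saturates well before
  $\sigma_{cif}$ reaches 0.5 (see above).
* The impulse-model alternative for trajectory factors and estimation of
  kinetic references from real data (an MCMC problem) are out of scope.
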