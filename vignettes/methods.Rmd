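---
title: "Methods: blind super-resolution and 3D reconstruction of single-cell Hi-C maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: blind super-resolution and 3D reconstruction of single-cell Hi-C maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Single-cell Hi-C assays measure pairwise chromatin contacts in one cell at a
time. The resulting contact matrices are extremely sparse and noisy: most
locus pairs have zero observed contacts, and the counts that are observed
are small. Two tasks dominate downstream analysis: (i) *enhancement* —
recovering a plausible high-coverage contact map from a low-coverage
observation, and (ii) *3D reconstruction* — inferring a three-dimensional
chromosome conformation whose pairwise distances explain the contact
frequencies. `schicsr` implements both, plus the evaluation metrics used to
judge them and a synthetic-data generator that makes the whole pipeline
testable at desk scale.

# Enhancement as blind super-resolution

## Degradation model

The observed low-coverage map $L$ is modeled as a degraded high-coverage
map $H$:

$$L = T(H) + E,$$

where $T$ is an unknown *degradation operator* and $E$ absorbs noise. In
sequencing terms the dominant degradation is read-depth loss — each contact
is retained with some probability — so $T$ is parameterized as a small
learnable convolution kernel (local blur/redistribution of counts) times a
learnable positive scale (the effective read retention). $T$ preserves
matrix dimensions: degradation here is depth loss, not spatial shrinkage.
Crucially, the retention is *not assumed known*: unlike enhancement methods
trained at a fixed downsampling ratio, the operator is estimated jointly
with the restored map ("blind" super-resolution), via the objective

$$J(H, T) = \lVert L - T(H)\rVert^2 + \beta\, P(H),$$

with $P$ a sparsity (`mean |H|`) or total-variation prior and $\beta \ge 0$
its weight. Norms are mean-squared, so $\beta$ does not scale with matrix
size (`degradation_objective()`).

## The alternating network

Joint minimization over $(H, T)$ alternates two sub-problems:

* **Estimator** — update the kernel given the current restored map:
  $T^{(k+1)} = \arg\min_T \lVert L - T(H^{(k)})\rVert^2$;
* **Restorer** — update the restored map given the kernel:
  $H^{(k+1)} = \arg\min_H \lVert L - T^{(k)}(H)\rVert^2 + \beta P(H)$.

`alternating_network()` unrolls $N$ rounds of this loop (default $N = 5$,
following the ablation study of the deep alternating design this
architecture adopts) into a compact differentiable network:

* a *degradation head* extracts convolutional features from the normalized
  input map;
* the *estimator* is a small MLP mapping summary statistics of $(L, H^{(k)})$
  — mean, spread, sparsity, and the depth ratio
  $\mathrm{mean}(L)/\mathrm{mean}(H^{(k)})$ — to a kernel representation: a
  $3\times 3$ kernel (identity plus a learned perturbation) and a softplus
  scale. The depth ratio is the statistic that identifies the retention, and
  after training the estimated scale correlates strongly with the true
  per-sample retention (this is tested);
* the *restorer* combines a learned residual convolution path with a
  gradient step on $\lVert L - T(H)\rVert^2$ under the currently estimated
  kernel (a Landweber-type update) — i.e. it literally descends the
  restorer sub-problem's data term — followed by a non-negativity clamp;
* the *image tail* applies a final learned residual refinement; the
  *degradation tail* maps the restored map back through the estimated
  kernel for consistency checking.

The whole network has only a few hundred parameters. Forward and reverse
passes are written directly in R (same-shape zero-padded convolutions built
from matrix shifts); the reverse pass is verified against central finite
differences to ~1e-6 relative error in the test suite. With patches of
40×40 bins, CPU training takes seconds to minutes — no GPU framework is
needed or used.

## Training loss

`train_enhancer()` minimizes, over high/low-coverage pairs,

$$w_r\,\lvert \hat H - H\rvert \;+\; w_k\,\lvert T_{dm}(H) - L\rvert
\;+\; w_c\,\lVert L - T_{est}(\hat H)\rVert^2 \;+\; \beta\,P(\hat H),$$

where $T_{dm}$ is the standalone degradation operator (trained to map true
high-coverage maps to their observed low-coverage counterparts) and
$T_{est}$ is the network's own kernel estimate applied through the
degradation tail. The first two terms use L1 (robust to count outliers;
an L2 variant is available). The third term is the blind-SR objective's
data term evaluated at the network's estimate: without it the estimator's
kernel receives no signal tying it to the observed map once restoration
dominates, and degradation consistency drifts during training. It lives on
a much smaller numeric scale than the restoration error, hence its large
default weight (`consistency_weight = 20`). Optimization is Adam with an
exponential learning-rate schedule decaying to 1% of the initial rate,
which stabilizes the late training trajectory. One master seed drives
weight initialization, batch shuffling and thinning draws; two runs with
the same config are bit-identical on one platform.

Enhancement of a full map (`enhance_map()`) tiles it into patches
(raster-order anchors, final anchors pulled back so every bin is covered),
restores each patch, reassembles with overlap averaging, symmetrizes and
clamps at zero.

# 3D reconstruction by maximum likelihood

## Wish distances

Contact frequencies are converted to target ("wish") distances by the
reciprocal power law

$$X_{ij} = \mathrm{IF}_{ij}^{-\alpha},$$

the convention of the maximum-likelihood reconstruction family this module
follows. Pairs with zero observed frequency carry no distance information
at single-cell depth and are excluded; $n$ below counts included pairs
only.

## Objective

A candidate structure $S$ (one 3D point per bin) is scored by

$$\mathcal{L}(S) = -\frac{n}{2} - n \log\left(\frac{1}{n}
\sum_{i=1}^{n}\left(X_i^s - X_i\right)^2\right),$$

where $X_i^s$ is the model distance of pair $i$. The mean squared deviation
is floored at `mse_floor` (default 1e-12) because the objective is
otherwise unbounded above at a perfect fit; at or below the floor the
likelihood is flat and the gradient is zero. The analytic gradient is
implemented in closed form and is validated against central finite
differences (max relative error < 1e-5 over random instances). The
likelihood depends only on pairwise distances, so it is invariant under
rigid motions and reflections — reconstructed structures are defined up to
a rigid transform and chirality, which is why structure comparisons
superpose first (and allow reflections by default).

## Optimization

`optimize_structure()` initializes coordinates uniformly in a cube scaled
to twice the mean wish distance (seeded) and ascends the likelihood with a
normalized gradient step and a backtracking rule: accepted steps (higher
likelihood) grow the step size by 1.2×, rejected steps halve it.
Convergence is declared after five consecutive accepted steps with
relative improvement below `tol` (default 1e-7), or `max_iters` proposals.
The accepted likelihood sequence is non-decreasing by construction.

## Estimating the conversion exponent

$\alpha$ is selected from a grid (default 0.1–2.0 in steps of 0.1) by
running a reduced-budget reconstruction per grid point (shared seed, so
runs differ only through $\alpha$) and scoring the Pearson correlation
between reconstructed and wish distances. Correlation rather than raw
likelihood is used because wish-distance *scales* differ across $\alpha$,
making likelihoods incomparable; ties break toward the smaller $\alpha$.
On noiseless synthetic data the true exponent is recovered exactly for
$\alpha_{true} \in \{0.5, 1.0, 1.5\}$.

## Ensembles

`build_ensemble()` repeats the reconstruction (default 20 members) from
distinct derived seeds at the chosen $\alpha$. Mutual consistency is
quantified by the minimum pairwise TM-score; a representative member is
selected either by best likelihood or as the TM-score medoid — both
selectors are exposed because the choice is not canonical.

# Evaluation metrics

* **PSNR** (dB): $10\log_{10}(\mathrm{MAX}^2/\mathrm{MSE})$; `MAX` defaults
  to the maximum over both matrices, and identical matrices return a
  documented 99 dB sentinel flagged `capped`.
* **SSIM**: windowed form of
  $\frac{(2\bar p\bar q + D_1)(2\delta_{pq} + D_2)}
  {(\bar p^2 + \bar q^2 + D_1)(\delta_p^2 + \delta_q^2 + D_2)}$
  with $D_1 = (0.01 M)^2$, $D_2 = (0.03 M)^2$; default 7×7 uniform sliding
  window (population moments, summed-area tables), global fallback for tiny
  matrices. Window choice shifts absolute values, so reports carry the
  convention used.
* **GenomeDISCO-style reproducibility**: each map row-normalized to a
  random-walk transition matrix, raised to `t_steps` (default 3); score is
  $1 - \sum\lvert A^t - B^t\rvert / \overline{\#\text{nonzero rows}}$,
  bounded above by 1.
* **Pearson correlation** for distance-vs-distance comparisons
  (via `stats::cor`, with degenerate input rejected).
* **Kabsch superposition**: closed-form SVD solution for the least-squares
  rigid transform; reflections allowed by default since contact data
  cannot determine chirality.
* **TM-score**: $\frac{1}{L}\sum_i \frac{1}{1 + (d_i/d_0)^2}$ with
  $d_0 = \max(1.24(L-15)^{1/3} - 1.8,\ 0.5)$ (the floor handles short
  chains, $L \le 21$), evaluated after a superposition refined for the TM
  objective by iteratively reweighted Kabsch fits (weights
  $(1+(d_i/d_0)^2)^{-2}$), keeping the best score seen.
* **Insulation scores**: for each interior bin, the mean count in the
  square window of `window_bins` upstream rows against downstream columns,
  log2-normalized by the genome-wide mean; minima mark TAD-boundary-like
  insulation points. `insulation_l2()` is the Euclidean distance between
  two maps' insulation profiles — a TAD-consistency statistic, not a TAD
  caller.

# The synthetic-data generator

`generate_structure()` builds a polymer-like chain of unit steps with a
bounded turning angle (default 35°) — a smooth, locally stiff curve, not a
molecular-dynamics simulation. `structure_to_contacts()` converts it to
expected counts $\lambda_{ij} = c\, d_{ij}^{-1/\alpha_{true}}$, the exact
inverse of the wish-distance rule when $c = 1$, with optional Poisson
counting noise and TAD-like diagonal block enrichment.
`thin_counts()` emulates reduced sequencing depth by binomial read
thinning; `make_training_pairs()` draws per-pair retentions uniformly from
a configurable range (default 0.3–0.95 — the comparator convention of 0.75
is a single point of this range, but blind estimation is only meaningful
when the retention varies).

What the generator reproduces: non-negative symmetric counts, power-law
distance decay, block (TAD-like) enrichment, Poisson counting noise,
binomial coverage loss. What it does not: locus-specific coverage biases,
translocations, inter-chromosomal contacts, the extreme (>99%) sparsity of
real single-cell maps, or realistic polymer physics. Passing tests
therefore demonstrate correctness of the algorithms under their own
generative assumptions — not performance on any real dataset, which
additionally depends on training scale and data quality.

# Problem sizes and numerical choices

The shipped tests and the reproduction script use: 60-locus chains for
reconstruction (all ~1,770 pairs retained in the noiseless setting);
80-bin maps tiled into 40×40 patches for enhancement, ~400 training steps
at batch 2; ensembles of 20; the default $\alpha$ grid of 20 points at a
reduced budget of 600 iterations per point. These sizes were chosen so the
full pipeline runs in well under a minute per stage on one CPU while
leaving comfortable statistical margins; all of them scale up through the
configs.

Other numerical choices, collected: duplicate triplet records are summed
before mirroring (making file round trips exact); patch reassembly
averages overlaps; the estimator's depth-ratio feature is guarded by a
1e-6 floor; coincident loci in the likelihood gradient are guarded by a
1e-9 distance floor; insulation scores use a 1e-9 pseudocount against
log2(0) in sparse windows; PDB output rescales coordinates to fit the
fixed-width field (the factor is recorded in a REMARK); checkpoints are
JSON text and round-trip weights to ~1 ulp.

# Known limitations

* The enhancer is a compact network intended for CPU-scale training on
  patches; reproducing published benchmark scores on real datasets would
  require larger models, more data and longer training than this package
  targets.
* The degradation kernel is single-channel and local (default 3×3); it
  cannot express long-range or bin-specific degradation.
* Reconstruction assumes one chromosome, one conformation; no mixture of
  cells, no multi-chromosome layout.
* Model units are arbitrary: wish distances fix relative geometry only, so
  FISH-style probe-distance comparisons are correlation-based
  (`probe_distance()` reports model units).
* `.cool`/`.hic` binary formats are not parsed; the interchange formats are
  sparse triplet text and dense whitespace matrices.
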