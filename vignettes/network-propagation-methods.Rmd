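---
title: "Predicting drug response by propagation over a heterogeneous cell-drug-target network"
author: "drugFlow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug response by propagation over a heterogeneous cell-drug-target network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugFlow)
```

## The problem

Large drug-screening panels measure the concentration at which a drug
inhibits half of a cancer cell line's viability (IC50). After per-drug
thresholding, each tested cell line-drug pair is *sensitive* or
*resistant*, and many pairs remain *unknown* (untested). The prediction
task is to rank, for each drug, the cell lines most likely to be sensitive
— both to recover held-out known associations and to nominate untested
pairs for experiments.

drugFlow addresses this with a heterogeneous network that couples five
sub-networks over three node types (cell lines, drugs, target genes):

1. **Cell similarity** `SIM_cc`: Pearson correlation of genome-wide
   expression profiles between cell lines.
2. **Drug similarity** `SIM_dd`: Pearson correlation of precomputed 1-D/2-D
   chemical descriptor vectors. Descriptor computation itself is out of
   scope; any numeric descriptor table is accepted.
3. **Target similarity** `SIM_tt`: a fusion of protein-protein interaction
   (PPI) confidences and gene co-expression.
4. **Cell-drug associations** `A_cd`: the binarized screen (1 = sensitive;
   resistant and unknown = 0, with a separate unknown mask).
5. **Drug-target interactions** `A_dt`: known therapeutic targets (0/1).

The premise is pharmacological: similar cell lines respond to similar
drugs, and drugs whose targets are functionally related behave alike. The
target layer lets evidence travel between drugs that share no chemical
similarity but hit interacting proteins.

## Similarity construction

For any two nodes with feature vectors $X, Y$,

$$r = \frac{\sum (X-\bar X)(Y-\bar Y)}
           {\sqrt{\sum (X-\bar X)^2 \sum (Y-\bar Y)^2}},$$

with a two-sided t-test p-value on $n-2$ degrees of freedom. An
off-diagonal entry is retained — keeping its signed value — only if its
absolute correlation ranks in the top fraction (default 50%) of all
distinct pairs **and** $p < 0.01$ (uncorrected; the cut is deliberately a
raw per-pair test, not an FDR procedure). All other entries are zeroed and
the diagonal is fixed at 1 so that propagation respects self-information.

Numerical choices worth knowing:

* The rank cutoff keeps $k = \lfloor \text{topFraction} \cdot
  \binom{n}{2}\rfloor$ pairs; ties at the cutoff value are all retained,
  which makes the result deterministic and invariant to node order.
* `topFraction = 0` yields the identity matrix (no edges); identical rows
  yield an all-ones matrix.
* Zero-variance feature rows are rejected outright — a constant profile
  has no defined correlation, and silently dropping it would desynchronize
  the index maps shared across the five sub-networks.

### The target layer

PPI confidences below 0.4 are discarded (a conventional
medium-confidence cut for STRING-style scores; configurable), then
degree-normalized:

$$\bar W_{ppi}(i,j) = \frac{W_{ppi}(i,j)}{\sqrt{D(i,i)\,D(j,j)}},
\qquad D(i,i)=\textstyle\sum_j W_{ppi}(i,j),$$

with $0/0 = 0$ for isolated genes. Gene co-expression $W_{corr}$ is
computed over the cell-line samples and passed through the same
rank/p-value filter as the other similarity networks (we chose to filter
here too: the filter exists to suppress weak, noise-driven correlations,
and gene pairs are far more numerous than cell or drug pairs; the
unfiltered variant remains available via `filterCorr = FALSE`). The two
evidence layers are combined by a noisy-OR,

$$SIM_{tt} = 1-(1-W_{corr})(1-\bar W_{ppi}),$$

so either source alone can establish similarity and a certain edge
(value 1) is absorbing. Because the noisy-OR presumes $[0,1]$ inputs,
negative co-expression values are clamped to 0 before fusion by default
(`signedCorr = TRUE` disables this for experimentation). Genes present in
only one evidence layer keep zero rows in the other, so the drug-target
gene universe is never silently shrunk. The diagonal is set to 1 after
fusion, consistent with the other similarity matrices.

## Propagation

Starting from $A_{cd}^0$ (binarized screen) and $A_{dt}^0$ (known
targets), the coupled updates

$$A_{cd}^{k+1} = \alpha\, A_{cd}^{k}\,
  N\!\left(SIM_{dd}\, A_{dt}^{k}\, SIM_{tt}\, A_{dt}^{k\top}\right)
  + (1-\alpha)\,A_{cd}^{0}$$

$$A_{dt}^{k+1} = \alpha\,
  N\!\left(A_{cd}^{k\top}\, SIM_{cc}\, A_{cd}^{k}\, SIM_{dd}\right)
  A_{dt}^{k} + (1-\alpha)\,A_{dt}^{0}$$

are iterated until the summed absolute change in $A_{cd}$ falls below
$10^{-4}$. Here $N$ is degree normalization,
$N(W)(i,j) = W(i,j)/\sqrt{\sum_k W(i,k)\sum_k W(k,j)}$, applied to the
bracketed drug-by-drug product *each iteration* — the similarity matrices
themselves enter unnormalized (an optional `normalizeSims` switch
pre-normalizes them for sensitivity analysis). Both brackets smooth
information across drugs: the first through shared and interacting
targets, the second through co-responding cell lines.

Design decisions a user should know:

* **Update order.** Both updates consume iteration-$k$ matrices (a
  simultaneous, Jacobi-style sweep); a Gauss-Seidel variant that feeds the
  fresh $A_{cd}^{k+1}$ into the second update is available for comparison
  (`gaussSeidel = TRUE`). Convergence is measured on $A_{cd}$ only, and
  $A_{dt}$ is reported as it stood at exit.
* **The mixing weight** $\alpha \in (0,1)$ balances network smoothing
  against the restart to the observed associations; the default 0.4
  follows the two-layer heterogeneous-graph-inference lineage this model
  extends. There is no universally right value; $\alpha = 0$ is admitted
  as a degenerate boundary (scores equal the input) because it anchors
  tests. Under nonnegative similarities every training sensitive pair
  keeps at least its restart floor $(1-\alpha)$.
* **Sign handling.** Retained similarities are signed by default at the
  matrix level, faithful to "use the correlation as the similarity score".
  However, with negative entries the normalized bracket is no longer
  substochastic-like and the iteration can diverge (we observed scores
  blowing past $10^{50}$ on synthetic folds). Degree normalization exists
  precisely to keep the iteration bounded, which it only guarantees for
  nonnegative weights; the assembled pipeline therefore clamps negative
  similarities to zero by default (`assembleFromBundle(clampNegative =
  TRUE)`), and entries of $N(W)$ whose row-sum/column-sum product is not
  positive are set to 0 (0/0, and negative products with no real square
  root).
* **Guards.** A 1000-iteration cap returns the last iterate with a
  warning; non-finite values abort with the iteration number.

## Evaluation protocol

Leave-one-out cross-validation masks each known **sensitive** pair in
turn (its entry set to 0), re-runs the propagation, and records only that
pair's score. Resistant pairs — whose initial entries are already 0, so
no label can leak — are scored once from a propagation on the full
training matrix. For each drug, only cell lines with *known* associations
are ranked (unknown pairs are excluded entirely); ties keep the stable
order of cell identifiers. AUC uses the rank (Mann-Whitney) formulation
with half-credit for ties, per-drug AUCs are averaged unweighted, and
retrieval counts report the sensitives found in the top
$\lceil p N \rceil$ of a ranking. Tissue-stratified AUC restricts each
drug's ranking to one tissue's cell lines and averages over drugs that
retain both classes there.

One subtlety: scoring a held-out positive from a network that lacks that
association is marginally conservative — the masked entry also weakens
its drug's bracket column — while resistant scores come from the intact
network. Where positives and negatives are otherwise indistinguishable
(see below), this small asymmetry resolves ties *against* the held-out
pair, which can push within-stratum AUC slightly below 0.5.

## The synthetic benchmark

`generateSynthetic()` produces a complete input bundle with planted
ground truth: cells, drugs and genes are partitioned into blocks; feature
vectors are a shared block basis plus Gaussian noise (within-block
correlation $s^2/(s^2+\sigma^2)$, solved for the basis scale $s$, so
tests can target a correlation analytically); the PPI is dense and
high-confidence within gene blocks and sparse/low-confidence across;
drugs target genes of their own block; a cell is sensitive to drugs of
its own block, with IC50 values drawn from two unit-variance Gaussians at
$\mp 2$ around the per-drug threshold; a fraction of entries is blanked
to unknown; tissue labels equal cell blocks. A single integer seed
determines the bundle, and the generator restores the caller's RNG
state.

The default configuration is the *clean, block-determined regime* used to
calibrate the pipeline end to end: 60 cells, 12 drugs, 40 genes, 3
blocks, within-block sensitivity 0.95, **no** off-block sensitivities,
strictly in-block drug targets, no label flips, 10% unknowns, 200
expression features and 100 descriptors (a scaled-down stand-in for
genome-wide profiles and descriptor panels; at much smaller dimensions,
spurious correlations survive the p-filter and blur the planted blocks).
Off-block sensitivity deserves a word: a cell sensitive to a random drug
of another block carries no signal that any network feature could
recover, so such labels are noise by construction — the clean regime sets
their rate to 0 for the same reason it sets the flip rate to 0, and both
are dials (`sensOffBlock`, `labelFlipRate`) for controlled degradation
experiments. Under the clean defaults, mean LOOCV per-drug AUC exceeds
0.9 across seeds; at `labelFlipRate = 0.5` it collapses to ~0.5,
bracketing the pipeline's dynamic range. These problem sizes keep the
full calibration (hundreds of leave-one-out propagations per seed) to
seconds per bundle.

What passing these checks does **not** show about real data: the
generator's labels are block-determined, so it cannot probe within-block
heterogeneity — an in-block resistant cell line looks identical to its
sensitive neighbours through every feature the model sees, which is why
within-tissue AUC hovers near chance on synthetic data while the
headline per-drug AUC is high. Real screens have graded IC50 structure,
batch effects, correlated unknown-ness, and drugs whose mechanism does not
respect any expression-defined partition; none of that is emulated.
Published results on public screens also depend on an unreported mixing
weight, so they identify a qualitative regime, not numbers a reimplementation
can match exactly.

## Known limitations

* Complexity is dominated by the gene axis (the $SIM_{tt}$ products);
  dense matrices only, no sparse backend.
* The target gene universe is taken as given input; deriving it from a
  PPI neighbourhood or pathway membership is the user's choice.
* Target similarity uses PPI + co-expression only; sequence-based target
  similarity is deliberately out of scope.
* Per-drug binarization thresholds are inputs, not derived from the IC50
  distributions.
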