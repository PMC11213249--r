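---
title: "Estimating cell-type transcriptional activity from bulk RNA-seq: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating cell-type transcriptional activity from bulk RNA-seq: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celldecon)
```

## The model

A bulk RNA-seq profile from a composite tissue such as a mature leaf is a
mixture of the expression programs of its constituent cell types
(epidermis, several mesophyll states, vascular tissue, guard cells, rare
types such as hydathodes).  `celldecon` models a bulk sample $b \in
\mathbb{R}^G_{\ge 0}$ over $G$ marker genes as

$$ b \approx S f, \qquad f \ge 0, $$

where $S$ is a $G \times K$ *signature matrix* of characteristic per-type
mean expression and $f$ the mixing coefficients.  After clamping at zero
and normalizing to sum to one, $f$ is the share of transcripts
attributable to each cell type's program.  We deliberately call this
*cell-type transcriptional activity* rather than cell-type proportion: a
shift can reflect a change in cell numbers, in per-cell transcription
rates, or in cells transiently adopting another type's program — the
deconvolution cannot distinguish these, and no interpretation in this
package assumes it can.

Two engines solve the fit, both on the linear scale and without quantile
normalization (quantile normalization is known to distort RNA-seq
mixtures and is disabled throughout):

* **nnls** (default): exact non-negative least squares by the
  Lawson–Hanson active-set algorithm, with the passive-set subproblems
  solved by QR on the original columns for stability when signature
  columns are collinear.  Deterministic; exact on noiseless mixtures.
* **svr**: $\nu$-support-vector regression with a linear kernel in the
  style of the SVR-based deconvolution family: mixture and signature are
  globally standardized, $\nu \in \{0.25, 0.5, 0.75\}$ are fitted, primal
  weights are recovered from the support vectors, negatives clamped, and
  the $\nu$ with the lowest reconstruction RMSE kept.

Fit significance is a permutation test: the gene labels of the bulk
vector are shuffled `n_perm` times (default 100), the model is refitted,
and $p$ is the smoothed fraction of permutations whose reconstruction
Pearson correlation reaches the observed one, $p = (\#\{r_{perm} \ge
r_{obs}\} + 1)/(n_{perm} + 1) \in (0, 1]$.

## Signature construction

`build_signature()` works from a labelled single-cell reference:

1. Genes are pre-filtered by `filter_genes()` on total abundance,
   retaining $\ln(\text{total count}) \in [4, 10]$ (inclusive): very low
   totals carry no signal, very high totals are dominated by
   housekeeping/structural genes that do not separate types.
2. Expression is depth-normalized to counts-per-10,000 per cell; no log
   transform, as the mixture model is linear.
3. Per type, genes are ranked one-vs-rest by a two-sided Wilcoxon
   rank-sum test (normal approximation with tie and continuity
   correction, vectorized over all genes and types; cross-checked against
   `stats::wilcox.test` in the test suite), Benjamini–Hochberg corrected
   within type.  Candidates need $q <$ `q_threshold` (default 0.3) and
   fold change above 1, and are ordered by fold change with gene-id
   lexicographic tie-breaks so the selection is deterministic.
4. For every marker count $g$ in `markers_range` (default 50–150) the
   top-$g$ markers of every type form a candidate basis; the $g$
   minimizing the 2-norm condition number $\kappa(S) =
   \sigma_{max}/\sigma_{min}$ is kept.  $\kappa$ measures how well-posed
   the inversion is; duplicated or confusable types drive it up, and a
   near-singular basis ($\kappa > 10^6$) triggers a warning.

The marker-count range and $q$ threshold are conventions of the
signature-matrix approach, exposed as parameters; the reference run that
motivated the defaults did not publish its internal settings.

## The simulated-mixture benchmark

Because true composition is unknowable in real bulks, accuracy is
assessed on pseudobulks with known composition:

* `split_train_test()` holds out 25% of cells per cluster
  (`round(0.75 n)` train, remainder test, at least one test cell).
* `simulate_single_type_bulks()` halves each type's test cells into two
  groups summed gene-wise (replicates 1 and 2).
* `simulate_mixed_bulks()` draws, per sample and type, a proportion from
  $\mathcal{N}(p_k, p_k)$ — mean *and* standard deviation equal to the
  type's reference share, read literally — clamps negatives to zero,
  scales by the average cells per sample (600) and rounds.  Cells are
  then sampled uniformly without replacement (a cap at the available
  pool is logged when it binds; with the default 25% test pool the cap
  binds routinely and realized samples average ~360 cells) and summed.
  Scoring uses the *realized* fractions of cells actually drawn:
  clamping and rounding make the raw normal draws unnormalized and
  unattainable as ground truth.

`benchmark_report()` scores per type across samples: Pearson r (accuracy
flag at $r > 0.8$), the OLS slope of predicted on true (1 is calibrated;
the intercept is reported, not scored), and the argmax confusion matrix
for single-type pseudobulks (ties broken lexicographically).  Undefined
correlations (constant columns) are reported as missing, never as zero.

## Synthetic data with planted truth

The generators produce every input the pipeline consumes, with ground
truth recorded for recovery tests.

**Reference** (`simulate_reference()`): 10 clusters by default — three
mesophyll groups, epidermis, vascular, phloem parenchyma, companion,
guard, sieve, and a rare hydathode-like cluster — with disjoint marker
blocks (60 genes per type, 8-fold elevation over a 0.5 counts/gene/cell
baseline, 3000 genes, ~2000 cells) and negative-binomial counts
(size 1).  Depth and dispersion are free parameters chosen as typical of
droplet single-cell data; the motivating study does not state them.  The
hydathode profile is mixed 80% toward mesophyll group 1 *before*
sampling, so its ground truth stays well defined while its signature
column becomes nearly collinear with its partner's.

**Bulk series** (`simulate_bulk_series()`): per-type weight trajectories
(diurnal cosine with a phase in hours, linear developmental trend, or
constant), replicate noise added on the weight scale and re-normalized so
fractions stay on the simplex, expected expression
$\sum_k f_k \cdot \text{profile}_k$ scaled to the target depth, Poisson
counts.  Four replicates per timepoint by default, mirroring replicated
diurnal designs.  Age-axis runs also emit monotone-plus-noise traits
(pseudotime, biomass, leaf area).

**Annotated network** (`simulate_network()`): every gene carries each
term independently with `annotation_prob`; edges are drawn without
replacement from all TF × target pairs with weights multiplied by the
enrichment factor of any planted term pair, so a planted (A, B, factor)
pair has expected count ≈ factor · p₀ · n_edges at small base rates.

What the generators do *not* emulate: real gene identities, UMI
chemistry, doublets, ambient RNA, within-cluster substructure, or
cross-platform batch effects.  Passing recovery tests therefore shows the
estimators are correct under the stated noise model, not that real-data
accuracy will match.

## Temporal and trait profiling

Fractions are summarized exactly as replicated time courses usually are:
replicate averaging per timepoint (`average_replicates()`), then
per-type z-scores.  Throughout the package z-scores use the sample (n−1)
standard deviation and constant columns map to zeros — both conventions
stated here because the source analyses leave them implicit.  Z-scoring
happens *after* replicate averaging; the output records the ordering
metadata.  `peak_time()` takes the argmax with earliest-tie resolution.
`trait_correlation()` uses Spearman rank correlation with average-rank
ties (two-sided p, `exact = FALSE`), suited to monotone but nonlinear
fraction–trait relations.  `geneset_cluster_profile()` computes per-gene
mean counts-per-10,000 per cluster and z-scores across clusters per
gene.  Hierarchical clustering of heatmap rows is display styling, out
of computational scope; row order is preserved.

## Group-mode imputation and gene assignment

`impute_group_expression()` inverts the mixture across samples: types
are ranked by mean fraction, the 9 most abundant kept and the remainder
pooled into "other" (fractions summed), and per gene the across-samples
system $b_g \approx F h_g,\ h_g \ge 0$ is solved by NNLS.  This needs at
least as many samples as retained types; a rank-deficient fraction
design (collinear trajectories) is flagged and the affected values
carry a degeneracy warning rather than being silently reported.
`assign_gene_to_celltype()` marks a gene as expected in every type whose
imputed value reaches `alpha` (default 0.5) of the gene's maximum — a
declared, parameterized substitute for an assignment rule whose original
is undocumented.

## Context networks and term-pair enrichment

`filter_network()` keeps a TF→target edge when both endpoints are
expressed in the context: strictly above the single-cell threshold in at
least one selected cell type AND strictly above the bulk threshold in at
least one selected sample.  Strict inequality and the ANY quantifier are
declared choices (configurable to ALL); genes absent from an expression
table fail conservatively and are logged.  Raising either threshold can
only remove edges, giving nested networks along any grid axis.

`pafway_term_network()` scores, for every ordered term pair (A, B), the
count of edges from an A-carrying source to a B-carrying target among
the N network edges.  Under the null, the count is Binomial(N, p₀) with
p₀ = frac(A) · frac(B), term frequencies computed over the genes present
in the network (the enrichment question is about the network's topology,
not the annotation universe).  The p-value is the exact upper binomial
tail — observed 0 gives p = 1 exactly — rather than any large-N
approximation.  Significance at p < 0.05 is used raw, matching the
stated criterion; BH correction is available behind a flag.

`threshold_scan()` evaluates the number of significant term pairs over a
threshold grid and flags, along each 1-D slice, strict local maxima and
sign changes of the discrete second difference (inflection points) —
the natural operating points for choosing thresholds.
`compare_condition_networks()` partitions significant term edges across
conditions into shared and condition-unique sets with Venn counts.

## Numerical choices and degenerate inputs

* All randomness flows through one explicit seed per call; the caller's
  RNG state is restored, and equal seeds reproduce byte-identical
  output.
* NNLS dual tolerance is scaled by $\max|A^T b|$; rank-deficient passive
  sets drop the undetermined direction instead of failing.
* All-zero bulk samples are flagged (`NA` fractions) rather than
  normalized into nonsense; all-zero genes never pass the abundance
  filter; empty gene intersections and empty selection sets are errors.
* Readers validate strictly (duplicate ids, negative entries, malformed
  lines with their line number) and never coerce silently; writers round
  floats to 6 significant digits and round-trip losslessly at that
  precision.

## Scales used by the test suite

The shipped tests run the full benchmark at a deliberately desk-sized
scale chosen as the package's reference study: 10 cell types, ~2000
cells, 3000 genes, 75/25 split, 500 mixed pseudobulks at a nominal 600
cells each, nnls engine (about 15 s end to end).  Permutation
calibration uses 200 null samples at 100 permutations; term-pair
calibration uses 200 simulated networks of 2000 genes and 600 edges
(sizes chosen so that binomial discreteness and the estimation error of
p₀ both stay small); temporal recovery uses a 6-type reference with
staggered 24-h phases sampled every 2 h with 4 replicates.

## Known limitations

* Activity fractions are relative shares on marker genes: they are
  comparable across samples for the same type, but systematic per-type
  compression (slopes away from 1) is expected and is why the benchmark
  scores slopes separately from correlations.
* Deliberately confusable types (collinear signature columns) cannot be
  reliably separated by any engine; the benchmark surfaces this as low
  per-type r and split fractions rather than hiding it.  Because the
  generator samples single-type pseudobulks and the signature from the
  same planted profile, the *direction* of the confusion is symmetric
  here, whereas real confusable types (e.g. rare clusters resembling a
  dominant one) can be absorbed systematically by their partner.
* Group-mode imputation recovers per-type means for a gene set, not
  per-sample per-gene expression; high-resolution per-sample imputation
  is out of scope.
* The permutation test calibrates the reconstruction fit, not the
  individual fractions; the term-pair statistic treats edges as
  exchangeable and ignores degree structure beyond term frequencies.
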