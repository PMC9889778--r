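---
title: "fibroscape: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fibroscape: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`fibroscape` implements the computational stages of a fibroblast-
heterogeneity analysis — stromal demarcation, batch-effect scoring,
sample-level marker discovery, pseudotime meta-analysis, deconvolution
benchmarking, survival cutpoint stratification, and histo-cytometry
classification — together with synthetic-data generators that emulate the
statistical structure each stage assumes. This vignette records the models,
their tunable parameters, and the design decisions taken where the
methodology was genuinely open.

## The synthetic cohort model

`generate_cohort()` draws counts from a negative binomial with variance
μ + μ²/θ. Defaults and rationale:

* **Gene base means**: lognormal (sdlog 1.2), rescaled so each cell's
  expected total is `lib_size_mean` (default 10,000) — the skewed
  mean-expression profile and depth typical of droplet data.
* **Dispersion θ = 10**: moderate overdispersion, typical of droplet
  protocols after UMI collapsing.
* **Library-size factors**: lognormal(0, 0.3); normalization rescales each
  cell to 10,000 counts before `log1p`, the convention the analysis layer
  assumes throughout.
* **Cell-type signatures**: disjoint blocks of genes whose means are
  multiplied by `2^signature_log2fc` in cells of that type. Signature size
  30 and log2FC 1.5 are the defaults, matching the separability of
  well-annotated stromal subpopulations.
* **Batch effects**: per patient, a random 30% of genes receive a
  multiplicative effect drawn N(0, `batch_sd`) on the log2 scale
  (default 0.5). Making the affected gene set patient-specific is what
  renders the kNN overlap score sensitive: a global shift shared by all
  patients would not distort neighbourhoods.

The trajectory generator plants a bifurcating differentiation process: each
cell gets a branch (uniform over the configured branches) and a pseudotime
t ~ U(0, 1). Module genes are boosted by `2^(amplitude × bump(t))`, where
`bump` is a squared sine supported on the module's activation window — a
smooth unimodal pulse. Four default modules tile [0, 1] in the order
progenitor, early-activation, proto-differentiation, differentiation.
Branch-identity genes decay as `2^(log2fc × (1 − t))` on their own branch
only, so the two progenitor states are distinct at t = 0 and fade into a
common terminal state at t = 1 — the convergent-transdifferentiation
structure the trajectory analysis is designed to recover. A consequence
worth stating plainly: cells very close to the terminal state carry *no*
branch information, so no method can assign them better than chance, and
measured branch-assignment accuracy saturates below 100% by construction.

The survival generator draws Weibull event times with the subject hazard
multiplied by `exp(log_hazard_per_unit × score)`, where the score is a
truncated normal on [0, 100] (a percentage-like abundance). Censoring is
`min(censor_time, U(0, 2 × censor_time))`, a mix of administrative and
random loss to follow-up.

What the generators do **not** emulate: ambient RNA, doublets, zero
inflation beyond NB sampling, gene–gene correlation within a cell state,
cell-size (total mRNA) differences between types, or read-level noise.
Passing tests therefore demonstrate correctness of the statistical
machinery on data satisfying its assumptions, not robustness to every
artefact of real tissue dissociation.

## Module scores and the demarcation rule

`score_gene_module()` bins genes into 25 equal-occupancy bins by mean
log-normalized expression and samples 100 control genes per set gene from
the set gene's bin (with replacement when the bin is smaller); the score is
the mean over set genes minus the mean over the pooled controls. 25/100 are
the canonical defaults of this procedure; sampling is seeded and the seed is
an explicit argument, since control sampling is the only stochastic step in
the scoring path.

`classify_stromal()` implements *fibroblast if fib − mural > 0.1 and
fib > 0*. The source methodology states only the fibroblast branch; we make
the mural branch symmetric and keep an explicit **unassigned** class for
cells satisfying neither, rather than force-assigning ambiguous cells —
consistent with an exclusion-based workflow where unclassifiable events are
dropped, and visible in the worked example where the planted third
population lands almost entirely in `unassigned`.

Fold changes throughout the package are computed on the linear scale
reconstructed from mean log-normalized values, `log2((expm1(a) + eps) /
(expm1(b) + eps))` with eps = 1e-9, since the fold-change scale is otherwise
underdetermined.

`classify_subpopulation()` is deliberately a simplified stand-in for
anchor-based label transfer: per-class reference centroids on shared genes,
per-cell Pearson correlation to each centroid, and probabilities by softmax
of correlation / temperature (default 1). It is not a re-implementation of
the anchor method; it provides calibrated-looking class probabilities that
behave correctly in the planted-truth regime.

## Batch-effect z-scores

For a group g of m cells, the observed statistic is each member's count of
k nearest neighbours inside g. The null is built from random m-subsets of
all cells, with the overlap computed against the drawn set itself; the
pooled mean and sd of the null per-cell overlaps standardize the observed
values, and the group is flagged when the median z exceeds 1.96. Two points
were open and are resolved as follows: aggregation is per-cell z summarized
by the **median** (the flag rule is stated on a median z-score), and null
sets are uniform random cell subsets of matched size. Neighbourhoods are
computed on the top 30 principal components of log-normalized expression by
default; both k and the embedding are arguments, and a precomputed
(e.g. externally batch-corrected) embedding can be passed directly —
that is the package's batch-correction plug point, since correction itself
(reciprocal-PCA integration and the like) is out of scope.

When every draw yields identical overlaps (e.g. a single all-encompassing
group), the null sd is zero; the z is reported as NA with a warning and the
group is not flagged.

## Sample-level markers and the resolution sweep

`pseudo_sample_profiles()` averages log-normalized expression per
(sample, cluster); pairs with fewer than 3 cells are dropped. The marker
criterion — sample-level average log2 fold change > 1, Bonferroni adjusted
p < 0.01, expressed (profile value > 0) in at least half the target-side
samples — is evaluated with a Wilcoxon test across profiles.

The test is **unpaired by default** (`paired` is an exposed switch). The
reason is arithmetic: a paired signed-rank over n samples has a smallest
attainable two-sided p of 2/2ⁿ, which at 12 samples is ≈ 4.9 × 10⁻⁴ — no
gene can survive a Bonferroni correction over ~2000 genes at α = 0.01,
however strong the effect. The unpaired rank-sum over profile columns
(target cluster's columns vs all other clusters' columns) is also what the
average-expression + marker-finding toolchain this mirrors actually
computes. For contrasts between disjoint sample groups (tumour vs control
within a subpopulation) the unpaired test is the natural choice anyway.

`resolution_sweep()` partitions a shared-nearest-neighbour graph (Jaccard
weights on the kNN structure, pruned below 1/15) by Leiden modularity
optimisation at each resolution, seeded; clusters are relabelled by
decreasing size. A resolution is *supported* when every cluster retains at
least `marker_min` passing markers, and the chosen resolution is the
largest supported one: over-clustering homogeneous populations yields
clusters with no markers and is rejected. The sweep is intended for
batch-corrected (or batch-free) data — on uncorrected data with strong
patient effects the SNN graph fragments by patient, which is precisely the
condition the batch QC stage is there to detect first.

## Trajectory inference and meta-analysis

`diffusion_map()` uses a Gaussian kernel on kNN distances with adaptive
per-cell width (the distance to the ⌈k/2⌉-th neighbour), density
normalization (dividing the kernel by the product of its row sums),
row-normalization to a Markov operator, and a symmetric
eigendecomposition; components are eigenvectors 2..n_comps+1 scaled by
their eigenvalues. When given a `cell_matrix` it first selects 200 highly
variable genes (variance above a loess mean–variance trend) and embeds on
10 principal components. HVG selection matters: trajectory signal is
carried by a minority of genes, and benchmarking planted-truth recovery
across independent synthetic realizations showed the all-gene embedding
loses substantial ordering accuracy. We use k = 15 for fine one-dimensional
ordering (small kernels preserve local order) and k = 30 — the signature
default — where the global branch geometry matters more than local order.

`diffusion_pseudotime()` defines dpt(i) as the Euclidean distance from the
root in the space of components rescaled by λ/(1−λ), min–max normalized;
branches are assigned by proximity to tips selected by farthest-point
sampling in that space. This tip-proximity rule is a documented simplified
stand-in for full DPT branch triangulation, and pseudotime is computed
jointly before the branch split. Root choice is the caller's: for a
convergent process, rooting at the terminal state and asking for two tips
recovers the two progenitor arms.

When expression data is passed alongside the embedding, the tip assignment
is refined by a seeded expression contrast: cells in the closest 60% of
own-tip distances act as high-confidence seeds (cells near a convergence
point are far from every tip and are excluded), the 100 genes best
separating each pair of seed sets define a linear contrast score with the
decision threshold at the midpoint of the seed-set means, and every cell is
re-assigned by majority vote over the pairwise contrasts. This step learns
the branch-identity genes from the data — which matters because the
geometric assignment degrades precisely on realizations where those genes
are weakly expressed — while leaving pseudotime itself untouched. Its
benefit is quantified in the test suite against planted branch labels.

`pseudotime_de()` fits a loess (degree 2, tricube weights, span 0.5) of
each gene on pseudotime and tests it against the intercept-only model with
the approximate F-test of local-regression ANOVA, using the smoother's
effective degrees of freedom (one-delta/two-delta corrections). The span
default follows the usual bias–variance compromise at a few hundred cells;
null calibration of the resulting p-values is verified by simulation in the
test suite. Fitted profiles are evaluated on a fixed 100-point grid.

`stouffer_meta()` combines per-dataset p-values as Z = Σ Φ⁻¹(1 − p_d)/√D,
adapting D to the datasets where the gene was testable; significance
requires Bonferroni-adjusted meta-p < 1e-10 **and** nominal p < 0.05 in at
least 3 datasets. Zero p-values are clamped to the smallest representable
positive value with a warning.

`consensus_modules()` z-scales each gene's fitted profile within each
dataset before taking the pointwise median across datasets — so datasets
with different depth or amplitude do not dominate the consensus — then
clusters genes by Ward agglomeration (ward.D2) on 1 − Pearson r and cuts at
k = 4 modules by default (the four-phase structure the trajectory model
plants). Modules are named by the pseudotime position of their mean
profile's peak, ascending: progenitor, early-activation,
proto-differentiation, differentiation. Naming by peak order makes the
labels invariant to dataset order, which the tests assert.

## Deconvolution benchmarking

`build_signature_matrix()` downsamples each type to 500 cells (seeded),
selects up to 50 genes per type by one-vs-rest rank-sum significance ranked
by fold change, and stores per-type mean linear-scale expression.
`simulate_pseudobulk()` follows the validation design: 200 samples, 1000
cells each drawn from 3 random patients, fibroblast content topped up or
down to a uniform target in [1%, 50%], mixtures as counts-per-million,
truth from realized cell counts. `deconvolve()` is non-negative least
squares of each mixture on the signature columns — a transparent stand-in
for external digital-cytometry services whose ν-SVR and batch-correction
internals are out of scope; externally produced fraction tables can be fed
into `evaluate_deconvolution()` and the survival stage unchanged.

Fibroblast subpopulation percentages are reported **relative to the summed
fibroblast coefficients** (× 100): dichotomisation thresholds in the
80–90% range are only attainable on a within-fibroblast scale, and this
convention is recorded in the result object. The synthetic benchmark is
generated without patient batch effects: the external tool's S-mode
correction, which absorbs such effects in the real workflow, is exactly
the part NNLS does not re-implement, so the benchmark isolates
mixture-composition recovery — which is what the stand-in claims to do.

## Survival analysis

`logrank_test()` is the standard two-group log-rank: hypergeometric
expectation and variance at each distinct event time, χ² = U²/Var with 1
df, plus the signed standardized statistic U/√Var used by the sweep.
`cutpoint_sweep()` evaluates every distinct score value whose split keeps
both groups at ≥ 10% of subjects (the conventional minimum-proportion
default) and returns the full sweep plus the |statistic|-maximizing
cutpoint. No maximally-selected-statistic p-value correction is applied on
purpose: the intended workflow defines the cutpoint on a test cohort and
assesses significance by ordinary log-rank on independent validation
cohorts, so the selection bias never meets the inference. The null
distribution of the maximal statistic is indeed anti-conservative relative
to 1.96, which is documented rather than corrected.

`cox_ph()` wraps the partial-likelihood fit of the survival package with
Efron ties by default (Breslow available for cross-checks), optional
administrative censoring at a horizon (48 months for four-year survival
analyses), and Wald 95% intervals. Stage enters as an ordinal numeric by
default; perfect separation and non-convergence surface as errors rather
than silently huge coefficients.

## Histo-cytometry rules

`hsd_to_pif8()` is exactly min(256, ceil(v/1.5 × 256)). The stated 8-bit
range caps at 256, one above a true 8-bit container, so values are kept as
plain integers rather than raw bytes. `subtract_background()` computes the
moving average over a window (default 151 × 151) with edge-replicated
padding — the padding rule was unstated and replicate padding avoids
darkening borders — and zeroes pixels less than 5 above background; in
red-channel mode pixels with red < 0.43 × brown are also zeroed.
`classify_histocytometry()` excludes cells positive for PanCK/CD31/MCAM,
calls the rest by argmax over ACTA2/POSTN/AOC3/CD34 coverages (ACTA2 and
POSTN both mean myofibroblast; AOC3 alveolar; CD34 adventitial), with
cell-level positivity at coverage ≥ 0.01 — the pixel-level staining
threshold of 7 applies inside coverage computation
(`marker_coverage()`) — and exact ties broken by the fixed priority
CD34 > AOC3 > POSTN > ACTA2 and flagged.

## Problem sizes and numerical notes

The bundled benchmarks use cohorts of 6000 cells × 2000 genes
(demarcation, batch QC), 12-sample cohorts of ~1200–1440 cells (markers,
sweep), 300–600-cell trajectory datasets, 200-sample pseudobulk sets, and
survival cohorts of 100–1000 subjects with 200–2000 simulation replicates
— sizes at which every planted effect is comfortably identifiable while
the full pipeline remains quick on a single CPU. Quantities whose
single-realization sampling noise is non-trivial (pseudotime ordering,
branch assignment) are reported as means over replicate simulated
datasets in the acceptance script. Other numerical choices: rank-based
equal-occupancy binning for module-score controls; continuity-corrected
normal approximation with tie correction for the vectorised rank-sum scan;
`qnorm(p, lower.tail = FALSE)` for small upper-tail quantiles in the
Stouffer path; eigenvector sign and scale fixed by unit-norm convention in
the diffusion map; and seeds threaded explicitly through every stochastic
operation so identical inputs give identical outputs.

## Known limitations

Branch assignment is tip-proximity, not trajectory triangulation, and
degrades where branches genuinely merge; the centroid classifier ignores
within-class covariance; NNLS has no noise model and no batch correction;
the resolution sweep inherits the sensitivity of modularity optimisation to
graph construction; and all validation is against the generators described
above, whose assumptions real tissue data will violate in the ways listed
there.
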