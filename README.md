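# fibroscape

Tools for dissecting fibroblast heterogeneity in lung tissue from
single-cell and bulk transcriptomic data.

Fibroblasts in non-small-cell lung cancer comprise distinct subpopulations —
tissue-resident adventitial and alveolar fibroblasts, and tumour-enriched
myofibroblasts — whose identification is complicated by their similarity to
mural cells (pericytes and smooth muscle cells, also ACTA2-high), by
patient-dependent batch effects, and by the scarcity of fibroblasts in
dissociated tissue. `fibroscape` implements, as composable R functions, the
bespoke computational procedures such a study needs:

- **Gene-module scoring** with expression-matched control genes: for a gene
  set *S*, score(cell) = mean(lognorm over *S*) − mean(lognorm over controls
  sampled from expression-matched bins), and the **demarcation rule**
  *fibroblast if score_fib − score_mural > 0.1 and score_fib > 0*
  (symmetric for mural cells; ambiguous cells stay unassigned).
- **Batch-effect detection** by k-nearest-neighbour overlap z-scores:
  z = (nOverlap − mean[random-set overlap]) / sd[random-set overlap],
  flagging groups with median z > 1.96.
- **Sample-level marker discovery** on pseudo-sample profiles with the
  criterion *sample-level average log2 fold change > 1, Bonferroni adj.P <
  0.01, expressed in ≥ 50% of samples*, and a clustering **resolution
  sweep** that rejects resolutions producing clusters without markers.
- **Diffusion pseudotime**: adaptive-kernel diffusion maps, pseudotime as
  distance from a root cell in λ/(1−λ)-scaled diffusion components,
  tip-based branch assignment, loess pseudotime differential expression,
  **Stouffer meta-analysis** (Z = Σ Φ⁻¹(1−p_d)/√D) across datasets, and
  consensus gene modules by Ward clustering on 1 − r.
- **Deconvolution benchmarking**: signature matrices from downsampled
  references, pseudobulk mixtures with known fractions, and non-negative
  least squares as a transparent stand-in for external digital-cytometry
  services.
- **Survival stratification**: two-group log-rank testing, maximally
  selected log-rank cutpoint sweeps for dichotomising continuous abundance
  scores, and Cox proportional-hazards models with covariates and an
  administrative horizon (e.g. 4-year survival).
- **Histo-cytometry rules** for multiplexed IHC: 8-bit pseudo-IF conversion
  (min(256, ceil(v/1.5·256))), 151×151 moving-average background
  subtraction with the red/brown guard (red < 0.43·brown → 0), and
  marker-argmax stromal classification.

Every stage has a matching synthetic-data generator (negative-binomial
counts with per-patient batch effects, planted signatures, bifurcating
trajectories with timed gene modules, survival cohorts with planted
hazards), so the whole pipeline is testable without external downloads.

## Worked example

```r
library(fibroscape)

# a synthetic cohort: 12 patients x 500 cells, fibroblast/mural/other with
# 30-gene signatures planted at log2FC 1.5
cm <- generate_cohort(cohort_config(seed = 42))
cm
#> <cell_matrix> 2000 genes x 6000 cells
#>   patients: 12; samples: 12
#>   metadata: tissue_type, dataset_id, true_type

sig <- attr(cm, "signature_genes")
fib  <- score_gene_module(cm, gene_set("fibroblast", sig$fibroblast), seed = 1)
mur  <- score_gene_module(cm, gene_set("mural", sig$mural), seed = 2)
lab  <- classify_stromal(fib, mur)           # the demarcation rule
truth <- cm$cell_meta$true_type
mean(lab[truth %in% c("fibroblast", "mural")] ==
     truth[truth %in% c("fibroblast", "mural")])
#> [1] 1
table(lab, truth)
#>             truth
#> lab          fibroblast mural other
#>   fibroblast       2998     0     1
#>   mural               0  1831     4
#>   unassigned          0     0  1166
```

All planted fibroblasts and mural cells are recovered; cells of the third
type, matching neither signature, are left unassigned rather than forced
into a class.

Batch-effect QC on the same cohort (patient effects are planted at sd 0.5
on the log2 scale, on 30% of genes each):

```r
graph <- knn_graph(cm, k = 20, n_pcs = 30)
report <- knn_overlap_zscores(graph, cm$cell_meta$patient_id,
                              n_random = 1000, seed = 3)
sum(report$groups$flagged)   # patients with median z > 1.96
#> [1] 12
```

All 12 patient groups are correctly flagged; with `batch_sd = 0` in the
generator, none are.

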