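# radjoint

Subtype discovery from **partially overlapping** radiomic and
somatic-mutation cohorts. In retrospective glioblastoma collections only a
fraction of patients have both pre-operative MRI radiomics and
targeted-panel sequencing; `radjoint` clusters *all* patients jointly
instead of discarding the incomplete ones, then characterizes the
resulting subtypes by survival, mutation architecture and cross-modal
correlation. It is aimed at methodologists and analysts working on
multi-modal integration with missing modalities; since such clinical
cohorts are typically not publicly deposited, the package ships a tested
synthetic-cohort generator with planted ground truth so the entire
pipeline is reproducible end to end.

## Methods at a glance

* **Pathway-supervised feature selection.** With X the features x subjects
  imaging matrix and Y the pathways x subjects alteration labels (OR over
  member genes of the RB1, P53, MAPK, PI3K and RTK pathways), solve
  `min ||W||_{2,1} s.t. W'X = Y` by iteratively reweighted least squares;
  the L2,1 norm zeroes whole rows of W, eliminating whole features, and
  the surviving rows ranked by `||w_i||_2` give the selected features
  (12 by default).
* **Anchor-based partial multi-modal clustering (APMC).** K anchor
  subjects observed in both modalities link the views. Per modality,
  Gaussian subject-to-anchor similarities `Z_ij` (s nearest anchors,
  row-normalized) are one-step transition probabilities of a bipartite
  random walk; rows are fused across modalities (average where both
  exist) and the two-step transition probabilities
  `S = Z diag(colSums Z)^{-1} Z'` — symmetric, row-stochastic, PSD —
  feed spectral clustering. The number of clusters comes from the gap
  statistic in the (eigenvalue-damped) spectral embedding. The procedure
  is transductive: discovery and replication cohorts are clustered
  jointly.
* **Survival.** Kaplan-Meier / log-rank across subtypes; univariate then
  multivariate Cox (Efron ties) over age, sex, MGMT, extent of resection
  and subtype; subtypes renamed by risk (subtype 1 = worst median OS).
* **Mutation architecture.** Per-subtype pairwise odds ratios
  (Haldane-Anscombe-corrected display) with two-sided Fisher exact
  p-values; OR > 1 co-occurrence, OR < 1 mutual exclusivity.
* **Radiogenomic coupling.** First-pair CCA between the 12 selected
  imaging features and the 13 pathway genes,
  `r = max_{a,b} cor(Xa, Yb)`, permutation-tested; kNN (k = 13) subtype
  prediction in the (u, v) latent plane; feature-gene correlation matrix.

## Worked example

The numbered scripts under `analysis/` run the full study on the default
synthetic cohort (500 subjects, three planted subtypes, 46%/33%/21%
availability). `Rscript analysis/01_simulate.R` through
`analysis/06_cca.R`, in order; together they print, among other things:

```
partial_mm_dataset: 500 subjects (225 both, 173 imaging-only, 102 genomic-only)
selection_result: 12 features selected of 100 | ||W||_21 = 13.424
Jaccard overlap with planted informative features: 0.85
subtype_assignment: 500 subjects in 3 clusters (sizes 187/160/153)
ARI against planted subtypes: 0.854
km_report: 3 groups | log-rank chi-sq = 19.2 (df = 2), p = 6.79e-05
 subtypeSubtype 2        0.697  0.535   0.909 7.57e-03 multivariate
 subtypeSubtype 3        0.562  0.432   0.730 1.63e-05 multivariate
whole        r = 0.7530 (permutation p = 0.001, n = 225)
kNN (k = 13) replication accuracy: 84.87%
```

Reading: the gap statistic selects k = 3 (the planted number); clustering
recovers the planted subtypes at ARI 0.85 despite 54% of subjects missing
a modality; the Cox hazard ratios for subtypes 2 and 3 against subtype 1
(0.70, 0.56) recover the planted multipliers (0.725, 0.586); the first
canonical correlation between the two views is strongly significant; and
replication-cohort subtypes are predicted at 85% accuracy from the
two-dimensional latent plane alone. Tables and figures land in
`results/`.

The same pipeline runs on real data by replacing the simulate step with
`run_pipeline(list(input_dir = "<dir>"), out_dir, seed)`, where `<dir>`
holds `imaging.csv`, `genomic.csv` and `clinical.csv` (subjects as rows,
`subject_id` first column; subjects missing a modality are simply absent
from that file).

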