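# rgstage

Radiogenomic staging of muscle-invasive bladder cancer in R: an
end-to-end, fully seeded pipeline that combines 3D radiomic features from
masked MR tumor volumes with RNA-seq-derived genomic predictors to
classify tumors as **intra-vesical** (confined to the bladder) or
**extra-vesical** (grown through the muscle wall) — the distinction that
separates bladder-preserving treatment from radical surgery.

## What it computes

* **Radiomics** — mask-constrained extraction of 101 features per
  parameter combination across seven families (15 first-order, 20 GLCM,
  15 GLRLM, 14 GLSZM, 12 GLDM, 5 NGTDM, 20 shape), swept over gray-level
  counts `2^x` for `x = 1..8`, kernel sizes 1–5 and four in-plane angles
  (4612 records per case for the full grid). Discretized-texture features
  are invariant to affine intensity transforms; inoperable values are
  flagged, never emitted as numbers.
* **Genomics** — median-of-ratios normalization; a transparent
  negative-binomial Wald test (method-of-moments dispersion, t reference,
  BH adjustment) for differential expression between stage groups;
  direction-consistent DEG intersection across datasets; single-sample
  gene-set enrichment scores (rank-weighted, `α = 0.25`); Kruskal–Wallis
  stage-trend tests with bucketed significance stars.
* **Screening** — cleaning of inoperable/constant features, greedy
  correlation pruning, pooled-variance Student t + Gaussian Bhattacharyya
  coefficient screening, Manhattan-plot data, random collapse of
  parameter variants, and count matching so the radiomic set size equals
  the genomic one.
* **Staging models** — naive Bayes, linear SVM, KNN, logistic regression
  and decision-tree classifiers with backward feature elimination scored
  by cross-validated **sensitivity** (extra-vesical = positive class),
  capped at 8 features per category, with frozen predictor sets for
  external validation and confusion-matrix evaluation
  (sensitivity = TP/P, specificity = TN/N, accuracy).
* **Synthetic cohorts** — a seeded generator of two-class radiogenomic
  cohorts (MR-like volumes whose *texture*, not size, separates classes;
  NB counts with planted fold changes including the nine canonical
  bladder-stage genes; gene-set catalogs with planted enrichment) that
  gives every stage of the pipeline a ground-truthed test surface.

## Worked example

```r
library(rgstage)

# a ground-truthed synthetic cohort: 10 + 10 cases, planted texture and
# expression effects
cfg <- cohort_config(n_intra = 10, n_extra = 10,
                     volume_shape = c(16, 24, 24),
                     texture_effect = 1.5, n_genes = 2000,
                     n_de_genes = 50, log2fc = 2, seed = 42)
cohort <- generate_cohort(cfg)

# differential expression recovers the planted genes
de <- nb_wald_de(cohort$counts, cohort$labels)
hits <- de$gene[!is.na(de$adj_p) & de$adj_p < 0.05]
mean(cohort$truth$de_genes$gene %in% hits)   # 1       (all 50 recovered)
subset(de, gene == "HOXB5")$direction        # "up_in_low"

# radiomic extraction + screening finds the planted texture signal
grid <- radiomic_grid(bin_exponents = 3, kernels = 1, angles = c(0, 90),
                      families = c("first_order", "glcm", "glrlm"))
feats <- do.call(rbind, lapply(names(cohort$volumes), function(id)
  extract_all(cohort$volumes[[id]], cohort$masks[[id]], grid)))
sel <- select_radiomic_features(feats, cohort$labels, k_target = 8, seed = 42)
nrow(sel$selected)                           # 8
head(sel$selected$feature_id, 3)
# "glcm|IMC2|b3|k1|a90" "glcm|IMC1|b3|k1|a0" "glrlm|RunEntropy|b3|a90"

# capped RFE staging model on both feature families
g <- t(normalize_expression(cohort$counts)[head(hits, 8), ])
r <- features_wide(feats)[, sel$selected$feature_id]
model <- train_rfe(g, r, cohort$labels, family = "NB",
                   config = model_config(cap = 8, seed = 42))
model
# <staging_model NB: 8 genomic + 8 radiomic features, CV sens 1.00 acc 1.00>
evaluate_predictions(predict(model, cbind(g, r)), cohort$labels)$accuracy  # 1
```

The first numbers mean: every planted differentially expressed gene was
recovered at BH-FDR 0.05 with the planted direction, the screening stage
returned the requested 8 texture features (the planted co-occurrence
signal ranks first), and the capped model separates the training cohort
perfectly — expected here, since the planted effects are strong; the
honest external-validation numbers come from `run_model_comparison()`,
which evaluates on an unseen test cohort.

A one-command version of the whole pipeline (simulate → extract → DE →
ssGSEA → screen → train → external validation, with a checksummed
manifest):

```r
manifest <- run_all(pipeline_config(seed = 1, out_dir = "run1"))
```

or from a shell: `Rscript inst/cli/rgstage.R run-all --seed 1 --out run1`
(the CLI also exposes `simulate` and `radiomics`; the remaining steps are
single function calls documented above).

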