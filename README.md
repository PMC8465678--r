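# mdlinker

Predicting **which kind of evidence** links an miRNA to a disease.

Curated resources record miRNA-disease associations under five heterogeneous
evidence types — genetics, epigenetics, circulating miRNAs, miRNA-target
interaction and tissue expression — and one pair can carry several types at
once. `mdlinker` scores every (miRNA, disease, type) triple with the
probability that the association of that specific type exists, so it can
complete the missing types of known pairs and propose types for entirely
unobserved pairs. It is aimed at computational biologists working with
HMDD-style association tables, MeSH-style disease tree codes and miRBase-style
precursor FASTA.

## Method

The pipeline embeds an attributed multi-layer heterogeneous network whose
layers are the five association types:

1. **Similarities.** Disease-disease semantic similarity on the hierarchy
   DAG: with ancestor contributions `D_P(P) = 1`,
   `D_P(t) = α · max { D_P(t′) : t′ ∈ children(t) }` (α = 0.5) and
   `DV(P) = Σ_t D_P(t)`,

       sim(P, Q) = Σ_{t ∈ N_P ∩ N_Q} (D_P(t) + D_Q(t)) / (DV(P) + DV(Q)).

   miRNA-miRNA similarity from chaos-game representations of precursor
   sequences (visit-frequency matrices over `2^k × 2^k` subregions of the
   unit square, Frobenius distance, min-max inverted).
2. **Node attributes.** Biased second-order random walks (`p = 1`, `q = 2`)
   on each similarity network plus skip-gram with negative sampling give
   every node an `NE`-dimensional attribute vector.
3. **Multi-layer embedding.** Per layer `r`, node `i` is represented as
   `v_{i,r} = β_r·Dz′x_i + h_z(x_i) + α_r·M_r′ D_i a_{i,r}`: an attribute
   term, a layer-shared base embedding, and a layer-specific edge term built
   by K-step neighbor aggregation whose cross-layer mixture weights
   `a_{i,r} = softmax(w_r′ tanh(W_r D_i))` come from a per-layer self-attention
   head — evidence of one type informs the others. Trained by skip-gram with
   negative sampling over within-layer meta-path walks.
4. **Classification.** A triple's feature is the concatenation
   `[v_{mirna,r} ‖ v_{disease,r}]`. Negatives are unconfirmed triples lying
   strictly beyond the mean distance from the per-type positive centroid,
   sampled 1:1; a seeded random forest (500 trees) outputs association
   probabilities.
5. **Evaluation.** Pair-level 10-fold CV (top-1 precision/recall/F1),
   triple-level 10-fold CV (AUPR/AUC/F1 against pool negatives), and
   consensus ranking of novel triples over repeated stochastic runs.
   Embeddings are retrained inside every fold on training edges only.

## Worked example

Everything runs from seeded synthetic data — no downloads. The generator
plants matched miRNA/disease blocks whose signal shows up in the sequences,
the disease hierarchy and the association layers alike:

```r
library(mdlinker)

ds  <- gen_planted_dataset(planted_config(n_mirna = 30, n_disease = 20,
                                          n_blocks = 3, p_within = 0.3,
                                          p_cross = 0.02, seed = 7))
ctl <- mdlinker_control("desk")   # reduced dims for desk-scale studies
fit <- mdlinker(ds$associations, ds$mesh, ds$sequences, control = ctl, seed = 7)
fit
#> Multi-layer miRNA-disease association-type model
#>   30 miRNAs, 20 diseases, 403 confirmed triples
#>   edges per layer: genetics=73, epigenetics=74, circulating=79, target=87, tissue=90
#>   dims: NE=32 BE=16 DE=16, aggregation depth K=2

scores <- predict(fit)            # every pair x all 5 types
head(scores[order(-scores$score), ], 5)
#>         mirna    disease        type score known
#> 1105 mirna011 disease008      tissue 0.993  TRUE
#> 1135 mirna017 disease008      tissue 0.992  TRUE
#> 1088 mirna008 disease008 circulating 0.990  TRUE
#> 1037 mirna028 disease007 epigenetics 0.990  TRUE
#> 2326 mirna016 disease016    genetics 0.990  TRUE
```

`score` is the predicted probability that the triple's association type is
real; `known` marks triples already present in the training data (they should
— and do — dominate the top of the ranking). Cross-validated performance on
the same data:

```r
dat <- mdlinker_prepare(ds$associations, ds$mesh, ds$sequences, ctl, seed = 7)
cv_triple(dat, ctl, seed = 7)
#> Cross-validation report (cv_triple), 10 folds
#> Mean metrics:
#>   aupr    auc     f1
#> 0.8718 0.8752 0.7984
```

AUC/AUPR near 0.88 on held-out triples means the model separates most true
held-out association types from distance-filtered negatives; the remaining
errors are dominated by cross-block positives and within-block unknowns that
carry no recoverable signal under leakage-free evaluation (see the methods
vignette for the decomposition).

Real data enter through `read_associations()` (TSV: miRNA, disease,
category, with precursor→mature mapping and category-synonym support),
`read_mesh()` (disease, tree code) and `read_fasta()`. A thin command-line
wrapper with `synth` / `fit` / `evaluate` / `consensus` subcommands lives in
`inst/scripts/mdlinker.R`.

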