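# camap

Cellular aging maps from masked-token models of single-cell expression.

Aging can be read as the behaviour of a dynamical system: some
coordinates of the system are *conservative* — they revisit the same
states throughout life — while others are *dissipative* and wander off
without returning. `camap` operationalizes that reading for single-cell
transcriptomes. Cells are tokenized (age bin, tissue, cell type,
disease flag, then one expression-bin token per gene at a fixed
position), a compact transformer encoder is trained by masked-token
prediction, and the trained model supplies every quantity of interest:

* **Embedding drift and gene classification.** Per gene g and age bin
  t, the mean contextual embedding E(g,t) yields the drift
  D_g(t) = ||E(g,t) − E(g,t0)||; genes with max_t D_g(t) at or below a
  percentile threshold δ are *conservative*, the rest *dissipative*,
  with the spread σ²_g = (1/N) Σ ||E(g,t_i) − Ē_g||² as a companion
  statistic.
* **Healthy-versus-diseased contrasts.** Per-condition classification
  at the same percentile plus per-gene drift ratios flag genes whose
  stability flips under disease.
* **An aging clock.** The masked age token's predictive distribution,
  restricted to age tokens, gives a continuous age prediction
  (expectation over bin midpoints); gaps are z-scored and summarized
  per tissue/cell type and per lifespan window.
* **Masked-token entropy.** Shannon entropy H = −Σ p log p of the
  model's predictive distribution for a masked token, conditioned on
  the age token, as a per-cell disorder metric.
* **Similarity rankings.** Tissue and cell-type tokens ranked by cosine
  similarity to the age-token centroid; per-gene cosine trajectories
  against the age embedding across the lifespan.

A seeded synthetic-corpus generator with planted ground truth
(conservative/dissipative genes, disease-induced flips, an
age-increasing noise tissue, optional fast-aging tissues) makes the
whole pipeline testable end to end. The transformer and its
backpropagation are implemented in the package (RcppArmadillo); no
external deep-learning framework is required.

## Worked example

```r
library(camap)

study  <- simulate_corpus(sim_config(seed = 101))
vocab  <- build_vocabulary(study)
tokens <- encode_study(study, vocab)

model <- init_mlm(vocab, model_config(seed = 201))
model <- train_mlm(model, tokens)

# aging clock on the held-out cells
val  <- model$val_cells
pred <- predict_age(model, tokens[val, ])
cor(pred, study$cell_meta$age_years[val])
#> [1] 0.9124236

# conservative / dissipative classification against the planted labels
trajs <- gene_age_embeddings(model, study, list(disease = 0L), tokens = tokens)
cls   <- classify_genes(drift_profiles(trajs), q = 80)
cls
#> camap_classification: delta = 5.693 (q = 80); 160 conservative, 40 dissipative
classification_balanced_accuracy(
  cls, study$gene_ids[study$ground_truth$dissipative_genes])
#> [1] 0.828125

# masked-token entropy rises with age in the planted noise-ramp tissue
ramp  <- study$ground_truth$noise_ramp_tissues
cells <- stratum_cells(study, list(tissue = ramp, disease = 0L))
recs  <- masked_entropy_profile(model, study, cells = cells, m = 24,
                                max_cells = 200, tokens = tokens, seed = 7)
entropy_by_age(recs)$spearman
#> [1] 0.9030303
```

The clock correlation of 0.91 says held-out cells' ages are recovered
from expression alone; the balanced accuracy of 0.83 says the drift
ranking finds the planted dissipative genes far above chance at the
matched 20% call rate; the Spearman coefficient of 0.90 says mean
prediction entropy increases almost monotonically across the ten age
bins of the noise-ramp tissue.

`run_pipeline(pipeline_config(outdir = "out", seed = 1))` orchestrates
all stages (simulate, tokenize, train, clock, similarity, dissipation,
entropy) and writes TSV reports plus a JSON manifest;
`inst/scripts/run_pipeline.R` wraps it for the shell.

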