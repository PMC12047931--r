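# Shared fixtures. Heavy objects are cached in a global-environment
# environment so that every test file in one run reuses them.

test_cache <- local({
  if (!exists(".camap_test_cache", envir = globalenv()))
    assign(".camap_test_cache", new.env(parent = emptyenv()),
           envir = globalenv())
  get(".camap_test_cache", envir = globalenv())
})

cached <- function(key, expr) {
  if (!exists(key, envir = test_cache))
    assign(key, force(expr), envir = test_cache)
  get(key, envir = test_cache)
}

# Small corpus: 30 genes, 600 cells, 5 age bins; carries every planted
# feature (dissipative genes, disease flips, a noise-ramp tissue).
small_sim_config <- function(seed = 42L, ...) {
  sim_config(n_genes = 30L, n_cells = 600L, n_age_bins = 5L,
             n_tissues = 2L, n_cell_types = 2L, diseased_fraction = 0.3,
             frac_dissipative = 0.2, n_modules = 3L, seed = seed, ...)
}

small_study <- function() cached("small_study", simulate_corpus(small_sim_config()))

small_vocab <- function() cached("small_vocab", build_vocabulary(small_study(), 6L))

small_tokens <- function() cached("small_tokens",
                                  encode_study(small_study(), small_vocab()))

small_model_config <- function(seed = 7L, epochs = 3L, ...) {
  model_config(d = 32L, n_layers = 2L, n_heads = 4L, d_ff = 64L,
               batch_size = 16L, epochs = epochs, seed = seed, ...)
}

# Trained-once small model shared by the mlm/cam/clock/dissipation/
# entropy unit tests.
small_model <- function() cached("small_model", {
  m <- init_mlm(small_vocab(), small_model_config())
  train_mlm(m, small_tokens())
})

# A tiny untrained model for shape/contract tests.
tiny_vocab_model <- function() cached("tiny_vocab_model", {
  study <- simulate_corpus(sim_config(n_genes = 6L, n_cells = 60L,
                                      n_age_bins = 3L, n_tissues = 1L,
                                      n_cell_types = 1L,
                                      diseased_fraction = 0.5, seed = 5L))
  vocab <- build_vocabulary(study, 3L)
  list(study = study, vocab = vocab,
       tokens = encode_study(study, vocab),
       model = init_mlm(vocab, model_config(d = 16L, n_layers = 1L,
                                            n_heads = 2L, d_ff = 24L,
                                            seed = 3L)))
})

# Random gene trajectory for oracle tests.
random_trajectory <- function(n_bins = 5L, d = 8L, seed = 1L, gene = "g") {
  set.seed(seed)
  new_gene_trajectory(gene, matrix(rnorm(n_bins * d), n_bins, d))
}
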