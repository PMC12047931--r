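test_that("cosine similarity matches closed forms and rejects zero vectors", {
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(2, 3, 4), c(2, 3, 4)), 1)
  expect_equal(cosine_similarity(c(1, 1), c(1, 0)), 1 / sqrt(2),
               tolerance = 1e-12)
  expect_error(cosine_similarity(c(0, 0), c(1, 0)), "zero-norm")
})

test_that("per-bin gene embeddings are means of per-cell embeddings", {
  fx <- tiny_vocab_model()
  v <- fx$vocab
  # a stratum of identical cells: the bin mean equals any cell's vectors
  study <- fx$study
  tok <- fx$tokens
  cell <- 1L
  same <- which(apply(tok, 1, function(r) all(r == tok[cell, ])))
  # force at least two identical rows by duplicating the study cell
  tok2 <- tok
  tok2[2, ] <- tok2[1, ]
  study2 <- study
  study2$cell_meta$age_bin[2] <- study2$cell_meta$age_bin[1]
  study2$cell_meta$tissue[2] <- study2$cell_meta$tissue[1]
  study2$cell_meta$disease[2] <- study2$cell_meta$disease[1]
  trajs <- gene_age_embeddings(fx$model, study2, "all", min_cells = 1L,
                               tokens = tok2, center = FALSE)
  H <- contextual_embeddings(fx$model, tok2[1, ])
  b <- study2$cell_meta$age_bin[1]
  bi <- match(b, trajs$bins)
  n_in_bin <- sum(study2$cell_meta$age_bin == b)
  # mean over the bin equals the column mean of contributing cells;
  # check against a direct recomputation
  rows <- which(study2$cell_meta$age_bin == b)
  Hs <- lapply(rows, function(r) contextual_embeddings(fx$model, tok2[r, ]))
  direct <- Reduce(`+`, Hs) / length(Hs)
  expect_equal(trajs$E[bi, , ], direct[-(1:4), ], tolerance = 1e-10)
  expect_equal(trajs$age_E[bi, ], direct[1, ], tolerance = 1e-10)
})

test_that("centered trajectories equal raw trajectories minus the per-cell gene mean", {
  fx <- tiny_vocab_model()
  raw <- gene_age_embeddings(fx$model, fx$study, "all", min_cells = 1L,
                             tokens = fx$tokens, center = FALSE)
  cen <- gene_age_embeddings(fx$model, fx$study, "all", min_cells = 1L,
                             tokens = fx$tokens, center = TRUE)
  # manual recomputation for one bin: centering each cell then averaging
  b <- raw$bins[1]
  rows <- which(fx$study$cell_meta$age_bin == b)
  L <- fx$vocab$seq_len
  mats <- lapply(rows, function(r) {
    H <- contextual_embeddings(fx$model, fx$tokens[r, ])[-(1:4), , drop = FALSE]
    sweep(H, 2, colMeans(H))
  })
  direct <- Reduce(`+`, mats) / length(mats)
  expect_equal(cen$E[1, , ], direct, tolerance = 1e-10)
  # the age-token trajectory is identical in both (never centered)
  expect_equal(cen$age_E, raw$age_E, tolerance = 1e-12)
})

test_that("unsupported bins are dropped and an all-unsupported stratum errors", {
  fx <- tiny_vocab_model()
  expect_error(gene_age_embeddings(fx$model, fx$study, "all",
                                   min_cells = 10000L, tokens = fx$tokens),
               "min_cells")
  trajs <- gene_age_embeddings(fx$model, fx$study, "all", min_cells = 1L,
                               tokens = fx$tokens)
  expect_true(all(trajs$support >= 1))
  expect_equal(trajs$bins, sort(trajs$bins))
})

test_that("trajectories are invariant to cell order", {
  fx <- tiny_vocab_model()
  t1 <- gene_age_embeddings(fx$model, fx$study, "all", min_cells = 1L,
                            tokens = fx$tokens)
  set.seed(8)
  perm <- sample(nrow(fx$tokens))
  study_p <- fx$study
  study_p$cell_meta <- study_p$cell_meta[perm, ]
  t2 <- gene_age_embeddings(fx$model, study_p, "all", min_cells = 1L,
                            tokens = fx$tokens[perm, , drop = FALSE])
  expect_equal(t1$E, t2$E, tolerance = 1e-10)
})

test_that("token similarity ranking is ordered, bounded, and tie-stable", {
  fx <- tiny_vocab_model()
  model <- fx$model
  # two tissues with identical static embeddings -> tied scores, ordered
  # by token id
  v <- model$vocab
  s <- simulate_corpus(sim_config(n_genes = 6, n_cells = 90, n_age_bins = 3,
                                  n_tissues = 3, n_cell_types = 1,
                                  diseased_fraction = 0.5, seed = 6))
  v3 <- build_vocabulary(s, 3)
  m3 <- init_mlm(v3, model_config(d = 16, n_layers = 1, n_heads = 2,
                                  d_ff = 24, seed = 3))
  tis_ids <- v3$tokens$token_id[v3$tokens$category == "tissue"]
  m3$params$E_tok[tis_ids[2] + 1, ] <- m3$params$E_tok[tis_ids[1] + 1, ]
  rk <- token_similarity_ranking(m3, "tissue")
  expect_equal(nrow(rk), 3)
  expect_true(all(rk$score >= -1 & rk$score <= 1))
  expect_equal(rk$rank, 1:3)
  expect_true(all(diff(rk$score) <= 0))
  tied <- rk[rk$score == rk$score[match(tis_ids[1], rk$token_id)], ]
  if (nrow(tied) >= 2) expect_equal(tied$token_id, sort(tied$token_id))

  rk1 <- token_similarity_ranking(fx$model, "cell_type")
  expect_equal(nrow(rk1), fx$vocab$n_cell_types)
})

test_that("gene-age similarity trajectories cover the trivial cases", {
  A <- matrix(c(1, 0, 0, 1, 1, 1), 3, 2, byrow = TRUE)
  rownames(A) <- 0:2
  traj_same <- new_gene_trajectory("g", A, bins = 0:2)
  sim <- gene_age_similarity_trajectory(traj_same, A)
  expect_equal(sim$similarity, rep(1, 3))

  B <- A[, 2:1]
  B[1, ] <- c(0, 1)  # orthogonal to A's first row
  B[2, ] <- c(1, 0)
  B[3, ] <- c(1, -1)
  traj_orth <- new_gene_trajectory("g", B, bins = 0:2)
  sim0 <- gene_age_similarity_trajectory(traj_orth, A)
  expect_equal(sim0$similarity, rep(0, 3))

  # disjoint bins error
  traj_late <- new_gene_trajectory("g", A, bins = 5:7)
  expect_error(gene_age_similarity_trajectory(traj_late, A), "no age bin")
})

test_that("healthy and diseased strata are disjoint cell sets", {
  s <- small_study()
  h <- stratum_cells(s, list(disease = 0L))
  d <- stratum_cells(s, list(disease = 1L))
  expect_length(intersect(h, d), 0)
  expect_equal(sort(c(h, d)), seq_len(nrow(s$cell_meta)))
})
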