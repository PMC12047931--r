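test_that("model configuration is validated", {
  expect_error(model_config(d = 30, n_heads = 4), "divisible")
  expect_error(model_config(lr = 0), "lr")
  expect_error(model_config(dropout = 1), "dropout")
  expect_error(model_config(gene_mask_rate = 1.5), "mask rates")
})

test_that("seeded initialization is reproducible", {
  v <- small_vocab()
  cfg <- small_model_config(seed = 77L)
  m1 <- init_mlm(v, cfg)
  m2 <- init_mlm(v, cfg)
  expect_identical(m1$params, m2$params)
})

test_that("an untrained model predicts near-uniformly (entropy near log k)", {
  fx <- tiny_vocab_model()
  set.seed(3)
  ms <- mask_sequence(fx$tokens[1, ], fx$vocab, 0.85, 0.5)
  P <- predict_masked(fx$model, ms)
  H <- apply(P, 1, token_entropy)
  expect_true(all(H > 0.995 * log(fx$vocab$k)))
})

test_that("analytic gradients match central finite differences", {
  fx <- tiny_vocab_model()
  cfg <- fx$model$config
  set.seed(9)
  mb <- camap:::mask_batch(fx$tokens[1:3, ], fx$vocab, 0.5, 0.5,
                           meta_weight = 5)
  loss_of <- function(params) {
    camap:::cpp_mlm_train_batch(mb$tokens, mb$targets, mb$weights, params,
                                cfg$n_layers, cfg$n_heads, 0, 0L, FALSE)$loss
  }
  out <- camap:::cpp_mlm_train_batch(mb$tokens, mb$targets, mb$weights,
                                     fx$model$params, cfg$n_layers,
                                     cfg$n_heads, 0, 0L, TRUE)
  set.seed(11)
  h <- 1e-5
  for (j in seq_along(fx$model$params)) {
    for (rep in 1:2) {
      i <- sample(length(fx$model$params[[j]]), 1)
      pp <- fx$model$params; pp[[j]][i] <- pp[[j]][i] + h
      pm <- fx$model$params; pm[[j]][i] <- pm[[j]][i] - h
      num <- (loss_of(pp) - loss_of(pm)) / (2 * h)
      ana <- out$grads[[j]][i]
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4)
    }
  }
})

test_that("training reduces held-out loss below the uniform baseline", {
  model <- small_model()
  v <- small_vocab()
  trace <- model$loss_trace
  expect_equal(nrow(trace), model$config$epochs)
  expect_true(all(is.finite(trace$train_loss)))
  expect_lt(tail(trace$val_loss, 1), log(v$k))
  # and below the untrained model's held-out loss
  untrained <- init_mlm(v, small_model_config())
  set.seed(model$config$seed + 1L)
  n <- nrow(small_tokens())
  val_idx <- sort(sample.int(n, round(0.1 * n)))
  vm <- camap:::mask_batch(small_tokens()[val_idx, , drop = FALSE], v,
                           0.85, 0.15, age_view_rate = 0.3)
  base_loss <- camap:::eval_loss(untrained, vm$tokens, vm$targets)
  expect_lt(tail(trace$val_loss, 1), base_loss)
})

test_that("zero epochs return the model unchanged; same seed gives same loss", {
  v <- small_vocab()
  m0 <- init_mlm(v, small_model_config(epochs = 0L))
  m1 <- train_mlm(m0, small_tokens())
  expect_identical(m0$params, m1$params)

  cfg <- small_model_config(seed = 21L, epochs = 1L)
  ma <- train_mlm(init_mlm(v, cfg), small_tokens())
  mb <- train_mlm(init_mlm(v, cfg), small_tokens())
  expect_lt(abs(tail(ma$loss_trace$val_loss, 1) -
                  tail(mb$loss_trace$val_loss, 1)), 1e-6)
  expect_equal(ma$params, mb$params, tolerance = 1e-12)
})

test_that("non-finite loss aborts with a diagnostic", {
  v <- small_vocab()
  m <- init_mlm(v, small_model_config(epochs = 1L))
  m$params$E_tok[1, 1] <- NaN
  expect_error(train_mlm(m, small_tokens()), "diverged")
})

test_that("contextual embeddings are deterministic, finite, and age-sensitive", {
  fx <- tiny_vocab_model()
  v <- fx$vocab
  H <- contextual_embeddings(fx$model, fx$tokens[1, ])
  expect_equal(dim(H), c(v$seq_len, fx$model$config$d))
  expect_true(all(is.finite(H)))
  expect_identical(H, contextual_embeddings(fx$model, fx$tokens[1, ]))

  # two identical cells give identical embedding matrices
  two <- rbind(fx$tokens[1, ], fx$tokens[1, ])
  H2 <- contextual_embeddings(fx$model, two)
  expect_equal(H2[1:v$seq_len, ], H2[v$seq_len + 1:v$seq_len, ])

  # changing only the age token displaces at least one gene embedding
  seq2 <- fx$tokens[1, ]
  cur <- seq2[1] - v$offsets[["age"]]
  seq2[1] <- v$offsets[["age"]] + ((cur + 1L) %% v$n_age_bins)
  Hb <- contextual_embeddings(fx$model, seq2)
  disp <- sqrt(rowSums((Hb - H)^2))[-(1:4)]
  expect_gt(max(disp), 0)
})

test_that("predict_masked returns normalized distributions; vacuous mask is empty", {
  fx <- tiny_vocab_model()
  set.seed(5)
  ms <- mask_sequence(fx$tokens[2, ], fx$vocab, 0.5, 1)
  P <- predict_masked(fx$model, ms)
  expect_equal(ncol(P), fx$vocab$k)
  expect_true(all(abs(rowSums(P) - 1) <= 1e-6))
  expect_true(all(P >= 0))
  P0 <- predict_masked(fx$model, fx$tokens[2, ])
  expect_equal(nrow(P0), 0)
})

test_that("token_embedding returns rows of the embedding table", {
  fx <- tiny_vocab_model()
  e <- token_embedding(fx$model, 3L)
  expect_equal(e[1, ], fx$model$params$E_tok[4, ])
  expect_error(token_embedding(fx$model, fx$vocab$k), "out of range")
  expect_error(token_embedding(fx$model, -1L), "out of range")
  expect_equal(cosine_similarity(e[1, ], e[1, ]), 1)
})

test_that("the trained model beats the most-frequent-bin base rate on masked genes", {
  model <- small_model()
  v <- small_vocab()
  tok <- small_tokens()
  val <- model$val_cells
  set.seed(13)
  correct <- 0L; total <- 0L; targets_all <- integer(0)
  for (i in val[seq_len(min(60, length(val)))]) {
    ms <- mask_sequence(tok[i, ], v, 0.85, 0)
    P <- predict_masked(model, ms)
    pred <- max.col(P) - 1L
    correct <- correct + sum(pred == ms$targets)
    total <- total + length(ms$targets)
    targets_all <- c(targets_all, ms$targets)
  }
  base_rate <- max(table(targets_all)) / length(targets_all)
  expect_gt(correct / total, base_rate)
})

test_that("checkpoints round-trip and corruption is reported", {
  fx <- tiny_vocab_model()
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fx$model, path)
  m2 <- load_checkpoint(path)
  expect_identical(m2$params, fx$model$params)
  expect_true(file.exists(paste0(path, ".json")))
  writeLines("garbage", path)
  expect_error(load_checkpoint(path), "corrupted|unreadable")
})
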