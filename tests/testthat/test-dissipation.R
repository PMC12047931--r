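test_that("drift matches closed forms", {
  tr <- new_gene_trajectory("g", rbind(c(0, 0), c(3, 4)), bins = 0:1)
  dp <- drift(tr)
  expect_equal(dp$drift, c(0, 5))
  expect_equal(dp$max_drift, 5)

  const <- new_gene_trajectory("g", matrix(2, 4, 3), bins = 0:3)
  expect_equal(drift(const)$drift, rep(0, 4))

  single <- new_gene_trajectory("g", matrix(1, 1, 3), bins = 0L)
  expect_error(drift(single), "at least two")
})

test_that("drift and variance match brute-force recomputation", {
  tr <- random_trajectory(n_bins = 5, d = 8, seed = 14)
  dp <- drift(tr)
  ev <- embedding_variance(tr)
  # independent element-wise loops
  D <- numeric(5)
  for (t in 1:5) {
    acc <- 0
    for (j in 1:8) acc <- acc + (tr$E[t, j] - tr$E[1, j])^2
    D[t] <- sqrt(acc)
  }
  expect_equal(dp$drift, D, tolerance = 1e-12)
  expect_equal(dp$drift[1], 0)
  Ebar <- numeric(8)
  for (j in 1:8) Ebar[j] <- sum(tr$E[, j]) / 5
  s2 <- 0
  for (t in 1:5) {
    acc <- 0
    for (j in 1:8) acc <- acc + (tr$E[t, j] - Ebar[j])^2
    s2 <- s2 + acc
  }
  expect_equal(ev$mean_E, Ebar, tolerance = 1e-12)
  expect_equal(ev$sigma2, s2 / 5, tolerance = 1e-12)
})

test_that("variance closed forms hold and sigma2 = 0 iff constant", {
  tr <- new_gene_trajectory("g", rbind(c(0, 0), c(2, 0)), bins = 0:1)
  ev <- embedding_variance(tr)
  expect_equal(ev$mean_E, c(1, 0))
  expect_equal(ev$sigma2, 1)

  const <- new_gene_trajectory("g", matrix(5, 3, 2), bins = 0:2)
  expect_equal(embedding_variance(const)$sigma2, 0)
  expect_equal(drift(const)$max_drift, 0)

  # drift-variance consistency on random trajectories
  for (s in 1:5) {
    tr <- random_trajectory(4, 6, seed = 100 + s)
    zero_var <- embedding_variance(tr)$sigma2 == 0
    zero_drift <- all(drift(tr)$drift == 0)
    expect_equal(zero_var, zero_drift)
  }
})

test_that("percentile classification matches the hand-computed threshold", {
  prof <- data.frame(gene = paste0("g", 1:4),
                     max_drift = c(0.1, 0.2, 0.9, 1.0))
  cls <- classify_genes(prof, 50)
  expect_equal(cls$delta, 0.55)  # type-7 interpolation of {.1,.2,.9,1}
  expect_equal(cls$conservative, c("g1", "g2"))
  expect_equal(cls$dissipative, c("g3", "g4"))
  # partition property
  expect_setequal(c(cls$conservative, cls$dissipative), prof$gene)

  cls100 <- classify_genes(prof, 100)
  expect_length(cls100$dissipative, 0)

  tied <- data.frame(gene = paste0("g", 1:3), max_drift = rep(0.4, 3))
  for (q in c(10, 50, 90)) {
    expect_length(classify_genes(tied, q)$dissipative, 0)
  }
  expect_error(classify_genes(prof[1, , drop = FALSE], 50), "at least two")
  expect_error(classify_genes(prof, 0), "q")
})

test_that("drift is invariant under a global orthogonal rotation", {
  set.seed(19)
  d <- 12
  Q <- qr.Q(qr(matrix(rnorm(d * d), d, d)))
  tr <- random_trajectory(n_bins = 6, d = d, seed = 23)
  tr_rot <- new_gene_trajectory("g", tr$E %*% Q, bins = tr$bins)
  expect_equal(drift(tr_rot)$drift, drift(tr)$drift, tolerance = 1e-10)
  expect_equal(embedding_variance(tr_rot)$sigma2,
               embedding_variance(tr)$sigma2, tolerance = 1e-10)
})

test_that("condition contrast covers identical and degenerate profiles", {
  prof <- data.frame(gene = paste0("g", 1:4),
                     max_drift = c(0.1, 0.2, 0.9, 1.0))
  con <- condition_contrast(prof, prof, q = 50)
  expect_equal(con$table$ratio, rep(1, 4))
  expect_true(all(con$table$change %in% c("C->C", "D->D")))

  prof0 <- prof; prof0$max_drift[1] <- 0
  con0 <- condition_contrast(prof0, prof, q = 50)
  expect_true(con0$table$floored[1])
  expect_equal(con0$table$ratio[1], 0.1 / 1e-9)

  prof_other <- prof; prof_other$gene <- rev(prof_other$gene)
  expect_error(condition_contrast(prof, prof_other), "same genes")
})

test_that("planted dissipative genes out-drift conservative ones in rank", {
  model <- small_model()
  s <- small_study()
  trajs <- gene_age_embeddings(model, s, list(disease = 0L), min_cells = 10L,
                               tokens = small_tokens())
  prof <- drift_profiles(trajs)
  gt <- s$ground_truth
  w <- wilcox.test(prof$max_drift[gt$dissipative_genes],
                   prof$max_drift[gt$conservative_genes],
                   alternative = "greater")
  expect_lt(w$p.value, 0.05)
  # drift matrix baseline column is exactly zero
  D <- attr(prof, "drift_matrix")
  expect_equal(unname(D[1, ]), rep(0, ncol(D)))
})

test_that("Lipschitz ratios are finite, seeded, and exclude null perturbations", {
  fx <- tiny_vocab_model()
  est1 <- estimate_lipschitz(fx$model, fx$tokens, n_pairs = 30, seed = 4)
  est2 <- estimate_lipschitz(fx$model, fx$tokens, n_pairs = 30, seed = 4)
  expect_identical(est1$ratios, est2$ratios)
  expect_true(all(is.finite(est1$ratios$ratio)))
  expect_true(all(est1$ratios$ratio >= 0))
  expect_gte(est1$L_max, est1$L_min)
  expect_true(all(est1$ratios$dx + est1$ratios$dt_years > 0))

  est_d <- estimate_lipschitz(fx$model, fx$tokens, n_pairs = 30,
                              dissipative_genes = 1:2, perturb = "gene",
                              seed = 4)
  pool <- est_d$ratios[est_d$ratios$gene %in% 1:2, ]
  expect_equal(est_d$L_min, min(pool$ratio))
})

test_that("flip enrichment counts the 2x2 table correctly", {
  tab <- data.frame(gene = paste0("g", 1:6),
                    drift_healthy = 1, drift_diseased = 1, ratio = 1,
                    floored = FALSE,
                    label_healthy = c("conservative", "conservative",
                                      "conservative", "conservative",
                                      "dissipative", "dissipative"),
                    label_diseased = c("dissipative", "conservative",
                                       "dissipative", "conservative",
                                       "dissipative", "conservative"),
                    change = c("C->D", "C->C", "C->D", "C->C",
                               "D->D", "D->C"))
  con <- structure(list(table = tab, q = 80, delta_healthy = 1,
                        delta_diseased = 1), class = "camap_contrast")
  fe <- flip_enrichment(con, c("g1", "g3"))
  expect_equal(unname(fe$table["in_set", "C->D"]), 2)
  expect_equal(unname(fe$table["in_set", "stable"]), 0)
  expect_equal(unname(fe$table["other", "C->D"]), 0)
  expect_equal(unname(fe$table["other", "stable"]), 2)
  expect_gt(fe$log_odds, 0)
})
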