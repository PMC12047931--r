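test_that("identical config and seed reproduce the corpus bit-identically", {
  cfg <- small_sim_config(seed = 7L)
  s1 <- simulate_corpus(cfg)
  s2 <- simulate_corpus(cfg)
  expect_identical(as.matrix(s1$counts), as.matrix(s2$counts))
  expect_identical(s1$cell_meta, s2$cell_meta)
  expect_identical(s1$ground_truth, s2$ground_truth)
  expect_identical(s1$latent_mu, s2$latent_mu)
})

test_that("counts are integral, non-negative, and metadata is consistent", {
  s <- small_study()
  x <- s$counts@x
  expect_true(all(x >= 0))
  expect_true(all(x == round(x)))
  expect_equal(nrow(s$cell_meta), nrow(s$counts))
  expect_true(all(s$cell_meta$age_bin >= 0 &
                    s$cell_meta$age_bin < s$n_age_bins))
  expect_equal(s$cell_meta$age_years,
               s$age_midpoints[s$cell_meta$age_bin + 1])
  gt <- s$ground_truth
  expect_length(intersect(gt$dissipative_genes, gt$conservative_genes), 0)
  expect_setequal(c(gt$dissipative_genes, gt$conservative_genes),
                  seq_along(s$gene_ids))
  expect_true(all(gt$disease_flipped_genes %in% gt$conservative_genes))
})

test_that("every (age bin, tissue, disease) stratum is populated", {
  s <- small_study()
  tab <- table(s$cell_meta$age_bin, s$cell_meta$tissue, s$cell_meta$disease)
  expect_true(all(tab >= 1))
})

test_that("infeasible stratification errors and names the empty stratum", {
  expect_error(
    simulate_corpus(sim_config(n_genes = 10, n_cells = 20, n_age_bins = 10,
                               n_tissues = 3, diseased_fraction = 0.3,
                               seed = 1)),
    "infeasible stratification.*age_bin")
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_age_bins = 2), "n_age_bins")
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(frac_dissipative = 1.2), "frac_dissipative")
  expect_error(sim_config(diseased_fraction = -0.1), "diseased_fraction")
  expect_error(sim_config(effect_size = -1), "effect_size")
  expect_error(sim_config(n_noise_tissues = 5, n_tissues = 2),
               "n_noise_tissues")
  expect_error(sim_config(tissue_age_accel = c(1, 2)), "tissue_age_accel")
})

# Cross-bin displacement of the latent per-bin mean log-expression,
# computed directly on the exposed latent matrix (healthy cells only, so
# disease flips do not contribute).
latent_displacement <- function(study) {
  healthy <- study$cell_meta$disease == 0
  mu <- study$latent_mu[healthy, , drop = FALSE]
  bins <- study$cell_meta$age_bin[healthy]
  per_bin <- apply(mu, 2, function(col) tapply(col, bins, mean))
  apply(per_bin, 2, function(m) mean(abs(m - m[1])))
}

test_that("dissipative genes displace their latent means more than conservative ones", {
  s <- small_study()
  disp <- latent_displacement(s)
  gt <- s$ground_truth
  expect_gt(mean(disp[gt$dissipative_genes]),
            2 * mean(disp[gt$conservative_genes]))
})

test_that("zero effect size leaves planted labels statistically indistinguishable", {
  s0 <- simulate_corpus(small_sim_config(seed = 9L, effect_size = 0))
  disp <- latent_displacement(s0)
  gt <- s0$ground_truth
  ratio <- mean(disp[gt$dissipative_genes]) / mean(disp[gt$conservative_genes])
  expect_lt(abs(log(ratio)), log(1.5))
})

test_that("dispersion in the noise-ramp tissue increases monotonically with age", {
  cfg <- sim_config(n_genes = 50, n_cells = 12000, n_age_bins = 5,
                    n_tissues = 2, n_cell_types = 1, diseased_fraction = 0,
                    noise_age_slope = 0.3, n_noise_tissues = 1, seed = 21)
  s <- simulate_corpus(cfg)
  ramp <- s$ground_truth$noise_ramp_tissues[1]
  counts <- as.matrix(s$counts)
  # conservative genes have an age-constant latent mean, so their
  # variance/mean ratio isolates the dispersion ramp
  cons <- s$ground_truth$conservative_genes
  keep <- s$cell_meta$tissue == ramp
  bins <- s$cell_meta$age_bin[keep]
  vm_per_bin <- vapply(sort(unique(bins)), function(b) {
    sub <- counts[keep, cons, drop = FALSE][bins == b, , drop = FALSE]
    mu <- colMeans(sub)
    v <- apply(sub, 2, var)
    ok <- mu > 2
    mean(v[ok] / mu[ok])  # empirical dispersion proxy per bin
  }, numeric(1))
  expect_true(all(diff(vm_per_bin) > 0))
})

test_that("negative-binomial marginals match the latent means", {
  cfg <- sim_config(n_genes = 30, n_cells = 6000, n_age_bins = 3,
                    n_tissues = 1, n_cell_types = 1, diseased_fraction = 0,
                    seed = 33)
  s <- simulate_corpus(cfg)
  counts <- as.matrix(s$counts)
  for (b in 0:2) {
    keep <- s$cell_meta$age_bin == b
    expect_gte(sum(keep), 2000)
    emp <- colMeans(counts[keep, , drop = FALSE])
    lat <- colMeans(exp(s$latent_mu[keep, , drop = FALSE]))
    ok <- lat > 0.5
    expect_lt(max(abs(emp[ok] - lat[ok]) / lat[ok]), 0.1)
  }
})

test_that("a fast-aging tissue expresses an older latent program", {
  cfg <- small_sim_config(seed = 15L, tissue_age_accel = c(1, 1.8))
  s <- simulate_corpus(cfg)
  meta <- s$cell_meta
  # mid-life bin of the accelerated tissue should match a later bin of
  # the nominal tissue better than the same bin
  b <- 2L
  mu_acc <- colMeans(s$latent_mu[meta$tissue == 1 & meta$age_bin == b &
                                   meta$disease == 0, , drop = FALSE])
  mu_same <- colMeans(s$latent_mu[meta$tissue == 0 & meta$age_bin == b &
                                    meta$disease == 0, , drop = FALSE])
  mu_old <- colMeans(s$latent_mu[meta$tissue == 0 & meta$age_bin == 4 &
                                   meta$disease == 0, , drop = FALSE])
  gt <- s$ground_truth
  dg <- gt$dissipative_genes
  # compare on dissipative genes (the age-coupled ones), ignoring the
  # tissue offset via centering
  d_same <- sum(((mu_acc - mean(mu_acc)) - (mu_same - mean(mu_same)))[dg]^2)
  d_old <- sum(((mu_acc - mean(mu_acc)) - (mu_old - mean(mu_old)))[dg]^2)
  expect_lt(d_old, d_same)
})
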