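test_that("vocabulary size is the sum of its category sizes", {
  s <- simulate_corpus(sim_config(n_genes = 5, n_cells = 300, n_age_bins = 10,
                                  n_tissues = 3, n_cell_types = 4,
                                  diseased_fraction = 0.3, seed = 4))
  v <- build_vocabulary(s, n_bins = 8)
  # (8+1) value bins + 10 age + 3 tissue + 4 cell type + 2 disease + 2 special
  expect_equal(v$k, 30)
  expect_equal(v$tokens$token_id, 0:29)
  expect_equal(anyDuplicated(v$tokens$token_id), 0L)
  expect_equal(as.integer(table(v$tokens$category)[
    c("value_bin", "age", "tissue", "cell_type", "disease", "special")]),
    c(9L, 10L, 3L, 4L, 2L, 2L))
})

test_that("vocabulary construction is deterministic and validates n_bins", {
  s <- small_study()
  expect_identical(build_vocabulary(s, 6), build_vocabulary(s, 6))
  expect_error(build_vocabulary(s, 1), "n_bins")
})

test_that("rank binning matches hand-computed cases", {
  expect_equal(bin_expression(c(0, 5, 10), 2), c(0L, 1L, 2L))
  expect_equal(bin_expression(rep(0, 7), 4), rep(0L, 7))
  expect_equal(bin_expression(c(7, 7, 7), 3), c(1L, 2L, 3L))
  expect_error(bin_expression(c(-1, 2), 2), "negative")
})

test_that("binning is monotone and scale-free", {
  set.seed(31)
  for (i in 1:20) {
    x <- rpois(40, 3)
    b <- bin_expression(x, 8)
    expect_identical(bin_expression(x * sample(1:7, 1), 8), b)
    o <- order(x)
    expect_true(all(diff(b[o]) >= 0 | diff(x[o]) > 0))
    # higher count implies bin at least as high
    for (pair in list(sample(40, 2))) {
      lo <- pair[which.min(x[pair])]; hi <- pair[which.max(x[pair])]
      if (x[lo] < x[hi]) expect_lte(b[lo], b[hi])
    }
  }
})

test_that("encode_cell places metadata and bins at the fixed layout", {
  s <- small_study()
  v <- build_vocabulary(s, 2)
  seqv <- encode_cell(c(0, 5, rep(0, v$n_genes - 2)), 2L, 0L, 1L, 0L, v)
  expect_length(seqv, v$seq_len)
  expect_equal(seqv[1], v$offsets[["age"]] + 2L)
  expect_equal(seqv[2], v$offsets[["tissue"]] + 0L)
  expect_equal(seqv[3], v$offsets[["cell_type"]] + 1L)
  expect_equal(seqv[4], v$offsets[["disease"]] + 0L)
  expect_equal(seqv[5], 0L)        # zero count -> BIN_0
  expect_equal(seqv[6], 2L)        # single non-zero -> top bin
  dec <- decode_cell(seqv, v)
  expect_equal(dec$age_bin, 2L)
  expect_equal(dec$tissue, 0L)
  expect_equal(dec$cell_type, 1L)
  expect_equal(dec$disease, 0L)
  expect_error(encode_cell(rep(0, v$n_genes), 0L, 99L, 0L, 0L, v),
               "unknown tissue")
  expect_error(encode_cell(rep(0, v$n_genes), 99L, 0L, 0L, 0L, v),
               "unknown age bin")
})

test_that("encode_study matches per-cell encoding", {
  s <- small_study(); v <- small_vocab()
  tok <- small_tokens()
  expect_equal(dim(tok), c(nrow(s$counts), v$seq_len))
  for (i in c(1L, 17L, nrow(tok))) {
    m <- s$cell_meta[i, ]
    expect_equal(tok[i, ],
                 encode_cell(as.numeric(s$counts[i, ]), m$age_bin, m$tissue,
                             m$cell_type, m$disease, v))
  }
})

test_that("masking count is exact, seeded, and respects the age flag", {
  s <- small_study(); v <- small_vocab(); tok <- small_tokens()
  n_mask <- round(0.85 * v$n_genes)
  set.seed(1)
  ms <- mask_sequence(tok[1, ], v, 0.85, 0.15)
  expect_equal(sum(ms$mask[-(1:4)]), n_mask)
  expect_equal(sum(ms$tokens == v$mask_id), sum(ms$mask))
  expect_equal(ms$targets, tok[1, ][ms$mask])
  set.seed(1)
  ms2 <- mask_sequence(tok[1, ], v, 0.85, 0.15)
  expect_identical(ms, ms2)

  ms0 <- mask_sequence(tok[1, ], v, 0, 0)
  expect_equal(sum(ms0$mask), 0)
  expect_identical(ms0$tokens, tok[1, ])

  for (i in 1:20) {
    msa <- mask_sequence(tok[1, ], v, 0.85, 1, keep_age = TRUE)
    expect_false(msa$mask[1])
    expect_true(all(msa$mask[2:4]))
  }
  expect_error(mask_sequence(tok[1, ], v, 1.2, 0), "mask rates")
})

test_that("masking count is exact across rates and gene counts", {
  s <- small_study(); v <- small_vocab(); tok <- small_tokens()
  set.seed(2)
  for (rate in c(0.1, 0.33, 0.5, 0.85, 1)) {
    ms <- mask_sequence(tok[3, ], v, rate, 0)
    expect_equal(sum(ms$mask), round(rate * v$n_genes))
  }
})
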