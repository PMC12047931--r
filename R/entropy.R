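#' Shannon entropy of a predictive distribution
#'
#' `H = -sum_i p_i log p_i` with the convention `0 log 0 = 0`. Natural
#' log by default, so `H` lies in `[0, log(k)]` for a distribution over
#' `k` tokens; `base = 2` gives bits.
#'
#' @param dist Non-negative probability vector summing to 1 within
#'   `tol`.
#' @param base Logarithm base (default `exp(1)`, nats).
#' @param tol Normalization tolerance.
#' @return Entropy (scalar, >= 0).
#' @examples
#' token_entropy(rep(1 / 4, 4))  # log(4)
#' @export
token_entropy <- function(dist, base = exp(1), tol = 1e-6) {
  if (any(dist < 0)) stop("probabilities must be non-negative")
  if (abs(sum(dist) - 1) > tol)
    stop(sprintf("distribution sums to %.8f, not 1 (tolerance %g)",
                 sum(dist), tol))
  p <- dist[dist > 0]
  -sum(p * log(p, base = base))
}

# Entropy of every row of a probability matrix (rows already normalized).
row_entropies <- function(P, base = exp(1)) {
  Pl <- P
  Pl[Pl <= 0] <- 1  # 0 log 0 = 0
  -rowSums(P * log(Pl, base = base))
}

#' Masked-token entropy records across a study
#'
#' For each sampled cell, masks `m` randomly chosen gene positions one at
#' a time — every other position stays visible, and the age token stays
#' visible iff `condition_on_age` — and scores the Shannon entropy of the
#' model's predictive distribution over the full vocabulary at the masked
#' position. High entropy reads as loss of molecular specificity: the
#' context no longer pins down the token.
#'
#' @param model A trained `camap_mlm`.
#' @param study The `camap_study`.
#' @param cells Cell row indices to profile (default: all; sampled down
#'   to `max_cells`).
#' @param m Gene positions scored per cell (uniform without replacement,
#'   so the per-cell mean entropy is an unbiased estimate over genes).
#' @param condition_on_age Keep the age token visible while predicting.
#' @param max_cells Upper bound on profiled cells.
#' @param tokens Optional pre-encoded token matrix.
#' @param base Log base for the entropy.
#' @param batch_size Sequences per forward pass.
#' @param seed Integer seed for cell and position sampling.
#' @return Data frame (`cell_id`, `position`, `gene`, `H`, `age_bin`,
#'   `tissue`, `cell_type`, `disease`, `conditioned_on_age`); zero rows
#'   when `m = 0`.
#' @export
masked_entropy_profile <- function(model, study, cells = NULL, m = 32L,
                                   condition_on_age = TRUE, max_cells = 200L,
                                   tokens = NULL, base = exp(1),
                                   batch_size = 64L, seed = 1L) {
  stopifnot(inherits(model, "camap_mlm"), inherits(study, "camap_study"))
  vocab <- model$vocab
  m <- as.integer(m)
  if (m < 0L) stop("'m' must be >= 0")
  if (m > vocab$n_genes)
    stop(sprintf("m = %d exceeds the %d available gene positions", m,
                 vocab$n_genes))
  set.seed(seed)
  if (is.null(cells)) cells <- seq_len(nrow(study$cell_meta))
  if (length(cells) > max_cells) cells <- sort(sample(cells, max_cells))
  if (m == 0L || length(cells) == 0L)
    return(data.frame(cell_id = character(0), position = integer(0),
                      gene = character(0), H = numeric(0),
                      age_bin = integer(0), tissue = integer(0),
                      cell_type = integer(0), disease = integer(0),
                      conditioned_on_age = logical(0)))
  if (is.null(tokens)) tokens <- encode_study(study, model$vocab)

  n_q <- length(cells) * m
  seqs <- matrix(0L, n_q, vocab$seq_len)
  pos <- integer(n_q)
  cell_of <- integer(n_q)
  row <- 0L
  for (ci in seq_along(cells)) {
    base_seq <- tokens[cells[ci], ]
    gene_pos <- 4L + sample.int(vocab$n_genes, m)
    for (p in gene_pos) {
      row <- row + 1L
      s <- base_seq
      s[p] <- vocab$mask_id
      if (!condition_on_age) s[1L] <- vocab$mask_id
      seqs[row, ] <- s
      pos[row] <- p
      cell_of[row] <- cells[ci]
    }
  }
  H <- numeric(n_q)
  for (start in seq(1L, n_q, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n_q)
    sel <- cbind(seq_along(idx), pos[idx])
    logits <- batch_logits(model, seqs[idx, , drop = FALSE], sel)
    H[idx] <- row_entropies(softmax_rows(logits), base = base)
  }
  meta <- study$cell_meta[cell_of, , drop = FALSE]
  data.frame(cell_id = meta$cell_id, position = pos,
             gene = vocab$gene_ids[pos - 4L], H = H,
             age_bin = meta$age_bin, tissue = meta$tissue,
             cell_type = meta$cell_type, disease = meta$disease,
             conditioned_on_age = condition_on_age,
             stringsAsFactors = FALSE)
}

#' Entropy summaries by age bin
#'
#' Summarizes entropy records per (age bin, disease flag) and reports
#' the Spearman rank correlation of the per-bin mean entropy against the
#' bin index, overall and per disease group. A degenerate (constant)
#' profile yields `NA` correlations, reported as not applicable.
#'
#' @param records [masked_entropy_profile()] output.
#' @param stratum Optional stratum filter applied to the records
#'   (named list with `tissue` / `cell_type` / `disease`).
#' @return List with `table` (per `age_bin` x `disease`: `n`, `mean_H`,
#'   `sd_H`, `q25`, `median_H`, `q75`), `spearman` (overall),
#'   `spearman_by_disease` (named vector).
#' @export
entropy_by_age <- function(records, stratum = NULL) {
  if (!is.null(stratum)) {
    if (!is.null(stratum$tissue))
      records <- records[records$tissue %in% stratum$tissue, , drop = FALSE]
    if (!is.null(stratum$cell_type))
      records <- records[records$cell_type %in% stratum$cell_type, , drop = FALSE]
    if (!is.null(stratum$disease))
      records <- records[records$disease %in% stratum$disease, , drop = FALSE]
  }
  if (nrow(records) == 0L) stop("no entropy records after stratum filtering")
  key <- interaction(records$age_bin, records$disease, drop = TRUE)
  groups <- split(records, key)
  rows <- lapply(groups, function(gr) {
    qs <- stats::quantile(gr$H, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(age_bin = gr$age_bin[1L], disease = gr$disease[1L],
               n = nrow(gr), mean_H = mean(gr$H), sd_H = stats::sd(gr$H),
               q25 = qs[1L], median_H = qs[2L], q75 = qs[3L])
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$disease, tab$age_bin), , drop = FALSE]
  rownames(tab) <- NULL

  spearman_of <- function(tt) {
    if (nrow(tt) < 2L || stats::sd(tt$mean_H) == 0) return(NA_real_)
    suppressWarnings(stats::cor(tt$age_bin, tt$mean_H, method = "spearman"))
  }
  overall <- stats::aggregate(H ~ age_bin, data = records, FUN = mean)
  names(overall) <- c("age_bin", "mean_H")
  sp_all <- spearman_of(overall)
  sp_dis <- vapply(split(tab, tab$disease), spearman_of, numeric(1))
  list(table = tab, spearman = sp_all, spearman_by_disease = sp_dis)
}

#' Paired healthy-versus-diseased entropy difference
#'
#' Mean entropy difference (diseased minus healthy) across age bins
#' present in both conditions.
#'
#' @param records [masked_entropy_profile()] output containing both
#'   conditions.
#' @return List with `per_bin` (data frame `age_bin`, `mean_H_healthy`,
#'   `mean_H_diseased`, `diff`) and `mean_diff`.
#' @export
entropy_disease_difference <- function(records) {
  if (!any(records$disease == 0) || !any(records$disease == 1))
    stop("records must contain both healthy and diseased cells")
  h <- stats::aggregate(H ~ age_bin, data = records[records$disease == 0, ],
                        FUN = mean)
  d <- stats::aggregate(H ~ age_bin, data = records[records$disease == 1, ],
                        FUN = mean)
  merged <- merge(h, d, by = "age_bin", suffixes = c("_healthy", "_diseased"))
  if (nrow(merged) == 0L)
    stop("no age bin contains both healthy and diseased records")
  names(merged) <- c("age_bin", "mean_H_healthy", "mean_H_diseased")
  merged$diff <- merged$mean_H_diseased - merged$mean_H_healthy
  list(per_bin = merged, mean_diff = mean(merged$diff))
}
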