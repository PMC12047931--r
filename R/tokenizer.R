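#' Build the token vocabulary for a study
#'
#' The vocabulary covers, in order: expression-value bin tokens
#' `BIN_0 .. BIN_B` (`BIN_0` is reserved for zero counts), one age token
#' per age bin, tissue tokens, cell-type tokens, the two disease tokens
#' (`HEALTHY`, `DISEASED`) and the special tokens `MASK` and `PAD`.
#' Token ids are contiguous from 0 and the total size `k` is the
#' dictionary size used by the entropy bound `log(k)`. The gene-to-position
#' layout is fixed at build time: position 0 holds the age token,
#' positions 1-3 tissue, cell type and disease, and positions
#' `4 .. n_genes + 3` the expression-bin token of the gene at that
#' position (gene order = `study$gene_ids`).
#'
#' @param study A `camap_study`.
#' @param n_bins Number of non-zero expression bins `B` (>= 2).
#' @return An object of class `camap_vocab`.
#' @export
build_vocabulary <- function(study, n_bins = 8L) {
  stopifnot(inherits(study, "camap_study"))
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L) stop("'n_bins' must be >= 2")
  n_tissues <- max(study$cell_meta$tissue) + 1L
  n_cell_types <- max(study$cell_meta$cell_type) + 1L
  n_age <- study$n_age_bins

  labels <- c(sprintf("BIN_%d", 0:n_bins),
              sprintf("AGE_%d", 0:(n_age - 1L)),
              sprintf("TISSUE_%d", 0:(n_tissues - 1L)),
              sprintf("CT_%d", 0:(n_cell_types - 1L)),
              c("HEALTHY", "DISEASED"),
              c("MASK", "PAD"))
  category <- rep(c("value_bin", "age", "tissue", "cell_type", "disease",
                    "special"),
                  c(n_bins + 1L, n_age, n_tissues, n_cell_types, 2L, 2L))
  tokens <- data.frame(token_id = seq_along(labels) - 1L,
                       category = category, label = labels,
                       stringsAsFactors = FALSE)
  offsets <- c(value_bin = 0L,
               age = n_bins + 1L,
               tissue = n_bins + 1L + n_age,
               cell_type = n_bins + 1L + n_age + n_tissues,
               disease = n_bins + 1L + n_age + n_tissues + n_cell_types,
               special = n_bins + 1L + n_age + n_tissues + n_cell_types + 2L)
  structure(list(
    tokens = tokens,
    n_value_bins = n_bins,
    n_age_bins = n_age,
    n_tissues = n_tissues,
    n_cell_types = n_cell_types,
    offsets = offsets,
    mask_id = unname(offsets["special"]),
    pad_id = unname(offsets["special"]) + 1L,
    k = nrow(tokens),
    gene_ids = study$gene_ids,
    n_genes = length(study$gene_ids),
    n_meta = 4L,
    seq_len = 4L + length(study$gene_ids),
    age_midpoints = study$age_midpoints,
    age_bin_width = study$age_bin_width
  ), class = "camap_vocab")
}

#' @exportS3Method base::print
print.camap_vocab <- function(x, ...) {
  cat(sprintf(paste0("camap_vocab: k = %d tokens (%d value bins + %d age + ",
                     "%d tissue + %d cell type + 2 disease + 2 special); ",
                     "sequence length %d\n"),
              x$k, x$n_value_bins + 1L, x$n_age_bins, x$n_tissues,
              x$n_cell_types, x$seq_len))
  invisible(x)
}

#' Age token ids of a vocabulary
#' @param vocab A `camap_vocab`.
#' @return Integer vector of the age-token ids (0-based), ordered by bin.
#' @export
age_token_ids <- function(vocab) {
  vocab$offsets[["age"]] + 0:(vocab$n_age_bins - 1L)
}

#' Serialize a vocabulary as TSV
#' @param vocab A `camap_vocab`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  utils::write.table(vocab$tokens, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Rank-based expression binning of one count row
#'
#' Zero counts map to bin 0. Non-zero counts are rank-transformed within
#' the cell (ties broken by gene position, ascending) and cut into `B`
#' equal-frequency bins `1 .. B`: the value with within-cell rank `r` out
#' of `n` non-zero values lands in bin `ceiling(r * B / n)`. Binning is
#' therefore monotone in the count and invariant to any positive scaling
#' of the row (depth-robust).
#'
#' @param counts Non-negative numeric/integer vector (one cell).
#' @param n_bins Number of non-zero bins `B`.
#' @return Integer vector of bin indices in `0 .. B`.
#' @examples
#' bin_expression(c(0, 5, 10), 2)  # 0 1 2
#' @export
bin_expression <- function(counts, n_bins) {
  if (any(counts < 0)) stop("negative counts are not allowed")
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("'n_bins' must be >= 1")
  bins <- integer(length(counts))
  nz <- which(counts > 0)
  n <- length(nz)
  if (n > 0L) {
    o <- order(counts[nz], nz)           # ties broken by position, ascending
    r <- integer(n); r[o] <- seq_len(n)  # within-cell rank of each value
    bins[nz] <- as.integer(ceiling(r * n_bins / n))
  }
  bins
}

#' Encode one cell as a token sequence
#'
#' Positions 0-3 carry the metadata tokens (age, tissue, cell type,
#' disease); positions 4 onward carry the expression-bin token of the gene
#' canonically assigned to that position.
#'
#' @param counts Count vector of length `n_genes` (gene order of the
#'   vocabulary).
#' @param age_bin,tissue,cell_type,disease 0-based metadata ids.
#' @param vocab A `camap_vocab`.
#' @return Integer vector of 0-based token ids, length `vocab$seq_len`.
#' @export
encode_cell <- function(counts, age_bin, tissue, cell_type, disease, vocab) {
  if (length(counts) != vocab$n_genes)
    stop(sprintf("count row has %d genes, vocabulary expects %d",
                 length(counts), vocab$n_genes))
  if (age_bin < 0L || age_bin >= vocab$n_age_bins)
    stop(sprintf("unknown age bin %d (vocabulary has %d)", age_bin,
                 vocab$n_age_bins))
  if (tissue < 0L || tissue >= vocab$n_tissues)
    stop(sprintf("unknown tissue id %d (vocabulary has %d)", tissue,
                 vocab$n_tissues))
  if (cell_type < 0L || cell_type >= vocab$n_cell_types)
    stop(sprintf("unknown cell type id %d (vocabulary has %d)", cell_type,
                 vocab$n_cell_types))
  if (!disease %in% c(0L, 1L)) stop("'disease' must be 0 or 1")
  bins <- bin_expression(counts, vocab$n_value_bins)
  as.integer(c(vocab$offsets[["age"]] + age_bin,
               vocab$offsets[["tissue"]] + tissue,
               vocab$offsets[["cell_type"]] + cell_type,
               vocab$offsets[["disease"]] + disease,
               bins))
}

#' Decode a token sequence back to metadata and bin indices
#' @param tokens Integer token-id vector as produced by [encode_cell()].
#' @param vocab A `camap_vocab`.
#' @return List with `age_bin`, `tissue`, `cell_type`, `disease` and
#'   `bins` (expression bin per gene).
#' @export
decode_cell <- function(tokens, vocab) {
  stopifnot(length(tokens) == vocab$seq_len)
  list(age_bin = tokens[1] - vocab$offsets[["age"]],
       tissue = tokens[2] - vocab$offsets[["tissue"]],
       cell_type = tokens[3] - vocab$offsets[["cell_type"]],
       disease = tokens[4] - vocab$offsets[["disease"]],
       bins = tokens[-(1:4)])
}

#' Encode every cell of a study
#'
#' @param study A `camap_study`.
#' @param vocab A `camap_vocab` built from the same study.
#' @return Integer matrix `n_cells x seq_len` of 0-based token ids, with
#'   cell ids as row names.
#' @export
encode_study <- function(study, vocab) {
  stopifnot(inherits(study, "camap_study"), inherits(vocab, "camap_vocab"))
  tc <- methods::as(Matrix::t(study$counts), "CsparseMatrix")  # genes x cells
  n_cells <- ncol(tc)
  out <- matrix(0L, n_cells, vocab$seq_len)
  meta <- study$cell_meta
  p <- tc@p; i <- tc@i; xval <- tc@x
  for (c_ in seq_len(n_cells)) {
    idx <- if (p[c_ + 1L] > p[c_]) (p[c_] + 1L):p[c_ + 1L] else integer(0)
    row <- numeric(vocab$n_genes)
    row[i[idx] + 1L] <- xval[idx]
    out[c_, ] <- encode_cell(row, meta$age_bin[c_], meta$tissue[c_],
                             meta$cell_type[c_], meta$disease[c_], vocab)
  }
  rownames(out) <- meta$cell_id
  out
}

#' Mask a token sequence for masked-token training or scoring
#'
#' Replaces exactly `round(gene_mask_rate * n_genes)` gene positions
#' (chosen uniformly without replacement) by `MASK`, and each metadata
#' position independently with probability `meta_mask_rate`. Original
#' tokens at masked positions are recorded as prediction targets. With
#' `keep_age = TRUE` the age position is never masked, so every
#' prediction stays conditioned on the age token.
#'
#' Uses the current R random number generator state; seed with
#' [set.seed()] for reproducible masks.
#'
#' @param tokens Integer token-id vector (one encoded cell).
#' @param vocab A `camap_vocab`.
#' @param gene_mask_rate Fraction of gene positions to mask, in `[0, 1]`.
#' @param meta_mask_rate Per-position masking probability of the metadata
#'   positions, in `[0, 1]`.
#' @param keep_age Never mask the age position.
#' @return List with `tokens` (masked sequence), `mask` (logical vector)
#'   and `targets` (original token ids at masked positions, in position
#'   order).
#' @export
mask_sequence <- function(tokens, vocab, gene_mask_rate = 0.85,
                          meta_mask_rate = 0.15, keep_age = FALSE) {
  if (gene_mask_rate < 0 || gene_mask_rate > 1 ||
      meta_mask_rate < 0 || meta_mask_rate > 1)
    stop("mask rates must lie in [0, 1]")
  L <- vocab$seq_len
  stopifnot(length(tokens) == L)
  n_genes <- vocab$n_genes
  n_mask <- round(gene_mask_rate * n_genes)
  mask <- logical(L)
  if (n_mask > 0L)
    mask[4L + sample.int(n_genes, n_mask)] <- TRUE
  meta_pos <- seq_len(4L)
  mask[meta_pos] <- stats::runif(4L) < meta_mask_rate
  if (keep_age) mask[1L] <- FALSE
  masked <- tokens
  masked[mask] <- vocab$mask_id
  list(tokens = as.integer(masked), mask = mask,
       targets = as.integer(tokens[mask]))
}

# Vectorized masking of a batch of sequences; returns the masked matrix,
# the target triplets (sequence row, position, original token id) and the
# per-target loss weights that the training loop feeds to the loss.
#
# Two kinds of training views are mixed. A fraction age_view_rate of the
# sequences become full-context age views: only the age token (plus the
# other metadata positions, each with meta_mask_rate) is masked and
# scored while every gene token stays visible — exactly the conditions
# under which the aging clock later queries the model. The remaining
# sequences are reconstruction views: the exact 85%-style gene masking
# with the age token left visible, so gene-token prediction is always
# learned conditioned on age (which keeps predictive entropy
# age-responsive) except for a recon_age_mask_rate fraction whose age
# token is masked too — some age-free gene prediction keeps gene
# representations from leaning on the age token alone and sharpens the
# drift contrast between stable and drifting genes. age_view_rate =
# NULL disables the split and masks every position at its nominal rate.
mask_batch <- function(tok_mat, vocab, gene_mask_rate = 0.85,
                       meta_mask_rate = 0.15, keep_age = FALSE,
                       meta_weight = 1, age_view_rate = NULL,
                       recon_age_mask_rate = 0) {
  B <- nrow(tok_mat); L <- ncol(tok_mat)
  n_genes <- vocab$n_genes
  n_mask <- round(gene_mask_rate * n_genes)
  rows <- integer(0); cols <- integer(0)
  age_view <- if (is.null(age_view_rate)) rep(FALSE, B)
              else stats::runif(B) < age_view_rate
  for (b in seq_len(B)) {
    if (age_view[b]) {
      mp <- unique(c(1L, which(stats::runif(4L) < meta_mask_rate)))
      pos <- sort(mp)
    } else {
      gp <- if (n_mask > 0L) 4L + sample.int(n_genes, n_mask) else integer(0)
      rates <- c(if (is.null(age_view_rate)) meta_mask_rate
                 else recon_age_mask_rate, rep(meta_mask_rate, 3L))
      mp <- which(stats::runif(4L) < rates)
      if (keep_age) mp <- setdiff(mp, 1L)
      pos <- c(mp, gp)
    }
    rows <- c(rows, rep.int(b, length(pos)))
    cols <- c(cols, pos)
  }
  idx <- cbind(rows, cols)
  targets <- cbind(seq_row = rows, pos = cols, token = tok_mat[idx])
  masked <- tok_mat
  masked[idx] <- vocab$mask_id
  list(tokens = masked, targets = targets,
       weights = ifelse(cols <= 4L, meta_weight, 1))
}
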