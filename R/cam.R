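#' Select cells of a study by stratum
#'
#' A stratum is a named list with any of `tissue`, `cell_type`, `disease`
#' (0-based ids / 0-1 flag); `NULL` entries (or the string `"all"`) leave
#' that dimension unrestricted.
#'
#' @param study A `camap_study`.
#' @param stratum Named list or `"all"`.
#' @return Integer vector of cell row indices.
#' @export
stratum_cells <- function(study, stratum = "all") {
  meta <- study$cell_meta
  keep <- rep(TRUE, nrow(meta))
  if (!identical(stratum, "all") && !is.null(stratum)) {
    if (!is.null(stratum$tissue)) keep <- keep & meta$tissue %in% stratum$tissue
    if (!is.null(stratum$cell_type))
      keep <- keep & meta$cell_type %in% stratum$cell_type
    if (!is.null(stratum$disease)) keep <- keep & meta$disease %in% stratum$disease
  }
  which(keep)
}

stratum_label <- function(stratum) {
  if (identical(stratum, "all") || is.null(stratum)) return("all")
  parts <- vapply(names(stratum), function(nm)
    paste0(nm, "=", paste(stratum[[nm]], collapse = "|")), character(1))
  paste(parts, collapse = ",")
}

# Shared accumulator: one forward pass over the selected cells, mean
# contextual embedding per (age bin, position). Returns per-bin means for
# gene positions and the age position, support counts, and supported bins.
#
# With center_genes = TRUE the per-cell mean hidden state across the
# gene positions is subtracted from each gene position before
# aggregation (metadata positions stay raw). This removes the global
# context component shared by every gene of a cell — which shifts with
# the age token and would otherwise dominate per-gene drift — and keeps
# the gene-specific part of the contextual embedding.
accumulate_embeddings <- function(model, tokens, age_bins, min_cells,
                                  batch_size = 64L, center_genes = TRUE) {
  vocab <- model$vocab
  L <- vocab$seq_len; d <- model$config$d
  n_meta <- vocab$n_meta
  n_bins <- vocab$n_age_bins
  n <- nrow(tokens)
  sums <- matrix(0, n_bins * L, d)  # row = bin * L + position
  counts <- integer(n_bins)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    B <- length(idx)
    H <- contextual_embeddings(model, tokens[idx, , drop = FALSE])
    if (center_genes) {
      seq_of <- rep(seq_len(B), each = L)
      is_gene <- rep.int(c(rep(FALSE, n_meta), rep(TRUE, L - n_meta)), B)
      gm <- rowsum(H[is_gene, , drop = FALSE], seq_of[is_gene],
                   reorder = FALSE) / (L - n_meta)
      H[is_gene, ] <- H[is_gene, , drop = FALSE] - gm[seq_of[is_gene], ,
                                                      drop = FALSE]
    }
    grp <- rep(age_bins[idx], each = L) * L + rep.int(seq_len(L) - 1L, B)
    S <- rowsum(H, grp, reorder = FALSE)
    key <- as.integer(rownames(S)) + 1L
    sums[key, ] <- sums[key, , drop = FALSE] + S
    counts <- counts + tabulate(age_bins[idx] + 1L, nbins = n_bins)
  }
  supported <- which(counts >= min_cells)
  if (length(supported) == 0L)
    stop(sprintf(paste0("no age bin reaches min_cells = %d; per-bin cell ",
                        "counts: %s"), min_cells,
                 paste(counts, collapse = ", ")))
  means <- array(0, dim = c(length(supported), L, d))
  for (i in seq_along(supported)) {
    b <- supported[i]
    rows <- (b - 1L) * L + seq_len(L)
    means[i, , ] <- sums[rows, , drop = FALSE] / counts[b]
  }
  list(means = means, counts = counts, supported_bins = supported - 1L)
}

#' Per-gene embedding trajectories across age bins
#'
#' Runs every selected cell through the encoder and averages, per age bin,
#' the contextual embedding at each gene position. By default the
#' per-cell mean across gene positions is removed first
#' (`center = TRUE`): the shared global-context component of a cell's
#' hidden states moves with the age token for every gene alike, and
#' subtracting it isolates the gene-specific part of the contextual
#' embedding, which is the quantity whose drift separates stable from
#' drifting genes. Bins supported by fewer than `min_cells` cells are
#' dropped (never zero-filled); the baseline bin `t0` is the earliest
#' supported bin.
#'
#' @param model A trained `camap_mlm`.
#' @param study The `camap_study` the tokens came from.
#' @param stratum Cell stratum (see [stratum_cells()]).
#' @param min_cells Minimum cells per bin for a bin to be kept.
#' @param tokens Optional pre-encoded token matrix ([encode_study()]);
#'   computed on the fly when missing.
#' @param batch_size Sequences per forward pass.
#' @param center Subtract each cell's mean gene-position hidden state
#'   from its gene positions before averaging (metadata positions stay
#'   raw).
#' @return An object of class `camap_trajectories`: array `E`
#'   (`bins x genes x d`), `age_E` (`bins x d`, the age-token trajectory),
#'   supported `bins` (0-based), per-bin `support`, bin `midpoints`,
#'   `gene_ids` and the stratum label. `t0` is row 1.
#' @export
gene_age_embeddings <- function(model, study, stratum = "all",
                                min_cells = 20L, tokens = NULL,
                                batch_size = 64L, center = TRUE) {
  stopifnot(inherits(model, "camap_mlm"), inherits(study, "camap_study"))
  cells <- stratum_cells(study, stratum)
  if (length(cells) == 0L) stop("stratum selects no cells")
  if (is.null(tokens)) tokens <- encode_study(study, model$vocab)
  acc <- accumulate_embeddings(model, tokens[cells, , drop = FALSE],
                               study$cell_meta$age_bin[cells], min_cells,
                               batch_size, center_genes = center)
  n_meta <- model$vocab$n_meta
  structure(list(
    E = acc$means[, -(seq_len(n_meta)), , drop = FALSE],
    age_E = acc$means[, 1L, , drop = TRUE],
    bins = acc$supported_bins,
    support = acc$counts[acc$supported_bins + 1L],
    midpoints = study$age_midpoints[acc$supported_bins + 1L],
    gene_ids = model$vocab$gene_ids,
    stratum = stratum_label(stratum),
    min_cells = min_cells,
    centered = center,
    d = model$config$d
  ), class = "camap_trajectories")
}

#' @exportS3Method base::print
print.camap_trajectories <- function(x, ...) {
  cat(sprintf(paste0("camap_trajectories: %d genes x %d supported age bins ",
                     "(d = %d), stratum '%s'\n"),
              length(x$gene_ids), length(x$bins), x$d, x$stratum))
  invisible(x)
}

#' Extract the trajectory of one gene
#'
#' @param trajs A `camap_trajectories`.
#' @param gene Gene id (character) or 1-based gene index.
#' @return A `camap_gene_trajectory`: matrix `E` (`bins x d`), supported
#'   `bins`, `midpoints`, the gene id and the stratum; the baseline `t0`
#'   is the first row.
#' @export
gene_trajectory <- function(trajs, gene) {
  stopifnot(inherits(trajs, "camap_trajectories"))
  g <- if (is.character(gene)) match(gene, trajs$gene_ids) else as.integer(gene)
  if (is.na(g) || g < 1L || g > length(trajs$gene_ids))
    stop(sprintf("unknown gene '%s'", as.character(gene)))
  E <- trajs$E[, g, , drop = TRUE]
  if (is.null(dim(E))) E <- matrix(E, nrow = length(trajs$bins))
  new_gene_trajectory(trajs$gene_ids[g], E, trajs$bins, trajs$midpoints,
                      trajs$stratum)
}

#' Construct a gene trajectory from raw per-bin vectors
#'
#' Mostly useful for tests and for users bringing their own embeddings.
#'
#' @param gene Gene identifier.
#' @param E Numeric matrix, one row per supported age bin.
#' @param bins 0-based age-bin indices (defaults to `0 .. nrow(E) - 1`).
#' @param midpoints Bin midpoints in years.
#' @param stratum Stratum label.
#' @return A `camap_gene_trajectory`.
#' @export
new_gene_trajectory <- function(gene, E, bins = seq_len(nrow(E)) - 1L,
                                midpoints = bins, stratum = "all") {
  E <- as.matrix(E)
  if (!all(is.finite(E))) stop("trajectory vectors must be finite")
  structure(list(gene = gene, E = E, bins = as.integer(bins),
                 midpoints = midpoints, stratum = stratum),
            class = "camap_gene_trajectory")
}

#' Age-token trajectory
#'
#' Mean contextual embedding at the age position, per supported age bin.
#'
#' @inheritParams gene_age_embeddings
#' @return Matrix `bins x d` with 0-based bin indices as row names, plus
#'   attributes `bins` and `midpoints`.
#' @export
age_token_trajectory <- function(model, study, stratum = "all",
                                 min_cells = 20L, tokens = NULL,
                                 batch_size = 64L) {
  trajs <- gene_age_embeddings(model, study, stratum, min_cells, tokens,
                               batch_size)  # age position is never centered
  A <- trajs$age_E
  if (is.null(dim(A))) A <- matrix(A, nrow = length(trajs$bins))
  rownames(A) <- trajs$bins
  attr(A, "bins") <- trajs$bins
  attr(A, "midpoints") <- trajs$midpoints
  A
}

#' Cosine similarity of two vectors
#'
#' @param u,v Numeric vectors of equal length with positive norm.
#' @return `u . v / (|u| |v|)`, in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("cosine similarity is undefined for zero-norm vectors")
  s <- sum(u * v) / (nu * nv)
  min(1, max(-1, s))
}

#' Rank tissues or cell types by similarity to the age token
#'
#' Compares the static (input-table) embedding of every token of the
#' chosen category against the age-token centroid, the mean of all
#' age-token static embeddings. Higher scores flag labels whose profile
#' the model couples more strongly to age.
#'
#' @param model A `camap_mlm`.
#' @param category `"tissue"` or `"cell_type"`.
#' @return Data frame (`token_id`, `label`, `score`, `rank`) sorted by
#'   descending score; ties keep token-id order.
#' @export
token_similarity_ranking <- function(model, category = c("tissue", "cell_type")) {
  category <- match.arg(category)
  vocab <- model$vocab
  ids <- vocab$tokens$token_id[vocab$tokens$category == category]
  centroid <- colMeans(token_embedding(model, age_token_ids(vocab)))
  scores <- vapply(ids, function(id)
    cosine_similarity(token_embedding(model, id)[1L, ], centroid), numeric(1))
  o <- order(-scores, ids)
  data.frame(token_id = ids[o],
             label = vocab$tokens$label[match(ids[o], vocab$tokens$token_id)],
             score = scores[o], rank = seq_along(ids),
             stringsAsFactors = FALSE)
}

#' Gene-versus-age similarity trajectory
#'
#' Cosine similarity between a gene's per-bin embedding and the age-token
#' trajectory, on the bins supported by both.
#'
#' @param traj A `camap_gene_trajectory`.
#' @param ages An age-token trajectory ([age_token_trajectory()]) or any
#'   matrix with 0-based bin indices as row names.
#' @return Data frame (`bin`, `midpoint`, `similarity`).
#' @export
gene_age_similarity_trajectory <- function(traj, ages) {
  stopifnot(inherits(traj, "camap_gene_trajectory"))
  age_bins <- if (!is.null(attr(ages, "bins"))) attr(ages, "bins")
              else as.integer(rownames(ages))
  common <- intersect(traj$bins, age_bins)
  if (length(common) == 0L) stop("no age bin supported by both inputs")
  sims <- vapply(common, function(b) {
    cosine_similarity(traj$E[match(b, traj$bins), ],
                      ages[match(b, age_bins), ])
  }, numeric(1))
  mids <- traj$midpoints[match(common, traj$bins)]
  data.frame(bin = common, midpoint = mids, similarity = sims)
}

#' Healthy and diseased trajectories with a leakage guard
#'
#' Builds per-condition trajectory sets from disjoint cell sets (asserted
#' on cell ids) for the healthy-versus-diseased drift contrast.
#'
#' @inheritParams gene_age_embeddings
#' @return List with elements `healthy` and `diseased`
#'   (`camap_trajectories`).
#' @export
condition_trajectories <- function(model, study, min_cells = 20L,
                                   tokens = NULL, batch_size = 64L,
                                   center = TRUE) {
  healthy_cells <- stratum_cells(study, list(disease = 0L))
  diseased_cells <- stratum_cells(study, list(disease = 1L))
  if (length(intersect(healthy_cells, diseased_cells)) != 0L)
    stop("healthy and diseased strata overlap")  # unreachable by construction
  if (is.null(tokens)) tokens <- encode_study(study, model$vocab)
  list(healthy = gene_age_embeddings(model, study, list(disease = 0L),
                                     min_cells, tokens, batch_size, center),
       diseased = gene_age_embeddings(model, study, list(disease = 1L),
                                      min_cells, tokens, batch_size, center))
}
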