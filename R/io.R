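#' Write a study to disk
#'
#' Serializes a study as plain interoperable files inside `path`:
#' `counts.mtx` (MatrixMarket coordinate format, cells as rows),
#' `cell_meta.tsv` (header `cell_id, age_bin, age_years, tissue, cell_type,
#' disease`; all ids 0-based), `genes.tsv`, `study.json` (age-bin layout)
#' and, when present, `ground_truth.json` (gene indices written 0-based).
#' The in-memory `latent_mu` matrix is a testing aid and is not serialized.
#'
#' @param study A `camap_study`.
#' @param path Output directory, created if missing.
#' @return `path`, invisibly.
#' @seealso [read_study()]
#' @export
write_study <- function(study, path) {
  stopifnot(inherits(study, "camap_study"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(study$counts, file.path(path, "counts.mtx"))
  utils::write.table(study$cell_meta, file.path(path, "cell_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene_id = study$gene_ids),
                     file.path(path, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(n_age_bins = study$n_age_bins,
               age_bin_width = study$age_bin_width,
               age_midpoints = study$age_midpoints)
  jsonlite::write_json(meta, file.path(path, "study.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(study$ground_truth)) {
    gt <- study$ground_truth
    out <- list(
      dissipative_genes = as.integer(gt$dissipative_genes) - 1L,
      conservative_genes = as.integer(gt$conservative_genes) - 1L,
      disease_flipped_genes = as.integer(gt$disease_flipped_genes) - 1L,
      noise_ramp_tissues = as.integer(gt$noise_ramp_tissues),
      module1 = as.integer(gt$module1) - 1L,
      module2 = as.integer(gt$module2) - 1L,
      tissue_age_accel = gt$tissue_age_accel,
      breakpoints = unname(lapply(gt$breakpoints, function(b)
        list(gene = b$gene - 1L, n_bp = b$n_bp, b1 = b$b1,
             b2 = if (is.na(b$b2)) NULL else b$b2, width = b$width)))
    )
    jsonlite::write_json(out, file.path(path, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a study from disk
#'
#' Inverse of [write_study()]: `read_study(write_study(s, p))` restores the
#' count matrix, metadata and ground truth exactly. Errors name the
#' offending file on a malformed MatrixMarket header or a row-count
#' mismatch between the matrix and the metadata table.
#'
#' @param path Directory written by [write_study()] (or assembled by hand
#'   with the same layout).
#' @return A `camap_study` (without `latent_mu`).
#' @export
read_study <- function(path) {
  mtx <- file.path(path, "counts.mtx")
  tsv <- file.path(path, "cell_meta.tsv")
  if (!file.exists(mtx)) stop(sprintf("missing count matrix '%s'", mtx))
  if (!file.exists(tsv)) stop(sprintf("missing cell metadata '%s'", tsv))
  header <- readLines(mtx, n = 1L)
  if (!grepl("^%%MatrixMarket", header))
    stop(sprintf("malformed MatrixMarket header in '%s': '%s'", mtx, header))
  counts <- methods::as(methods::as(Matrix::readMM(mtx), "generalMatrix"),
                        "CsparseMatrix")
  cell_meta <- utils::read.table(tsv, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
  need <- c("cell_id", "age_bin", "age_years", "tissue", "cell_type", "disease")
  missing_cols <- setdiff(need, names(cell_meta))
  if (length(missing_cols))
    stop(sprintf("cell metadata '%s' lacks column(s): %s", tsv,
                 paste(missing_cols, collapse = ", ")))
  if (nrow(cell_meta) != nrow(counts))
    stop(sprintf(paste0("row-count mismatch: counts.mtx has %d cells but ",
                        "cell_meta.tsv has %d rows"),
                 nrow(counts), nrow(cell_meta)))
  genes_file <- file.path(path, "genes.tsv")
  gene_ids <- if (file.exists(genes_file))
    utils::read.table(genes_file, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)$gene_id
  else sprintf("gene_%04d", seq_len(ncol(counts)))
  if (length(gene_ids) != ncol(counts))
    stop(sprintf("genes.tsv lists %d genes but counts.mtx has %d columns",
                 length(gene_ids), ncol(counts)))
  dimnames(counts) <- list(cell_meta$cell_id, gene_ids)

  sj <- file.path(path, "study.json")
  if (file.exists(sj)) {
    meta <- jsonlite::read_json(sj, simplifyVector = TRUE)
    n_age_bins <- as.integer(meta$n_age_bins)
    bin_width <- as.numeric(meta$age_bin_width)
    midpoints <- as.numeric(meta$age_midpoints)
  } else {
    n_age_bins <- max(cell_meta$age_bin) + 1L
    ages <- tapply(cell_meta$age_years, cell_meta$age_bin, function(a) a[1])
    midpoints <- as.numeric(ages[as.character(0:(n_age_bins - 1L))])
    bin_width <- if (n_age_bins > 1L) diff(midpoints[1:2]) else NA_real_
  }
  if (any(cell_meta$age_bin < 0L | cell_meta$age_bin >= n_age_bins))
    stop("cell_meta age_bin indices fall outside [0, n_age_bins)")

  gtf <- file.path(path, "ground_truth.json")
  ground_truth <- NULL
  if (file.exists(gtf)) {
    gt <- jsonlite::read_json(gtf, simplifyVector = TRUE)
    ints <- function(x) if (length(x)) as.integer(unlist(x)) else integer(0)
    bps <- lapply(seq_len(nrow(as.data.frame(gt$breakpoints))), function(i) {
      b <- gt$breakpoints[i, ]
      list(gene = as.integer(b$gene) + 1L, n_bp = as.integer(b$n_bp),
           b1 = as.numeric(b$b1),
           b2 = if (is.null(b$b2) || is.na(b$b2)) NA_real_ else as.numeric(b$b2),
           width = as.numeric(b$width))
    })
    names(bps) <- vapply(bps, function(b) as.character(b$gene), character(1))
    ground_truth <- list(
      dissipative_genes = ints(gt$dissipative_genes) + 1L,
      conservative_genes = ints(gt$conservative_genes) + 1L,
      disease_flipped_genes = ints(gt$disease_flipped_genes) + 1L,
      noise_ramp_tissues = ints(gt$noise_ramp_tissues),
      module1 = ints(gt$module1) + 1L,
      module2 = ints(gt$module2) + 1L,
      breakpoints = bps,
      tissue_age_accel = as.numeric(gt$tissue_age_accel)
    )
  }

  structure(list(
    counts = counts,
    cell_meta = cell_meta,
    gene_ids = gene_ids,
    n_age_bins = n_age_bins,
    age_bin_width = bin_width,
    age_midpoints = midpoints,
    ground_truth = ground_truth,
    latent_mu = NULL,
    config = NULL
  ), class = "camap_study")
}
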