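#' Embedding drift of one gene
#'
#' Euclidean distance between the gene's per-bin embedding and its
#' baseline embedding at the earliest supported bin `t0`:
#' `D_g(t) = || E_{g,t} - E_{g,t0} ||_2`, with `D_g(t0) = 0`.
#'
#' @param traj A `camap_gene_trajectory` with at least two supported bins.
#' @return A `camap_drift_profile`: per-bin `drift`, `max_drift`, the
#'   supported `bins` and the gene id.
#' @export
drift <- function(traj) {
  stopifnot(inherits(traj, "camap_gene_trajectory"))
  if (nrow(traj$E) < 2L)
    stop("drift needs at least two supported bins (a baseline and one later bin)")
  base <- traj$E[1L, ]
  d <- sqrt(rowSums(sweep(traj$E, 2L, base)^2))
  structure(list(gene = traj$gene, bins = traj$bins, drift = d,
                 max_drift = max(d), stratum = traj$stratum),
            class = "camap_drift_profile")
}

#' Mean embedding and embedding variance of one gene
#'
#' Across the `N` supported bins: `mean_E = (1/N) sum_t E_{g,t}` and
#' `sigma2 = (1/N) sum_t || E_{g,t} - mean_E ||^2` (population
#' normalization).
#'
#' @param traj A `camap_gene_trajectory`.
#' @return List with `mean_E` (d-vector) and `sigma2` (scalar >= 0).
#' @export
embedding_variance <- function(traj) {
  stopifnot(inherits(traj, "camap_gene_trajectory"))
  mean_E <- colMeans(traj$E)
  sigma2 <- mean(rowSums(sweep(traj$E, 2L, mean_E)^2))
  list(mean_E = mean_E, sigma2 = sigma2)
}

#' Drift profiles for every gene of a trajectory set
#'
#' Vectorized drift + variance over all genes.
#'
#' @param trajs A `camap_trajectories`.
#' @return Data frame (`gene`, `stratum`, `max_drift`, `sigma2`) with the
#'   per-bin drift matrix (`bins x genes`) attached as attribute
#'   `drift_matrix`.
#' @export
drift_profiles <- function(trajs) {
  stopifnot(inherits(trajs, "camap_trajectories"))
  if (length(trajs$bins) < 2L)
    stop("drift needs at least two supported bins (a baseline and one later bin)")
  E <- trajs$E                                   # bins x genes x d
  nb <- dim(E)[1L]; G <- dim(E)[2L]
  base <- E[rep(1L, nb), , , drop = FALSE]
  D <- sqrt(apply((E - base)^2, c(1L, 2L), sum)) # bins x genes
  mean_E <- apply(E, c(2L, 3L), mean)            # genes x d
  centered <- sweep(E, c(2L, 3L), mean_E)
  sigma2 <- apply(centered^2, 2L, sum) / nb
  out <- data.frame(gene = trajs$gene_ids, stratum = trajs$stratum,
                    max_drift = apply(D, 2L, max), sigma2 = sigma2,
                    stringsAsFactors = FALSE)
  attr(out, "drift_matrix") <- D
  attr(out, "bins") <- trajs$bins
  out
}

#' Classify genes as conservative or dissipative
#'
#' The drift threshold `delta` is the `q`-th percentile (linear
#' interpolation) of the max-drift distribution across all genes; genes
#' with `max_drift <= delta` form the conservative set `G_C`, the rest
#' the dissipative set `G_D` (so `G_C` and `G_D` partition the genes).
#'
#' @param profiles A data frame with `gene` and `max_drift` columns
#'   ([drift_profiles()]), or a `camap_trajectories`.
#' @param q Percentile in `(0, 100)` (or exactly 100 to call every gene
#'   conservative).
#' @return A `camap_classification`: `delta`, `q`, the per-gene `table`
#'   (`gene`, `max_drift`, `label`), and the `conservative` /
#'   `dissipative` gene-id vectors.
#' @export
classify_genes <- function(profiles, q = 80) {
  if (inherits(profiles, "camap_trajectories"))
    profiles <- drift_profiles(profiles)
  if (nrow(profiles) < 2L) stop("classification needs at least two genes")
  if (q <= 0 || q > 100) stop("'q' must lie in (0, 100]")
  delta <- unname(stats::quantile(profiles$max_drift, q / 100, type = 7))
  label <- ifelse(profiles$max_drift <= delta, "conservative", "dissipative")
  tab <- data.frame(gene = profiles$gene, max_drift = profiles$max_drift,
                    label = label, stringsAsFactors = FALSE)
  structure(list(delta = delta, q = q, table = tab,
                 conservative = tab$gene[label == "conservative"],
                 dissipative = tab$gene[label == "dissipative"]),
            class = "camap_classification")
}

#' @exportS3Method base::print
print.camap_classification <- function(x, ...) {
  cat(sprintf("camap_classification: delta = %.4g (q = %g); %d conservative, %d dissipative\n",
              x$delta, x$q, length(x$conservative), length(x$dissipative)))
  invisible(x)
}

#' Healthy-versus-diseased drift contrast
#'
#' Per-gene ratio of diseased to healthy max drift (denominator floored
#' at `eps`, flagged when floored) and the label change between
#' per-condition classifications, each at the same percentile `q` with
#' its own threshold.
#'
#' @param profiles_healthy,profiles_diseased [drift_profiles()] outputs
#'   (or `camap_trajectories`) for the two conditions, same gene set.
#' @param q Classification percentile applied to both conditions.
#' @param eps Pseudo-floor for the healthy drift in the ratio.
#' @return A `camap_contrast`: per-gene `table` (`gene`, `drift_healthy`,
#'   `drift_diseased`, `ratio`, `floored`, `label_healthy`,
#'   `label_diseased`, `change` in `{C->C, C->D, D->C, D->D}`) plus both
#'   `delta` values.
#' @export
condition_contrast <- function(profiles_healthy, profiles_diseased,
                               q = 80, eps = 1e-9) {
  if (inherits(profiles_healthy, "camap_trajectories"))
    profiles_healthy <- drift_profiles(profiles_healthy)
  if (inherits(profiles_diseased, "camap_trajectories"))
    profiles_diseased <- drift_profiles(profiles_diseased)
  if (!identical(profiles_healthy$gene, profiles_diseased$gene))
    stop("the two profile sets must cover the same genes in the same order")
  cls_h <- classify_genes(profiles_healthy, q)
  cls_d <- classify_genes(profiles_diseased, q)
  dh <- profiles_healthy$max_drift
  dd <- profiles_diseased$max_drift
  floored <- dh < eps
  ratio <- dd / pmax(dh, eps)
  short <- c(conservative = "C", dissipative = "D")
  change <- paste0(short[cls_h$table$label], "->", short[cls_d$table$label])
  tab <- data.frame(gene = profiles_healthy$gene,
                    drift_healthy = dh, drift_diseased = dd,
                    ratio = ratio, floored = floored,
                    label_healthy = cls_h$table$label,
                    label_diseased = cls_d$table$label,
                    change = change, stringsAsFactors = FALSE)
  structure(list(table = tab, q = q, delta_healthy = cls_h$delta,
                 delta_diseased = cls_d$delta),
            class = "camap_contrast")
}

#' Enrichment of a gene set among conservative-to-dissipative flips
#'
#' 2x2 association between membership in `genes` (for instance the
#' planted disease-flipped genes) and a `C->D` label change in a
#' [condition_contrast()], restricted to genes that are conservative in
#' the healthy condition. Association is summarized by the
#' Haldane-corrected log odds ratio and Fisher's exact test.
#'
#' @param contrast A `camap_contrast`.
#' @param genes Character vector of gene ids.
#' @return List with the 2x2 `table`, `log_odds` (> 0 means enrichment)
#'   and `p_value`.
#' @export
flip_enrichment <- function(contrast, genes) {
  stopifnot(inherits(contrast, "camap_contrast"))
  tab <- contrast$table
  cons_h <- tab$label_healthy == "conservative"
  flips <- tab$change == "C->D"
  in_set <- tab$gene %in% genes
  m <- matrix(c(sum(cons_h & in_set & flips), sum(cons_h & in_set & !flips),
                sum(cons_h & !in_set & flips), sum(cons_h & !in_set & !flips)),
              2L, 2L, byrow = TRUE,
              dimnames = list(set = c("in_set", "other"),
                              change = c("C->D", "stable")))
  log_odds <- log((m[1, 1] + 0.5) * (m[2, 2] + 0.5) /
                    ((m[1, 2] + 0.5) * (m[2, 1] + 0.5)))
  p <- stats::fisher.test(m, alternative = "greater")$p.value
  list(table = m, log_odds = log_odds, p_value = p)
}

#' Empirical Lipschitz ratios of the embedding map
#'
#' Samples cells, perturbs a single gene token by one expression-bin
#' level and/or the age token by one bin, and records the ratio of the
#' embedding displacement at the perturbed position to the input
#' displacement `||dx|| + |dt|` (bin levels; `dt` in years). The extreme
#' ratios bound the local sensitivity of the embedding map; the minimum
#' can be restricted to perturbations of a dissipative gene set.
#'
#' Perturbations that do not change the sequence are excluded from the
#' ratio distribution and counted in `n_excluded`.
#'
#' @param model A `camap_mlm`.
#' @param tokens Encoded sequences (matrix).
#' @param n_pairs Number of sampled perturbations.
#' @param dissipative_genes Optional 1-based gene indices over which the
#'   minimum ratio is taken (default: all perturbed genes).
#' @param perturb One of `"gene"`, `"age"`, `"both"` — which token(s)
#'   each sampled pair perturbs.
#' @param seed Integer seed.
#' @return A `camap_lipschitz`: `L_max`, `L_min`, `n_pairs`, `n_excluded`,
#'   and the ratio table (`cell`, `gene`, `dx`, `dt_years`, `ratio`).
#' @export
estimate_lipschitz <- function(model, tokens, n_pairs = 100L,
                               dissipative_genes = NULL,
                               perturb = c("both", "gene", "age"),
                               seed = 1L) {
  perturb <- match.arg(perturb)
  vocab <- model$vocab
  set.seed(seed)
  n <- nrow(tokens)
  rows <- sample.int(n, n_pairs, replace = n_pairs > n)
  genes <- sample.int(vocab$n_genes, n_pairs, replace = TRUE)
  recs <- vector("list", n_pairs)
  n_excluded <- 0L
  for (i in seq_len(n_pairs)) {
    seq0 <- tokens[rows[i], ]
    seq1 <- seq0
    dx <- 0; dt <- 0
    do_gene <- perturb %in% c("gene", "both")
    do_age <- perturb == "age" || (perturb == "both" && i %% 2L == 0L)
    pos <- 4L + genes[i]
    if (do_gene) {
      bin <- seq0[pos]
      new_bin <- if (bin >= vocab$n_value_bins) bin - 1L else bin + 1L
      seq1[pos] <- new_bin
      dx <- abs(new_bin - bin)
    }
    if (do_age) {
      age <- seq0[1L] - vocab$offsets[["age"]]
      new_age <- if (age >= vocab$n_age_bins - 1L) age - 1L else age + 1L
      seq1[1L] <- vocab$offsets[["age"]] + new_age
      dt <- abs(new_age - age) * vocab$age_bin_width
    }
    if (all(seq1 == seq0)) { n_excluded <- n_excluded + 1L; next }
    H0 <- contextual_embeddings(model, seq0)
    H1 <- contextual_embeddings(model, seq1)
    at <- if (do_gene) pos else 1L
    disp <- sqrt(sum((H1[at, ] - H0[at, ])^2))
    recs[[i]] <- data.frame(cell = rows[i],
                            gene = if (do_gene) genes[i] else NA_integer_,
                            dx = dx, dt_years = dt, ratio = disp / (dx + dt))
  }
  ratios <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(ratios) || nrow(ratios) == 0L)
    stop("every sampled perturbation was excluded; nothing to estimate")
  min_pool <- if (is.null(dissipative_genes)) ratios
              else ratios[!is.na(ratios$gene) & ratios$gene %in% dissipative_genes, ]
  structure(list(L_max = max(ratios$ratio),
                 L_min = if (nrow(min_pool)) min(min_pool$ratio) else NA_real_,
                 n_pairs = nrow(ratios), n_excluded = n_excluded,
                 ratios = ratios, seed = seed),
            class = "camap_lipschitz")
}

#' @exportS3Method base::print
print.camap_lipschitz <- function(x, ...) {
  cat(sprintf("camap_lipschitz: L_max = %.4g, L_min = %.4g over %d pairs (%d excluded)\n",
              x$L_max, x$L_min, x$n_pairs, x$n_excluded))
  invisible(x)
}

#' Balanced accuracy of a classification against planted labels
#'
#' @param classification A `camap_classification`.
#' @param truth_dissipative Gene ids (or 1-based indices into the
#'   classification table) planted as dissipative.
#' @return Balanced accuracy `(sensitivity + specificity) / 2` of the
#'   dissipative call.
#' @export
classification_balanced_accuracy <- function(classification, truth_dissipative) {
  stopifnot(inherits(classification, "camap_classification"))
  tab <- classification$table
  if (is.numeric(truth_dissipative))
    truth_dissipative <- tab$gene[truth_dissipative]
  truth <- tab$gene %in% truth_dissipative
  pred <- tab$label == "dissipative"
  sens <- if (any(truth)) sum(pred & truth) / sum(truth) else NA_real_
  spec <- if (any(!truth)) sum(!pred & !truth) / sum(!truth) else NA_real_
  (sens + spec) / 2
}
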