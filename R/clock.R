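#' Expected age of a distribution over age bins
#'
#' Given probabilities restricted to the age tokens (any non-negative
#' weights; renormalized internally) returns the expectation of the bin
#' midpoints — the soft age prediction. `argmax` returns the midpoint of
#' the most probable bin instead.
#'
#' @param probs Non-negative weight vector, one entry per age bin.
#' @param midpoints Bin midpoints in years.
#' @param method `"expectation"` (default) or `"argmax"`.
#' @return Predicted age in years.
#' @export
expected_age <- function(probs, midpoints, method = c("expectation", "argmax")) {
  method <- match.arg(method)
  stopifnot(length(probs) == length(midpoints))
  if (any(probs < 0)) stop("probabilities must be non-negative")
  total <- sum(probs)
  if (total <= 0) stop("no probability mass on the age tokens")
  p <- probs / total
  if (method == "argmax") midpoints[which.max(p)] else sum(p * midpoints)
}

#' Predict chronological age from the masked age token
#'
#' Masks the age position only, asks the model for the distribution at
#' that position, restricts it to the age tokens, renormalizes and takes
#' the expectation of the bin midpoints.
#'
#' @param model A trained `camap_mlm`.
#' @param tokens One encoded sequence (vector) or a matrix of sequences.
#' @param method Passed to [expected_age()].
#' @param batch_size Sequences per forward pass.
#' @return Predicted age(s) in years, always inside
#'   `[min(midpoints), max(midpoints)]`.
#' @export
predict_age <- function(model, tokens, method = "expectation",
                        batch_size = 64L) {
  vocab <- model$vocab
  single <- is.null(dim(tokens))
  tok <- if (single) matrix(as.integer(tokens), 1L) else tokens
  tok[, 1L] <- vocab$mask_id
  age_ids <- age_token_ids(vocab)
  n <- nrow(tok)
  preds <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    sel <- cbind(seq_along(idx), 1L)
    logits <- batch_logits(model, tok[idx, , drop = FALSE], sel)
    probs <- softmax_rows(logits)[, age_ids + 1L, drop = FALSE]
    preds[idx] <- apply(probs, 1L, expected_age,
                        midpoints = vocab$age_midpoints, method = method)
  }
  if (single) preds[1L] else preds
}

#' Per-cell age-gap records
#'
#' Predicts age for the selected cells and tabulates the gap
#' (predicted minus true age) together with the stratum labels.
#'
#' @param model A trained `camap_mlm`.
#' @param study The `camap_study`.
#' @param cells Cell row indices to evaluate (default: all).
#' @param tokens Optional pre-encoded token matrix.
#' @param method Passed to [expected_age()].
#' @return Data frame (`cell_id`, `true_age`, `predicted_age`, `gap`,
#'   `age_bin`, `tissue`, `cell_type`, `disease`).
#' @export
age_gap_records <- function(model, study, cells = NULL, tokens = NULL,
                            method = "expectation") {
  stopifnot(inherits(model, "camap_mlm"), inherits(study, "camap_study"))
  if (is.null(cells)) cells <- seq_len(nrow(study$cell_meta))
  if (is.null(tokens)) tokens <- encode_study(study, model$vocab)
  pred <- predict_age(model, tokens[cells, , drop = FALSE], method = method)
  meta <- study$cell_meta[cells, , drop = FALSE]
  data.frame(cell_id = meta$cell_id, true_age = meta$age_years,
             predicted_age = pred, gap = pred - meta$age_years,
             age_bin = meta$age_bin, tissue = meta$tissue,
             cell_type = meta$cell_type, disease = meta$disease,
             stringsAsFactors = FALSE)
}

#' z-scored age gaps
#'
#' Standardizes the gaps across the evaluation set:
#' `z = (gap - mean(gap)) / sd(gap)` with the population standard
#' deviation, so the z-scores have mean 0 and sd 1 by construction.
#' With `center = FALSE` only the scaling is applied. A degenerate set
#' with zero gap spread yields all-zero z-scores with a warning.
#'
#' @param records [age_gap_records()] output.
#' @param center Subtract the mean gap before scaling.
#' @return `records` with a `zscore` column appended.
#' @export
age_gap_zscores <- function(records, center = TRUE) {
  g <- records$gap
  mu <- if (center) mean(g) else 0
  sdev <- sqrt(mean((g - mean(g))^2))
  if (sdev == 0) {
    warning("all gaps identical; z-scores set to 0")
    records$zscore <- rep(0, length(g))
  } else {
    records$zscore <- (g - mu) / sdev
  }
  records
}

#' Per-group correlation of predicted and true age
#'
#' Pearson correlation per level of a grouping column, with a gap
#' summary. Groups with fewer than `min_n` cells are omitted and listed
#' in the `omitted` attribute.
#'
#' @param records [age_gap_records()] output (with or without z-scores).
#' @param group_key Column name to group by (e.g. `"tissue"`,
#'   `"cell_type"`).
#' @param min_n Minimum group size.
#' @return Data frame (`group`, `n`, `r`, `mean_gap`, `mean_z`, `sd_z`);
#'   `mean_z`/`sd_z` are `NA` when z-scores are absent.
#' @export
group_correlation <- function(records, group_key, min_n = 10L) {
  stopifnot(group_key %in% names(records))
  groups <- split(records, records[[group_key]])
  keep <- vapply(groups, nrow, integer(1)) >= min_n
  rows <- lapply(groups[keep], function(gr) {
    r <- if (stats::sd(gr$true_age) == 0 || stats::sd(gr$predicted_age) == 0)
      NA_real_ else stats::cor(gr$predicted_age, gr$true_age)
    data.frame(group = gr[[group_key]][1L], n = nrow(gr), r = r,
               mean_gap = mean(gr$gap),
               mean_z = if ("zscore" %in% names(gr)) mean(gr$zscore) else NA_real_,
               sd_z = if ("zscore" %in% names(gr)) stats::sd(gr$zscore) else NA_real_)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(group = character(0), n = integer(0), r = numeric(0),
                      mean_gap = numeric(0), mean_z = numeric(0),
                      sd_z = numeric(0))
  rownames(out) <- NULL
  attr(out, "omitted") <- names(groups)[!keep]
  out
}

#' z-scored age-gap profile along the lifespan
#'
#' Bins cells into fixed-width chronological-age windows and summarizes
#' the z-scored gap per window.
#'
#' @param records [age_gap_zscores()] output.
#' @param bin_width_years Window width in years.
#' @return Data frame (`age_lo`, `age_hi`, `n`, `mean_z`, `q25`, `median_z`,
#'   `q75`).
#' @export
gap_by_age_profile <- function(records, bin_width_years = 5) {
  if (!"zscore" %in% names(records))
    records <- age_gap_zscores(records)
  win <- floor(records$true_age / bin_width_years)
  groups <- split(records, win)
  rows <- lapply(groups, function(gr) {
    qs <- stats::quantile(gr$zscore, c(0.25, 0.5, 0.75), names = FALSE)
    w <- floor(gr$true_age[1L] / bin_width_years)
    data.frame(age_lo = w * bin_width_years,
               age_hi = (w + 1) * bin_width_years,
               n = nrow(gr), mean_z = mean(gr$zscore),
               q25 = qs[1L], median_z = qs[2L], q75 = qs[3L])
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$age_lo), , drop = FALSE]
  rownames(out) <- NULL
  out
}
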