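#' Model configuration for the masked-token transformer
#'
#' Desk-scale defaults: a 64-dimensional, 2-layer, 4-head encoder trains
#' on a 200-gene, 5000-cell corpus in minutes on one CPU core while
#' leaving room for the planted signal.
#'
#' @param d Embedding dimension (must be divisible by `n_heads`).
#' @param n_layers Number of encoder blocks.
#' @param n_heads Attention heads per block.
#' @param d_ff Feed-forward width.
#' @param dropout Dropout probability applied to attention and
#'   feed-forward outputs during training (0 disables).
#' @param lr Adam learning rate.
#' @param batch_size Sequences per optimizer step.
#' @param epochs Training epochs.
#' @param gene_mask_rate Fraction of gene positions masked per training
#'   sequence (exact count, not in expectation).
#' @param meta_mask_rate Independent masking probability of the tissue,
#'   cell-type and disease positions during training.
#' @param age_view_rate Fraction of training sequences presented as
#'   full-context age views: only the age token (and other metadata at
#'   `meta_mask_rate`) is masked while every gene token stays visible —
#'   the exact conditions under which [predict_age()] later queries the
#'   model. The remaining sequences are reconstruction views with
#'   `gene_mask_rate` gene masking, so gene predictions are learned
#'   mostly conditioned on a visible age token.
#' @param recon_age_mask_rate Probability of masking the age token of a
#'   reconstruction view. Some age-free gene prediction keeps gene
#'   representations from leaning on the age token alone, which sharpens
#'   the embedding-drift contrast between stable and drifting genes.
#' @param meta_loss_weight Loss weight of a masked metadata target
#'   relative to a masked gene target. Gene positions outnumber metadata
#'   positions by about two orders of magnitude, so without upweighting
#'   the metadata reconstruction (age in particular) receives a
#'   negligible share of the gradient.
#' @param warmup_steps Linear learning-rate warmup steps.
#' @param lr_decay Cosine-decay the learning rate after warmup down to
#'   10 percent of its peak by the final step (stabilizes the last
#'   epochs).
#' @param val_fraction Held-out fraction used for the per-epoch
#'   validation loss.
#' @param seed Integer seed controlling initialization, data split,
#'   masking and batch order.
#' @return An object of class `camap_model_config`.
#' @export
model_config <- function(d = 64L, n_layers = 2L, n_heads = 4L, d_ff = 128L,
                         dropout = 0, lr = 3e-3, batch_size = 16L,
                         epochs = 5L, gene_mask_rate = 0.85,
                         meta_mask_rate = 0.15, age_view_rate = 0.3,
                         recon_age_mask_rate = 0,
                         meta_loss_weight = 40,
                         warmup_steps = 50L, lr_decay = TRUE,
                         val_fraction = 0.1,
                         seed = 1L) {
  cfg <- list(d = as.integer(d), n_layers = as.integer(n_layers),
              n_heads = as.integer(n_heads), d_ff = as.integer(d_ff),
              dropout = as.numeric(dropout), lr = as.numeric(lr),
              batch_size = as.integer(batch_size), epochs = as.integer(epochs),
              gene_mask_rate = as.numeric(gene_mask_rate),
              meta_mask_rate = as.numeric(meta_mask_rate),
              age_view_rate = as.numeric(age_view_rate),
              recon_age_mask_rate = as.numeric(recon_age_mask_rate),
              meta_loss_weight = as.numeric(meta_loss_weight),
              warmup_steps = as.integer(warmup_steps),
              lr_decay = isTRUE(lr_decay),
              val_fraction = as.numeric(val_fraction), seed = as.integer(seed))
  if (any(vapply(cfg[c("d", "n_layers", "n_heads", "d_ff", "batch_size")],
                 function(x) is.na(x) || x < 1L, logical(1))))
    stop("d, n_layers, n_heads, d_ff and batch_size must be positive integers")
  if (cfg$epochs < 0L) stop("'epochs' must be >= 0")
  if (cfg$d %% cfg$n_heads != 0L)
    stop(sprintf("embedding dimension d = %d is not divisible by n_heads = %d",
                 cfg$d, cfg$n_heads))
  if (cfg$dropout < 0 || cfg$dropout >= 1) stop("'dropout' must lie in [0, 1)")
  if (cfg$lr <= 0) stop("'lr' must be positive")
  if (cfg$gene_mask_rate < 0 || cfg$gene_mask_rate > 1 ||
      cfg$meta_mask_rate < 0 || cfg$meta_mask_rate > 1 ||
      cfg$age_view_rate < 0 || cfg$age_view_rate > 1 ||
      cfg$recon_age_mask_rate < 0 || cfg$recon_age_mask_rate > 1)
    stop("mask rates must lie in [0, 1]")
  if (cfg$val_fraction < 0 || cfg$val_fraction >= 1)
    stop("'val_fraction' must lie in [0, 1)")
  if (cfg$meta_loss_weight <= 0) stop("'meta_loss_weight' must be positive")
  if (cfg$warmup_steps < 0L) stop("'warmup_steps' must be >= 0")
  structure(cfg, class = "camap_model_config")
}

# Fixed parameter order shared with the C++ kernels.
param_order <- function(n_layers) {
  per_layer <- c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo",
                 "g1", "be1", "W1", "b1", "W2", "b2", "g2", "be2")
  c("E_tok", "E_pos",
    unlist(lapply(seq_len(n_layers), function(l) paste0(per_layer, "_", l))),
    "gf", "bf", "Whd", "bhd")
}

#' Initialize an untrained masked-token model
#'
#' Weights are drawn from N(0, 0.02^2), layer-norm gains start at 1 and
#' all biases at 0, so the untrained output head emits near-zero logits
#' and its predictive distributions are close to uniform (entropy near
#' `log(k)`).
#'
#' @param vocab A `camap_vocab`.
#' @param config A [model_config()].
#' @return An object of class `camap_mlm` holding the parameter list, the
#'   vocabulary and an empty loss trace.
#' @export
init_mlm <- function(vocab, config = model_config()) {
  stopifnot(inherits(vocab, "camap_vocab"))
  if (!inherits(config, "camap_model_config"))
    config <- do.call(model_config, as.list(config))
  d <- config$d; k <- vocab$k; L <- vocab$seq_len; ff <- config$d_ff
  set.seed(config$seed)
  gauss <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.02), nr, nc)
  ones <- function(nc) matrix(1, 1, nc)
  zeros <- function(nc) matrix(0, 1, nc)
  params <- list(E_tok = gauss(k, d), E_pos = gauss(L, d))
  for (l in seq_len(config$n_layers)) {
    layer <- list(gauss(d, d), zeros(d), gauss(d, d), zeros(d),
                  gauss(d, d), zeros(d), gauss(d, d), zeros(d),
                  ones(d), zeros(d),
                  gauss(d, ff), zeros(ff), gauss(ff, d), zeros(d),
                  ones(d), zeros(d))
    names(layer) <- paste0(c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo",
                             "g1", "be1", "W1", "b1", "W2", "b2", "g2", "be2"),
                           "_", l)
    params <- c(params, layer)
  }
  params <- c(params, list(gf = ones(d), bf = zeros(d),
                           Whd = gauss(d, k), bhd = zeros(k)))
  stopifnot(identical(names(params), param_order(config$n_layers)))
  structure(list(params = params, vocab = vocab, config = config,
                 loss_trace = data.frame(epoch = integer(0),
                                         train_loss = numeric(0),
                                         val_loss = numeric(0)),
                 trained = FALSE),
            class = "camap_mlm")
}

#' @exportS3Method base::print
print.camap_mlm <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("camap_mlm: d = %d, %d layers, %d heads, ff = %d, ",
                     "k = %d, sequence length %d (%s)\n"),
              cfg$d, cfg$n_layers, cfg$n_heads, cfg$d_ff, x$vocab$k,
              x$vocab$seq_len,
              if (x$trained) sprintf("trained, final val loss %.4f",
                                     utils::tail(x$loss_trace$val_loss, 1))
              else "untrained"))
  invisible(x)
}

# Evaluate mean masked-token cross-entropy of fixed (tokens, targets)
# pairs in batches, without gradients. Unweighted (every target counts
# once) so the trace is comparable to the log(k) uniform baseline.
eval_loss <- function(model, tokens, targets, batch_size = 64L) {
  n <- nrow(tokens)
  total <- 0; n_tot <- 0
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    keep <- targets[, 1L] %in% idx
    tmask <- targets[keep, , drop = FALSE]
    if (nrow(tmask) == 0L) next
    tmask[, 1L] <- match(tmask[, 1L], idx)
    out <- cpp_mlm_train_batch(tokens[idx, , drop = FALSE],
                               tmask, rep(1, nrow(tmask)), model$params,
                               model$config$n_layers, model$config$n_heads,
                               0, 0L, FALSE)
    total <- total + out$loss * nrow(tmask)
    n_tot <- n_tot + nrow(tmask)
  }
  total / n_tot
}

#' Train the masked-token model
#'
#' Adam optimization of the masked-token cross-entropy. Each epoch draws
#' fresh masks (exactly `round(gene_mask_rate * n_genes)` gene positions
#' per sequence plus independently masked metadata positions), shuffles
#' the training split and records the mean training loss and the loss on
#' a fixed held-out split with fixed masks. Training is fully seeded:
#' the same seed gives the same final parameters and loss trace. A
#' non-finite loss aborts with a diagnostic naming the epoch and batch.
#'
#' @param model An (untrained or trained) `camap_mlm`.
#' @param tokens Integer matrix of encoded sequences ([encode_study()]).
#' @param config Optional [model_config()] overriding the model's.
#' @return The trained `camap_mlm` with an updated `loss_trace`
#'   (`epoch`, `train_loss`, `val_loss`).
#' @export
train_mlm <- function(model, tokens, config = NULL) {
  stopifnot(inherits(model, "camap_mlm"))
  cfg <- if (is.null(config)) model$config else config
  if (!inherits(cfg, "camap_model_config"))
    cfg <- do.call(model_config, as.list(cfg))
  vocab <- model$vocab
  n <- nrow(tokens)
  if (is.null(n) || n < 1L) stop("need at least one sequence to train on")
  if (ncol(tokens) != vocab$seq_len)
    stop(sprintf("sequences have length %d, vocabulary expects %d",
                 ncol(tokens), vocab$seq_len))
  if (cfg$epochs == 0L) return(model)

  set.seed(cfg$seed + 1L)
  n_val <- round(cfg$val_fraction * n)
  val_idx <- if (n_val > 0L) sort(sample.int(n, n_val)) else integer(0)
  train_idx <- setdiff(seq_len(n), val_idx)
  val_masked <- NULL
  if (n_val > 0L) {
    vm <- mask_batch(tokens[val_idx, , drop = FALSE], vocab,
                     cfg$gene_mask_rate, cfg$meta_mask_rate,
                     age_view_rate = cfg$age_view_rate,
                     recon_age_mask_rate = cfg$recon_age_mask_rate)
    val_masked <- vm
  }

  params <- model$params
  m_state <- lapply(params, function(p) array(0, dim(p)))
  v_state <- lapply(params, function(p) array(0, dim(p)))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  total_steps <- cfg$epochs * ceiling(length(train_idx) / cfg$batch_size)
  trace <- model$loss_trace

  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(train_idx)
    batch_losses <- numeric(0)
    for (start in seq(1L, length(ord), by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      mb <- mask_batch(tokens[idx, , drop = FALSE], vocab,
                       cfg$gene_mask_rate, cfg$meta_mask_rate,
                       meta_weight = cfg$meta_loss_weight,
                       age_view_rate = cfg$age_view_rate,
                     recon_age_mask_rate = cfg$recon_age_mask_rate)
      if (nrow(mb$targets) == 0L) next
      step <- step + 1L
      drop_seed <- as.integer((as.numeric(cfg$seed) * 1000 + step) %%
                                2147483647)
      out <- cpp_mlm_train_batch(mb$tokens, mb$targets, mb$weights, params,
                                 cfg$n_layers, cfg$n_heads,
                                 cfg$dropout, drop_seed, TRUE)
      if (!is.finite(out$loss))
        stop(sprintf(paste0("training diverged: non-finite loss at epoch %d, ",
                            "batch %d; lower the learning rate"),
                     epoch, step))
      batch_losses <- c(batch_losses, out$loss)
      lr_t <- cfg$lr * sqrt(1 - beta2^step) / (1 - beta1^step)
      if (cfg$warmup_steps > 0L)
        lr_t <- lr_t * min(1, step / cfg$warmup_steps)
      if (isTRUE(cfg$lr_decay)) {
        prog <- max(0, (step - cfg$warmup_steps) /
                      max(1, total_steps - cfg$warmup_steps))
        lr_t <- lr_t * (0.1 + 0.9 * 0.5 * (1 + cos(pi * min(1, prog))))
      }
      for (j in seq_along(params)) {
        g <- out$grads[[j]]
        m_state[[j]] <- beta1 * m_state[[j]] + (1 - beta1) * g
        v_state[[j]] <- beta2 * v_state[[j]] + (1 - beta2) * g * g
        params[[j]] <- params[[j]] -
          lr_t * m_state[[j]] / (sqrt(v_state[[j]]) + eps)
      }
    }
    model$params <- params
    val_loss <- if (n_val > 0L)
      eval_loss(model, val_masked$tokens, val_masked$targets) else NA_real_
    trace <- rbind(trace, data.frame(epoch = epoch,
                                     train_loss = mean(batch_losses),
                                     val_loss = val_loss))
  }
  model$params <- params
  model$loss_trace <- trace
  model$trained <- TRUE
  model$val_cells <- val_idx
  model
}

#' Contextual embeddings of a token sequence
#'
#' Runs the full (unmasked) sequence through the encoder and returns the
#' final-layer hidden state at every position. Position 1 is the age
#' token; gene `g` sits at position `4 + g`.
#'
#' @param model A `camap_mlm`.
#' @param tokens Integer token-id vector, or a matrix of sequences.
#' @return A `seq_len x d` matrix for a single sequence, or a
#'   `n_seq * seq_len x d` matrix (sequence-major) for a matrix input.
#' @export
contextual_embeddings <- function(model, tokens) {
  stopifnot(inherits(model, "camap_mlm"))
  single <- is.null(dim(tokens))
  tok <- if (single) matrix(as.integer(tokens), 1L) else tokens
  H <- cpp_mlm_hidden(tok, model$params, model$config$n_layers,
                      model$config$n_heads)
  H
}

#' Predictive distributions at masked positions
#'
#' @param model A `camap_mlm`.
#' @param masked A masked sequence as returned by [mask_sequence()], or a
#'   plain integer vector containing `MASK` tokens.
#' @return Matrix with one row per masked position (in position order) and
#'   `k` columns of probabilities summing to 1; zero rows when nothing is
#'   masked. Row names give the masked positions (1-based).
#' @export
predict_masked <- function(model, masked) {
  vocab <- model$vocab
  tokens <- if (is.list(masked)) masked$tokens else as.integer(masked)
  pos <- which(tokens == vocab$mask_id)
  if (length(pos) == 0L)
    return(matrix(numeric(0), 0L, vocab$k))
  sel <- cbind(1L, pos)
  logits <- cpp_mlm_logits(matrix(tokens, 1L), sel, model$params,
                           model$config$n_layers, model$config$n_heads)
  probs <- softmax_rows(logits)
  rownames(probs) <- pos
  probs
}

# Row-wise softmax with the usual max-shift for numerical stability.
softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Logits at arbitrary (sequence, position) pairs of a batch.
batch_logits <- function(model, tokens, sel) {
  cpp_mlm_logits(tokens, sel, model$params, model$config$n_layers,
                 model$config$n_heads)
}

#' Static embedding of a token
#'
#' Row of the (input) token-embedding table; these are the vectors the
#' tissue/cell-type versus age similarity ranking compares. The output
#' head is untied from this table, so static similarities and predictive
#' distributions are independent measurements.
#'
#' @param model A `camap_mlm`.
#' @param token_id 0-based token id (scalar or vector).
#' @return Numeric matrix, one row per requested token.
#' @export
token_embedding <- function(model, token_id) {
  k <- model$vocab$k
  if (any(token_id < 0L | token_id >= k))
    stop(sprintf("token id out of range [0, %d)", k))
  model$params$E_tok[token_id + 1L, , drop = FALSE]
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single binary file with a JSON sidecar recording
#' the architecture, so a checkpoint can be inspected without loading it.
#'
#' @param model A `camap_mlm`.
#' @param path Checkpoint file path (`.rds`); the sidecar gets `.json`
#'   appended.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  cfg <- model$config
  jsonlite::write_json(list(d = cfg$d, n_layers = cfg$n_layers,
                            n_heads = cfg$n_heads, d_ff = cfg$d_ff,
                            k = model$vocab$k, seq_len = model$vocab$seq_len,
                            seed = cfg$seed, trained = model$trained),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- tryCatch(readRDS(path), error = function(e)
    stop(sprintf("corrupted or unreadable checkpoint '%s': %s", path,
                 conditionMessage(e))))
  if (!inherits(model, "camap_mlm"))
    stop(sprintf("corrupted checkpoint '%s': not a camap_mlm object", path))
  model
}
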