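#' Pipeline configuration
#'
#' Bundles the simulation and model configurations with the analysis
#' parameters and a single global seed. Per-stage seeds are derived from
#' the global seed by hashing the stage name, so each stage is
#' independently reproducible.
#'
#' @param outdir Artifact directory.
#' @param sim A [sim_config()].
#' @param model A [model_config()] (its `seed` is overridden by the
#'   derived stage seed).
#' @param n_expression_bins Expression bins for the vocabulary.
#' @param q Classification percentile.
#' @param min_cells Trajectory support threshold.
#' @param entropy_m Gene positions scored per cell in the entropy stage.
#' @param entropy_cells Cells profiled in the entropy stage.
#' @param bin_width_years Window width of the age-gap profile.
#' @param seed Global seed.
#' @param stages Stages to run, a subset of
#'   `c("simulate", "tokenize", "train", "clock", "cam", "dissipation",
#'   "entropy")`.
#' @return A `camap_pipeline_config`.
#' @export
pipeline_config <- function(outdir,
                            sim = sim_config(),
                            model = model_config(),
                            n_expression_bins = 8L,
                            q = 80, min_cells = 20L,
                            entropy_m = 32L, entropy_cells = 200L,
                            bin_width_years = 5,
                            seed = 1L,
                            stages = c("simulate", "tokenize", "train",
                                       "clock", "cam", "dissipation",
                                       "entropy")) {
  all_stages <- c("simulate", "tokenize", "train", "clock", "cam",
                  "dissipation", "entropy")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  structure(list(outdir = outdir, sim = sim, model = model,
                 n_expression_bins = as.integer(n_expression_bins),
                 q = q, min_cells = as.integer(min_cells),
                 entropy_m = as.integer(entropy_m),
                 entropy_cells = as.integer(entropy_cells),
                 bin_width_years = bin_width_years,
                 seed = as.integer(seed),
                 stages = stages),
            class = "camap_pipeline_config")
}

# Deterministic per-stage seed: global seed plus a small hash of the
# stage name, kept inside the 32-bit integer range.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147483629)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate, tokenize, train, clock, CAM similarity,
#' dissipation and entropy stages, writing every report as TSV plus a
#' JSON run manifest with the derived seeds and output file hashes.
#' Re-running with the same configuration and seed reproduces every TSV
#' byte-identically. Stages not selected must find their upstream
#' artifacts in `outdir`, otherwise the missing artifact is named in an
#' error.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage products
#'   (`study`, `vocab`, `tokens`, `model`, analysis tables) and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "camap_pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sel <- config$stages
  manifest <- list(global_seed = config$seed, stage_seeds = list(),
                   outputs = list(),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   package_version = as.character(utils::packageVersion("camap")))
  outputs <- character(0)

  # ---- simulate -------------------------------------------------------
  study_dir <- file.path(outdir, "study")
  if ("simulate" %in% sel) {
    sim_cfg <- config$sim
    sim_cfg$seed <- stage_seed(config$seed, "simulate")
    manifest$stage_seeds$simulate <- sim_cfg$seed
    study <- simulate_corpus(sim_cfg)
    write_study(study, study_dir)
    outputs <- c(outputs, file.path(study_dir,
                                    c("counts.mtx", "cell_meta.tsv",
                                      "genes.tsv", "study.json",
                                      "ground_truth.json")))
  } else {
    if (!file.exists(file.path(study_dir, "counts.mtx")))
      stop(sprintf("stage 'simulate' skipped but upstream artifact '%s' is missing",
                   file.path(study_dir, "counts.mtx")))
    study <- read_study(study_dir)
  }

  # ---- tokenize -------------------------------------------------------
  vocab_file <- file.path(outdir, "vocabulary.tsv")
  vocab <- build_vocabulary(study, config$n_expression_bins)
  tokens <- encode_study(study, vocab)
  if ("tokenize" %in% sel) {
    write_vocabulary(vocab, vocab_file)
    outputs <- c(outputs, vocab_file)
  }

  # ---- train ----------------------------------------------------------
  ckpt <- file.path(outdir, "model.rds")
  if ("train" %in% sel) {
    mdl_cfg <- config$model
    mdl_cfg$seed <- stage_seed(config$seed, "train")
    manifest$stage_seeds$train <- mdl_cfg$seed
    model <- init_mlm(vocab, mdl_cfg)
    model <- train_mlm(model, tokens)
    save_checkpoint(model, ckpt)
    write_tsv(model$loss_trace, file.path(outdir, "loss_trace.tsv"))
    outputs <- c(outputs, ckpt, paste0(ckpt, ".json"),
                 file.path(outdir, "loss_trace.tsv"))
  } else if (any(c("clock", "cam", "dissipation", "entropy") %in% sel)) {
    if (!file.exists(ckpt))
      stop(sprintf("stage 'train' skipped but upstream artifact '%s' is missing",
                   ckpt))
    model <- load_checkpoint(ckpt)
  } else model <- NULL

  results <- list(study = study, vocab = vocab, tokens = tokens,
                  model = model)

  # ---- clock ----------------------------------------------------------
  if ("clock" %in% sel) {
    eval_cells <- if (length(model$val_cells)) model$val_cells
                  else seq_len(nrow(tokens))
    records <- age_gap_records(model, study, cells = eval_cells,
                               tokens = tokens)
    records <- age_gap_zscores(records)
    by_tissue <- group_correlation(records, "tissue")
    by_ct <- group_correlation(records, "cell_type")
    profile <- gap_by_age_profile(records, config$bin_width_years)
    outputs <- c(outputs,
                 write_tsv(records, file.path(outdir, "clock_records.tsv")),
                 write_tsv(by_tissue, file.path(outdir, "clock_by_tissue.tsv")),
                 write_tsv(by_ct, file.path(outdir, "clock_by_cell_type.tsv")),
                 write_tsv(profile, file.path(outdir, "clock_gap_profile.tsv")))
    results$clock <- list(records = records, by_tissue = by_tissue,
                          by_cell_type = by_ct, profile = profile)
  }

  # ---- cam similarity --------------------------------------------------
  if ("cam" %in% sel) {
    rank_t <- token_similarity_ranking(model, "tissue")
    rank_c <- token_similarity_ranking(model, "cell_type")
    outputs <- c(outputs,
                 write_tsv(rank_t, file.path(outdir, "similarity_tissue.tsv")),
                 write_tsv(rank_c, file.path(outdir, "similarity_cell_type.tsv")))
    results$cam <- list(tissue = rank_t, cell_type = rank_c)
  }

  # ---- dissipation -----------------------------------------------------
  if ("dissipation" %in% sel) {
    trajs <- condition_trajectories(model, study, config$min_cells, tokens)
    prof_h <- drift_profiles(trajs$healthy)
    prof_d <- drift_profiles(trajs$diseased)
    cls <- classify_genes(prof_h, config$q)
    contrast <- condition_contrast(prof_h, prof_d, config$q)
    cls_tab <- cls$table
    cls_tab$delta <- cls$delta
    cls_tab$q <- cls$q
    outputs <- c(outputs,
                 write_tsv(prof_h, file.path(outdir, "drift_healthy.tsv")),
                 write_tsv(prof_d, file.path(outdir, "drift_diseased.tsv")),
                 write_tsv(cls_tab, file.path(outdir, "classification.tsv")),
                 write_tsv(contrast$table, file.path(outdir, "contrast.tsv")))
    results$dissipation <- list(trajectories = trajs, profiles_healthy = prof_h,
                                profiles_diseased = prof_d,
                                classification = cls, contrast = contrast)
  }

  # ---- entropy ---------------------------------------------------------
  if ("entropy" %in% sel) {
    ent_seed <- stage_seed(config$seed, "entropy")
    manifest$stage_seeds$entropy <- ent_seed
    recs <- masked_entropy_profile(model, study, m = config$entropy_m,
                                   max_cells = config$entropy_cells,
                                   tokens = tokens, seed = ent_seed)
    summ <- entropy_by_age(recs)
    outputs <- c(outputs,
                 write_tsv(recs, file.path(outdir, "entropy_records.tsv")),
                 write_tsv(summ$table, file.path(outdir, "entropy_by_age.tsv")))
    results$entropy <- list(records = recs, summary = summ)
  }

  manifest$outputs <- as.list(tools::md5sum(outputs[file.exists(outputs)]))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}
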