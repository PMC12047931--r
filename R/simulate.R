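#' Simulation configuration for a synthetic single-cell aging corpus
#'
#' Builds and validates the parameter set of the synthetic corpus generator.
#' The generator plants two kinds of gene dynamics into a module-structured
#' negative-binomial count model: *conservative* genes keep a fixed loading
#' onto their co-expression module across the lifespan, while *dissipative*
#' genes rotate their loading between two modules across one or two age
#' breakpoints, so that their contextual role (not merely their marginal
#' mean) drifts with age. Disease can flip a subset of conservative genes
#' into dissipative behaviour, and designated "noise-ramp" tissues have
#' negative-binomial dispersion that grows linearly with age.
#'
#' @param n_genes Number of genes.
#' @param n_cells Number of cells.
#' @param n_age_bins Number of equal-width age bins covering `[0, age_max]`
#'   years; bin midpoints are used as chronological age labels. Must be
#'   at least 3 (a baseline bin plus two later bins).
#' @param age_max Upper end of the lifespan in years.
#' @param n_tissues,n_cell_types Number of tissue and cell-type labels.
#' @param diseased_fraction Proportion of cells carrying the disease flag.
#' @param frac_dissipative Proportion of genes planted as dissipative.
#' @param n_modules Number of gene co-expression modules.
#' @param effect_size Dimensionless amplitude of the age-dependent loading
#'   rotation of dissipative genes; `0` makes planted dissipative genes
#'   statistically indistinguishable from conservative ones.
#' @param nb_dispersion_base Baseline negative-binomial dispersion
#'   (`variance = mu + dispersion * mu^2`).
#' @param noise_age_slope Per-bin multiplicative increase of dispersion in
#'   noise-ramp tissues: dispersion scales with `1 + noise_age_slope * t`.
#' @param disease_flip_fraction Proportion of conservative genes that adopt
#'   dissipative dynamics in diseased cells.
#' @param disease_dispersion_factor Multiplicative dispersion inflation in
#'   diseased cells (applies to all genes).
#' @param n_noise_tissues Number of tissues (the first ones by index) whose
#'   dispersion ramps with age.
#' @param activity_sd Per-cell standard deviation of module activities
#'   around their smooth age profile; controls co-expression strength.
#' @param tissue_age_accel Optional numeric vector of length `n_tissues`
#'   with per-tissue aging-rate multipliers; a tissue with multiplier
#'   greater than 1 expresses the transcriptional program of an older age
#'   than its chronological label (a planted fast-aging tissue). `NULL`
#'   means all tissues age at the nominal rate.
#' @param seed Integer seed; identical configuration and seed give a
#'   bit-identical corpus.
#' @return An object of class `camap_sim_config`.
#' @seealso [simulate_corpus()]
#' @export
sim_config <- function(n_genes = 200L,
                       n_cells = 5000L,
                       n_age_bins = 10L,
                       age_max = 80,
                       n_tissues = 3L,
                       n_cell_types = 3L,
                       diseased_fraction = 0.3,
                       frac_dissipative = 0.2,
                       n_modules = 5L,
                       effect_size = 3.5,
                       nb_dispersion_base = 0.3,
                       noise_age_slope = 0.5,
                       disease_flip_fraction = 0.15,
                       disease_dispersion_factor = 1.6,
                       n_noise_tissues = 1L,
                       activity_sd = 0.35,
                       tissue_age_accel = NULL,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
    n_age_bins = as.integer(n_age_bins), age_max = as.numeric(age_max),
    n_tissues = as.integer(n_tissues), n_cell_types = as.integer(n_cell_types),
    diseased_fraction = as.numeric(diseased_fraction),
    frac_dissipative = as.numeric(frac_dissipative),
    n_modules = as.integer(n_modules), effect_size = as.numeric(effect_size),
    nb_dispersion_base = as.numeric(nb_dispersion_base),
    noise_age_slope = as.numeric(noise_age_slope),
    disease_flip_fraction = as.numeric(disease_flip_fraction),
    disease_dispersion_factor = as.numeric(disease_dispersion_factor),
    n_noise_tissues = as.integer(n_noise_tissues),
    activity_sd = as.numeric(activity_sd),
    tissue_age_accel = if (is.null(tissue_age_accel)) NULL else as.numeric(tissue_age_accel),
    seed = as.integer(seed)
  )
  counts <- c("n_genes", "n_cells", "n_age_bins", "n_tissues", "n_cell_types",
              "n_modules")
  for (nm in counts) {
    if (length(cfg[[nm]]) != 1L || is.na(cfg[[nm]]) || cfg[[nm]] < 1L)
      stop(sprintf("'%s' must be a single integer >= 1", nm))
  }
  if (cfg$n_age_bins < 3L)
    stop("'n_age_bins' must be >= 3 (a baseline bin plus at least two later bins)")
  props <- c("diseased_fraction", "frac_dissipative", "disease_flip_fraction")
  for (nm in props) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop(sprintf("'%s' must lie in [0, 1]", nm))
  }
  if (cfg$age_max <= 0) stop("'age_max' must be positive")
  if (cfg$nb_dispersion_base <= 0) stop("'nb_dispersion_base' must be positive")
  if (cfg$noise_age_slope < 0) stop("'noise_age_slope' must be non-negative")
  if (cfg$disease_dispersion_factor <= 0)
    stop("'disease_dispersion_factor' must be positive")
  if (cfg$n_noise_tissues < 0L || cfg$n_noise_tissues > cfg$n_tissues)
    stop("'n_noise_tissues' must lie in [0, n_tissues]")
  if (cfg$effect_size < 0) stop("'effect_size' must be non-negative")
  if (cfg$activity_sd < 0) stop("'activity_sd' must be non-negative")
  if (!is.null(cfg$tissue_age_accel)) {
    if (length(cfg$tissue_age_accel) != cfg$n_tissues ||
        any(!is.finite(cfg$tissue_age_accel)) || any(cfg$tissue_age_accel <= 0))
      stop("'tissue_age_accel' must be a positive numeric vector of length n_tissues")
  }
  if (is.na(cfg$seed)) stop("'seed' must be an integer")
  structure(cfg, class = "camap_sim_config")
}

# Smooth ramp r(tau) in [0,1] encoding the loading rotation of a dynamic
# gene: one breakpoint = monotone transition, two = up-then-down.
ramp_value <- function(bp, tau) {
  r <- stats::plogis((tau - bp$b1) / bp$width)
  if (bp$n_bp == 2L) r <- r - stats::plogis((tau - bp$b2) / bp$width)
  r
}

#' Generate a synthetic single-cell aging corpus
#'
#' Draws a cell-by-gene negative-binomial count matrix under a
#' module-structured latent model. Each gene loads on a co-expression
#' module whose activity follows a smooth, module-specific age profile;
#' per-cell activities scatter around that profile. The cell-level log-mean
#' is `mu = base + loading(age) . activity + tissue and cell-type offsets`.
#' Conservative genes keep a constant loading; dissipative genes rotate
#' their loading between two modules across one or two age breakpoints
#' with amplitude `effect_size`; disease-flipped genes do the same but
#' only in diseased cells. Dispersion grows linearly with age in
#' noise-ramp tissues and is inflated in diseased cells.
#'
#' Cells are allocated deterministically so that every
#' (age bin, tissue, disease) stratum is populated; an error names the
#' first empty stratum when `n_cells` is too small.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `camap_study` with elements
#'   \describe{
#'     \item{counts}{sparse `dgCMatrix`, cells x genes, non-negative integers}
#'     \item{cell_meta}{data frame with `cell_id`, `age_bin` (0-based),
#'       `age_years` (bin midpoint), `tissue`, `cell_type` (0-based ids) and
#'       `disease` (0/1)}
#'     \item{gene_ids}{character vector of gene identifiers}
#'     \item{ground_truth}{planted labels: `dissipative_genes`,
#'       `conservative_genes`, `disease_flipped_genes` (1-based gene
#'       indices), `noise_ramp_tissues` (0-based tissue ids), module
#'       membership and breakpoints, and `tissue_age_accel`}
#'     \item{latent_mu}{dense matrix of latent log-means, exposed for
#'       recovery testing (not serialized by [write_study()])}
#'   }
#' @examples
#' study <- simulate_corpus(sim_config(n_genes = 20, n_cells = 120,
#'                                     n_age_bins = 4, seed = 1))
#' dim(study$counts)
#' @export
simulate_corpus <- function(config) {
  if (!inherits(config, "camap_sim_config"))
    config <- do.call(sim_config, as.list(config))
  cfg <- config
  set.seed(cfg$seed)

  T <- cfg$n_age_bins
  bin_width <- cfg$age_max / T
  midpoints <- (seq_len(T) - 0.5) * bin_width

  # ---- deterministic stratum allocation -------------------------------
  disease_levels <- if (cfg$diseased_fraction <= 0) 0L
                    else if (cfg$diseased_fraction >= 1) 1L
                    else c(0L, 1L)
  strata <- expand.grid(age_bin = 0:(T - 1L), tissue = 0:(cfg$n_tissues - 1L),
                        disease = disease_levels, KEEP.OUT.ATTRS = FALSE)
  dw <- ifelse(strata$disease == 1L, cfg$diseased_fraction,
               1 - cfg$diseased_fraction)
  if (length(disease_levels) == 1L) dw[] <- 1
  w <- dw / (T * cfg$n_tissues)
  n_s <- floor(cfg$n_cells * w)
  rem <- cfg$n_cells - sum(n_s)
  if (rem > 0) {
    frac <- cfg$n_cells * w - n_s
    add <- order(frac, seq_along(frac), decreasing = TRUE)[seq_len(rem)]
    n_s[add] <- n_s[add] + 1L
  }
  if (any(n_s == 0L)) {
    i <- which(n_s == 0L)[1L]
    stop(sprintf(paste0("infeasible stratification: stratum (age_bin=%d, ",
                        "tissue=%d, disease=%d) receives no cells; ",
                        "increase n_cells (need at least %d)"),
                 strata$age_bin[i], strata$tissue[i], strata$disease[i],
                 nrow(strata)))
  }
  cell_meta <- strata[rep(seq_len(nrow(strata)), n_s), , drop = FALSE]
  cell_meta$cell_type <- sample.int(cfg$n_cell_types, nrow(cell_meta),
                                    replace = TRUE) - 1L
  cell_meta <- cell_meta[sample.int(nrow(cell_meta)), , drop = FALSE]
  rownames(cell_meta) <- NULL
  n_cells <- nrow(cell_meta)
  cell_meta$age_years <- midpoints[cell_meta$age_bin + 1L]
  cell_meta$cell_id <- sprintf("cell_%05d", seq_len(n_cells))
  cell_meta <- cell_meta[, c("cell_id", "age_bin", "age_years", "tissue",
                             "cell_type", "disease")]

  # ---- planted gene labels --------------------------------------------
  G <- cfg$n_genes
  n_diss <- round(cfg$frac_dissipative * G)
  dissipative <- sort(sample.int(G, n_diss))
  conservative <- setdiff(seq_len(G), dissipative)
  n_flip <- round(cfg$disease_flip_fraction * length(conservative))
  flipped <- if (n_flip > 0) sort(sample(conservative, n_flip)) else integer(0)
  noise_tissues <- if (cfg$n_noise_tissues > 0) 0:(cfg$n_noise_tissues - 1L)
                   else integer(0)

  module1 <- sample.int(cfg$n_modules, G, replace = TRUE)
  module2 <- vapply(module1, function(m) {
    if (cfg$n_modules == 1L) return(m)
    sample(setdiff(seq_len(cfg$n_modules), m), 1L)
  }, integer(1))

  dynamic <- sort(union(dissipative, flipped))
  breakpoints <- lapply(dynamic, function(g) {
    n_bp <- sample(1:2, 1L)
    b1 <- stats::runif(1, 0.1, 0.65)
    b2 <- if (n_bp == 2L) stats::runif(1, min(b1 + 0.2, 0.9), 0.95) else NA_real_
    list(gene = g, n_bp = n_bp, b1 = b1, b2 = b2, width = 0.08)
  })
  names(breakpoints) <- as.character(dynamic)

  # ---- latent model ----------------------------------------------------
  # Each module has a smooth age-coupled activity profile plus per-cell
  # fluctuation. Conservative genes couple only to their module's
  # age-centered fluctuation (stable mean and stable contextual role);
  # dissipative genes rotate, across their breakpoints, into the *full*
  # (age-coupled) activity of a second module, so both their conditional
  # mean given age and their co-expression partners drift.
  amp <- stats::runif(cfg$n_modules, 1.0, 1.5)
  freq <- sample(c(0.5, 0.75, 1, 1.25, 1.5), cfg$n_modules, replace = TRUE)
  phase <- stats::runif(cfg$n_modules, 0, 2 * pi)
  module_profile <- function(m, tau) amp[m] * sin(2 * pi * freq[m] * tau + phase[m])

  base <- stats::rnorm(G, mean = log(15), sd = 0.7)
  loading <- stats::runif(G, 0.5, 1.0)
  tissue_off <- matrix(stats::rnorm(cfg$n_tissues * G, sd = 0.2),
                       cfg$n_tissues, G)
  ct_off <- matrix(stats::rnorm(cfg$n_cell_types * G, sd = 0.2),
                   cfg$n_cell_types, G)

  accel <- if (is.null(cfg$tissue_age_accel)) rep(1, cfg$n_tissues)
           else cfg$tissue_age_accel
  tau <- if (T > 1L) cell_meta$age_bin / (T - 1L) else rep(0, n_cells)
  tau_eff <- pmin(1, tau * accel[cell_meta$tissue + 1L])

  # per-cell module fluctuations and full (trend + fluctuation) activities
  A_noise <- matrix(stats::rnorm(n_cells * cfg$n_modules,
                                 sd = cfg$activity_sd),
                    n_cells, cfg$n_modules)
  A_trend <- vapply(seq_len(cfg$n_modules), function(m)
    module_profile(m, tau_eff), numeric(n_cells))
  A_full <- A_trend + A_noise

  contrib <- A_noise[, module1, drop = FALSE]
  contrib <- sweep(contrib, 2L, loading, `*`)
  # dissipative-style rotation between primary and secondary module
  diseased_cell <- cell_meta$disease == 1L
  for (key in names(breakpoints)) {
    bp <- breakpoints[[key]]
    g <- bp$gene
    r <- cfg$effect_size * ramp_value(bp, tau_eff)
    rotated <- loading[g] * ((1 - r) * A_noise[, module1[g]] +
                               r * A_full[, module2[g]])
    if (g %in% dissipative) {
      contrib[, g] <- rotated
    } else {
      contrib[diseased_cell, g] <- rotated[diseased_cell]
    }
  }

  mu <- matrix(base, n_cells, G, byrow = TRUE) + contrib +
    tissue_off[cell_meta$tissue + 1L, , drop = FALSE] +
    ct_off[cell_meta$cell_type + 1L, , drop = FALSE]
  mu <- pmin(mu, log(5e3))

  dispersion <- rep(cfg$nb_dispersion_base, n_cells)
  in_ramp <- cell_meta$tissue %in% noise_tissues
  dispersion[in_ramp] <- dispersion[in_ramp] *
    (1 + cfg$noise_age_slope * cell_meta$age_bin[in_ramp])
  dispersion[diseased_cell] <- dispersion[diseased_cell] *
    cfg$disease_dispersion_factor

  counts <- matrix(0L, n_cells, G)
  for (g in seq_len(G)) {
    counts[, g] <- stats::rnbinom(n_cells, size = 1 / dispersion,
                                  mu = exp(mu[, g]))
  }
  gene_ids <- sprintf("gene_%04d", seq_len(G))
  dimnames(counts) <- list(cell_meta$cell_id, gene_ids)

  ground_truth <- list(
    dissipative_genes = dissipative,
    conservative_genes = conservative,
    disease_flipped_genes = flipped,
    noise_ramp_tissues = noise_tissues,
    module1 = module1, module2 = module2,
    breakpoints = breakpoints,
    tissue_age_accel = accel
  )

  structure(list(
    counts = methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                     "generalMatrix"), "CsparseMatrix"),
    cell_meta = cell_meta,
    gene_ids = gene_ids,
    n_age_bins = T,
    age_bin_width = bin_width,
    age_midpoints = midpoints,
    ground_truth = ground_truth,
    latent_mu = mu,
    config = cfg
  ), class = "camap_study")
}

#' @exportS3Method base::print
print.camap_study <- function(x, ...) {
  cat(sprintf("camap_study: %d cells x %d genes, %d age bins (width %.1f y)\n",
              nrow(x$counts), ncol(x$counts), x$n_age_bins, x$age_bin_width))
  cat(sprintf("  tissues: %d, cell types: %d, diseased cells: %d\n",
              length(unique(x$cell_meta$tissue)),
              length(unique(x$cell_meta$cell_type)),
              sum(x$cell_meta$disease)))
  if (!is.null(x$ground_truth))
    cat(sprintf("  ground truth: %d dissipative / %d conservative / %d flipped genes\n",
                length(x$ground_truth$dissipative_genes),
                length(x$ground_truth$conservative_genes),
                length(x$ground_truth$disease_flipped_genes)))
  invisible(x)
}
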