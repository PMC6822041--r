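# Full study workflow: simulate/load -> arc measurement -> GPA (+ sliding)
# -> species means -> traditional and geometric-morphometric statistics ->
# modularity/integration -> traditional-vs-GM comparison -> report.

#' Pipeline run configuration
#'
#' @param scenario A [scenario()] for synthetic data, or `NULL` to read the
#'   file inputs.
#' @param tps,tree,metadata Input file paths (TPS landmarks, Newick tree,
#'   CSV metadata) used when `scenario` is `NULL`.
#' @param slide Slide semilandmarks after GPA?
#' @param slide_iters Outer sliding iterations.
#' @param n_perm Permutations for all permutation tests (>= 99).
#' @param n_sim Brownian simulations for the phylogenetic ANOVAs.
#' @param seed Master seed; all stage seeds derive from it.
#' @param length_method `"arc"` or `"chord"` lengths for the traditional
#'   protocol.
#' @param ci_level,ci_method Confidence-interval level and type
#'   (`"t"` or `"percentile"`).
#' @param out_dir Optional output directory for JSON/CSV artifacts.
#' @return A list of class `run_config`.
#' @export
run_config <- function(scenario = NULL, tps = NULL, tree = NULL,
                       metadata = NULL, slide = TRUE, slide_iters = 3L,
                       n_perm = 999L, n_sim = 1000L, seed = 1L,
                       length_method = c("arc", "chord"), ci_level = 0.95,
                       ci_method = c("t", "percentile"), out_dir = NULL) {
  length_method <- match.arg(length_method)
  ci_method <- match.arg(ci_method)
  if (n_perm < 99L) stop("`n_perm` must be at least 99", call. = FALSE)
  if (is.null(scenario) && (is.null(tps) || is.null(tree) || is.null(metadata)))
    stop("provide either a scenario or tps + tree + metadata paths", call. = FALSE)
  structure(list(scenario = scenario, tps = tps, tree = tree,
                 metadata = metadata, slide = isTRUE(slide),
                 slide_iters = as.integer(slide_iters),
                 n_perm = as.integer(n_perm), n_sim = as.integer(n_sim),
                 seed = as.integer(seed), length_method = length_method,
                 ci_level = ci_level, ci_method = ci_method,
                 out_dir = out_dir),
            class = "run_config")
}

#' Confidence interval for a mean
#'
#' @param values Numeric vector (n >= 2).
#' @param level Confidence level.
#' @param method `"t"` (mean +/- t quantile * se) or `"percentile"`
#'   (empirical quantiles of the values).
#' @return A named vector `c(lo, hi)`.
#' @export
confidence_intervals <- function(values, level = 0.95,
                                 method = c("t", "percentile")) {
  method <- match.arg(method)
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("need at least 2 values for a confidence interval", call. = FALSE)
  if (method == "t") {
    m <- mean(values)
    half <- stats::qt(1 - (1 - level) / 2, df = n - 1L) *
      stats::sd(values) / sqrt(n)
    c(lo = m - half, hi = m + half)
  } else {
    q <- stats::quantile(values, c((1 - level) / 2, 1 - (1 - level) / 2),
                         names = FALSE)
    c(lo = q[1L], hi = q[2L])
  }
}

claw_test_summary <- function(x) {
  out <- list(statistic = x$statistic, p_value = x$p_value)
  if (!is.null(x$effect_size_z)) out$effect_size_z <- x$effect_size_z
  if (!is.null(x$n_perm)) out$n_perm <- x$n_perm
  if (!is.null(x$seed)) out$seed <- x$seed
  if (!is.null(x$lambda)) out$lambda <- x$lambda
  if (!is.null(x$null_summary))
    out$null <- list(mean = x$null_summary$mean, sd = x$null_summary$sd)
  out
}

#' Run the complete claw-shape analysis pipeline
#'
#' Executes, in order: data load/simulation, per-specimen arc measurement,
#' GPA with optional bending-energy sliding, per-specimen PCA (individual
#' variation), species means, PGLS and simulation-based phylogenetic ANOVA
#' on the traditional metrics with log centroid size as covariate, K-mult,
#' the allometry (CAC) test, the phylogenetic Procrustes ANOVA, disparity,
#' the core-vs-sheath analyses (PGLS, residual ANOVA, paired t, CR
#' modularity, phylogenetic PLS, per-group PLS comparison), and the
#' traditional-vs-geometric-morphometric two-block PLS (species means with
#' phylogeny; individuals without). Deterministic for a fixed config.
#'
#' @param config A [run_config()].
#' @return A list of class `study_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  np <- config$n_perm

  ## stage: data
  if (!is.null(config$scenario)) {
    sim <- simulate_dataset(config$scenario, seed = seed)
    configs <- sim$configs; metadata <- sim$metadata; tree <- sim$tree
    truth <- sim$truth
  } else {
    configs <- read_tps(config$tps)
    metadata <- read_metadata(config$metadata)
    configs <- apply_metadata(configs, metadata)
    tree <- read_newick(config$tree)
    truth <- NULL
  }

  ## stage: traditional arc measurement
  trad <- measure_claws(configs, length_method = config$length_method)
  excluded <- attr(trad, "excluded")
  if (length(excluded) > 0L)
    configs <- configs[!vapply(configs, function(x)
      x$specimen_id %in% excluded, TRUE)]

  ## stage: superimposition
  aligned <- gpa(configs)
  if (config$slide)
    aligned <- slide_semilandmarks(aligned, outer_iters = config$slide_iters)

  ## stage: individual variation (all specimens)
  pca_all <- shape_pca(aligned)

  ## stage: species means
  sp_shapes <- species_means(aligned)
  trad$log_core_arc <- log(trad$core_arc_deg)
  trad$log_sheath_arc <- log(trad$sheath_arc_deg)
  sp_trad <- species_means(trad)
  sp <- sp_shapes$species
  stopifnot(identical(sort(sp), sort(sp_trad$species)))
  sp_trad <- sp_trad[match(sp, sp_trad$species), ]
  logcs <- log(sp_shapes$centroid_sizes)
  eco <- factor(sp_shapes$ecology)
  tree_p <- prune_tree(tree, sp)
  C <- phylo_covariance(tree_p, sp)
  Ysp <- as_shape_matrix(sp_shapes)

  ## stage: traditional metrics vs ecology (PGLS with size, phylo ANOVA)
  metrics <- c(length_ratio = "length_ratio", log_core_arc = "log_core_arc",
               log_sheath_arc = "log_sheath_arc")
  trad_tests <- lapply(seq_along(metrics), function(mi) {
    m <- metrics[mi]
    y <- sp_trad[[m]]
    fit <- pgls_ml_lambda(y, data.frame(logCS = logcs, ecology = eco), C)
    size_fit <- pgls_ml_lambda(y, data.frame(logCS = logcs), C)
    anova_res <- phylo_anova_sim(size_fit$residuals, eco, C,
                                 n_sim = config$n_sim, seed = seed + 100L + mi)
    list(metric = unname(m), pgls = fit, anova = anova_res)
  })
  names(trad_tests) <- names(metrics)

  ## stage: geometric morphometrics, ecological signal
  km <- k_mult(Ysp, C, n_perm = np, seed = seed + 201L)
  pca_sp <- shape_pca(sp_shapes)
  cac <- common_allometric_component(sp_shapes, n_perm = np, seed = seed + 202L)
  panova <- phylo_procrustes_anova(Ysp, logcs, eco, C, n_perm = np,
                                   seed = seed + 203L)
  disp <- morphological_disparity(sp_shapes, eco, n_perm = np,
                                  seed = seed + 204L)

  ## stage: bony core vs keratinous sheath
  core_sheath_pgls <- pgls_ml_lambda(sp_trad$log_sheath_arc,
                                     data.frame(log_core_arc = sp_trad$log_core_arc,
                                                logCS = logcs), C)
  resid_anova <- phylo_anova_sim(core_sheath_pgls$residuals, eco, C,
                                 n_sim = config$n_sim, seed = seed + 301L)
  paired_t <- phylo_paired_t(sp_trad$log_core_arc, sp_trad$log_sheath_arc, C)
  part <- landmark_partition()
  cr <- modularity_cr(Ysp, part, C = C, n_perm = np, seed = seed + 302L)
  core_cols <- landmark_cols(part$core)
  sheath_cols <- landmark_cols(part$sheath)
  pls_cs <- phylo_two_block_pls(Ysp[, core_cols], Ysp[, sheath_cols], C = C,
                                n_perm = np, seed = seed + 303L)
  # per-ecology integration, compared pairwise (groups need enough species)
  pls_groups <- list()
  for (g in levels(eco)) {
    i <- which(eco == g)
    if (length(i) >= 4L) {
      Cg <- C[i, i, drop = FALSE]
      pls_groups[[g]] <- phylo_two_block_pls(Ysp[i, core_cols],
                                             Ysp[i, sheath_cols], C = Cg,
                                             n_perm = np,
                                             seed = seed + 310L + length(pls_groups))
    }
  }
  pls_compare <- if (length(pls_groups) >= 2L) compare_pls(pls_groups) else NULL

  ## stage: traditional vs geometric morphometric data
  trad_block_sp <- as.matrix(sp_trad[, c("length_ratio", "log_core_arc",
                                         "log_sheath_arc")])
  pls_trad_gm <- phylo_two_block_pls(trad_block_sp, Ysp, C = C, n_perm = np,
                                     seed = seed + 401L)
  trad_block_ind <- as.matrix(trad[, c("length_ratio", "log_core_arc",
                                       "log_sheath_arc")])
  pls_trad_gm_ind <- phylo_two_block_pls(trad_block_ind,
                                         as_shape_matrix(aligned), C = NULL,
                                         n_perm = np, seed = seed + 402L)

  ## stage: traditional-metric summaries with confidence intervals
  ci_of <- function(v) confidence_intervals(v, config$ci_level, config$ci_method)
  metric_cols <- c("length_ratio", "core_arc_deg", "sheath_arc_deg")
  overall_ci <- lapply(metric_cols, function(m) ci_of(trad[[m]]))
  names(overall_ci) <- metric_cols
  top_sp <- names(sort(table(trad$species), decreasing = TRUE))
  top_sp <- top_sp[seq_len(min(4L, length(top_sp)))]
  species_ci <- lapply(top_sp, function(s) {
    v <- trad[trad$species == s, metric_cols, drop = FALSE]
    if (nrow(v) < 2L) return(NULL)
    lapply(as.list(v), ci_of)
  })
  names(species_ci) <- top_sp

  report <- structure(list(
    config = list(n_perm = np, n_sim = config$n_sim, seed = seed,
                  slide = config$slide, slide_iters = config$slide_iters,
                  length_method = config$length_method,
                  ci_level = config$ci_level, ci_method = config$ci_method,
                  synthetic = !is.null(config$scenario)),
    counts = list(n_specimens = nrow(trad), n_species = length(sp),
                  n_excluded = length(excluded), excluded = excluded,
                  groups = as.list(table(eco))),
    traditional = list(summary_ci = overall_ci, species_ci = species_ci,
                       tests = lapply(trad_tests, function(tt) list(
                         metric = tt$metric,
                         pgls = list(lambda = tt$pgls$lambda, r2 = tt$pgls$r2,
                                     coefficients = tt$pgls$coefficients),
                         anova = c(claw_test_summary(tt$anova),
                                   list(pairwise = tt$anova$pairwise))))),
    gm = list(pca_species = list(percent_variance = pca_sp$percent_variance,
                                 scores = pca_sp$scores[, seq_len(min(4L, ncol(pca_sp$scores))), drop = FALSE]),
              pca_individuals = list(percent_variance = pca_all$percent_variance),
              k_mult = claw_test_summary(km),
              allometry = c(claw_test_summary(cac), list(r2 = cac$r2)),
              procrustes_anova = list(table = panova$table,
                                      pairwise = panova$pairwise),
              disparity = list(group_pv = as.list(disp$group_pv),
                               pairwise_p = as.list(disp$pairwise_p))),
    core_sheath = list(
      pgls = list(lambda = core_sheath_pgls$lambda, r2 = core_sheath_pgls$r2,
                  slope = unname(core_sheath_pgls$coefficients["log_core_arc",
                                                               "estimate"]),
                  coefficients = core_sheath_pgls$coefficients),
      residual_anova = claw_test_summary(resid_anova),
      paired_t = list(statistic = paired_t$statistic, p_value = paired_t$p_value,
                      lambda = paired_t$lambda, df = paired_t$df),
      modularity_cr = claw_test_summary(cr),
      pls = claw_test_summary(pls_cs),
      pls_by_group = lapply(pls_groups, claw_test_summary),
      pls_group_comparison = pls_compare),
    trad_vs_gm = list(pls_species = claw_test_summary(pls_trad_gm),
                      pls_individuals = claw_test_summary(pls_trad_gm_ind)),
    objects = list(aligned = aligned, species_shapes = sp_shapes,
                   traditional = trad, species_traditional = sp_trad,
                   tree = tree_p, C = C, pca_species = pca_sp,
                   pca_individuals = pca_all, truth = truth)),
    class = "study_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("study_report: %d specimens, %d species (%d excluded)\n",
              x$counts$n_specimens, x$counts$n_species, x$counts$n_excluded))
  cat(sprintf("  K_mult = %.3f (p = %.3g); allometry R2 = %.3f (p = %.3g)\n",
              x$gm$k_mult$statistic, x$gm$k_mult$p_value,
              x$gm$allometry$r2, x$gm$allometry$p_value))
  cat(sprintf("  core~sheath PGLS: lambda = %.3f, m = %.3f, R2 = %.3f\n",
              x$core_sheath$pgls$lambda, x$core_sheath$pgls$slope,
              x$core_sheath$pgls$r2))
  cat(sprintf("  CR = %.3f (p = %.3g); core-sheath r-PLS = %.3f (p = %.3g)\n",
              x$core_sheath$modularity_cr$statistic,
              x$core_sheath$modularity_cr$p_value,
              x$core_sheath$pls$statistic, x$core_sheath$pls$p_value))
  invisible(x)
}

#' Write a study report to disk
#'
#' Emits `report.json` (all statistics, no timestamps, deterministic for a
#' fixed config and seed) plus CSV tables of traditional measurements,
#' species means, and species PC scores.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json <- report[setdiff(names(report), "objects")]
  jsonlite::write_json(json, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  utils::write.csv(report$objects$traditional,
                   file.path(dir, "traditional_measurements.csv"),
                   row.names = FALSE)
  utils::write.csv(report$objects$species_traditional,
                   file.path(dir, "species_traditional.csv"), row.names = FALSE)
  scores <- report$objects$pca_species$scores
  utils::write.csv(data.frame(species = rownames(scores), scores,
                              check.names = FALSE),
                   file.path(dir, "species_pc_scores.csv"), row.names = FALSE)
  ape::write.tree(report$objects$tree, file.path(dir, "pruned_tree.nwk"))
  invisible(dir)
}
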