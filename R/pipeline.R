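# plain TSV readers/writers for the pipeline's on-disk interfaces

#' Write / read a gene x sample count matrix as TSV
#'
#' Header row carries sample ids; first column the gene id.
#' @param counts Integer matrix.
#' @param path File path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write a data.frame as plain TSV
#' @param df Data.frame.
#' @param path File path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects the analysis thresholds (all overridable, defaults as used
#' throughout the package), the RNG seed, the output directory and the
#' simulation configuration for runs that start from synthetic data.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Global seed; per-stage seeds are derived by fixed offsets so
#'   stages stay reproducible when others are skipped.
#' @param sim [sim_config()] for the simulate stage.
#' @param de_fdr,pheno_fdr DE / phenotype-association FDR thresholds.
#' @param r_threshold,min_donors Reproducibility filter parameters.
#' @param k Number of temporal clusters.
#' @param snp_alpha GWAS significance level.
#' @param windows TSS window sweep in bp.
#' @param target_score Network edge score threshold.
#' @param activity_p Differential-activity call threshold.
#' @param stages Character vector of stages to run, in order.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1, sim = sim_config(seed = seed),
                            de_fdr = 1e-4, pheno_fdr = 1e-2,
                            r_threshold = 0.8, min_donors = 6, k = 8,
                            snp_alpha = 5e-8,
                            windows = c(50, 100, 250, 500, 1000, 2500) * 1e3,
                            target_score = 2, activity_p = 1e-3,
                            stages = c("simulate", "de", "filter", "cluster",
                                       "enrich", "gwas", "mara", "network",
                                       "coexpr")) {
  stopifnot(de_fdr > 0, de_fdr < 1, pheno_fdr > 0, pheno_fdr < 1,
            r_threshold >= -1, r_threshold <= 1, min_donors >= 1, k >= 2,
            snp_alpha > 0, snp_alpha < 1, all(windows > 0), target_score >= 0,
            activity_p > 0, activity_p < 1)
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 de_fdr = de_fdr, pheno_fdr = pheno_fdr,
                 r_threshold = r_threshold, min_donors = min_donors, k = k,
                 snp_alpha = snp_alpha, windows = windows,
                 target_score = target_score, activity_p = activity_p,
                 stages = stages),
            class = "pipeline_config")
}

#' Run the analysis pipeline end to end
#'
#' Executes the enabled stages in order -- simulate, normalize/DE, filter,
#' cluster, enrichment, GWAS window enrichment, motif activity, network,
#' coexpression -- writing every stage's outputs as TSV under
#' `config$out_dir` together with the resolved configuration (JSON) and a
#' manifest listing each file with its md5 checksum. A stage failure halts
#' the run with an error naming the stage; outputs of completed stages are
#' retained. When the simulate stage is skipped, later stages read their
#' inputs from `out_dir` and halt (naming themselves) if an input is
#' missing. Deterministic given `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest data.frame (file, md5).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  env <- new.env(parent = emptyenv())
  stage_fns <- list(simulate = .stage_simulate, de = .stage_de,
                    filter = .stage_filter, cluster = .stage_cluster,
                    enrich = .stage_enrich, gwas = .stage_gwas,
                    mara = .stage_mara, network = .stage_network,
                    coexpr = .stage_coexpr)
  unknown <- setdiff(config$stages, names(stage_fns))
  if (length(unknown) > 0) stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  t_all <- Sys.time()
  for (st in config$stages) {
    t0 <- Sys.time()
    tryCatch(stage_fns[[st]](config, env),
             error = function(e) {
               stop(sprintf("stage '%s' failed: %s", st, conditionMessage(e)),
                    call. = FALSE)
             })
    message(sprintf("[%s] done in %.1fs", st,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  cfg <- config
  cfg$sim <- unclass(cfg$sim)
  cfg$out_dir <- NULL   # keep the resolved config path-free and reproducible
  jsonlite::write_json(unclass(cfg), file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- sort(setdiff(list.files(config$out_dir), "manifest.tsv"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(config$out_dir, files))),
    stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(config$out_dir, "manifest.tsv"))
  message(sprintf("pipeline finished in %.1fs",
                  as.numeric(difftime(Sys.time(), t_all, units = "secs"))))
  invisible(manifest)
}

.path <- function(config, name) file.path(config$out_dir, name)

.need <- function(config, env, key, file, reader) {
  if (!is.null(env[[key]])) return(env[[key]])
  p <- .path(config, file)
  if (!file.exists(p)) stop("required input '", file, "' not found")
  env[[key]] <- reader(p)
  env[[key]]
}

.stage_simulate <- function(config, env) {
  sim <- config$sim
  sim$seed <- .child_seed(config$seed, 1)
  sim <- do.call(sim_config, sim[setdiff(names(sim), character(0))])
  world <- generate_timecourse(sim)
  env$counts <- world$counts
  env$design <- world$design
  env$truth <- world$truth
  env$ann <- generate_annotation(rownames(world$counts),
                                 seed = .child_seed(config$seed, 2))
  reg <- generate_regulatory_truth(n_tfs = 40, n_genes = 500,
                                   targets_per_tf = 10, n_clusters = 12,
                                   coupling = 0.8,
                                   seed = .child_seed(config$seed, 3))
  env$reg <- reg
  planted <- split(world$truth$gene_id[world$truth$archetype != "null"],
                   world$truth$archetype[world$truth$archetype != "null"])
  write_counts(world$counts, .path(config, "counts.tsv"))
  write_tsv(world$design, .path(config, "design.tsv"))
  write_tsv(world$truth, .path(config, "truth.tsv"))
  write_tsv(env$ann, .path(config, "annotation.tsv"))
  write_gmt(planted, .path(config, "planted_sets.gmt"))
  sig_arch <- world$truth$archetype[world$truth$archetype != "null"][1]
  target <- world$truth$gene_id[world$truth$archetype == sig_arch &
                                  world$truth$donor_consistent]
  env$gwas <- generate_gwas(env$ann, target, n_snps = 20000, window_bp = 250e3,
                            sig_rate_near = 0.2, sig_rate_bg = 0.02,
                            seed = .child_seed(config$seed, 4))
  env$gwas_target <- target
  write_tsv(env$gwas, .path(config, "gwas_snps.tsv"))
  mc <- reg$motif_counts
  write_tsv(data.frame(gene = rownames(mc), mc, check.names = FALSE),
            .path(config, "motif_counts.tsv"))
  ce <- reg$cluster_expr
  write_tsv(data.frame(gene = rownames(ce), ce, check.names = FALSE),
            .path(config, "cluster_expression.tsv"))
  write_tsv(reg$truth, .path(config, "regulatory_truth.tsv"))
  invisible(NULL)
}

.stage_de <- function(config, env) {
  counts <- .need(config, env, "counts", "counts.tsv", read_counts)
  design <- .need(config, env, "design", "design.tsv", utils::read.delim)
  sf <- size_factors(counts)
  env$sf <- sf
  env$de <- lrt_timepoint(counts, sf, design, fdr_threshold = config$de_fdr)
  env$de$log2fc_last_vs_second <- log2fc(counts, sf, design,
                                         sort(unique(design$day))[2],
                                         max(design$day))
  write_tsv(data.frame(sample = names(sf), size_factor = sf),
            .path(config, "size_factors.tsv"))
  write_tsv(env$de, .path(config, "de_timepoint.tsv"))
  invisible(NULL)
}

.stage_filter <- function(config, env) {
  counts <- .need(config, env, "counts", "counts.tsv", read_counts)
  design <- .need(config, env, "design", "design.tsv", utils::read.delim)
  if (is.null(env$sf)) env$sf <- size_factors(counts)
  if (is.null(env$de)) stop("de stage outputs not available")
  de_genes <- env$de$gene[env$de$de]
  prof <- donor_profiles(counts, env$sf, design)
  filt <- reproducibility_filter(prof, config$r_threshold, config$min_donors)
  env$prof <- prof
  env$kept <- intersect(de_genes, filt$kept)
  write_tsv(filt$records, .path(config, "reproducibility.tsv"))
  invisible(NULL)
}

.stage_cluster <- function(config, env) {
  if (is.null(env$prof) || is.null(env$kept)) stop("filter stage outputs not available")
  mp <- env$prof$mean_profile[env$kept, , drop = FALSE]
  ca <- kmeans_cluster(mp, k = config$k, seed = .child_seed(config$seed, 5),
                       timepoints = env$prof$timepoints)
  ca <- label_archetypes(ca)
  env$clusters <- ca
  write_tsv(ca$assignment, .path(config, "clusters.tsv"))
  write_tsv(data.frame(cluster = rownames(ca$centroids),
                       archetype = ca$labels, ca$centroids,
                       check.names = FALSE),
            .path(config, "centroids.tsv"))
  invisible(NULL)
}

.stage_enrich <- function(config, env) {
  if (is.null(env$clusters)) stop("cluster stage outputs not available")
  p <- .path(config, "planted_sets.gmt")
  if (!file.exists(p)) stop("required input 'planted_sets.gmt' not found")
  collection <- read_gmt(p)
  universe <- env$de$gene[env$de$status == "tested"]
  res <- enrich_matrix(env$clusters, collection, universe, adjust = TRUE)
  write_tsv(res, .path(config, "enrichment_planted.tsv"))
  invisible(NULL)
}

.stage_gwas <- function(config, env) {
  snps <- .need(config, env, "gwas", "gwas_snps.tsv", utils::read.delim)
  ann <- .need(config, env, "ann", "annotation.tsv", utils::read.delim)
  if (is.null(env$clusters)) stop("cluster stage outputs not available")
  snps <- classify_snps(snps, config$snp_alpha)
  res <- cluster_snp_enrichment(snps, ann, env$clusters, config$windows)
  write_tsv(res, .path(config, "snp_enrichment.tsv"))
  invisible(NULL)
}

.read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

.stage_mara <- function(config, env) {
  if (is.null(env$reg)) {
    env$reg <- list(
      motif_counts = local({
        p <- .path(config, "motif_counts.tsv")
        if (!file.exists(p)) stop("required input 'motif_counts.tsv' not found")
        .read_matrix_tsv(p)
      }),
      cluster_expr = local({
        p <- .path(config, "cluster_expression.tsv")
        if (!file.exists(p)) stop("required input 'cluster_expression.tsv' not found")
        .read_matrix_tsv(p)
      }))
  }
  N <- env$reg$motif_counts
  set.seed(.child_seed(config$seed, 6))
  A_star <- matrix(stats::rnorm(ncol(N) * 6), ncol(N), 6,
                   dimnames = list(colnames(N), paste0("s", 1:6)))
  E <- simulate_motif_expression(N, A_star, noise_sd = 0.1,
                                 seed = .child_seed(config$seed, 7))
  fit <- fit_motif_activity(E, N, lambda = "auto",
                            seed = .child_seed(config$seed, 8))
  env$mara <- fit
  act <- fit$activity
  write_tsv(data.frame(motif = rownames(act), act, check.names = FALSE),
            .path(config, "activity.tsv"))
  write_tsv(activity_significance(fit, config$activity_p),
            .path(config, "activity_significance.tsv"))
  write_tsv(score_targets(fit), .path(config, "edges.tsv"))
  invisible(NULL)
}

.stage_network <- function(config, env) {
  edges <- if (!is.null(env$mara)) {
    score_targets(env$mara)
  } else {
    p <- .path(config, "edges.tsv")
    if (!file.exists(p)) stop("required input 'edges.tsv' not found")
    utils::read.delim(p)
  }
  net <- build_network(edges, config$target_score)
  env$net <- net
  set.seed(.child_seed(config$seed, 9))
  expr <- env$reg$cluster_expr
  tf_genes <- intersect(unique(net$edges$tf), rownames(expr))
  rows <- list()
  all_targets <- unique(net$edges$target)
  for (tf in tf_genes[seq_len(min(10, length(tf_genes)))]) {
    rows[[tf]] <- neat_test(net, tf, network_targets(net, tf),
                            name_a = tf, name_b = paste0("targets_", tf))
  }
  if (length(rows) > 0) write_tsv(do.call(rbind, rows), .path(config, "neat.tsv"))
  reg_enr <- regulator_enrichment(net, sample(all_targets,
                                              min(50, length(all_targets))),
                                  universe = unique(c(net$edges$target,
                                                      rownames(expr))))
  write_tsv(reg_enr, .path(config, "regulators.tsv"))
  invisible(NULL)
}

.stage_coexpr <- function(config, env) {
  if (is.null(env$net)) stop("network stage outputs not available")
  expr <- env$reg$cluster_expr
  co <- tf_target_coexpression(expr, env$net)
  write_tsv(co, .path(config, "coexpression.tsv"))
  invisible(NULL)
}
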