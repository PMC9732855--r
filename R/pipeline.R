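#' Pipeline configuration
#'
#' All knobs of the end-to-end synthetic study: one GWAS cohort provides the
#' LD reference and summary statistics; independent molecular cohorts
#' (two proteome-like, one transcriptome-like by default) provide weight
#' training panels. Genes occupy disjoint SNP blocks along one synthetic
#' chromosome. Defaults are the package's standing study conditions.
#'
#' @param seed master seed; every stage derives its stream from it.
#' @param n_ref individuals in the LD reference / GWAS panel.
#' @param n_cohort individuals per molecular (weight-training) cohort.
#' @param n_genes number of genes.
#' @param snps_per_gene SNPs in each gene's cis block.
#' @param spacing_bp base pairs between adjacent SNPs.
#' @param ld_decay latent AR(1) neighbour correlation.
#' @param maf_range minor-allele-frequency interval.
#' @param cis_h2 cis heritability of each molecular trait.
#' @param n_causal causal SNPs per gene.
#' @param n_mediated genes whose abundance mediates the trait.
#' @param lambda expected gene-level association Z of mediated genes.
#' @param methods weight estimators to fit.
#' @param cv_folds CV folds for weight selection.
#' @param alpha_h2 heritability screening threshold.
#' @param n_perm_assoc permutations per gene in the association stage.
#' @param n_perm_gsea permutations per gene set.
#' @param alpha significance level on permutation P values.
#' @param panel_tags labels of the molecular cohorts (first two are treated
#'   as the discovery/replication pair, any further ones as comparison
#'   panels).
#' @param n_sets,set_size_range,n_enriched_sets,enrichment_strength
#'   chemical-set generator parameters.
#' @param gsea_mode null mode for the enrichment stage.
#' @param coloc_gate_alpha association P gate for colocalization.
#' @param gwas_n effective GWAS sample size used for Wakefield variances.
#' @return a classed list (\code{pipeline_config}).
#' @export
pipeline_config <- function(seed = 1L,
                            n_ref = 400L, n_cohort = 400L,
                            n_genes = 200L, snps_per_gene = 30L,
                            spacing_bp = 10000L, ld_decay = 0.6,
                            maf_range = c(0.05, 0.5),
                            cis_h2 = 0.5, n_causal = 2L,
                            n_mediated = 3L, lambda = 6,
                            methods = c("top1", "ridge_blup",
                                        "elastic_net", "spike_slab"),
                            cv_folds = 5L, alpha_h2 = 0.01,
                            n_perm_assoc = 200L, n_perm_gsea = 500L,
                            alpha = 0.05,
                            panel_tags = c("discovery_proteome",
                                           "replication_proteome",
                                           "transcriptome"),
                            n_sets = 50L, set_size_range = c(5L, 20L),
                            n_enriched_sets = 5L, enrichment_strength = 8,
                            gsea_mode = "gene_shuffle",
                            coloc_gate_alpha = 0.05, gwas_n = 1e5) {
  cfg <- as.list(environment())
  if (cfg$n_mediated > cfg$n_genes) stopf("n_mediated exceeds n_genes")
  structure(cfg, class = c("pipeline_config", "list"))
}

# short deterministic fingerprint of a config (hex of a rolling hash)
config_hash <- function(config) {
  s <- yaml::as.yaml(unclass(config))
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 2^28
  sprintf("%07x", h)
}

#' Simulate a molecular trait from an existing gene model
#'
#' Applies a \code{gene_model}'s causal SNPs and true weights to a (possibly
#' different) cohort's genotypes, so independent cohorts share one genetic
#' architecture: trait = sqrt(cis_h2) * standardized genetic score +
#' sqrt(1 - cis_h2) * noise.
#'
#' @param panel cohort \code{\link{reference_panel}} (must contain the
#'   model's causal SNPs).
#' @param model a \code{gene_model}.
#' @param seed integer seed for the noise draw.
#' @return numeric trait vector.
#' @export
simulate_trait_from_model <- function(panel, model, seed = 1L) {
  idx <- match(model$causal_snp_ids, panel$snps$snp_id)
  if (anyNA(idx))
    stopf("gene %s: causal SNPs missing from cohort panel", model$gene_id)
  X <- standardize(panel$genotypes[, idx, drop = FALSE])
  g <- drop(X %*% model$true_weights)
  if (stats::sd(g) == 0) g <- g + stats::rnorm(length(g)) * 1e-8
  g <- (g - mean(g)) / stats::sd(g)
  local_seed(seed, {
    sqrt(model$cis_h2) * g +
      sqrt(1 - model$cis_h2) * stats::rnorm(nrow(panel$genotypes))
  })
}

train_cohort <- function(cfg, models, cohort_seed) {
  cohort <- simulate_reference_panel(cfg$n_cohort,
                                     cfg$n_genes * cfg$snps_per_gene,
                                     ld_decay = cfg$ld_decay,
                                     maf_range = cfg$maf_range,
                                     seed = cohort_seed,
                                     spacing_bp = cfg$spacing_bp)
  wp <- vector("list", length(models))
  names(wp) <- vapply(models, `[[`, "", "gene_id")
  qtl <- vector("list", length(models))
  names(qtl) <- names(wp)
  for (i in seq_along(models)) {
    m <- models[[i]]
    trait <- simulate_trait_from_model(cohort, m,
                                       seed = derive_seed(cohort_seed, i))
    wp[[i]] <- fit_weight_models(cohort, trait, m$cis_snp_ids,
                                 methods = cfg$methods,
                                 cv_folds = cfg$cv_folds,
                                 seed = derive_seed(cohort_seed, i + 100000L),
                                 gene_id = m$gene_id)
    qtl[[i]] <- qtl_summary(cohort, trait, m$cis_snp_ids)
  }
  list(weights = wp, qtl = qtl)
}

#' Run the full synthetic discovery/replication pipeline
#'
#' Simulates one GWAS (LD reference + summary Z-scores under the mediation
#' model), trains weight models in independent molecular cohorts, runs the
#' gene-level association scan on each, intersects the significant genes of
#' the first two cohorts (discovery/replication) and of any further cohorts
#' (transcriptome comparison), colocalizes the intersected genes, and runs
#' chemical gene-set enrichment on each cohort's statistics. All stages are
#' pure functions of \code{config$seed}; with an output directory the
#' result tables, a config copy, and a run manifest are written.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir optional output directory.
#' @return object of class \code{xwas_pipeline}: scans (per cohort),
#'   intersections, coloc and GSEA results, gene models, manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  cfg <- config
  t0 <- Sys.time()
  m_total <- cfg$n_genes * cfg$snps_per_gene

  ld_panel <- simulate_reference_panel(cfg$n_ref, m_total,
                                       ld_decay = cfg$ld_decay,
                                       maf_range = cfg$maf_range,
                                       seed = derive_seed(cfg$seed, 1L),
                                       spacing_bp = cfg$spacing_bp)

  # gene models on disjoint SNP blocks; the first n_mediated genes carry
  # the mediated effect
  half_block <- ((cfg$snps_per_gene - 1L) * cfg$spacing_bp) %/% 2L
  models <- vector("list", cfg$n_genes)
  for (g in seq_len(cfg$n_genes)) {
    first <- (g - 1L) * cfg$snps_per_gene + 1L
    anchor <- ld_panel$snps$pos[first] + half_block
    models[[g]] <- simulate_gene_trait(
      ld_panel, anchor, cis_window_bp = half_block,
      n_causal = cfg$n_causal, cis_h2 = cfg$cis_h2,
      seed = derive_seed(cfg$seed, 1000L + g),
      gene_id = sprintf("gene%04d", g),
      lambda_effect = if (g <= cfg$n_mediated) cfg$lambda else 0)$model
  }

  gwas <- simulate_gwas_summary(ld_panel, models,
                                seed = derive_seed(cfg$seed, 2L))

  scans <- list()
  qtls <- list()
  wps <- list()
  for (p in seq_along(cfg$panel_tags)) {
    tag <- cfg$panel_tags[p]
    tc <- train_cohort(cfg, models, derive_seed(cfg$seed, 3L + p))
    wp <- filter_heritable(tc$weights, cfg$alpha_h2, quiet = TRUE)
    if (!length(wp)) stopf("cohort %s: no gene passed the heritability screen", tag)
    scans[[tag]] <- xwas(gwas, wp, ld_panel, n_perm = cfg$n_perm_assoc,
                         alpha = cfg$alpha,
                         seed = derive_seed(cfg$seed, 10L + p),
                         panel_tag = tag)
    qtls[[tag]] <- tc$qtl
    wps[[tag]] <- wp
  }

  disc_rep <- intersect_significant(scans[[1]], scans[[2]])
  all_panels <- if (length(scans) > 2L)
    intersect_significant(scans) else disc_rep

  # colocalize the discovery-panel signal for replicated genes
  coloc_res <- NULL
  if (nrow(disc_rep)) {
    sub <- scans[[1]]
    sub$table <- sub$table[sub$table$gene_id %in% disc_rep$gene_id, ,
                           drop = FALSE]
    coloc_res <- run_coloc(sub, gwas, qtls[[1]], ld_panel,
                           gate_alpha = cfg$coloc_gate_alpha,
                           gwas_n = cfg$gwas_n)
  }

  gsea_res <- list()
  for (tag in names(scans)) {
    z <- stats::setNames(scans[[tag]]$table$z_xwas,
                         scans[[tag]]$table$gene_id)
    universe <- names(z)
    ranks <- rank(-abs(z), ties.method = "first")
    coll <- simulate_chemical_sets(universe, cfg$n_sets,
                                   cfg$set_size_range,
                                   n_enriched = cfg$n_enriched_sets,
                                   enrichment_strength = cfg$enrichment_strength,
                                   xwas_ranks = ranks,
                                   seed = derive_seed(cfg$seed, 20L))
    gsea_res[[tag]] <- run_gsea(z, coll, n_perm = cfg$n_perm_gsea,
                                mode = cfg$gsea_mode,
                                seed = derive_seed(cfg$seed, 30L),
                                alpha = cfg$alpha,
                                xwas_inputs = if (cfg$gsea_mode == "snp_shuffle")
                                  list(gwas = gwas,
                                       weight_panel = wps[[tag]],
                                       panel = ld_panel) else NULL)
  }

  manifest <- list(config_hash = config_hash(cfg),
                   seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("xwas")),
                   wall_clock_sec = as.numeric(difftime(Sys.time(), t0,
                                                        units = "secs")))
  out <- structure(list(config = cfg, gwas = gwas, models = models,
                        scans = scans,
                        discovery_replication = disc_rep,
                        all_panel_overlap = all_panels,
                        coloc = coloc_res, gsea = gsea_res,
                        manifest = manifest),
                   class = "xwas_pipeline")
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

#' @export
print.xwas_pipeline <- function(x, ...) {
  cat(sprintf("Synthetic X-WAS pipeline (seed %d, config %s)\n",
              x$config$seed, x$manifest$config_hash))
  for (tag in names(x$scans)) print(x$scans[[tag]])
  cat(sprintf("Discovery/replication overlap: %d gene(s)%s\n",
              nrow(x$discovery_replication),
              if (nrow(x$discovery_replication))
                paste0(" (", paste(x$discovery_replication$gene_id,
                                   collapse = ", "), ")") else ""))
  if (!is.null(x$coloc)) print(x$coloc)
  invisible(x)
}

write_pipeline <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- x$manifest$config_hash
  stamp <- function(df) { df$config_hash <- hash; df }
  write_config(x$config, file.path(out_dir, "config.yaml"))
  write_gwas_summary(x$gwas, file.path(out_dir, "gwas_summary.tsv"))
  for (tag in names(x$scans)) {
    utils::write.table(stamp(x$scans[[tag]]$table),
                       file.path(out_dir, sprintf("xwas_%s.tsv", tag)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(stamp(x$gsea[[tag]]$table),
                       file.path(out_dir, sprintf("gsea_%s.tsv", tag)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(stamp(x$discovery_replication),
                     file.path(out_dir, "discovery_replication_overlap.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(x$coloc))
    utils::write.table(stamp(x$coloc$table),
                       file.path(out_dir, "coloc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(x$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
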