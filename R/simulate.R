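#' Simulate a cis-heritable molecular trait for one gene
#'
#' Draws causal SNPs within the cis window around the gene anchor, forms a
#' genetic score from standardized dosages, and mixes it with Gaussian noise
#' so the trait has variance ~ 1 and a genetic fraction \code{cis_h2}:
#' trait = sqrt(cis_h2) * scaled genetic score + sqrt(1 - cis_h2) * noise.
#' At \code{cis_h2 = 1} the trait is exactly the standardized genetic score;
#' at \code{cis_h2 = 0} it is pure noise.
#'
#' @param panel a \code{\link{reference_panel}}.
#' @param gene_anchor_pos base-pair anchor (e.g. TSS) of the gene.
#' @param cis_window_bp window half-width around the anchor (default 1 Mb
#'   per side, the usual cis-locus definition).
#' @param n_causal number of causal SNPs (>= 1).
#' @param cis_h2 fraction of trait variance explained by the causal SNPs,
#'   in [0, 1].
#' @param seed integer seed.
#' @param gene_id gene label.
#' @param lambda_effect mediated trait effect: the expected gene-level
#'   association Z when the weight vector is scaled to unit LD variance
#'   (W'SW = 1). Used by \code{\link{simulate_gwas_summary}}.
#' @return list with \code{model} (class \code{gene_model}: gene_id, anchor,
#'   cis window, cis/causal SNP ids, true weights, cis_h2, lambda_effect)
#'   and \code{trait} (numeric vector, one value per panel individual).
#' @export
simulate_gene_trait <- function(panel, gene_anchor_pos, cis_window_bp = 1e6,
                                n_causal = 1L, cis_h2 = 0.5, seed = 1L,
                                gene_id = "gene1", lambda_effect = 0) {
  if (cis_h2 < 0 || cis_h2 > 1) stopf("cis_h2 must be in [0, 1]")
  if (n_causal < 1L) stopf("need n_causal >= 1")
  cis <- which(abs(panel$snps$pos - gene_anchor_pos) <= cis_window_bp)
  if (!length(cis))
    stopf("gene %s: no SNPs within %d bp of position %d",
          gene_id, as.integer(cis_window_bp), as.integer(gene_anchor_pos))
  if (length(cis) < n_causal)
    stopf("gene %s: only %d cis SNPs for %d causal", gene_id, length(cis),
          n_causal)
  local_seed(seed, {
    causal <- sort(sample(cis, n_causal))
    w <- stats::rnorm(n_causal)
    X <- standardize(panel$genotypes[, causal, drop = FALSE])
    g <- drop(X %*% w)
    if (stats::sd(g) == 0) g <- g + stats::rnorm(length(g)) * 1e-8
    g <- (g - mean(g)) / stats::sd(g)
    n <- nrow(panel$genotypes)
    trait <- sqrt(cis_h2) * g + sqrt(1 - cis_h2) * stats::rnorm(n)
    model <- structure(list(
      gene_id = gene_id,
      anchor_pos = as.integer(gene_anchor_pos),
      cis_window_bp = as.integer(cis_window_bp),
      cis_snp_ids = panel$snps$snp_id[cis],
      causal_snp_ids = panel$snps$snp_id[causal],
      true_weights = w,
      cis_h2 = cis_h2,
      lambda_effect = lambda_effect
    ), class = "gene_model")
    list(model = model, trait = trait)
  })
}

# Weight vector over all panel SNPs, rescaled so W'SW = 1; lambda then has
# the interpretation "expected gene-level association Z".
scaled_true_weights <- function(model, panel, S) {
  w <- numeric(nrow(panel$snps))
  idx <- match(model$causal_snp_ids, panel$snps$snp_id)
  w[idx] <- model$true_weights
  q <- drop(crossprod(w, S %*% w))
  if (q <= 0) stopf("gene %s: degenerate true-weight variance", model$gene_id)
  w / sqrt(q)
}

#' Simulate GWAS summary Z-scores under a mediation model
#'
#' Draws one vector of per-SNP association Z-scores from
#' MVN(sum_g lambda_g * S * W_g, S), where S is the panel SNP-correlation
#' matrix and each gene's true weight vector W_g is rescaled to W'SW = 1, so
#' that \code{lambda_effect} equals the expected gene-level association Z.
#' With all lambda = 0 this is the global null: Z ~ MVN(0, S).
#'
#' @param panel a \code{\link{reference_panel}}.
#' @param gene_models list of \code{gene_model} objects (may be empty).
#' @param seed integer seed.
#' @param flip_fraction fraction of SNPs whose allele labels (and Z sign)
#'   are flipped in the output, to exercise orientation harmonization;
#'   downstream results must be invariant to this.
#' @return data.frame of class \code{gwas_summary} with columns SNP, CHR,
#'   POS, A1, A2, Z (Z is the association Z-score of allele A1).
#' @export
simulate_gwas_summary <- function(panel, gene_models = list(), seed = 1L,
                                  flip_fraction = 0) {
  S <- ld_matrix(panel, stabilize = TRUE)
  m <- nrow(S)
  R <- tryCatch(chol(S), error = function(e)
    stopf("LD matrix not positive definite after stabilization: %s",
          conditionMessage(e)))
  mu <- numeric(m)
  for (gm in gene_models) {
    if (gm$lambda_effect == 0) next
    wt <- scaled_true_weights(gm, panel, S)
    mu <- mu + gm$lambda_effect * drop(S %*% wt)
  }
  local_seed(seed, {
    z <- unname(mu + drop(crossprod(R, stats::rnorm(m))))
    out <- data.frame(SNP = panel$snps$snp_id,
                      CHR = panel$snps$chrom,
                      POS = panel$snps$pos,
                      A1 = panel$snps$a1,
                      A2 = panel$snps$a2,
                      Z = z,
                      stringsAsFactors = FALSE)
    if (flip_fraction > 0) {
      k <- sample.int(m, size = round(flip_fraction * m))
      if (length(k)) {
        tmp <- out$A1[k]
        out$A1[k] <- out$A2[k]
        out$A2[k] <- tmp
        out$Z[k] <- -out$Z[k]
      }
    }
    class(out) <- c("gwas_summary", "data.frame")
    out
  })
}

#' Gene-set collection
#'
#' @param sets named list of character vectors (member gene ids per set).
#' @param universe all scorable gene ids.
#' @param descriptions optional named character vector of set descriptions.
#' @return object of class \code{gene_set_collection}.
#' @export
gene_set_collection <- function(sets, universe,
                                descriptions = NULL) {
  if (!length(sets)) stopf("empty gene-set collection")
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stopf("sets must have unique names")
  for (id in names(sets)) {
    g <- sets[[id]]
    if (!length(g)) stopf("set %s is empty", id)
    if (anyDuplicated(g)) stopf("set %s has duplicated members", id)
    bad <- setdiff(g, universe)
    if (length(bad))
      stopf("set %s has members outside the universe: %s", id,
            paste(utils::head(bad, 5), collapse = ", "))
  }
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = sets,
                 descriptions = descriptions[names(sets)],
                 universe = as.character(universe)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sz <- lengths(x$sets)
  cat(sprintf("Gene-set collection: %d sets over %d genes (sizes %d-%d)\n",
              length(x$sets), length(x$universe), min(sz), max(sz)))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Simulate chemical-gene sets with controlled enrichment
#'
#' Emulates a chemical-gene interaction database: most sets are uniform
#' draws from the gene universe; \code{n_enriched} sets oversample genes
#' from the top of a supplied ranking, with sampling weight
#' exp(-strength * rank percentile), so enrichment strength 0 reduces to
#' uniform sampling.
#'
#' @param universe character vector of scorable gene ids.
#' @param n_sets number of sets.
#' @param size_range integer interval of set sizes, within
#'   \code{[2, length(universe)]}.
#' @param n_enriched how many sets are enriched (placed first, ids prefixed
#'   \code{"enr"}).
#' @param enrichment_strength nonnegative; 0 = no enrichment.
#' @param xwas_ranks integer rank per universe gene (1 = strongest
#'   statistic), in universe order.
#' @param seed integer seed.
#' @return a \code{\link{gene_set_collection}}.
#' @export
simulate_chemical_sets <- function(universe, n_sets, size_range = c(5L, 20L),
                                   n_enriched = 0L, enrichment_strength = 0,
                                   xwas_ranks = seq_along(universe),
                                   seed = 1L) {
  N <- length(universe)
  if (size_range[1] < 2L || size_range[2] > N)
    stopf("size_range must lie within [2, %d]", N)
  if (n_enriched > n_sets) stopf("n_enriched exceeds n_sets")
  if (length(xwas_ranks) != N) stopf("xwas_ranks must match the universe")
  pct <- (xwas_ranks - 1) / max(N - 1, 1)
  w_enr <- exp(-enrichment_strength * pct)
  local_seed(seed, {
    sets <- vector("list", n_sets)
    nm <- character(n_sets)
    for (i in seq_len(n_sets)) {
      k <- if (size_range[1] == size_range[2]) size_range[1] else
        sample(seq(size_range[1], size_range[2]), 1L)
      enriched <- i <= n_enriched
      prob <- if (enriched) w_enr else NULL
      sets[[i]] <- sample(universe, k, prob = prob)
      nm[i] <- sprintf(if (enriched) "enr_set%03d" else "set%03d", i)
    }
    names(sets) <- nm
    gene_set_collection(sets, universe,
                        stats::setNames(rep("synthetic chemical set", n_sets), nm))
  })
}
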