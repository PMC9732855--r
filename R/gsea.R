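#' Rank genes by their association statistic
#'
#' Orders genes from largest to smallest ranking statistic for gene-set
#' enrichment. By default the magnitude |z| of the gene-level association is
#' used (two-sided relevance); signed ranking is available. Ties are broken
#' deterministically by gene id (lexicographic).
#'
#' @param stats named numeric vector (gene-level statistics) or an
#'   \code{\link{xwas}} object (its z_xwas column is used).
#' @param use_abs rank by |statistic| (default) or by the signed value.
#' @return object of class \code{ranked_genes}: \code{gene_id} (ordered) and
#'   \code{stat} (the ranking statistic, same order).
#' @export
rank_genes <- function(stats, use_abs = TRUE) {
  if (inherits(stats, "xwas"))
    stats <- stats::setNames(stats$table$z_xwas, stats$table$gene_id)
  if (is.null(names(stats)) || anyDuplicated(names(stats)))
    stopf("stats must be a named vector with unique gene ids")
  key <- if (use_abs) abs(stats) else stats
  o <- order(-key, names(stats), method = "radix")
  structure(list(gene_id = names(stats)[o], stat = unname(key[o]),
                 use_abs = use_abs),
            class = "ranked_genes")
}

#' @export
print.ranked_genes <- function(x, ...) {
  cat(sprintf("Ranked gene list: %d genes, statistic range %.3f .. %.3f (%s)\n",
              length(x$gene_id), x$stat[1], x$stat[length(x$stat)],
              if (x$use_abs) "|z|" else "signed z"))
  invisible(x)
}

# ES from hit positions only: the running sum increases only at hits and
# ends at 0, so its maximum is max(0, peak after each hit). Equivalent to
# the full prefix scan: peak_j = cumsum(w_hits)_j / N_R - (pos_j - j)/(N - N_C).
es_from_positions <- function(w, pos, N) {
  k <- length(pos)
  nr <- sum(w[pos])
  if (N == k) return(1)                       # set = universe: no miss terms
  if (nr == 0) return(structure(0, zero_nr = TRUE))
  peaks <- cumsum(w[pos]) / nr - (pos - seq_len(k)) / (N - k)
  max(0, peaks)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' The running-sum enrichment score of a gene set C against a ranked gene
#' list: walking down the list, the sum gains |GS_i|^H / N_R at members
#' (N_R = sum of |GS|^H over members) and loses 1/(N - N_C) at non-members;
#' ES is the maximum of the running sum. Because the sum terminates at 0,
#' ES lies in [0, 1]; H = 1 is the classic weighting, and ES is invariant
#' to rescaling all statistics by a positive constant.
#'
#' @param ranked a \code{\link{rank_genes}} object.
#' @param gene_set character vector of member gene ids; members outside the
#'   ranked universe are dropped (and counted in the
#'   \code{"n_dropped"} attribute).
#' @param H weighting exponent (default 1).
#' @return the enrichment score, with attributes \code{n_members_scored},
#'   \code{n_dropped}, and \code{zero_nr} when all member statistics are 0
#'   (ES defined as 0 in that case).
#' @export
enrichment_score <- function(ranked, gene_set, H = 1) {
  N <- length(ranked$gene_id)
  pos <- sort(match(unique(gene_set), ranked$gene_id))
  n_dropped <- length(unique(gene_set)) - sum(!is.na(pos))
  pos <- pos[!is.na(pos)]
  if (!length(pos)) stopf("gene set has no member in the ranked universe")
  w <- abs(ranked$stat)^H
  es <- es_from_positions(w, pos, N)
  structure(as.numeric(es), n_members_scored = length(pos),
            n_dropped = n_dropped,
            zero_nr = isTRUE(attr(es, "zero_nr")))
}

#' Permutation null distribution of the enrichment score
#'
#' Two null modes. \code{"snp_shuffle"} (faithful): the SNP-to-Z assignment
#' of the GWAS is randomly shuffled, every gene's association statistic is
#' recomputed, the list is re-ranked, and ES recomputed — the null carries
#' the full pipeline's dependence structure. \code{"gene_shuffle"} (fast):
#' the gene-to-statistic assignment is permuted, equivalent to drawing a
#' uniformly random member set of the same size on the fixed ranking.
#'
#' @param ranked a \code{\link{rank_genes}} object (the observed ranking).
#' @param gene_set member gene ids.
#' @param n_perm number of permutations (>= 1).
#' @param mode \code{"gene_shuffle"} or \code{"snp_shuffle"}.
#' @param seed integer seed.
#' @param H weighting exponent.
#' @param xwas_inputs for \code{"snp_shuffle"}: list with elements
#'   \code{gwas}, \code{weight_panel}, \code{panel} used to recompute the
#'   gene statistics under shuffled SNP labels.
#' @param use_abs ranking convention for recomputed statistics
#'   (snp_shuffle only).
#' @return numeric vector of \code{n_perm} null enrichment scores.
#' @export
gsea_null <- function(ranked, gene_set, n_perm, mode = c("gene_shuffle",
                                                         "snp_shuffle"),
                      seed = 1L, H = 1, xwas_inputs = NULL, use_abs = TRUE) {
  mode <- match.arg(mode)
  if (n_perm < 1L) stopf("need n_perm >= 1")
  N <- length(ranked$gene_id)
  k <- sum(!is.na(match(unique(gene_set), ranked$gene_id)))
  if (k == 0L) stopf("gene set has no member in the ranked universe")
  if (mode == "gene_shuffle") {
    w <- abs(ranked$stat)^H
    local_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        pos <- sort(sample.int(N, k))
        as.numeric(es_from_positions(w, pos, N))
      }, numeric(1))
    })
  } else {
    if (is.null(xwas_inputs))
      stopf("snp_shuffle mode needs xwas_inputs = list(gwas, weight_panel, panel)")
    pre <- precompute_xwas_stats(xwas_inputs$gwas, xwas_inputs$weight_panel,
                                 xwas_inputs$panel)
    local_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        zperm <- xwas_inputs$gwas$Z[sample.int(length(xwas_inputs$gwas$Z))]
        stats <- eval_xwas_stats(pre, zperm)
        rk <- rank_genes(stats, use_abs = use_abs)
        as.numeric(enrichment_score(rk, gene_set, H = H))
      }, numeric(1))
    })
  }
}

# Alignment cache so SNP-shuffled statistics cost one dot product per gene.
precompute_xwas_stats <- function(gwas, weight_panel, panel) {
  out <- list()
  for (gw in weight_panel) {
    h <- harmonize(gwas, gw, panel)
    if (is.null(h)) next
    q <- drop(crossprod(h$W, h$S %*% h$W))
    if (q <= 1e-8) next
    gi <- match(h$snp_ids, gwas$SNP)
    out[[gw$gene_id]] <- list(idx = gi, w = h$W * h$z_sign / sqrt(q))
  }
  if (!length(out)) stopf("no scorable gene for snp_shuffle null")
  out
}

eval_xwas_stats <- function(pre, z) {
  vapply(pre, function(p) sum(p$w * z[p$idx]), numeric(1))
}

#' Normalized enrichment score and empirical P
#'
#' NES standardizes the observed ES by the mean and standard deviation of
#' its permutation null (sample SD, n - 1 denominator), adjusting for
#' gene-set size; the empirical P is the add-one exceedance rate
#' (1 + #\{ES_null >= ES_obs\})/(n_perm + 1).
#'
#' @param es_obs observed enrichment score.
#' @param null_es numeric vector of null enrichment scores.
#' @param n_perm number of permutations the null was built from (defaults
#'   to \code{length(null_es)}).
#' @return list: \code{nes} (NA with \code{zero_sd} flag when the null is
#'   degenerate), \code{p_emp}, \code{null_mean}, \code{null_sd}.
#' @export
nes_and_p <- function(es_obs, null_es, n_perm = length(null_es)) {
  if (length(null_es) < 2L) stopf("need a null sample of size >= 2 for NES")
  mu <- mean(null_es)
  sdv <- stats::sd(null_es)
  nes <- if (sdv > 0) (es_obs - mu) / sdv else NA_real_
  p <- (1 + sum(null_es >= es_obs)) / (n_perm + 1)
  list(nes = nes, p_emp = p, null_mean = mu, null_sd = sdv,
       zero_sd = sdv == 0)
}

#' Gene-set enrichment scan over a collection
#'
#' Computes ES, NES, and permutation-based empirical P for every set in a
#' collection against the ranked gene-level association statistics.
#' Significance is flagged at \code{p_emp < alpha}. Per-set RNG substreams
#' are derived from the master seed by set index so results do not depend
#' on set ordering; disable them to give identical sets identical nulls.
#'
#' @param stats named statistic vector or an \code{\link{xwas}} object.
#' @param collection a \code{\link{gene_set_collection}}.
#' @param n_perm permutations per set (default 20000).
#' @param mode null mode, see \code{\link{gsea_null}}; defaults to the
#'   faithful \code{"snp_shuffle"} when \code{xwas_inputs} is supplied and
#'   \code{"gene_shuffle"} otherwise.
#' @param seed master seed.
#' @param H weighting exponent (default 1).
#' @param alpha significance level on the empirical P.
#' @param use_abs ranking convention.
#' @param xwas_inputs see \code{\link{gsea_null}}.
#' @param per_set_substreams derive an independent stream per set (default
#'   TRUE).
#' @return object of class \code{gsea_result}: \code{$table} with set_id,
#'   n_members_scored, es, nes, p_emp, significant, mode; \code{$skipped}.
#' @export
run_gsea <- function(stats, collection, n_perm = 20000L, mode = NULL,
                     seed = 1L, H = 1, alpha = 0.05, use_abs = TRUE,
                     xwas_inputs = NULL, per_set_substreams = TRUE) {
  if (is.null(mode))
    mode <- if (is.null(xwas_inputs)) "gene_shuffle" else "snp_shuffle"
  mode <- match.arg(mode, c("gene_shuffle", "snp_shuffle"))
  if (!length(collection$sets)) stopf("empty collection")
  ranked <- rank_genes(stats, use_abs = use_abs)
  rows <- list()
  skipped <- list()
  for (i in seq_along(collection$sets)) {
    sid <- names(collection$sets)[i]
    members <- collection$sets[[i]]
    if (!any(members %in% ranked$gene_id)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(set_id = sid, reason = "no scorable member")
      next
    }
    es <- enrichment_score(ranked, members, H = H)
    sseed <- if (per_set_substreams) derive_seed(seed, i) else seed
    null_es <- gsea_null(ranked, members, n_perm = n_perm, mode = mode,
                         seed = sseed, H = H, xwas_inputs = xwas_inputs,
                         use_abs = use_abs)
    np <- nes_and_p(as.numeric(es), null_es, n_perm)
    rows[[length(rows) + 1L]] <- data.frame(
      set_id = sid,
      n_members_scored = attr(es, "n_members_scored"),
      es = as.numeric(es),
      nes = np$nes,
      p_emp = np$p_emp,
      significant = np$p_emp < alpha,
      mode = mode,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stopf("no set could be scored")
  structure(list(table = do.call(rbind, rows),
                 skipped = if (length(skipped)) do.call(rbind, skipped) else
                   data.frame(set_id = character(), reason = character()),
                 n_perm = n_perm, mode = mode, alpha = alpha, H = H,
                 use_abs = use_abs, seed = seed),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("GSEA [%s null, n_perm = %d]: %d sets scored, %d significant at P < %g\n",
              x$mode, x$n_perm, nrow(x$table), sum(x$table$significant),
              x$alpha))
  top <- x$table[order(x$table$p_emp), , drop = FALSE]
  print(utils::head(top, 10), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
as.data.frame.gsea_result <- function(x, ...) x$table
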