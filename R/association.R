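#' Harmonize GWAS, weight, and LD-panel alleles for one gene
#'
#' Matches SNPs by id across the three sources, orients everything to the
#' weight model's effect allele (flipping the GWAS Z sign and the LD matrix
#' rows/columns where a1/a2 are swapped), drops SNPs whose allele pairs
#' disagree, drops strand-ambiguous pairs (A/T, C/G), and drops SNPs missing
#' from any source. Dropped SNPs are counted by reason.
#'
#' @param gwas data.frame with SNP, A1, A2, Z (a \code{gwas_summary}).
#' @param weights a \code{gene_weights} object.
#' @param panel a \code{\link{reference_panel}}.
#' @return list with aligned \code{W}, \code{Z}, \code{S}, \code{snp_ids},
#'   and \code{dropped} (named counts: missing, allele_mismatch, ambiguous),
#'   or NULL (with attribute "reason") when no SNP survives.
#' @export
harmonize <- function(gwas, weights, panel) {
  wt <- weights$snps
  dropped <- c(missing = 0L, allele_mismatch = 0L, ambiguous = 0L)

  amb <- paste0(wt$a1, wt$a2) %in% c("AT", "TA", "CG", "GC")
  dropped["ambiguous"] <- sum(amb)
  wt <- wt[!amb, , drop = FALSE]

  gi <- match(wt$snp_id, gwas$SNP)
  pi <- match(wt$snp_id, panel$snps$snp_id)
  present <- !is.na(gi) & !is.na(pi)
  dropped["missing"] <- sum(!present)
  wt <- wt[present, , drop = FALSE]
  gi <- gi[present]; pi <- pi[present]
  if (!nrow(wt)) {
    out <- NULL; attr(out, "reason") <- "no overlapping SNPs"
    return(out)
  }

  # GWAS orientation relative to the weight model
  same_g <- gwas$A1[gi] == wt$a1 & gwas$A2[gi] == wt$a2
  swap_g <- gwas$A1[gi] == wt$a2 & gwas$A2[gi] == wt$a1
  # LD panel orientation relative to the weight model
  same_p <- panel$snps$a1[pi] == wt$a1 & panel$snps$a2[pi] == wt$a2
  swap_p <- panel$snps$a1[pi] == wt$a2 & panel$snps$a2[pi] == wt$a1
  ok <- (same_g | swap_g) & (same_p | swap_p)
  dropped["allele_mismatch"] <- sum(!ok)
  if (!any(ok)) {
    out <- NULL; attr(out, "reason") <- "no allele-consistent SNPs"
    return(out)
  }
  wt <- wt[ok, , drop = FALSE]
  gi <- gi[ok]; pi <- pi[ok]
  zsign <- ifelse(swap_g[ok], -1, 1)
  psign <- ifelse(swap_p[ok], -1, 1)

  S <- ld_matrix(panel, wt$snp_id, stabilize = TRUE)
  if (any(psign < 0)) S <- S * tcrossprod(psign)
  list(W = wt$weight,
       Z = gwas$Z[gi] * zsign,
       S = S,
       snp_ids = wt$snp_id,
       z_sign = zsign,
       dropped = dropped)
}

#' Gene-level association Z from summary statistics
#'
#' The TWAS/PWAS statistic for a gene with cis-SNP weights W, GWAS Z-scores
#' Z, and SNP-correlation matrix S:
#' \deqn{z = W'Z / \sqrt{W'SW}.}
#' Scale-invariant in W; with an indicator weight vector it reduces to the
#' GWAS Z of that SNP.
#'
#' @param W,Z aligned weight and Z vectors.
#' @param S aligned SNP-correlation matrix (unit diagonal).
#' @param eps minimum admissible W'SW; below this the weighted variance is
#'   degenerate and the gene should be skipped.
#' @return the association Z (scalar).
#' @export
xwas_z <- function(W, Z, S, eps = 1e-8) {
  q <- drop(crossprod(W, S %*% W))
  if (!is.finite(q) || q <= eps)
    stopf("degenerate weight variance (W'SW = %.3g <= %.1g)", q, eps)
  drop(crossprod(W, Z)) / sqrt(q)
}

#' Permutation-based empirical P for the gene-level statistic
#'
#' Builds the null by permuting the assignment of weights to SNPs within the
#' locus (conditioning on the observed GWAS signal and LD) and recomputing
#' the statistic; the empirical P uses the add-one rule
#' (1 + #exceedances)/(n_perm + 1), so it is never 0 and never below
#' 1/(n_perm + 1). Exceedance is two-sided (|z_perm| >= |z_obs|). A
#' sign-flip mode (random +/-1 on each weight) is available for sensitivity
#' checks. With fewer than 2 SNPs the permutation null is degenerate and the
#' asymptotic P is returned with a flag.
#'
#' @param W,Z,S aligned inputs as in \code{\link{xwas_z}}.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @param mode "shuffle" (weight-to-SNP permutation) or "signflip".
#' @return list: \code{p_perm}, \code{z_obs}, \code{n_perm},
#'   \code{degenerate} (TRUE when the single-SNP fallback was used).
#' @export
permutation_test <- function(W, Z, S, n_perm = 5000L, seed = 1L,
                             mode = c("shuffle", "signflip")) {
  mode <- match.arg(mode)
  if (n_perm < 1L) stopf("need n_perm >= 1")
  z_obs <- xwas_z(W, Z, S)
  m <- length(W)
  if (m < 2L) {
    return(list(p_perm = 2 * stats::pnorm(-abs(z_obs)), z_obs = z_obs,
                n_perm = 0L, degenerate = TRUE))
  }
  b <- 0L
  local_seed(seed, {
    for (i in seq_len(n_perm)) {
      Wp <- if (mode == "shuffle") W[sample.int(m)] else
        W * sample(c(-1, 1), m, replace = TRUE)
      q <- drop(crossprod(Wp, S %*% Wp))
      if (q <= 1e-12) next  # degenerate permutation counts as non-exceeding
      zp <- drop(crossprod(Wp, Z)) / sqrt(q)
      if (abs(zp) >= abs(z_obs)) b <- b + 1L
    }
  })
  list(p_perm = (1 + b) / (n_perm + 1), z_obs = z_obs, n_perm = n_perm,
       degenerate = FALSE)
}

#' Proteome/transcriptome-wide association scan
#'
#' The central fitting function: for every gene in a weight panel, harmonize
#' alleles across the GWAS summary statistics, the weight model, and the LD
#' reference panel, compute the gene-level association Z = W'Z/sqrt(W'SW),
#' its two-sided asymptotic P, a BH-FDR-adjusted P (utility column), and a
#' permutation-based empirical P; flag genes significant at
#' \code{p_perm < alpha}.
#'
#' @param gwas a \code{gwas_summary} data.frame (SNP, CHR, POS, A1, A2, Z).
#' @param weight_panel list of \code{gene_weights} (a "weight panel").
#' @param panel the LD \code{\link{reference_panel}}.
#' @param n_perm permutations per gene (default 5000).
#' @param alpha significance level on the permutation P (default 0.05).
#' @param seed integer seed; per-gene permutation streams are derived from
#'   it, so results do not depend on gene order.
#' @param panel_tag label stored with the results (e.g. "discovery").
#' @param perm_mode permutation scheme, see \code{\link{permutation_test}}.
#' @param drop_nonpredictive skip genes flagged non-predictive at training.
#' @return object of class \code{xwas}: \code{$table} with one row per
#'   scored gene (gene_id, chrom, n_snps_used, n_snps_dropped, z_xwas,
#'   p_asymptotic, p_bh, p_perm, perm_degenerate, significant), plus
#'   \code{$skipped} (gene_id, reason), \code{$alpha}, \code{$n_perm},
#'   \code{$panel_tag}.
#' @seealso \code{\link{xwas_z}}, \code{\link{permutation_test}},
#'   \code{\link{intersect_significant}}
#' @export
xwas <- function(gwas, weight_panel, panel, n_perm = 5000L, alpha = 0.05,
                 seed = 1L, panel_tag = "panel",
                 perm_mode = c("shuffle", "signflip"),
                 drop_nonpredictive = TRUE) {
  perm_mode <- match.arg(perm_mode)
  if (!length(weight_panel)) stopf("empty weight panel")
  if (is.null(names(weight_panel)))
    names(weight_panel) <- vapply(weight_panel, `[[`, "", "gene_id")
  rows <- list()
  skipped <- list()
  for (i in seq_along(weight_panel)) {
    gw <- weight_panel[[i]]
    if (drop_nonpredictive && isTRUE(gw$nonpredictive)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(gene_id = gw$gene_id, reason = "non-predictive model")
      next
    }
    h <- harmonize(gwas, gw, panel)
    if (is.null(h)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(gene_id = gw$gene_id, reason = attr(h, "reason"))
      next
    }
    z <- tryCatch(xwas_z(h$W, h$Z, h$S), error = function(e) NULL)
    if (is.null(z)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(gene_id = gw$gene_id, reason = "degenerate weight variance")
      next
    }
    pt <- permutation_test(h$W, h$Z, h$S, n_perm = n_perm,
                           seed = derive_seed(seed, i), mode = perm_mode)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = gw$gene_id,
      chrom = gw$snps$chrom[1],
      n_snps_used = length(h$W),
      n_snps_dropped = sum(h$dropped),
      z_xwas = z,
      p_asymptotic = 2 * stats::pnorm(-abs(z)),
      p_perm = pt$p_perm,
      perm_degenerate = pt$degenerate,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stopf("no gene could be scored")
  tab <- do.call(rbind, rows)
  tab$p_bh <- stats::p.adjust(tab$p_asymptotic, method = "BH")
  tab$significant <- tab$p_perm < alpha
  tab <- tab[, c("gene_id", "chrom", "n_snps_used", "n_snps_dropped",
                 "z_xwas", "p_asymptotic", "p_bh", "p_perm",
                 "perm_degenerate", "significant")]
  structure(list(table = tab,
                 skipped = if (length(skipped)) do.call(rbind, skipped) else
                   data.frame(gene_id = character(), reason = character()),
                 alpha = alpha, n_perm = n_perm, panel_tag = panel_tag,
                 perm_mode = perm_mode, seed = seed),
            class = "xwas")
}

#' @export
print.xwas <- function(x, ...) {
  cat(sprintf("X-WAS scan [%s]: %d genes scored, %d skipped, %d significant at permutation P < %g (n_perm = %d)\n",
              x$panel_tag, nrow(x$table), nrow(x$skipped),
              sum(x$table$significant), x$alpha, x$n_perm))
  invisible(x)
}

#' @export
summary.xwas <- function(object, ...) {
  tab <- object$table
  sig <- tab[tab$significant, , drop = FALSE]
  sig <- sig[order(sig$p_perm), , drop = FALSE]
  out <- list(panel_tag = object$panel_tag, n_genes = nrow(tab),
              n_skipped = nrow(object$skipped),
              n_significant = nrow(sig), alpha = object$alpha,
              significant = sig)
  class(out) <- "summary.xwas"
  out
}

#' @export
print.summary.xwas <- function(x, ...) {
  cat(sprintf("X-WAS scan [%s]\n", x$panel_tag))
  cat(sprintf("  genes scored: %d (skipped: %d)\n", x$n_genes, x$n_skipped))
  cat(sprintf("  significant at permutation P < %g: %d\n", x$alpha,
              x$n_significant))
  if (nrow(x$significant)) {
    print(x$significant[, c("gene_id", "chrom", "z_xwas", "p_asymptotic",
                            "p_perm")], row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
coef.xwas <- function(object, ...) {
  stats::setNames(object$table$z_xwas, object$table$gene_id)
}

#' @export
as.data.frame.xwas <- function(x, ...) x$table

#' Manhattan-style plot of an association scan
#'
#' Plots -log10 of the asymptotic P per gene, ordered by chromosome and
#' highlighting permutation-significant genes. Plumbing, not publication
#' graphics.
#' @param x an \code{xwas} object.
#' @param ... passed to \code{plot}.
#' @export
plot.xwas <- function(x, ...) {
  tab <- x$table[order(x$table$chrom), ]
  y <- -log10(pmax(tab$p_asymptotic, 1e-300))
  graphics::plot(seq_len(nrow(tab)), y, pch = 20,
                 col = ifelse(tab$significant, "firebrick", "grey40"),
                 xlab = "gene (ordered by chromosome)",
                 ylab = expression(-log[10](P[asymptotic])),
                 main = sprintf("X-WAS [%s]", x$panel_tag), ...)
  graphics::abline(h = -log10(0.05), lty = 2, col = "grey60")
  invisible(x)
}

#' Genes significant in every scan
#'
#' The discovery/replication intersection: genes whose permutation P is
#' below each scan's alpha in all supplied scans.
#'
#' @param ... two or more \code{xwas} objects.
#' @return data.frame with gene_id and per-scan z and p_perm columns.
#' @export
intersect_significant <- function(...) {
  scans <- list(...)
  if (length(scans) == 1L && is.list(scans[[1]]) &&
      !inherits(scans[[1]], "xwas")) scans <- scans[[1]]
  if (length(scans) < 2L) stopf("need at least two scans")
  sig <- lapply(scans, function(s) s$table[s$table$significant, , drop = FALSE])
  common <- Reduce(intersect, lapply(sig, `[[`, "gene_id"))
  out <- data.frame(gene_id = common, stringsAsFactors = FALSE)
  for (i in seq_along(scans)) {
    tag <- scans[[i]]$panel_tag %||% as.character(i)
    idx <- match(common, scans[[i]]$table$gene_id)
    out[[paste0("z_", tag)]] <- scans[[i]]$table$z_xwas[idx]
    out[[paste0("p_perm_", tag)]] <- scans[[i]]$table$p_perm[idx]
  }
  out
}
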