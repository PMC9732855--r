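#' Wakefield approximate Bayes factor per SNP
#'
#' Log approximate Bayes factor for association at one SNP from its Z-score
#' and the squared standard error v of the effect estimate:
#' \deqn{\log ABF = \tfrac12 \log(1 - r) + r z^2 / 2,\quad
#'   r = \frac{prior\_var}{prior\_var + v}.}
#' When no standard error is available, v is derived for a standardized
#' trait from the allele frequency f and sample size n as
#' v = 1/(2 f (1 - f) n).
#'
#' @param z per-SNP Z-scores.
#' @param v squared standard errors; omit to derive from \code{maf} and
#'   \code{n}.
#' @param prior_var prior variance of the true effect (0.15^2 is the usual
#'   choice for quantitative molecular traits, 0.2^2 for binary traits).
#' @param maf,n allele frequency and sample size, used only when \code{v}
#'   is missing.
#' @return vector of log ABFs (natural log).
#' @export
wakefield_abf <- function(z, v = NULL, prior_var = 0.15^2, maf = NULL,
                          n = NULL) {
  if (is.null(v)) {
    if (is.null(maf) || is.null(n))
      stopf("need either v (squared SE) or both maf and n")
    v <- 1 / (2 * maf * (1 - maf) * n)
  }
  if (any(v <= 0)) stopf("v must be positive")
  if (prior_var <= 0) stopf("prior_var must be positive")
  r <- prior_var / (prior_var + v)
  0.5 * log1p(-r) + r * z^2 / 2
}

#' Five-hypothesis colocalization posterior
#'
#' Combines per-SNP log ABFs of two traits over a shared SNP list into
#' posterior probabilities of the five single-causal-variant hypotheses:
#' H0 no association, H1/H2 association with one trait only, H3 both traits
#' but different causal variants, H4 both traits sharing one causal
#' variant. Sums over configurations are computed in log space with
#' log-sum-exp, so |z| up to 40 does not overflow. For a single-SNP region
#' the H3 cross-term cancels exactly and PP3 = 0 by construction.
#'
#' @param labf1,labf2 log ABF vectors over the same harmonized SNPs.
#' @param p1,p2 prior probability a SNP is causal for trait 1 / trait 2
#'   only (defaults 1e-4).
#' @param p12 prior probability a SNP is causal for both (default 1e-5).
#' @param gene_id optional label.
#' @return object of class \code{coloc_result}: gene_id, n_snps,
#'   pp0..pp4 (summing to 1), priors.
#' @export
coloc_pp <- function(labf1, labf2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                     gene_id = NA_character_) {
  if (length(labf1) != length(labf2))
    stopf("trait ABF vectors differ in length")
  if (!length(labf1)) stopf("no SNPs")
  l1 <- logsumexp(labf1)
  l2 <- logsumexp(labf2)
  l12 <- logsumexp(labf1 + labf2)
  # H3: sum over i != j = (sum_i)(sum_j) - sum_{i=j}, in log space
  l3cross <- logdiffexp(l1 + l2, l12)
  lh <- c(h0 = 0,
          h1 = log(p1) + l1,
          h2 = log(p2) + l2,
          h3 = log(p1) + log(p2) + l3cross,
          h4 = log(p12) + l12)
  denom <- logsumexp(lh)
  pp <- exp(lh - denom)
  structure(list(gene_id = gene_id, n_snps = length(labf1),
                 pp = stats::setNames(pp, c("pp0", "pp1", "pp2", "pp3", "pp4")),
                 priors = c(p1 = p1, p2 = p2, p12 = p12)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Colocalization%s over %d SNPs:\n",
              if (is.na(x$gene_id)) "" else paste0(" [", x$gene_id, "]"),
              x$n_snps))
  print(round(x$pp, 4))
  cat(sprintf("  favoured: %s\n", names(x$pp)[which.max(x$pp)]))
  invisible(x)
}

#' Colocalization of GWAS and QTL signals for screened genes
#'
#' For each gene passing the association screen (GWAS-side P below
#' \code{gate_alpha}; genes not passing are emitted ungated with empty
#' posteriors), computes Wakefield log ABFs for the GWAS trait and the
#' molecular (QTL) trait over the gene's harmonizable SNPs and combines
#' them into the five-hypothesis posterior. PP4 — both traits driven by
#' the same causal variant — is the quantity of interest.
#'
#' @param xwas_result an \code{\link{xwas}} object.
#' @param gwas the GWAS \code{gwas_summary}.
#' @param qtl_summaries named list (by gene_id) of per-SNP QTL summary
#'   data.frames as produced by \code{\link{qtl_summary}} (columns SNP, A1,
#'   A2, Z, SE and/or N + MAF).
#' @param panel the LD \code{\link{reference_panel}} (SNP universe).
#' @param gate_alpha genes with association P below this enter
#'   colocalization (default 0.05).
#' @param gate_on which association P gates: asymptotic (default, the usual
#'   screening convention) or the permutation P.
#' @param gwas_n effective GWAS sample size used to derive per-SNP
#'   variances (the GWAS side carries Z only).
#' @param prior_var_gwas,prior_var_qtl Wakefield prior effect variances.
#' @param p1,p2,p12 colocalization priors.
#' @return object of class \code{coloc_scan}: data.frame with gene_id,
#'   n_snps, pp0..pp4, gated.
#' @export
run_coloc <- function(xwas_result, gwas, qtl_summaries, panel,
                      gate_alpha = 0.05,
                      gate_on = c("asymptotic", "permutation"),
                      gwas_n = 1e5,
                      prior_var_gwas = 0.2^2, prior_var_qtl = 0.15^2,
                      p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  gate_on <- match.arg(gate_on)
  tab <- xwas_result$table
  gate_p <- if (gate_on == "asymptotic") tab$p_asymptotic else tab$p_perm
  rows <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    gid <- tab$gene_id[i]
    row <- data.frame(gene_id = gid, n_snps = NA_integer_,
                      pp0 = NA_real_, pp1 = NA_real_, pp2 = NA_real_,
                      pp3 = NA_real_, pp4 = NA_real_, gated = FALSE,
                      stringsAsFactors = FALSE)
    if (gate_p[i] < gate_alpha && !is.null(qtl_summaries[[gid]])) {
      qtl <- qtl_summaries[[gid]]
      gi <- match(qtl$SNP, gwas$SNP)
      keep <- !is.na(gi)
      qtl <- qtl[keep, , drop = FALSE]
      gi <- gi[keep]
      if (nrow(qtl)) {
        swap <- gwas$A1[gi] == qtl$A2 & gwas$A2[gi] == qtl$A1
        zg <- gwas$Z[gi] * ifelse(swap, -1, 1)
        pidx <- match(qtl$SNP, panel$snps$snp_id)
        maf <- ifelse(!is.na(pidx), panel$snps$maf[pidx],
                      if ("MAF" %in% names(qtl)) qtl$MAF else NA)
        labf_g <- wakefield_abf(zg, prior_var = prior_var_gwas,
                                maf = maf, n = gwas_n)
        labf_q <- if ("SE" %in% names(qtl))
          wakefield_abf(qtl$Z, v = qtl$SE^2, prior_var = prior_var_qtl)
        else
          wakefield_abf(qtl$Z, prior_var = prior_var_qtl, maf = maf,
                        n = qtl$N)
        cp <- coloc_pp(labf_g, labf_q, p1 = p1, p2 = p2, p12 = p12,
                       gene_id = gid)
        row[c("pp0", "pp1", "pp2", "pp3", "pp4")] <- as.list(cp$pp)
        row$n_snps <- cp$n_snps
        row$gated <- TRUE
      }
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  structure(list(table = out, gate_alpha = gate_alpha, gate_on = gate_on,
                 priors = c(p1 = p1, p2 = p2, p12 = p12)),
            class = "coloc_scan")
}

#' @export
print.coloc_scan <- function(x, ...) {
  tab <- x$table
  cat(sprintf("Colocalization scan: %d genes, %d gated in at %s P < %g\n",
              nrow(tab), sum(tab$gated), x$gate_on, x$gate_alpha))
  g <- tab[tab$gated, , drop = FALSE]
  if (nrow(g)) {
    g$favoured <- c("pp0", "pp1", "pp2", "pp3", "pp4")[
      max.col(as.matrix(g[, c("pp0", "pp1", "pp2", "pp3", "pp4")]))]
    print(g[, c("gene_id", "n_snps", "pp3", "pp4", "favoured")],
          row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @export
as.data.frame.coloc_scan <- function(x, ...) x$table
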