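#' Reference panel of genotype dosages
#'
#' Container for an LD reference panel: an individuals x SNPs dosage matrix
#' (0/1/2 counts) plus per-SNP metadata. The panel is the source of the
#' SNP-correlation matrix S used by the gene-level association statistic.
#'
#' @param genotypes numeric matrix, individuals x SNPs, dosages in 0/1/2.
#' @param snp_ids unique SNP identifiers (character).
#' @param chrom chromosome label per SNP.
#' @param pos 1-based base-pair position per SNP; strictly increasing within
#'   a chromosome.
#' @param a1,a2 effect / other allele codes (single characters in A,C,G,T).
#' @return An object of class \code{ref_panel} with fields \code{genotypes}
#'   and a \code{snps} data.frame (snp_id, chrom, pos, a1, a2, maf). The
#'   stored \code{maf} is the minor-allele frequency recomputed from the
#'   dosage matrix.
#' @export
reference_panel <- function(genotypes, snp_ids, chrom, pos, a1, a2) {
  genotypes <- as.matrix(genotypes)
  m <- ncol(genotypes)
  if (length(snp_ids) != m || length(pos) != m)
    stopf("SNP metadata length does not match %d genotype columns", m)
  if (anyDuplicated(snp_ids))
    stopf("duplicated snp_ids: %s",
          paste(unique(snp_ids[duplicated(snp_ids)]), collapse = ", "))
  if (length(chrom) == 1L) chrom <- rep(chrom, m)
  if (length(a1) == 1L) a1 <- rep(a1, m)
  if (length(a2) == 1L) a2 <- rep(a2, m)
  if (!all(c(a1, a2) %in% c("A", "C", "G", "T")))
    stopf("allele codes must be one of A, C, G, T")
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (any(diff(p) <= 0))
      stopf("positions not strictly increasing on chromosome %s", ch)
  }
  v <- apply(genotypes, 2, stats::var)
  if (any(v == 0))
    stopf("monomorphic SNP(s): %s", paste(snp_ids[v == 0], collapse = ", "))
  af <- unname(colMeans(genotypes)) / 2
  maf <- pmin(af, 1 - af)
  colnames(genotypes) <- snp_ids
  structure(list(
    genotypes = genotypes,
    snps = data.frame(snp_id = as.character(snp_ids),
                      chrom = as.character(chrom),
                      pos = as.integer(pos),
                      a1 = a1, a2 = a2, maf = maf,
                      stringsAsFactors = FALSE)
  ), class = "ref_panel")
}

#' @export
print.ref_panel <- function(x, ...) {
  cat(sprintf("Reference panel: %d individuals x %d SNPs on chromosome(s) %s\n",
              nrow(x$genotypes), ncol(x$genotypes),
              paste(unique(x$snps$chrom), collapse = ", ")))
  cat(sprintf("  MAF range %.3f-%.3f, positions %d-%d\n",
              min(x$snps$maf), max(x$snps$maf),
              min(x$snps$pos), max(x$snps$pos)))
  invisible(x)
}

#' @export
dim.ref_panel <- function(x) dim(x$genotypes)

#' Simulate an LD-structured reference panel
#'
#' Dosages are generated from a latent Gaussian AR(1) process: each haplotype
#' of each individual is a correlated Gaussian vector with neighbour
#' correlation \code{ld_decay}, thresholded at the per-SNP allele-frequency
#' quantile, and the two haplotype indicators are summed to a 0/1/2 dosage.
#' This gives a single LD knob: adjacent-SNP dosage correlation increases
#' monotonically with \code{ld_decay}, and \code{ld_decay = 0} yields
#' independent SNPs.
#'
#' @param n_individuals number of individuals (>= 2).
#' @param m_snps number of SNPs (>= 1).
#' @param ld_decay latent AR(1) neighbour correlation, in [0, 1).
#' @param maf_range target minor-allele-frequency interval, subset of
#'   (0, 0.5].
#' @param seed integer seed; the generator is a pure function of it.
#' @param chrom chromosome label.
#' @param spacing_bp base-pair gap between adjacent SNPs.
#' @param start_pos position of the first SNP (1-based).
#' @param max_retries regenerations allowed for columns that come out
#'   monomorphic before failing.
#' @return A \code{\link{reference_panel}}. Allele codes are fixed to A
#'   (effect) / C (other); exporters can flip a subset to exercise
#'   harmonization.
#' @export
simulate_reference_panel <- function(n_individuals, m_snps, ld_decay = 0.6,
                                     maf_range = c(0.05, 0.5), seed = 1L,
                                     chrom = "1", spacing_bp = 10000L,
                                     start_pos = 1L, max_retries = 20L) {
  if (n_individuals < 2L) stopf("need n_individuals >= 2")
  if (m_snps < 1L) stopf("need m_snps >= 1")
  if (ld_decay < 0 || ld_decay >= 1) stopf("ld_decay must be in [0, 1)")
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stopf("maf_range must be an interval within (0, 0.5]")
  local_seed(seed, {
    maf <- stats::runif(m_snps, maf_range[1], maf_range[2])
    thr <- stats::qnorm(maf)
    draw_hap <- function() {
      # latent AR(1) across SNPs, one row per individual
      z <- matrix(stats::rnorm(n_individuals * m_snps), n_individuals, m_snps)
      if (ld_decay > 0 && m_snps > 1L) {
        w <- sqrt(1 - ld_decay^2)
        for (j in 2:m_snps) z[, j] <- ld_decay * z[, j - 1L] + w * z[, j]
      }
      z
    }
    G <- (sweep(draw_hap(), 2, thr, "<") + 0) +
         (sweep(draw_hap(), 2, thr, "<") + 0)
    # regenerate monomorphic columns independently (rare at small n / low maf)
    for (try in seq_len(max_retries)) {
      mono <- which(apply(G, 2, stats::var) == 0)
      if (!length(mono)) break
      for (j in mono) {
        h <- (stats::rnorm(n_individuals) < thr[j]) +
             (stats::rnorm(n_individuals) < thr[j])
        G[, j] <- h
      }
    }
    if (any(apply(G, 2, stats::var) == 0))
      stopf("monomorphic SNPs persist after %d retries; raise n_individuals or maf_range",
            max_retries)
    reference_panel(
      genotypes = G,
      snp_ids = sprintf("rs%06d", seq_len(m_snps)),
      chrom = chrom,
      pos = as.integer(start_pos + (seq_len(m_snps) - 1L) * spacing_bp),
      a1 = "A", a2 = "C")
  })
}

#' SNP-correlation (LD) matrix of a panel
#'
#' @param panel a \code{ref_panel}.
#' @param snp_ids optional subset (order preserved).
#' @param stabilize add a small ridge and rescale back to unit diagonal,
#'   \code{(S + eps I)/(1 + eps)}; finite-panel correlation matrices are
#'   near-singular and this keeps them positive definite while leaving the
#'   diagonal exactly 1.
#' @param eps ridge size.
#' @return symmetric correlation matrix with unit diagonal, dimnames = SNP
#'   ids.
#' @export
ld_matrix <- function(panel, snp_ids = NULL, stabilize = TRUE, eps = 1e-6) {
  G <- panel$genotypes
  if (!is.null(snp_ids)) {
    miss <- setdiff(snp_ids, colnames(G))
    if (length(miss)) stopf("SNPs not in panel: %s", paste(miss, collapse = ", "))
    G <- G[, snp_ids, drop = FALSE]
  }
  S <- stats::cor(G)
  if (stabilize) S <- stabilize_ld(S, eps)
  S
}

#' Stabilize a correlation matrix
#'
#' Adds \code{eps} to the diagonal and rescales by \code{1/(1 + eps)} so the
#' result is positive definite with diagonal exactly 1.
#' @param S symmetric correlation matrix.
#' @param eps ridge size (default 1e-6).
#' @export
stabilize_ld <- function(S, eps = 1e-6) {
  S <- (S + diag(eps, nrow(S))) / (1 + eps)
  (S + t(S)) / 2
}
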