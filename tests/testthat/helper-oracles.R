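# Independent brute-force oracles and tiny fixture builders. These share no
# code with the package internals they check.

# Gene-level association Z by explicit loops: W'Z / sqrt(W'SW).
brute_xwas_z <- function(W, Z, S) {
  num <- 0
  for (i in seq_along(W)) num <- num + W[i] * Z[i]
  q <- 0
  for (i in seq_along(W)) for (j in seq_along(W))
    q <- q + W[i] * S[i, j] * W[j]
  num / sqrt(q)
}

# Enrichment score by the full running-sum prefix scan of the printed
# formula: hits add |gs|^H / N_R, misses subtract 1/(N - N_C); ES is the
# maximum prefix value (the sum ends at 0, so ES >= 0).
brute_es <- function(gs, is_member, H = 1) {
  N <- length(gs)
  nc <- sum(is_member)
  nr <- sum(abs(gs[is_member])^H)
  run <- 0
  best <- -Inf
  for (i in seq_len(N)) {
    run <- run + if (is_member[i]) abs(gs[i])^H / nr else -1 / (N - nc)
    best <- max(best, run)
  }
  best
}

# random positive-definite correlation matrix with unit diagonal
random_corr <- function(m) {
  A <- matrix(rnorm(m * m), m)
  S <- crossprod(A) + diag(m) * 0.5
  d <- sqrt(diag(S))
  S / tcrossprod(d)
}

# small panel fixture
tiny_panel <- function(n = 200, m = 30, ld = 0.6, seed = 42) {
  simulate_reference_panel(n, m, ld_decay = ld, maf_range = c(0.1, 0.5),
                           seed = seed)
}

# a gwas_summary data.frame built directly from vectors (for hand cases)
hand_gwas <- function(snp, z, a1 = "A", a2 = "C", chrom = "1",
                      pos = seq_along(snp)) {
  structure(data.frame(SNP = snp, CHR = chrom, POS = pos, A1 = a1, A2 = a2,
                       Z = z, stringsAsFactors = FALSE),
            class = c("gwas_summary", "data.frame"))
}

# a gene_weights object built directly from vectors
hand_weights <- function(snp, w, a1 = "A", a2 = "C", chrom = "1",
                         pos = seq_along(snp), gene_id = "g1",
                         cv_r2 = 0.5, h2_est = 0.5, h2_p = 1e-4) {
  structure(list(
    gene_id = gene_id,
    snps = data.frame(snp_id = snp, chrom = chrom, pos = pos, a1 = a1,
                      a2 = a2, maf = 0.3, weight = w,
                      stringsAsFactors = FALSE),
    model_tag = "top1", cv_r2 = cv_r2, h2_est = h2_est, h2_p = h2_p,
    nonpredictive = FALSE), class = "gene_weights")
}
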