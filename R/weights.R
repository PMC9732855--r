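#' Estimate cis heritability by Haseman-Elston regression
#'
#' Moment estimator of the fraction of trait variance explained by the cis
#' SNPs: the off-diagonal trait cross-products y_i * y_j are regressed on
#' the corresponding entries of the cis genetic relatedness matrix
#' K = X X'/m (X standardized dosages). For a standardized trait the slope
#' estimates cis h2. The P value is one-sided (h2 > 0) from the asymptotic
#' normal of the slope; under the null the cross-products are uncorrelated
#' across pairs, so the OLS standard error is valid there.
#'
#' @param panel a \code{\link{reference_panel}}.
#' @param trait numeric trait vector, one value per individual.
#' @param cis_snps character vector of >= 2 SNP ids.
#' @return list: \code{h2_est} (clipped to [0, 1]), \code{h2_p},
#'   \code{h2_raw} (pre-clip slope), \code{truncated} (TRUE if clipping
#'   changed the estimate), \code{se} (large-sample SE of the slope).
#' @details The P value is the upper tail of the score statistic
#'   T = y'Ky - tr(K), a quadratic form in y whose null distribution is a
#'   mixture of chi-squares with few effective degrees of freedom at
#'   realistic cis-locus sizes; the tail is therefore approximated by
#'   moment matching (the Liu-Tang-Zhang scaled noncentral chi-square)
#'   rather than a plain normal, which is too light-tailed here.
#' @export
estimate_cis_h2 <- function(panel, trait, cis_snps) {
  n <- nrow(panel$genotypes)
  if (n < 10L) stopf("heritability estimation needs >= 10 individuals, got %d", n)
  if (length(cis_snps) < 2L) stopf("need >= 2 cis SNPs")
  if (length(trait) != n) stopf("trait length != number of individuals")
  X <- standardize(panel$genotypes[, cis_snps, drop = FALSE])
  y <- drop(scale(trait))
  m <- ncol(X)
  K <- tcrossprod(X) / m
  ut <- upper.tri(K)
  kk <- K[ut]
  yy <- tcrossprod(y)[ut]
  vx <- stats::var(kk)
  if (vx == 0) stopf("degenerate relatedness matrix (constant off-diagonals)")
  b <- stats::cov(kk, yy) / vx
  resid <- yy - mean(yy) - b * (kk - mean(kk))
  s2 <- sum(resid^2) / (length(kk) - 2)
  se <- sqrt(s2 / ((length(kk) - 1) * vx))
  # score statistic and its chi-square-mixture null
  Tstat <- drop(crossprod(y, K %*% y)) - sum(diag(K))
  ev_k <- eigen(crossprod(X) / m, symmetric = TRUE, only.values = TRUE)$values
  lam <- c(ev_k - sum(ev_k) / n, rep(-sum(ev_k) / n, n - m))
  p <- quadform_upper_p(Tstat, lam)
  h2 <- min(max(b, 0), 1)
  list(h2_est = h2, h2_p = p, h2_raw = b, truncated = !identical(h2, b),
       se = se)
}

# Upper-tail P of Q = sum(lambda_i * chisq_1) by Liu-Tang-Zhang moment
# matching to a scaled noncentral chi-square.
quadform_upper_p <- function(q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  if (c2 <= 0) return(NA_real_)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    delta <- 0
    l <- if (s1 == 0) Inf else 1 / s1^2
  }
  if (!is.finite(l)) return(stats::pnorm((q - c1) / sqrt(2 * c2),
                                         lower.tail = FALSE))
  tstar <- (q - c1) / sqrt(2 * c2)
  stats::pchisq(tstar * sqrt(2 * l + 4 * delta) + l + delta, df = l,
                ncp = delta, lower.tail = FALSE)
}

# ---- individual weight estimators (standardized X and y) -------------------

fit_top1 <- function(X, y, ...) {
  r <- drop(stats::cor(X, y))
  j <- which.max(abs(r))
  w <- numeric(ncol(X))
  w[j] <- r[j]
  w
}

# Ridge / BLUP with shrinkage tied to the cis heritability estimate:
# kappa = m * (1 - h2) / h2, the standard BLUP ratio for m exchangeable
# cis effects. h2 is clamped to [0.01, 0.99] so kappa stays finite.
fit_ridge_blup <- function(X, y, h2 = 0.5, ...) {
  h2 <- min(max(h2, 0.01), 0.99)
  m <- ncol(X)
  kappa <- m * (1 - h2) / h2
  drop(solve(crossprod(X) + diag(kappa, m), crossprod(X, y)))
}

# The penalty is chosen once per gene (cv.glmnet on the full data) and held
# fixed across the outer CV folds; refitting the path per fold is then a
# single cheap glmnet call.
fit_elastic_net <- function(X, y, seed = 1L, alpha = 0.5, lambda = NULL, ...) {
  if (ncol(X) < 2L) return(fit_top1(X, y))
  if (is.null(lambda)) lambda <- elastic_net_lambda(X, y, seed, alpha)
  fit <- glmnet::glmnet(X, y, alpha = alpha, standardize = FALSE)
  drop(as.matrix(stats::coef(fit, s = lambda, exact = FALSE)))[-1]
}

elastic_net_lambda <- function(X, y, seed = 1L, alpha = 0.5) {
  local_seed(seed, {
    foldid <- sample(rep_len(1:5, nrow(X)))
    glmnet::cv.glmnet(X, y, alpha = alpha, foldid = foldid,
                      standardize = FALSE)$lambda.min
  })
}

# Gibbs spike-and-slab: y = X b + e, b_j ~ pi N(0, sb2) + (1 - pi) delta_0.
# A deliberately compact surrogate for sparse Bayesian linear mixed models:
# point-mass spike, conjugate normal slab, Beta prior on the inclusion
# probability, inverse-gamma updates on the variances. The sampler itself
# is compiled (src/spike_slab.cpp) and uses R's RNG, so it is a pure
# function of the seed. Returns the posterior mean of b.
fit_spike_slab <- function(X, y, seed = 1L, n_iter = 600L, burn = 200L, ...) {
  m <- ncol(X)
  sb2 <- 0.2 / max(1, m * 0.1)   # slab variance init, weakly scaled to m
  local_seed(seed,
    .spike_slab_gibbs(X, y, as.integer(n_iter), as.integer(burn), sb2, 0.1))
}

weight_fitters <- list(top1 = fit_top1, ridge_blup = fit_ridge_blup,
                       elastic_net = fit_elastic_net,
                       spike_slab = fit_spike_slab)

# tie-break precedence when cv_r2 is equal
method_precedence <- c("spike_slab", "elastic_net", "ridge_blup", "top1")

#' Train per-gene cis-SNP weight models
#'
#' Fits a menu of weight estimators on standardized cis dosages and a
#' standardized molecular trait, scores each by k-fold cross-validated
#' out-of-sample R2 (1 - SSE/SST, clamped to [-1, 1]), and keeps the best
#' (ties broken by fixed precedence: spike_slab > elastic_net > ridge_blup
#' > top1). The spike-and-slab Gibbs sampler is a compact surrogate for the
#' sparse Bayesian linear mixed models usually used to train such weights.
#' Genes whose best cross-validated R2 is <= 0 are flagged non-predictive
#' and should be excluded downstream.
#'
#' @param panel a \code{\link{reference_panel}}.
#' @param trait molecular trait vector (one value per individual).
#' @param cis_snps SNP ids to use as predictors (>= 2).
#' @param methods subset of \code{c("top1", "ridge_blup", "elastic_net",
#'   "spike_slab")}.
#' @param cv_folds number of CV folds (>= 2).
#' @param seed integer seed (fold assignment and stochastic fitters).
#' @param gene_id gene label.
#' @return object of class \code{gene_weights}: snp table with per-SNP
#'   weights of the selected model, \code{model_tag}, \code{cv_r2} (and
#'   \code{cv_r2_all}), Haseman-Elston \code{h2_est}/\code{h2_p}, and a
#'   \code{nonpredictive} flag.
#' @export
fit_weight_models <- function(panel, trait, cis_snps,
                              methods = c("top1", "ridge_blup",
                                          "elastic_net", "spike_slab"),
                              cv_folds = 5L, seed = 1L, gene_id = "gene1") {
  methods <- match.arg(methods, names(weight_fitters), several.ok = TRUE)
  if (cv_folds < 2L) stopf("need cv_folds >= 2")
  idx <- match(cis_snps, panel$snps$snp_id)
  if (anyNA(idx)) stopf("gene %s: cis SNPs missing from panel", gene_id)
  X <- standardize(panel$genotypes[, cis_snps, drop = FALSE])
  y <- drop(scale(trait))
  n <- nrow(X)
  he <- estimate_cis_h2(panel, trait, cis_snps)

  folds <- local_seed(seed, sample(rep_len(seq_len(cv_folds), n)))
  cv_r2 <- stats::setNames(numeric(length(methods)), methods)
  fits <- stats::setNames(vector("list", length(methods)), methods)
  sst <- sum((y - mean(y))^2)
  enet_lambda <- if ("elastic_net" %in% methods && ncol(X) >= 2L)
    elastic_net_lambda(X, y, seed = derive_seed(seed, 999L)) else NULL
  for (mth in methods) {
    f <- weight_fitters[[mth]]
    pred <- numeric(n)
    for (k in seq_len(cv_folds)) {
      te <- folds == k
      w <- f(X[!te, , drop = FALSE], y[!te], h2 = he$h2_est,
             seed = derive_seed(seed, k), lambda = enet_lambda)
      pred[te] <- X[te, , drop = FALSE] %*% w
    }
    cv_r2[mth] <- max(-1, 1 - sum((y - pred)^2) / sst)
    fits[[mth]] <- f(X, y, h2 = he$h2_est, seed = derive_seed(seed, 0L),
                     lambda = enet_lambda)
  }

  ord <- method_precedence[method_precedence %in% methods]
  best <- NULL
  for (mth in ord[order(-cv_r2[ord])]) {
    if (any(fits[[mth]] != 0)) { best <- mth; break }
  }
  if (is.null(best)) best <- ord[which.max(cv_r2[ord])]
  nonpredictive <- cv_r2[best] <= 0 || all(fits[[best]] == 0)

  structure(list(
    gene_id = gene_id,
    snps = data.frame(snp_id = cis_snps,
                      chrom = panel$snps$chrom[idx],
                      pos = panel$snps$pos[idx],
                      a1 = panel$snps$a1[idx],
                      a2 = panel$snps$a2[idx],
                      maf = panel$snps$maf[idx],
                      weight = fits[[best]],
                      stringsAsFactors = FALSE),
    model_tag = best,
    cv_r2 = unname(cv_r2[best]),
    cv_r2_all = cv_r2,
    h2_est = he$h2_est,
    h2_p = he$h2_p,
    h2_raw = he$h2_raw,
    h2_truncated = he$truncated,
    nonpredictive = nonpredictive
  ), class = "gene_weights")
}

#' @export
print.gene_weights <- function(x, ...) {
  cat(sprintf("Gene %s: %d cis SNPs, model %s (cv R2 = %.3f), h2 = %.3f (P = %.3g)%s\n",
              x$gene_id, nrow(x$snps), x$model_tag, x$cv_r2, x$h2_est,
              x$h2_p, if (x$nonpredictive) " [non-predictive]" else ""))
  invisible(x)
}

#' Filter genes to the significantly heritable subset
#'
#' Keeps weight models whose Haseman-Elston heritability test is significant
#' at \code{alpha_h2}. Genes flagged non-predictive are also dropped when
#' \code{drop_nonpredictive} is TRUE.
#'
#' @param genes list of \code{gene_weights}.
#' @param alpha_h2 heritability P-value threshold (default 0.01).
#' @param drop_nonpredictive also drop genes whose best CV R2 <= 0.
#' @param quiet suppress the retention message.
#' @return filtered list of \code{gene_weights}.
#' @export
filter_heritable <- function(genes, alpha_h2 = 0.01,
                             drop_nonpredictive = TRUE, quiet = FALSE) {
  if (!length(genes)) return(genes)
  keep <- vapply(genes, function(g) {
    if (is.null(g$h2_p)) stopf("gene %s has no heritability P value", g$gene_id)
    g$h2_p < alpha_h2 && !(drop_nonpredictive && isTRUE(g$nonpredictive))
  }, logical(1))
  if (!quiet)
    message(sprintf("filter_heritable: retained %d / %d genes at alpha_h2 = %g",
                    sum(keep), length(genes), alpha_h2))
  genes[keep]
}

#' Per-SNP marginal QTL summary statistics
#'
#' Marginal regressions of the (standardized) molecular trait on each
#' standardized dosage, the way pQTL/eQTL summary statistics arise. Used as
#' the molecular-trait side of colocalization.
#'
#' @param panel a \code{\link{reference_panel}}.
#' @param trait trait vector.
#' @param snp_ids SNPs to test (default: all panel SNPs).
#' @return data.frame with SNP, CHR, POS, A1, A2, Z, SE, N, MAF; Z is the
#'   Wald statistic of the standardized marginal effect.
#' @export
qtl_summary <- function(panel, trait, snp_ids = NULL) {
  if (is.null(snp_ids)) snp_ids <- panel$snps$snp_id
  idx <- match(snp_ids, panel$snps$snp_id)
  if (anyNA(idx)) stopf("unknown SNP ids in qtl_summary")
  X <- standardize(panel$genotypes[, snp_ids, drop = FALSE])
  y <- drop(scale(trait))
  n <- length(y)
  r <- drop(stats::cor(X, y))
  r <- pmin(pmax(r, -0.999999), 0.999999)
  se <- sqrt((1 - r^2) / (n - 2))
  data.frame(SNP = snp_ids,
             CHR = panel$snps$chrom[idx],
             POS = panel$snps$pos[idx],
             A1 = panel$snps$a1[idx],
             A2 = panel$snps$a2[idx],
             Z = r / se,
             SE = se,
             N = n,
             MAF = panel$snps$maf[idx],
             stringsAsFactors = FALSE)
}
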