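test_that("Haseman-Elston estimator recovers the extremes", {
  p <- tiny_panel(n = 400, m = 25, seed = 21)
  st <- simulate_gene_trait(p, 125000, 125000, n_causal = 3, cis_h2 = 1,
                            seed = 22)
  he <- estimate_cis_h2(p, st$trait, st$model$cis_snp_ids)
  expect_gt(he$h2_est, 0.6)
  expect_lt(he$h2_p, 1e-4)
  # permuting the trait destroys the signal: estimate centred on 0
  h0 <- replicate(30, {
    estimate_cis_h2(p, sample(st$trait), st$model$cis_snp_ids)$h2_raw
  })
  expect_lt(abs(mean(h0)), 0.1)
})

test_that("Haseman-Elston P is calibrated under the null", {
  # null traits: ~5% of one-sided P values below 0.05
  p <- tiny_panel(n = 200, m = 20, seed = 23)
  ps <- replicate(300, {
    estimate_cis_h2(p, rnorm(200), p$snps$snp_id)$h2_p
  })
  frac <- mean(ps < 0.05)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.09)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.001)
})

test_that("heritability estimator refuses degenerate input", {
  p <- tiny_panel(n = 100, m = 10, seed = 24)
  expect_error(estimate_cis_h2(p, rnorm(100), p$snps$snp_id[1]), ">= 2")
  small <- reference_panel(p$genotypes[1:6, 1:5], p$snps$snp_id[1:5], "1",
                           p$snps$pos[1:5], "A", "C")
  expect_error(estimate_cis_h2(small, rnorm(6), small$snps$snp_id), "10")
})

test_that("top1 identifies the causal SNP without LD", {
  hits <- replicate(20, {
    s <- sample.int(1e6, 1)
    p <- simulate_reference_panel(500, 10, ld_decay = 0, seed = s,
                                  maf_range = c(0.2, 0.5))
    st <- simulate_gene_trait(p, 50000, 50000, n_causal = 1, cis_h2 = 0.8,
                              seed = s + 1)
    w <- fit_weight_models(p, st$trait, p$snps$snp_id, methods = "top1",
                           seed = s + 2)
    # oracle: argmax marginal |correlation|
    r <- abs(cor(scale(p$genotypes), st$trait))
    sel <- w$snps$snp_id[w$snps$weight != 0]
    identical(sel, p$snps$snp_id[which.max(r)]) &&
      sel == st$model$causal_snp_ids
  })
  expect_gt(mean(hits), 0.9)
})

test_that("ridge/BLUP weights match the closed form", {
  p <- tiny_panel(n = 150, m = 2, seed = 26)
  y <- rnorm(150)
  w <- fit_weight_models(p, y, p$snps$snp_id, methods = "ridge_blup",
                         cv_folds = 3, seed = 27)
  # oracle: direct matrix inversion with the documented kappa
  X <- scale(p$genotypes)
  ys <- drop(scale(y))
  he <- estimate_cis_h2(p, y, p$snps$snp_id)
  h2 <- min(max(he$h2_est, 0.01), 0.99)
  kappa <- ncol(X) * (1 - h2) / h2
  w_cf <- solve(crossprod(X) + diag(kappa, 2), crossprod(X, ys))
  expect_equal(w$snps$weight, as.vector(w_cf), tolerance = 1e-10)
})

test_that("pure-noise traits are flagged non-predictive", {
  flags <- replicate(20, {
    s <- sample.int(1e6, 1)
    p <- simulate_reference_panel(200, 10, ld_decay = 0.3, seed = s)
    w <- fit_weight_models(p, rnorm(200), p$snps$snp_id, seed = s + 1)
    w$nonpredictive
  })
  expect_gt(mean(flags), 0.5)
})

test_that("selected model has the best cross-validated R2", {
  p <- tiny_panel(n = 300, m = 20, seed = 29)
  st <- simulate_gene_trait(p, 100000, 100000, n_causal = 2, cis_h2 = 0.6,
                            seed = 30)
  w <- fit_weight_models(p, st$trait, st$model$cis_snp_ids, seed = 31)
  expect_true(all(w$cv_r2 >= w$cv_r2_all - 1e-12))
  expect_true(w$model_tag %in% names(w$cv_r2_all))
  expect_true(all(w$cv_r2_all >= -1 & w$cv_r2_all <= 1))
  expect_true(any(w$snps$weight != 0))
})

test_that("cv_r2 approaches cis_h2 from below as n grows", {
  r2_at <- function(n) {
    mean(replicate(8, {
      s <- sample.int(1e6, 1)
      p <- simulate_reference_panel(n, 15, ld_decay = 0.4, seed = s)
      st <- simulate_gene_trait(p, 75000, 75000, n_causal = 2, cis_h2 = 0.5,
                                seed = s + 1)
      fit_weight_models(p, st$trait, st$model$cis_snp_ids,
                        methods = c("top1", "ridge_blup"), seed = s + 2)$cv_r2
    }))
  }
  small <- r2_at(150)
  large <- r2_at(1200)
  expect_gt(large, small)
  expect_lt(large, 0.55)
  expect_gt(large, 0.3)
})

test_that("weight orientation flips with allele recoding, predictions unchanged", {
  p <- tiny_panel(n = 250, m = 10, seed = 33)
  st <- simulate_gene_trait(p, 50000, 50000, n_causal = 1, cis_h2 = 0.8,
                            seed = 34)
  w1 <- fit_weight_models(p, st$trait, p$snps$snp_id, methods = "ridge_blup",
                          seed = 35)
  # flip dosage coding and allele labels of SNP 3
  G2 <- p$genotypes
  G2[, 3] <- 2 - G2[, 3]
  a1 <- p$snps$a1; a2 <- p$snps$a2
  tmp <- a1[3]; a1[3] <- a2[3]; a2[3] <- tmp
  p2 <- reference_panel(G2, p$snps$snp_id, p$snps$chrom, p$snps$pos, a1, a2)
  w2 <- fit_weight_models(p2, st$trait, p$snps$snp_id, methods = "ridge_blup",
                          seed = 35)
  expect_equal(w2$snps$weight[3], -w1$snps$weight[3], tolerance = 1e-10)
  expect_equal(w2$snps$weight[-3], w1$snps$weight[-3], tolerance = 1e-10)
  pred1 <- scale(p$genotypes) %*% w1$snps$weight
  pred2 <- scale(G2) %*% w2$snps$weight
  expect_equal(pred1, pred2, tolerance = 1e-10)
})

test_that("heritability filter retains the right genes", {
  mk <- function(p_val) hand_weights("s1", 1, h2_p = p_val)
  genes <- list(mk(0.001), mk(0.05), mk(0.5))
  expect_length(filter_heritable(genes, 0.01, quiet = TRUE), 1)
  expect_length(filter_heritable(genes, 1, quiet = TRUE), 3)
  expect_length(filter_heritable(genes, 0, quiet = TRUE), 0)
})

test_that("null-gene retention rate matches the binomial expectation", {
  p <- tiny_panel(n = 150, m = 15, seed = 37)
  ps <- replicate(400, estimate_cis_h2(p, rnorm(150), p$snps$snp_id)$h2_p)
  retained <- sum(ps < 0.01)
  expect_lt(retained, qbinom(0.999, 400, 0.01) + 3)
})

test_that("QTL summary matches per-SNP marginal regression", {
  p <- tiny_panel(n = 200, m = 5, seed = 39)
  y <- rnorm(200)
  q <- qtl_summary(p, y)
  fit <- summary(lm(scale(y) ~ scale(p$genotypes[, 2])))$coefficients
  expect_equal(q$Z[2], fit[2, "t value"], tolerance = 1e-8)
  expect_equal(q$SE[2], fit[2, "Std. Error"], tolerance = 1e-3)
})
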