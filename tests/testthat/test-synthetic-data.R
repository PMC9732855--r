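test_that("reference panel generator is a pure function of its seed", {
  p1 <- simulate_reference_panel(100, 40, ld_decay = 0.5, seed = 7)
  p2 <- simulate_reference_panel(100, 40, ld_decay = 0.5, seed = 7)
  p3 <- simulate_reference_panel(100, 40, ld_decay = 0.5, seed = 8)
  expect_identical(p1$genotypes, p2$genotypes)
  expect_identical(p1$snps, p2$snps)
  expect_false(identical(p1$genotypes, p3$genotypes))
})

test_that("ld_decay controls adjacent-SNP correlation", {
  p0 <- simulate_reference_panel(200, 50, ld_decay = 0, seed = 1,
                                 maf_range = c(0.1, 0.5))
  p9 <- simulate_reference_panel(200, 50, ld_decay = 0.9, seed = 1,
                                 maf_range = c(0.1, 0.5))
  r0 <- cor(p0$genotypes)
  r9 <- cor(p9$genotypes)
  off <- upper.tri(r0)
  expect_lt(mean(abs(r0[off])), 0.15)          # independence case
  adj <- cbind(1:49, 2:50)
  expect_gt(mean(r9[adj]), mean(r0[adj]))      # monotonicity in ld_decay
  expect_gt(mean(r9[adj]), 0.4)
})

test_that("panel invariants hold: maf matches dosages, positions increase", {
  p <- simulate_reference_panel(150, 25, ld_decay = 0.3, seed = 3)
  af <- colMeans(p$genotypes) / 2
  expect_equal(unname(pmin(af, 1 - af)), p$snps$maf, tolerance = 1e-12)
  expect_true(all(diff(p$snps$pos) > 0))
  expect_true(all(p$snps$maf > 0 & p$snps$maf <= 0.5))
  expect_false(anyDuplicated(p$snps$snp_id) > 0)
})

test_that("monomorphic columns are rejected at construction", {
  G <- cbind(c(0, 1, 2, 1), c(1, 1, 1, 1))
  expect_error(reference_panel(G, c("s1", "s2"), "1", c(1, 2), "A", "C"),
               "monomorphic")
})

test_that("gene trait respects cis_h2 at both extremes", {
  p <- tiny_panel(n = 300, m = 30, seed = 2)
  st1 <- simulate_gene_trait(p, 150000, 150000, n_causal = 2, cis_h2 = 1,
                             seed = 4)
  X <- scale(p$genotypes[, st1$model$causal_snp_ids])
  g <- as.vector(scale(X %*% st1$model$true_weights))
  expect_equal(st1$trait, g, tolerance = 1e-12)
  r0 <- replicate(30, {
    st0 <- simulate_gene_trait(p, 150000, 150000, n_causal = 2, cis_h2 = 0,
                               seed = sample.int(1e6, 1))
    cor(st0$trait, g)
  })
  expect_lt(abs(mean(r0)), 0.05)
})

test_that("realized genetic variance matches cis_h2 (regression oracle)", {
  # one causal SNP, no LD: R2 of trait on the causal dosage estimates cis_h2
  r2 <- replicate(200, {
    s <- sample.int(1e6, 1)
    p <- simulate_reference_panel(500, 5, ld_decay = 0, seed = s,
                                  maf_range = c(0.2, 0.5))
    st <- simulate_gene_trait(p, 25000, 25000, n_causal = 1, cis_h2 = 0.5,
                              seed = s + 1)
    x <- p$genotypes[, st$model$causal_snp_ids]
    summary(lm(st$trait ~ x))$r.squared
  })
  expect_equal(mean(r2), 0.5, tolerance = 0.03)
})

test_that("cis window is enforced and empty windows fail by name", {
  p <- tiny_panel(n = 100, m = 20, seed = 5)
  st <- simulate_gene_trait(p, 50000, 30000, n_causal = 1, seed = 1,
                            gene_id = "gX")
  pos <- p$snps$pos[match(st$model$causal_snp_ids, p$snps$snp_id)]
  expect_true(all(abs(pos - 50000) <= 30000))
  expect_error(
    simulate_gene_trait(p, 5e7, 1000, n_causal = 1, gene_id = "gFar"),
    "gFar")
})

test_that("null GWAS Z-scores are standard normal per SNP", {
  p <- tiny_panel(n = 300, m = 40, seed = 6)
  zs <- sapply(1:60, function(i) simulate_gwas_summary(p, seed = i)$Z)
  expect_lt(abs(mean(zs)), 3 / sqrt(length(zs)))
  expect_gt(var(as.vector(zs)), 0.9)
  expect_lt(var(as.vector(zs)), 1.1)
})

test_that("exported allele flips are recovered by harmonization", {
  p <- tiny_panel(n = 250, m = 30, seed = 8)
  st <- simulate_gene_trait(p, 150000, 150000, n_causal = 2, cis_h2 = 0.8,
                            seed = 9, lambda_effect = 4)
  w <- fit_weight_models(p, st$trait, st$model$cis_snp_ids,
                         methods = "top1", seed = 10)
  g0 <- simulate_gwas_summary(p, list(st$model), seed = 11, flip_fraction = 0)
  g1 <- simulate_gwas_summary(p, list(st$model), seed = 11,
                              flip_fraction = 0.5)
  h0 <- harmonize(g0, w, p)
  h1 <- harmonize(g1, w, p)
  expect_equal(xwas_z(h0$W, h0$Z, h0$S), xwas_z(h1$W, h1$Z, h1$S),
               tolerance = 1e-12)
})

test_that("chemical-set generator is uniform at strength 0 and top-heavy otherwise", {
  universe <- sprintf("g%04d", 1:500)
  ranks <- 1:500
  # aggregate member-rank uniformity over many null sets
  pcts <- unlist(lapply(1:40, function(i) {
    coll <- simulate_chemical_sets(universe, 5, c(10, 20), n_enriched = 0,
                                   enrichment_strength = 0,
                                   xwas_ranks = ranks, seed = i)
    (unlist(lapply(coll$sets, match, universe)) - 1) / 499
  }))
  expect_gt(suppressWarnings(ks.test(pcts, "punif"))$p.value, 0.01)
  coll <- simulate_chemical_sets(universe, 10, c(10, 20), n_enriched = 5,
                                 enrichment_strength = 10,
                                 xwas_ranks = ranks, seed = 3)
  mean_pct <- vapply(coll$sets, function(g) mean(match(g, universe) / 500),
                     numeric(1))
  enr <- grepl("^enr", names(coll$sets))
  expect_lt(mean(mean_pct[enr]), mean(mean_pct[!enr]))
  expect_error(simulate_chemical_sets(universe, 2, c(5, 600)), "size_range")
})

test_that("traits projected onto a second cohort keep the architecture", {
  p1 <- tiny_panel(n = 300, m = 30, seed = 12)
  p2 <- tiny_panel(n = 300, m = 30, seed = 13)
  st <- simulate_gene_trait(p1, 150000, 150000, n_causal = 2, cis_h2 = 1,
                            seed = 14)
  tr2 <- simulate_trait_from_model(p2, st$model, seed = 15)
  X2 <- scale(p2$genotypes[, st$model$causal_snp_ids])
  g2 <- as.vector(scale(X2 %*% st$model$true_weights))
  expect_equal(tr2, g2, tolerance = 1e-12)  # h2 = 1: deterministic transfer
})
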