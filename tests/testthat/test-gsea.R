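ranked3 <- rank_genes(c(gene1 = 3, gene2 = 2, gene3 = 1))

test_that("enrichment score matches hand evaluation of the running sum", {
  # gs = (3, 2, 1), C = {gene1}: running sum (1, 1/2, 0) -> ES = 1
  expect_equal(as.numeric(enrichment_score(ranked3, "gene1")), 1)
  # C = {gene3}: running sum (-1/2, -1, 0) -> ES = 0
  expect_equal(as.numeric(enrichment_score(ranked3, "gene3")), 0)
  # C = universe: no miss terms, N_R normalizes the whole sum -> ES = 1
  expect_equal(as.numeric(enrichment_score(ranked3,
                                           c("gene1", "gene2", "gene3"))), 1)
  # middle gene: running sum (-1/2, 1/2, 0) -> ES = 1/2
  expect_equal(as.numeric(enrichment_score(ranked3, "gene2")), 0.5)
})

test_that("hit-position evaluation equals the full prefix-scan oracle", {
  set.seed(90)
  for (i in 1:50) {
    N <- sample(5:60, 1)
    gs <- sort(abs(rnorm(N, sd = 2)), decreasing = TRUE)
    names(gs) <- sprintf("g%03d", seq_len(N))
    ranked <- rank_genes(gs)
    k <- sample(seq_len(N - 1), 1)
    members <- sample(names(gs), k)
    es <- as.numeric(enrichment_score(ranked, members))
    oracle <- brute_es(ranked$stat, ranked$gene_id %in% members)
    expect_equal(es, max(0, oracle), tolerance = 1e-12)
    expect_gte(es, 0)
    expect_lte(es, 1)
  }
})

test_that("ES is invariant to positive rescaling of the statistics", {
  set.seed(91)
  gs <- setNames(abs(rnorm(30)), sprintf("g%02d", 1:30))
  members <- sample(names(gs), 8)
  e1 <- as.numeric(enrichment_score(rank_genes(gs), members))
  e2 <- as.numeric(enrichment_score(rank_genes(gs * 17.3), members))
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("zero member statistics give ES 0 with a flag", {
  gs <- c(a = 5, b = 4, c = 0, d = 0)
  es <- enrichment_score(rank_genes(gs), c("c", "d"))
  expect_equal(as.numeric(es), 0)
  expect_true(attr(es, "zero_nr"))
})

test_that("null ES sample is deterministic, in range, and mode-tagged", {
  set.seed(92)
  gs <- setNames(abs(rnorm(40)), sprintf("g%02d", 1:40))
  ranked <- rank_genes(gs)
  n1 <- gsea_null(ranked, names(gs)[1:6], n_perm = 50, seed = 5)
  n2 <- gsea_null(ranked, names(gs)[1:6], n_perm = 50, seed = 5)
  expect_identical(n1, n2)
  expect_true(all(n1 >= 0 & n1 <= 1))
  expect_length(gsea_null(ranked, names(gs)[1:6], n_perm = 1, seed = 1), 1)
  expect_error(gsea_null(ranked, names(gs)[1:6], n_perm = 0), "n_perm")
})

test_that("NES follows the printed normalization and counting rules", {
  # null = (0.2, 0.4), es = 0.6: NES = (0.6 - 0.3)/sd = 2.1213...
  np <- nes_and_p(0.6, c(0.2, 0.4), n_perm = 2)
  expect_equal(np$nes, (0.6 - 0.3) / sd(c(0.2, 0.4)), tolerance = 1e-12)
  expect_equal(np$nes, 2.1213, tolerance = 1e-4)
  expect_equal(np$p_emp, 1 / 3)
  # es equal to the null mean: NES = 0
  expect_equal(nes_and_p(0.3, c(0.2, 0.4))$nes, 0, tolerance = 1e-12)
  # es below every null value: p = 1
  expect_equal(nes_and_p(0.1, c(0.2, 0.4))$p_emp, 1)
  # degenerate null: NES missing but p still counted
  np0 <- nes_and_p(0.5, c(0.3, 0.3))
  expect_true(np0$zero_sd)
  expect_true(is.na(np0$nes))
  expect_equal(np0$p_emp, 1 / 3)
})

test_that("gene_shuffle null matches brute-force enumeration on tiny lists", {
  # N = 6 genes, k = 2: enumerate all C(6,2) = 15 memberships
  set.seed(93)
  gs <- setNames(sort(abs(rnorm(6, sd = 2)), decreasing = TRUE),
                 sprintf("g%d", 1:6))
  ranked <- rank_genes(gs)
  combos <- combn(6, 2)
  exact <- apply(combos, 2, function(ix)
    max(0, brute_es(ranked$stat, seq_len(6) %in% ix)))
  null_es <- gsea_null(ranked, c("g1", "g2"), n_perm = 6000, seed = 7)
  vals <- sort(unique(round(exact, 12)))
  p_exact <- vapply(vals, function(v) mean(round(exact, 12) == v), numeric(1))
  p_hat <- vapply(vals, function(v) mean(round(null_es, 12) == v), numeric(1))
  expect_equal(sum(p_hat), 1)                  # null support = enumeration
  expect_lt(0.5 * sum(abs(p_hat - p_exact)), 0.05)
})

test_that("empirical P is uniform for random sets under gene_shuffle", {
  set.seed(94)
  gs <- setNames(abs(rnorm(200)), sprintf("g%03d", 1:200))
  ranked <- rank_genes(gs)
  ps <- replicate(150, {
    members <- sample(names(gs), 10)
    es <- as.numeric(enrichment_score(ranked, members))
    null_es <- gsea_null(ranked, members, n_perm = 99,
                         seed = sample.int(1e6, 1))
    nes_and_p(es, null_es, 99)$p_emp
  })
  frac <- mean(ps < 0.05)
  expect_gt(frac, 0.01)
  expect_lt(frac, 0.10)
})

test_that("snp_shuffle null recomputes statistics from shuffled GWAS labels", {
  p <- tiny_panel(n = 200, m = 40, seed = 95)
  models <- list()
  wp <- list()
  for (g in 1:4) {
    anchor <- (g - 1) * 100000 + 45000
    st <- simulate_gene_trait(p, anchor, 45000, n_causal = 1, cis_h2 = 0.7,
                              seed = 96 + g, gene_id = paste0("g", g))
    models[[g]] <- st$model
    wp[[paste0("g", g)]] <- fit_weight_models(
      p, st$trait, st$model$cis_snp_ids, methods = "ridge_blup",
      seed = 200 + g, gene_id = paste0("g", g))
  }
  gwas <- simulate_gwas_summary(p, models, seed = 97)
  scan <- xwas(gwas, wp, p, n_perm = 50, seed = 98)
  z <- setNames(scan$table$z_xwas, scan$table$gene_id)
  ranked <- rank_genes(z)
  inputs <- list(gwas = gwas, weight_panel = wp, panel = p)
  n1 <- gsea_null(ranked, c("g1", "g2"), n_perm = 30, mode = "snp_shuffle",
                  seed = 3, xwas_inputs = inputs)
  n2 <- gsea_null(ranked, c("g1", "g2"), n_perm = 30, mode = "snp_shuffle",
                  seed = 3, xwas_inputs = inputs)
  expect_identical(n1, n2)
  expect_true(all(n1 >= 0 & n1 <= 1))
  expect_gt(length(unique(n1)), 1)
})

test_that("full GSEA scan flags enriched sets and honours substreams", {
  set.seed(99)
  z <- setNames(c(abs(rnorm(20, 5)), abs(rnorm(180))), sprintf("g%03d", 1:200))
  coll <- simulate_chemical_sets(names(z), 20, c(8, 15), n_enriched = 5,
                                 enrichment_strength = 12,
                                 xwas_ranks = rank(-z, ties.method = "first"),
                                 seed = 100)
  res <- run_gsea(z, coll, n_perm = 200, seed = 101)
  tab <- res$table
  enr <- grepl("^enr", tab$set_id)
  expect_lt(median(tab$p_emp[enr]), median(tab$p_emp[!enr]))
  expect_true(all(tab$p_emp >= 1 / 201))
  # duplicated set under two ids: same ES; same p when substreams disabled
  dup <- gene_set_collection(list(a = coll$sets[[1]], b = coll$sets[[1]]),
                             coll$universe)
  r2 <- run_gsea(z, dup, n_perm = 100, seed = 5, per_set_substreams = FALSE)
  expect_equal(r2$table$es[1], r2$table$es[2])
  expect_equal(r2$table$p_emp[1], r2$table$p_emp[2])
})

test_that("NES of the null sample itself is centred and scaled", {
  set.seed(102)
  gs <- setNames(abs(rnorm(100)), sprintf("g%03d", 1:100))
  ranked <- rank_genes(gs)
  null_es <- gsea_null(ranked, names(gs)[1:10], n_perm = 2000, seed = 11)
  nes <- (null_es - mean(null_es)) / sd(null_es)
  expect_lt(abs(mean(nes)), 1e-12)
  expect_equal(sd(nes), 1, tolerance = 1e-12)
})
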