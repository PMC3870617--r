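test_that("hypergeometric p matches exact combinatorial enumeration", {
  # N=10, K=4, n=5, k=4: C(4,4)C(6,1)/C(10,5) = 6/252
  universe <- sprintf("g%02d", 1:10)
  coll <- gene_set_collection(list(S = universe[1:4]),
    universe = universe)
  res <- hypergeom_enrich(universe[c(1:4, 10)], coll, min_overlap = 1L)
  expect_equal(res$k, 4L)
  expect_equal(res$p, 6 / 252, tolerance = 1e-12)
  # k = 0 -> upper tail is 1
  res0 <- hypergeom_enrich(universe[9:10], coll, min_overlap = 0L)
  expect_equal(res0$p, 1)
})

test_that("hypergeometric p equals one-sided Fisher exact on random tables", {
  set.seed(20)
  universe <- sprintf("g%03d", 1:60)
  for (i in 1:500) {
    K <- sample(3:30, 1)
    n <- sample(3:30, 1)
    gset <- sample(universe, K)
    query <- sample(universe, n)
    coll <- gene_set_collection(list(S = gset), universe = universe)
    res <- suppressWarnings(hypergeom_enrich(query, coll,
      min_overlap = 0L))
    k <- length(intersect(gset, query))
    tab <- matrix(c(k, K - k, n - k, 60 - K - n + k), 2, 2)
    p_fisher <- fisher.test(tab, alternative = "greater")$p.value
    expect_lt(abs(res$p - p_fisher), 1e-12)
  }
})

test_that("BH adjustment matches the hand-worked step-up and a naive oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.42), 0.42)
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  naive_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    for (i in seq_len(m)) # step-up: min over j >= i of p_(j) * m / j
      adj[o[i]] <- min(1, min(p[o][i:m] * m / (i:m)))
    adj
  }
  set.seed(21)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), naive_bh(p), tolerance = 1e-15)
  }
})

test_that("retention requires overlap >= 5, raw p and FDR below threshold", {
  set.seed(22)
  universe <- sprintf("g%03d", 1:300)
  pool <- universe[1:40]
  sets <- c(
    list(planted = c(pool[1:20], universe[251:260])),
    setNames(lapply(1:10, function(i) sample(universe, 30)),
      paste0("bg", 1:10)),
    list(tiny = c(pool[1:3], universe[290:292]))
  )
  coll <- gene_set_collection(sets, universe = universe)
  res <- hypergeom_enrich(pool, coll)
  expect_true(res$retained[res$set_id == "planted"])
  expect_false(res$retained[res$set_id == "tiny"]) # k < 5 blocks it
  expect_true(all(res$k[res$retained] >= 5L))
  expect_true(all(res$p[res$retained] < 0.05))
  expect_true(all(res$fdr_p[res$retained] < 0.05))
  # sets excluded by the overlap filter carry no FDR value
  expect_true(all(is.na(res$fdr_p[res$k < 5])))
  # empty query -> empty result
  expect_equal(nrow(hypergeom_enrich(character(), coll)), 0L)
  # out-of-universe query genes are dropped with a warning
  expect_warning(hypergeom_enrich(c(pool, "NOPE"), coll), "dropped")
})

test_that("false-positive control and planted-set power hold over seeds", {
  n_retained <- integer(15L)
  all5 <- logical(15L)
  genes <- sprintf("GENE%05d", 1:2000)
  for (s in 1:15) {
    cfg0 <- simulation_config(planted_enriched_sets = 0L,
      seed = 700L + s)
    gs0 <- simulate_gene_sets(genes, cfg0)
    set.seed(800L + s)
    query <- sample(genes, 150)
    res0 <- hypergeom_enrich(query, gs0$collection)
    n_retained[s] <- sum(res0$retained)

    cfg5 <- simulation_config(planted_enriched_sets = 5L,
      seed = 700L + s)
    pool <- query
    gs5 <- simulate_gene_sets(genes, cfg5, up_targets = pool)
    res5 <- hypergeom_enrich(pool, gs5$collection)
    all5[s] <- all(gs5$enriched_ids %in% res5$set_id[res5$retained])
  }
  expect_lte(mean(n_retained), 1)
  expect_gte(mean(all5), 0.95)
})

test_that("term overlap counts shared retained sets by category", {
  universe <- sprintf("g%03d", 1:200)
  sets <- setNames(lapply(1:6, function(i) universe[((i - 1) * 20 + 1):
    (i * 20)]), paste0("S", 1:6))
  coll <- gene_set_collection(sets, categories = rep(c("GO", "KEGG"), 3),
    universe = universe)
  res_a <- hypergeom_enrich(universe[1:45], coll)   # hits S1, S2 (+S3)
  res_b <- hypergeom_enrich(universe[21:65], coll)  # hits S2, S3 (+S4)
  ov <- term_overlap(res_a, res_b)
  ra <- res_a$set_id[res_a$retained]
  rb <- res_b$set_id[res_b$retained]
  expect_equal(ov$overlap[ov$category == "total"],
    length(intersect(ra, rb)))
  expect_equal(sum(ov$overlap[ov$category != "total"]),
    ov$overlap[ov$category == "total"])
  # identical results overlap completely; different collections error
  ov_same <- term_overlap(res_a, res_a)
  expect_equal(ov_same$overlap[ov_same$category == "total"], length(ra))
  coll2 <- gene_set_collection(sets[1:5],
    categories = rep("GO", 5), universe = universe)
  res_c <- hypergeom_enrich(universe[1:45], coll2)
  expect_error(term_overlap(res_a, res_c), "different")
})

test_that("GMT files round-trip with categories intact", {
  universe <- sprintf("g%03d", 1:100)
  coll <- gene_set_collection(
    list(A = universe[1:10], B = universe[5:30]),
    categories = c("GO", "KEGG"), universe = universe)
  path <- tempfile(fileext = ".gmt")
  write_gmt(coll, path)
  back <- read_gmt(path, universe = universe)
  expect_identical(back$sets, coll$sets)
  expect_identical(back$info$category, coll$info$category)
  expect_error(gene_set_collection(list(E = "not-in-universe"),
    universe = universe), "empty")
})
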