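test_that("expression simulator honours the configured design and seed", {
  cfg <- simulation_config(n_mirnas = 100L,
    group_sizes = c(Normal = 7L, LGDHS = 3L), n_de_per_group = 10L,
    de_log2fc = 1, seed = 1L)
  sim1 <- simulate_expression(cfg)
  expect_equal(dim(sim1$expr$values), c(100L, 10L))
  expect_equal(nrow(sim1$truth$de_mirnas$LGDHS), 10L)
  expect_true(all(sim1$truth$de_mirnas$LGDHS$mirna_id %in%
    rownames(sim1$expr$values)))
  sim2 <- simulate_expression(cfg)
  expect_identical(sim1$expr$values, sim2$expr$values)
  expect_error(
    simulate_expression(simulation_config(
      group_sizes = c(Control = 7L, LGDHS = 3L))),
    "Normal")
})

test_that("planted shifts land in the right group with the right sign", {
  cfg <- simulation_config(n_mirnas = 200L, n_de_per_group = 20L,
    de_log2fc = 3, inv_gamma_shape = 20, inv_gamma_scale = 20, seed = 5L)
  sim <- simulate_expression(cfg)
  es <- sim$expr
  for (g in names(sim$truth$de_mirnas)) {
    tt <- sim$truth$de_mirnas[[g]]
    diff <- rowMeans(es$values[tt$mirna_id, es$groups == g, drop = FALSE]) -
      rowMeans(es$values[tt$mirna_id, es$groups == "Normal", drop = FALSE])
    expect_true(all(sign(diff) == ifelse(tt$direction == "up", 1, -1)))
  }
})

test_that("with no planted effects the differential null is calibrated", {
  cfg <- simulation_config(n_mirnas = 2000L,
    group_sizes = c(Normal = 7L, LGDHS = 3L), n_de_per_group = 0L,
    seed = 11L)
  sim <- simulate_expression(cfg)
  de <- differential_mirnas(sim$expr, "LGDHS", "Normal")
  frac <- mean(de$p < 0.05)
  expect_gte(frac, 0.05 - 0.015)
  expect_lte(frac, 0.05 + 0.015)
})

test_that("prediction tables encode the consensus conditions by construction", {
  cfg1 <- simulation_config(n_mirnas = 40L, n_genes = 300L,
    program_agreement = 1, seed = 2L)
  mi <- sprintf("miR-%04d", 1:40)
  ge <- sprintf("GENE%05d", 1:300)
  p1 <- simulate_prediction_tables(mi, ge, cfg1)
  cons1 <- suppressWarnings(consensus_targets(p1$ensemble, mirnas = mi))
  got <- lapply(cons1$per_mirna, `[[`, "consensus")
  expect_identical(got[names(p1$true_targets)], p1$true_targets)

  cfg0 <- simulation_config(n_mirnas = 40L, n_genes = 300L,
    program_agreement = 0, seed = 2L)
  p0 <- simulate_prediction_tables(mi, ge, cfg0)
  cons0 <- suppressWarnings(consensus_targets(p0$ensemble, mirnas = mi))
  rec0 <- unlist(lapply(mi, function(m)
    intersect(cons0$per_mirna[[m]]$consensus, p0$true_targets[[m]])))
  expect_length(rec0, 0L)
})

test_that("partial program agreement recovers the matching fraction of true pairs", {
  cfg <- simulation_config(n_mirnas = 70L, n_genes = 400L,
    program_agreement = 0.8, targets_per_mirna = 8, seed = 9L)
  mi <- sprintf("miR-%04d", 1:70)
  ge <- sprintf("GENE%05d", 1:400)
  p <- simulate_prediction_tables(mi, ge, cfg)
  n_true <- sum(lengths(p$true_targets))
  expect_gt(n_true, 400L)
  cons <- suppressWarnings(consensus_targets(p$ensemble, mirnas = mi))
  n_rec <- sum(vapply(mi, function(m)
    length(intersect(cons$per_mirna[[m]]$consensus, p$true_targets[[m]])),
    integer(1L)))
  expect_lt(abs(n_rec / n_true - 0.8), 0.05)
})

test_that("gene-set simulator plants enrichable sets and validates inputs", {
  genes <- sprintf("GENE%05d", 1:500)
  pool <- sample(genes, 80)
  cfg <- simulation_config(n_genes = 500L, n_gene_sets = 20L,
    planted_enriched_sets = 3L, gene_set_size_range = c(10L, 40L),
    seed = 4L)
  gs <- simulate_gene_sets(genes, cfg, up_targets = pool)
  expect_length(gs$collection$sets, 20L)
  expect_length(gs$enriched_ids, 3L)
  expect_true(all(lengths(gs$collection$sets) >= 5L))
  expect_true(all(unlist(gs$collection$sets) %in% genes))
  # planted sets are visibly pool-heavy
  planted_frac <- vapply(gs$collection$sets[gs$enriched_ids],
    function(s) mean(s %in% pool), numeric(1L))
  expect_true(all(planted_frac > 0.3))
  expect_error(
    simulate_gene_sets(genes[1:30], cfg, up_targets = pool),
    "smaller")
  expect_error(simulate_gene_sets(genes, cfg), "up_targets")
})

test_that("all three generators are deterministic under a fixed seed", {
  cfg <- tiny_sim(seed = 31L)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$expr$values, s2$expr$values)
  expect_identical(s1$ensemble$scored, s2$ensemble$scored)
  expect_identical(s1$collection$sets, s2$collection$sets)
  expect_identical(s1$truth$de_mirnas, s2$truth$de_mirnas)
  # ground-truth ids always subset of emitted ids
  expect_true(all(unlist(lapply(s1$truth$de_mirnas, `[[`, "mirna_id"))
    %in% rownames(s1$expr$values)))
  expect_true(all(names(s1$truth$true_targets) %in%
    rownames(s1$expr$values)))
  expect_true(all(unlist(s1$truth$true_targets) %in%
    s1$collection$universe))
  expect_true(all(s1$truth$enriched_ids %in%
    names(s1$collection$sets)))
})

test_that("pooled variances of null miRNAs match the inverse-gamma prior", {
  cfg <- simulation_config(n_mirnas = 3000L,
    group_sizes = c(Normal = 7L, LGDHS = 3L), n_de_per_group = 0L,
    inv_gamma_shape = 3, inv_gamma_scale = 3, seed = 21L)
  sim <- simulate_expression(cfg)
  de <- differential_mirnas(sim$expr, "LGDHS", "Normal")
  fit <- attr(de, "rvm_fit")
  expect_lt(abs(fit$a - 3) / 3, 0.2)
  expect_lt(abs(fit$b - 3) / 3, 0.2)
})
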