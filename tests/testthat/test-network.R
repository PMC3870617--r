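test_that("network construction matches a hand-counted example", {
  edges <- data.frame(
    mirna_id = c("miR-a", "miR-a", "miR-b"),
    gene_id = c("g1", "g2", "g2"), stringsAsFactors = FALSE)
  de <- fake_de(c("miR-a", "miR-b"), log2fc = c(2, -1.5))
  net <- build_weighted_network(fake_consensus(edges), de)
  validate_network(net)
  expect_equal(nrow(net$edges), 3L)
  expect_equal(net$genes$weight[net$genes$id == "g2"], 2)
  expect_equal(net$genes$weight[net$genes$id == "g1"], 1)
  expect_equal(sum(net$mirnas$degree), 3L)
  expect_equal(net$mirnas$weight, c(2, 1.5)) # |log2fc|
  expect_equal(net$mirnas$direction, c("up", "down"))
})

test_that("non-significant miRNAs are excluded and missing DE records are an error", {
  edges <- data.frame(mirna_id = c("miR-a", "miR-b"),
    gene_id = c("g1", "g2"), stringsAsFactors = FALSE)
  de <- fake_de(c("miR-a", "miR-b"), log2fc = c(2, 2),
    significant = c(TRUE, FALSE))
  net <- build_weighted_network(fake_consensus(edges), de)
  expect_equal(net$mirnas$id, "miR-a")
  de_short <- fake_de("miR-a", 2)
  expect_error(build_weighted_network(fake_consensus(edges), de_short),
    "miR-b")
  # empty consensus gives an empty but valid network
  empty <- fake_consensus(edges[0, ])
  net0 <- build_weighted_network(empty, de)
  validate_network(net0)
  expect_equal(nrow(net0$edges), 0L)
})

test_that("structural invariants hold across random simulated networks", {
  set.seed(14)
  for (i in 1:100) {
    net <- random_network()
    expect_true(validate_network(net))
    expect_equal(sum(net$mirnas$degree), nrow(net$edges))
    expect_equal(sum(net$genes$degree), nrow(net$edges))
  }
})

test_that("hub extraction keeps exactly the high-degree nodes and is idempotent", {
  # star miRNA with 6 targets survives at threshold 5
  edges <- data.frame(mirna_id = "miR-hub",
    gene_id = sprintf("g%d", 1:6), stringsAsFactors = FALSE)
  de <- fake_de("miR-hub", 2)
  net <- build_weighted_network(fake_consensus(edges), de)
  hub <- extract_hubs(net, 5L)
  expect_true(hub$mirnas$hub[hub$mirnas$id == "miR-hub"])
  expect_equal(nrow(hub$edges), 6L)
  # all-degrees-below-threshold gives an empty subnetwork
  small <- build_weighted_network(
    fake_consensus(edges[1:2, ]), de)
  expect_equal(nrow(extract_hubs(small, 5L)$edges), 0L)

  set.seed(15)
  for (i in 1:40) {
    net <- random_network(n_mirnas = 10L, n_genes = 12L, mean_deg = 4)
    hub <- extract_hubs(net, 3L)
    validate_network(hub)
    # hub-flagged nodes had degree >= threshold in the PARENT network
    flagged <- c(hub$mirnas$id[hub$mirnas$hub],
      hub$genes$id[hub$genes$hub])
    parent_deg <- setNames(c(net$mirnas$degree, net$genes$degree),
      c(net$mirnas$id, net$genes$id))
    expect_true(all(parent_deg[flagged] >= 3L))
    # idempotence
    hub2 <- extract_hubs(hub, 3L)
    expect_identical(hub$edges, hub2$edges)
    expect_identical(hub$mirnas, hub2$mirnas)
    expect_identical(hub$genes, hub2$genes)
  }
})

test_that("up-subnetwork fraction is exact arithmetic on directions", {
  edges <- data.frame(
    mirna_id = rep(sprintf("miR-%d", 1:8), each = 2),
    gene_id = paste0("g", 1:16), stringsAsFactors = FALSE)
  de <- fake_de(sprintf("miR-%d", 1:8),
    log2fc = c(2, 2, 2, -2, -2, -2, -2, -2))
  net <- build_weighted_network(fake_consensus(edges), de)
  up <- up_subnetwork(net)
  expect_equal(up$up_fraction, 37.5) # 3 of 8
  expect_equal(sort(up$network$mirnas$id), sprintf("miR-%d", 1:3))
  expect_true(all(up$network$mirnas$direction == "up"))
  # no up miRNAs -> empty subnetwork, 0%
  de_dn <- fake_de(sprintf("miR-%d", 1:8), log2fc = rep(-2, 8))
  net_dn <- build_weighted_network(fake_consensus(edges), de_dn)
  up0 <- up_subnetwork(net_dn)
  expect_equal(up0$up_fraction, 0)
  expect_equal(nrow(up0$network$edges), 0L)
})

test_that("planted 50/50 directions give a near-half up fraction at scale", {
  cfg <- simulation_config(n_mirnas = 800L,
    group_sizes = c(Normal = 7L, LGDHS = 3L), n_de_per_group = 400L,
    de_log2fc = 2.5, seed = 23L)
  sim <- simulate_expression(cfg)
  de <- differential_mirnas(sim$expr, "LGDHS", "Normal")
  sig <- de$mirna_id[de$significant]
  edges <- data.frame(mirna_id = sig, gene_id = paste0("g", seq_along(sig)),
    stringsAsFactors = FALSE)
  up <- up_subnetwork(build_weighted_network(fake_consensus(edges), de))
  expect_lt(abs(up$up_fraction - 50), 6)
})

test_that("identical networks compare with rank correlation 1 and no rank changes", {
  set.seed(16)
  net <- random_network(n_mirnas = 10L, n_genes = 20L)
  cmp <- compare_networks(net, net, n_perm = 500L)
  expect_setequal(cmp$shared_mirnas, net$mirnas$id)
  expect_equal(cmp$rank_correlation, 1)
  expect_true(all(cmp$deregulated$rank_change == 0))
})

test_that("rank-reversed weights give correlation -1 with an extreme permutation p", {
  mirnas <- sprintf("miR-%02d", 1:20)
  edges <- function(pref) data.frame(mirna_id = mirnas,
    gene_id = paste0(pref, 1:20), stringsAsFactors = FALSE)
  de_a <- fake_de(mirnas, log2fc = seq(0.1, 2, by = 0.1))
  de_b <- fake_de(mirnas, log2fc = seq(2, 0.1, by = -0.1))
  net_a <- build_weighted_network(fake_consensus(edges("ga")), de_a)
  net_b <- build_weighted_network(fake_consensus(edges("gb")), de_b)
  n_perm <- 2000L
  cmp <- compare_networks(net_a, net_b, n_perm = n_perm, seed = 2L)
  expect_equal(cmp$n_shared_nodes, 20L) # gene sides disjoint
  expect_equal(cmp$rank_correlation, -1)
  expect_lte(cmp$permutation_p, 2 / (n_perm + 1))
  # overlap counting is symmetric
  cmp_rev <- compare_networks(net_b, net_a, n_perm = 100L, seed = 2L)
  expect_setequal(cmp$shared_mirnas, cmp_rev$shared_mirnas)
})

test_that("disjoint networks yield empty overlap and an uncomputable rank test", {
  net_a <- build_weighted_network(
    fake_consensus(data.frame(mirna_id = "miR-a", gene_id = "g1")),
    fake_de("miR-a", 2))
  net_b <- build_weighted_network(
    fake_consensus(data.frame(mirna_id = "miR-b", gene_id = "g2")),
    fake_de("miR-b", 2))
  cmp <- compare_networks(net_a, net_b, n_perm = 100L)
  expect_length(cmp$shared_mirnas, 0L)
  expect_false(cmp$rank_test_computable)
  expect_true(is.na(cmp$rank_correlation))
})

test_that("networks export to edge-list TSV and GraphML", {
  set.seed(19)
  net <- random_network()
  ep <- tempfile(fileext = ".tsv")
  write_network_edges(net, ep)
  tab <- read.delim(ep)
  expect_equal(nrow(tab), nrow(net$edges))
  expect_true(all(c("mirna_weight", "gene_weight", "direction") %in%
    names(tab)))
  gp <- tempfile(fileext = ".graphml")
  write_network_graphml(net, gp)
  g <- igraph::read_graph(gp, format = "graphml")
  expect_equal(igraph::gorder(g), nrow(net$mirnas) + nrow(net$genes))
  expect_equal(igraph::gsize(g), nrow(net$edges))
})
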