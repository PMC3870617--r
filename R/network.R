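#' Build a node-weighted bipartite miRNA-target network
#'
#' One network per case-vs-control comparison: nodes are the significant
#' miRNAs and their consensus/validated target genes, edges run only
#' between the two sides. miRNA nodes are weighted by |log2 fold change|
#' and carry their regulation direction; gene nodes are weighted by their
#' degree in the network.
#'
#' @param cons a [consensus_targets()] result.
#' @param de a [differential_mirnas()] result covering every consensus
#'   miRNA.
#' @param comparison label for the comparison (e.g. `"LGDHS/Normal"`).
#' @return Object of class `mirna_target_network`: list with `mirnas`
#'   (data.frame `id`, `weight`, `direction`, `degree`, `hub`), `genes`
#'   (data.frame `id`, `weight`, `degree`, `hub`), `edges` (`mirna_id`,
#'   `gene_id`, `source`) and `comparison`.
#' @export
build_weighted_network <- function(cons, de, comparison = "") {
  stopifnot(inherits(cons, "consensus_target_set"),
    inherits(de, "differential_result"))
  missing <- setdiff(names(cons$per_mirna), de$mirna_id)
  if (length(missing))
    stop("consensus miRNA(s) missing from the differential table: ",
      paste(missing, collapse = ", "))
  sig <- de$mirna_id[de$significant]
  edges <- cons$edges[cons$edges$mirna_id %in% sig, , drop = FALSE]
  rownames(edges) <- NULL
  new_network(edges, de, comparison)
}

# Assemble the network object from an edge list + DE table; degrees and
# gene weights are always recomputed here so the weight-equals-degree
# invariant holds by construction.
new_network <- function(edges, de, comparison, hub_mirnas = NULL,
                        hub_genes = NULL) {
  m_ids <- sort(unique(edges$mirna_id))
  g_ids <- sort(unique(edges$gene_id))
  m_deg <- as.integer(table(factor(edges$mirna_id, levels = m_ids)))
  g_deg <- as.integer(table(factor(edges$gene_id, levels = g_ids)))
  de_idx <- match(m_ids, de$mirna_id)
  mirnas <- data.frame(
    id = m_ids,
    weight = abs(de$log2fc[de_idx]),
    direction = de$direction[de_idx],
    degree = m_deg,
    hub = if (is.null(hub_mirnas)) rep(NA, length(m_ids)) else
      m_ids %in% hub_mirnas,
    stringsAsFactors = FALSE
  )
  genes <- data.frame(
    id = g_ids,
    weight = as.numeric(g_deg),
    degree = g_deg,
    hub = if (is.null(hub_genes)) rep(NA, length(g_ids)) else
      g_ids %in% hub_genes,
    stringsAsFactors = FALSE
  )
  structure(list(mirnas = mirnas, genes = genes,
    edges = edges[, c("mirna_id", "gene_id", "source")],
    comparison = comparison, de = de),
    class = "mirna_target_network")
}

#' @export
print.mirna_target_network <- function(x, ...) {
  cat(sprintf(
    "mirna_target_network%s: %d miRNAs, %d genes, %d edges\n",
    if (nzchar(x$comparison)) paste0(" [", x$comparison, "]") else "",
    nrow(x$mirnas), nrow(x$genes), nrow(x$edges)))
  invisible(x)
}

#' Check the structural invariants of a network object
#'
#' Bipartiteness (edges only between the miRNA and gene sides), gene
#' weight equal to degree, and the degree-sum identity (miRNA degrees,
#' gene degrees and edge count all agree).
#'
#' @param net a `mirna_target_network`.
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "mirna_target_network"))
  if (length(intersect(net$mirnas$id, net$genes$id)))
    stop("node id appears on both sides; network not bipartite")
  if (!all(net$edges$mirna_id %in% net$mirnas$id) ||
      !all(net$edges$gene_id %in% net$genes$id))
    stop("edge endpoint missing from node tables")
  g_deg <- table(factor(net$edges$gene_id, levels = net$genes$id))
  if (!all(net$genes$weight == as.integer(g_deg)))
    stop("gene weight != degree")
  if (sum(net$mirnas$degree) != nrow(net$edges) ||
      sum(net$genes$degree) != nrow(net$edges))
    stop("degree-sum identity violated")
  invisible(TRUE)
}

#' Extract the hub subnetwork
#'
#' Hub nodes are those with degree at or above `min_degree` in the input
#' network. The subnetwork keeps the hub nodes, every edge incident to a
#' hub, and the endpoints of those edges (non-hub neighbours come along
#' and are flagged `hub = FALSE`); degrees and gene weights are
#' recomputed within the subnetwork. With a fixed threshold the
#' extraction is idempotent.
#'
#' @param net a `mirna_target_network`.
#' @param min_degree hub threshold (default 5, i.e. degree >= 5).
#' @return A `mirna_target_network` with the `hub` column filled in.
#' @export
extract_hubs <- function(net, min_degree = 5L) {
  stopifnot(inherits(net, "mirna_target_network"))
  hub_m <- net$mirnas$id[net$mirnas$degree >= min_degree]
  hub_g <- net$genes$id[net$genes$degree >= min_degree]
  keep <- net$edges$mirna_id %in% hub_m | net$edges$gene_id %in% hub_g
  edges <- net$edges[keep, , drop = FALSE]
  rownames(edges) <- NULL
  new_network(edges, net$de,
    comparison = net$comparison,
    hub_mirnas = hub_m, hub_genes = hub_g)
}

#' Extract the up-regulation subnetwork
#'
#' The subgraph induced by the up-regulated miRNAs and their targets
#' (targets read as down-regulated genes, since miRNAs repress), plus the
#' share of up-regulated miRNAs in the parent network.
#'
#' @param net a `mirna_target_network`.
#' @return List with `network` (the up subnetwork) and `up_fraction`
#'   (percent of miRNA nodes that are up-regulated, one decimal).
#' @export
up_subnetwork <- function(net) {
  stopifnot(inherits(net, "mirna_target_network"))
  up <- net$mirnas$id[net$mirnas$direction == "up"]
  edges <- net$edges[net$edges$mirna_id %in% up, , drop = FALSE]
  rownames(edges) <- NULL
  frac <- if (nrow(net$mirnas)) 100 * length(up) / nrow(net$mirnas) else 0
  list(
    network = new_network(edges, net$de, comparison = net$comparison),
    up_fraction = round(frac, 1L)
  )
}

network_node_weights <- function(net) {
  stats::setNames(
    c(net$mirnas$weight, net$genes$weight),
    c(paste0("miRNA:", net$mirnas$id), paste0("gene:", net$genes$id))
  )
}

#' Compare two syndrome networks by node overlap and weight ranks
#'
#' Reports the shared miRNAs (and those up-regulated in both networks),
#' and tests weight-rank similarity over all shared nodes: Spearman
#' correlation (mid-ranks for ties) with a two-sided permutation p-value
#' obtained by shuffling one network's weights. Shared nodes are returned
#' ranked by absolute rank change — the operational definition of
#' deregulated nodes.
#'
#' @param net_a,net_b `mirna_target_network` objects.
#' @param n_perm permutation count for the rank test (default 10000).
#' @param top_k deregulated nodes to report (default 20).
#' @param seed seed for the permutation draw.
#' @return Object of class `network_comparison`: `shared_mirnas`,
#'   `shared_up_mirnas`, `n_shared_nodes`, `rank_correlation`,
#'   `permutation_p`, `rank_test_computable` and `deregulated` (data.frame
#'   node, rank_a, rank_b, rank_change).
#' @export
compare_networks <- function(net_a, net_b, n_perm = 10000L, top_k = 20L,
                             seed = 1L) {
  stopifnot(inherits(net_a, "mirna_target_network"),
    inherits(net_b, "mirna_target_network"))
  shared_m <- intersect(net_a$mirnas$id, net_b$mirnas$id)
  up_a <- net_a$mirnas$id[net_a$mirnas$direction == "up"]
  up_b <- net_b$mirnas$id[net_b$mirnas$direction == "up"]
  shared_up <- intersect(intersect(up_a, up_b), shared_m)

  wa <- network_node_weights(net_a)
  wb <- network_node_weights(net_b)
  shared_nodes <- intersect(names(wa), names(wb))
  out <- list(
    comparison = paste(net_a$comparison, "vs", net_b$comparison),
    shared_mirnas = sort(shared_m),
    shared_up_mirnas = sort(shared_up),
    n_shared_nodes = length(shared_nodes),
    rank_test_computable = length(shared_nodes) >= 3L,
    rank_correlation = NA_real_,
    permutation_p = NA_real_,
    deregulated = data.frame(node = character(), rank_a = numeric(),
      rank_b = numeric(), rank_change = numeric())
  )
  if (!out$rank_test_computable) {
    class(out) <- "network_comparison"
    return(out)
  }
  va <- wa[shared_nodes]
  vb <- wb[shared_nodes]
  ra <- rank(va)
  rb <- rank(vb)
  obs <- stats::cor(ra, rb)
  set.seed(seed)
  perm <- replicate(n_perm, stats::cor(ra, sample(rb)))
  out$rank_correlation <- obs
  out$permutation_p <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) /
    (n_perm + 1)
  dr <- data.frame(node = shared_nodes, rank_a = ra, rank_b = rb,
    rank_change = abs(ra - rb), stringsAsFactors = FALSE)
  dr <- dr[order(-dr$rank_change, dr$node), ]
  rownames(dr) <- NULL
  out$deregulated <- utils::head(dr, top_k)
  class(out) <- "network_comparison"
  out
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(sprintf("network_comparison %s\n", x$comparison))
  cat(sprintf("  shared miRNAs: %d (up in both: %d)\n",
    length(x$shared_mirnas), length(x$shared_up_mirnas)))
  if (x$rank_test_computable)
    cat(sprintf("  weight-rank Spearman r = %.3f (permutation p = %.2g)\n",
      x$rank_correlation, x$permutation_p))
  else
    cat("  rank test not computable (< 3 shared nodes)\n")
  invisible(x)
}

#' Convert a network to an igraph object
#'
#' @param net a `mirna_target_network`.
#' @return An undirected bipartite `igraph` graph with `type`, `weight`,
#'   `direction` and `hub` vertex attributes and `source` edge attribute.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "mirna_target_network"))
  verts <- data.frame(
    name = c(net$mirnas$id, net$genes$id),
    type = rep(c("miRNA", "gene"), c(nrow(net$mirnas), nrow(net$genes))),
    weight = c(net$mirnas$weight, net$genes$weight),
    direction = c(net$mirnas$direction, rep(NA_character_,
      nrow(net$genes))),
    stringsAsFactors = FALSE
  )
  igraph::graph_from_data_frame(
    net$edges[, c("mirna_id", "gene_id", "source")],
    directed = FALSE, vertices = verts)
}

#' Export a network in GraphML format
#'
#' @param net a `mirna_target_network`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' Write a network edge list to TSV
#'
#' Columns: `mirna_id`, `gene_id`, `source`, `mirna_weight`,
#' `gene_weight`, `direction`.
#'
#' @param net a `mirna_target_network`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_network_edges <- function(net, path) {
  e <- net$edges
  mi <- match(e$mirna_id, net$mirnas$id)
  gi <- match(e$gene_id, net$genes$id)
  out <- data.frame(e,
    mirna_weight = net$mirnas$weight[mi],
    gene_weight = net$genes$weight[gi],
    direction = net$mirnas$direction[mi])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(path)
}
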