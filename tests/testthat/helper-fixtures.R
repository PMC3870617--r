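# Shared fixtures and independent oracles used across the suite.

# An rvm_fit with chosen hyperparameters (bypasses estimation).
make_rvm_fit <- function(a, b, f) {
  structure(list(a = a, b = b, f = f, loglik = 0, converged = TRUE,
    n = NA_integer_), class = "rvm_fit")
}

# Draw per-feature sample variances from the RVM model:
# sigma^2 inverse-gamma with precision ~ Gamma(shape = a, scale = b),
# then s^2 | sigma^2 ~ sigma^2 * chisq(f) / f.
simulate_model_variances <- function(n, a, b, f) {
  sigma2 <- 1 / stats::rgamma(n, shape = a, scale = b)
  sigma2 * stats::rchisq(n, df = f) / f
}

# RVM marginal log-likelihood of variances (the quantity the fitter
# maximizes), written independently for grid-search cross-checks.
rvm_loglik <- function(a, b, variances, f) {
  x <- variances * a * b
  sum(log(a * b) + stats::df(x, df1 = f, df2 = 2 * a, log = TRUE))
}

# Naive O(n^3) UPGMA agglomeration: returns merge heights in order.
naive_upgma_heights <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in seq((i + 1L), length(clusters))) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_h)
    merged <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters <- c(clusters[-best], list(merged))
  }
  heights
}

# Random 9-program prediction ensemble over a small gene pool.
random_ensemble <- function(n_genes = 20L, mirna = "miR-X",
                            hit_prob = 0.15) {
  genes <- sprintf("g%02d", seq_len(n_genes))
  binary <- stats::setNames(lapply(1:9, function(p) {
    hit <- genes[stats::runif(n_genes) < hit_prob]
    data.frame(mirna_id = rep(mirna, length(hit)), gene_id = hit,
      stringsAsFactors = FALSE)
  }), paste0("P", 1:9))
  scored <- data.frame(mirna_id = mirna, gene_id = genes,
    score = stats::runif(n_genes, 0, 100), stringsAsFactors = FALSE)
  prediction_ensemble(binary, scored)
}

# Vote-counting oracle for Data A: genes hit by >= 2 binary programs.
vote_count_oracle <- function(ensemble, mirna) {
  hits <- unlist(lapply(ensemble$binary, function(d)
    unique(d$gene_id[d$mirna_id == mirna])))
  sort(names(which(table(hits) >= 2L)))
}

# Tiny differential_result for constructing networks directly.
fake_de <- function(mirnas, log2fc, direction = NULL, significant = TRUE) {
  direction <- direction %||% ifelse(log2fc >= 0, "up", "down")
  structure(data.frame(
    mirna_id = mirnas, mean_case = log2fc, mean_control = 0,
    log2fc = log2fc, t = 0, df = 10, p = 0.001,
    significant = rep_len(significant, length(mirnas)),
    direction = direction, stringsAsFactors = FALSE),
    class = c("differential_result", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Consensus set built directly from an edge list (mirna -> genes).
fake_consensus <- function(edges) {
  per <- lapply(split(edges$gene_id, edges$mirna_id), function(g)
    list(data_a = sort(g), data_b = sort(g), consensus = sort(g),
      validated_added = character()))
  structure(list(per_mirna = per,
    edges = data.frame(edges, source = rep("consensus", nrow(edges)),
      stringsAsFactors = FALSE),
    threshold = 60), class = "consensus_target_set")
}

# Random bipartite network with controllable weights via fake DE.
random_network <- function(n_mirnas = 8L, n_genes = 15L,
                           mean_deg = 3, prefix = "") {
  mirnas <- sprintf("miR-%s%02d", prefix, seq_len(n_mirnas))
  genes <- sprintf("G%s%02d", prefix, seq_len(n_genes))
  edges <- unique(do.call(rbind, lapply(mirnas, function(m) {
    k <- max(1L, stats::rpois(1L, mean_deg))
    data.frame(mirna_id = m,
      gene_id = sample(genes, min(k, n_genes)),
      stringsAsFactors = FALSE)
  })))
  de <- fake_de(mirnas, log2fc = round(stats::runif(n_mirnas, -3, 3), 2))
  build_weighted_network(fake_consensus(edges), de, comparison = "test")
}

# A small, fast simulation configuration for integration-style tests.
tiny_sim <- function(seed = 1L, ...) {
  simulation_config(n_mirnas = 120L, n_genes = 400L,
    n_de_per_group = 15L, n_gene_sets = 20L, planted_enriched_sets = 2L,
    gene_set_size_range = c(10L, 40L), seed = seed, ...)
}
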