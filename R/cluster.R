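#' One-minus-Pearson-correlation distance matrix
#'
#' The clustering metric used throughout: d(i, j) = 1 - r(i, j) with
#' centered Pearson correlation, giving distances in \[0, 2\].
#'
#' @param m numeric matrix (or [expression_set()]).
#' @param axis cluster `"rows"` (miRNAs, default) or `"cols"` (samples).
#' @return Symmetric distance matrix with zero diagonal and the ids as
#'   dimnames.
#' @export
correlation_distance <- function(m, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  if (inherits(m, "expression_set")) m <- m$values
  v <- if (axis == "rows") t(m) else m
  if (ncol(v) < 2L) stop("need at least 2 vectors to compute distances")
  sds <- apply(v, 2L, stats::sd)
  bad <- which(sds < .Machine$double.eps^0.5)
  if (length(bad))
    stop("constant vector(s), correlation undefined: ",
      paste(colnames(v)[bad], collapse = ", "))
  d <- 1 - stats::cor(v)
  # exact zero diagonal and symmetry despite floating-point round-off
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerates with inter-cluster distance equal to the mean pairwise
#' distance. Rows/columns are sorted lexicographically by id before
#' clustering so tie-breaking — and with it the leaf order — is
#' deterministic regardless of input order.
#'
#' @param d symmetric distance matrix with ids as dimnames (e.g. from
#'   [correlation_distance()]).
#' @return An object of class `hclust` with `merge`, `height`, `order`
#'   and `labels`.
#' @export
average_linkage <- function(d) {
  if (!is.matrix(d)) d <- as.matrix(d)
  if (is.null(rownames(d))) dimnames(d) <- list(
    paste0("item", seq_len(nrow(d))), paste0("item", seq_len(nrow(d))))
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8))
    stop("`d` must be a symmetric distance matrix")
  ord <- order(rownames(d))
  d <- d[ord, ord]
  stats::hclust(stats::as.dist(d), method = "average")
}

#' Export a dendrogram as a Newick tree string
#'
#' @param hc an `hclust` object, e.g. from [average_linkage()].
#' @param path optional file path; when given the tree is written there.
#' @return The Newick string, invisibly when `path` is given.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Cluster samples of an expression set and reorder the matrix
#'
#' Clusters both samples and miRNAs with the one-minus-correlation /
#' average-linkage combination and returns the matrix in dendrogram leaf
#' order — the deterministic heatmap layout.
#'
#' @param es an [expression_set()] (typically restricted to significant
#'   miRNAs and z-scored).
#' @return List with `sample_hclust`, `mirna_hclust` and `matrix` (values
#'   reordered to leaf order on both axes).
#' @export
cluster_heatmap <- function(es) {
  stopifnot(inherits(es, "expression_set"))
  hs <- average_linkage(correlation_distance(es, axis = "cols"))
  hm <- average_linkage(correlation_distance(es, axis = "rows"))
  m <- es$values[hm$labels[hm$order], hs$labels[hs$order], drop = FALSE]
  list(sample_hclust = hs, mirna_hclust = hm, matrix = m)
}
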