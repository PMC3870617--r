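#' Gene-set collection
#'
#' @param sets named list of character vectors (gene ids per set).
#' @param categories character vector, one per set, e.g. `"GO"`,
#'   `"KEGG"`, `"BIOCARTA"`; anything else becomes `"other"`.
#' @param universe gene universe; set members outside it are dropped.
#'   Defaults to the union of all set members.
#' @return Object of class `gene_set_collection`: list with `sets`,
#'   `info` (data.frame `set_id`, `category`, `size`) and `universe`.
#' @export
gene_set_collection <- function(sets, categories = NULL,
                                universe = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("`sets` must be a uniquely named list")
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  categories <- categories %||% rep("other", length(sets))
  categories <- ifelse(categories %in% c("GO", "KEGG", "BIOCARTA"),
    categories, "other")
  sets <- lapply(sets, function(g) sort(unique(intersect(g, universe))))
  empty <- names(sets)[lengths(sets) == 0L]
  if (length(empty))
    stop("empty gene set(s) after restriction to the universe: ",
      paste(empty, collapse = ", "))
  structure(list(
    sets = sets,
    info = data.frame(set_id = names(sets), category = categories,
      size = lengths(sets), row.names = NULL, stringsAsFactors = FALSE),
    universe = sort(unique(universe))
  ), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf(
    "gene_set_collection: %d sets (%s) over %d genes\n",
    length(x$sets),
    paste(sprintf("%s: %d", names(table(x$info$category)),
      table(x$info$category)), collapse = ", "),
    length(x$universe)))
  invisible(x)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-delimited — set id, description,
#' then member genes. The description field is used as the category tag
#' when it is one of GO/KEGG/BIOCARTA.
#'
#' @param path GMT file path.
#' @param universe optional gene universe (default: union of members).
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("malformed GMT line(s) (need id, description, >=1 gene): ",
      paste(bad, collapse = ", "))
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1L), 1L)
  categories <- vapply(parts, `[[`, character(1L), 2L)
  gene_set_collection(sets, categories, universe)
}

#' Write a gene-set collection to a GMT file
#'
#' @param collection a [gene_set_collection()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(seq_along(collection$sets), function(i) {
    paste(c(collection$info$set_id[i], collection$info$category[i],
      collection$sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone in the sorted order and capped at
#' 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric gene-set over-representation analysis
#'
#' For every set, the exact upper-tail hypergeometric probability of
#' observing at least the seen overlap between the query list and the set
#' within the collection's universe — the same over-representation test
#' DAVID-style services perform, computed locally. Retention follows the
#' conjunction rule: overlap of at least `min_overlap` genes, raw
#' p < `alpha` and BH-adjusted p < `fdr_alpha`. By default the
#' minimum-overlap filter is applied before the FDR adjustment, so only
#' sets that survive it enter the BH ranking.
#'
#' @param genes character vector: the query gene list; ids outside the
#'   universe are dropped with a warning.
#' @param collection a [gene_set_collection()].
#' @param min_overlap minimum overlap k to keep a set (default 5).
#' @param alpha raw-p threshold (default 0.05).
#' @param fdr_alpha FDR threshold (default 0.05).
#' @param filter_order `"overlap_first"` (default) applies the
#'   minimum-overlap filter before BH; `"fdr_first"` adjusts all sets
#'   then filters.
#' @return Data.frame of class `enrichment_result`, one row per set:
#'   `set_id`, `category`, `k` (overlap), `K` (set size), `n` (query
#'   size), `N` (universe size), `p`, `fdr_p` (NA for sets excluded from
#'   the BH ranking), `retained`.
#' @export
hypergeom_enrich <- function(genes, collection, min_overlap = 5L,
                             alpha = 0.05, fdr_alpha = 0.05,
                             filter_order = c("overlap_first",
                               "fdr_first")) {
  stopifnot(inherits(collection, "gene_set_collection"))
  filter_order <- match.arg(filter_order)
  genes <- unique(genes)
  outside <- setdiff(genes, collection$universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    genes <- intersect(genes, collection$universe)
  }
  res <- data.frame(
    set_id = collection$info$set_id,
    category = collection$info$category,
    k = vapply(collection$sets, function(s)
      length(intersect(s, genes)), integer(1L)),
    K = collection$info$size,
    n = length(genes),
    N = length(collection$universe),
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (!length(genes)) {
    res <- res[0L, ]
    res$p <- numeric()
    res$fdr_p <- numeric()
    res$retained <- logical()
    class(res) <- c("enrichment_result", "data.frame")
    return(res)
  }
  # exact upper tail P[X >= k], X ~ Hypergeom(N, K, n)
  res$p <- stats::phyper(res$k - 1L, res$K, res$N - res$K, res$n,
    lower.tail = FALSE)
  res$fdr_p <- NA_real_
  if (filter_order == "overlap_first") {
    in_rank <- res$k >= min_overlap
    if (any(in_rank)) res$fdr_p[in_rank] <- bh_fdr(res$p[in_rank])
  } else {
    res$fdr_p <- bh_fdr(res$p)
  }
  res$retained <- res$k >= min_overlap & res$p < alpha &
    !is.na(res$fdr_p) & res$fdr_p < fdr_alpha
  attr(res, "collection_id") <- paste(collection$info$set_id,
    collapse = "|")
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Count retained gene sets shared between two comparisons
#'
#' @param res_a,res_b [hypergeom_enrich()] results computed on the same
#'   collection.
#' @return Data.frame with one row per category (`GO`, `KEGG`,
#'   `BIOCARTA`, `other` as present) plus a `total` row: columns
#'   `category`, `retained_a`, `retained_b`, `overlap`.
#' @export
term_overlap <- function(res_a, res_b) {
  stopifnot(inherits(res_a, "enrichment_result"),
    inherits(res_b, "enrichment_result"))
  if (!identical(attr(res_a, "collection_id"),
    attr(res_b, "collection_id")))
    stop("results come from different gene-set collections")
  cats <- unique(res_a$category)
  rows <- lapply(cats, function(ct) {
    a <- res_a$set_id[res_a$retained & res_a$category == ct]
    b <- res_b$set_id[res_b$retained & res_b$category == ct]
    data.frame(category = ct, retained_a = length(a),
      retained_b = length(b), overlap = length(intersect(a, b)))
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(category = "total",
    retained_a = sum(out$retained_a), retained_b = sum(out$retained_b),
    overlap = sum(out$overlap)))
  out
}

#' Write an enrichment result to TSV
#'
#' @param res an [hypergeom_enrich()] result.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_enrichment <- function(res, path) {
  utils::write.table(as.data.frame(res), path, sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(path)
}
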