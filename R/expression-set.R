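#' Expression set: log2 matrix with sample-to-group labels
#'
#' Lightweight container for a log2-scale miRNA expression matrix
#' (miRNAs in rows, samples in columns) together with the group label of
#' every sample. All pipeline stages accept and return this class.
#'
#' @param values numeric matrix, log2 units, with miRNA ids as rownames and
#'   sample ids as colnames; ids must be unique and values finite.
#' @param groups named character vector mapping every sample id (names) to a
#'   group label.
#' @return An object of class `expression_set`: a list with elements
#'   `values` and `groups` (reordered to match the matrix columns).
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'   dimnames = list(paste0("miR-", 1:3), paste0("s", 1:4)))
#' es <- expression_set(m, setNames(c("Normal", "Normal", "A", "A"),
#'   colnames(m)))
#' @export
expression_set <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have miRNA rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate miRNA ids in `values`")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in `values`")
  if (!all(is.finite(values)))
    stop("`values` must be finite")
  groups <- unlist(groups)
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing))
    stop("samples without a group label: ", paste(missing, collapse = ", "))
  structure(
    list(values = values, groups = as.character(groups[colnames(values)])),
    names = c("values", "groups"),
    class = "expression_set"
  )
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf(
    "expression_set: %d miRNAs x %d samples (%s)\n",
    nrow(x$values), ncol(x$values),
    paste(sprintf("%s: %d", names(table(x$groups)), table(x$groups)),
      collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.expression_set <- function(x) dim(x$values)

#' Subset an expression set to the samples of given groups
#'
#' @param es an [expression_set()].
#' @param groups character vector of group labels to keep.
#' @return An `expression_set` restricted to the matching samples.
#' @export
subset_groups <- function(es, groups) {
  stopifnot(inherits(es, "expression_set"))
  unknown <- setdiff(groups, es$groups)
  if (length(unknown))
    stop("unknown group label(s): ", paste(unknown, collapse = ", "))
  keep <- es$groups %in% groups
  expression_set(es$values[, keep, drop = FALSE],
    stats::setNames(es$groups[keep], colnames(es$values)[keep]))
}

group_samples <- function(es, group) {
  which(es$groups == group)
}

#' Read an expression matrix and its sample-group map from TSV files
#'
#' The matrix file is tab-delimited with a header row of sample ids and
#' miRNA ids in the first column; the groups file has two columns,
#' `sample_id` and `group`.
#'
#' @param matrix_path path to the expression TSV.
#' @param groups_path path to the two-column sample-to-group TSV.
#' @return An [expression_set()].
#' @export
read_expression <- function(matrix_path, groups_path) {
  tab <- utils::read.delim(matrix_path, check.names = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- as.character(tab[[1L]])
  g <- utils::read.delim(groups_path, check.names = FALSE)
  expression_set(m, stats::setNames(as.character(g[[2L]]),
    as.character(g[[1L]])))
}

#' Write an expression set to matrix and group TSV files
#'
#' @param es an [expression_set()].
#' @inheritParams read_expression
#' @return Invisibly, the two paths written.
#' @export
write_expression <- function(es, matrix_path, groups_path) {
  stopifnot(inherits(es, "expression_set"))
  tab <- data.frame(mirna_id = rownames(es$values), es$values,
    check.names = FALSE)
  utils::write.table(tab, matrix_path, sep = "\t", quote = FALSE,
    row.names = FALSE)
  g <- data.frame(sample_id = colnames(es$values), group = es$groups)
  utils::write.table(g, groups_path, sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(c(matrix_path, groups_path))
}
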