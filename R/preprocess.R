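#' Transform a raw intensity matrix to log2 scale
#'
#' @param raw non-negative numeric matrix of raw intensities.
#' @param pseudocount non-negative offset added before taking logs; the
#'   default 0 assumes strictly positive intensities.
#' @param groups optional named sample-to-group vector; when supplied the
#'   result is an [expression_set()], otherwise a plain matrix.
#' @return log2-transformed matrix (or `expression_set`).
#' @examples
#' log2_transform(matrix(c(1, 8), 1, 2,
#'   dimnames = list("m1", c("s1", "s2"))))
#' @export
log2_transform <- function(raw, pseudocount = 0, groups = NULL) {
  if (!is.numeric(raw)) stop("`raw` must be numeric")
  if (any(raw < 0, na.rm = TRUE)) stop("`raw` must be non-negative")
  if (pseudocount < 0) stop("`pseudocount` must be non-negative")
  out <- log2(raw + pseudocount)
  if (is.null(groups)) out else expression_set(out, groups)
}

#' Standardize each sample to zero mean and unit variance
#'
#' Column-wise z-scoring with the sample (n - 1) variance denominator, the
#' scale on which clustering and class prediction operate.
#'
#' @param es an [expression_set()] (or bare matrix).
#' @return Object of the same class with every sample column at mean 0,
#'   variance 1.
#' @export
standardize_samples <- function(es) {
  m <- if (inherits(es, "expression_set")) es$values else es
  sds <- apply(m, 2L, stats::sd)
  bad <- which(sds < .Machine$double.eps^0.5)
  if (length(bad))
    stop("constant sample column(s), cannot standardize: ",
      paste(colnames(m)[bad], collapse = ", "))
  out <- scale(m, center = TRUE, scale = sds)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  if (inherits(es, "expression_set")) {
    expression_set(out, stats::setNames(es$groups, colnames(es$values)))
  } else {
    out
  }
}

#' Median-center each sample column
#'
#' Subtracts the per-sample median so every patient has a median log ratio
#' of 0; the scale used for differential testing.
#'
#' @inheritParams standardize_samples
#' @return Object of the same class with every column median exactly 0.
#' @export
median_center_samples <- function(es) {
  m <- if (inherits(es, "expression_set")) es$values else es
  med <- apply(m, 2L, stats::median)
  out <- sweep(m, 2L, med, "-")
  if (inherits(es, "expression_set")) {
    expression_set(out, stats::setNames(es$groups, colnames(es$values)))
  } else {
    out
  }
}
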