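#' Container for multi-program target predictions
#'
#' Holds the hit tables of the binary prediction programs (DIANAmT,
#' miRanda, miRWalk, RNAhybrid, PicTar4/5, PITA, RNA22, TargetScan style),
#' one score-valued program table (miRDB style, scores in \[0, 100\]) and
#' an optional table of experimentally validated interactions (TarBase
#' style).
#'
#' @param binary named list of data.frames, one per program, with columns
#'   `mirna_id` and `gene_id`; nine programs expected unless
#'   `allow_other_counts = TRUE`.
#' @param scored data.frame with columns `mirna_id`, `gene_id`, `score`.
#' @param validated optional data.frame with columns `mirna_id`,
#'   `gene_id` (extra columns kept).
#' @param allow_other_counts permit a number of binary programs other
#'   than nine.
#' @return Object of class `prediction_ensemble`.
#' @export
prediction_ensemble <- function(binary, scored, validated = NULL,
                                allow_other_counts = FALSE) {
  if (is.null(names(binary)) || anyDuplicated(names(binary)))
    stop("`binary` must be a uniquely named list of program tables")
  if (length(binary) != 9L && !allow_other_counts)
    stop("expected 9 binary programs, got ", length(binary),
      " (set allow_other_counts = TRUE to override)")
  for (p in names(binary))
    if (!all(c("mirna_id", "gene_id") %in% names(binary[[p]])))
      stop("program table '", p, "' lacks mirna_id/gene_id columns")
  if (!all(c("mirna_id", "gene_id", "score") %in% names(scored)))
    stop("`scored` needs mirna_id, gene_id and score columns")
  if (any(!is.finite(scored$score)))
    stop("scores must be finite")
  if (any(scored$score < 0 | scored$score > 100))
    warning("score(s) outside [0, 100] kept as-is")
  if (!is.null(validated) &&
      !all(c("mirna_id", "gene_id") %in% names(validated)))
    stop("`validated` needs mirna_id and gene_id columns")
  structure(list(binary = binary, scored = scored,
    validated = validated %||%
      data.frame(mirna_id = character(), gene_id = character())),
    class = "prediction_ensemble")
}

#' @export
print.prediction_ensemble <- function(x, ...) {
  cat(sprintf(
    "prediction_ensemble: %d binary programs, %d scored pairs, %d validated pairs\n",
    length(x$binary), nrow(x$scored), nrow(x$validated)))
  invisible(x)
}

#' Read prediction tables from a long-format TSV
#'
#' Expects columns `program`, `mirna_id`, `gene_id` and optionally
#' `score`; rows of the one program with scores form the scored table.
#'
#' @param predictions_path path to the predictions TSV.
#' @param scored_program name of the score-valued program in the
#'   `program` column.
#' @param validated_path optional path to a validated-interaction TSV
#'   (`mirna_id`, `gene_id`, extra columns kept).
#' @return A [prediction_ensemble()].
#' @export
read_prediction_ensemble <- function(predictions_path, scored_program,
                                     validated_path = NULL) {
  tab <- utils::read.delim(predictions_path, stringsAsFactors = FALSE)
  scored <- tab[tab$program == scored_program,
    c("mirna_id", "gene_id", "score")]
  rest <- tab[tab$program != scored_program, ]
  binary <- lapply(split(rest, rest$program), function(d)
    d[, c("mirna_id", "gene_id")])
  validated <- if (!is.null(validated_path))
    utils::read.delim(validated_path, stringsAsFactors = FALSE)
  prediction_ensemble(binary, scored, validated,
    allow_other_counts = TRUE)
}

#' Write a prediction ensemble to TSV files
#'
#' @param ensemble a [prediction_ensemble()].
#' @param predictions_path,validated_path output paths; the scored
#'   program is written with program name `"miRDB"`.
#' @return Invisibly, the paths written.
#' @export
write_prediction_ensemble <- function(ensemble, predictions_path,
                                      validated_path = NULL) {
  long <- do.call(rbind, lapply(names(ensemble$binary), function(p)
    data.frame(program = p, ensemble$binary[[p]], score = NA_real_)))
  long <- rbind(long, data.frame(program = "miRDB",
    ensemble$scored[, c("mirna_id", "gene_id")],
    score = ensemble$scored$score))
  utils::write.table(long, predictions_path, sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (!is.null(validated_path))
    utils::write.table(ensemble$validated, validated_path, sep = "\t",
      quote = FALSE, row.names = FALSE)
  invisible(c(predictions_path, validated_path))
}

program_hits <- function(ensemble, mirna) {
  lapply(ensemble$binary, function(d)
    unique(d$gene_id[d$mirna_id == mirna]))
}

#' Data A: pairwise-intersection union over the binary programs
#'
#' For one miRNA, intersects the hit sets of every unordered pair of
#' binary programs and unites all those intersections — which equals the
#' set of genes predicted by at least two programs. The pairwise
#' construction is implemented literally; the vote-count equivalence is
#' enforced by tests.
#'
#' @param ensemble a [prediction_ensemble()].
#' @param mirna one miRNA id.
#' @return Sorted character vector of gene ids.
#' @export
data_a <- function(ensemble, mirna) {
  hits <- program_hits(ensemble, mirna)
  np <- length(hits)
  out <- character()
  for (i in seq_len(np - 1L))
    for (j in seq((i + 1L), np))
      out <- union(out, intersect(hits[[i]], hits[[j]]))
  sort(out)
}

#' Data B: score-valued predictions above threshold
#'
#' @param ensemble a [prediction_ensemble()].
#' @param mirna one miRNA id.
#' @param threshold score cut-off; strictly greater-than (default 60).
#' @return Sorted character vector of gene ids with score > `threshold`.
#' @export
data_b <- function(ensemble, mirna, threshold = 60) {
  sc <- ensemble$scored[ensemble$scored$mirna_id == mirna, ]
  sort(unique(sc$gene_id[sc$score > threshold]))
}

#' Consensus target selection: Data A intersected with Data B
#'
#' Applies the two-way screen per miRNA — genes predicted by at least two
#' binary programs (Data A) AND scoring above the threshold in the
#' score-valued program (Data B) — then unions in the validated
#' interactions, flagged by source. Validated pairs bypass the consensus
#' filter by design: experimental evidence outranks prediction agreement.
#'
#' @param ensemble a [prediction_ensemble()].
#' @param mirnas miRNA ids to process (default: all ids seen in any
#'   table).
#' @param threshold Data B score cut-off (default 60, strict).
#' @param program_p_filter reserved hook for per-program significance
#'   filtering of predictions; standard program exports carry no p-values,
#'   so any non-NULL value only raises a warning and is otherwise ignored.
#' @return Object of class `consensus_target_set`: list with `per_mirna`
#'   (per miRNA: `data_a`, `data_b`, `consensus`, `validated_added`) and
#'   `edges` (data.frame `mirna_id`, `gene_id`,
#'   `source` in consensus/validated/both).
#' @export
consensus_targets <- function(ensemble, mirnas = NULL, threshold = 60,
                              program_p_filter = NULL) {
  stopifnot(inherits(ensemble, "prediction_ensemble"))
  if (!is.null(program_p_filter))
    warning("per-program significance filtering is not defined for ",
      "standard prediction exports; `program_p_filter` ignored")
  if (is.null(mirnas))
    mirnas <- sort(unique(c(
      unlist(lapply(ensemble$binary, `[[`, "mirna_id")),
      ensemble$scored$mirna_id, ensemble$validated$mirna_id)))

  per <- list()
  edge_rows <- list()
  for (m in mirnas) {
    a <- data_a(ensemble, m)
    b <- data_b(ensemble, m, threshold)
    cons <- intersect(a, b)
    val <- sort(unique(
      ensemble$validated$gene_id[ensemble$validated$mirna_id == m]))
    if (!length(a) && !length(b) && !length(val) &&
        !m %in% ensemble$scored$mirna_id &&
        !any(vapply(ensemble$binary, function(d) m %in% d$mirna_id,
          logical(1L))))
      warning("miRNA absent from all prediction tables: ", m)
    genes <- union(cons, val)
    if (length(genes)) {
      src <- ifelse(genes %in% cons & genes %in% val, "both",
        ifelse(genes %in% cons, "consensus", "validated"))
      edge_rows[[m]] <- data.frame(mirna_id = m, gene_id = genes,
        source = src, stringsAsFactors = FALSE)
    }
    per[[m]] <- list(data_a = a, data_b = b, consensus = cons,
      validated_added = setdiff(val, cons))
  }
  edges <- if (length(edge_rows)) do.call(rbind, c(edge_rows,
    make.row.names = FALSE)) else
    data.frame(mirna_id = character(), gene_id = character(),
      source = character())
  structure(list(per_mirna = per, edges = edges, threshold = threshold),
    class = "consensus_target_set")
}

#' @export
print.consensus_target_set <- function(x, ...) {
  cat(sprintf(
    "consensus_target_set: %d miRNAs, %d edges (%d consensus, %d validated-only)\n",
    length(x$per_mirna), nrow(x$edges),
    sum(x$edges$source != "validated"),
    sum(x$edges$source == "validated")))
  invisible(x)
}

#' Write consensus target edges to TSV
#'
#' @param cons a [consensus_targets()] result.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_consensus <- function(cons, path) {
  utils::write.table(cons$edges, path, sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(path)
}
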