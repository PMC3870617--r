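#' Univariate parametric feature selection
#'
#' Selects the features whose ordinary equal-variance two-sample t-test
#' between the two label groups has p < `alpha` — the filter applied at
#' every node of the classification tree (and re-applied inside every
#' training fold, so no information leaks from test samples).
#'
#' @param m numeric matrix, features x samples.
#' @param labels vector with exactly two distinct values, one per sample.
#' @param alpha significance level (default 0.01).
#' @return Character vector of selected feature ids.
#' @export
select_features <- function(m, labels, alpha = 0.01) {
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  if (length(lv) != 2L)
    stop("`labels` must have exactly 2 distinct values")
  tt <- row_t_test(m, which(labels == lv[1L]), which(labels == lv[2L]))
  sel <- rownames(m)[tt$p < alpha]
  if (!length(sel))
    stop("no features pass alpha = ", alpha,
      "; consider relaxing the significance level")
  sel
}

# Fold-internal variant: falls back to the top-ranked features instead of
# failing, so null-data cross-validation stays runnable.
select_features_or_top <- function(m, labels, alpha, top = 10L) {
  lv <- sort(unique(labels))
  tt <- row_t_test(m, which(labels == lv[1L]), which(labels == lv[2L]))
  sel <- which(tt$p < alpha)
  if (!length(sel)) sel <- order(tt$p)[seq_len(min(top, nrow(m)))]
  rownames(m)[sel]
}

# Stratified fold assignment: shuffles within each class and deals fold
# numbers cyclically, so every fold's training set keeps both classes
# whenever a class has >= 2 samples.
stratified_folds <- function(labels, n_folds) {
  folds <- integer(length(labels))
  for (lv in unique(labels)) {
    idx <- sample(which(labels == lv))
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

svm_fit_predict <- function(m, train, test, labels, alpha, cost) {
  feats <- select_features_or_top(m[, train, drop = FALSE], labels[train],
    alpha)
  fit <- e1071::svm(
    x = t(m[feats, train, drop = FALSE]),
    y = factor(labels[train]),
    kernel = "linear", cost = cost, scale = FALSE
  )
  as.character(stats::predict(fit, t(m[feats, test, drop = FALSE])))
}

# Repeated stratified k-fold CV percent-correct for a binary labelling.
cv_percent_correct <- function(m, labels, alpha, n_folds, n_repeats, cost) {
  n <- length(labels)
  n_folds_eff <- min(n_folds, n)
  correct <- 0L
  total <- 0L
  for (r in seq_len(n_repeats)) {
    folds <- stratified_folds(labels, n_folds_eff)
    for (fd in sort(unique(folds))) {
      test <- folds == fd
      if (length(unique(labels[!test])) < 2L) next
      pred <- svm_fit_predict(m, !test, test, labels, alpha, cost)
      correct <- correct + sum(pred == labels[test])
      total <- total + sum(test)
    }
  }
  100 * correct / total
}

# .632 bootstrap percent-correct: 0.368 * apparent + 0.632 * out-of-bag.
boot632_percent_correct <- function(m, labels, alpha, cost, n_boot) {
  n <- length(labels)
  pred_app <- svm_fit_predict(m, seq_len(n), seq_len(n), labels, alpha,
    cost)
  apparent <- mean(pred_app == labels)
  oob_correct <- 0L
  oob_total <- 0L
  for (b in seq_len(n_boot)) {
    boot <- unlist(lapply(unique(labels), function(lv) {
      idx <- which(labels == lv)
      sample(idx, length(idx), replace = TRUE)
    }))
    oob <- setdiff(seq_len(n), boot)
    if (!length(oob) || length(unique(labels[boot])) < 2L) next
    pred <- svm_fit_predict(m, boot, oob, labels, alpha, cost)
    oob_correct <- oob_correct + sum(pred == labels[oob])
    oob_total <- oob_total + length(oob)
  }
  oob_acc <- if (oob_total > 0L) oob_correct / oob_total else NA_real_
  100 * (0.368 * apparent + 0.632 * oob_acc)
}

# All unordered bipartitions of a class set (each side non-empty),
# enumerated deterministically: subsets containing the first class.
class_bipartitions <- function(classes) {
  k <- length(classes)
  out <- list()
  for (mask in seq_len(2^(k - 1L)) - 1L) {
    left <- classes[c(TRUE, as.logical(bitwAnd(mask, 2^(seq_len(k - 1L) -
      1L))))]
    right <- setdiff(classes, left)
    if (length(right)) out[[length(out) + 1L]] <- list(left = left,
      right = right)
  }
  out
}

#' SVM binary-tree class prediction with cross-validated node scores
#'
#' Recursively splits the set of class labels: at each node every
#' bipartition of the node's classes is scored by repeated stratified
#' k-fold cross-validation of a linear support vector machine (feature
#' selection by univariate t-test at `alpha`, re-run inside each training
#' fold), and the bipartition with the highest mean percent-correct is
#' kept. The node score is that CV percent-correct; a .632 bootstrap
#' percent-correct is reported alongside, as the CV estimate is noisy when
#' classes are smaller than about twice the fold count. Fold counts degrade
#' gracefully to leave-one-out when a node has fewer samples than folds.
#'
#' @param es an [expression_set()], typically z-scored; all of its groups
#'   become classes.
#' @param alpha feature-selection significance level (default 0.01).
#' @param n_folds,n_repeats cross-validation folds and repeats (default
#'   10-fold, 10 times).
#' @param cost linear-SVM cost parameter (default 1).
#' @param n_boot bootstrap resamples for the .632 estimate (default 30).
#' @param seed integer seed governing fold assignment and bootstrap draws.
#' @return Object of class `classification_tree`: list with `classes` and
#'   `nodes`, each node holding `id`, `classes`, `left`, `right`, `score`
#'   (integer percent), `cv_score`, `boot632_score`, `n_features` and
#'   `features` (selected on the full node data, for reporting).
#' @export
build_binary_tree <- function(es, alpha = 0.01, n_folds = 10L,
                              n_repeats = 10L, cost = 1, n_boot = 30L,
                              seed = 1L) {
  stopifnot(inherits(es, "expression_set"))
  ord <- order(colnames(es$values))
  m <- es$values[, ord, drop = FALSE]
  labels <- es$groups[ord]
  classes <- sort(unique(labels))
  set.seed(seed)

  singletons <- names(which(table(labels) < 2L))
  if (length(singletons))
    warning("class(es) with a single sample (leave-one-out used): ",
      paste(singletons, collapse = ", "))

  nodes <- list()
  node_id <- 0L
  recurse <- function(cls) {
    if (length(cls) < 2L) return(invisible(NULL))
    node_id <<- node_id + 1L
    this_id <- node_id
    in_node <- labels %in% cls
    mn <- m[, in_node, drop = FALSE]
    ln <- labels[in_node]
    best <- NULL
    for (bp in class_bipartitions(cls)) {
      side <- ifelse(ln %in% bp$left, "L", "R")
      sc <- cv_percent_correct(mn, side, alpha, n_folds, n_repeats, cost)
      if (is.null(best) || sc > best$score + 1e-9)
        best <- list(bp = bp, score = sc)
    }
    side <- ifelse(ln %in% best$bp$left, "L", "R")
    boot <- boot632_percent_correct(mn, side, alpha, cost, n_boot)
    feats <- tryCatch(select_features(mn, side, alpha),
      error = function(e) character())
    nodes[[this_id]] <<- list(
      id = this_id,
      classes = cls,
      left = best$bp$left,
      right = best$bp$right,
      score = as.integer(round(best$score)),
      cv_score = best$score,
      boot632_score = boot,
      n_features = length(feats),
      features = feats
    )
    recurse(best$bp$left)
    recurse(best$bp$right)
  }
  recurse(classes)
  structure(list(classes = classes, nodes = nodes,
    params = list(alpha = alpha, n_folds = n_folds, n_repeats = n_repeats,
      cost = cost, n_boot = n_boot, seed = seed)),
    class = "classification_tree")
}

#' @export
print.classification_tree <- function(x, ...) {
  cat(sprintf("classification_tree over {%s}\n",
    paste(x$classes, collapse = ", ")))
  for (nd in x$nodes)
    cat(sprintf("  node %d: {%s} vs {%s}, score = %d (CV %.1f%%, .632 %.1f%%)\n",
      nd$id, paste(nd$left, collapse = ","),
      paste(nd$right, collapse = ","), nd$score, nd$cv_score,
      nd$boot632_score))
  invisible(x)
}

#' Write a classification tree to JSON
#'
#' @param tree a [build_binary_tree()] result.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_classification_tree <- function(tree, path) {
  jsonlite::write_json(
    list(classes = tree$classes, params = tree$params, nodes = tree$nodes),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
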