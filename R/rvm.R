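#' Fit the random-variance-model hyperparameters
#'
#' The random variance model assumes each feature's true variance sigma^2
#' is drawn from an inverse-gamma prior such that the scaled sample
#' variance obeys s^2 * a * b ~ F(f, 2a), where f is the residual degrees
#' of freedom of each feature's variance estimate. (a, b) are estimated by
#' maximum likelihood over all features of a comparison, by Nelder-Mead
#' optimization on the log-parameter scale from a moment-based start.
#'
#' @param variances positive numeric vector of per-feature pooled sample
#'   variances (at least 10).
#' @param f residual degrees of freedom of each variance (n1 + n2 - 2 for
#'   a two-group comparison).
#' @return Object of class `rvm_fit`: list with `a`, `b`, `f`, `loglik`,
#'   `converged` and `n` (number of variances used).
#' @references Wright & Simon-style moderated variance estimation for
#'   small-sample microarray studies.
#' @export
fit_rvm_hyperparams <- function(variances, f) {
  variances <- as.numeric(variances)
  if (length(variances) < 10L)
    stop("need at least 10 variances to fit the prior")
  if (any(!is.finite(variances)) || any(variances <= 0))
    stop("all variances must be finite and > 0")
  f <- as.integer(f)
  if (f < 1L) stop("`f` must be >= 1")
  if (diff(range(variances)) < 1e-12 * max(variances))
    stop("all variances are identical; the variance prior is degenerate ",
      "- use an ordinary t-test instead")

  negll <- function(par) {
    a <- exp(par[1L])
    b <- exp(par[2L])
    x <- variances * a * b
    -sum(log(a * b) + stats::df(x, df1 = f, df2 = 2 * a, log = TRUE))
  }
  # moment start: E[s^2] = 1/(b(a-1)) for a > 1
  starts <- lapply(c(1.5, 2, 5), function(a0)
    log(c(a0, 1 / (mean(variances) * (a0 - 1)))))
  fits <- lapply(starts, function(s)
    stats::optim(s, negll, method = "Nelder-Mead",
      control = list(maxit = 5000L, reltol = 1e-12)))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1L), "value"))]]
  structure(list(
    a = exp(best$par[1L]),
    b = exp(best$par[2L]),
    f = f,
    loglik = -best$value,
    converged = best$convergence == 0L,
    n = length(variances)
  ), class = "rvm_fit")
}

#' @export
print.rvm_fit <- function(x, ...) {
  cat(sprintf(
    "RVM variance prior: a = %.4f, b = %.4f (f = %d, n = %d, logLik = %.2f%s)\n",
    x$a, x$b, x$f, x$n, x$loglik,
    if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

# Moderated variance and t statistic, vectorized over features.
rvm_moderate <- function(s2, n1, n2, fit) {
  f <- n1 + n2 - 2L
  s2_tilde <- (f * s2 + 2 / fit$b) / (f + 2 * fit$a)
  if (any(s2_tilde <= 0)) stop("zero moderated variance")
  list(s2_tilde = s2_tilde, df = f + 2 * fit$a)
}

#' Random-variance-model moderated t-test for one feature
#'
#' Shrinks the pooled sample variance toward the fitted inverse-gamma
#' prior: sigma~^2 = (f s^2 + 2/b) / (f + 2a), and refers
#' t = (mean(x) - mean(y)) / sqrt(sigma~^2 (1/n1 + 1/n2)) to a t law with
#' f + 2a degrees of freedom — always more than the ordinary f, which is
#' where the small-sample power gain comes from.
#'
#' @param x,y numeric vectors of case and control values (each length
#'   >= 2).
#' @param fit an [fit_rvm_hyperparams()] result.
#' @return List with `t`, `df` and two-sided `p`.
#' @export
rvm_t_test <- function(x, y, fit) {
  stopifnot(inherits(fit, "rvm_fit"))
  if (!fit$converged)
    warning("variance-prior fit did not converge; statistics may be off")
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 values per group")
  f <- n1 + n2 - 2L
  s2 <- ((n1 - 1L) * stats::var(x) + (n2 - 1L) * stats::var(y)) / f
  mod <- rvm_moderate(s2, n1, n2, fit)
  t <- (mean(x) - mean(y)) / sqrt(mod$s2_tilde * (1 / n1 + 1 / n2))
  list(t = t, df = mod$df, p = 2 * stats::pt(-abs(t), df = mod$df))
}

#' Differential miRNA calling with the RVM test and a fold-change filter
#'
#' Runs the moderated t-test on every miRNA for one case group against the
#' control group, then applies the conjunction rule: a miRNA is called
#' significant when its fold change exceeds `fc_thresh` (checked as
#' |log2 fold change| > log2(fc_thresh)) AND its p-value is below
#' `p_thresh`. Fold changes are computed on the log2-scale matrix supplied
#' here, which must not be z-scored (fold change is undefined after
#' per-sample standardization). Hyperparameters are fitted once on all
#' miRNAs of the comparison and reused per miRNA.
#'
#' @param es an [expression_set()] on the log2 scale.
#' @param case_group,control_group group labels to compare.
#' @param fc_thresh fold-change threshold on the linear scale (default
#'   1.5).
#' @param p_thresh significance threshold (default 0.05), applied to the
#'   raw p-value unless `adjust = "BH"`.
#' @param adjust `"none"` (default; raw p against `p_thresh`) or `"BH"`
#'   (Benjamini-Hochberg adjusted p against `p_thresh`).
#' @param fit optional pre-computed [fit_rvm_hyperparams()] result.
#' @return A data.frame of class `differential_result` with one row per
#'   miRNA: `mirna_id`, `mean_case`, `mean_control`, `log2fc`, `t`, `df`,
#'   `p`, (`p_adj` when `adjust = "BH"`), `significant`, `direction`; the
#'   RVM fit is attached as attribute `rvm_fit`.
#' @export
differential_mirnas <- function(es, case_group, control_group,
                                fc_thresh = 1.5, p_thresh = 0.05,
                                adjust = c("none", "BH"), fit = NULL) {
  stopifnot(inherits(es, "expression_set"))
  adjust <- match.arg(adjust)
  for (g in c(case_group, control_group))
    if (!g %in% es$groups) stop("unknown group label: ", g)
  idx_case <- group_samples(es, case_group)
  idx_ctrl <- group_samples(es, control_group)
  if (length(idx_case) < 2L || length(idx_ctrl) < 2L)
    stop("both groups need at least 2 samples")

  m <- es$values
  base <- row_t_test(m, idx_case, idx_ctrl)
  if (is.null(fit)) fit <- fit_rvm_hyperparams(base$s2, base$df)
  n1 <- length(idx_case)
  n2 <- length(idx_ctrl)
  mod <- rvm_moderate(base$s2, n1, n2, fit)
  t <- (base$mean1 - base$mean2) / sqrt(mod$s2_tilde * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(t), df = mod$df)
  log2fc <- base$mean1 - base$mean2

  p_crit <- if (adjust == "BH") bh_fdr(p) else p
  res <- data.frame(
    mirna_id = rownames(m),
    mean_case = base$mean1,
    mean_control = base$mean2,
    log2fc = log2fc,
    t = t,
    df = mod$df,
    p = p,
    significant = abs(log2fc) > log2(fc_thresh) & p_crit < p_thresh,
    direction = ifelse(log2fc >= 0, "up", "down"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (adjust == "BH") res$p_adj <- p_crit
  attr(res, "rvm_fit") <- fit
  attr(res, "comparison") <- paste0(case_group, "/", control_group)
  class(res) <- c("differential_result", "data.frame")
  res
}

#' Write a differential-expression table to TSV
#'
#' @param de a [differential_mirnas()] result.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_differential <- function(de, path) {
  utils::write.table(as.data.frame(de), path, sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(path)
}
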