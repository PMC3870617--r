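#' @keywords internal
"_PACKAGE"

# Derive a reproducible per-stage seed from one master seed. Offsets are fixed
# so each stage can be re-run in isolation; result kept inside 32-bit range.
stage_seed <- function(seed, stage) {
  offsets <- c(
    expression = 101L, predictions = 211L, gene_sets = 307L,
    classify = 401L, compare = 503L
  )
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Equal-variance two-sample t-test applied row-wise; returns t, df and
# two-sided p for every feature at once (used by feature selection and as
# the building block the moderated test extends).
row_t_test <- function(m, idx1, idx2) {
  n1 <- length(idx1)
  n2 <- length(idx2)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 samples per group")
  m1 <- rowMeans(m[, idx1, drop = FALSE])
  m2 <- rowMeans(m[, idx2, drop = FALSE])
  v1 <- apply(m[, idx1, drop = FALSE], 1L, stats::var)
  v2 <- apply(m[, idx2, drop = FALSE], 1L, stats::var)
  f <- n1 + n2 - 2L
  s2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / f
  se <- sqrt(s2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t), df = f)
  list(mean1 = m1, mean2 = m2, t = t, df = f, p = p, s2 = s2)
}
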