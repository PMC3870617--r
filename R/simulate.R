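#' Configuration for the synthetic study generator
#'
#' Default values emulate the study design the pipeline targets: three
#' disease-syndrome groups of 3 patients each against 7 healthy controls,
#' measured on a log2-scale miRNA array, with heteroscedastic per-miRNA
#' noise whose variance follows an inverse-gamma law (the same prior the
#' moderated t-test assumes, so calibration checks are meaningful).
#'
#' The noise hyperparameters default to `inv_gamma_shape = 3`,
#' `inv_gamma_scale = 3`, i.e. a mean residual variance of
#' 1/(scale * (shape - 1)) = 1/6 — a typical within-group spread of about
#' 0.4 log2 units for serum array data.
#'
#' @param n_mirnas number of miRNAs on the simulated array.
#' @param n_genes size of the simulated gene universe.
#' @param group_sizes named integer vector of samples per group; must
#'   contain a `Normal` control group.
#' @param n_de_per_group number of differentially expressed miRNAs planted
#'   in each non-control group (drawn independently per group, so syndromes
#'   share DE miRNAs by chance as real syndromes do).
#' @param de_log2fc planted shift, in log2 units; half the planted miRNAs
#'   go up, half down.
#' @param inv_gamma_shape,inv_gamma_scale hyperparameters (a, b) of the
#'   variance prior: per-miRNA precision 1/sigma^2 ~ Gamma(shape = a,
#'   scale = b), so sigma^2 is inverse-gamma and the scaled sample variance
#'   s2*a*b follows F(f, 2a).
#' @param baseline_mean,baseline_sd location and spread of per-miRNA
#'   baseline log2 intensities.
#' @param n_prediction_programs number of target-prediction programs; the
#'   last one is score-valued (miRDB-style), the rest binary.
#' @param program_agreement probability that a true miRNA-target pair is
#'   supported by the consensus rule (>= 2 binary programs and score > 60).
#' @param targets_per_mirna mean number of true target genes per miRNA.
#' @param decoy_fraction number of decoy (non-target) predicted pairs, as a
#'   fraction of the number of true pairs.
#' @param validated_fraction fraction of true pairs additionally reported
#'   in the validated-interaction (TarBase-style) table.
#' @param n_gene_sets number of gene sets in the simulated collection.
#' @param gene_set_size_range inclusive range of gene-set sizes.
#' @param planted_enriched_sets number of sets over-populated with targets
#'   of up-regulated miRNAs.
#' @param enriched_fraction fraction of a planted set's members drawn from
#'   the up-target pool.
#' @param seed integer master seed.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_mirnas = 400L,
                              n_genes = 2000L,
                              group_sizes = c(Normal = 7L, LGDHS = 3L,
                                LDSDS = 3L, LKYDS = 3L),
                              n_de_per_group = 40L,
                              de_log2fc = 2,
                              inv_gamma_shape = 3,
                              inv_gamma_scale = 3,
                              baseline_mean = 7,
                              baseline_sd = 1.5,
                              n_prediction_programs = 10L,
                              program_agreement = 0.8,
                              targets_per_mirna = 8,
                              decoy_fraction = 0.6,
                              validated_fraction = 0.05,
                              n_gene_sets = 50L,
                              gene_set_size_range = c(20L, 100L),
                              planted_enriched_sets = 5L,
                              enriched_fraction = 0.5,
                              seed = 1L) {
  cfg <- list(
    n_mirnas = as.integer(n_mirnas), n_genes = as.integer(n_genes),
    group_sizes = group_sizes, n_de_per_group = as.integer(n_de_per_group),
    de_log2fc = de_log2fc, inv_gamma_shape = inv_gamma_shape,
    inv_gamma_scale = inv_gamma_scale, baseline_mean = baseline_mean,
    baseline_sd = baseline_sd,
    n_prediction_programs = as.integer(n_prediction_programs),
    program_agreement = program_agreement,
    targets_per_mirna = targets_per_mirna,
    decoy_fraction = decoy_fraction,
    validated_fraction = validated_fraction,
    n_gene_sets = as.integer(n_gene_sets),
    gene_set_size_range = as.integer(gene_set_size_range),
    planted_enriched_sets = as.integer(planted_enriched_sets),
    enriched_fraction = enriched_fraction, seed = as.integer(seed)
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  stopifnot(
    cfg$n_mirnas > 0L, cfg$n_genes > 0L,
    all(cfg$group_sizes > 0L),
    cfg$n_de_per_group >= 0L, cfg$n_de_per_group <= cfg$n_mirnas,
    is.finite(cfg$de_log2fc),
    cfg$inv_gamma_shape > 1, cfg$inv_gamma_scale > 0,
    cfg$n_prediction_programs >= 2L,
    cfg$program_agreement >= 0, cfg$program_agreement <= 1,
    cfg$n_gene_sets > 0L,
    cfg$planted_enriched_sets >= 0L,
    cfg$planted_enriched_sets <= cfg$n_gene_sets,
    cfg$enriched_fraction > 0, cfg$enriched_fraction <= 1
  )
  if (!"Normal" %in% names(cfg$group_sizes))
    stop("`group_sizes` must contain a 'Normal' control group")
  invisible(cfg)
}

mirna_ids <- function(n) sprintf("miR-%04d", seq_len(n))
gene_ids <- function(n) sprintf("GENE%05d", seq_len(n))

#' Simulate a log2 miRNA expression matrix with known ground truth
#'
#' Per-miRNA baseline intensities get Gaussian noise on the log2 scale with
#' miRNA-specific variances drawn from the inverse-gamma prior, then the
#' planted differentially expressed miRNAs of each disease group are
#' shifted by +/- `de_log2fc` in that group's samples. Identical seeds
#' yield bitwise-identical matrices.
#'
#' @param config a [simulation_config()].
#' @return A list with `expr` (an [expression_set()]) and `truth`, where
#'   `truth$de_mirnas` maps each disease group to a data.frame of planted
#'   miRNA ids and directions.
#' @export
simulate_expression <- function(config) {
  validate_simulation_config(config)
  set.seed(stage_seed(config$seed, "expression"))
  ids <- mirna_ids(config$n_mirnas)
  groups <- rep(names(config$group_sizes), config$group_sizes)
  samples <- unlist(lapply(names(config$group_sizes), function(g)
    sprintf("%s_%d", g, seq_len(config$group_sizes[[g]]))))
  n_s <- length(samples)

  baseline <- stats::rnorm(config$n_mirnas, config$baseline_mean,
    config$baseline_sd)
  sigma2 <- 1 / stats::rgamma(config$n_mirnas,
    shape = config$inv_gamma_shape, scale = config$inv_gamma_scale)
  m <- baseline + matrix(stats::rnorm(config$n_mirnas * n_s), ncol = n_s) *
    sqrt(sigma2)
  dimnames(m) <- list(ids, samples)

  disease <- setdiff(names(config$group_sizes), "Normal")
  de <- list()
  for (g in disease) {
    if (config$n_de_per_group == 0L) {
      de[[g]] <- data.frame(mirna_id = character(), direction = character())
      next
    }
    picked <- sort(sample(ids, config$n_de_per_group))
    n_up <- ceiling(length(picked) / 2)
    dir <- rep(c("up", "down"), c(n_up, length(picked) - n_up))
    shift <- ifelse(dir == "up", config$de_log2fc, -config$de_log2fc)
    cols <- which(groups == g)
    m[picked, cols] <- m[picked, cols] + shift
    de[[g]] <- data.frame(mirna_id = picked, direction = dir)
  }

  list(
    expr = expression_set(m, stats::setNames(groups, samples)),
    truth = list(de_mirnas = de, sigma2 = stats::setNames(sigma2, ids))
  )
}

binary_program_names <- function(n) {
  std <- c("DIANAmT", "miRanda", "miRWalk", "RNAhybrid", "PicTar4",
    "PicTar5", "PITA", "RNA22", "TargetScan")
  if (n <= length(std)) std[seq_len(n)] else
    c(std, sprintf("program%02d", seq_len(n - length(std))))
}

#' Simulate per-program miRNA-target prediction tables
#'
#' Produces nine binary-hit program tables plus one score-valued table
#' (scores in \[0, 100\]). A true miRNA-target pair is "supported" with
#' probability `program_agreement`: it then appears in at least two binary
#' programs and scores above 60 in the scored program — exactly the
#' conditions of the consensus rule. Unsupported true pairs and decoy
#' pairs fail at least one of the two conditions by construction.
#'
#' @param mirnas character vector of miRNA ids.
#' @param genes character vector of candidate target gene ids.
#' @param config a [simulation_config()].
#' @return A list with `ensemble` (a [prediction_ensemble()]),
#'   `true_targets` (named list miRNA id -> character vector of target
#'   gene ids) and `supported_targets` (the subset of true pairs the
#'   consensus rule can recover).
#' @export
simulate_prediction_tables <- function(mirnas, genes, config) {
  if (!length(mirnas) || !length(genes)) stop("ids must be non-empty")
  validate_simulation_config(config)
  set.seed(stage_seed(config$seed, "predictions"))
  n_binary <- config$n_prediction_programs - 1L
  programs <- binary_program_names(n_binary)

  # skewed target-gene popularity so some genes are targeted by many
  # miRNAs and the hub filter has something to find
  pool <- genes[seq_len(min(length(genes), max(50L, length(genes) %/% 4L)))]
  pool_w <- 1 / seq_along(pool)^0.7

  true_pairs <- do.call(rbind, lapply(mirnas, function(m) {
    k <- max(1L, stats::rpois(1L, config$targets_per_mirna))
    k <- min(k, length(pool))
    data.frame(mirna_id = m,
      gene_id = sample(pool, k, prob = pool_w), stringsAsFactors = FALSE)
  }))
  n_true <- nrow(true_pairs)
  supported <- stats::runif(n_true) < config$program_agreement

  n_decoy <- round(config$decoy_fraction * n_true)
  decoy <- data.frame(
    mirna_id = sample(mirnas, n_decoy, replace = TRUE),
    gene_id = sample(genes, n_decoy, replace = TRUE),
    stringsAsFactors = FALSE
  )
  key <- function(d) paste(d$mirna_id, d$gene_id)
  decoy <- decoy[!duplicated(key(decoy)) & !key(decoy) %in% key(true_pairs), ]
  # decoy failure modes: (1) two programs but low score, (2) one program
  # with high score, (3) one program with low score — never both conditions
  decoy_mode <- sample(1:3, nrow(decoy), replace = TRUE)

  rows_scored <- vector("list", n_true + nrow(decoy))
  hit_rows <- vector("list", n_binary)
  append_hit <- function(progs, m, g) {
    for (p in progs)
      hit_rows[[p]][[length(hit_rows[[p]]) + 1L]] <<- c(m, g)
  }
  for (i in seq_len(n_true)) {
    m <- true_pairs$mirna_id[i]
    g <- true_pairs$gene_id[i]
    if (supported[i]) {
      k <- sample(2:4, 1L)
      append_hit(sample.int(n_binary, k), m, g)
      score <- stats::runif(1L, 61, 100)
    } else {
      append_hit(sample.int(n_binary, 1L), m, g)
      score <- stats::runif(1L, 0, 60)
    }
    rows_scored[[i]] <- data.frame(mirna_id = m, gene_id = g, score = score)
  }
  for (j in seq_len(nrow(decoy))) {
    m <- decoy$mirna_id[j]
    g <- decoy$gene_id[j]
    score <- switch(decoy_mode[j],
      {
        append_hit(sample.int(n_binary, 2L), m, g)
        stats::runif(1L, 0, 60)
      },
      {
        append_hit(sample.int(n_binary, 1L), m, g)
        stats::runif(1L, 61, 100)
      },
      {
        append_hit(sample.int(n_binary, 1L), m, g)
        stats::runif(1L, 0, 60)
      })
    rows_scored[[n_true + j]] <-
      data.frame(mirna_id = m, gene_id = g, score = score)
  }
  binary <- stats::setNames(lapply(seq_len(n_binary), function(p) {
    if (!length(hit_rows[[p]]))
      return(data.frame(mirna_id = character(), gene_id = character(),
        stringsAsFactors = FALSE))
    d <- as.data.frame(do.call(rbind, hit_rows[[p]]),
      stringsAsFactors = FALSE)
    names(d) <- c("mirna_id", "gene_id")
    d
  }), programs)
  scored <- do.call(rbind, rows_scored)

  n_val <- round(config$validated_fraction * n_true)
  val_idx <- if (n_val > 0L) sample.int(n_true, n_val) else integer()
  validated <- data.frame(
    mirna_id = true_pairs$mirna_id[val_idx],
    gene_id = true_pairs$gene_id[val_idx],
    evidence = "curated", stringsAsFactors = FALSE
  )

  split_map <- function(pairs) {
    out <- split(pairs$gene_id, pairs$mirna_id)
    lapply(out, function(g) sort(unique(g)))
  }
  list(
    ensemble = prediction_ensemble(binary, scored, validated),
    true_targets = split_map(true_pairs),
    supported_targets = split_map(true_pairs[supported, , drop = FALSE])
  )
}

#' Simulate a gene-set collection with planted over-representation
#'
#' Background sets are uniform draws from the gene universe; planted sets
#' take `enriched_fraction` of their members from the pool of genes
#' targeted by up-regulated miRNAs, producing a strong overlap odds ratio
#' for the enrichment stage to recover. Every set has at least 5 members
#' so the minimum-overlap filter is exercisable.
#'
#' @param genes character vector: the gene universe.
#' @param config a [simulation_config()].
#' @param up_targets character vector of genes targeted by up-regulated
#'   miRNAs; required when `planted_enriched_sets > 0`.
#' @return A list with `collection` (a [gene_set_collection()]) and
#'   `enriched_ids` (ids of the planted sets).
#' @export
simulate_gene_sets <- function(genes, config, up_targets = NULL) {
  validate_simulation_config(config)
  set.seed(stage_seed(config$seed, "gene_sets"))
  rng <- config$gene_set_size_range
  if (max(rng) > length(genes))
    stop("gene universe smaller than requested set sizes")
  n_planted <- config$planted_enriched_sets
  if (n_planted > 0L && is.null(up_targets))
    stop("`up_targets` required when planting enriched sets")
  up_targets <- intersect(unique(up_targets), genes)
  if (n_planted > 0L && !length(up_targets))
    stop("`up_targets` has no genes inside the universe")

  set_id <- sprintf("SET%03d", seq_len(config$n_gene_sets))
  categories <- rep(c("GO", "KEGG", "BIOCARTA"),
    length.out = config$n_gene_sets)
  planted <- seq_len(n_planted)
  sets <- vector("list", config$n_gene_sets)
  for (i in seq_len(config$n_gene_sets)) {
    size <- sample(seq(rng[1L], rng[2L]), 1L)
    if (i %in% planted) {
      k_pool <- min(round(config$enriched_fraction * size),
        length(up_targets))
      members <- c(sample(up_targets, k_pool),
        sample(setdiff(genes, up_targets), size - k_pool))
    } else {
      members <- sample(genes, size)
    }
    sets[[i]] <- sort(unique(members))
  }
  names(sets) <- set_id
  list(
    collection = gene_set_collection(sets, categories, universe = genes),
    enriched_ids = set_id[planted]
  )
}

#' Generate every pipeline input for one synthetic study
#'
#' Convenience wrapper tying the three generators together: expression
#' matrix, prediction ensemble and gene-set collection, with a combined
#' ground-truth record.
#'
#' @param config a [simulation_config()].
#' @return A list with `expr`, `ensemble`, `collection` and `truth`
#'   (`de_mirnas`, `true_targets`, `supported_targets`, `enriched_ids`).
#' @export
simulate_study <- function(config = simulation_config()) {
  ex <- simulate_expression(config)
  genes <- gene_ids(config$n_genes)
  pred <- simulate_prediction_tables(rownames(ex$expr$values), genes, config)
  up_mirnas <- unique(unlist(lapply(ex$truth$de_mirnas, function(d)
    d$mirna_id[d$direction == "up"])))
  up_targets <- unique(unlist(pred$true_targets[up_mirnas]))
  gs <- simulate_gene_sets(genes, config, up_targets = up_targets)
  list(
    expr = ex$expr,
    ensemble = pred$ensemble,
    collection = gs$collection,
    truth = list(
      de_mirnas = ex$truth$de_mirnas,
      sigma2 = ex$truth$sigma2,
      true_targets = pred$true_targets,
      supported_targets = pred$supported_targets,
      enriched_ids = gs$enriched_ids,
      up_target_pool = up_targets
    )
  )
}
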