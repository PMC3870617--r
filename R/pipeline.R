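#' Pipeline configuration
#'
#' Gathers every stage's thresholds in one place, defaulting to the
#' analysis' canonical values: fold change > 1.5 with P < 0.05 for
#' differential calls, feature selection at P = 0.01 for classification,
#' score > 60 for the scored prediction program, hub degree >= 5, minimum
#' gene-set overlap 5 and FDR < 0.05 for enrichment.
#'
#' @param simulation a [simulation_config()]; used when no external
#'   `inputs` are supplied.
#' @param inputs optional named list of file paths for user data:
#'   `matrix`, `groups`, `predictions`, `scored_program`, `validated`
#'   (optional), `gmt` (optional; enrichment is skipped with a warning
#'   when absent).
#' @param fc_thresh,p_thresh differential-expression thresholds.
#' @param classify_alpha feature-selection level for the SVM tree.
#' @param score_threshold Data B score cut-off (strict).
#' @param hub_min_degree hub-extraction degree threshold.
#' @param min_overlap,fdr_alpha enrichment retention thresholds.
#' @param universe_mode `"ensemble"` (default) restricts the enrichment
#'   universe to genes appearing in the prediction ensemble;
#'   `"collection"` keeps the collection's own universe.
#' @param n_perm permutations for the cross-network rank test.
#' @param seed master seed; fanned out to per-stage seeds via a fixed
#'   derivation so each stage is individually reproducible.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            inputs = NULL,
                            fc_thresh = 1.5, p_thresh = 0.05,
                            classify_alpha = 0.01,
                            score_threshold = 60,
                            hub_min_degree = 5L,
                            min_overlap = 5L, fdr_alpha = 0.05,
                            universe_mode = c("ensemble", "collection"),
                            n_perm = 10000L,
                            seed = simulation$seed) {
  structure(list(
    simulation = simulation, inputs = inputs,
    fc_thresh = fc_thresh, p_thresh = p_thresh,
    classify_alpha = classify_alpha, score_threshold = score_threshold,
    hub_min_degree = as.integer(hub_min_degree),
    min_overlap = as.integer(min_overlap), fdr_alpha = fdr_alpha,
    universe_mode = match.arg(universe_mode),
    n_perm = as.integer(n_perm), seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized top-level keys mirror the arguments of
#' [pipeline_config()]; the `simulation` block mirrors
#' [simulation_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$simulation %||% list()
  if (!is.null(sim_args$group_sizes))
    sim_args$group_sizes <- unlist(sim_args$group_sizes)
  if (!is.null(sim_args$gene_set_size_range))
    sim_args$gene_set_size_range <- unlist(sim_args$gene_set_size_range)
  y$simulation <- do.call(simulation_config, sim_args)
  do.call(pipeline_config, y)
}

restrict_collection <- function(collection, universe) {
  keep <- vapply(collection$sets, function(s)
    length(intersect(s, universe)) > 0L, logical(1L))
  gene_set_collection(collection$sets[keep],
    collection$info$category[keep], universe = universe)
}

load_pipeline_inputs <- function(config) {
  if (is.null(config$inputs)) {
    sim <- simulate_study(config$simulation)
    return(sim)
  }
  inp <- config$inputs
  list(
    expr = read_expression(inp$matrix, inp$groups),
    ensemble = read_prediction_ensemble(inp$predictions,
      inp$scored_program %||% "miRDB", inp$validated),
    collection = if (!is.null(inp$gmt)) read_gmt(inp$gmt),
    truth = NULL
  )
}

#' Run the full analysis pipeline
#'
#' One run per disease-group-vs-Normal comparison: preprocessing
#' (median centering for the differential branch, per-sample z-scoring
#' for clustering and classification), RVM differential testing,
#' hierarchical clustering of the significant miRNAs, consensus target
#' selection, weighted network construction with hub and up-regulation
#' subnetworks, and gene-set enrichment of the up-subnetwork targets;
#' plus the SVM binary classification tree over the disease groups and
#' all pairwise cross-comparison reports. Every output is written under
#' `out_dir` and hashed into `manifest.json`; re-running with the same
#' configuration and seed reproduces identical hashes.
#'
#' @param config a [pipeline_config()] (or path to a YAML file).
#' @param out_dir output directory, created if needed.
#' @return Invisibly, a list with the in-memory results (`de`,
#'   `networks`, `hubs`, `up`, `enrichment`, `tree`, `comparisons`,
#'   `term_overlaps`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
        call. = FALSE))
  }
  fp <- function(...) file.path(out_dir, ...)

  sim <- stage("inputs", load_pipeline_inputs(config))
  stage("inputs", {
    write_expression(sim$expr, fp("expression.tsv"), fp("groups.tsv"))
    write_prediction_ensemble(sim$ensemble, fp("predictions.tsv"),
      fp("validated.tsv"))
    if (!is.null(sim$collection))
      write_gmt(sim$collection, fp("gene_sets.gmt"))
  })

  es_de <- stage("preprocess", median_center_samples(sim$expr))
  es_z <- stage("preprocess", standardize_samples(sim$expr))
  disease <- setdiff(unique(sim$expr$groups), "Normal")

  collection <- sim$collection
  if (!is.null(collection) && config$universe_mode == "ensemble") {
    ens_genes <- sort(unique(c(
      unlist(lapply(sim$ensemble$binary, `[[`, "gene_id")),
      sim$ensemble$scored$gene_id)))
    collection <- stage("enrichment",
      restrict_collection(collection, ens_genes))
  }

  tree <- stage("classify", build_binary_tree(
    subset_groups(es_z, disease), alpha = config$classify_alpha,
    seed = stage_seed(config$seed, "classify")))
  write_classification_tree(tree, fp("classification_tree.json"))

  de <- list()
  networks <- list()
  hubs <- list()
  up <- list()
  enr <- list()
  for (g in disease) {
    cmp <- paste0(g, "/Normal")
    de[[g]] <- stage(paste0("differential:", g), differential_mirnas(
      es_de, g, "Normal", fc_thresh = config$fc_thresh,
      p_thresh = config$p_thresh))
    write_differential(de[[g]], fp(sprintf("de_%s.tsv", g)))
    sig <- de[[g]]$mirna_id[de[[g]]$significant]

    if (length(sig) >= 3L) {
      stage(paste0("cluster:", g), {
        sub <- subset_groups(es_z, c(g, "Normal"))
        sub$values <- sub$values[sig, , drop = FALSE]
        hm <- cluster_heatmap(expression_set(sub$values,
          stats::setNames(sub$groups, colnames(sub$values))))
        dendrogram_newick(hm$sample_hclust,
          fp(sprintf("dendrogram_samples_%s.nwk", g)))
        dendrogram_newick(hm$mirna_hclust,
          fp(sprintf("dendrogram_mirnas_%s.nwk", g)))
        utils::write.table(
          data.frame(mirna_id = rownames(hm$matrix), hm$matrix,
            check.names = FALSE),
          fp(sprintf("heatmap_%s.tsv", g)), sep = "\t", quote = FALSE,
          row.names = FALSE)
      })
    } else {
      warning("fewer than 3 significant miRNAs in ", cmp,
        "; clustering skipped")
    }

    cons <- stage(paste0("consensus:", g), suppressWarnings(
      consensus_targets(sim$ensemble, mirnas = sig,
        threshold = config$score_threshold)))
    write_consensus(cons, fp(sprintf("consensus_%s.tsv", g)))

    networks[[g]] <- stage(paste0("network:", g),
      build_weighted_network(cons, de[[g]], comparison = cmp))
    validate_network(networks[[g]])
    write_network_edges(networks[[g]], fp(sprintf("network_%s.tsv", g)))
    write_network_graphml(networks[[g]],
      fp(sprintf("network_%s.graphml", g)))
    hubs[[g]] <- stage(paste0("hubs:", g),
      extract_hubs(networks[[g]], config$hub_min_degree))
    write_network_edges(hubs[[g]], fp(sprintf("hubs_%s.tsv", g)))
    up[[g]] <- stage(paste0("up_subnetwork:", g),
      up_subnetwork(networks[[g]]))
    write_network_edges(up[[g]]$network, fp(sprintf("up_%s.tsv", g)))

    if (!is.null(collection)) {
      query <- unique(up[[g]]$network$edges$gene_id)
      enr[[g]] <- stage(paste0("enrichment:", g), suppressWarnings(
        hypergeom_enrich(query, collection,
          min_overlap = config$min_overlap, alpha = config$p_thresh,
          fdr_alpha = config$fdr_alpha)))
      write_enrichment(enr[[g]], fp(sprintf("enrichment_%s.tsv", g)))
    } else {
      warning("no gene-set collection configured; enrichment skipped")
    }
  }

  comparisons <- list()
  overlaps <- list()
  if (length(disease) >= 2L) {
    pairs <- utils::combn(disease, 2L, simplify = FALSE)
    for (i in seq_along(pairs)) {
      pr <- pairs[[i]]
      key <- paste(pr, collapse = "_vs_")
      comparisons[[key]] <- stage(paste0("compare:", key),
        compare_networks(networks[[pr[1L]]], networks[[pr[2L]]],
          n_perm = config$n_perm,
          seed = stage_seed(config$seed, "compare") + i))
      if (!is.null(collection))
        overlaps[[key]] <- stage(paste0("term_overlap:", key),
          term_overlap(enr[[pr[1L]]], enr[[pr[2L]]]))
    }
  }

  report <- list(
    per_comparison = lapply(disease, function(g) list(
      comparison = paste0(g, "/Normal"),
      n_significant = sum(de[[g]]$significant),
      n_network_mirnas = nrow(networks[[g]]$mirnas),
      n_network_genes = nrow(networks[[g]]$genes),
      n_edges = nrow(networks[[g]]$edges),
      n_hub_mirnas = sum(hubs[[g]]$mirnas$hub),
      n_hub_genes = sum(hubs[[g]]$genes$hub),
      up_fraction = up[[g]]$up_fraction,
      n_retained_sets = if (!is.null(collection))
        sum(enr[[g]]$retained) else NA
    )),
    classification = lapply(tree$nodes, function(nd) list(
      node = nd$id, left = nd$left, right = nd$right, score = nd$score,
      boot632 = round(nd$boot632_score, 1L))),
    cross_comparison = lapply(names(comparisons), function(k) list(
      pair = k,
      shared_mirnas = length(comparisons[[k]]$shared_mirnas),
      shared_up_mirnas = length(comparisons[[k]]$shared_up_mirnas),
      rank_correlation = comparisons[[k]]$rank_correlation,
      permutation_p = comparisons[[k]]$permutation_p,
      term_overlap = if (!is.null(collection))
        overlaps[[k]]$overlap[overlaps[[k]]$category == "total"]
      else NA
    ))
  )
  names(report$per_comparison) <- disease
  jsonlite::write_json(report, fp("report.json"), auto_unbox = TRUE,
    digits = NA, pretty = TRUE)

  files <- setdiff(list.files(out_dir, recursive = TRUE),
    "manifest.json")
  manifest <- list(
    package = "syndromirnet",
    version = as.character(utils::packageVersion("syndromirnet")),
    seed = config$seed,
    thresholds = config[c("fc_thresh", "p_thresh", "classify_alpha",
      "score_threshold", "hub_min_degree", "min_overlap", "fdr_alpha")],
    created = format(Sys.time(), tz = "UTC"),
    hashes = as.list(tools::md5sum(file.path(out_dir, sort(files))))
  )
  names(manifest$hashes) <- sort(files)
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
    digits = NA, pretty = TRUE)

  invisible(list(de = de, networks = networks, hubs = hubs, up = up,
    enrichment = enr, tree = tree, comparisons = comparisons,
    term_overlaps = overlaps, report = report, manifest = manifest,
    truth = sim$truth))
}
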