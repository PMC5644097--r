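#' Pipeline configuration
#'
#' Validated bundle of every setting of the end-to-end LA pipeline. Unknown
#' keys are rejected so typos in config files fail loudly.
#'
#' @param matrix_path path to the expression matrix TSV.
#' @param out_dir output directory (created if absent).
#' @param trait_path optional trait TSV; enables the gene-trait stage.
#' @param candidates_path optional one-identifier-per-line file of
#'   candidate X genes for the gene-trait stage and the network export;
#'   required when \code{trait_path} is given.
#' @param max_missing gene missing-rate retention cutoff.
#' @param tail_quantile,top_k_laps,conditional_r_max,conditional_la_min,leader_min_linkages,n_permutations
#'   see \code{\link{scan_config}}.
#' @param n_perm_local local permutation count of the gene-trait stage.
#' @param p_cutoff gene-trait local permutation P cutoff.
#' @param sampler null construction of the reference distribution
#'   (\code{"cells"} or \code{"rows"}).
#' @param seed master seed for every stage.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(matrix_path, out_dir, trait_path = NULL,
                            candidates_path = NULL, max_missing = 0.20,
                            tail_quantile = 1e-5, top_k_laps = 1000L,
                            conditional_r_max = 0.17,
                            conditional_la_min = 0.60,
                            leader_min_linkages = 5e5,
                            n_permutations = 1e4, n_perm_local = 1e4,
                            p_cutoff = 1e-4, sampler = "cells", seed = 1L) {
  sc <- scan_config(tail_quantile, top_k_laps, conditional_r_max,
                    conditional_la_min, leader_min_linkages,
                    n_permutations, seed)   # reuse its validation
  if (max_missing < 0 || max_missing > 1) stop("'max_missing' must be in [0, 1]")
  if (p_cutoff <= 0 || p_cutoff > 1) stop("'p_cutoff' must be in (0, 1]")
  if (n_perm_local < 1) stop("'n_perm_local' must be >= 1")
  sampler <- match.arg(sampler, c("cells", "rows"))
  if (!is.null(trait_path) && is.null(candidates_path))
    stop("'candidates_path' is required when 'trait_path' is given")
  structure(c(list(matrix_path = matrix_path, out_dir = out_dir,
                   trait_path = trait_path, candidates_path = candidates_path,
                   max_missing = max_missing, n_perm_local = as.integer(n_perm_local),
                   p_cutoff = p_cutoff, sampler = sampler),
              unclass(sc)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of \code{\link{pipeline_config}}; unknown keys
#' are rejected.
#'
#' @param path YAML file path.
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Run the full LA pipeline
#'
#' Stages: read and preprocess the matrix (missing-rate filter, mean
#' imputation, normal-score transform), build the permutation reference
#' distribution, genome-wide scan, conditional-LAP filter, scouting-gene
#' linkage counts and leader selection, optional gene-trait LA, network
#' export for the candidate genes, and a run manifest recording the seed,
#' a configuration hash and the stage counts. Any stage failure aborts
#' with a stage-tagged message and leaves an \code{INCOMPLETE} marker in
#' the output directory.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return invisibly, a list with the stage outputs and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  marker <- file.path(config$out_dir, "INCOMPLETE")
  file.create(marker)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  counts <- list()

  raw <- stage("read", read_expression_matrix(config$matrix_path))
  counts$genes_in <- nrow(raw)
  mat <- stage("preprocess", preprocess_matrix(raw, config$max_missing))
  counts$genes_retained <- nrow(mat)
  counts$samples <- ncol(mat)
  write_expression_matrix(mat, file.path(config$out_dir, "transformed.tsv"))

  ref <- stage("permute", build_reference_distribution(
    mat, config$n_permutations, seed = config$seed, sampler = config$sampler))
  write_reference(ref, file.path(config$out_dir, "reference.tsv"))

  sc <- scan_config(config$tail_quantile, config$top_k_laps,
                    config$conditional_r_max, config$conditional_la_min,
                    config$leader_min_linkages, config$n_permutations,
                    config$seed)
  results <- stage("scan", scan_all(mat, ref, sc))
  counts$triplets_evaluated <- attr(results, "n_evaluated")
  counts$triplets_significant <- attr(results, "n_significant")
  write_triplet_results(results, file.path(config$out_dir, "triplets.tsv"))

  cond <- stage("classify", classify_conditional_laps(
    utils::head(results[order(-abs(results$la)), , drop = FALSE],
                config$top_k_laps),
    config$conditional_r_max, config$conditional_la_min))
  counts$conditional_laps <- nrow(cond)
  write_triplet_results(cond, file.path(config$out_dir, "conditional_laps.tsv"))

  linkage <- stage("count", count_linkages_per_scout(results))
  utils::write.table(linkage, file.path(config$out_dir, "scout_linkages.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  leaders_pos <- stage("leaders", select_leaders(
    linkage, config$leader_min_linkages, "positive"))
  leaders_neg <- stage("leaders", select_leaders(
    linkage, config$leader_min_linkages, "negative"))
  counts$leaders_positive <- nrow(leaders_pos)
  counts$leaders_negative <- nrow(leaders_neg)

  trait_results <- NULL
  if (!is.null(config$trait_path)) {
    trait <- stage("trait-read", read_trait(config$trait_path))
    cands <- stage("trait-read",
                   readLines(config$candidates_path, warn = FALSE))
    cands <- cands[nzchar(cands)]
    trait_results <- stage("trait-la", gene_trait_la(
      raw, cands, trait, p_cutoff = config$p_cutoff,
      n_perm = config$n_perm_local, seed = config$seed))
    counts$trait_triplets <- nrow(trait_results)
    write_triplet_results(trait_results,
                          file.path(config$out_dir, "trait_la.tsv"))
    net <- stage("network", export_network(
      data.frame(x_id = trait_results$gene_id, z_id = trait_results$z_id,
                 la = trait_results$la, p_value = trait_results$p_value,
                 stringsAsFactors = FALSE), cands))
    counts$network_nodes <- attr(net, "n_nodes")
    counts$network_edges <- attr(net, "n_edges")
    utils::write.table(net, file.path(config$out_dir, "network.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(package_version = as.character(utils::packageVersion("liquidassoc")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   seed = config$seed,
                   config_hash = config_hash(unclass(config)),
                   counts = counts)
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  file.remove(marker)
  invisible(list(matrix = mat, reference = ref, results = results,
                 conditional_laps = cond, linkage = linkage,
                 leaders_positive = leaders_pos, leaders_negative = leaders_neg,
                 trait_results = trait_results, manifest = manifest))
}
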