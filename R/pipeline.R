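#' Pipeline configuration
#'
#' Collects every tunable of the mechanism-of-action workflow with its
#' default: FPKM expression floor 0.1, restart probability 0.3, 100
#' random-target draws for the node null, 1000 permutations per gene set,
#' 95th-percentile probability thresholding, FDR 5%, top-fraction 5%, node
#' p-value cutoff 0.005.
#'
#' @param fpkm_min expression floor.
#' @param alpha restart probability.
#' @param n_random_nodes random target draws for the node null.
#' @param n_random_go permutation draws per gene set.
#' @param percentile probability-thresholding percentile.
#' @param fdr false discovery rate for term selection.
#' @param top_fraction fraction defining the node top flag.
#' @param p_cut node p-value cutoff.
#' @param rng_seed root seed; per-stage child seeds are derived from it by
#'   fixed offsets so cached stages rerun identically.
#' @param weight_fun edge-weight form (see [weight_edges()]).
#' @param impact_terms `"selected"` (FDR-selected terms; falls back to all
#'   terms when the selection is empty) or `"all"`.
#' @return list of class `moa_config`.
#' @export
moa_config <- function(fpkm_min = 0.1, alpha = 0.3, n_random_nodes = 100,
                       n_random_go = 1000, percentile = 95, fdr = 0.05,
                       top_fraction = 0.05, p_cut = 0.005, rng_seed = 1,
                       weight_fun = "min_abs_log2",
                       impact_terms = c("selected", "all")) {
  stopifnot(alpha > 0, alpha <= 1, fpkm_min >= 0,
            n_random_nodes >= 1, n_random_go >= 1,
            percentile >= 0, percentile <= 100,
            fdr > 0, fdr < 1, top_fraction > 0, top_fraction < 1,
            p_cut > 0, p_cut <= 1)
  structure(
    list(fpkm_min = fpkm_min, alpha = alpha,
         n_random_nodes = n_random_nodes, n_random_go = n_random_go,
         percentile = percentile, fdr = fdr, top_fraction = top_fraction,
         p_cut = p_cut, rng_seed = rng_seed, weight_fun = weight_fun,
         impact_terms = match.arg(impact_terms)),
    class = "moa_config"
  )
}

moa_log <- function(stage, fmt, ...) {
  message(sprintf("[moanet:%s] %s", stage, sprintf(fmt, ...)))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full mechanism-of-action workflow
#'
#' Orchestrates: expression filter -> co-regulation edge weights -> random
#' walk with restart from the spectral-count seeds -> random-target node
#' null and empirical node significance -> perturbed-subnetwork extraction
#' -> thresholded gene-set scores with permutation p-values and BH selection
#' -> leave-one-target-out impact matrix. All outputs plus a provenance
#' manifest are written under `out_dir` as TSV; reruns with the same config
#' and inputs are byte-identical.
#'
#' @param network `igraph` interaction network (or path to an edge list).
#' @param profile expression profile (or path to an expression TSV).
#' @param counts spectral-count table (or path to a seeds TSV).
#' @param collection named list of gene sets (or path to a GMT file).
#' @param out_dir output directory, created if needed.
#' @param config a [moa_config()].
#' @return invisibly, a list with every intermediate (`wnet`, `seeds`,
#'   `diffusion`, `node_sig`, `subnetwork`, `go_table`, `impact`,
#'   `manifest`).
#' @export
run_moa <- function(network, profile, counts, collection,
                    out_dir = "moa_run", config = moa_config()) {
  stopifnot(inherits(config, "moa_config"))
  if (is.character(network)) {
    network <- run_stage("read_network", read_edge_list(network))
  }
  if (is.character(profile)) {
    profile <- run_stage("read_expression", read_expression(profile))
  }
  if (is.character(counts)) counts <- run_stage("read_seeds", read.delim(counts))
  if (is.character(collection)) {
    collection <- run_stage("read_genesets", read_gmt(collection))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  fnet <- run_stage("filter_expressed",
                    filter_expressed(network, profile, config$fpkm_min))
  log_tab <- attr(fnet, "filter_log")
  moa_log("network", "expression filter kept %d/%d nodes, %d/%d edges",
          log_tab$nodes[2], log_tab$nodes[1], log_tab$edges[2], log_tab$edges[1])

  wnet <- run_stage("weight_edges",
                    weight_edges(fnet, profile, config$weight_fun))
  write_weighted_network(wnet, file.path(out_dir, "weighted_network.tsv"))

  seeds <- run_stage("seeds", seeds_from_counts(counts))
  diffusion <- run_stage("rwr", rwr(wnet, seeds, alpha = config$alpha))
  moa_log("diffusion", "converged in %d iterations (residual %.2g)",
          diffusion$iterations, diffusion$residual)

  null <- run_stage("node_null", node_null(
    wnet, seeds, alpha = config$alpha, n_random = config$n_random_nodes,
    rng_seed = child_seed(config$rng_seed, 1)))
  node_sig <- run_stage("node_significance", node_significance(
    diffusion, null, top_fraction = config$top_fraction, p_cut = config$p_cut))
  write_node_significance(node_sig, file.path(out_dir, "node_significance.tsv"))

  sub <- run_stage("subnetwork", extract_perturbed_subnetwork(
    wnet, node_sig, seeds, p_cut = config$p_cut))
  write_subnetwork(sub, file.path(out_dir, "perturbed_subnetwork.tsv"))
  moa_log("subnetwork", "%d nodes with p < %g (%d direct-edge)",
          igraph::vcount(sub), config$p_cut,
          sum(igraph::E(sub)$interaction == "direct"))

  go_table <- run_stage("go_scores", go_pvalues(
    diffusion, collection, n_random = config$n_random_go,
    percentile = config$percentile,
    rng_seed = child_seed(config$rng_seed, 2), fdr = config$fdr))
  write_go_scores(go_table, file.path(out_dir, "go_scores.tsv"))
  moa_log("go", "%d/%d terms selected at FDR %g",
          sum(go_table$selected), nrow(go_table), config$fdr)

  impact <- NULL
  if (nrow(seeds) >= 2L) {
    terms <- if (config$impact_terms == "selected") {
      sel <- go_table$term_id[go_table$selected]
      if (length(sel) == 0L) {
        moa_log("impact", "no FDR-selected terms; scoring impact on all terms")
        go_table$term_id
      } else sel
    } else go_table$term_id
    impact <- run_stage("impact", target_impact(
      wnet, seeds, collection, terms = terms,
      alpha = config$alpha, percentile = config$percentile))
    write_impact_matrix(impact, file.path(out_dir, "target_impact.tsv"))
  } else {
    moa_log("impact", "single target: leave-one-out impact skipped")
  }

  manifest <- c(
    list(package_version = as.character(utils::packageVersion("moanet")),
         nodes = igraph::vcount(wnet), edges = igraph::ecount(wnet),
         n_targets = nrow(seeds), n_terms = length(collection)),
    unclass(config)
  )
  writeLines(
    paste(names(manifest), vapply(manifest, paste, character(1)), sep = "\t"),
    file.path(out_dir, "manifest.tsv"))

  invisible(list(wnet = wnet, seeds = seeds, diffusion = diffusion,
                 node_sig = node_sig, subnetwork = sub, go_table = go_table,
                 impact = impact, manifest = manifest))
}

#' Generate a complete synthetic fixture directory
#'
#' Emits every pipeline input (edge list, expression TSV, spectral counts,
#' GMT, dose-response CSV, screen plate CSV, fingerprint TSV) plus a
#' ground-truth manifest, all derived from one root seed.
#'
#' @param out_dir output directory.
#' @param n_nodes,mean_degree network size parameters.
#' @param module_size planted co-regulated module size.
#' @param logfc_effect,noise_sd planted and background expression effects.
#' @param n_targets drug targets (the 11 of a staurosporine-like kinase
#'   inhibitor pull-down by default).
#' @param n_terms decoy gene sets.
#' @param rng_seed root seed; stage seeds are derived by fixed offsets.
#' @return invisibly, a list with all generated objects and the merged truth.
#' @export
simulate_fixture <- function(out_dir, n_nodes = 500, mean_degree = 10,
                             module_size = 50, logfc_effect = 2,
                             noise_sd = 0.1, n_targets = 11, n_terms = 200,
                             rng_seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  net <- gen_ppi_network(n_nodes, mean_degree, child_seed(rng_seed, 1))
  # a few targets anchor the planted module; the rest land elsewhere, so the
  # leave-one-out impact contrasts proximal and distal targets
  expr <- gen_expression(net, module_size, logfc_effect, noise_sd,
                         child_seed(rng_seed, 2),
                         n_seeds = min(n_targets, 3))
  targets <- gen_targets(net, n_targets, rng_seed = child_seed(rng_seed, 3),
                         genes = if (module_size > 0) expr$truth$seed_genes)
  gs <- gen_genesets(net, n_terms,
                     size_range = c(min(10, n_nodes), min(200, n_nodes)),
                     truth = expr$truth, rng_seed = child_seed(rng_seed, 4))
  dr <- gen_dose_response(bliss_interaction = 0.2, noise_sd = 0.02,
                          rng_seed = child_seed(rng_seed, 5))
  screen <- gen_screen(rng_seed = child_seed(rng_seed, 6))
  fp <- gen_fingerprints(104, n_clusters = 8, flip_prob = 0.05,
                         rng_seed = child_seed(rng_seed, 7))

  write_edge_list(net, file.path(out_dir, "network.tsv"))
  write_expression(expr$profile, file.path(out_dir, "expression.tsv"))
  write.table(targets, file.path(out_dir, "targets.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(gs$collection, file.path(out_dir, "genesets.gmt"))
  write_dose_response(dr$drm, file.path(out_dir, "dose_response.csv"))
  write_plates(screen$plates, file.path(out_dir, "screen_plates.csv"))
  write_fingerprints(fp$fps, file.path(out_dir, "fingerprints.tsv"))

  truth <- c(gs$truth, dr$truth, screen$truth, fp$truth)
  truth_lines <- c(
    paste0("planted_module\t", paste(truth$planted_module, collapse = ",")),
    paste0("seed_genes\t", paste(truth$seed_genes, collapse = ",")),
    paste0("planted_term_id\t", truth$planted_term_id),
    paste0("synergy_flag\t", truth$synergy_flag),
    paste0("true_hits\t", paste(truth$true_hits, collapse = ",")),
    paste0("true_clusters\t",
           paste(names(truth$true_clusters), truth$true_clusters,
                 sep = ":", collapse = ","))
  )
  writeLines(truth_lines, file.path(out_dir, "truth.tsv"))
  invisible(list(network = net, expression = expr$profile, targets = targets,
                 collection = gs$collection, dose_response = dr,
                 screen = screen$plates, fingerprints = fp$fps, truth = truth))
}
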