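#' Read a gene-set collection from a GMT file
#'
#' @param path GMT file (term id, description, then member genes, tab
#'   separated).
#' @return named list of character vectors (term id -> members).
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  lapply(sets, unique)
}

#' Write a gene-set collection as GMT
#'
#' @param collection named list of character vectors.
#' @param path output file path.
#' @param descriptions optional named character vector of term descriptions.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  lines <- vapply(names(collection), function(id) {
    desc <- if (!is.null(descriptions) && id %in% names(descriptions)) {
      descriptions[[id]]
    } else "na"
    paste(c(id, desc, collection[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Suppress low diffusion probabilities
#'
#' Sets node probabilities strictly below the given percentile of the full
#' probability vector to zero, limiting the noise floor before gene sets are
#' scored. Ties at the threshold are retained.
#'
#' @param result a `diffusion_result`, or a named probability vector.
#' @param percentile percentile in \[0, 100\]; 95 by default.
#' @return named numeric vector of thresholded probabilities.
#' @export
threshold_probabilities <- function(result, percentile = 95) {
  p <- if (inherits(result, "diffusion_result")) result$p else result
  stopifnot(percentile >= 0, percentile <= 100)
  thr <- quantile(p, percentile / 100, names = FALSE)
  p[p < thr] <- 0
  p
}

#' Score a gene set on a thresholded probability landscape
#'
#' The score of a term is the sum of (thresholded) node probabilities over
#' its member genes; genes absent from the network contribute 0.
#'
#' @param thresholded named probability vector from
#'   [threshold_probabilities()].
#' @param members character vector of member gene ids.
#' @return non-negative scalar score.
#' @export
go_score <- function(thresholded, members) {
  sum(thresholded[intersect(names(thresholded), members)])
}

#' Permutation p-values for gene-set scores
#'
#' Scores every term of the collection on the thresholded diffusion
#' landscape, then compares each observed score with scores of `n_random`
#' uniformly drawn node sets of the same size (drawn from the network's
#' nodes, where the probabilities live). Empirical p-values use the add-one
#' estimator `(1 + #\{null >= observed\}) / (1 + n_random)`; q-values and an
#' FDR selection flag come from [bh_adjust()].
#'
#' @param result a `diffusion_result`, or a named probability vector.
#' @param collection named list of gene sets.
#' @param n_random permutation draws per term (1000 by default).
#' @param percentile thresholding percentile passed to
#'   [threshold_probabilities()].
#' @param rng_seed integer seed for the permutation draws.
#' @param fdr false discovery rate for term selection (0.05).
#' @return data.frame with columns `term_id`, `size`, `score`, `p_value`,
#'   `q_value`, `selected`.
#' @export
go_pvalues <- function(result, collection, n_random = 1000, percentile = 95,
                       rng_seed = 1, fdr = 0.05) {
  tp <- threshold_probabilities(result, percentile)
  n <- length(tp)
  sizes <- lengths(collection)
  if (any(sizes == 0L)) stop("empty gene set in collection")
  if (any(sizes > n)) stop("gene set larger than the network")
  obs <- vapply(collection, function(m) go_score(tp, m), numeric(1))
  # network-size of each term: only member genes present in the network are
  # exchangeable with the null draws
  net_sizes <- vapply(collection,
                      function(m) length(intersect(names(tp), m)), integer(1))
  p <- with_rng(rng_seed, {
    vapply(seq_along(collection), function(i) {
      k <- net_sizes[i]
      if (k == 0L) return(1)
      null <- vapply(seq_len(n_random),
                     function(j) sum(tp[sample.int(n, k)]), numeric(1))
      (1 + sum(null >= obs[i] - 1e-12)) / (1 + n_random)
    }, numeric(1))
  })
  adj <- bh_adjust(p, fdr = fdr)
  data.frame(
    term_id = names(collection), size = unname(sizes), score = unname(obs),
    p_value = unname(p), q_value = adj$q_value, selected = adj$selected,
    row.names = NULL
  )
}

#' Benjamini-Hochberg step-up adjustment and FDR selection
#'
#' @param p vector of p-values.
#' @param fdr false discovery rate (0.05).
#' @return data.frame with columns `p_value`, `q_value`, `selected`
#'   (`q_value <= fdr`).
#' @export
bh_adjust <- function(p, fdr = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  q <- p.adjust(p, method = "BH")
  data.frame(p_value = p, q_value = q, selected = q <= fdr)
}

#' Leave-one-target-out impact of each drug target on gene-set scores
#'
#' For each target, the diffusion is rerun with that target removed and the
#' remaining seed probabilities renormalized to sum to 1; the entry for
#' (target, term) is `log10((score_without + epsilon) / (score_full +
#' epsilon))`. Negative entries mean the term loses association when the
#' target is dropped — the target is potentially essential for that part of
#' the drug's mechanism. Entries where both scores are below `epsilon` are
#' set to 0.
#'
#' @param wnet weighted `igraph` network.
#' @param seeds seed profile with at least two targets.
#' @param collection named list of gene sets.
#' @param terms character vector of term ids to evaluate (typically the
#'   FDR-selected ones); defaults to all terms in `collection`.
#' @param alpha restart probability.
#' @param percentile thresholding percentile.
#' @param epsilon guard added to both scores before the log ratio.
#' @return numeric matrix, targets (rows) by terms (columns).
#' @export
target_impact <- function(wnet, seeds, collection, terms = names(collection),
                          alpha = 0.3, percentile = 95, epsilon = 1e-12) {
  if (nrow(seeds) < 2L) stop("leave-one-out impact needs at least two targets")
  terms <- intersect(terms, names(collection))
  op <- transition_operator(wnet)
  score_terms <- function(res) {
    tp <- threshold_probabilities(res, percentile)
    vapply(collection[terms], function(m) go_score(tp, m), numeric(1))
  }
  full <- score_terms(rwr(wnet, seeds, alpha = alpha, operator = op))
  impact <- matrix(0, nrow = nrow(seeds), ncol = length(terms),
                   dimnames = list(seeds$gene_id, terms))
  for (t in seq_len(nrow(seeds))) {
    rest <- seeds[-t, , drop = FALSE]
    if (sum(rest$strength) <= 0) stop("removing a target leaves no seed mass")
    rest$p0 <- rest$strength / sum(rest$strength)
    if (seeds$strength[t] == 0) next  # removal changes nothing: row stays 0
    without <- score_terms(rwr(wnet, rest, alpha = alpha, operator = op))
    ratio <- log10((without + epsilon) / (full + epsilon))
    ratio[without < epsilon & full < epsilon] <- 0
    impact[t, ] <- ratio
  }
  impact
}

#' Write a gene-set score table as TSV
#' @param scores table from [go_pvalues()].
#' @param path output file path.
#' @export
write_go_scores <- function(scores, path) {
  write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an impact matrix as TSV (targets in rows)
#' @param impact matrix from [target_impact()].
#' @param path output file path.
#' @export
write_impact_matrix <- function(impact, path) {
  out <- data.frame(target = rownames(impact), impact, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
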