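#' Seed profile from chemical-proteomics spectral counts
#'
#' Each drug target's interaction strength is the ratio of spectral counts in
#' the immobilized-compound experiment to the free-drug competition
#' experiment; a pseudocount on the competition counts keeps the ratio finite
#' when a protein is fully competed away. Restart probabilities are the
#' strengths normalized to sum to 1.
#'
#' @param counts data.frame with columns `gene_id`, `sc_immobilized`,
#'   `sc_competition` (non-negative integers), or `gene_id`, `strength`.
#' @param pseudocount added to competition counts before the ratio.
#' @return data.frame with columns `gene_id`, `strength`, `p0`.
#' @export
seeds_from_counts <- function(counts, pseudocount = 1) {
  counts <- as.data.frame(counts)
  if (anyDuplicated(counts$gene_id)) stop("duplicate gene_id among targets")
  if (!is.null(counts$strength)) {
    strength <- counts$strength
  } else {
    stopifnot(all(c("sc_immobilized", "sc_competition") %in% names(counts)))
    if (any(counts$sc_immobilized < 0) || any(counts$sc_competition < 0)) {
      stop("spectral counts must be non-negative")
    }
    strength <- counts$sc_immobilized / (counts$sc_competition + pseudocount)
  }
  if (any(strength < 0)) stop("strengths must be non-negative")
  if (sum(strength) <= 0) stop("all seed strengths are zero")
  data.frame(gene_id = as.character(counts$gene_id),
             strength = strength,
             p0 = strength / sum(strength))
}

#' Read a seed/target TSV
#'
#' Accepts either (`gene_id`, `sc_immobilized`, `sc_competition`) or
#' (`gene_id`, `strength`).
#'
#' @param path file path.
#' @inheritParams seeds_from_counts
#' @export
read_seeds <- function(path, pseudocount = 1) {
  seeds_from_counts(read.delim(path), pseudocount = pseudocount)
}

# Restart vector over the network's nodes. Seeds outside the kept network are
# dropped with a warning and the remaining mass renormalized.
restart_vector <- function(wnet, seeds) {
  nodes <- igraph::V(wnet)$name
  keep <- seeds$gene_id %in% nodes
  if (!any(keep & seeds$p0 > 0)) stop("no seed with positive mass lies in the network")
  if (!all(keep)) {
    warning(sprintf("%d seed(s) outside the network dropped; mass renormalized",
                    sum(!keep)))
    seeds <- seeds[keep, , drop = FALSE]
  }
  p0 <- setNames(numeric(length(nodes)), nodes)
  p0[seeds$gene_id] <- seeds$p0
  p0 / sum(p0)
}

#' Random walk with restart over a weighted network
#'
#' Diffuses the seed restart distribution over the network by power iteration
#' on `p <- (1 - alpha) * T p + alpha * p0`, where `T` is the
#' column-stochastic transition operator combining topology and
#' co-regulation edge weights, and `alpha` is the restart probability. The
#' asymptotic probabilities measure each node's network proximity to the drug
#' targets.
#'
#' @param wnet weighted `igraph` network.
#' @param seeds seed profile (see [seeds_from_counts()]), or a named numeric
#'   vector of restart probabilities.
#' @param alpha restart probability in (0, 1]; 0.3 by default.
#' @param tol L1 convergence tolerance.
#' @param max_iter iteration cap; exceeding it is an error.
#' @param operator optional precomputed transition operator (reused across
#'   the many diffusions of a permutation null).
#' @return object of class `diffusion_result`: a list with `p` (named
#'   probability vector summing to 1), `alpha`, `iterations`, `residual`.
#' @export
rwr <- function(wnet, seeds, alpha = 0.3, tol = 1e-10, max_iter = 10000,
                operator = NULL) {
  stopifnot(alpha > 0, alpha <= 1)
  p0 <- if (is.numeric(seeds)) seeds else restart_vector(wnet, seeds)
  op <- operator %||% transition_operator(wnet)
  p <- p0
  iter <- 0L
  residual <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    p_new <- as.numeric((1 - alpha) * (op %*% p)) + alpha * p0
    residual <- sum(abs(p_new - p))
    p <- p_new
    if (residual < tol) break
  }
  if (residual >= tol) {
    stop(sprintf("random walk did not converge in %d iterations (residual %.3g)",
                 max_iter, residual))
  }
  structure(
    list(p = setNames(p, names(p0)), alpha = alpha,
         iterations = iter, residual = residual),
    class = "diffusion_result"
  )
}

#' Random walk with restart by direct linear solve
#'
#' Solves `(I - (1 - alpha) T) p = alpha * p0` with a sparse LU
#' factorization. Serves as the closed-form reference for the iterative
#' solver; the two must agree to numerical precision.
#'
#' @inheritParams rwr
#' @return object of class `diffusion_result` (iterations = 0).
#' @export
rwr_direct <- function(wnet, seeds, alpha = 0.3, operator = NULL) {
  stopifnot(alpha > 0, alpha <= 1)
  p0 <- if (is.numeric(seeds)) seeds else restart_vector(wnet, seeds)
  op <- operator %||% transition_operator(wnet)
  n <- length(p0)
  lhs <- Diagonal(n) - (1 - alpha) * op
  p <- as.numeric(Matrix::solve(lhs, alpha * p0))
  structure(
    list(p = setNames(p, names(p0)), alpha = alpha,
         iterations = 0L, residual = 0),
    class = "diffusion_result"
  )
}

#' @export
print.diffusion_result <- function(x, ...) {
  cat(sprintf(
    "Random walk with restart (alpha = %g): %d nodes, %d iterations, residual %.2g\n",
    x$alpha, length(x$p), x$iterations, x$residual))
  cat("Top nodes:\n")
  print(head(sort(x$p, decreasing = TRUE), 5))
  invisible(x)
}

#' Pooled node-probability null from random target sets
#'
#' Repeats the diffusion for `n_random` uniformly drawn target sets of the
#' same size as the true seeds, reusing the true strength multiset (assigned
#' in its given order to the sampled nodes), and pools all asymptotic node
#' probabilities into one null sample of size `n_random * |nodes|`.
#'
#' @inheritParams rwr
#' @param n_random number of random target draws (100 by default).
#' @param rng_seed integer seed; draws are deterministic given it.
#' @return numeric vector of pooled null probabilities, with attribute
#'   `n_random`.
#' @export
node_null <- function(wnet, seeds, alpha = 0.3, n_random = 100, rng_seed = 1,
                      tol = 1e-10, max_iter = 10000) {
  stopifnot(n_random >= 1)
  nodes <- igraph::V(wnet)$name
  k <- nrow(seeds)
  if (k > length(nodes)) stop("more seeds than network nodes")
  op <- transition_operator(wnet)
  strengths <- seeds$strength
  pooled <- with_rng(rng_seed, {
    out <- vector("list", n_random)
    for (r in seq_len(n_random)) {
      pick <- sample(nodes, k)
      fake <- data.frame(gene_id = pick, strength = strengths,
                         p0 = strengths / sum(strengths))
      out[[r]] <- rwr(wnet, fake, alpha = alpha, tol = tol,
                      max_iter = max_iter, operator = op)$p
    }
    out
  })
  structure(unlist(pooled, use.names = FALSE), n_random = n_random)
}

#' Empirical node significance against a pooled null
#'
#' Per-node empirical p-value `(1 + #\{null >= p_obs\}) / (1 + |null|)` (the
#' add-one estimator standard in permutation testing, so p is never 0), a
#' `top5` flag for nodes at or above the 95th percentile of the pooled null,
#' and a `sig005` flag for `p < p_cut`.
#'
#' @param result a `diffusion_result` for the true seeds.
#' @param null_sample pooled null probabilities from [node_null()].
#' @param top_fraction fraction defining the top-percentile flag (0.05).
#' @param p_cut p-value cutoff for the significance flag (0.005).
#' @return data.frame with columns `node`, `probability`, `p_value`, `top5`,
#'   `sig005`.
#' @export
node_significance <- function(result, null_sample, top_fraction = 0.05,
                              p_cut = 0.005) {
  if (length(null_sample) == 0L) stop("empty null sample")
  obs <- result$p
  sorted_null <- sort(null_sample)
  n <- length(sorted_null)
  # #{null >= obs} via rank in the sorted null
  n_ge <- n - findInterval(obs, sorted_null, left.open = TRUE)
  p <- (1 + n_ge) / (1 + n)
  thr <- quantile(sorted_null, 1 - top_fraction, names = FALSE)
  data.frame(
    node = names(obs),
    probability = unname(obs),
    p_value = unname(p),
    top5 = unname(obs >= thr),   # ties at the threshold are kept
    sig005 = unname(p < p_cut),
    row.names = NULL
  )
}

#' Extract the significantly perturbed subnetwork
#'
#' Induced subgraph on nodes with empirical p below `p_cut`; each surviving
#' edge is annotated `direct` when incident to a drug-target seed and
#' `indirect` otherwise, and edge weights are carried through.
#'
#' @param wnet weighted `igraph` network.
#' @param sig node significance table from [node_significance()].
#' @param seeds seed profile; defines which edges count as direct.
#' @param p_cut p-value cutoff (0.005).
#' @return `igraph` subnetwork with edge attributes `weight` and `interaction`
#'   (`"direct"`/`"indirect"`).
#' @export
extract_perturbed_subnetwork <- function(wnet, sig, seeds, p_cut = 0.005) {
  keep <- sig$node[sig$p_value < p_cut]
  sub <- igraph::induced_subgraph(wnet, intersect(igraph::V(wnet)$name, keep))
  if (igraph::ecount(sub) > 0) {
    el <- igraph::as_edgelist(sub)
    direct <- el[, 1] %in% seeds$gene_id | el[, 2] %in% seeds$gene_id
    igraph::E(sub)$interaction <- ifelse(direct, "direct", "indirect")
  }
  sub
}

#' Write a node significance table as TSV
#' @param sig table from [node_significance()].
#' @param path output file path.
#' @export
write_node_significance <- function(sig, path) {
  write.table(sig, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an annotated subnetwork as a TSV edge list
#' @param sub subnetwork from [extract_perturbed_subnetwork()].
#' @param path output file path.
#' @export
write_subnetwork <- function(sub, path) {
  el <- igraph::as_edgelist(sub)
  out <- data.frame(
    gene_a = el[, 1], gene_b = el[, 2],
    weight = igraph::E(sub)$weight %||% rep(1, nrow(el)),
    interaction = igraph::E(sub)$interaction %||% character(nrow(el))
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
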