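#' Build an interaction network from an edge table
#'
#' Protein-protein interaction networks are handled as undirected simple
#' [igraph][igraph::graph_from_data_frame] graphs with gene identifiers as
#' vertex names. Self-loops are dropped and duplicate edges collapsed, since
#' both are meaningless for diffusion.
#'
#' @param edges two-column data.frame (or matrix) of gene id pairs.
#' @return an undirected simple `igraph` object.
#' @export
interaction_network <- function(edges) {
  edges <- as.data.frame(edges)[, 1:2]
  edges[] <- lapply(edges, as.character)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Read a network edge list (TSV or SIF)
#'
#' Two-column TSV (`gene_a<TAB>gene_b`, header optional) or three-column SIF
#' (`gene_a<TAB>relation<TAB>gene_b`; the relation is ignored).
#'
#' @param path file path.
#' @return an undirected simple `igraph` object.
#' @export
read_edge_list <- function(path) {
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  header <- any(tolower(first[1]) %in% c("gene_a", "source", "from", "node1"))
  tab <- read.delim(path, header = header, colClasses = "character")
  if (ncol(tab) >= 3L) tab <- tab[, c(1L, 3L)]  # SIF: middle column is the relation
  interaction_network(tab)
}

#' Write a network as a two-column TSV edge list
#'
#' @param network an `igraph` network.
#' @param path output file path.
#' @export
write_edge_list <- function(network, path) {
  el <- igraph::as_edgelist(network)
  write.table(data.frame(gene_a = el[, 1], gene_b = el[, 2]),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble an expression profile with treated/control fold changes
#'
#' Fold change is computed as `(fpkm_treated + pseudocount) /
#' (fpkm_control + pseudocount)`; the pseudocount (default 0.1, the same
#' value as the expression floor) keeps ratios finite for unexpressed genes.
#' A supplied `fold_change` column overrides the computed ratio.
#'
#' @param x data.frame with columns `gene_id`, `fpkm_control`, `fpkm_treated`
#'   and optionally `fold_change`.
#' @param pseudocount added to both FPKM values before taking the ratio.
#' @return data.frame with columns `gene_id`, `fpkm_control`, `fpkm_treated`,
#'   `fold_change`.
#' @export
expression_profile <- function(x, pseudocount = 0.1) {
  x <- as.data.frame(x)
  stopifnot(all(c("gene_id", "fpkm_control", "fpkm_treated") %in% names(x)))
  if (anyDuplicated(x$gene_id)) stop("duplicate gene_id in expression profile")
  if (any(x$fpkm_control < 0) || any(x$fpkm_treated < 0)) {
    stop("FPKM values must be non-negative")
  }
  if (is.null(x$fold_change)) {
    x$fold_change <- (x$fpkm_treated + pseudocount) / (x$fpkm_control + pseudocount)
  }
  if (any(!is.finite(x$fold_change)) || any(x$fold_change <= 0)) {
    stop("fold changes must be finite and positive")
  }
  x[, c("gene_id", "fpkm_control", "fpkm_treated", "fold_change")]
}

#' Read an expression TSV
#'
#' Expected columns: `gene_id`, `fpkm_control`, `fpkm_treated`, optional
#' `fold_change` (which overrides the computed ratio).
#'
#' @inheritParams expression_profile
#' @param path file path.
#' @export
read_expression <- function(path, pseudocount = 0.1) {
  expression_profile(read.delim(path), pseudocount = pseudocount)
}

#' Write an expression profile TSV
#' @param profile expression profile data.frame.
#' @param path output file path.
#' @export
write_expression <- function(profile, path) {
  write.table(profile, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict a network to expressed genes
#'
#' Keeps the induced subgraph on genes whose FPKM exceeds `fpkm_min` in
#' either condition (genes absent from the profile count as not expressed),
#' then drops nodes left isolated so the diffusion operator stays
#' well-defined.
#'
#' @param network an `igraph` interaction network.
#' @param profile expression profile (see [expression_profile()]).
#' @param fpkm_min expression floor; a gene is expressed when control or
#'   treated FPKM exceeds it.
#' @return the filtered `igraph`, with a `filter_log` attribute recording
#'   node/edge counts before and after.
#' @export
filter_expressed <- function(network, profile, fpkm_min = 0.1) {
  expressed <- profile$gene_id[profile$fpkm_control > fpkm_min |
                               profile$fpkm_treated > fpkm_min]
  keep <- intersect(igraph::V(network)$name, expressed)
  sub <- igraph::induced_subgraph(network, keep)
  sub <- igraph::delete_vertices(sub, igraph::V(sub)[igraph::degree(sub) == 0])
  if (igraph::vcount(sub) == 0L) {
    stop("no expressed genes with interactions remain; diffusion undefined")
  }
  attr(sub, "filter_log") <- data.frame(
    stage = c("input", "filtered"),
    nodes = c(igraph::vcount(network), igraph::vcount(sub)),
    edges = c(igraph::ecount(network), igraph::ecount(sub))
  )
  sub
}

#' Weight network edges by transcriptional co-regulation
#'
#' An edge linking proteins A and B is taken as evidence of concerted
#' activity; when both endpoints change expression under treatment the
#' interaction gains relevance. The default weight is
#' `w_AB = 1 + min(|log2 fC_A|, |log2 fC_B|)`: symmetric, equal to the
#' baseline 1 whenever either endpoint is unregulated (fold change 1), and
#' increasing only when both endpoints are regulated (in either direction —
#' absolute log2 fold change is used). The geometric-mean alternative
#' `1 + sqrt(|log2 fC_A| * |log2 fC_B|)` shares these properties.
#'
#' @param network an `igraph` interaction network.
#' @param profile expression profile; genes missing from it get fold change 1.
#' @param weight_fun `"min_abs_log2"` (default) or `"geom_mean_log2"`.
#' @return the network with an edge attribute `weight` (all >= 1).
#' @export
weight_edges <- function(network, profile,
                         weight_fun = c("min_abs_log2", "geom_mean_log2")) {
  weight_fun <- match.arg(weight_fun)
  fc <- setNames(profile$fold_change, profile$gene_id)
  if (any(fc <= 0)) stop("fold changes must be positive")
  nodes <- igraph::V(network)$name
  lfc <- abs(log2(fc[nodes]))
  lfc[is.na(lfc)] <- 0  # genes without measured fold change count as unregulated
  names(lfc) <- nodes
  el <- igraph::as_edgelist(network)
  a <- lfc[el[, 1]]
  b <- lfc[el[, 2]]
  w <- switch(weight_fun,
    min_abs_log2  = 1 + pmin(a, b),
    geom_mean_log2 = 1 + sqrt(a * b)
  )
  igraph::E(network)$weight <- unname(w)
  network
}

#' Read a weighted network from a 3-column TSV
#'
#' Expects columns `gene_a`, `gene_b`, `weight` as written by
#' [write_weighted_network()].
#'
#' @param path file path.
#' @return an `igraph` network with a `weight` edge attribute.
#' @export
read_weighted_network <- function(path) {
  tab <- read.delim(path)
  stopifnot(all(c("gene_a", "gene_b", "weight") %in% names(tab)))
  g <- igraph::graph_from_data_frame(
    tab[, c("gene_a", "gene_b", "weight")], directed = FALSE)
  igraph::simplify(g, edge.attr.comb = list(weight = "first"))
}

#' Write a weighted network as a 3-column TSV
#' @param wnet weighted network (see [weight_edges()]).
#' @param path output file path.
#' @export
write_weighted_network <- function(wnet, path) {
  el <- igraph::as_edgelist(wnet)
  write.table(
    data.frame(gene_a = el[, 1], gene_b = el[, 2],
               weight = igraph::E(wnet)$weight),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Column-stochastic transition operator of a weighted network
#'
#' Entry (B, A) is `w_AB / sum_C w_AC`: the probability that a walker at A
#' steps to B. Unweighted networks get unit weights. Every column sums to 1;
#' isolated nodes are an error (prevent them with [filter_expressed()]).
#'
#' @param wnet `igraph` network, optionally with a `weight` edge attribute.
#' @return a sparse `dgCMatrix` with node names as dimnames.
#' @export
transition_operator <- function(wnet) {
  n <- igraph::vcount(wnet)
  if (any(igraph::degree(wnet) == 0)) {
    stop("isolated node: transition operator undefined")
  }
  w <- igraph::E(wnet)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(wnet))
  el <- igraph::as_edgelist(wnet, names = FALSE)
  nodes <- igraph::V(wnet)$name
  # symmetric weighted adjacency, then normalize columns
  adj <- sparseMatrix(
    i = c(el[, 1], el[, 2]), j = c(el[, 2], el[, 1]), x = c(w, w),
    dims = c(n, n), dimnames = list(nodes, nodes)
  )
  op <- adj %*% Diagonal(x = 1 / Matrix::colSums(adj))
  dimnames(op) <- list(nodes, nodes)  # Diagonal products drop colnames
  op
}
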