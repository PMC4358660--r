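# Tiny fixtures shared across test files. Everything is built in code.

# path graph A-B-C-D
toy_path <- function() {
  interaction_network(data.frame(a = c("A", "B", "C"), b = c("B", "C", "D")))
}

# single-edge network with all seed mass on A
toy_pair <- function() {
  list(
    net = interaction_network(data.frame(a = "A", b = "B")),
    seeds = data.frame(gene_id = "A", strength = 1, p0 = 1)
  )
}

flat_profile <- function(genes, fpkm = 10, fold_change = 1) {
  expression_profile(data.frame(
    gene_id = genes, fpkm_control = fpkm, fpkm_treated = fpkm,
    fold_change = fold_change
  ))
}

# mid-size synthetic study: network, expression with planted module,
# spectral-count targets anchored on the module seeds, gene sets
synthetic_study <- function(seed = 1, n_nodes = 500, mean_degree = 10,
                            module_size = 50, n_targets = 11, n_terms = 200,
                            n_seeds = 3) {
  net <- gen_ppi_network(n_nodes, mean_degree, rng_seed = seed)
  expr <- gen_expression(net, module_size, logfc_effect = 2, noise_sd = 0.1,
                         rng_seed = seed + 1000, n_seeds = n_seeds)
  targets <- gen_targets(net, n_targets, ratio_range = c(2, 20),
                         rng_seed = seed + 2000,
                         genes = expr$truth$seed_genes)
  gs <- gen_genesets(net, n_terms,
                     size_range = c(10, min(200, max(11, n_nodes %/% 3))),
                     truth = expr$truth, rng_seed = seed + 3000)
  wnet <- weight_edges(filter_expressed(net, expr$profile), expr$profile)
  list(net = net, profile = expr$profile, truth = gs$truth,
       targets = targets, seeds = seeds_from_counts(targets),
       collection = gs$collection, wnet = wnet)
}

# brute-force false-discovery-rate adjustment: q_i is the smallest
# m * t / #{p <= t} over every achievable rejection threshold t >= p_i,
# enumerated explicitly; independent of stats::p.adjust
bh_oracle <- function(p) {
  m <- length(p)
  vapply(seq_len(m), function(i) {
    cand <- p[p >= p[i]]
    min(1, vapply(cand, function(t) m * t / sum(p <= t), numeric(1)))
  }, numeric(1))
}
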