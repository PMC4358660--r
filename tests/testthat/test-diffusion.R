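test_that("seed strengths are spectral-count ratios normalized to probabilities", {
  single <- seeds_from_counts(data.frame(
    gene_id = "A", sc_immobilized = 100, sc_competition = 10))
  expect_equal(single$p0, 1)
  expect_equal(single$strength, 100 / 11)

  two <- seeds_from_counts(data.frame(
    gene_id = c("A", "B"), sc_immobilized = c(100, 50),
    sc_competition = c(9, 49)))
  expect_equal(two$strength, c(10, 1))
  expect_equal(two$p0, c(10 / 11, 1 / 11))
  expect_equal(sum(two$p0), 1)

  expect_error(seeds_from_counts(data.frame(
    gene_id = "A", sc_immobilized = 0, sc_competition = 0)), "zero")
  direct <- seeds_from_counts(data.frame(gene_id = c("A", "B"),
                                         strength = c(3, 1)))
  expect_equal(direct$p0, c(0.75, 0.25))
})

test_that("restart walk matches the closed-form two-node solution", {
  pair <- toy_pair()
  res <- rwr(pair$net, pair$seeds, alpha = 0.3)
  # pA = 0.3 + 0.7 pB, pB = 0.7 pA  =>  pA = 0.3/0.51, pB = 0.21/0.51
  expect_equal(unname(res$p["A"]), 0.3 / 0.51, tolerance = 1e-9)
  expect_equal(unname(res$p["B"]), 0.21 / 0.51, tolerance = 1e-9)
  direct <- rwr_direct(pair$net, pair$seeds, alpha = 0.3)
  expect_equal(unname(direct$p["A"]), 0.3 / 0.51, tolerance = 1e-12)
  expect_equal(unname(direct$p["B"]), 0.21 / 0.51, tolerance = 1e-12)
})

test_that("pure restart returns the seed distribution and mass is conserved", {
  study <- synthetic_study(seed = 5, n_nodes = 200, mean_degree = 8,
                           module_size = 20, n_terms = 5)
  pure <- rwr(study$wnet, study$seeds, alpha = 1)
  expected <- setNames(numeric(igraph::vcount(study$wnet)),
                       igraph::V(study$wnet)$name)
  expected[study$seeds$gene_id] <- study$seeds$p0
  expect_equal(pure$p, expected / sum(expected), tolerance = 1e-12)
  expect_equal(unname(rwr_direct(study$wnet, study$seeds, alpha = 1)$p),
               unname(expected / sum(expected)), tolerance = 1e-12)

  for (a in c(0.1, 0.3, 0.9)) {
    res <- rwr(study$wnet, study$seeds, alpha = a)
    expect_true(all(res$p >= 0))
    expect_lt(abs(sum(res$p) - 1), 1e-9)
  }
})

test_that("iterative and direct solvers agree on random weighted networks", {
  for (seed in 1:5) {
    study <- synthetic_study(seed = seed, n_nodes = 150 + 50 * seed,
                             mean_degree = 8, module_size = 20, n_terms = 5)
    it <- rwr(study$wnet, study$seeds, alpha = 0.3)
    dr <- rwr_direct(study$wnet, study$seeds, alpha = 0.3)
    expect_lt(max(abs(it$p - dr$p)), 1e-8)
  }
})

test_that("seeds outside the network are dropped with renormalization", {
  pair <- toy_pair()
  seeds <- data.frame(gene_id = c("A", "MISSING"), strength = c(1, 1),
                      p0 = c(0.5, 0.5))
  expect_warning(res <- rwr(pair$net, seeds, alpha = 1), "renormalized")
  expect_equal(unname(res$p["A"]), 1)
  lost <- data.frame(gene_id = "MISSING", strength = 1, p0 = 1)
  expect_error(suppressWarnings(rwr(pair$net, lost)), "seed")
})

test_that("diffusion enriches the planted module over the network average", {
  study <- synthetic_study(seed = 6)
  res <- rwr(study$wnet, study$seeds)
  module <- intersect(study$truth$planted_module, names(res$p))
  expect_gt(mean(res$p[module]), mean(res$p))
})

test_that("the node null pools the right sample and concentrates on a regular graph", {
  study <- synthetic_study(seed = 7, n_nodes = 150, mean_degree = 6,
                           module_size = 20, n_terms = 5)
  null <- node_null(study$wnet, study$seeds, n_random = 10, rng_seed = 3)
  expect_length(null, 10 * igraph::vcount(study$wnet))
  expect_identical(as.numeric(null),
                   as.numeric(node_null(study$wnet, study$seeds,
                                        n_random = 10, rng_seed = 3)))

  # unweighted cycle: every node is equivalent, so at a small restart
  # probability the walk mixes and null mass concentrates near 1/|nodes|
  n <- 20
  ring <- interaction_network(data.frame(
    a = paste0("N", 1:n), b = paste0("N", c(2:n, 1))))
  seeds <- data.frame(gene_id = c("N1", "N2"), strength = c(1, 1),
                      p0 = c(0.5, 0.5))
  rnull <- node_null(ring, seeds, alpha = 0.01, n_random = 20, rng_seed = 5)
  expect_equal(mean(rnull), 1 / n, tolerance = 1e-6)
  expect_true(all(rnull > 0.5 / n & rnull < 2 / n))

  expect_error(node_null(ring, data.frame(
    gene_id = paste0("X", 1:41), strength = 1, p0 = 1 / 41), rng_seed = 1),
    "more seeds")
})

test_that("empirical node p-values use the add-one estimator with consistent flags", {
  obs <- structure(list(p = setNames(c(0.5, 0.05, 0.001), c("A", "B", "C")),
                        alpha = 0.3, iterations = 1, residual = 0),
                   class = "diffusion_result")
  null <- seq(0.001, 0.1, length.out = 999)
  sig <- node_significance(obs, null, top_fraction = 0.05, p_cut = 0.005)
  expect_equal(sig$p_value[sig$node == "A"], 1 / 1000)  # above the null maximum
  # C sits at the null minimum: every null value >= it
  expect_equal(sig$p_value[sig$node == "C"], 1)
  expect_true(all(sig$p_value > 0 & sig$p_value <= 1))
  expect_true(sig$top5[sig$node == "A"])
  expect_true(sig$sig005[sig$node == "A"])
  expect_false(sig$sig005[sig$node == "C"])

  # a node at the null median scores p ~ 0.5
  mid <- structure(list(p = setNames(0.0505, "M"), alpha = 0.3,
                        iterations = 1, residual = 0),
                   class = "diffusion_result")
  expect_equal(node_significance(mid, null)$p_value, 0.5, tolerance = 0.01)
  expect_error(node_significance(obs, numeric(0)), "empty")
})

test_that("perturbed subnetwork keeps significant nodes and flags direct edges", {
  star <- interaction_network(data.frame(a = "S", b = c("L1", "L2", "L3")))
  seeds <- data.frame(gene_id = "S", strength = 1, p0 = 1)
  sig <- data.frame(node = c("S", "L1", "L2", "L3"),
                    probability = c(0.7, 0.1, 0.1, 0.1),
                    p_value = c(0.001, 0.001, 0.5, 0.001),
                    top5 = TRUE, sig005 = c(TRUE, TRUE, FALSE, TRUE))
  sub <- extract_perturbed_subnetwork(star, sig, seeds, p_cut = 0.005)
  expect_setequal(igraph::V(sub)$name, c("S", "L1", "L3"))
  expect_true(all(igraph::E(sub)$interaction == "direct"))

  whole <- extract_perturbed_subnetwork(star, sig, seeds, p_cut = 1.01)
  expect_equal(igraph::vcount(whole), 4)
  none <- extract_perturbed_subnetwork(star, transform(sig, p_value = 0.5),
                                       seeds, p_cut = 0.005)
  expect_equal(igraph::vcount(none), 0)

  # an edge between two significant non-seed nodes is indirect
  tri <- interaction_network(data.frame(a = c("S", "S", "L1"),
                                        b = c("L1", "L3", "L3")))
  sub2 <- extract_perturbed_subnetwork(tri, sig, seeds, p_cut = 0.005)
  el <- igraph::as_edgelist(sub2)
  ind <- igraph::E(sub2)$interaction[el[, 1] == "L1" & el[, 2] == "L3" |
                                     el[, 1] == "L3" & el[, 2] == "L1"]
  expect_equal(ind, "indirect")
})

test_that("null-calibrated seeds give uniform node p-values", {
  study <- synthetic_study(seed = 8)
  null <- node_null(study$wnet, study$seeds, n_random = 100, rng_seed = 17)
  nodes <- igraph::V(study$wnet)$name
  fake <- with(list(), {
    set.seed(23)
    g <- sample(nodes, nrow(study$seeds))
    data.frame(gene_id = g, strength = study$seeds$strength,
               p0 = study$seeds$p0)
  })
  res <- rwr(study$wnet, fake)
  sig <- node_significance(res, null)
  d <- suppressWarnings(
    stats::ks.test(sig$p_value, "punif"))$statistic
  crit_1pct <- 1.6276 / sqrt(nrow(sig))
  expect_lt(d, crit_1pct)
})
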