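test_that("scale-free network generator respects size, simplicity and connectivity", {
  tiny <- gen_ppi_network(2, 1, rng_seed = 1)
  expect_equal(igraph::vcount(tiny), 2)
  expect_equal(igraph::ecount(tiny), 1)

  net <- gen_ppi_network(500, 10, rng_seed = 7)
  expect_equal(igraph::vcount(net), 500)
  expect_true(abs(igraph::ecount(net) - 2500) < 125)
  expect_true(igraph::is_connected(net))
  expect_false(igraph::any_multiple(net))
  expect_equal(sum(igraph::which_loop(net)), 0)
  # heavy tail: max degree far above the mean
  expect_gt(max(igraph::degree(net)), 4 * mean(igraph::degree(net)))

  expect_error(gen_ppi_network(1, 1), "n_nodes")
  expect_error(gen_ppi_network(10, 0), "mean_degree")
  expect_error(gen_ppi_network(10, 20), "mean_degree")
})

test_that("generators are deterministic given the seed", {
  net <- gen_ppi_network(100, 6, rng_seed = 3)
  expect_identical(igraph::as_edgelist(net),
                   igraph::as_edgelist(gen_ppi_network(100, 6, rng_seed = 3)))
  e1 <- gen_expression(net, 20, 2, 0.1, rng_seed = 5)
  e2 <- gen_expression(net, 20, 2, 0.1, rng_seed = 5)
  expect_identical(e1, e2)
  s1 <- gen_screen(n_plates = 1, wells_per_plate = 96, rng_seed = 9)
  s2 <- gen_screen(n_plates = 1, wells_per_plate = 96, rng_seed = 9)
  expect_identical(s1, s2)
  # the generators restore the caller's RNG stream
  set.seed(42); before <- runif(1)
  set.seed(42); invisible(gen_ppi_network(50, 4, rng_seed = 1)); after <- runif(1)
  expect_identical(before, after)
})

test_that("expression generator plants the module at the requested effect size", {
  net <- gen_ppi_network(500, 10, rng_seed = 7)
  out <- gen_expression(net, 50, logfc_effect = 2, noise_sd = 0.1, rng_seed = 3)
  prof <- out$profile
  truth <- out$truth
  expect_length(truth$planted_module, 50)
  expect_true(all(truth$planted_module %in% igraph::V(net)$name))
  expect_true(all(truth$seed_genes %in% truth$planted_module))
  expect_true(all(prof$fpkm_control > 0.1))

  lfc <- abs(log2(prof$fold_change))
  inside <- prof$gene_id %in% truth$planted_module
  expect_equal(mean(lfc[inside]), 2, tolerance = 0.05)
  # half-normal mean of background |log2 fc|: noise_sd * sqrt(2/pi)
  expect_equal(mean(lfc[!inside]), 0.1 * sqrt(2 / pi), tolerance = 0.15)

  flat <- gen_expression(net, 50, logfc_effect = 0, noise_sd = 0, rng_seed = 3)
  expect_true(all(flat$profile$fold_change == 1))
  none <- gen_expression(net, 0, logfc_effect = 2, noise_sd = 0.1, rng_seed = 3)
  expect_length(none$truth$planted_module, 0)
})

test_that("spectral-count generator keeps integer counts with ratios in range", {
  net <- gen_ppi_network(200, 6, rng_seed = 2)
  tg <- gen_targets(net, 11, ratio_range = c(2, 20), rng_seed = 4)
  expect_equal(nrow(tg), 11)
  expect_false(anyDuplicated(tg$gene_id) > 0)
  expect_true(all(tg$sc_immobilized == round(tg$sc_immobilized)))
  expect_true(all(tg$sc_immobilized >= 0 & tg$sc_competition >= 0))
  ratio <- tg$sc_immobilized / tg$sc_competition
  expect_true(all(ratio >= 2 & ratio <= 20))

  forced <- gen_targets(net, 5, ratio_range = c(5, 5), rng_seed = 4)
  expect_true(all(forced$sc_immobilized / forced$sc_competition == 5))

  anchored <- gen_targets(net, 3, rng_seed = 4,
                          genes = igraph::V(net)$name[1:3])
  expect_identical(anchored$gene_id, igraph::V(net)$name[1:3])
  expect_error(gen_targets(net, 201, rng_seed = 1), "node count")
  expect_error(gen_targets(net, 2, ratio_range = c(0.5, 2)), ">= 1")
})

test_that("gene-set generator emits decoys plus the planted term", {
  net <- gen_ppi_network(300, 8, rng_seed = 2)
  expr <- gen_expression(net, 30, 2, 0.1, rng_seed = 3)
  gs <- gen_genesets(net, 200, size_range = c(10, 200), truth = expr$truth,
                     rng_seed = 5)
  expect_length(gs$collection, 201)
  sizes <- lengths(gs$collection)
  decoys <- setdiff(names(gs$collection), gs$truth$planted_term_id)
  expect_true(all(sizes[decoys] >= 10 & sizes[decoys] <= 200))
  expect_true(all(unlist(gs$collection) %in% igraph::V(net)$name))
  expect_setequal(gs$collection[[gs$truth$planted_term_id]],
                  expr$truth$planted_module)

  only <- gen_genesets(net, 0, truth = expr$truth, rng_seed = 5)
  expect_identical(names(only$collection), only$truth$planted_term_id)
})

test_that("dose-response generator is Bliss-additive unless an interaction is planted", {
  flat <- gen_dose_response(bliss_interaction = 0, noise_sd = 0, rng_seed = 1)
  expect_true(all(flat$drm$viability >= 0 & flat$drm$viability <= 1))
  expect_equal(max(abs(synergy_matrix(flat$drm)$deviation)), 0)

  modest <- list(x = list(emax = 0.5, ec50 = 1, hill = 1),
                 y = list(emax = 0.5, ec50 = 1, hill = 1))
  syn <- gen_dose_response(hill_params = modest, bliss_interaction = 0.2,
                           noise_sd = 0, rng_seed = 1)
  expect_true(syn$truth$synergy_flag)
  d <- synergy_matrix(syn$drm)$deviation
  expect_equal(unname(as.vector(d)), rep(0.2, length(d)))
})

test_that("screen generator places controls and duplicates every compound", {
  out <- gen_screen(n_plates = 2, wells_per_plate = 96, n_pos_ctrl = 4,
                    n_neg_ctrl = 4, hit_fraction = 0.05, rng_seed = 6)
  expect_length(out$plates, 4)  # 2 layouts x 2 replicates
  for (p in out$plates) {
    expect_equal(sum(p$compound_id == "POS"), 4)
    expect_equal(sum(p$compound_id == "NEG"), 4)
    expect_true(all(p$signal >= 0))
  }
  cmp <- do.call(rbind, out$plates)
  cmp <- cmp[!cmp$compound_id %in% c("POS", "NEG"), ]
  expect_true(all(table(cmp$compound_id) == 2))
  expect_true(all(out$truth$true_hits %in% cmp$compound_id))

  clean <- gen_screen(n_plates = 1, wells_per_plate = 96, hit_fraction = 0,
                      rng_seed = 6)
  expect_length(clean$truth$true_hits, 0)
})

test_that("fingerprint generator plants recoverable structural clusters", {
  out <- gen_fingerprints(104, n_bits = 128, n_clusters = 8,
                          flip_prob = 0.05, rng_seed = 4)
  expect_equal(dim(out$fps), c(104, 128))
  expect_true(all(out$fps %in% c(0, 1)))
  expect_true(all(rowSums(out$fps) >= 1))
  expect_equal(sort(unique(out$truth$true_clusters)), 1:8)

  sim <- 1 - as.matrix(jaccard_distance(out$fps))
  same <- outer(out$truth$true_clusters, out$truth$true_clusters, `==`)
  diag(same) <- NA
  expect_gt(mean(sim[which(same)]), mean(sim[which(!same)]))

  exact <- gen_fingerprints(20, n_bits = 64, n_clusters = 4, flip_prob = 0,
                            rng_seed = 4)
  sim0 <- 1 - as.matrix(jaccard_distance(exact$fps))
  same0 <- outer(exact$truth$true_clusters, exact$truth$true_clusters, `==`)
  expect_true(all(sim0[which(same0)] == 1))

  one <- gen_fingerprints(10, n_clusters = 1, flip_prob = 0.05, rng_seed = 2)
  expect_true(all(one$truth$true_clusters == 1))
})
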