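#!/usr/bin/env Rscript
# Generate the synthetic study: a scale-free interaction network with a
# co-regulated module planted around three future drug-target genes, a
# chemical-proteomics spectral-count table anchored on those genes, 200
# decoy gene sets plus the planted one, a dose-response matrix with planted
# synergy, a duplicate screen with planted hits, and clustered fingerprints.
# Everything lands under results/fixtures/ with a truth manifest.

library(moanet)

fx <- simulate_fixture("results/fixtures", n_nodes = 500, mean_degree = 10,
                       module_size = 50, logfc_effect = 2, noise_sd = 0.1,
                       n_targets = 11, n_terms = 200, rng_seed = 20260901)

cat(sprintf("network: %d nodes / %d edges\n",
            igraph::vcount(fx$network), igraph::ecount(fx$network)))
cat(sprintf("planted module: %d genes around seeds %s\n",
            length(fx$truth$planted_module),
            paste(fx$truth$seed_genes, collapse = ", ")))
cat(sprintf("targets: %d | gene sets: %d (planted: %s)\n",
            nrow(fx$targets), length(fx$collection), fx$truth$planted_term_id))
cat(sprintf("screen: %d plates, %d planted hits | fingerprints: %d compounds\n",
            length(fx$screen), length(fx$truth$true_hits),
            nrow(fx$fingerprints)))
cat("fixture written to results/fixtures/\n")
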