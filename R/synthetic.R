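#' Synthetic scale-free protein-interaction network
#'
#' Preferential-attachment (Barabasi-Albert) graph trimmed to its largest
#' connected component: PPI degree distributions are heavy-tailed, and the
#' diffusion model assumes a connected network. Edge counts approximate
#' `n_nodes * mean_degree / 2`.
#'
#' @param n_nodes number of nodes (>= 2).
#' @param mean_degree target mean degree (positive, < `n_nodes` - 1).
#' @param rng_seed integer seed; output is deterministic given it.
#' @return an undirected simple connected `igraph` with gene-style node names.
#' @export
gen_ppi_network <- function(n_nodes, mean_degree, rng_seed = 1) {
  if (n_nodes < 2) stop("n_nodes must be >= 2")
  if (mean_degree <= 0 || mean_degree > n_nodes - 1) {
    stop("mean_degree must be positive and at most n_nodes - 1")
  }
  with_rng(rng_seed, {
    # per-node attachment counts averaging mean_degree / 2 edges per node
    target_edges <- round(n_nodes * mean_degree / 2)
    base <- floor(target_edges / (n_nodes - 1))
    extra <- target_edges - base * (n_nodes - 1)
    out_seq <- c(0L, rep(base, n_nodes - 1))
    if (extra > 0) {
      bump <- sample(2:n_nodes, extra)
      out_seq[bump] <- out_seq[bump] + 1L
    }
    g <- igraph::sample_pa(n_nodes, out.seq = out_seq, directed = FALSE)
    g <- igraph::simplify(g)
    comp <- igraph::components(g)
    g <- igraph::induced_subgraph(
      g, which(comp$membership == which.max(comp$csize)))
    igraph::V(g)$name <- sprintf("G%0*d", nchar(igraph::vcount(g)) + 1,
                                 seq_len(igraph::vcount(g)))
    g
  })
}

#' Synthetic expression profile with a planted co-regulated module
#'
#' Control FPKM values are log-normal (shifted above the 0.1 expression
#' floor). A breadth-first neighborhood of `module_size` genes around
#' `n_seeds` randomly chosen future drug-target genes receives log2 fold
#' changes of magnitude centered at `logfc_effect` with random sign per gene
#' (regulation in either direction counts); all other genes get log2 fold
#' change ~ Normal(0, `noise_sd`). Fold changes are stored exactly
#' (`2^lfc`), so the planted effect is not distorted by the FPKM
#' pseudocount.
#'
#' @param network `igraph` network whose nodes are the genes.
#' @param module_size number of co-regulated genes planted around the seeds.
#' @param logfc_effect planted |log2 fold change| center.
#' @param noise_sd sd of background log2 fold changes (and of the planted
#'   magnitude).
#' @param rng_seed integer seed.
#' @param n_seeds number of future drug-target genes anchoring the module.
#' @return list with `profile` (see [expression_profile()]) and `truth`
#'   (fields `planted_module`, `seed_genes`).
#' @export
gen_expression <- function(network, module_size, logfc_effect, noise_sd,
                           rng_seed = 1, n_seeds = 3) {
  n <- igraph::vcount(network)
  if (n == 0L) stop("empty network")
  if (module_size > n) stop("module_size exceeds node count")
  nodes <- igraph::V(network)$name
  with_rng(rng_seed, {
    roots <- sample(nodes, min(n_seeds, n))
    # breadth-first neighborhood: order nodes by hop distance to the roots
    d <- apply(igraph::distances(network, v = roots), 2, min)
    module <- nodes[order(d, seq_len(n))][seq_len(module_size)]
    lfc <- rnorm(n, 0, noise_sd)
    in_mod <- nodes %in% module
    sign <- sample(c(-1, 1), sum(in_mod), replace = TRUE)
    lfc[in_mod] <- sign * (logfc_effect + rnorm(sum(in_mod), 0, noise_sd))
    fpkm_control <- 0.1 + rlnorm(n, meanlog = log(10), sdlog = 1)
    profile <- expression_profile(data.frame(
      gene_id = nodes,
      fpkm_control = fpkm_control,
      fpkm_treated = fpkm_control * 2^lfc,
      fold_change = 2^lfc
    ))
    list(profile = profile,
         truth = list(planted_module = module, seed_genes = roots))
  })
}

#' Synthetic chemical-proteomics spectral-count table
#'
#' Emulates a pull-down experiment: for each target gene a pair of integer
#' spectral counts (immobilized compound, free-drug competition) whose ratio
#' falls inside `ratio_range`.
#'
#' @param network `igraph` network.
#' @param n_targets number of drug targets.
#' @param ratio_range `c(low, high)` bounds on the count ratio, `low >= 1`.
#' @param rng_seed integer seed.
#' @param genes optional character vector to draw targets from (e.g. the
#'   `seed_genes` recorded by [gen_expression()]); defaults to random
#'   network genes.
#' @return data.frame with columns `gene_id`, `sc_immobilized`,
#'   `sc_competition`.
#' @export
gen_targets <- function(network, n_targets, ratio_range = c(2, 20),
                        rng_seed = 1, genes = NULL) {
  nodes <- igraph::V(network)$name
  if (n_targets > length(nodes)) stop("n_targets exceeds node count")
  if (ratio_range[1] < 1) stop("ratio_range low bound must be >= 1")
  if (ratio_range[2] < ratio_range[1]) stop("ratio_range must be ordered")
  with_rng(rng_seed, {
    if (is.null(genes)) {
      genes <- sample(nodes, n_targets)
    } else if (length(genes) >= n_targets) {
      genes <- genes[seq_len(n_targets)]
    } else {
      # anchor on the supplied genes, fill the rest at random
      genes <- c(genes, sample(setdiff(nodes, genes), n_targets - length(genes)))
    }
    comp_candidates <- 5:60
    feasible <- comp_candidates[ceiling(ratio_range[1] * comp_candidates) <=
                                floor(ratio_range[2] * comp_candidates)]
    if (length(feasible) == 0L) {
      stop("ratio_range too narrow for integer spectral counts")
    }
    comp <- sample(feasible, n_targets, replace = TRUE)
    # strongest binding goes to the first genes: when targets are anchored on
    # the module seed genes, the co-regulated response forms around the
    # drug's strongest binders, as the diffusion model assumes
    r <- sort(runif(n_targets, ratio_range[1], ratio_range[2]),
              decreasing = TRUE)
    imm <- pmin(pmax(round(r * comp), ceiling(ratio_range[1] * comp)),
                floor(ratio_range[2] * comp))
    data.frame(gene_id = genes, sc_immobilized = as.integer(imm),
               sc_competition = as.integer(comp))
  })
}

#' Synthetic gene-set collection with one planted seed-proximal term
#'
#' `n_terms` decoy sets drawn uniformly from network genes, plus one term
#' equal to the planted co-regulated module.
#'
#' @param network `igraph` network.
#' @param n_terms number of decoy terms.
#' @param size_range `c(min, max)` decoy set sizes.
#' @param truth truth list from [gen_expression()] (needs a non-empty
#'   `planted_module`).
#' @param rng_seed integer seed.
#' @param planted_term_id identifier of the planted term.
#' @return list with `collection` (named list of gene sets, planted term
#'   included) and `truth` (with `planted_term_id` added).
#' @export
gen_genesets <- function(network, n_terms, size_range = c(10, 200), truth,
                         rng_seed = 1, planted_term_id = "GS_PLANTED") {
  nodes <- igraph::V(network)$name
  if (length(truth$planted_module) == 0L) {
    stop("truth$planted_module is empty; no planted term to emit")
  }
  if (size_range[2] > length(nodes)) stop("size_range exceeds node count")
  collection <- with_rng(rng_seed, {
    sizes <- if (n_terms > 0) {
      sample(size_range[1]:size_range[2], n_terms, replace = TRUE)
    } else integer(0)
    decoys <- lapply(sizes, function(s) sample(nodes, s))
    names(decoys) <- sprintf("GS%04d", seq_len(n_terms))
    decoys
  })
  collection[[planted_term_id]] <- truth$planted_module
  truth$planted_term_id <- planted_term_id
  list(collection = collection, truth = truth)
}

#' Synthetic dose-response matrix with optional planted Bliss interaction
#'
#' Single-agent effects follow Hill curves on two-fold dilution series
#' bracketing each drug's EC50; the combination effect is the Bliss
#' expectation plus `bliss_interaction` plus Gaussian noise, clamped to
#' \[0, 1\]. Viability is `1 - effect`; the untreated well is exactly 1.
#'
#' @param n_doses_x,n_doses_y number of non-zero doses per drug.
#' @param hill_params list with elements `x` and `y`, each
#'   `list(emax=, ec50=, hill=)`.
#' @param bliss_interaction planted deviation from Bliss additivity (> 0 =
#'   synergy).
#' @param noise_sd sd of Gaussian measurement noise on combination wells.
#' @param rng_seed integer seed.
#' @return list with `drm` (a [dose_response_matrix()]), `truth` (field
#'   `synergy_flag`), and `effect_raw` (combination effects before
#'   clamping).
#' @export
gen_dose_response <- function(n_doses_x = 8, n_doses_y = 8,
                              hill_params = list(
                                x = list(emax = 0.8, ec50 = 1, hill = 1),
                                y = list(emax = 0.8, ec50 = 1, hill = 1)),
                              bliss_interaction = 0, noise_sd = 0,
                              rng_seed = 1) {
  hill <- function(d, p) p$emax * d^p$hill / (p$ec50^p$hill + d^p$hill)
  dil <- function(n, ec50) ec50 * 2^(seq_len(n) - ceiling(n / 2))
  dx <- c(0, dil(n_doses_x, hill_params$x$ec50))
  dy <- c(0, dil(n_doses_y, hill_params$y$ec50))
  ex <- hill(dx, hill_params$x)
  ey <- hill(dy, hill_params$y)
  with_rng(rng_seed, {
    e <- outer(ex, ey, bliss_expected)
    interior <- outer(dx > 0, dy > 0, `&`)
    e_raw <- e
    # interaction and measurement noise live on the combination wells;
    # single agents follow the Hill curves exactly
    e_raw[interior] <- e[interior] + bliss_interaction +
      rnorm(sum(interior), 0, noise_sd)
    e_clamped <- pmin(pmax(e_raw, 0), 1)
    drm <- dose_response_matrix(1 - e_clamped, dx, dy, normalize = FALSE)
    list(drm = drm,
         truth = list(synergy_flag = bliss_interaction != 0),
         effect_raw = e_raw)
  })
}

#' Synthetic duplicate screen with planted hit compounds
#'
#' Each plate holds negative (vehicle) and positive (toxic) control wells
#' plus compounds; every plate is produced twice with independent noise
#' (replicates 1 and 2), so each compound appears on two replicate plates.
#' Negative controls are Normal(`mu`, `sigma`); positive controls sit near
#' zero signal; a `hit_fraction` of compounds is shifted down by
#' `hit_effect * sigma`.
#'
#' @param n_plates number of distinct plate layouts (each emitted twice).
#' @param wells_per_plate total wells per plate (controls included).
#' @param n_pos_ctrl,n_neg_ctrl control wells per plate.
#' @param hit_fraction fraction of compounds with a real effect.
#' @param hit_effect planted shift, in units of `sigma`.
#' @param rng_seed integer seed.
#' @param mu,sigma negative-control signal mean and sd (arbitrary
#'   luminescence units).
#' @return list with `plates` (list of plate data.frames) and `truth`
#'   (field `true_hits`).
#' @export
gen_screen <- function(n_plates = 2, wells_per_plate = 384, n_pos_ctrl = 16,
                       n_neg_ctrl = 16, hit_fraction = 0.01, hit_effect = 6,
                       rng_seed = 1, mu = 1000, sigma = 100) {
  n_cmp_per_plate <- wells_per_plate - n_pos_ctrl - n_neg_ctrl
  if (n_cmp_per_plate < 1L) stop("no compound wells left on the plate")
  n_compounds <- n_plates * n_cmp_per_plate
  with_rng(rng_seed, {
    compounds <- sprintf("C%05d", seq_len(n_compounds))
    hits <- compounds[runif(n_compounds) < hit_fraction]
    plates <- list()
    for (p in seq_len(n_plates)) {
      cmp <- compounds[(p - 1) * n_cmp_per_plate + seq_len(n_cmp_per_plate)]
      roles <- c(cmp, rep("NEG", n_neg_ctrl), rep("POS", n_pos_ctrl))
      for (rep_idx in 1:2) {
        signal <- numeric(length(roles))
        is_neg <- roles == "NEG"
        is_pos <- roles == "POS"
        is_cmp <- !is_neg & !is_pos
        centers <- numeric(length(roles))
        centers[is_neg] <- mu
        centers[is_pos] <- 0.02 * mu
        centers[is_cmp] <- ifelse(roles[is_cmp] %in% hits,
                                  mu - hit_effect * sigma, mu)
        spread <- ifelse(is_pos, 0.2 * sigma, sigma)
        signal <- pmax(0, rnorm(length(roles), centers, spread))
        plates[[length(plates) + 1L]] <- data.frame(
          plate_id = sprintf("P%03d", p),
          well_id = sprintf("W%03d", seq_along(roles)),
          compound_id = roles,
          replicate = rep_idx,
          signal = signal
        )
      }
    }
    list(plates = plates, truth = list(true_hits = hits))
  })
}

#' Synthetic binary fingerprints with planted structural clusters
#'
#' Each cluster gets a random prototype bit vector; members are the
#' prototype with independent bit flips at `flip_prob`. Every fingerprint is
#' guaranteed at least one set bit.
#'
#' @param n_compounds number of compounds.
#' @param n_bits fingerprint length.
#' @param n_clusters number of planted scaffold clusters.
#' @param flip_prob per-bit flip probability.
#' @param rng_seed integer seed.
#' @return list with `fps` (binary matrix, compounds in rows) and `truth`
#'   (field `true_clusters`, a named integer partition).
#' @export
gen_fingerprints <- function(n_compounds, n_bits = 128, n_clusters = 8,
                             flip_prob = 0.05, rng_seed = 1) {
  if (n_clusters < 1 || n_clusters > n_compounds) {
    stop("n_clusters must be between 1 and n_compounds")
  }
  with_rng(rng_seed, {
    protos <- matrix(rbinom(n_clusters * n_bits, 1, 0.3),
                     nrow = n_clusters, ncol = n_bits)
    protos[rowSums(protos) == 0, 1] <- 1L
    assignment <- sort(rep_len(seq_len(n_clusters), n_compounds))
    flips <- matrix(rbinom(n_compounds * n_bits, 1, flip_prob),
                    nrow = n_compounds, ncol = n_bits)
    fps <- abs(protos[assignment, , drop = FALSE] - flips)  # XOR
    fps[rowSums(fps) == 0, 1] <- 1L
    rownames(fps) <- sprintf("C%05d", seq_len(n_compounds))
    names(assignment) <- rownames(fps)
    list(fps = fps, truth = list(true_clusters = assignment))
  })
}
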