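#' Generate a scale-free interaction network
#'
#' Preferential-attachment (Barabasi–Albert) graph standing in for a merged
#' human protein interaction network, whose degree distribution is heavy
#' tailed. Each new node attaches to `edges_per_new_node` existing nodes
#' without duplicating edges, so the graph is simple and connected. Node
#' labels are deterministic synthetic gene symbols (`G0001`, `G0002`, ...).
#'
#' @param n_nodes Number of nodes (>= `edges_per_new_node + 1`).
#' @param edges_per_new_node Edges added per new node (>= 1).
#' @param seed Integer seed; identical arguments give identical graphs.
#' @param rewire If `TRUE`, apply degree-preserving rewiring after generation
#'   (an alternative null topology with the same degree sequence).
#' @return An interaction network (`igraph`).
#' @export
generate_scale_free_network <- function(n_nodes, edges_per_new_node = 2,
                                        seed = 1, rewire = FALSE) {
  if (!is.numeric(n_nodes) || !is.numeric(edges_per_new_node) ||
      edges_per_new_node < 1 || n_nodes < edges_per_new_node + 1) {
    stop_param("Require n_nodes >= edges_per_new_node + 1 >= 2.")
  }
  g <- with_seed(seed, {
    g <- igraph::sample_pa(n_nodes, m = edges_per_new_node, directed = FALSE)
    if (rewire) {
      g <- igraph::rewire(g, igraph::keeping_degseq(niter = igraph::ecount(g) * 10))
    }
    g
  })
  igraph::V(g)$name <- sprintf("G%04d", seq_len(n_nodes))
  igraph::simplify(g)
}

#' Plant a connected module in a network
#'
#' Grows a connected gene set of the requested size by seeded random
#' breadth-first expansion from a random start node; the returned set always
#' induces a connected subgraph.
#'
#' @param network An interaction network.
#' @param size Module size (1 <= size <= number of nodes).
#' @param seed Integer seed.
#' @return Sorted character vector of module gene symbols.
#' @export
plant_module <- function(network, size, seed = 1) {
  n <- igraph::vcount(network)
  if (!is.numeric(size) || size < 1 || size > n) {
    stop_param("`size` must satisfy 1 <= size <= number of nodes.")
  }
  comp <- igraph::components(network)
  if (max(comp$csize) < size) {
    abort("Requested module size exceeds the largest connected component.",
          class = "pinmod_error_infeasible")
  }
  with_seed(seed, {
    # start inside a component large enough to host the module
    ok <- which(comp$membership %in% which(comp$csize >= size))
    start <- sample(ok, 1)
    members <- igraph::V(network)$name[start]
    frontier <- setdiff(igraph::neighbors(network, start)$name, members)
    while (length(members) < size) {
      nxt <- if (length(frontier) == 1) frontier else sample(frontier, 1)
      members <- c(members, nxt)
      frontier <- setdiff(
        unique(c(frontier, igraph::neighbors(network, nxt)$name)), members)
    }
    sort(members)
  })
}

#' Assemble the ground truth of a synthetic scenario
#'
#' Bundles the planted module, its per-gene effect signs, the beta-uniform
#' signal parameters and the seed. The miRNA target map and pathway
#' membership slots are filled by their generators.
#'
#' @param network The generated interaction network.
#' @param module_size Planted module size.
#' @param lambda_mix Background (uniform) mixing fraction of the p-value
#'   mixture the scenario realizes.
#' @param a_shape Beta shape of the signal component, in (0,1).
#' @param seed Integer seed.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(network, module_size = 25, lambda_mix = 0.7,
                            a_shape = 0.2, seed = 1) {
  if (a_shape <= 0 || a_shape >= 1) stop_param("`a_shape` must be in (0,1).")
  if (lambda_mix < 0 || lambda_mix > 1) stop_param("`lambda_mix` must be in [0,1].")
  module_genes <- plant_module(network, module_size, seed = child_seed(seed, 1))
  effect_sign <- with_seed(child_seed(seed, 2), {
    setNames(sample(c(-1, 1), length(module_genes), replace = TRUE),
             module_genes)
  })
  structure(
    list(
      module_genes = module_genes,
      effect_sign = effect_sign,
      mirna_targets = list(),
      pathway_membership = list(),
      signal_params = c(lambda_mix = lambda_mix, a_shape = a_shape),
      seed = as.integer(seed)
    ),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> %d module genes, %d miRNA target sets, %d pathways (seed %d)\n",
    length(x$module_genes), length(x$mirna_targets),
    length(x$pathway_membership), x$seed))
  invisible(x)
}

#' Simulate per-gene differential-expression statistics
#'
#' Realizes the beta-uniform mixture assumption that node scoring inverts:
#' p-values of background genes are Uniform(0,1) and p-values of planted
#' module genes are Beta(`signal_a`, 1). Log2 fold changes of module genes
#' are a per-gene signed effect (`truth$effect_sign * effect_logfc`) plus
#' Gaussian noise; background genes are centred at zero.
#'
#' @param network An interaction network providing the gene universe.
#' @param truth A [synthetic_truth()] object with `module_genes` a subset of
#'   the network nodes.
#' @param signal_a Beta shape of the module p-value component, in (0,1).
#' @param effect_logfc Magnitude of the module log2 fold-change effect.
#' @param lfc_noise_sd Standard deviation of the fold-change noise
#'   (default 0.25).
#' @param seed Integer seed.
#' @return A gene-statistics tibble (`gene`, `p_value`, `log_fc`, `fdr`).
#' @export
simulate_gene_stats <- function(network, truth, signal_a = 0.2,
                                effect_logfc = 2, lfc_noise_sd = 0.25,
                                seed = 1) {
  if (signal_a <= 0 || signal_a >= 1) stop_param("`signal_a` must be in (0,1).")
  genes <- igraph::V(network)$name
  if (!all(truth$module_genes %in% genes)) {
    stop_param("truth$module_genes must be a subset of the network nodes.")
  }
  in_mod <- genes %in% truth$module_genes
  with_seed(seed, {
    p <- runif(length(genes))
    p[in_mod] <- rbeta(sum(in_mod), signal_a, 1)
    p <- pmax(p, .Machine$double.xmin)  # keep p in (0,1]
    lfc <- rnorm(length(genes), 0, lfc_noise_sd)
    sgn <- truth$effect_sign[genes[in_mod]]
    lfc[in_mod] <- lfc[in_mod] + sgn * effect_logfc
    tibble(gene = genes, p_value = p, log_fc = as.numeric(lfc),
           fdr = p.adjust(p, "BH"))
  })
}

#' Simulate two-condition log2 expression matrices
#'
#' Control and treated matrices (genes x replicates) on the log2 scale:
#' per-gene Gaussian baselines, Gaussian replicate noise of standard
#' deviation `noise_sd`, and a per-gene signed shift of `effect_logfc` for
#' planted module genes in the treated arm. Defaults mirror a seven-donor
#' hepatocyte culture design (`n_reps = 7` biologic replicates per arm).
#'
#' @param truth A [synthetic_truth()] object.
#' @param genes Character vector of gene symbols (rows).
#' @param n_reps Replicates per arm (>= 2; default 7).
#' @param effect_logfc Module shift magnitude in log2 units (default 4).
#' @param noise_sd Replicate noise standard deviation (default 0.5).
#' @param baseline_mean,baseline_sd Per-gene baseline distribution
#'   (log2 scale; defaults 8 and 2).
#' @param seed Integer seed.
#' @return A list with matrices `control` and `treated`.
#' @export
simulate_expression_matrices <- function(truth, genes, n_reps = 7,
                                         effect_logfc = 4, noise_sd = 0.5,
                                         baseline_mean = 8, baseline_sd = 2,
                                         seed = 1) {
  if (!is.numeric(n_reps) || n_reps < 2) {
    stop_param("`n_reps` must be >= 2 (a two-sample test needs >= 2 per arm).")
  }
  genes <- as.character(genes)
  in_mod <- genes %in% truth$module_genes
  with_seed(seed, {
    base <- rnorm(length(genes), baseline_mean, baseline_sd)
    shift <- numeric(length(genes))
    shift[in_mod] <- truth$effect_sign[genes[in_mod]] * effect_logfc
    control <- base + matrix(rnorm(length(genes) * n_reps, 0, noise_sd),
                             nrow = length(genes))
    treated <- base + shift + matrix(rnorm(length(genes) * n_reps, 0, noise_sd),
                                     nrow = length(genes))
    dimnames(control) <- list(genes, sprintf("C%02d", seq_len(n_reps)))
    dimnames(treated) <- list(genes, sprintf("T%02d", seq_len(n_reps)))
    list(control = control, treated = treated)
  })
}

#' Simulate a miRNA layer with anti-correlated module targeting
#'
#' A fraction of miRNAs is designated significant (p drawn below 0.05); each
#' significant miRNA receives a direction (fold change above or below 1) and
#' target genes drawn from planted module genes whose log2 fold-change sign
#' is opposite to the miRNA's direction, topped up with random background
#' genes when the module offers too few compatible targets. Non-significant
#' miRNAs receive Uniform(0,1) p-values and random targets. Every pair is
#' labelled with 1–4 synthetic source-database names.
#'
#' @param truth A [synthetic_truth()] object (supplies module genes and
#'   effect signs).
#' @param genes Gene universe to draw background targets from.
#' @param n_mirnas Number of miRNAs (>= 1).
#' @param targets_per_mirna Targets per miRNA (>= 1).
#' @param frac_significant Fraction of miRNAs that are significant.
#' @param seed Integer seed.
#' @return A list with `mirna_stats` (tibble: `mirna`, `p_value`,
#'   `fold_change`) and `target_pairs` (tibble: `mirna`, `gene`, `sources`).
#' @export
simulate_mirna_layer <- function(truth, genes, n_mirnas = 50,
                                 targets_per_mirna = 10,
                                 frac_significant = 0.3, seed = 1) {
  if (n_mirnas < 1 || targets_per_mirna < 1) {
    stop_param("`n_mirnas` and `targets_per_mirna` must be >= 1.")
  }
  if (frac_significant < 0 || frac_significant > 1) {
    stop_param("`frac_significant` must be in [0,1].")
  }
  genes <- as.character(genes)
  source_names <- c("predictdb1", "predictdb2", "predictdb3", "validated")
  with_seed(seed, {
    ids <- sprintf("mir-%03d", seq_len(n_mirnas))
    n_sig <- round(frac_significant * n_mirnas)
    sig <- seq_len(n_mirnas) <= n_sig
    p <- runif(n_mirnas)
    p[sig] <- runif(n_sig, 0, 0.05)
    up_genes <- names(truth$effect_sign)[truth$effect_sign > 0]
    down_genes <- names(truth$effect_sign)[truth$effect_sign < 0]
    fold_change <- numeric(n_mirnas)
    pair_list <- vector("list", n_mirnas)
    for (i in seq_len(n_mirnas)) {
      if (sig[i]) {
        # an up-miRNA must have downregulated targets and vice versa
        feasible <- c("up", "down")[c(length(down_genes) > 0, length(up_genes) > 0)]
        dir <- if (length(feasible) == 1) feasible else sample(feasible, 1)
        fold_change[i] <- if (dir == "up") runif(1, 1.2, 3) else runif(1, 0.3, 0.85)
        pool <- if (dir == "up") down_genes else up_genes
        k_mod <- min(targets_per_mirna, length(pool))
        tg <- if (k_mod == 0) character() else
          if (length(pool) == 1) pool else sample(pool, k_mod)
        extra <- targets_per_mirna - length(tg)
        if (extra > 0) {
          tg <- c(tg, sample(setdiff(genes, c(tg, truth$module_genes)), extra))
        }
      } else {
        fold_change[i] <- exp(rnorm(1, 0, 0.3))
        tg <- sample(genes, min(targets_per_mirna, length(genes)))
      }
      pair_list[[i]] <- tibble(mirna = ids[i], gene = tg)
    }
    pairs <- bind_rows(pair_list)
    pairs$sources <- vapply(seq_len(nrow(pairs)), function(j) {
      paste(sort(sample(source_names, sample(1:4, 1))), collapse = ";")
    }, "")
    list(
      mirna_stats = tibble(mirna = ids, p_value = p, fold_change = fold_change),
      target_pairs = pairs
    )
  })
}

#' Generate pathway gene sets with known enriched truth
#'
#' `enriched_sets` pathways oversample the planted module (at least half of
#' each enriched set's members are module genes, capped by module size); the
#' remaining sets are uniform draws from the gene universe. Set sizes are
#' uniform in `set_size_range`. Enriched sets receive names containing the
#' keyword `"drug"` so the focus-term stage can recognize them; background
#' sets get neutral names.
#'
#' @param genes Gene universe.
#' @param truth A [synthetic_truth()] object.
#' @param n_sets Number of pathways.
#' @param set_size_range Length-2 integer vector of minimum and maximum set
#'   size.
#' @param enriched_sets Number of module-enriched pathways (<= `n_sets`).
#' @param seed Integer seed.
#' @return A [pathway_collection()]; the ids of the enriched sets are stored
#'   in its `enriched` attribute (and belong in `truth$pathway_membership`).
#' @export
generate_pathway_sets <- function(genes, truth, n_sets = 30,
                                  set_size_range = c(10, 40),
                                  enriched_sets = 3, seed = 1) {
  if (enriched_sets > n_sets) stop_param("`enriched_sets` must be <= `n_sets`.")
  if (max(set_size_range) > length(genes)) {
    stop_param("Upper bound of `set_size_range` exceeds the gene universe.")
  }
  genes <- as.character(genes)
  with_seed(seed, {
    ids <- sprintf("P%03d", seq_len(n_sets))
    sizes <- sample(seq(set_size_range[1], set_size_range[2]), n_sets,
                    replace = TRUE)
    member <- vector("list", n_sets)
    for (i in seq_len(n_sets)) {
      if (i <= enriched_sets) {
        k_mod <- min(ceiling(sizes[i] / 2), length(truth$module_genes))
        from_mod <- sample(truth$module_genes, k_mod)
        rest <- sample(setdiff(genes, from_mod), sizes[i] - k_mod)
        member[[i]] <- sort(c(from_mod, rest))
      } else {
        member[[i]] <- sort(sample(genes, sizes[i]))
      }
    }
    nm <- ifelse(seq_len(n_sets) <= enriched_sets,
                 sprintf("drug response set %d", seq_len(n_sets)),
                 sprintf("pathway %d", seq_len(n_sets)))
    cat_lab <- rep(c("GO_BP", "KEGG"), length.out = n_sets)
    sets <- tibble(pathway = ids, name = nm, category = cat_lab,
                   genes = member)
    out <- pathway_collection(sets, universe = genes)
    attr(out, "enriched") <- ids[seq_len(enriched_sets)]
    out
  })
}
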