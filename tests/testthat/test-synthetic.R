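test_that("scale-free generator obeys the attachment scheme's edge count", {
  tree <- generate_scale_free_network(5, 1, seed = 1)
  expect_equal(igraph::vcount(tree), 5)
  expect_equal(igraph::ecount(tree), 4)
  expect_true(igraph::is_connected(tree))

  # m = 2: the second node can only attach once, every later node twice
  g <- generate_scale_free_network(200, 2, seed = 7)
  expect_equal(igraph::ecount(g), 1 + 2 * (200 - 2))
  expect_true(igraph::is_simple(g))
  expect_true(igraph::is_connected(g))

  expect_identical(network_edges(generate_scale_free_network(50, 2, seed = 3)),
                   network_edges(generate_scale_free_network(50, 2, seed = 3)))
  expect_false(identical(
    network_edges(generate_scale_free_network(50, 2, seed = 3)),
    network_edges(generate_scale_free_network(50, 2, seed = 4))))
  expect_error(generate_scale_free_network(2, 2), class = "pinmod_error_parameter")
})

test_that("planted modules are connected subgraphs of the requested size", {
  p5 <- path_graph(sprintf("P%d", 1:5))
  expect_length(plant_module(p5, 1, seed = 0), 1)
  expect_setequal(plant_module(p5, 5, seed = 3), sprintf("P%d", 1:5))

  net <- generate_scale_free_network(200, 2, seed = 1)
  mod <- plant_module(net, 20, seed = 9)
  expect_length(mod, 20)
  expect_true(igraph::is_connected(igraph::induced_subgraph(net, mod)))
  expect_identical(plant_module(net, 20, seed = 9), mod)

  # infeasible: module larger than the biggest component
  two_comp <- interaction_network(data.frame(a = c("A", "C"), b = c("B", "D")))
  expect_error(plant_module(two_comp, 3), class = "pinmod_error_infeasible")
})

test_that("simulated gene statistics realize the beta-uniform mixture", {
  net <- generate_scale_free_network(10500, 2, seed = 2)
  truth <- synthetic_truth(net, module_size = 500, seed = 2)
  stats <- simulate_gene_stats(net, truth, signal_a = 0.2, effect_logfc = 2,
                               seed = 11)
  in_mod <- stats$gene %in% truth$module_genes
  # mean of Beta(a, 1) is a / (a + 1); n = 500 module genes
  m <- 0.2 / 1.2
  se <- sqrt(0.2 / (1.2^2 * 2.2)) / sqrt(500)
  expect_lt(abs(mean(stats$p_value[in_mod]) - m), 3 * se)
  # background is Uniform(0, 1) at n = 10^4 (KS)
  ks <- suppressWarnings(ks.test(stats$p_value[!in_mod], "punif"))
  expect_gt(ks$p.value, 0.01)
  # signed effects follow the truth's per-gene signs
  sgn <- truth$effect_sign[stats$gene[in_mod]]
  expect_gt(mean(sign(stats$log_fc[in_mod]) == sgn), 0.95)
  expect_identical(stats,
                   simulate_gene_stats(net, truth, signal_a = 0.2,
                                       effect_logfc = 2, seed = 11))
  expect_error(simulate_gene_stats(net, truth, signal_a = 1.2),
               class = "pinmod_error_parameter")
})

test_that("expression simulation yields calibrated nulls and powered effects", {
  net <- generate_scale_free_network(300, 2, seed = 4)
  truth <- synthetic_truth(net, module_size = 20, seed = 4)
  genes <- igraph::V(net)$name

  null_expr <- simulate_expression_matrices(truth, genes, n_reps = 7,
                                            effect_logfc = 0, seed = 5)
  p0 <- de_test(null_expr$control, null_expr$treated)$p_value
  expect_gt(suppressWarnings(ks.test(p0, "punif"))$p.value, 0.01)

  # Welch power at shift 4, noise 0.5, n = 7: essentially certain detection
  rec <- vapply(1:20, function(s) {
    e <- simulate_expression_matrices(truth, genes, n_reps = 7,
                                      effect_logfc = 4, noise_sd = 0.5,
                                      seed = s)
    st <- de_test(e$control, e$treated)
    mean(st$p_value[st$gene %in% truth$module_genes] < 0.01)
  }, 0)
  expect_gt(mean(rec), 0.95)

  expect_identical(simulate_expression_matrices(truth, genes, seed = 8),
                   simulate_expression_matrices(truth, genes, seed = 8))
  expect_error(simulate_expression_matrices(truth, genes, n_reps = 1),
               class = "pinmod_error_parameter")
})

test_that("miRNA layer respects significance fraction and anti-correlation", {
  net <- generate_scale_free_network(200, 2, seed = 6)
  truth <- synthetic_truth(net, module_size = 15, seed = 6)
  genes <- igraph::V(net)$name

  # frac_significant = 0: only chance discoveries at p < 0.05
  counts <- vapply(1:50, function(s) {
    layer <- simulate_mirna_layer(truth, genes, n_mirnas = 40,
                                  frac_significant = 0, seed = s)
    sum(layer$mirna_stats$p_value < 0.05)
  }, 0)
  expect_lte(mean(counts), 0.05 * 40 + 3 * sqrt(40 * 0.05 * 0.95 / 50))

  # a single downregulated target forces an upregulated miRNA
  mono <- structure(
    list(module_genes = "G001", effect_sign = c(G001 = -1),
         mirna_targets = list(), pathway_membership = list(),
         signal_params = c(lambda_mix = 0.7, a_shape = 0.2), seed = 1L),
    class = "synthetic_truth")
  layer1 <- simulate_mirna_layer(mono, genes, n_mirnas = 1,
                                 targets_per_mirna = 1,
                                 frac_significant = 1, seed = 3)
  expect_gt(layer1$mirna_stats$fold_change, 1)
  expect_equal(layer1$target_pairs$gene, "G001")

  l2 <- simulate_mirna_layer(truth, genes, seed = 12)
  expect_identical(l2, simulate_mirna_layer(truth, genes, seed = 12))
  # source labels come from exactly four synthetic databases
  srcs <- unique(unlist(strsplit(l2$target_pairs$sources, ";")))
  expect_true(all(srcs %in% c("predictdb1", "predictdb2", "predictdb3",
                              "validated")))
})

test_that("pathway generator plants enriched sets and respects bounds", {
  net <- generate_scale_free_network(300, 2, seed = 8)
  truth <- synthetic_truth(net, module_size = 20, seed = 8)
  genes <- igraph::V(net)$name
  pw <- generate_pathway_sets(genes, truth, n_sets = 12,
                              set_size_range = c(10, 30),
                              enriched_sets = 3, seed = 9)
  expect_s3_class(pw, "pathway_collection")
  expect_equal(nrow(pw$sets), 12)
  sizes <- lengths(pw$sets$genes)
  expect_true(all(sizes >= 10 & sizes <= 30))
  enriched <- attr(pw, "enriched")
  expect_length(enriched, 3)
  for (id in enriched) {
    set <- pw$sets$genes[[match(id, pw$sets$pathway)]]
    expect_gte(length(intersect(set, truth$module_genes)) / length(set),
               0.4)  # at least ~half planted from the module
  }
  expect_identical(
    generate_pathway_sets(genes, truth, n_sets = 12,
                          set_size_range = c(10, 30), enriched_sets = 3,
                          seed = 9)$sets,
    pw$sets)
  expect_error(generate_pathway_sets(genes[1:20], truth, n_sets = 3,
                                     set_size_range = c(10, 25),
                                     enriched_sets = 0),
               class = "pinmod_error_parameter")
})
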