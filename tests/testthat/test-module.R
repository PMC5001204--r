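test_that("degenerate score patterns give the contractual modules", {
  g <- random_scored_graph(8, 0.4, seed = 1)
  neg <- as_scored(g$network, -abs(g$scores) - 0.1)
  expect_warning(mod <- max_scoring_subnetwork(neg), "empty module")
  expect_length(mod$genes, 0)

  # one positive component, peripheral negatives: module = that component
  pg <- path_graph(c("A", "B", "C", "D", "E"))
  sc <- c(A = -1, B = 2, C = 3, D = -5, E = 1)
  mod <- max_scoring_subnetwork(as_scored(pg, sc), method = "exact")
  expect_equal(mod$genes, c("B", "C"))
  expect_equal(mod$aggregate_score, 5)
  # a profitable bridge through a negative connector is taken
  sc2 <- c(A = -1, B = 2, C = 3, D = -0.5, E = 1)
  mod2 <- max_scoring_subnetwork(as_scored(pg, sc2), method = "exact")
  expect_equal(mod2$genes, c("B", "C", "D", "E"))
})

test_that("exact and heuristic searches agree with the enumeration oracle", {
  n_exact_match <- 0
  n_heur_match <- 0
  n_inst <- 40
  for (s in seq_len(n_inst)) {
    g <- random_scored_graph(sample(6:12, 1), runif(1, 0.2, 0.5), seed = 1000 + s)
    oracle <- oracle_best_connected(g$network, g$scores)
    scored <- as_scored(g$network, g$scores)
    if (oracle$score == 0) next
    ex <- suppressWarnings(max_scoring_subnetwork(scored, method = "exact"))
    he <- suppressWarnings(max_scoring_subnetwork(scored, method = "heuristic"))
    expect_equal(ex$aggregate_score, oracle$score, tolerance = 1e-9)
    n_exact_match <- n_exact_match + 1
    # heuristic is valid (never exceeds optimum) and at least as good as
    # its guaranteed floor, the best single positive component
    expect_lte(he$aggregate_score, oracle$score + 1e-9)
    pos <- g$scores[g$scores > 0]
    comp <- igraph::components(
      igraph::induced_subgraph(g$network, names(pos)))
    floor_score <- max(vapply(seq_len(comp$no), function(k) {
      sum(pos[names(comp$membership)[comp$membership == k]])
    }, 0))
    expect_gte(he$aggregate_score, floor_score - 1e-9)
    if (abs(he$aggregate_score - oracle$score) < 1e-9) {
      n_heur_match <- n_heur_match + 1
    }
  }
  message(sprintf("heuristic matched the optimum on %d/%d instances",
                  n_heur_match, n_exact_match))
  expect_gt(n_heur_match / max(n_exact_match, 1), 0.7)
})

test_that("module objects carry consistent scores, edges and tidiers", {
  g <- random_scored_graph(10, 0.4, seed = 5)
  scored <- as_scored(g$network, g$scores)
  mod <- suppressWarnings(max_scoring_subnetwork(scored))
  expect_equal(mod$aggregate_score, sum(g$scores[mod$genes]), tolerance = 1e-9)
  expect_true(all(mod$edges$from %in% mod$genes) &&
                all(mod$edges$to %in% mod$genes))
  if (length(mod$genes) > 0) {
    expect_true(igraph::is_connected(
      igraph::induced_subgraph(g$network, mod$genes)))
  }
  expect_equal(nrow(tidy(mod)), length(mod$genes))
  expect_equal(glance(mod)$n_edges, nrow(mod$edges))
})

test_that("module size shrinks with stricter FDR and truth rows are exact", {
  shrinks <- vapply(1:20, function(s) {
    net <- generate_scale_free_network(300, 2, seed = s)
    truth <- synthetic_truth(net, module_size = 20, seed = s)
    stats <- simulate_gene_stats(net, truth, signal_a = 0.1, seed = s)
    scan <- suppressMessages(fdr_scan(net, stats,
                                      fdr_grid = 10^seq(-6, -1),
                                      truth = truth$module_genes))
    all(diff(scan$table$module_size) >= 0)
  }, TRUE)
  expect_gte(mean(shrinks), 0.9)  # monotone tau; rare heuristic ties allowed

  # a scan whose module equals the truth at some FDR reports tp = precision = 1
  net <- generate_scale_free_network(400, 2, seed = 99)
  truth <- synthetic_truth(net, module_size = 15, seed = 99)
  stats <- simulate_gene_stats(net, truth, signal_a = 0.05, seed = 99)
  scan <- suppressMessages(fdr_scan(net, stats, fdr_grid = 10^seq(-7, -2),
                                    truth = truth$module_genes))
  expect_equal(scan$table$f1[scan$table$fdr == scan$selected_fdr],
               max(scan$table$f1))
  expect_s3_class(tidy(scan), "tbl_df")
  expect_error(fdr_scan(net, stats, fdr_grid = numeric(0)),
               class = "pinmod_error_parameter")
})

test_that("size-band selection picks the smallest qualifying FDR", {
  net <- generate_scale_free_network(400, 2, seed = 12)
  truth <- synthetic_truth(net, module_size = 20, seed = 12)
  stats <- simulate_gene_stats(net, truth, signal_a = 0.05, seed = 12)
  scan <- suppressMessages(fdr_scan(net, stats, fdr_grid = 10^seq(-7, -2),
                                    size_band = c(5, 60)))
  tab <- scan$table
  in_band <- tab$fdr[tab$module_size >= 5 & tab$module_size <= 60]
  expect_equal(scan$selected_fdr, min(in_band))
})

test_that("active modules are disjoint, null-calibrated, and recover planted cliques", {
  # null: all p equal -> calibrated scores are not extreme
  net <- generate_scale_free_network(80, 2, seed = 21)
  flat <- tibble::tibble(gene = igraph::V(net)$name, p_value = 0.5)
  mods <- suppressWarnings(active_modules(net, flat, n_modules = 3, seed = 1))
  for (m in mods) expect_lt(abs(attr(m, "calibrated_score")), 3)

  # planted clique of low-p genes
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    base <- igraph::sample_gnp(60, 0.05)
    igraph::V(base)$name <- sprintf("G%02d", 1:60)
    clique_genes <- sprintf("G%02d", 1:6)
    extra <- t(combn(clique_genes, 2))
    net2 <- merge_networks(
      base, interaction_network(data.frame(a = extra[, 1], b = extra[, 2])))
    p <- runif(60, 0.05, 1)
    names(p) <- sprintf("G%02d", 1:60)
    p[clique_genes] <- runif(6, 0, 1e-4)
    stats <- tibble::tibble(gene = names(p), p_value = as.numeric(p))
    top <- suppressWarnings(
      active_modules(net2, stats, n_modules = 1, max_depth = 2, seed = s))[[1]]
    if (length(intersect(top$genes, clique_genes)) >= 0.8 * 6) hits <- hits + 1
  }
  expect_gte(hits, 8)

  # overlap = 0 contract: pairwise disjoint
  net3 <- generate_scale_free_network(100, 2, seed = 31)
  truth <- synthetic_truth(net3, module_size = 10, seed = 31)
  stats3 <- simulate_gene_stats(net3, truth, seed = 31)
  mods3 <- suppressWarnings(active_modules(net3, stats3, n_modules = 4, seed = 2))
  genes_all <- unlist(lapply(mods3, function(m) m$genes))
  expect_equal(anyDuplicated(genes_all), 0)
  # determinism under seed
  mods3b <- suppressWarnings(active_modules(net3, stats3, n_modules = 4, seed = 2))
  expect_identical(lapply(mods3, function(m) m$genes),
                   lapply(mods3b, function(m) m$genes))
})
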