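toy_collection <- function() {
  universe <- sprintf("G%02d", 1:20)
  pathway_collection(
    tibble::tibble(
      pathway = c("P1", "P2"),
      name = c("drug handling", "housekeeping"),
      category = c("KEGG", "GO_BP"),
      genes = list(sprintf("G%02d", 1:5), sprintf("G%02d", 6:15))),
    universe = universe)
}

test_that("hypergeometric p equals the exact combinatorial tail", {
  pw <- toy_collection()
  # query of 5 = pathway of 5, full overlap: p = 1 / C(20, 5)
  res <- hypergeometric_enrich(sprintf("G%02d", 1:5), pw)
  expect_equal(res$p_value[res$pathway == "P1"], 1 / choose(20, 5),
               tolerance = 1e-12)
  expect_equal(res$count[res$pathway == "P1"], 5)
  expect_equal(res$percent[res$pathway == "P1"], 100)
  # query = universe: every pathway fully covered at p = 1
  res2 <- hypergeometric_enrich(pw$universe, pw)
  expect_equal(res2$p_value, c(1, 1))
  expect_equal(res2$count, lengths(pw$sets$genes)[match(res2$pathway, pw$sets$pathway)])
  # empty query
  expect_equal(nrow(hypergeometric_enrich(character(0), pw)), 0)
  # genes outside the universe are dropped with a message
  expect_message(hypergeometric_enrich(c("G01", "NOPE"), pw), "dropped")
})

test_that("hypergeometric p matches a permutation estimate (spot check)", {
  set.seed(7)
  universe <- sprintf("U%02d", 1:40)
  for (i in 1:3) {
    set_genes <- sample(universe, 10)
    query <- sample(universe, 8)
    pw <- pathway_collection(
      tibble::tibble(pathway = "S", name = "S", category = "KEGG",
                     genes = list(set_genes)),
      universe = universe)
    p <- hypergeometric_enrich(query, pw)$p_value
    obs <- length(intersect(query, set_genes))
    B <- 5000
    perm <- vapply(seq_len(B), function(b) {
      length(intersect(sample(universe, 8), set_genes)) >= obs
    }, TRUE)
    phat <- mean(perm)
    se <- sqrt(p * (1 - p) / B)
    expect_lt(abs(p - phat), 3 * se + 2 / B)
  }
})

test_that("BH adjustment preserves the p-value ordering", {
  set.seed(8)
  universe <- sprintf("U%03d", 1:100)
  sets <- tibble::tibble(
    pathway = sprintf("P%d", 1:15), name = sprintf("P%d", 1:15),
    category = "KEGG",
    genes = lapply(1:15, function(i) sample(universe, sample(5:20, 1))))
  pw <- pathway_collection(sets, universe)
  res <- hypergeometric_enrich(sample(universe, 12), pw)
  expect_true(all(res$adjusted_p >= res$p_value))
  # rows arrive sorted by p; BH must be monotone along that order
  expect_true(all(diff(res$adjusted_p) >= -1e-12))
})

test_that("focus-term selection joins keyword GO rows with top KEGG rows", {
  rows <- tibble::tibble(
    name = c("response to drug", "apoptosis", "K1", "K2", "K3"),
    category = c("GO_BP", "GO_BP", "KEGG", "KEGG", "KEGG"),
    p_value = c(0.03, 0.001, 0.01, 0.02, 0.04))
  sel <- select_focus_terms(rows, top_kegg = 2)
  expect_equal(sel$name, c("K1", "K2", "response to drug"))
  # fewer KEGG rows than requested: all kept, no keyword GO matches
  sel2 <- select_focus_terms(rows[2:4, ], top_kegg = 6)
  expect_equal(sort(sel2$name), c("K1", "K2"))
  # duplicate names across categories collapse
  dup <- tibble::tibble(name = c("metabolism of drug", "metabolism of drug"),
                        category = c("GO_BP", "KEGG"),
                        p_value = c(0.01, 0.02))
  expect_equal(nrow(select_focus_terms(dup, top_kegg = 6)), 1)
})

test_that("key-gene extraction is a normalized union", {
  terms <- tibble::tibble(
    name = c("t1", "t2"),
    genes = list(c("a", "B"), c("b", "C")))
  expect_equal(extract_key_genes(terms), c("A", "B", "C"))
  expect_equal(extract_key_genes("t1", term_genes = list(t1 = c("x", "y"))),
               c("X", "Y"))
  expect_error(extract_key_genes("t9", term_genes = list(t1 = "x")),
               class = "pinmod_error_parameter")
  # brute-force union oracle on random lists
  set.seed(9)
  tg <- lapply(1:6, function(i) sample(LETTERS, sample(3:10, 1)))
  names(tg) <- sprintf("t%d", 1:6)
  expect_setequal(extract_key_genes(names(tg), term_genes = tg),
                  unique(unlist(tg)))
})

test_that("relative abundance is the query fraction per focal pathway", {
  pw <- toy_collection()
  ra <- relative_abundance(sprintf("G%02d", 1:5), pw, "P1")
  expect_equal(ra$e_value, 1)
  ra2 <- relative_abundance(sprintf("G%02d", c(1, 2, 3, 16:22)), pw, c("P1", "P2"))
  expect_equal(ra2$e_value[ra2$pathway == "P1"], 0.3)
  expect_equal(ra2$s_count[ra2$pathway == "P1"], 3)
  # per-pathway denominator variant
  ra3 <- relative_abundance(sprintf("G%02d", 1:5), pw, "P1",
                            denominator = "pathway")
  expect_equal(ra3$n_total, 5)
  expect_error(relative_abundance(character(0), pw, "P1"),
               class = "pinmod_error_parameter")
  expect_error(relative_abundance("G01", pw, "P99"),
               class = "pinmod_error_parameter")
})

test_that("module genes are more concentrated on planted pathways than all SDGs", {
  # the stated default world: 1000 genes, module of 25, log2 shift 4 at
  # noise 0.5 with 7 replicates per arm, so the SDG list mixes the module
  # with uniformly scattered false positives
  wins <- vapply(1:20, function(s) {
    net <- generate_scale_free_network(1000, 2, seed = s)
    truth <- synthetic_truth(net, module_size = 25, seed = s)
    genes <- igraph::V(net)$name
    expr <- simulate_expression_matrices(truth, genes, n_reps = 7,
                                         effect_logfc = 4, noise_sd = 0.5,
                                         seed = s)
    stats <- de_test(expr$control, expr$treated)
    sdgs <- select_sdgs(stats, 0.01)
    pw <- generate_pathway_sets(genes, truth, n_sets = 15,
                                set_size_range = c(10, 30),
                                enriched_sets = 3, seed = s)
    enriched <- attr(pw, "enriched")
    rrpin <- suppressMessages(induce_subnetwork(net, sdgs))
    scan <- suppressMessages(
      fdr_scan(rrpin, stats, fit = fit_bum(stats$p_value),
               fdr_grid = 10^seq(-6, -2), truth = truth$module_genes))
    mod_genes <- scan$module$genes
    if (length(mod_genes) == 0 || length(sdgs) == 0) return(NA)
    e_mod <- relative_abundance(mod_genes, pw, enriched)$e_value
    e_sdg <- relative_abundance(sdgs, pw, enriched)$e_value
    all(e_mod >= e_sdg)
  }, TRUE)
  expect_gte(mean(wins, na.rm = TRUE), 0.9)
})

test_that("GMT files round-trip", {
  pw <- toy_collection()
  f <- withr::local_tempfile()
  write_gmt(pw, f)
  back <- read_gmt(f, universe = pw$universe)
  expect_equal(back$sets$genes, pw$sets$genes)
  expect_equal(back$sets$pathway, pw$sets$pathway)
  bad <- withr::local_tempfile(lines = "just_a_name\tdesc")
  expect_error(read_gmt(bad), class = "pinmod_error_parse")
})
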