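#' Synthetic scenario parameters
#'
#' Defaults describe the stated world the generator emulates: a
#' scale-free interaction network of 1000 genes, a planted connected module
#' of 25 genes, two-condition log2 expression with 7 biologic replicates
#' per arm, a module shift of 4 log2 units against replicate noise of 0.5,
#' a 50-miRNA layer with 30% significant miRNAs targeting module genes
#' anti-correlatedly, and 30 pathway sets of which 3 oversample the module.
#'
#' @param n_nodes,edges_per_new_node Network size and attachment density.
#' @param module_size Planted module size.
#' @param n_reps Replicates per arm.
#' @param effect_logfc,noise_sd Module shift and replicate noise (log2).
#' @param stats_source `"expression"` (default; statistics via [de_test()])
#'   or `"pvalues"` (direct beta-uniform draws via [simulate_gene_stats()]).
#' @param signal_a Beta shape used when `stats_source = "pvalues"`.
#' @param n_mirnas,targets_per_mirna,frac_significant miRNA layer shape.
#' @param n_sets,set_size_range,enriched_sets Pathway collection shape.
#' @return A list of scenario parameters.
#' @export
synthetic_scenario <- function(n_nodes = 1000, edges_per_new_node = 2,
                               module_size = 25, n_reps = 7,
                               effect_logfc = 4, noise_sd = 0.5,
                               stats_source = c("expression", "pvalues"),
                               signal_a = 0.2,
                               n_mirnas = 50, targets_per_mirna = 10,
                               frac_significant = 0.3,
                               n_sets = 30, set_size_range = c(10, 40),
                               enriched_sets = 3) {
  list(n_nodes = n_nodes, edges_per_new_node = edges_per_new_node,
       module_size = module_size, n_reps = n_reps,
       effect_logfc = effect_logfc, noise_sd = noise_sd,
       stats_source = match.arg(stats_source), signal_a = signal_a,
       n_mirnas = n_mirnas, targets_per_mirna = targets_per_mirna,
       frac_significant = frac_significant, n_sets = n_sets,
       set_size_range = set_size_range, enriched_sets = enriched_sets)
}

#' Pipeline configuration
#'
#' Collects every tunable threshold of the workflow in one validated
#' object; stage code never hard-codes a threshold. Either a synthetic
#' `scenario` or file `inputs` must be given (not neither).
#'
#' @param scenario A [synthetic_scenario()] list, or `NULL` when file
#'   inputs are used.
#' @param inputs A list of file paths: `networks` (character vector of edge
#'   lists), either `control`/`treated` expression TSVs or a `gene_stats`
#'   TSV, `mirna_stats`, `target_pairs`, `gmt`; `NULL` for synthetic runs.
#' @param sdg_alpha Gene significance threshold, strict `<` (default 0.01,
#'   uncorrected).
#' @param mirna_alpha miRNA significance threshold, strict `<`
#'   (default 0.05).
#' @param fdr Default module FDR recorded in the configuration
#'   (default 1e-4).
#' @param fdr_grid FDR grid scanned by [fdr_scan()].
#' @param size_band Module-size band for truth-free FDR selection.
#' @param n_modules,max_depth,overlap Active-module search parameters
#'   (defaults 5, 2, 0).
#' @param hub_min_degree Hub degree threshold (default 4).
#' @param keywords,top_kegg Focus-term selection parameters.
#' @param min_sources,required_sources Target-pair combination rule.
#' @param extension_levels Interaction levels for the key-gene extension
#'   network (default 1).
#' @param seed Master seed; all randomness derives from it.
#' @param out_dir Output directory (`NULL` to skip writing files).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = synthetic_scenario(), inputs = NULL,
                            sdg_alpha = 0.01, mirna_alpha = 0.05,
                            fdr = 1e-4, fdr_grid = 10^seq(-8, -1),
                            size_band = c(10, 100),
                            n_modules = 5, max_depth = 2, overlap = 0,
                            hub_min_degree = 4,
                            keywords = c("drug", "metabolism"), top_kegg = 6,
                            min_sources = 1, required_sources = NULL,
                            extension_levels = 1,
                            seed = 1, out_dir = NULL) {
  if (is.null(scenario) && is.null(inputs)) {
    stop_param("Provide either a synthetic `scenario` or file `inputs`.")
  }
  stopifnot(sdg_alpha > 0, sdg_alpha < 1, mirna_alpha > 0, mirna_alpha < 1,
            fdr > 0, fdr < 1, all(fdr_grid > 0 & fdr_grid < 1),
            n_modules >= 1, max_depth >= 0, overlap >= 0, overlap <= 1,
            hub_min_degree >= 0, top_kegg >= 0, min_sources >= 1,
            extension_levels >= 0)
  structure(
    list(scenario = scenario, inputs = inputs, sdg_alpha = sdg_alpha,
         mirna_alpha = mirna_alpha, fdr = fdr, fdr_grid = sort(fdr_grid),
         size_band = size_band, n_modules = n_modules,
         max_depth = max_depth, overlap = overlap,
         hub_min_degree = hub_min_degree, keywords = keywords,
         top_kegg = top_kegg, min_sources = min_sources,
         required_sources = required_sources,
         extension_levels = extension_levels,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)),
          class = c("pinmod_error_stage", "pinmod_error"),
          stage = name, parent = e)
  })
}

# Generate every synthetic input for a run from the master seed.
generate_scenario_inputs <- function(sc, seed) {
  network <- generate_scale_free_network(sc$n_nodes, sc$edges_per_new_node,
                                         seed = child_seed(seed, 11))
  truth <- synthetic_truth(network, module_size = sc$module_size,
                           seed = child_seed(seed, 12))
  genes <- igraph::V(network)$name
  if (sc$stats_source == "expression") {
    expr <- simulate_expression_matrices(
      truth, genes, n_reps = sc$n_reps, effect_logfc = sc$effect_logfc,
      noise_sd = sc$noise_sd, seed = child_seed(seed, 13))
    stats <- de_test(expr$control, expr$treated)
  } else {
    expr <- NULL
    stats <- simulate_gene_stats(network, truth, signal_a = sc$signal_a,
                                 effect_logfc = sc$effect_logfc,
                                 seed = child_seed(seed, 13))
  }
  mirna <- simulate_mirna_layer(truth, genes, n_mirnas = sc$n_mirnas,
                                targets_per_mirna = sc$targets_per_mirna,
                                frac_significant = sc$frac_significant,
                                seed = child_seed(seed, 14))
  pathways <- generate_pathway_sets(genes, truth, n_sets = sc$n_sets,
                                    set_size_range = sc$set_size_range,
                                    enriched_sets = sc$enriched_sets,
                                    seed = child_seed(seed, 15))
  truth$mirna_targets <- split(mirna$target_pairs$gene,
                               mirna$target_pairs$mirna)
  truth$pathway_membership <- setNames(pathways$sets$genes,
                                       pathways$sets$pathway)
  list(network = network, truth = truth, expression = expr, stats = stats,
       mirna_stats = mirna$mirna_stats, target_pairs = mirna$target_pairs,
       pathways = pathways)
}

load_file_inputs <- function(inputs) {
  nets <- lapply(inputs$networks, read_edge_list)
  network <- Reduce(merge_networks, nets)
  stats <- if (!is.null(inputs$gene_stats)) {
    read_gene_stats(inputs$gene_stats)
  } else {
    de_test(read_expression_tsv(inputs$control),
            read_expression_tsv(inputs$treated))
  }
  list(network = network, truth = NULL, expression = NULL, stats = stats,
       mirna_stats = read_mirna_stats(inputs$mirna_stats),
       target_pairs = readr::read_tsv(inputs$target_pairs,
                                      show_col_types = FALSE),
       pathways = read_gmt(inputs$gmt))
}

#' Run the full module-detection and miRNA-integration pipeline
#'
#' Executes, in order: input generation or loading, differential statistics,
#' SDG selection, network merge, SDG-induced subnetwork (RrPIN analogue),
#' beta-uniform mixture fit, FDR scan with module selection, active-module
#' search, hypergeometric enrichment of the selected module, focus-term
#' selection, key-gene extraction, key-gene extension network, hub
#' detection, pathway relative abundance (module vs all SDGs), miRNA
#' filtering, target-source combination, miRNA-regulated PIN construction,
#' and miRNA function assignment. Per-stage gene/edge counts are logged so
#' the funnel is reproducible on any input. When `out_dir` is set every
#' intermediate is written as a tab-separated file along with a JSON
#' manifest (config, seed, package version, output checksums) and a
#' human-readable report; identical config and seed give byte-identical
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @return A result bundle (list) with the inputs, per-stage results, and
#'   when ground truth is known an `evaluation` block with the selected
#'   module's true-positive rate, precision and F1.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  inp <- run_stage("inputs", {
    if (!is.null(config$scenario)) {
      generate_scenario_inputs(config$scenario, seed)
    } else {
      load_file_inputs(config$inputs)
    }
  })
  stats <- inp$stats
  sdgs <- run_stage("sdg_selection", select_sdgs(stats, config$sdg_alpha))
  inform(sprintf("SDG selection: %d of %d genes at p < %g.",
                 length(sdgs), nrow(stats), config$sdg_alpha))
  rrpin <- run_stage("induce_rrpin",
                     suppressMessages(induce_subnetwork(inp$network, sdgs)))
  inform(sprintf("Induced subnetwork: %d nodes, %d edges.",
                 igraph::vcount(rrpin), igraph::ecount(rrpin)))
  fit <- run_stage("bum_fit", fit_bum(stats$p_value))
  truth_genes <- if (!is.null(inp$truth)) inp$truth$module_genes else NULL
  scan <- run_stage("fdr_scan", suppressMessages(
    fdr_scan(rrpin, stats, fit = fit, fdr_grid = config$fdr_grid,
             truth = truth_genes, size_band = config$size_band)))
  module <- scan$module
  inform(sprintf("Selected module (FDR %.3g): %d genes, %d interactions.",
                 scan$selected_fdr, length(module$genes), nrow(module$edges)))
  act <- run_stage("active_modules", suppressWarnings(
    active_modules(rrpin, stats, n_modules = config$n_modules,
                   max_depth = config$max_depth, overlap = config$overlap,
                   seed = child_seed(seed, 21))))
  enr <- run_stage("enrichment", suppressMessages(
    hypergeometric_enrich(module$genes, inp$pathways)))
  focal <- run_stage("focus_terms",
                     select_focus_terms(enr, keywords = config$keywords,
                                        top_kegg = config$top_kegg))
  key_genes <- run_stage("key_genes", extract_key_genes(focal))
  ext <- run_stage("extension_network", suppressMessages(
    extension_network(rrpin, key_genes, levels = config$extension_levels)))
  hubs <- run_stage("hubs", find_hubs(ext, config$hub_min_degree))
  ra <- run_stage("relative_abundance", {
    if (nrow(focal) > 0 && length(module$genes) > 0 && length(sdgs) > 0) {
      bind_rows(
        mutate(relative_abundance(module$genes, inp$pathways, focal$pathway),
               query = "module"),
        mutate(relative_abundance(sdgs, inp$pathways, focal$pathway),
               query = "sdgs"))
    } else {
      tibble(pathway = character(), s_count = integer(),
             n_total = integer(), e_value = numeric(), query = character())
    }
  })
  sig_mirnas <- run_stage("mirna_selection",
                          select_significant_mirnas(inp$mirna_stats,
                                                    config$mirna_alpha))
  pairs <- run_stage("target_combination",
                     combine_target_sources(inp$target_pairs,
                                            min_sources = config$min_sources,
                                            required_sources = config$required_sources))
  mirna_pin <- run_stage("mirna_pin", suppressMessages(
    build_mirna_pin(module, inp$network, sig_mirnas, pairs, stats)))
  mirna_fun <- run_stage("mirna_functions",
                         assign_mirna_functions(mirna_pin, focal))
  evaluation <- NULL
  if (!is.null(truth_genes)) {
    tp <- length(intersect(module$genes, truth_genes))
    tp_rate <- tp / length(truth_genes)
    precision <- if (length(module$genes) == 0) 0 else tp / length(module$genes)
    f1 <- if (tp_rate + precision == 0) 0 else
      2 * tp_rate * precision / (tp_rate + precision)
    evaluation <- tibble(tp_rate = tp_rate, precision = precision, f1 = f1)
  }
  bundle <- list(
    config = config, network = inp$network, truth = inp$truth,
    stats = stats, sdgs = sdgs, rrpin = rrpin, fit = fit, scan = scan,
    module = module, active_modules = act, enrichment = enr,
    focal_terms = focal, key_genes = key_genes, extension = ext,
    hubs = hubs, relative_abundance = ra, sig_mirnas = sig_mirnas,
    target_pairs = pairs, mirna_pin = mirna_pin,
    mirna_functions = mirna_fun, evaluation = evaluation
  )
  if (!is.null(config$out_dir)) {
    run_stage("write_outputs", write_bundle(bundle, config$out_dir))
  }
  bundle
}

# Serialize every intermediate of a run; returns the manifest path.
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)
  write_gene_stats(bundle$stats, fp("gene_stats.tsv"))
  writeLines(bundle$sdgs, fp("sdgs.txt"))
  write_network(bundle$rrpin, fp("rrpin_edges.tsv"), "tsv_edges")
  readr::write_tsv(bundle$scan$table, fp("fdr_scan.tsv"))
  module_table <- function(mod, id) {
    tidy(mod) |> mutate(module_id = id)
  }
  readr::write_tsv(module_table(bundle$module, "max_scoring"),
                   fp("module_genes.tsv"))
  if (length(bundle$active_modules) > 0) {
    readr::write_tsv(
      bind_rows(lapply(seq_along(bundle$active_modules), function(i) {
        module_table(bundle$active_modules[[i]], sprintf("active_%d", i))
      })),
      fp("active_modules.tsv"))
  }
  readr::write_tsv(select(bundle$enrichment, -"genes"), fp("enrichment.tsv"))
  if (nrow(bundle$focal_terms) > 0) {
    readr::write_tsv(
      mutate(bundle$focal_terms,
             genes = vapply(.data$genes, paste, "", collapse = ",")),
      fp("focal_terms.tsv"))
  }
  writeLines(bundle$key_genes, fp("key_genes.txt"))
  write_network(bundle$extension, fp("extension_edges.tsv"), "tsv_edges")
  writeLines(bundle$hubs, fp("hubs.txt"))
  readr::write_tsv(bundle$relative_abundance, fp("relative_abundance.tsv"))
  readr::write_tsv(bundle$sig_mirnas, fp("significant_mirnas.tsv"))
  readr::write_tsv(bundle$target_pairs, fp("target_pairs.tsv"))
  write_mirna_pin(bundle$mirna_pin, fp("mirna_pin.sif"))
  readr::write_tsv(bundle$mirna_functions, fp("mirna_functions.tsv"))
  write_report(bundle, fp("report.txt"))
  outputs <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(
    package = "pinmod",
    version = as.character(utils::packageVersion("pinmod")),
    seed = bundle$config$seed,
    config = bundle$config[setdiff(names(bundle$config),
                                   c("scenario", "inputs", "out_dir"))],
    scenario = bundle$config$scenario,
    checksums = as.list(tools::md5sum(file.path(out_dir, sort(outputs))))
  )
  names(manifest$checksums) <- sort(outputs)
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  fp("manifest.json")
}

#' Write a human-readable pipeline report
#'
#' One plain-text summary of a run: module sizes, the FDR scan table,
#' focal terms, key genes, hubs, and the miRNA function table. Empty
#' sections render as explicit "none" lines.
#'
#' @param bundle A result bundle from [run_pipeline()].
#' @param path Output path; when `NULL` the report lines are returned.
#' @return The report lines, invisibly when written to `path`.
#' @export
write_report <- function(bundle, path = NULL) {
  fmt_tab <- function(df) {
    if (nrow(df) == 0) return("  none")
    utils::capture.output(as.data.frame(df), print.gap = 2)
  }
  fmt_set <- function(x) if (length(x) == 0) "  none" else
    paste0("  ", paste(x, collapse = ", "))
  eval_lines <- if (is.null(bundle$evaluation)) {
    "  none (no ground truth)"
  } else {
    sprintf("  tp_rate %.3f  precision %.3f  F1 %.3f",
            bundle$evaluation$tp_rate, bundle$evaluation$precision,
            bundle$evaluation$f1)
  }
  lines <- c(
    "== Module detection pipeline report ==",
    sprintf("seed: %d", bundle$config$seed),
    sprintf("network: %d nodes, %d edges",
            igraph::vcount(bundle$network), igraph::ecount(bundle$network)),
    sprintf("SDGs (p < %g): %d", bundle$config$sdg_alpha, length(bundle$sdgs)),
    sprintf("SDG subnetwork: %d nodes, %d edges",
            igraph::vcount(bundle$rrpin), igraph::ecount(bundle$rrpin)),
    sprintf("BUM fit: lambda = %.3f, a = %.3f",
            bundle$fit$lambda_mix, bundle$fit$a_shape),
    "",
    "FDR scan:",
    fmt_tab(bundle$scan$table),
    sprintf("selected FDR: %.3g", bundle$scan$selected_fdr),
    sprintf("maximally scoring module: %d genes, %d interactions",
            length(bundle$module$genes), nrow(bundle$module$edges)),
    sprintf("active modules: %d (sizes: %s)",
            length(bundle$active_modules),
            if (length(bundle$active_modules) == 0) "none" else
              paste(vapply(bundle$active_modules,
                           function(m) length(m$genes), 0L), collapse = ", ")),
    "module evaluation vs truth:",
    eval_lines,
    "",
    "focal terms:",
    fmt_tab(if (nrow(bundle$focal_terms) == 0) bundle$focal_terms else
      select(bundle$focal_terms, -dplyr::any_of("genes"))),
    "key genes:",
    fmt_set(bundle$key_genes),
    sprintf("hubs (degree >= %d in the key-gene extension network):",
            bundle$config$hub_min_degree),
    fmt_set(bundle$hubs),
    "",
    sprintf("significant miRNAs (p < %g): %d",
            bundle$config$mirna_alpha, nrow(bundle$sig_mirnas)),
    sprintf("miRNA-regulated PIN: %d miRNAs, %d genes, %d miRNA-gene edges",
            length(bundle$mirna_pin$mirna_nodes),
            length(bundle$mirna_pin$gene_nodes),
            nrow(bundle$mirna_pin$bipartite_edges)),
    "miRNA functions:",
    fmt_tab(bundle$mirna_functions)
  )
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
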