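#' Combine multi-source miRNA target pairs
#'
#' Deduplicates (miRNA, gene) pairs, taking the union of their source
#' databases, and keeps a pair when it is supported by at least
#' `min_sources` databases — or by any database named in
#' `required_sources` (for example an experimentally validated interaction
#' resource) regardless of count.
#'
#' @param pairs A tibble with columns `mirna`, `gene`, and `sources`
#'   (either a `;`-separated string or a list column of database names).
#' @param min_sources Minimum number of supporting databases (default 1,
#'   the union rule).
#' @param required_sources Optional character vector of database names that
#'   qualify a pair on their own.
#' @return The filtered tibble with `sources` as a sorted `;`-separated
#'   string and `n_sources` counts.
#' @export
combine_target_sources <- function(pairs, min_sources = 1,
                                   required_sources = NULL) {
  stopifnot(all(c("mirna", "gene", "sources") %in% names(pairs)))
  pairs <- as_tibble(pairs)
  src_list <- if (is.list(pairs$sources)) pairs$sources else
    strsplit(as.character(pairs$sources), ";", fixed = TRUE)
  pairs$sources <- vapply(src_list, function(s) paste(sort(unique(s)), collapse = ";"), "")
  pairs$gene <- normalize_symbols(pairs$gene)
  out <- pairs |>
    group_by(.data$mirna, .data$gene) |>
    summarise(
      sources = paste(sort(unique(unlist(strsplit(.data$sources, ";", fixed = TRUE)))),
                      collapse = ";"),
      .groups = "drop"
    ) |>
    mutate(n_sources = lengths(strsplit(.data$sources, ";", fixed = TRUE)))
  keep <- out$n_sources >= min_sources
  if (!is.null(required_sources)) {
    has_req <- vapply(strsplit(out$sources, ";", fixed = TRUE),
                      function(s) any(s %in% required_sources), TRUE)
    keep <- keep | has_req
  }
  out[keep, , drop = FALSE]
}

#' Anti-correlation rule for miRNA–gene pairs
#'
#' A miRNA–gene edge is anti-correlated when the miRNA's direction of
#' change opposes the gene's log2 fold-change sign: an upregulated miRNA
#' (fold change above 1) with a downregulated gene, or a downregulated
#' miRNA (fold change below 1) with an upregulated gene. Pairs at either
#' null point (gene log fold change 0 or miRNA fold change exactly 1) are
#' not anti-correlated.
#'
#' @param gene_log_fc Signed gene log2 fold change (vectorized).
#' @param mirna_fold_change miRNA fold change, a positive ratio
#'   (treated/control).
#' @return Logical vector.
#' @examples
#' is_anti_correlated(-1.43, 1.33)  # down gene, up miRNA: TRUE
#' @export
is_anti_correlated <- function(gene_log_fc, mirna_fold_change) {
  if (any(mirna_fold_change <= 0, na.rm = TRUE)) {
    stop_param("miRNA fold changes must be > 0.")
  }
  (gene_log_fc < 0 & mirna_fold_change > 1) |
    (gene_log_fc > 0 & mirna_fold_change < 1)
}

#' Build the miRNA-regulated protein interaction network
#'
#' Retains the bipartite miRNA–gene edges whose gene belongs to the
#' functional module, whose miRNA is among the significant miRNAs, and —
#' unless `enforce_anticorrelation = FALSE` — which pass
#' [is_anti_correlated()]. Gene nodes are the genes incident to at least
#' one retained edge; the gene–gene layer is the PPI subnetwork induced on
#' them; miRNAs with no retained edge are dropped. Edge counts removed by
#' each filter are reported so discrepancies with externally stated filters
#' are visible rather than silently absorbed.
#'
#' @param module A `pin_module` or character vector of module genes.
#' @param ppi The source interaction network.
#' @param sig_mirnas A miRNA statistics tibble (`mirna`, `p_value`,
#'   `fold_change`), typically from [select_significant_mirnas()].
#' @param pairs A target-pair tibble (`mirna`, `gene`, optionally
#'   `sources`).
#' @param gene_stats A gene-statistics tibble supplying `log_fc`.
#' @param enforce_anticorrelation Apply the anti-correlation rule
#'   (default `TRUE`). Disabling it never removes edges.
#' @return An object of class `mirna_pin`: list with `mirna_nodes`,
#'   `gene_nodes`, `bipartite_edges` (tibble: `mirna`, `gene`,
#'   `gene_log_fc`, `p_value`, `fold_change`, `mirna_direction`), and
#'   `ppi_edges`.
#' @export
build_mirna_pin <- function(module, ppi, sig_mirnas, pairs, gene_stats,
                            enforce_anticorrelation = TRUE) {
  module_genes <- if (inherits(module, "pin_module")) module$genes else
    normalize_symbols(module)
  pairs <- as_tibble(pairs)
  pairs$gene <- normalize_symbols(pairs$gene)
  n0 <- nrow(pairs)
  pairs <- filter(pairs, .data$gene %in% module_genes)
  n1 <- nrow(pairs)
  pairs <- filter(pairs, .data$mirna %in% sig_mirnas$mirna)
  n2 <- nrow(pairs)
  pairs <- pairs |>
    left_join(sig_mirnas[, c("mirna", "p_value", "fold_change")], by = "mirna") |>
    left_join(tibble(gene = normalize_symbols(gene_stats$gene),
                     gene_log_fc = gene_stats$log_fc), by = "gene")
  if (enforce_anticorrelation) {
    pairs <- filter(pairs,
                    is_anti_correlated(.data$gene_log_fc, .data$fold_change))
  }
  inform(sprintf(
    "miRNA PIN filters: %d pairs -> %d in module -> %d significant -> %d retained.",
    n0, n1, n2, nrow(pairs)))
  pairs <- pairs |>
    mutate(mirna_direction = ifelse(.data$fold_change > 1, "up",
                                    ifelse(.data$fold_change < 1, "down",
                                           "ambiguous"))) |>
    distinct(.data$mirna, .data$gene, .keep_all = TRUE) |>
    arrange(.data$gene, .data$mirna)
  gene_nodes <- sort(unique(pairs$gene))
  ppi_edges <- network_edges(
    igraph::induced_subgraph(ppi, intersect(gene_nodes, igraph::V(ppi)$name)))
  structure(
    list(mirna_nodes = sort(unique(pairs$mirna)), gene_nodes = gene_nodes,
         bipartite_edges = pairs,
         ppi_edges = ppi_edges[, c("from", "to"), drop = FALSE]),
    class = "mirna_pin"
  )
}

#' @export
print.mirna_pin <- function(x, ...) {
  cat(sprintf(
    "<mirna_pin> %d miRNAs, %d genes, %d miRNA-gene edges, %d PPI edges\n",
    length(x$mirna_nodes), length(x$gene_nodes),
    nrow(x$bipartite_edges), nrow(x$ppi_edges)))
  invisible(x)
}

#' @rdname build_mirna_pin
#' @param x A `mirna_pin`.
#' @param ... Unused.
#' @export
tidy.mirna_pin <- function(x, ...) x$bipartite_edges

#' Write a miRNA-regulated PIN as SIF plus node attributes
#'
#' Gene–gene edges use relation token `pp`, miRNA–gene edges use `mt`. A
#' companion `<path>.nodes.tsv` records node type and regulation direction.
#'
#' @param pin A `mirna_pin`.
#' @param path Output SIF path.
#' @return Invisibly, `path`.
#' @export
write_mirna_pin <- function(pin, path) {
  lines <- c(
    sprintf("%s\tpp\t%s", pin$ppi_edges$from, pin$ppi_edges$to),
    sprintf("%s\tmt\t%s", pin$bipartite_edges$mirna, pin$bipartite_edges$gene)
  )
  writeLines(lines, path)
  nodes <- bind_rows(
    tibble(node = pin$gene_nodes, type = "gene"),
    tibble(node = pin$mirna_nodes, type = "mirna")
  )
  readr::write_tsv(nodes, paste0(path, ".nodes.tsv"))
  invisible(path)
}

#' Assign functions to miRNAs through their retained targets
#'
#' A miRNA is assigned a focal term when at least one of its retained
#' target genes belongs to that term's gene list; miRNAs with no assigned
#' term are omitted. The output is invariant to input row order.
#'
#' @param pin A `mirna_pin`.
#' @param focal_terms Character vector of term names, or an enrichment
#'   tibble with `name` and `genes` columns.
#' @param term_genes Named list mapping term name to gene vector (not
#'   needed when `focal_terms` carries a `genes` column).
#' @return A long tibble (`mirna`, `term`), sorted by term then miRNA.
#' @export
assign_mirna_functions <- function(pin, focal_terms, term_genes = NULL) {
  if (is.data.frame(focal_terms) && "genes" %in% names(focal_terms)) {
    term_genes <- setNames(focal_terms$genes, focal_terms$name)
    focal_terms <- focal_terms$name
  }
  edges <- pin$bipartite_edges
  rows <- purrr::map(focal_terms, function(tm) {
    tg <- normalize_symbols(term_genes[[tm]])
    hit <- sort(unique(edges$mirna[edges$gene %in% tg]))
    if (length(hit) == 0) return(NULL)
    tibble(mirna = hit, term = tm)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) return(tibble(mirna = character(), term = character()))
  arrange(out, match(.data$term, focal_terms), .data$mirna)
}
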