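#' Pathway gene-set collections
#'
#' A light container for pathway gene sets against a background universe.
#' Pathway genes falling outside the universe are dropped with a message.
#'
#' @param sets A tibble/data frame with columns `pathway` (id), `name`,
#'   `category` (`"GO_BP"`, `"KEGG"` or `"other"`), and `genes` (list
#'   column of symbol vectors).
#' @param universe Character vector: the background gene universe.
#' @return An object of class `pathway_collection`.
#' @export
pathway_collection <- function(sets, universe) {
  sets <- as_tibble(sets)
  stopifnot(all(c("pathway", "genes") %in% names(sets)))
  if (!"name" %in% names(sets)) sets$name <- sets$pathway
  if (!"category" %in% names(sets)) sets$category <- "other"
  universe <- sort(unique(normalize_symbols(universe)))
  sets$genes <- lapply(sets$genes, function(g) {
    sort(unique(normalize_symbols(g)))
  })
  n_out <- sum(vapply(sets$genes, function(g) sum(!g %in% universe), 0L))
  if (n_out > 0) {
    inform(sprintf("%d pathway gene(s) outside the universe were dropped.", n_out))
    sets$genes <- lapply(sets$genes, function(g) intersect(g, universe))
  }
  structure(list(sets = sets, universe = universe),
            class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("<pathway_collection> %d sets over %d universe genes\n",
              nrow(x$sets), length(x$universe)))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line — name, description, then member genes,
#' tab-separated.
#'
#' @param path Path to a GMT file.
#' @param universe Optional background universe; defaults to the union of
#'   all set members.
#' @param category Category label applied to every set (default `"other"`),
#'   or a function of the set name returning a label.
#' @return A [pathway_collection()].
#' @export
read_gmt <- function(path, universe = NULL, category = "other") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 3)
  if (length(bad) > 0) {
    abort(sprintf("Malformed GMT line %d in %s (need name, description, >=1 gene).",
                  bad[1], path),
          class = "pinmod_error_parse")
  }
  nm <- vapply(fields, `[[`, "", 1L)
  genes <- lapply(fields, function(f) f[-(1:2)])
  cat_lab <- if (is.function(category)) vapply(nm, category, "") else category
  sets <- tibble(pathway = nm, name = nm, category = cat_lab, genes = genes)
  pathway_collection(sets, universe = universe %||% unique(unlist(genes)))
}

#' @rdname read_gmt
#' @param pathways A [pathway_collection()].
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(seq_len(nrow(pathways$sets)), function(i) {
    paste(c(pathways$sets$pathway[i], pathways$sets$name[i],
            pathways$sets$genes[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric gene-set enrichment
#'
#' For each pathway, the p-value is the upper hypergeometric tail
#' \eqn{P(X \ge k)} of drawing `k` pathway genes in a query of size `n`
#' from a universe containing `K` pathway genes — a local re-implementation
#' of annotation-server enrichment over user-supplied gene sets, with
#' Benjamini–Hochberg adjustment across all tested pathways.
#'
#' @param query Character vector of query genes. Genes outside the universe
#'   are dropped with a message.
#' @param pathways A [pathway_collection()].
#' @return A tibble sorted by p-value with columns `pathway`, `name`,
#'   `category`, `count`, `percent` (overlap / query size x 100),
#'   `p_value`, `adjusted_p`, and `genes` (list column of overlap genes).
#' @export
hypergeometric_enrich <- function(query, pathways) {
  query <- sort(unique(normalize_symbols(query)))
  outside <- setdiff(query, pathways$universe)
  if (length(outside) > 0) {
    inform(sprintf("%d query gene(s) outside the universe were dropped.",
                   length(outside)))
    query <- setdiff(query, outside)
  }
  if (length(query) == 0) {
    return(tibble(pathway = character(), name = character(),
                  category = character(), count = integer(),
                  percent = numeric(), p_value = numeric(),
                  adjusted_p = numeric(), genes = list()))
  }
  N <- length(pathways$universe)
  n <- length(query)
  rows <- purrr::map(seq_len(nrow(pathways$sets)), function(i) {
    set <- pathways$sets$genes[[i]]
    hits <- intersect(query, set)
    k <- length(hits)
    K <- length(set)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(pathway = pathways$sets$pathway[i], name = pathways$sets$name[i],
           category = pathways$sets$category[i], count = k,
           percent = 100 * k / n, p_value = p, genes = list(hits))
  })
  bind_rows(rows) |>
    mutate(adjusted_p = p.adjust(.data$p_value, "BH")) |>
    arrange(.data$p_value, .data$pathway) |>
    select("pathway", "name", "category", "count", "percent",
           "p_value", "adjusted_p", "genes")
}

#' Select focal enrichment terms
#'
#' Keeps the GO biological-process rows whose names contain any of the
#' keywords (case-insensitive) together with the best `top_kegg` KEGG rows
#' by p-value, eliminating duplicate names; order is preserved by p-value.
#'
#' @param rows An enrichment tibble (needs `name`, `category`, `p_value`).
#' @param keywords Keywords matched against GO term names
#'   (default `c("drug", "metabolism")`).
#' @param top_kegg Number of top KEGG pathways to keep (default 6).
#' @return The focal subset of `rows`, sorted by p-value.
#' @export
select_focus_terms <- function(rows, keywords = c("drug", "metabolism"),
                               top_kegg = 6) {
  stopifnot(all(c("name", "category", "p_value") %in% names(rows)))
  rows <- as_tibble(rows)
  go <- rows |>
    filter(.data$category == "GO_BP",
           grepl(paste(keywords, collapse = "|"), .data$name,
                 ignore.case = TRUE))
  kegg <- rows |>
    filter(.data$category == "KEGG") |>
    arrange(.data$p_value) |>
    slice_head(n = top_kegg)
  bind_rows(go, kegg) |>
    distinct(.data$name, .keep_all = TRUE) |>
    arrange(.data$p_value)
}

#' Extract key genes from focal terms
#'
#' The union of the focal terms' gene lists, symbol-normalized and sorted.
#'
#' @param focal_terms An enrichment tibble with a `genes` list column, or a
#'   character vector of term names (then `term_genes` must be supplied).
#' @param term_genes Optional named list mapping term name to gene vector.
#' @return Sorted character vector of key gene symbols.
#' @export
extract_key_genes <- function(focal_terms, term_genes = NULL) {
  if (is.data.frame(focal_terms) && "genes" %in% names(focal_terms)) {
    genes <- unlist(focal_terms$genes)
  } else {
    terms <- if (is.data.frame(focal_terms)) focal_terms$name else focal_terms
    missing <- setdiff(terms, names(term_genes))
    if (length(missing) > 0) {
      stop_param(sprintf("No gene list for term(s): %s",
                         paste(missing, collapse = ", ")))
    }
    genes <- unlist(term_genes[terms])
  }
  sort(unique(normalize_symbols(genes)))
}

#' Pathway relative abundance
#'
#' For each focal pathway i, E(i) = S(i) / N with S(i) the number of query
#' genes annotated to pathway i and N the query-set size; computed for any
#' query so module genes and the full SDG list can be compared on the same
#' terms. The `denominator = "pathway"` variant divides by the pathway size
#' instead.
#'
#' @param query Character vector of query genes (non-empty).
#' @param pathways A [pathway_collection()].
#' @param focal_terms Character vector of pathway ids (subset of
#'   `pathways$sets$pathway`).
#' @param denominator `"query"` (default) or `"pathway"`.
#' @return A tibble with columns `pathway`, `s_count`, `n_total`,
#'   `e_value`.
#' @export
relative_abundance <- function(query, pathways, focal_terms,
                               denominator = c("query", "pathway")) {
  denominator <- match.arg(denominator)
  query <- unique(normalize_symbols(query))
  if (length(query) == 0) {
    abort("Relative abundance is undefined for an empty query.",
          class = "pinmod_error_parameter")
  }
  missing <- setdiff(focal_terms, pathways$sets$pathway)
  if (length(missing) > 0) {
    stop_param(sprintf("Unknown pathway id(s): %s",
                       paste(missing, collapse = ", ")))
  }
  ix <- match(focal_terms, pathways$sets$pathway)
  rows <- purrr::map(ix, function(i) {
    set <- pathways$sets$genes[[i]]
    s <- length(intersect(query, set))
    n <- if (denominator == "query") length(query) else length(set)
    tibble(pathway = pathways$sets$pathway[i], s_count = s,
           n_total = n, e_value = s / n)
  })
  bind_rows(rows)
}
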