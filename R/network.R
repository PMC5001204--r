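#' Build an undirected interaction network from an edge table
#'
#' Constructs a simple undirected [igraph][igraph::igraph-package] graph from a
#' two-column edge table of gene symbols. Self-loops are dropped and duplicate
#' undirected edges are collapsed; when an optional `source` column is present,
#' provenance tags of collapsed duplicates are concatenated (`;`-separated).
#'
#' @param edges A data frame whose first two columns are interactor symbols;
#'   an optional third column `source` carries a per-edge provenance tag.
#' @param nodes Optional character vector of node symbols to include even when
#'   they touch no edge (isolated nodes).
#' @param symbol_case `"upper"` (default) to uppercase symbols, `"preserve"`
#'   to keep them as-is.
#' @return An undirected simple `igraph` object with vertex attribute `name`
#'   and, when provenance was supplied, edge attribute `source`.
#' @examples
#' net <- interaction_network(data.frame(a = c("tp53", "mdm2"),
#'                                       b = c("MDM2", "EP300")))
#' igraph::vcount(net)
#' @export
interaction_network <- function(edges, nodes = NULL,
                                symbol_case = c("upper", "preserve")) {
  symbol_case <- match.arg(symbol_case)
  edges <- as.data.frame(edges)
  if (ncol(edges) >= 2 && nrow(edges) > 0) {
    from <- normalize_symbols(edges[[1]], symbol_case)
    to <- normalize_symbols(edges[[2]], symbol_case)
    src <- if ("source" %in% names(edges)) as.character(edges$source) else NULL
    keep <- from != to & from != "" & to != ""
    n_loops <- sum(from == to)
    if (n_loops > 0) {
      inform(sprintf("Dropped %d self-loop(s).", n_loops))
    }
    from <- from[keep]; to <- to[keep]
    if (!is.null(src)) src <- src[keep]
    a <- pmin(from, to)
    b <- pmax(from, to)
    tab <- tibble(from = a, to = b)
    if (!is.null(src)) tab$source <- src
    if (is.null(src)) {
      tab <- distinct(tab)
    } else {
      tab <- tab |>
        group_by(.data$from, .data$to) |>
        summarise(
          source = paste(sort(unique(unlist(strsplit(.data$source, ";", fixed = TRUE)))),
                         collapse = ";"),
          .groups = "drop"
        )
    }
  } else {
    tab <- tibble(from = character(), to = character())
  }
  verts <- sort(unique(c(tab$from, tab$to,
                         normalize_symbols(nodes %||% character(), symbol_case))))
  g <- igraph::graph_from_data_frame(tab, directed = FALSE,
                                     vertices = data.frame(name = verts))
  g
}

#' Edge table of an interaction network
#'
#' @param network An `igraph` interaction network.
#' @return A tibble with columns `from`, `to` (canonically ordered so
#'   `from <= to`) and `source` when provenance is recorded.
#' @export
network_edges <- function(network) {
  el <- igraph::as_edgelist(network, names = TRUE)
  out <- tibble(from = pmin(el[, 1], el[, 2]), to = pmax(el[, 1], el[, 2]))
  if ("source" %in% igraph::edge_attr_names(network)) {
    out$source <- igraph::edge_attr(network, "source")
  }
  arrange(out, .data$from, .data$to)
}

#' Read an interaction network from a tab-separated edge list
#'
#' Two dialects are supported: `two_column` (interactor symbols in the first
#' two columns, an optional third column with a provenance tag) and
#' `hprd_flat` (flat files where the interactor symbols sit in configurable
#' columns, by default 1 and 4 as in HPRD-style exports).
#'
#' @param path Path to a tab-separated file.
#' @param dialect `"two_column"` (default) or `"hprd_flat"`.
#' @param symbol_case `"upper"` (default) or `"preserve"`.
#' @param header Does the file carry a header row? Default `FALSE`.
#' @param symbol_columns For `hprd_flat`, the two column indices holding the
#'   interactor symbols (default `c(1, 4)`).
#' @return An interaction network (`igraph`).
#' @export
read_edge_list <- function(path, dialect = c("two_column", "hprd_flat"),
                           symbol_case = c("upper", "preserve"),
                           header = FALSE, symbol_columns = c(1L, 4L)) {
  dialect <- match.arg(dialect)
  symbol_case <- match.arg(symbol_case)
  if (!file.exists(path)) stop_param(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (header && length(lines) > 0) lines <- lines[-1]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warn("Empty edge-list file: returning an empty network.")
    return(interaction_network(data.frame(a = character(), b = character())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # whitespace-delimited fallback for hand-written two-column files
  if (dialect == "two_column") {
    fields <- lapply(seq_along(fields), function(i) {
      f <- fields[[i]]
      if (length(f) < 2) f <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
      f
    })
  }
  need <- if (dialect == "two_column") 2L else max(symbol_columns)
  bad <- which(vapply(fields, length, 1L) < need)
  if (length(bad) > 0) {
    abort(sprintf("Malformed line %d in %s: expected at least %d field(s).",
                  bad[1] + as.integer(header), path, need),
          class = "pinmod_error_parse")
  }
  if (dialect == "two_column") {
    df <- data.frame(
      a = vapply(fields, `[[`, "", 1L),
      b = vapply(fields, `[[`, "", 2L)
    )
    third <- vapply(fields, function(f) if (length(f) >= 3) f[[3]] else NA_character_, "")
    if (all(!is.na(third))) df$source <- third
  } else {
    df <- data.frame(
      a = vapply(fields, `[[`, "", symbol_columns[1]),
      b = vapply(fields, `[[`, "", symbol_columns[2]),
      source = "hprd"
    )
  }
  interaction_network(df, symbol_case = symbol_case)
}

#' Merge two interaction networks
#'
#' Node set is the union of both node sets; edges are the union of both edge
#' sets with unordered-pair deduplication. Provenance tags of edges present in
#' both inputs are concatenated. The merge is commutative, associative and
#' idempotent.
#'
#' @param a,b Interaction networks (`igraph`).
#' @return The merged interaction network.
#' @export
merge_networks <- function(a, b) {
  ea <- network_edges(a)
  eb <- network_edges(b)
  if (!"source" %in% names(ea) && "source" %in% names(eb)) ea$source <- NA_character_
  if (!"source" %in% names(eb) && "source" %in% names(ea)) eb$source <- NA_character_
  edges <- bind_rows(ea, eb)
  if ("source" %in% names(edges)) {
    edges$source[is.na(edges$source)] <- ""
    edges <- edges |>
      group_by(.data$from, .data$to) |>
      summarise(
        source = paste(sort(unique(setdiff(unlist(strsplit(.data$source, ";", fixed = TRUE)), ""))),
                       collapse = ";"),
        .groups = "drop"
      )
  }
  interaction_network(edges,
                      nodes = union(igraph::V(a)$name, igraph::V(b)$name),
                      symbol_case = "preserve")
}

#' Induce the subnetwork on a set of genes
#'
#' Keeps the genes present in the network (absent ones are silently excluded,
#' with a message) and every network edge whose two endpoints both survive.
#' Genes with no surviving partner are retained as isolated nodes: they are
#' still members of the induced network even though connected-module search
#' ignores them.
#'
#' @param network An interaction network.
#' @param genes Character vector of gene symbols.
#' @return The induced interaction network.
#' @export
induce_subnetwork <- function(network, genes) {
  genes <- normalize_symbols(genes)
  present <- intersect(genes, igraph::V(network)$name)
  missing <- setdiff(genes, present)
  if (length(missing) > 0) {
    inform(sprintf("%d gene(s) absent from the network were excluded.",
                   length(missing)))
  }
  igraph::induced_subgraph(network, present)
}

#' Extend a seed gene set by network neighbourhood
#'
#' Returns the subnetwork induced on all nodes within graph distance
#' `levels` of any seed gene (distances computed in `network`). With
#' `levels = 0` this equals [induce_subnetwork()].
#'
#' @param network An interaction network.
#' @param seeds Character vector of seed gene symbols.
#' @param levels Number of interaction levels to extend by (default 1).
#' @return The extension network (`igraph`).
#' @export
extension_network <- function(network, seeds, levels = 1) {
  if (!is.numeric(levels) || levels < 0) stop_param("`levels` must be >= 0.")
  seeds <- normalize_symbols(seeds)
  present <- intersect(seeds, igraph::V(network)$name)
  if (length(setdiff(seeds, present)) > 0) {
    inform(sprintf("%d seed(s) absent from the network were excluded.",
                   length(setdiff(seeds, present))))
  }
  if (length(present) == 0) {
    return(igraph::induced_subgraph(network, character()))
  }
  hood <- igraph::ego(network, order = levels, nodes = present)
  keep <- sort(unique(unlist(lapply(hood, function(v) v$name))))
  igraph::induced_subgraph(network, keep)
}

#' Find hub genes by degree
#'
#' @param network An interaction network.
#' @param min_degree Minimum number of interactions for a node to qualify as
#'   a hub (default 4).
#' @return Sorted character vector of hub gene symbols.
#' @export
find_hubs <- function(network, min_degree = 4) {
  if (!is.numeric(min_degree) || min_degree < 0) {
    stop_param("`min_degree` must be >= 0.")
  }
  deg <- igraph::degree(network)
  sort(names(deg)[deg >= min_degree])
}

#' Write an interaction network to disk
#'
#' Formats: `tsv_edges` (tab-separated two/three-column edge list, no header),
#' `sif` (simple interaction format with relation token `pp`; isolated nodes
#' are written as single-token lines), or `graphml`.
#'
#' @param network An interaction network.
#' @param path Output file path.
#' @param format One of `"tsv_edges"`, `"sif"`, `"graphml"`.
#' @return Invisibly, `path`.
#' @export
write_network <- function(network, path,
                          format = c("tsv_edges", "sif", "graphml")) {
  format <- match.arg(format)
  edges <- network_edges(network)
  if (format == "tsv_edges") {
    readr::write_tsv(edges, path, col_names = FALSE)
  } else if (format == "sif") {
    lines <- sprintf("%s\tpp\t%s", edges$from, edges$to)
    iso <- setdiff(igraph::V(network)$name, c(edges$from, edges$to))
    writeLines(c(lines, iso), path)
  } else {
    igraph::write_graph(network, path, format = "graphml")
  }
  invisible(path)
}

#' Read a network from a SIF file
#'
#' Parses lines of the form `source relation target [target ...]`; bare
#' single-token lines are read as isolated nodes.
#'
#' @param path Path to a SIF file (tab- or space-delimited).
#' @param symbol_case `"upper"` (default) or `"preserve"`.
#' @return An interaction network (`igraph`).
#' @export
read_sif <- function(path, symbol_case = c("upper", "preserve")) {
  symbol_case <- match.arg(symbol_case)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[\t ]+")
  iso <- character()
  from <- character(); to <- character()
  for (f in fields) {
    if (length(f) == 1) {
      iso <- c(iso, f)
    } else if (length(f) >= 3) {
      from <- c(from, rep(f[1], length(f) - 2))
      to <- c(to, f[3:length(f)])
    } else {
      abort(sprintf("Malformed SIF line in %s: %s", path, paste(f, collapse = " ")),
            class = "pinmod_error_parse")
    }
  }
  interaction_network(data.frame(a = from, b = to), nodes = iso,
                      symbol_case = symbol_case)
}
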