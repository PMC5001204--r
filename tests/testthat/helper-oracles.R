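# Independent brute-force oracles, deliberately implemented with different
# algorithms and data structures than the package internals.

# Best-scoring connected induced subgraph by recursive enumeration over
# adjacency lists (include/exclude branching from each root; each connected
# vertex set containing its root is visited exactly once).
oracle_best_connected <- function(network, scores) {
  genes <- igraph::V(network)$name
  nbrs <- lapply(igraph::as_adj_list(network), function(v) v$name)
  names(nbrs) <- genes
  best <- list(score = 0, genes = character(0))
  consider <- function(sub) {
    s <- sum(scores[sub])
    if (s > best$score) best <<- list(score = s, genes = sort(sub))
  }
  rec <- function(sub, ext, banned) {
    if (length(ext) == 0) return()
    u <- ext[1]
    # include u
    sub2 <- c(sub, u)
    consider(sub2)
    ext2 <- unique(c(ext[-1], setdiff(nbrs[[u]], c(sub2, ext, banned))))
    rec(sub2, ext2, banned)
    # exclude u permanently
    rec(sub, ext[-1], c(banned, u))
  }
  for (i in seq_along(genes)) {
    r <- genes[i]
    consider(r)
    rec(r, setdiff(nbrs[[r]], genes[seq_len(i)]), genes[seq_len(i)])
  }
  best
}

# Random connected-ish scored graph for module-search tests.
random_scored_graph <- function(n, p_edge = 0.3, seed = 1) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p_edge)
  igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
  scores <- stats::setNames(round(stats::rnorm(n, 0, 2), 2),
                            igraph::V(g)$name)
  list(network = g, scores = scores)
}

# Wrap raw scores as a scored_network so max_scoring_subnetwork accepts them.
as_scored <- function(network, scores) {
  structure(
    list(network = network,
         scores = tibble::tibble(gene = names(scores),
                                 p_value = NA_real_,
                                 score = as.numeric(scores)),
         fit = NULL, fdr = NA_real_, tau = NA_real_),
    class = "scored_network"
  )
}

# Tiny deterministic graphs used across files.
path_graph <- function(symbols) {
  pinmod::interaction_network(
    data.frame(a = symbols[-length(symbols)], b = symbols[-1]))
}

star_graph <- function(center, leaves) {
  pinmod::interaction_network(
    data.frame(a = rep(center, length(leaves)), b = leaves))
}
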