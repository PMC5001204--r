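#' Functional module objects
#'
#' A `pin_module` is a connected gene subnetwork together with its member
#' scores. `tidy()` returns one row per member gene; `glance()` returns the
#' one-row module summary.
#'
#' @param genes Character vector of member genes.
#' @param network The interaction network the module lives in.
#' @param scores Optional tibble (`gene`, `p_value`, `score`) of member
#'   statistics.
#' @param method_tag `"max_scoring"` or `"active"`.
#' @return An object of class `pin_module`.
#' @export
pin_module <- function(genes, network, scores = NULL,
                       method_tag = c("max_scoring", "active")) {
  method_tag <- match.arg(method_tag)
  genes <- sort(unique(genes))
  sub <- igraph::induced_subgraph(network, genes)
  edges <- network_edges(sub)[, c("from", "to")]
  if (!is.null(scores)) {
    scores <- as_tibble(scores) |>
      filter(.data$gene %in% genes) |>
      arrange(.data$gene)
  }
  structure(
    list(genes = genes, edges = edges,
         aggregate_score = if (is.null(scores)) NA_real_ else sum(scores$score),
         scores = scores, method_tag = method_tag),
    class = "pin_module"
  )
}

#' @export
print.pin_module <- function(x, ...) {
  cat(sprintf("<pin_module:%s> %d genes, %d interactions, score %.3f\n",
              x$method_tag, length(x$genes), nrow(x$edges), x$aggregate_score))
  invisible(x)
}

#' @rdname pin_module
#' @param x A `pin_module`.
#' @param ... Unused.
#' @export
tidy.pin_module <- function(x, ...) {
  if (is.null(x$scores)) tibble(gene = x$genes) else x$scores
}

#' @rdname pin_module
#' @export
glance.pin_module <- function(x, ...) {
  tibble(n_genes = length(x$genes), n_edges = nrow(x$edges),
         aggregate_score = x$aggregate_score, method = x$method_tag)
}

# ---- exact maximum-weight connected subgraph by bitmask enumeration -------

# Exhaustive search over all vertex subsets (n <= 24 enforced by caller;
# connectivity checked by bitmask BFS). Returns the gene names of the best
# positive-score connected subset, character(0) if none is positive.
mwcs_exact <- function(network, scores) {
  genes <- igraph::V(network)$name
  n <- length(genes)
  stopifnot(n <= 24)
  bits <- bitwShiftL(1L, 0:(n - 1))
  adj_list <- igraph::as_adj_list(network)
  adj <- vapply(adj_list, function(v) {
    ix <- as.integer(v)
    if (length(ix) == 0) 0L else Reduce(bitwOr, bits[ix])
  }, 0L)
  w <- scores[match(genes, names(scores))]
  best_score <- 0
  best_set <- integer(0)
  for (S in seq_len(bitwShiftL(1L, n) - 1L)) {
    members <- which(bitwAnd(S, bits) != 0L)
    sc <- sum(w[members])
    if (sc <= best_score) next
    # connectivity: BFS over bitmasks from the lowest member
    reached <- bits[members[1]]
    repeat {
      nxt <- bitwAnd(bitwOr(reached, Reduce(bitwOr, adj[which(bitwAnd(reached, bits) != 0L)])), S)
      if (nxt == reached) break
      reached <- nxt
    }
    if (reached == S) {
      best_score <- sc
      best_set <- members
    }
  }
  genes[best_set]
}

# ---- heuristic: positive-component contraction + greedy bridge merging ----

# Multi-source Dijkstra on node costs c(v) = max(0, -score(v)); returns
# distances (cost to *enter* each node from the source set) and parents.
node_dijkstra <- function(adj, cost, sources) {
  n <- length(adj)
  dist <- rep(Inf, n)
  parent <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  dist[sources] <- 0
  done[sources] <- TRUE
  for (s in sources) {
    for (v in adj[[s]]) {
      nd <- cost[v]
      if (!done[v] && nd < dist[v]) { dist[v] <- nd; parent[v] <- s }
    }
  }
  repeat {
    cand <- which(!done & is.finite(dist))
    if (length(cand) == 0) break
    u <- cand[which.min(dist[cand])]
    done[u] <- TRUE
    for (v in adj[[u]]) {
      nd <- dist[u] + cost[v]
      if (!done[v] && nd < dist[v]) { dist[v] <- nd; parent[v] <- u }
    }
  }
  list(dist = dist, parent = parent)
}

mwcs_heuristic <- function(network, scores) {
  genes <- igraph::V(network)$name
  w <- scores[match(genes, names(scores))]
  pos <- which(w > 0)
  if (length(pos) == 0) return(character(0))
  adj <- lapply(igraph::as_adj_list(network), as.integer)
  cost <- pmax(0, -w)
  # components of the positive-induced subgraph
  sub <- igraph::induced_subgraph(network, pos)
  memb <- igraph::components(sub)$membership
  comp_of <- rep(NA_integer_, length(genes))
  comp_of[match(igraph::V(sub)$name, genes)] <- memb
  comp_ids <- sort(unique(memb))
  comp_weight <- vapply(comp_ids, function(k) sum(w[which(comp_of == k)]), 0)
  comp_min_gene <- vapply(comp_ids, function(k) min(genes[which(comp_of == k)]), "")
  # start from the heaviest component (ties: lexicographic smallest gene)
  ord <- order(-comp_weight, comp_min_gene)
  current <- which(comp_of == comp_ids[ord[1]])
  remaining <- setdiff(comp_ids, comp_ids[ord[1]])
  while (length(remaining) > 0) {
    dj <- node_dijkstra(adj, cost, current)
    gains <- vapply(remaining, function(k) {
      nodes_k <- which(comp_of == k)
      comp_weight[match(k, comp_ids)] - min(dj$dist[nodes_k])
    }, 0)
    if (max(gains) <= 1e-12) break
    tie <- remaining[gains >= max(gains) - 1e-12]
    k_star <- tie[order(comp_min_gene[match(tie, comp_ids)])][1]
    nodes_k <- which(comp_of == k_star)
    entry_d <- dj$dist[nodes_k]
    v_star <- nodes_k[order(entry_d, genes[nodes_k])][1]
    # walk the bridge back to the current module
    path <- integer(0)
    v <- v_star
    while (!is.na(v) && !(v %in% current)) {
      path <- c(path, v)
      v <- dj$parent[v]
    }
    current <- unique(c(current, path, nodes_k))
    # any other positive component touched by the bridge is absorbed too
    absorbed <- unique(stats::na.omit(comp_of[current]))
    remaining <- setdiff(remaining, absorbed)
  }
  sort(genes[current])
}

#' Maximum-scoring connected subnetwork
#'
#' Finds a connected module maximizing the sum of signed node scores. Small
#' networks (at most `exact_limit` nodes) are solved exactly by exhaustive
#' enumeration over vertex subsets; larger networks use a deterministic
#' heuristic that contracts connected components of positive-scoring nodes
#' and greedily merges them through the cheapest negative-node bridges
#' (multi-source Dijkstra on node costs) while the merge gain stays
#' positive. Ties are broken by lexicographic gene symbol. With no
#' positive-scoring node an empty module is returned with a warning.
#'
#' @param scored A `scored_network` from [score_nodes()].
#' @param method `"auto"` (default), `"exact"`, or `"heuristic"`.
#' @param exact_limit Largest node count solved exactly under `"auto"`
#'   (default 15).
#' @return A `pin_module` with `method_tag = "max_scoring"`.
#' @export
max_scoring_subnetwork <- function(scored, method = c("auto", "exact", "heuristic"),
                                   exact_limit = 15) {
  method <- match.arg(method)
  network <- scored$network
  scores <- setNames(scored$scores$score, scored$scores$gene)
  if (!any(scores > 0)) {
    warn("No positive-scoring node: returning an empty module.")
    return(pin_module(character(0), network, scored$scores, "max_scoring"))
  }
  if (method == "auto") {
    method <- if (igraph::vcount(network) <= exact_limit) "exact" else "heuristic"
  }
  genes <- if (method == "exact") {
    if (igraph::vcount(network) > 24) {
      stop_param("Exact search supports at most 24 nodes.")
    }
    mwcs_exact(network, scores)
  } else {
    mwcs_heuristic(network, scores)
  }
  pin_module(genes, network, scored$scores, "max_scoring")
}

#' Scan false discovery rates and select a module
#'
#' Runs [score_nodes()] and [max_scoring_subnetwork()] across a grid of
#' FDRs. Each row reports the module size and, when a ground-truth gene set
#' is supplied, the true-positive rate `|module ∩ truth| / |truth|` and
#' precision `|module ∩ truth| / |module|`. Selection: with truth, the FDR
#' maximizing F1 (ties towards the smaller, more stringent FDR); without
#' truth, the smallest FDR whose module size falls inside `size_band`
#' (falling back, with a message, to the FDR whose size is closest to the
#' band).
#'
#' @param network An interaction network (typically the subnetwork induced
#'   on the significantly differentially expressed genes).
#' @param stats A gene-statistics tibble covering the network nodes.
#' @param fit Optional `bum_fit`; fitted on `stats$p_value` when `NULL`.
#' @param fdr_grid Numeric vector of FDRs in (0, 1).
#' @param truth Optional character vector: the true module gene set.
#' @param size_band Length-2 numeric vector, the acceptable module size
#'   range used when no truth is available (default `c(10, 100)`).
#' @param method Passed to [max_scoring_subnetwork()].
#' @return An object of class `fdr_scan`: list with `table` (one row per
#'   FDR: `fdr`, `module_size`, `tp_rate`, `precision`, `f1`),
#'   `selected_fdr`, and `module` (the selected `pin_module`).
#' @export
fdr_scan <- function(network, stats, fit = NULL, fdr_grid = 10^seq(-8, -1),
                     truth = NULL, size_band = c(10, 100),
                     method = "auto") {
  if (length(fdr_grid) == 0) stop_param("`fdr_grid` must be non-empty.")
  if (any(fdr_grid <= 0 | fdr_grid >= 1)) {
    stop_param("All FDRs must lie in (0, 1).")
  }
  fdr_grid <- sort(fdr_grid)
  if (is.null(fit)) fit <- fit_bum(stats$p_value)
  modules <- vector("list", length(fdr_grid))
  rows <- vector("list", length(fdr_grid))
  for (i in seq_along(fdr_grid)) {
    scored <- score_nodes(network, stats, fit, fdr_grid[i])
    mod <- suppressWarnings(max_scoring_subnetwork(scored, method = method))
    modules[[i]] <- mod
    size <- length(mod$genes)
    if (!is.null(truth)) {
      tp <- length(intersect(mod$genes, truth))
      tp_rate <- tp / length(truth)
      precision <- if (size == 0) 0 else tp / size
      f1 <- if (tp_rate + precision == 0) 0 else
        2 * tp_rate * precision / (tp_rate + precision)
    } else {
      tp_rate <- NA_real_; precision <- NA_real_; f1 <- NA_real_
    }
    rows[[i]] <- tibble(fdr = fdr_grid[i], module_size = size,
                        tp_rate = tp_rate, precision = precision, f1 = f1)
  }
  tab <- bind_rows(rows)
  if (!is.null(truth)) {
    sel <- which(tab$f1 >= max(tab$f1) - 1e-12)[1]
  } else {
    inside <- which(tab$module_size >= size_band[1] &
                      tab$module_size <= size_band[2])
    if (length(inside) > 0) {
      sel <- inside[1]
    } else {
      dist_band <- pmax(size_band[1] - tab$module_size,
                        tab$module_size - size_band[2], 0)
      sel <- which.min(dist_band)
      inform(sprintf(
        "No module size inside [%d, %d]; selected FDR %.3g (size %d) closest to the band.",
        size_band[1], size_band[2], tab$fdr[sel], tab$module_size[sel]))
    }
  }
  structure(
    list(table = tab, selected_fdr = tab$fdr[sel], module = modules[[sel]],
         fit = fit),
    class = "fdr_scan"
  )
}

#' @export
print.fdr_scan <- function(x, ...) {
  cat(sprintf("<fdr_scan> %d FDRs; selected %.3g -> module of %d genes\n",
              nrow(x$table), x$selected_fdr, length(x$module$genes)))
  print(x$table)
  invisible(x)
}

#' @rdname fdr_scan
#' @param x An `fdr_scan`.
#' @param ... Unused.
#' @export
tidy.fdr_scan <- function(x, ...) x$table

#' @rdname fdr_scan
#' @export
glance.fdr_scan <- function(x, ...) {
  tibble(selected_fdr = x$selected_fdr,
         module_size = length(x$module$genes),
         lambda_mix = x$fit$lambda_mix, a_shape = x$fit$a_shape)
}

#' Multiple active modules by calibrated z-score search
#'
#' Aggregates per-gene z-scores \eqn{z_i = \Phi^{-1}(1 - p_i)} over a
#' candidate gene set A as \eqn{z_A = \sum_i z_i / \sqrt{|A|}} and
#' calibrates against Monte-Carlo means and standard deviations of random
#' same-size sets. Modules are grown greedily from the lowest-p start
#' nodes, restricted to within `max_depth` of each start, and returned
#' modules may share at most an `overlap` fraction of nodes (0 means
#' pairwise disjoint). Ranked by calibrated score.
#'
#' @param network An interaction network.
#' @param stats A gene-statistics tibble covering the network nodes.
#' @param n_modules Number of modules sought (default 5).
#' @param max_depth Maximum graph distance from the start node (default 2).
#' @param overlap Maximum allowed pairwise overlap fraction
#'   (`|A ∩ B| / min(|A|, |B|)`, default 0).
#' @param seed Integer seed for the Monte-Carlo calibration.
#' @param n_perm Random sets per size for calibration (default 200).
#' @return A list of `pin_module` objects (method `"active"`), each with a
#'   `calibrated_score` attribute, ranked by calibrated score.
#' @export
active_modules <- function(network, stats, n_modules = 5, max_depth = 2,
                           overlap = 0, seed = 1, n_perm = 200) {
  if (n_modules < 1) stop_param("`n_modules` must be >= 1.")
  genes <- igraph::V(network)$name
  p <- stats$p_value[match(genes, stats$gene)]
  p[is.na(p)] <- 1
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  z <- qnorm(1 - p)
  names(z) <- genes
  with_seed(seed, {
    calib_cache <- new.env(parent = emptyenv())
    calib <- function(k) {
      key <- as.character(k)
      if (!is.null(calib_cache[[key]])) return(calib_cache[[key]])
      if (k >= length(z)) {
        val <- c(mean = sum(z) / sqrt(k), sd = 1)
      } else {
        sims <- vapply(seq_len(n_perm),
                       function(i) sum(z[sample.int(length(z), k)]) / sqrt(k), 0)
        val <- c(mean = mean(sims), sd = max(sd(sims), 1e-8))
      }
      calib_cache[[key]] <- val
      val
    }
    cal_score <- function(set) {
      k <- length(set)
      cl <- calib(k)
      (sum(z[set]) / sqrt(k) - cl[["mean"]]) / cl[["sd"]]
    }
    ord <- order(p, genes)
    used <- character(0)
    accepted <- list()
    ok_overlap <- function(set) {
      if (overlap <= 0) return(!any(set %in% used))
      all(vapply(accepted, function(m) {
        length(intersect(set, m$genes)) / min(length(set), length(m$genes)) <= overlap
      }, TRUE))
    }
    for (s_ix in ord) {
      if (length(accepted) >= n_modules) break
      start <- genes[s_ix]
      if (overlap <= 0 && start %in% used) next
      allowed <- igraph::ego(network, order = max_depth, nodes = start)[[1]]$name
      if (overlap <= 0) allowed <- setdiff(allowed, used)
      current <- start
      best <- cal_score(current)
      repeat {
        nb <- setdiff(
          intersect(unique(unlist(lapply(
            igraph::ego(network, order = 1, nodes = current), function(v) v$name))),
            allowed),
          current)
        nb <- nb[vapply(nb, function(g) ok_overlap(c(current, g)), TRUE)]
        if (length(nb) == 0) break
        cand_scores <- vapply(nb, function(g) cal_score(c(current, g)), 0)
        j <- order(-cand_scores, nb)[1]
        if (cand_scores[j] <= best + 1e-12) break
        current <- c(current, nb[j])
        best <- cand_scores[j]
      }
      if (!ok_overlap(current)) next
      mod <- pin_module(current, network,
                        tibble(gene = genes, p_value = p, score = z),
                        method_tag = "active")
      attr(mod, "calibrated_score") <- best
      accepted <- c(accepted, list(mod))
      if (overlap <= 0) used <- union(used, current)
    }
    if (length(accepted) < n_modules) {
      warn(sprintf("Only %d of %d requested active modules could be formed.",
                   length(accepted), n_modules))
    }
    accepted[order(-vapply(accepted, function(m) attr(m, "calibrated_score"), 0))]
  })
}
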