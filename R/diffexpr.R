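#' Two-sample differential-expression test on log2 expression
#'
#' Per-gene Welch two-sample t-test on log2-scale values (the default
#' stand-in when the upstream study's exact test is unknown), with
#' `log_fc = mean(treated) - mean(control)`. A paired t-test variant is
#' available for designs where the arms share donors. When both arms have
#' zero variance and equal means the p-value is defined as 1.
#'
#' @param control,treated Numeric matrices (genes x samples, log2 scale)
#'   with identical rownames, >= 2 columns each.
#' @param method `"welch"` (default) or `"paired"` (requires equal numbers
#'   of columns).
#' @return A gene-statistics tibble (`gene`, `p_value`, `log_fc`, `fdr`),
#'   `fdr` being the Benjamini–Hochberg adjustment of `p_value`.
#' @export
de_test <- function(control, treated, method = c("welch", "paired")) {
  method <- match.arg(method)
  if (is.null(rownames(control)) || is.null(rownames(treated)) ||
      !identical(rownames(control), rownames(treated))) {
    abort("`control` and `treated` must carry identical gene rownames.",
          class = "pinmod_error_alignment")
  }
  if (ncol(control) < 2 || ncol(treated) < 2) {
    stop_param("Each arm needs at least 2 samples.")
  }
  n1 <- ncol(control); n2 <- ncol(treated)
  m1 <- rowMeans(control); m2 <- rowMeans(treated)
  v1 <- rowSums((control - m1)^2) / (n1 - 1)
  v2 <- rowSums((treated - m2)^2) / (n2 - 1)
  lfc <- m2 - m1
  if (method == "welch") {
    se2 <- v1 / n1 + v2 / n2
    t_stat <- (m2 - m1) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * pt(-abs(t_stat), df)
  } else {
    if (n1 != n2) stop_param("Paired test requires equal sample counts.")
    d <- treated - control
    md <- rowMeans(d)
    vd <- rowSums((d - md)^2) / (n1 - 1)
    t_stat <- md / sqrt(vd / n1)
    p <- 2 * pt(-abs(t_stat), n1 - 1)
  }
  # degenerate rows: no variance anywhere
  degen <- !is.finite(p)
  p[degen] <- ifelse(abs(lfc[degen]) < .Machine$double.eps^0.5, 1,
                     .Machine$double.xmin)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  tibble(gene = rownames(control), p_value = as.numeric(p),
         log_fc = as.numeric(lfc), fdr = p.adjust(p, "BH"))
}

#' Select significantly differentially expressed genes (SDGs)
#'
#' Genes with `p_value` strictly below `alpha`, deliberately without
#' multiple-testing correction: the loose pre-selection feeds a network
#' stage that reduces false positives by requiring collective differential
#' expression.
#'
#' @param stats A gene-statistics tibble (needs `gene`, `p_value`).
#' @param alpha Significance threshold (default 0.01, strict `<`).
#' @return Sorted character vector of SDG symbols.
#' @export
select_sdgs <- function(stats, alpha = 0.01) {
  stopifnot(all(c("gene", "p_value") %in% names(stats)))
  sort(unique(stats$gene[stats$p_value < alpha]))
}

#' Select significant differentially expressed miRNAs
#'
#' Rows with `p_value` strictly below `alpha`, annotated with a regulation
#' direction from the fold change (treated/control ratio): above 1 is
#' upregulated, below 1 downregulated, exactly 1 kept but flagged
#' `"ambiguous"`. When no `fold_change` column is present a `direction`
#' column (`"up"`/`"down"`) is used as-is.
#'
#' @param stats A miRNA statistics tibble (`mirna`, `p_value`, and
#'   `fold_change` or `direction`).
#' @param alpha Significance threshold (default 0.05, strict `<`).
#' @return The filtered tibble with a `direction` column, ordered
#'   upregulated first, then by p-value.
#' @export
select_significant_mirnas <- function(stats, alpha = 0.05) {
  stopifnot(all(c("mirna", "p_value") %in% names(stats)))
  out <- as_tibble(stats)[stats$p_value < alpha, , drop = FALSE]
  if ("fold_change" %in% names(out)) {
    if (any(out$fold_change <= 0)) stop_param("`fold_change` must be > 0.")
    out$direction <- ifelse(out$fold_change > 1, "up",
                            ifelse(out$fold_change < 1, "down", "ambiguous"))
  } else if (!"direction" %in% names(out)) {
    stop_param("`stats` needs a `fold_change` or `direction` column.")
  }
  out |>
    mutate(.dir_rank = match(.data$direction, c("up", "down", "ambiguous"))) |>
    arrange(.data$.dir_rank, .data$p_value) |>
    select(-".dir_rank")
}

#' Read a log2 expression matrix from TSV
#'
#' Expects a header row of sample ids and gene symbols in the first column.
#'
#' @param path Path to a tab-separated file.
#' @return A numeric matrix, genes x samples.
#' @export
read_expression_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- normalize_symbols(df[[1]])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop_param("Expression matrix contains missing values.")
  m
}

#' Read/write gene statistics TSV
#'
#' Tab-separated with columns `gene`, `p_value`, `log_fc` and optional
#' `fdr` (the additional-file schema: gene, p-value, fold change, FDR).
#'
#' @param path File path.
#' @return `read_gene_stats()` returns a tibble; `write_gene_stats()`
#'   invisibly returns `path`.
#' @export
read_gene_stats <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("gene", "p_value", "log_fc") %in% names(df)))
  df$gene <- normalize_symbols(df$gene)
  as_tibble(df)
}

#' @rdname read_gene_stats
#' @param stats A gene-statistics tibble.
#' @export
write_gene_stats <- function(stats, path) {
  readr::write_tsv(stats, path)
  invisible(path)
}

#' Read a miRNA statistics TSV (`mirna`, `p_value`, `fold_change`)
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_mirna_stats <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("mirna", "p_value") %in% names(df)))
  as_tibble(df)
}
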