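#' Fit a beta-uniform mixture (BUM) to p-values
#'
#' Models a p-value distribution as uniform noise plus a Beta(a, 1) signal
#' component, with density
#' \deqn{f(p) = \lambda + (1-\lambda)\, a\, p^{a-1}, \quad p \in (0, 1],}
#' and fits \eqn{(\lambda, a)} by maximum likelihood using bounded
#' quasi-Newton optimization from a deterministic grid of starting points.
#'
#' @param p_values Numeric vector of p-values in (0, 1], length >= 50.
#' @return An object of class `bum_fit` with elements `lambda_mix`,
#'   `a_shape`, `log_likelihood`, `n_points`.
#' @examples
#' p <- c(rbeta(300, 0.2, 1), runif(700))
#' fit <- fit_bum(p)
#' glance(fit)
#' @export
fit_bum <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop_param("All p-values must lie in (0, 1].")
  }
  if (length(p) < 50) stop_param("Need at least 50 p-values to fit the mixture.")
  if (diff(range(p)) < .Machine$double.eps) {
    abort("All p-values are identical: the mixture fit is degenerate.",
          class = "pinmod_error_degenerate")
  }
  lp <- log(p)
  nll <- function(par) {
    lambda <- par[1]; a <- par[2]
    -sum(log(lambda + (1 - lambda) * a * exp((a - 1) * lp)))
  }
  eps <- 1e-6
  starts <- expand.grid(lambda = c(0.1, 0.5, 0.9), a = c(0.1, 0.3, 0.6, 0.9))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(c(starts$lambda[i], starts$a[i]), nll, method = "L-BFGS-B",
            lower = c(eps, eps), upper = c(1 - eps, 1 - eps)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    abort("Beta-uniform mixture optimization failed from every start.",
          class = "pinmod_error_degenerate")
  }
  structure(
    list(lambda_mix = best$par[1], a_shape = best$par[2],
         log_likelihood = -best$value, n_points = length(p)),
    class = "bum_fit"
  )
}

#' Beta-uniform mixture density
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param fit A `bum_fit`, or a list with `lambda_mix` and `a_shape`.
#' @return The mixture density at `p`.
#' @export
bum_density <- function(p, fit) {
  fit$lambda_mix + (1 - fit$lambda_mix) * fit$a_shape * p^(fit$a_shape - 1)
}

#' @export
print.bum_fit <- function(x, ...) {
  cat(sprintf(
    "<bum_fit> lambda = %.4f, a = %.4f (logLik %.2f, n = %d)\n",
    x$lambda_mix, x$a_shape, x$log_likelihood, x$n_points))
  invisible(x)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname fit_bum
#' @param x A `bum_fit`.
#' @param ... Unused.
#' @export
tidy.bum_fit <- function(x, ...) {
  tibble(term = c("lambda_mix", "a_shape"),
         estimate = c(x$lambda_mix, x$a_shape))
}

#' @rdname fit_bum
#' @export
glance.bum_fit <- function(x, ...) {
  tibble(lambda_mix = x$lambda_mix, a_shape = x$a_shape,
         log_likelihood = x$log_likelihood, n_points = x$n_points)
}

#' p-value threshold at which the node score crosses zero
#'
#' For a fitted mixture, the estimated noise fraction is bounded by
#' \eqn{\pi = \lambda + (1-\lambda)a}. The threshold
#' \deqn{\tau(\mathrm{FDR}) = \left(\frac{\pi - \mathrm{FDR}\,\lambda}
#'   {\mathrm{FDR}\,(1-\lambda)}\right)^{1/(a-1)}}
#' is the p-value at which the mixture's signal/noise posterior odds reach
#' the chosen false discovery rate; node scores are positive below it and
#' negative above it. \eqn{\tau} is strictly increasing in the FDR, which is
#' how the FDR acts as the module-size dial.
#'
#' @param fit A `bum_fit`.
#' @param fdr False discovery rate in (0, 1).
#' @return The threshold p-value (may exceed 1 for very permissive FDRs, in
#'   which case every node scores positive).
#' @export
tau_threshold <- function(fit, fdr) {
  if (!is.numeric(fdr) || any(fdr <= 0) || any(fdr >= 1)) {
    stop_param("`fdr` must lie in (0, 1).")
  }
  pi_noise <- fit$lambda_mix + (1 - fit$lambda_mix) * fit$a_shape
  ((pi_noise - fdr * fit$lambda_mix) /
      (fdr * (1 - fit$lambda_mix)))^(1 / (fit$a_shape - 1))
}

#' Score network nodes from differential-expression p-values
#'
#' Converts each node's p-value into the signed log-likelihood-ratio score
#' \deqn{s(p) = (a - 1)\,(\ln p - \ln \tau(\mathrm{FDR})),}
#' positive for \eqn{p < \tau} and negative for \eqn{p > \tau}. Network
#' nodes without a p-value are assigned p = 1 (with a message).
#'
#' @param network An interaction network.
#' @param stats A gene-statistics tibble (`gene`, `p_value`).
#' @param fit A `bum_fit` (typically fitted on the full p-value vector, not
#'   only the network's nodes).
#' @param fdr False discovery rate controlling the score zero-crossing.
#' @return An object of class `scored_network`: list with `network`,
#'   `scores` (tibble `gene`, `p_value`, `score`), `fit`, `fdr`, `tau`.
#' @export
score_nodes <- function(network, stats, fit, fdr) {
  genes <- igraph::V(network)$name
  p <- stats$p_value[match(genes, stats$gene)]
  n_missing <- sum(is.na(p))
  if (n_missing > 0) {
    inform(sprintf("%d network node(s) without a p-value were assigned p = 1.",
                   n_missing))
    p[is.na(p)] <- 1
  }
  tau <- tau_threshold(fit, fdr)
  score <- (fit$a_shape - 1) * (log(p) - log(tau))
  structure(
    list(network = network,
         scores = tibble(gene = genes, p_value = p, score = as.numeric(score)),
         fit = fit, fdr = fdr, tau = tau),
    class = "scored_network"
  )
}

#' @export
print.scored_network <- function(x, ...) {
  cat(sprintf(
    "<scored_network> %d nodes (%d positive) at FDR %.3g, tau = %.4g\n",
    nrow(x$scores), sum(x$scores$score > 0), x$fdr, x$tau))
  invisible(x)
}
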