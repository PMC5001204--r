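#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr filter mutate arrange select group_by summarise ungroup
#'   distinct bind_rows left_join pull rename slice_head n desc across
#' @importFrom stats p.adjust phyper pt qnorm rbeta rbinom rnorm runif
#'   optim setNames t.test sd
#' @importFrom utils head
NULL

# Normalize gene/miRNA symbols: trim whitespace, optionally uppercase.
normalize_symbols <- function(x, case = c("upper", "preserve")) {
  case <- match.arg(case)
  x <- trimws(as.character(x))
  if (case == "upper") x <- toupper(x)
  x
}

stop_param <- function(msg, ...) {
  abort(msg, class = "pinmod_error_parameter", ...)
}

# Run code with a locally seeded RNG, restoring the caller's RNG state.
# All generators route randomness through this so they are pure in `seed`.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_param("`seed` must be a single integer.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific child seed from a master seed (stays < 2^31).
child_seed <- function(seed, stream) {
  (as.integer(seed) * 1103L + as.integer(stream) * 12289L) %% 2147483547L
}
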