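# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Rating scales are discretised with conventional "round half up" rather than
#' the IEEE banker's rounding that [base::round()] applies at .5 ties.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
#' @noRd
round_half_up <- function(x) {
  floor(x + 0.5)
}

#' Clamp to a closed interval
#' @noRd
clamp <- function(x, lo, hi) {
  pmin(hi, pmax(lo, x))
}

#' Discretise a latent rating onto the 1-10 scale
#' @noRd
discretise_rating <- function(x) {
  as.integer(clamp(round_half_up(x), 1L, 10L))
}

#' Standardise a vector (z-score); constant input yields zeros
#' @noRd
z_standardise <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores (or removes) the global `.Random.seed` afterwards so generators are
#' deterministic without clobbering the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  }
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a named sub-seed from a top-level seed
#'
#' All randomness in a pipeline run flows from one seed through named
#' sub-streams (e.g. "design", "human", "agent:gpt-4o", "bootstrap"). The
#' derivation hashes the label into a 31-bit integer so downstream
#' `set.seed()` calls stay within R's integer range.
#'
#' @param seed integer top-level seed.
#' @param label character stream label.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "human")
#' derive_seed(1, "agent:gpt-4o")
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label),
            length(label) == 1)
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(label)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

#' Abort unless required columns are present, naming the first missing one
#' @noRd
check_columns <- function(data, cols, what = "input") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing required column '%s'", what, missing[[1]]),
         call. = FALSE)
  }
  invisible(data)
}

CONTEXTS <- c("fitting", "unfitting")

#' Validate a context label vector
#' @noRd
check_context <- function(context) {
  context <- match.arg(context, CONTEXTS)
  context
}
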