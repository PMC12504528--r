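# A-priori power analysis for the matched-pairs design.
#
# The context manipulation is within subject, so the planning tool is the
# one-sample t-test on paired differences. Power is evaluated with the exact
# noncentral-t distribution (noncentrality d * sqrt(n), df = n - 1); no normal
# approximation is used anywhere.

#' Specify a power analysis
#'
#' @param effect_size_d Cohen's d of the paired differences (> 0 for
#'   [required_n()]).
#' @param alpha significance level in (0, 1).
#' @param target_power desired power in (0, 1); must exceed `alpha`.
#' @param tail `"two"` (default) or `"one"`.
#' @return a `power_spec` list.
#' @export
#' @examples
#' power_spec(effect_size_d = 0.62, alpha = 0.001, target_power = 0.95)
power_spec <- function(effect_size_d, alpha = 0.05, target_power = 0.80,
                       tail = c("two", "one")) {
  tail <- match.arg(tail)
  stopifnot(is.numeric(effect_size_d), length(effect_size_d) == 1,
            alpha > 0, alpha < 1,
            target_power > 0, target_power < 1)
  if (target_power <= alpha) {
    stop("`target_power` must exceed `alpha`", call. = FALSE)
  }
  structure(list(effect_size_d = effect_size_d, alpha = alpha,
                 target_power = target_power, tail = tail),
            class = "power_spec")
}

#' Achieved power of a matched-pairs t-test
#'
#' @param n number of pairs (>= 2).
#' @param spec a [power_spec()].
#' @return rejection probability under the alternative, from the noncentral-t
#'   CDF. Monotone non-decreasing in `n` and in the effect size; at d = 0 it
#'   equals `alpha`.
#' @export
#' @examples
#' achieved_power(69, power_spec(0.62, alpha = 0.001, target_power = 0.95))
achieved_power <- function(n, spec) {
  stopifnot(inherits(spec, "power_spec"))
  if (!is.numeric(n) || length(n) != 1 || n < 2) {
    stop("`n` must be at least 2", call. = FALSE)
  }
  df <- n - 1
  ncp <- spec$effect_size_d * sqrt(n)
  if (spec$tail == "two") {
    tcrit <- stats::qt(1 - spec$alpha / 2, df)
    stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-tcrit, df, ncp = ncp)
  } else {
    tcrit <- stats::qt(1 - spec$alpha, df)
    stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE)
  }
}

#' Smallest sample size reaching the target power
#'
#' @param spec a [power_spec()] with a strictly positive effect size.
#' @param n_max search ceiling (guards unreachable targets).
#' @return smallest integer `n >= 2` whose [achieved_power()] meets
#'   `spec$target_power`.
#' @export
#' @examples
#' required_n(power_spec(0.62, alpha = 0.001, target_power = 0.95)) # 69
required_n <- function(spec, n_max = 1e6) {
  stopifnot(inherits(spec, "power_spec"))
  if (spec$effect_size_d <= 0) {
    stop("`effect_size_d` must be positive to reach power above alpha",
         call. = FALSE)
  }
  # Bracket by doubling, then binary-search: power is monotone in n.
  lo <- 2L
  if (achieved_power(lo, spec) >= spec$target_power) {
    return(lo)
  }
  hi <- 4
  while (achieved_power(hi, spec) < spec$target_power) {
    lo <- hi
    hi <- hi * 2
    if (hi > n_max) {
      stop("target power not reached below `n_max`", call. = FALSE)
    }
  }
  while (hi - lo > 1) {
    mid <- (lo + hi) %/% 2
    if (achieved_power(mid, spec) >= spec$target_power) hi <- mid else lo <- mid
  }
  as.integer(hi)
}
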