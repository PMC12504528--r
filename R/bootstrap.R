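# The cross-agent prediction engine: pair an agent's JOLs with human
# recognition outcomes and bootstrap the JOL-accuracy slope while preserving
# the grouping by units (subjects or replicates) and items.

#' Configure the structured bootstrap
#'
#' @param n_iterations bootstrap iterations (default 1000).
#' @param ci_level confidence level for the percentile interval (default
#'   0.95).
#' @param resample_mode `"cluster"` (default): resample units and items with
#'   replacement, the mode used for confidence intervals. `"permute_null"`:
#'   shuffle JOL values within each unit to produce a null slope
#'   distribution, kept as a diagnostic.
#' @param seed integer seed; the run is deterministic given the seed.
#' @return a `bootstrap_config` list.
#' @export
bootstrap_config <- function(n_iterations = 1000, ci_level = 0.95,
                             resample_mode = c("cluster", "permute_null"),
                             seed = 1) {
  resample_mode <- match.arg(resample_mode)
  stopifnot(n_iterations >= 1, ci_level > 0, ci_level < 1)
  structure(list(n_iterations = as.integer(n_iterations),
                 ci_level = ci_level, resample_mode = resample_mode,
                 seed = as.integer(seed)),
            class = "bootstrap_config")
}

#' Pair one agent's ratings with human recognition outcomes
#'
#' For the human agent, each row pairs a subject's JOL for a studied item with
#' that same subject's binary recognition correctness (one row per subject x
#' studied item in the requested context). For a machine agent, each row
#' pairs one stochastic replicate's JOL for an item with the human cohort's
#' per-item accuracy proportion in that context (one row per replicate x
#' item); by construction every replicate of an item shares the item's
#' outcome. JOLs are z-standardised within agent x context over the paired
#' rows, making slopes comparable across agents.
#'
#' @param ratings rating rows for a single agent (columns `agent`, `unit_id`,
#'   `item_id`, `context`, `jol`).
#' @param recognition human recognition rows (columns `subject_id`,
#'   `item_id`, `role`, `context`, `correct`).
#' @param context `"fitting"` or `"unfitting"`.
#' @return a `paired_dataset` tibble with columns `agent`, `context`,
#'   `unit_id`, `item_id`, `jol_z`, `outcome`.
#' @export
pair_agent_with_human <- function(ratings, recognition, context) {
  context <- check_context(context)
  check_columns(ratings, c("agent", "unit_id", "item_id", "context", "jol"),
                "ratings")
  check_columns(recognition, c("subject_id", "item_id", "role", "context",
                               "correct"), "recognition")
  agent <- unique(ratings$agent)
  if (length(agent) != 1) {
    stop("`ratings` must contain a single agent", call. = FALSE)
  }
  r <- dplyr::filter(ratings, .data$context == !!context)
  targets <- dplyr::filter(recognition, .data$role == "target",
                           .data$context == !!context)
  if (nrow(r) == 0 || nrow(targets) == 0) {
    stop("pairing error: no ratings or no target trials in this context",
         call. = FALSE)
  }

  if (identical(agent, "human")) {
    paired <- dplyr::inner_join(
      dplyr::select(r, "unit_id", "item_id", "jol"),
      dplyr::select(targets, unit_id = "subject_id", "item_id", "correct"),
      by = c("unit_id", "item_id")
    )
    if (nrow(paired) == 0) {
      stop("pairing error: no overlap between ratings and recognition trials",
           call. = FALSE)
    }
    out <- tibble::tibble(
      agent = agent, context = context,
      unit_id = paired$unit_id, item_id = paired$item_id,
      jol_z = z_standardise(paired$jol),
      outcome = as.numeric(paired$correct)
    )
  } else {
    item_acc <- dplyr::summarise(
      dplyr::group_by(targets, .data$item_id),
      outcome = mean(as.numeric(.data$correct)), .groups = "drop")
    paired <- dplyr::inner_join(
      dplyr::select(r, "unit_id", "item_id", "jol"),
      item_acc, by = "item_id")
    if (nrow(paired) == 0) {
      stop("pairing error: no overlapping items between agent ratings and human trials",
           call. = FALSE)
    }
    out <- tibble::tibble(
      agent = agent, context = context,
      unit_id = paired$unit_id, item_id = paired$item_id,
      jol_z = z_standardise(paired$jol),
      outcome = paired$outcome
    )
  }
  class(out) <- c("paired_dataset", class(out))
  out
}

#' Run the structured bootstrap of the JOL-accuracy slope
#'
#' In `cluster` mode each iteration draws units with replacement and items
#' with replacement, assembles the crossed rows present in the original data
#' (resampled clusters keep their internal structure and get fresh
#' identities), and refits the crossed random-intercept slope model
#' ([fit_slope_lmm()]); in `permute_null` mode each iteration instead
#' shuffles the JOL values within each unit and refits on the intact design,
#' yielding a null distribution. Iterations whose fit fails or does not
#' converge are dropped and counted. The point estimate is the mean of the
#' slope draws; the interval is the percentile interval at `ci_level`.
#'
#' @param data a [pair_agent_with_human()] result, or any data frame with
#'   columns `unit_id`, `item_id`, `jol_z`, `outcome` (and optionally
#'   `agent`, `context`).
#' @param config a [bootstrap_config()].
#' @return a `slope_distribution`: list with `agent`, `context`, `slopes`
#'   (one per successful iteration), `point_estimate`, `ci_lower`,
#'   `ci_upper`, `excludes_zero`, `n_failed`, plus the configuration used.
#' @export
run_bootstrap <- function(data, config = bootstrap_config()) {
  stopifnot(inherits(config, "bootstrap_config"))
  check_columns(data, c("unit_id", "item_id", "jol_z", "outcome"),
                "paired data")
  units <- sort(unique(data$unit_id))
  items <- sort(unique(data$item_id))
  if (length(units) < 2 || length(items) < 2) {
    stop("need at least 2 units and 2 items to bootstrap", call. = FALSE)
  }
  U <- length(units)
  I <- length(items)
  ui <- match(data$unit_id, units)
  ii <- match(data$item_id, items)
  M <- matrix(NA_integer_, U, I)
  M[cbind(ui, ii)] <- seq_len(nrow(data))
  y <- as.numeric(data$outcome)
  jz <- as.numeric(data$jol_z)
  unit_split <- split(seq_len(nrow(data)), ui)

  one_iteration <- function() {
    if (config$resample_mode == "cluster") {
      su <- sample.int(U, U, replace = TRUE)
      si <- sample.int(I, I, replace = TRUE)
      sub <- M[su, si, drop = FALSE]
      keep <- which(!is.na(sub))
      rows <- sub[keep]
      fit_slope_lmm(y[rows], jz[rows],
                    subject_ids = ((keep - 1L) %% U) + 1L,
                    item_ids = ((keep - 1L) %/% U) + 1L)
    } else {
      perm <- jz
      for (idx in unit_split) {
        perm[idx] <- jz[idx][sample.int(length(idx))]
      }
      fit_slope_lmm(y, perm, subject_ids = ui, item_ids = ii)
    }
  }

  slopes <- numeric(0)
  n_failed <- 0L
  with_seed(config$seed, {
    for (b in seq_len(config$n_iterations)) {
      fit <- tryCatch(one_iteration(), error = function(e) NULL)
      if (is.null(fit) || !isTRUE(fit$converged)) {
        n_failed <- n_failed + 1L
      } else {
        slopes <- c(slopes, unname(fit$coefficients[["jol"]]))
      }
    }
  })
  if (length(slopes) == 0) {
    stop("bootstrap failure: all iterations failed", call. = FALSE)
  }
  a <- (1 - config$ci_level) / 2
  ci <- unname(stats::quantile(slopes, c(a, 1 - a)))
  # Zero-inclusion up to solver precision: interval endpoints within machine
  # noise of zero (e.g. from exactly-zero slope fits) cannot exclude it.
  eps <- sqrt(.Machine$double.eps)
  structure(list(
    agent = if ("agent" %in% names(data)) unique(data$agent) else NA_character_,
    context = if ("context" %in% names(data)) unique(data$context) else NA_character_,
    slopes = slopes,
    point_estimate = mean(slopes),
    ci_lower = ci[[1]],
    ci_upper = ci[[2]],
    excludes_zero = ci[[1]] > eps || ci[[2]] < -eps,
    n_failed = n_failed,
    n_iterations = config$n_iterations,
    ci_level = config$ci_level,
    resample_mode = config$resample_mode,
    seed = config$seed
  ), class = "slope_distribution")
}

#' @export
print.slope_distribution <- function(x, ...) {
  cat(sprintf(
    "<slope_distribution> %s / %s: B = %.3f, %d%% CI [%.3f, %.3f]%s (%d draws, %d failed, mode %s)\n",
    x$agent, x$context, x$point_estimate, round(100 * x$ci_level),
    x$ci_lower, x$ci_upper,
    if (x$excludes_zero) " *excludes zero*" else "",
    length(x$slopes), x$n_failed, x$resample_mode))
  invisible(x)
}

#' Bootstrap every agent x context and tabulate the slope distributions
#'
#' Runs [run_bootstrap()] for each paired dataset with an independent
#' sub-seed derived from `config$seed` and the agent/context labels, so runs
#' are reproducible end to end while agents get distinct streams. A failing
#' agent yields a flagged row rather than aborting the comparison.
#'
#' @param datasets list of `paired_dataset` objects (e.g. human and each
#'   machine rater, per context).
#' @param config a [bootstrap_config()]; its seed is the master seed.
#' @return list with `summary` (tibble: `agent`, `context`, `B`, `ci_lower`,
#'   `ci_upper`, `excludes_zero`, `n_failed`, `failed`) and `distributions`
#'   (named list of `slope_distribution`, `NULL` where a run failed).
#' @export
compare_agents <- function(datasets, config = bootstrap_config()) {
  stopifnot(length(datasets) >= 1)
  rows <- vector("list", length(datasets))
  dists <- vector("list", length(datasets))
  labels <- character(length(datasets))
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    agent <- unique(d$agent)
    context <- unique(d$context)
    labels[[i]] <- paste0("bootstrap:", agent, ":", context)
    sub <- config
    sub$seed <- derive_seed(config$seed, labels[[i]])
    res <- tryCatch(run_bootstrap(d, sub), error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- tibble::tibble(
        agent = agent, context = context, B = NA_real_,
        ci_lower = NA_real_, ci_upper = NA_real_, excludes_zero = NA,
        n_failed = NA_integer_, failed = TRUE)
      dists[i] <- list(NULL)
    } else {
      rows[[i]] <- tibble::tibble(
        agent = agent, context = context, B = res$point_estimate,
        ci_lower = res$ci_lower, ci_upper = res$ci_upper,
        excludes_zero = res$excludes_zero, n_failed = res$n_failed,
        failed = FALSE)
      dists[[i]] <- res
    }
  }
  names(dists) <- make.unique(labels)
  list(summary = dplyr::bind_rows(rows), distributions = dists)
}
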