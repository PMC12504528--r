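# End-to-end orchestration: simulate the study's data streams, run the
# confirmatory GLMM and the cross-agent bootstrap, and write tabular/JSON
# outputs with a reproducibility manifest. All randomness flows from the
# single top-level seed through named sub-streams (items, human,
# agent:<label>, bootstrap).

DEFAULT_AGENTS <- c("gpt-3.5-turbo-0125", "gpt-4-turbo-2024-04-09",
                    "gpt-4o-2024-05-13")

#' Assemble a pipeline run configuration
#'
#' @param seed mandatory top-level integer seed.
#' @param n_subjects human cohort size (default 78).
#' @param n_items item-bank size (default 45).
#' @param omit_item_id item omitted from human designs (default 8); machine
#'   raters always see the full bank.
#' @param agent_labels machine rater labels (default: the three chat models
#'   compared against the human cohort).
#' @param human named list of overrides for [human_cohort_params()].
#' @param agents named list of overrides for [agent_sampler_config()]
#'   (applied to every agent).
#' @param bootstrap named list of overrides for [bootstrap_config()].
#' @param power named list with `effect_size_d`, `alpha`, `target_power`,
#'   `tail` for [power_spec()].
#' @return a `run_config` list.
#' @export
run_config <- function(seed,
                       n_subjects = 78,
                       n_items = 45,
                       omit_item_id = 8,
                       agent_labels = DEFAULT_AGENTS,
                       human = list(),
                       agents = list(),
                       bootstrap = list(),
                       power = list()) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("`seed` is mandatory", call. = FALSE)
  }
  power_defaults <- list(effect_size_d = 0.62, alpha = 0.001,
                         target_power = 0.95, tail = "two")
  structure(list(
    seed = as.integer(seed),
    n_subjects = as.integer(n_subjects),
    n_items = as.integer(n_items),
    omit_item_id = omit_item_id,
    agent_labels = agent_labels,
    human = human,
    agents = agents,
    bootstrap = bootstrap,
    power = utils::modifyList(power_defaults, power)
  ), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' The file is a flat key-value document mirroring the arguments of
#' [run_config()]; `seed` is mandatory.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file '%s' does not exist", path), call. = FALSE)
  }
  vals <- yaml::read_yaml(path)
  if (is.null(vals$seed)) {
    stop("config must set `seed`", call. = FALSE)
  }
  do.call(run_config, vals)
}

write_table_atomic <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  utils::write.csv(df, tmp, row.names = FALSE)
  if (!file.rename(tmp, path)) {
    stop(sprintf("could not write '%s'", path), call. = FALSE)
  }
  invisible(path)
}

read_table_checked <- function(path, cols, what) {
  if (!file.exists(path)) {
    stop(sprintf("validation error: required file '%s' is missing", path),
         call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, cols, what)
  tibble::as_tibble(df)
}

#' Simulate the full study data and write it to disk
#'
#' Writes the item bank, the counterbalanced design, the human learning-phase
#' ratings and recognition test, and one rating table per machine agent
#' (100 replicates x items x 2 contexts each), plus `manifest.json` recording
#' seeds, parameter values, row counts and file checksums. Files are written
#' atomically (temp file + rename).
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
cmd_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, mode = 2) != 0) {
    stop(sprintf("output directory '%s' is not writable", out_dir),
         call. = FALSE)
  }
  items <- build_item_bank(config$n_items, seed = derive_seed(config$seed, "items"))
  design <- build_design(items, config$n_subjects,
                         omit_item_id = config$omit_item_id)
  hp <- do.call(human_cohort_params, utils::modifyList(
    list(n_subjects = config$n_subjects,
         seed = derive_seed(config$seed, "human")),
    config$human))
  human <- simulate_human_cohort(hp, design, items)
  agent_tabs <- lapply(config$agent_labels, function(lab) {
    cfg <- do.call(agent_sampler_config, utils::modifyList(
      list(model_label = lab, seed = derive_seed(config$seed, paste0("agent:", lab))),
      config$agents))
    sample_agent_ratings(cfg, items)
  })
  agent_ratings <- dplyr::bind_rows(agent_tabs)

  files <- list(
    items = "items.csv", design = "design.csv",
    human_ratings = "human_ratings.csv",
    human_recognition = "human_recognition.csv",
    agent_ratings = "agent_ratings.csv"
  )
  tables <- list(items, design_table(design), human$ratings,
                 human$recognition, agent_ratings)
  for (k in seq_along(files)) {
    write_table_atomic(tables[[k]], file.path(out_dir, files[[k]]))
  }
  manifest <- list(
    seed = config$seed,
    sub_seeds = c(
      stats::setNames(list(derive_seed(config$seed, "items"),
                           derive_seed(config$seed, "human")),
                      c("items", "human")),
      stats::setNames(
        lapply(config$agent_labels,
               function(l) derive_seed(config$seed, paste0("agent:", l))),
        paste0("agent:", config$agent_labels))),
    params = list(n_subjects = config$n_subjects, n_items = config$n_items,
                  omit_item_id = config$omit_item_id,
                  base_accuracy = as.list(hp$base_accuracy),
                  jol_slope = as.list(hp$jol_slope),
                  subject_sd = hp$subject_sd, item_sd = hp$item_sd),
    row_counts = stats::setNames(lapply(tables, nrow), names(files)),
    md5 = stats::setNames(
      as.list(unname(tools::md5sum(file.path(out_dir, unlist(files))))),
      unlist(files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Analyze simulated or user-supplied study tables
#'
#' Reads the tables written by [cmd_simulate()] (or user-supplied files with
#' the same schemas), fits the confirmatory binomial GLMM with its type-2
#' Wald table, pairs every agent with the human recognition outcomes in both
#' contexts, runs the structured bootstrap per agent x context, and writes:
#' `glmm_fit.json`, `term_tests.csv`, `slope_summary.csv`, one
#' `slopes_<agent>_<context>.csv` of raw draws per cell, and a one-page
#' `report.txt` stating which agents' intervals exclude zero per context.
#'
#' @param config a [run_config()].
#' @param data_dir directory holding the input tables.
#' @param out_dir output directory (default: `data_dir`).
#' @return invisibly, a list with the GLMM `mixed_fit`, the term-test tibble
#'   and the [compare_agents()] result.
#' @export
cmd_analyze <- function(config, data_dir, out_dir = data_dir) {
  stopifnot(inherits(config, "run_config"))
  ratings_h <- read_table_checked(
    file.path(data_dir, "human_ratings.csv"),
    c("agent", "unit_id", "item_id", "context", "relatedness", "jol"),
    "human ratings")
  recognition <- read_table_checked(
    file.path(data_dir, "human_recognition.csv"),
    c("subject_id", "item_id", "role", "context", "response", "correct"),
    "human recognition")
  agent_ratings <- read_table_checked(
    file.path(data_dir, "agent_ratings.csv"),
    c("agent", "unit_id", "item_id", "context", "relatedness", "jol"),
    "agent ratings")
  recognition$correct <- as.logical(recognition$correct)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # Confirmatory GLMM on target trials (JOLs exist only for studied items).
  trials <- dplyr::inner_join(
    dplyr::select(ratings_h, subject_id = "unit_id", "item_id", "context", "jol"),
    dplyr::select(dplyr::filter(recognition, .data$role == "target"),
                  "subject_id", "item_id", "context", "correct"),
    by = c("subject_id", "item_id", "context"))
  glmm <- fit_binomial_glmm(trials)
  tests <- type2_anova(glmm)

  bc <- do.call(bootstrap_config, utils::modifyList(
    list(seed = derive_seed(config$seed, "bootstrap")), config$bootstrap))
  datasets <- list()
  for (ctx in CONTEXTS) {
    datasets <- c(datasets, list(pair_agent_with_human(ratings_h, recognition, ctx)))
    for (lab in unique(agent_ratings$agent)) {
      one <- dplyr::filter(agent_ratings, .data$agent == !!lab)
      datasets <- c(datasets, list(pair_agent_with_human(one, recognition, ctx)))
    }
  }
  cmp <- compare_agents(datasets, bc)

  jsonlite::write_json(list(
    coefficients = as.list(glmm$coefficients),
    se = as.list(stats::setNames(sqrt(diag(glmm$vcov)),
                                 names(glmm$coefficients))),
    variance_components = as.list(glmm$variance_components),
    converged = glmm$converged, n_obs = glmm$n_obs,
    term_tests = tests
  ), file.path(out_dir, "glmm_fit.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
  write_table_atomic(tests, file.path(out_dir, "term_tests.csv"))
  write_table_atomic(cmp$summary, file.path(out_dir, "slope_summary.csv"))
  for (d in cmp$distributions) {
    if (is.null(d)) next
    write_table_atomic(
      tibble::tibble(iteration = seq_along(d$slopes), slope = d$slopes),
      file.path(out_dir, sprintf("slopes_%s_%s.csv",
                                 gsub("[^A-Za-z0-9.-]", "_", d$agent),
                                 d$context)))
  }
  writeLines(render_report(cmp$summary, tests, bc), file.path(out_dir, "report.txt"))
  invisible(list(glmm = glmm, term_tests = tests, comparison = cmp))
}

render_report <- function(summary, tests, bc) {
  lines <- c(
    "Cross-agent prediction of human recognition memory from JOLs",
    "============================================================",
    "",
    sprintf("Bootstrap: %d iterations, %d%% percentile CIs, mode '%s'.",
            bc$n_iterations, round(100 * bc$ci_level), bc$resample_mode),
    "",
    "Confirmatory GLMM (type-2 Wald tests):",
    sprintf("  %-12s chi^2(%d) = %6.2f, p = %.4g",
            tests$term, tests$df, tests$chisq, tests$p_value),
    "")
  for (ctx in CONTEXTS) {
    lines <- c(lines, sprintf("In the %s context:", ctx))
    s <- summary[summary$context == ctx, ]
    for (k in seq_len(nrow(s))) {
      row <- s[k, ]
      verdict <- if (isTRUE(row$failed)) {
        "bootstrap FAILED"
      } else if (isTRUE(row$excludes_zero)) {
        "CI excludes zero: significant positive JOL-accuracy slope"
      } else {
        "CI includes zero: no reliable JOL-accuracy relationship"
      }
      lines <- c(lines, sprintf("  %-24s B = %6.3f, CI [%6.3f, %6.3f] - %s",
                                row$agent, row$B, row$ci_lower, row$ci_upper,
                                verdict))
    }
    lines <- c(lines, "")
  }
  lines
}

#' Sample-size planning summary
#'
#' @param config a [run_config()] (its `power` block) or a [power_spec()].
#' @return list with the spec, `required_n` and the power achieved at that n.
#' @export
cmd_power <- function(config) {
  spec <- if (inherits(config, "power_spec")) {
    config
  } else {
    do.call(power_spec, config$power)
  }
  n <- required_n(spec)
  list(effect_size_d = spec$effect_size_d, alpha = spec$alpha,
       target_power = spec$target_power, tail = spec$tail,
       required_n = n, achieved_power = achieved_power(n, spec))
}
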