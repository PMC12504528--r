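# Synthetic human cohorts and stochastic machine raters.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: a within-subject context manipulation of recognition accuracy, a
# positive within-person JOL-accuracy association injected on the linear
# probability scale per standard deviation of JOL, crossed subject and item
# heterogeneity, and machine raters whose per-item rating distributions carry
# no information about individual human outcomes unless a link is requested.

#' Parameters of a synthetic human cohort
#'
#' @param n_subjects cohort size (default 78, the study's final sample).
#' @param base_accuracy named probabilities `c(fitting=, unfitting=)`: target
#'   hit rates at average JOL for an average subject and item. Defaults 0.66 /
#'   0.56 put accuracy higher in the fitting context while leaving headroom so
#'   the linear-probability JOL effect is essentially unclamped.
#' @param jol_slope named reals `c(fitting=, unfitting=)`: change in accuracy
#'   per 1 SD of JOL, injected on the probability scale. Defaults 0.167 /
#'   0.104, the human slope estimates the package is designed to recover.
#' @param subject_sd,item_sd SDs of crossed random intercepts on the accuracy
#'   scale (defaults 0.06 and 0.05).
#' @param jol_relatedness_weight weight in `[0,1]` of the relatedness cue
#'   (vs. latent memory strength) in JOL formation; default 0.85 reflects
#'   cue-driven JOLs with a modest mnemonic component.
#' @param correct_rejection_rate probability a distractor is correctly called
#'   "new" (default 0.75); distractor trials never enter JOL models.
#' @param relatedness_mean named means of the latent relatedness cue on the
#'   1-10 scale per context; the fitting context reads as far more related.
#' @param relatedness_sd SD of the latent relatedness cue.
#' @param jol_mean,jol_sd location/scale mapping the combined latent JOL
#'   signal onto the 1-10 scale, per context for the mean.
#' @param memory_noise_sd SD (logit scale) of trial-level noise in latent
#'   memory strength.
#' @param seed integer seed; generation is deterministic given the seed.
#' @return a `human_cohort_params` list.
#' @export
human_cohort_params <- function(n_subjects = 78,
                                base_accuracy = c(fitting = 0.66, unfitting = 0.56),
                                jol_slope = c(fitting = 0.167, unfitting = 0.104),
                                subject_sd = 0.06,
                                item_sd = 0.05,
                                jol_relatedness_weight = 0.85,
                                correct_rejection_rate = 0.75,
                                relatedness_mean = c(fitting = 7.2, unfitting = 4.8),
                                relatedness_sd = 1.6,
                                jol_mean = c(fitting = 6.4, unfitting = 5.2),
                                jol_sd = 1.7,
                                memory_noise_sd = 1,
                                seed = 1) {
  stopifnot(n_subjects >= 1,
            all(CONTEXTS %in% names(base_accuracy)),
            all(base_accuracy > 0 & base_accuracy < 1),
            all(CONTEXTS %in% names(jol_slope)),
            subject_sd >= 0, item_sd >= 0,
            jol_relatedness_weight >= 0, jol_relatedness_weight <= 1,
            correct_rejection_rate > 0, correct_rejection_rate < 1,
            relatedness_sd >= 0, jol_sd >= 0, memory_noise_sd >= 0)
  structure(list(
    n_subjects = as.integer(n_subjects),
    base_accuracy = base_accuracy[CONTEXTS],
    jol_slope = jol_slope[CONTEXTS],
    subject_sd = subject_sd, item_sd = item_sd,
    jol_relatedness_weight = jol_relatedness_weight,
    correct_rejection_rate = correct_rejection_rate,
    relatedness_mean = relatedness_mean[CONTEXTS],
    relatedness_sd = relatedness_sd,
    jol_mean = jol_mean[CONTEXTS], jol_sd = jol_sd,
    memory_noise_sd = memory_noise_sd,
    seed = as.integer(seed)
  ), class = "human_cohort_params")
}

#' Simulate a human cohort's learning-phase ratings and recognition test
#'
#' For every studied trial a latent relatedness cue (higher in the fitting
#' context) and a latent memory strength (logit of the context base accuracy
#' plus subject and item intercepts plus noise) are drawn; the JOL is a convex
#' combination of the two standardised signals, mapped to the 1-10 scale and
#' discretised (round half up, clamp). Recognition correctness for targets is
#' Bernoulli with probability `base_accuracy[context] + jol_slope[context] *
#' z(JOL) + u_subject + w_item` clamped to `[0.01, 0.99]`, where `z()`
#' standardises within context and `u`, `w` are the same subject/item draws
#' that entered memory strength, on the accuracy scale. Distractor responses
#' are correct rejections with fixed probability.
#'
#' @param params a [human_cohort_params()] object.
#' @param design list of design assignments ([build_design()]); its length
#'   must equal `params$n_subjects`.
#' @param items optional item bank; when supplied, design item ids are
#'   validated against it.
#' @return list with `ratings` (tibble: `agent`, `unit_id`, `item_id`,
#'   `context`, `relatedness`, `jol`) and `recognition` (tibble: `subject_id`,
#'   `item_id`, `role`, `context`, `response`, `correct`).
#' @export
simulate_human_cohort <- function(params, design, items = NULL) {
  stopifnot(inherits(params, "human_cohort_params"))
  if (length(design) == 0) {
    stop("`design` must be non-empty", call. = FALSE)
  }
  if (length(design) != params$n_subjects) {
    stop(sprintf("`design` has %d assignments but params$n_subjects is %d",
                 length(design), params$n_subjects), call. = FALSE)
  }
  studied <- dplyr::bind_rows(lapply(design, function(a) {
    tibble::tibble(subject_id = a$participant_index + 1L,
                   item_id = a$studied$item_id, context = a$studied$context)
  }))
  distract <- dplyr::bind_rows(lapply(design, function(a) {
    tibble::tibble(subject_id = a$participant_index + 1L,
                   item_id = a$distractors)
  }))
  if (!is.null(items)) {
    unknown <- setdiff(unique(c(studied$item_id, distract$item_id)),
                       items$item_id)
    if (length(unknown) > 0) {
      stop(sprintf("design references unknown item id %d", unknown[[1]]),
           call. = FALSE)
    }
  }

  with_seed(params$seed, {
    subjects <- sort(unique(c(studied$subject_id, distract$subject_id)))
    item_ids <- sort(unique(c(studied$item_id, distract$item_id)))
    u <- stats::setNames(stats::rnorm(length(subjects), 0, params$subject_sd),
                         subjects)
    w <- stats::setNames(stats::rnorm(length(item_ids), 0, params$item_sd),
                         item_ids)

    ctx <- studied$context
    base <- params$base_accuracy[ctx]
    u_s <- u[as.character(studied$subject_id)]
    w_i <- w[as.character(studied$item_id)]

    # Latent relatedness cue: what JOLs are inferred from.
    r_latent <- stats::rnorm(nrow(studied), params$relatedness_mean[ctx],
                             params$relatedness_sd)
    relatedness <- discretise_rating(r_latent)

    # Latent memory strength on the logit scale; the shared subject/item
    # draws are rescaled from the accuracy scale by the logistic derivative
    # at the grand mean accuracy so both signals use the same heterogeneity.
    pbar <- mean(params$base_accuracy)
    logit_scale <- 1 / (pbar * (1 - pbar))
    m_latent <- stats::qlogis(base) + (u_s + w_i) * logit_scale +
      stats::rnorm(nrow(studied), 0, params$memory_noise_sd)

    alpha <- params$jol_relatedness_weight
    jol_latent <- numeric(nrow(studied))
    for (cc in CONTEXTS) {
      idx <- which(ctx == cc)
      sig <- alpha * z_standardise(r_latent[idx]) +
        (1 - alpha) * z_standardise(m_latent[idx])
      jol_latent[idx] <- params$jol_mean[cc] + params$jol_sd * z_standardise(sig)
    }
    jol <- discretise_rating(jol_latent)

    jol_z <- numeric(nrow(studied))
    for (cc in CONTEXTS) {
      idx <- which(ctx == cc)
      jol_z[idx] <- z_standardise(jol[idx])
    }
    p_correct <- clamp(base + params$jol_slope[ctx] * jol_z + u_s + w_i,
                       0.01, 0.99)
    hit <- stats::rbinom(nrow(studied), 1, p_correct) == 1

    ratings <- tibble::tibble(
      agent = "human",
      unit_id = studied$subject_id,
      item_id = studied$item_id,
      context = ctx,
      relatedness = relatedness,
      jol = jol
    )
    rec_targets <- tibble::tibble(
      subject_id = studied$subject_id,
      item_id = studied$item_id,
      role = "target",
      context = ctx,
      response = ifelse(hit, "old", "new"),
      correct = hit
    )
    cr <- stats::rbinom(nrow(distract), 1, params$correct_rejection_rate) == 1
    rec_distract <- tibble::tibble(
      subject_id = distract$subject_id,
      item_id = distract$item_id,
      role = "distractor",
      context = NA_character_,
      response = ifelse(cr, "new", "old"),
      correct = cr
    )
    list(ratings = ratings,
         recognition = dplyr::arrange(
           dplyr::bind_rows(rec_targets, rec_distract),
           .data$subject_id, .data$role, .data$item_id))
  })
}

#' Configuration of a stochastic machine rater
#'
#' Emulates querying a chat model for relatedness and JOL ratings of each
#' sentence pair in each context, with `n_replicates` independent samples per
#' pair at a given sampling temperature. Each item x context gets a latent
#' mean rating; replicates scatter around it with SD `temperature *
#' within_item_sd`, so temperature 0 collapses all replicates of an item onto
#' one value.
#'
#' @param model_label rater name, e.g. `"gpt-4o-2024-05-13"`.
#' @param n_replicates samples per item x context (default 100).
#' @param temperature non-negative dispersion multiplier (default 1).
#' @param item_mean_sd SD of latent per-item mean ratings around the context
#'   mean (default 1).
#' @param within_item_sd replicate-level rating SD at temperature 1
#'   (default 2).
#' @param link_slope shift of an item's JOL mean per unit of an external
#'   per-item signal (default 0: ratings carry no item-level link to human
#'   outcomes, the study's null construction).
#' @param relatedness_mean,jol_mean named per-context means on the 1-10 scale.
#' @param seed integer seed.
#' @return an `agent_sampler_config` list.
#' @export
agent_sampler_config <- function(model_label,
                                 n_replicates = 100,
                                 temperature = 1,
                                 item_mean_sd = 1,
                                 within_item_sd = 2,
                                 link_slope = 0,
                                 relatedness_mean = c(fitting = 7.5, unfitting = 4.0),
                                 jol_mean = c(fitting = 6.5, unfitting = 5.5),
                                 seed = 1) {
  stopifnot(is.character(model_label), length(model_label) == 1,
            n_replicates >= 1, temperature >= 0,
            item_mean_sd >= 0, within_item_sd >= 0,
            all(CONTEXTS %in% names(relatedness_mean)),
            all(CONTEXTS %in% names(jol_mean)))
  structure(list(
    model_label = model_label,
    n_replicates = as.integer(n_replicates),
    temperature = temperature,
    item_mean_sd = item_mean_sd,
    within_item_sd = within_item_sd,
    link_slope = link_slope,
    relatedness_mean = relatedness_mean[CONTEXTS],
    jol_mean = jol_mean[CONTEXTS],
    seed = as.integer(seed)
  ), class = "agent_sampler_config")
}

#' Sample stochastic machine ratings for an item bank
#'
#' The mock sampling backend behind this generator answers the same two
#' prompts a live API adapter would use (see [prompt_template()]), always with
#' an integer in 1-10.
#'
#' @param config an [agent_sampler_config()].
#' @param items item bank; all items are rated in both contexts (machine
#'   raters see the full bank, including any item omitted from human designs).
#' @param item_signal optional named numeric vector (names = item ids) of an
#'   external per-item signal scaled by `config$link_slope`; default none.
#' @return tibble with `agent`, `unit_id` (replicate index), `item_id`,
#'   `context`, `relatedness`, `jol`; `n_replicates` rows per item x context.
#' @export
#' @examples
#' bank <- build_item_bank(45, seed = 1)
#' cfg <- agent_sampler_config("gpt-4o-2024-05-13", seed = 2)
#' nrow(sample_agent_ratings(cfg, bank)) # 9000
sample_agent_ratings <- function(config, items, item_signal = NULL) {
  stopifnot(inherits(config, "agent_sampler_config"))
  check_columns(items, "item_id", "items")
  if (nrow(items) == 0) {
    stop("`items` must be non-empty", call. = FALSE)
  }
  with_seed(config$seed, {
    cells <- tidyr::expand_grid(item_id = sort(items$item_id),
                                context = CONTEXTS)
    shift <- rep(0, nrow(cells))
    if (!is.null(item_signal) && config$link_slope != 0) {
      s <- item_signal[as.character(cells$item_id)]
      s[is.na(s)] <- 0
      shift <- config$link_slope * s
    }
    cells$rel_mean <- stats::rnorm(nrow(cells),
                                   config$relatedness_mean[cells$context],
                                   config$item_mean_sd)
    cells$jol_mean <- stats::rnorm(nrow(cells),
                                   config$jol_mean[cells$context],
                                   config$item_mean_sd) + shift

    out <- tidyr::expand_grid(cells, unit_id = seq_len(config$n_replicates))
    noise_sd <- config$temperature * config$within_item_sd
    out$relatedness <- discretise_rating(
      out$rel_mean + stats::rnorm(nrow(out), 0, noise_sd))
    out$jol <- discretise_rating(
      out$jol_mean + stats::rnorm(nrow(out), 0, noise_sd))
    tibble::tibble(
      agent = config$model_label,
      unit_id = out$unit_id,
      item_id = out$item_id,
      context = out$context,
      relatedness = out$relatedness,
      jol = out$jol
    )
  })
}

#' Read a rating prompt template
#'
#' The two templates (relatedness and JOL/memorability, both on a 1-10 scale)
#' are stored as text assets with `{sentence1}` / `{sentence2}` slots so a
#' live API adapter can consume them unchanged; the mock backend used by
#' [sample_agent_ratings()] implements their numeric answer contract.
#'
#' @param type `"relatedness"` or `"jol"`.
#' @return single string with placeholder slots.
#' @export
prompt_template <- function(type = c("relatedness", "jol")) {
  type <- match.arg(type)
  path <- system.file("extdata", "prompts", paste0(type, "_prompt.txt"),
                      package = "jolcross", mustWork = TRUE)
  paste(readLines(path, warn = FALSE), collapse = "\n")
}

#' Fill a prompt template with a sentence pair
#'
#' @param template string with `{sentence1}` / `{sentence2}` slots.
#' @param sentence1,sentence2 context and garden-path sentence texts.
#' @return rendered prompt string.
#' @export
render_prompt <- function(template, sentence1, sentence2) {
  out <- gsub("{sentence1}", sentence1, template, fixed = TRUE)
  gsub("{sentence2}", sentence2, out, fixed = TRUE)
}
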