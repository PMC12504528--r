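# Item bank, counterbalanced within-subject design, participant exclusions.

#' Build a placeholder garden-path item bank
#'
#' Generates `n_items` sentence-pair items with template-based garden-path
#' texts of the form "Because <name> <verb>s <noun> is never ...": sentences
#' that read as a subordinate clause until the main verb forces reanalysis.
#' Each item carries a fitting context sentence (same topic as the garden-path
#' sentence) and an unfitting one (unrelated topic). The texts are synthetic
#' placeholders; real materials can be supplied as a data frame with the same
#' four columns wherever an item bank is accepted.
#'
#' @param n_items number of items to generate (positive integer).
#' @param seed integer seed; the bank is deterministic given the seed.
#' @return a tibble with columns `item_id` (1..n_items), `garden_path_text`,
#'   `fitting_context_text`, `unfitting_context_text`.
#' @export
#' @examples
#' bank <- build_item_bank(45, seed = 1)
#' nrow(bank)
build_item_bank <- function(n_items, seed) {
  if (!is.numeric(n_items) || length(n_items) != 1 || is.na(n_items) ||
      n_items < 1) {
    stop("`n_items` must be a positive integer", call. = FALSE)
  }
  n_items <- as.integer(n_items)

  names_pool <- c("Bill", "Anna", "Carlos", "Dana", "Emre", "Fiona", "Gustav",
                  "Hana", "Igor", "Jana", "Kofi", "Lena", "Marta", "Nils",
                  "Olga", "Pavel", "Quinn", "Rosa", "Sven", "Tara")
  verbs_pool <- c("drink", "paint", "collect", "repair", "grow", "bake",
                  "polish", "study", "trade", "carve", "brew", "knit",
                  "archive", "photograph", "restore", "compose")
  nouns_pool <- c("wine", "porcelain", "stamps", "clocks", "orchids", "bread",
                  "silver", "maps", "spices", "oak", "cider", "wool",
                  "letters", "bridges", "furniture", "songs")
  hobbies_pool <- c("play golf", "watch films", "jog at dawn", "sail boats",
                    "read novels", "climb hills", "swim laps", "fly kites")

  combos <- expand.grid(name = names_pool, k = seq_along(verbs_pool),
                        stringsAsFactors = FALSE)
  if (n_items > nrow(combos)) {
    stop(sprintf("at most %d distinct placeholder items are supported",
                 nrow(combos)), call. = FALSE)
  }
  with_seed(seed, {
    pick <- combos[sample.int(nrow(combos), n_items), ] # unique name/verb pairs
    name <- pick$name
    verb <- verbs_pool[pick$k]
    noun <- nouns_pool[pick$k] # verb/noun pairing keeps sentences plausible
    hobby <- sample(hobbies_pool, n_items, replace = TRUE)
    tibble::tibble(
      item_id = seq_len(n_items),
      garden_path_text = sprintf(
        "Because %s %ss %s is never kept in the house.", name, verb, noun),
      fitting_context_text = sprintf(
        "%s %ss %s every single day.", name, verb, noun),
      unfitting_context_text = sprintf(
        "%s likes to %s.", name, hobby)
    )
  })
}

#' Assign one participant to a counterbalance condition
#'
#' Implements a 4-group Latin-square rotation over the item bank. After
#' omitting `omit_item_id`, the remaining items are partitioned by id order
#' into four fixed groups g1..g4 of equal size. Condition c (participants are
#' cycled through conditions as `(participant_index mod 4) + 1`) studies group
#' g_c in the fitting context and the next group (cyclically) in the unfitting
#' context; the remaining two groups are test distractors. Across the four
#' conditions every item serves as fitting target once, unfitting target once,
#' and distractor twice.
#'
#' @param items item bank (as from [build_item_bank()]).
#' @param participant_index non-negative integer.
#' @param omit_item_id item id dropped before grouping (default 8, the id
#'   omitted from the human design; use `NULL` to keep all items, as for
#'   machine raters).
#' @return a `design_assignment`: list with `participant_index`,
#'   `counterbalance_condition`, `studied` (tibble of `item_id`, `context`),
#'   and `distractors` (integer vector of item ids).
#' @export
#' @examples
#' bank <- build_item_bank(45, seed = 1)
#' a <- assign_counterbalance(bank, participant_index = 0)
#' nrow(a$studied); length(a$distractors)
assign_counterbalance <- function(items, participant_index, omit_item_id = 8) {
  check_columns(items, "item_id", "items")
  if (!is.numeric(participant_index) || length(participant_index) != 1 ||
      participant_index < 0) {
    stop("`participant_index` must be a non-negative integer", call. = FALSE)
  }
  ids <- sort(items$item_id)
  if (!is.null(omit_item_id)) {
    ids <- setdiff(ids, omit_item_id)
  }
  if (length(ids) %% 4 != 0) {
    stop(sprintf(
      "design error: %d items after omission are not divisible into 4 groups",
      length(ids)), call. = FALSE)
  }
  m <- length(ids) %/% 4
  groups <- split(ids, rep(1:4, each = m))
  cond <- (as.integer(participant_index) %% 4L) + 1L
  rot <- function(offset) groups[[((cond - 1L + offset) %% 4L) + 1L]]

  studied <- tibble::tibble(
    item_id = c(rot(0L), rot(1L)),
    context = rep(CONTEXTS, each = m)
  )
  structure(
    list(
      participant_index = as.integer(participant_index),
      counterbalance_condition = cond,
      studied = studied,
      distractors = as.integer(c(rot(2L), rot(3L)))
    ),
    class = "design_assignment"
  )
}

#' @export
print.design_assignment <- function(x, ...) {
  cat(sprintf(
    "<design_assignment> participant %d, condition %d: %d studied (%d fitting / %d unfitting), %d distractors\n",
    x$participant_index, x$counterbalance_condition, nrow(x$studied),
    sum(x$studied$context == "fitting"), sum(x$studied$context == "unfitting"),
    length(x$distractors)))
  invisible(x)
}

#' Build the full cohort design
#'
#' Applies [assign_counterbalance()] to participants `0..n_subjects-1`
#' (sequential mod-4 condition cycling).
#'
#' @param items item bank.
#' @param n_subjects number of participants.
#' @param omit_item_id see [assign_counterbalance()].
#' @return list of `design_assignment` objects.
#' @export
build_design <- function(items, n_subjects, omit_item_id = 8) {
  stopifnot(n_subjects >= 1)
  lapply(seq_len(n_subjects) - 1L, function(p) {
    assign_counterbalance(items, p, omit_item_id = omit_item_id)
  })
}

#' Flatten a design to one row per participant x item
#'
#' @param design list of `design_assignment` objects.
#' @return tibble with `participant`, `item_id`, `role` (target/distractor),
#'   `context` (`NA` for distractors).
#' @export
design_table <- function(design) {
  rows <- lapply(design, function(a) {
    dplyr::bind_rows(
      tibble::tibble(participant = a$participant_index,
                     item_id = a$studied$item_id, role = "target",
                     context = a$studied$context),
      tibble::tibble(participant = a$participant_index,
                     item_id = a$distractors, role = "distractor",
                     context = NA_character_)
    )
  })
  dplyr::bind_rows(rows)
}

#' Create a participant exclusion ledger
#'
#' @param n_recruited number recruited.
#' @param incomplete,vision,other logical vectors of length `n_recruited`
#'   flagging participants who did not complete the study, failed the
#'   normal/corrected-to-normal vision requirement, or met another exclusion
#'   criterion (e.g. confused response keys).
#' @return an `exclusion_ledger` list.
#' @export
exclusion_ledger <- function(n_recruited,
                             incomplete = logical(n_recruited),
                             vision = logical(n_recruited),
                             other = logical(n_recruited)) {
  stopifnot(n_recruited >= 0)
  flags <- list(incomplete = incomplete, vision = vision, other = other)
  for (nm in names(flags)) {
    f <- flags[[nm]]
    if (!is.logical(f) || length(f) != n_recruited || anyNA(f)) {
      stop(sprintf("`%s` must be a logical vector of length %d", nm,
                   n_recruited), call. = FALSE)
    }
  }
  structure(c(list(n_recruited = as.integer(n_recruited)), flags),
            class = "exclusion_ledger")
}

#' Apply the participant exclusion cascade
#'
#' Removals are attributed to the first applicable reason in the fixed order
#' incomplete, vision, other — so e.g. a participant flagged for both
#' incompleteness and vision counts once, under "incomplete". The retained set
#' itself does not depend on the order.
#'
#' @param ledger an [exclusion_ledger()].
#' @return list with `retained_ids` (integer indices of retained participants)
#'   and `summary` (tibble of counts per stage: recruited, removals by reason,
#'   retained).
#' @export
#' @examples
#' led <- exclusion_ledger(5, incomplete = c(TRUE, rep(FALSE, 4)))
#' apply_exclusions(led)$retained_ids
apply_exclusions <- function(ledger) {
  stopifnot(inherits(ledger, "exclusion_ledger"))
  ids <- seq_len(ledger$n_recruited)
  excluded <- rep(FALSE, ledger$n_recruited)
  counts <- integer(0)
  for (reason in c("incomplete", "vision", "other")) {
    hit <- ledger[[reason]] & !excluded
    counts[reason] <- sum(hit)
    excluded <- excluded | hit
  }
  retained <- ids[!excluded]
  summary <- tibble::tibble(
    stage = c("recruited", names(counts), "retained"),
    n = c(ledger$n_recruited, -as.integer(counts), length(retained))
  )
  list(retained_ids = retained, summary = summary)
}
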