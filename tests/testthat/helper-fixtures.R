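# Shared fixtures, built in code at test time.

# Small item bank whose size stays divisible by 4 without omission.
small_bank <- function(n = 16, seed = 42) {
  build_item_bank(n, seed = seed)
}

# A compact human cohort: `n_subjects` over a small bank, no omitted item.
small_cohort <- function(n_subjects = 20, n_items = 16, seed = 1, ...) {
  bank <- small_bank(n_items)
  design <- build_design(bank, n_subjects, omit_item_id = NULL)
  params <- human_cohort_params(n_subjects = n_subjects, seed = seed, ...)
  c(simulate_human_cohort(params, design, bank),
    list(bank = bank, design = design, params = params))
}

# The study-sized cohort: 78 subjects, 45-item bank with item 8 omitted.
study_cohort <- function(seed = 1, ...) {
  bank <- build_item_bank(45, seed = 1)
  design <- build_design(bank, 78, omit_item_id = 8)
  params <- human_cohort_params(seed = seed, ...)
  c(simulate_human_cohort(params, design, bank),
    list(bank = bank, design = design, params = params))
}
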