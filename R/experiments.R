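# Simulations: L1 training with age checkpoints, L2 continuation over the
# AoA grid, and run bookkeeping.  One model year = 1,000 training trials
# (one sentence presentation each); a 20,000-pair training set is cycled
# when a run needs more input than one pass provides.

#' Simulation specification
#'
#' Bundles everything that defines one simulation: output activation and
#' learning-rate schedule, the L2 input regime, the AoA grid, subject
#' count and problem sizes.
#'
#' * Simulation 1 — logistic output, constant rate 0.1 (entrenchment via
#'   the activation-function derivative only).
#' * Simulation 2 — softmax output, single stretched-Z rate (0.1 to 0.025
#'   between model years 10 and 16).
#' * Simulation 3 — softmax output, dual rates: syntactic stretched-Z to a
#'   floor of 0, lexical constant at 0.1.
#' * Simulation 4 — as 3 but with 50/50 interleaved English/Korean L2
#'   input and a language feature on every message.
#'
#' @param sim_id Simulation number 1-4.
#' @param preset `"full"` (AoA 3..21 by 3, 10 subjects, 20 L2 years) or
#'   `"scaled"` (AoA \{3, 12, 21\}, 3 subjects, 10 L2 years) — the scaled
#'   preset is the desk-scale configuration used by the package's own
#'   checks.
#' @param aoa_grid,n_subjects,l2_years,eval_interval_years Optional
#'   overrides of the preset.
#' @param n_items Judgment items per rule at each evaluation.
#' @param n_test Test sentences per language at each evaluation.
#' @return An object of class `dp_simulation_spec`.
#' @export
simulation_spec <- function(sim_id, preset = c("full", "scaled"),
                            aoa_grid = NULL, n_subjects = NULL,
                            l2_years = NULL, eval_interval_years = NULL,
                            n_items = 100, n_test = 200) {
  preset <- match.arg(preset)
  stopifnot(sim_id %in% 1:4)
  spec <- list(
    sim_id = sim_id,
    output_activation = if (sim_id == 1) "logistic" else "softmax",
    schedule = switch(sim_id, learning_schedule("constant"),
                      learning_schedule("stretched_z"),
                      learning_schedule("dual_rate"),
                      learning_schedule("dual_rate")),
    l2_input = if (sim_id == 4) "bilingual" else "en",
    momentum = if (sim_id == 1) 0.9 else 0,
    aoa_grid = if (preset == "full") seq(3, 21, by = 3) else c(3, 12, 21),
    n_subjects = if (preset == "full") 10L else 3L,
    # the scaled design keeps the full 20 L2 years except for the
    # constant-rate simulation, whose scaled form uses 10
    l2_years = if (preset == "full" || sim_id != 1) 20L else 10L,
    trials_per_year = 1000L,
    checkpoint_interval_years = 3L,
    eval_interval_years = if (preset == "full") 3L else 2L,
    corpus_size = 20000L,
    messageless_fraction = 0.25,
    n_items = n_items,
    n_test = n_test,
    params = grammar_params("table7-tuned")
  )
  if (!is.null(aoa_grid)) spec$aoa_grid <- aoa_grid
  if (!is.null(n_subjects)) spec$n_subjects <- as.integer(n_subjects)
  if (!is.null(l2_years)) spec$l2_years <- as.integer(l2_years)
  if (!is.null(eval_interval_years))
    spec$eval_interval_years <- as.integer(eval_interval_years)
  stopifnot(all(spec$aoa_grid %% spec$checkpoint_interval_years == 0))
  class(spec) <- "dp_simulation_spec"
  spec
}

# Train for a whole number of years on a cycled encoded corpus, applying
# the schedule at each sentence's exact age.  Returns the new trial count.
.dp_train_years <- function(net, enc, schedule, start_trial, years,
                            trials_per_year) {
  n <- length(enc$sents)
  trial <- start_trial
  for (y in seq_len(years)) {
    idx <- ((trial + seq_len(trials_per_year) - 1L) %% n) + 1L
    ages <- (trial + seq_len(trials_per_year) - 1L) / trials_per_year
    rates <- lr_at_age(schedule, ages)
    chunk <- list(sents = enc$sents[idx], binds = enc$binds[idx],
                  evs = enc$evs[idx])
    train_network(net, chunk, rates[, "lexical"], rates[, "syntactic"])
    trial <- trial + trials_per_year
  }
  trial
}

#' Train the L1 (Korean) model with age checkpoints
#'
#' Trains a freshly initialized network on a newly generated Korean corpus
#' with the spec's schedule applied by age, emitting an independent weight
#' snapshot every `checkpoint_interval_years` up to `max_age_years`.
#'
#' @param spec A [simulation_spec()].
#' @param max_age_years Final L1 age (defaults to the largest AoA in the
#'   grid).
#' @param seed Subject seed (all corpus generation and weight
#'   initialization derive from it).
#' @return `list(network, checkpoints)`; `checkpoints` is a list keyed by
#'   age (as character) of `dp_network` snapshots with an `age` field.
#' @export
train_l1 <- function(spec, max_age_years = max(spec$aoa_grid), seed = 1L) {
  stopifnot(max_age_years >= max(spec$aoa_grid))
  set.seed(seed)
  corpus <- generate_corpus(spec$params, spec$corpus_size,
                            spec$messageless_fraction, "ko")
  net <- init_network(network_config(
    output_activation = spec$output_activation, momentum = spec$momentum))
  enc <- .dp_encode_corpus(net$config, corpus)
  checkpoints <- list()
  trial <- 0L
  for (year in seq_len(max_age_years)) {
    trial <- .dp_train_years(net, enc, spec$schedule, trial, 1L,
                             spec$trials_per_year)
    if (year %% spec$checkpoint_interval_years == 0) {
      snap <- copy_network(net)
      snap$age <- year
      checkpoints[[as.character(year)]] <- snap
    }
  }
  list(network = net, checkpoints = checkpoints)
}

# Metrics for one network state; returns one row per rule.
.dp_evaluate <- function(net, spec, sim, subject, aoa, loe, cps, seed) {
  set.seed(seed)
  bilingual <- spec$l2_input == "bilingual"
  test_en <- generate_test_sentences(spec$params, spec$n_test, "en",
                                     lang_feature = bilingual)
  test_ko <- generate_test_sentences(spec$params, spec$n_test, "ko",
                                     lang_feature = bilingual)
  acc_en <- word_prediction_accuracy(net, test_en)
  acc_ko <- word_prediction_accuracy(net, test_ko)
  props <- vapply(.dp_rules, function(r) {
    items <- generate_judgment_items(r, spec$n_items, spec$params)
    if (bilingual) {
      items <- lapply(items, function(it) {
        it$message$event <- c(it$message$event, "LANG_EN")
        it
      })
    }
    rule_proportion(net, items)$proportion
  }, numeric(1))
  cs_msgs <- lapply(seq_len(50), function(i) {
    m <- sample_message(spec$params)
    if (bilingual) m$event <- c(m$event, "LANG_EN")
    m
  })
  cs <- code_switch_rate(net, cs_msgs)
  tibble::tibble(sim = sim, subject = subject, aoa = aoa, loe = loe,
                 rule = .dp_rules,
                 rule_cp = cps[.dp_rules],
                 rule_proportion = unname(props),
                 word_accuracy_en = acc_en, word_accuracy_ko = acc_ko,
                 code_switch_rate = cs)
}

#' L2 continuation from an L1 checkpoint
#'
#' Continues training from an age checkpoint on English-only (simulations
#' 1-3) or 50/50 interleaved bilingual input (simulation 4).  The schedule
#' stays indexed by total model age (AoA + years of exposure).  Metrics
#' are collected every `eval_interval_years` of exposure with fresh,
#' seeded evaluation draws.
#'
#' @param spec A [simulation_spec()].
#' @param checkpoint A `dp_network` checkpoint whose `age` is the AoA.
#' @param l2_years Years of L2 input.
#' @param seed Seed for the L2 corpus and evaluation draws.
#' @param subject Subject label for the results table.
#' @return A tibble, one row per evaluation point and rule.
#' @export
train_l2 <- function(spec, checkpoint, l2_years = spec$l2_years, seed = 1L,
                     subject = 1L) {
  aoa <- checkpoint$age
  if (is.null(aoa) || is.na(aoa))
    stop("checkpoint carries no age; incompatible with the AoA design",
         call. = FALSE)
  if (checkpoint$config$output_activation != spec$output_activation)
    stop("checkpoint output activation does not match the spec",
         call. = FALSE)
  net <- copy_network(checkpoint)
  set.seed(seed)
  corpus <- generate_corpus(spec$params, spec$corpus_size,
                            spec$messageless_fraction, spec$l2_input)
  enc <- .dp_encode_corpus(net$config, corpus)
  # rule-CP predictor measured on the English portion of this input
  en_part <- corpus[vapply(corpus, function(r) r$language == "en", logical(1))]
  cps_tab <- rule_cps(count_rule_events(en_part))
  cps <- stats::setNames(cps_tab$cp, cps_tab$rule)

  rows <- list()
  trial <- aoa * spec$trials_per_year
  loe_points <- seq(spec$eval_interval_years, l2_years,
                    by = spec$eval_interval_years)
  prev_loe <- 0L
  for (loe in loe_points) {
    trial <- .dp_train_years(net, enc, spec$schedule, trial,
                             loe - prev_loe, spec$trials_per_year)
    rows[[length(rows) + 1L]] <-
      .dp_evaluate(net, spec, spec$sim_id, subject, aoa, loe, cps,
                   seed = (seed + 7919L * loe) %% .Machine$integer.max)
    prev_loe <- loe
  }
  out <- do.call(rbind, rows)
  attr(out, "network") <- net
  out
}

#' Run a full simulation over the AoA grid
#'
#' For each of `n_subjects` seeds: generate fresh training corpora, train
#' the L1 model once with checkpoints shared across AoA groups, continue
#' each checkpoint on L2 input, and assemble the metrics into one tidy
#' table.  Identical `spec` and `seed` reproduce the table exactly.
#'
#' @param spec A [simulation_spec()].
#' @param seed Master seed; per-subject corpus, initialization and
#'   evaluation seeds derive from it deterministically.
#' @return A tibble with one row per subject, AoA, evaluation point and
#'   rule (columns `sim`, `subject`, `aoa`, `loe`, `rule`, `rule_cp`,
#'   `rule_proportion`, `word_accuracy_en`, `word_accuracy_ko`,
#'   `code_switch_rate`).
#' @export
run_simulation <- function(spec, seed = 1L) {
  rows <- list()
  for (subject in seq_len(spec$n_subjects)) {
    subj_seed <- (seed * 10000L + subject * 101L) %% .Machine$integer.max
    l1 <- train_l1(spec, seed = subj_seed)
    for (aoa in spec$aoa_grid) {
      ckpt <- l1$checkpoints[[as.character(aoa)]]
      rows[[length(rows) + 1L]] <-
        train_l2(spec, ckpt, spec$l2_years,
                 seed = (subj_seed + 13L * aoa) %% .Machine$integer.max,
                 subject = subject)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "network") <- NULL
  out
}
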