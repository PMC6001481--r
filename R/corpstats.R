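# Forward conditional-probability statistics over token corpora, plus the
# printed reference constants (raw CHILDES counts, CHILDES/COCA rule CPs,
# and the target CP profile of the model grammar).

.dp_rules <- c("DET", "PL", "PAR", "3PS", "PST")

# Suffix morphemes are absorbed into the preceding verb/noun unit before
# computing adjacency, so "touch -ed the" counts as verb-followed-by-
# determiner.  This mirrors tagged-word corpus searches, which operate on
# inflected words rather than on the model's spaced morphemes.
.dp_suffix_categories <- c("morpheme", "verb-ending")

# Split a token sequence into units: each unit is a head token plus any
# directly attached suffix tokens.
.dp_units <- function(tokens, lex) {
  idx <- match(tokens, lex$token)
  if (anyNA(idx)) {
    stop("unknown token '", tokens[which(is.na(idx))[1L]], "'", call. = FALSE)
  }
  cat <- lex$category[idx]
  is_suffix <- cat %in% .dp_suffix_categories
  if (is_suffix[1L]) is_suffix[1L] <- FALSE   # degenerate: suffix-initial
  unit_id <- cumsum(!is_suffix)
  list(head_category = cat[!is_suffix],
       members = split(tokens, unit_id))
}

#' Count rule-relevant events in a corpus
#'
#' Computes the raw counts entering the five forward conditional
#' probabilities over verb and noun units (suffix morphemes absorbed into
#' their head): verb units, verb units immediately followed by a
#' determiner, verb units immediately followed by a particle, nouns, plural
#' (`-z`) nouns, third-person (`-ss`) verbs and past (`-ed`) verbs.  Korean
#' sentences contribute to the denominators but never to the
#' English-specific numerators.
#'
#' @param corpus A `dp_corpus` list, or a plain list of token vectors.
#' @return A named list of class `dp_rule_counts`.
#' @export
count_rule_events <- function(corpus) {
  lex <- dp_lexicon()
  verb_cats <- c("intransitive-verb", "transitive-verb", "dative-verb")
  noun_cats <- c("animate-noun", "inanimate-noun")
  counts <- c(verb_units = 0, verb_det = 0, verb_particle = 0, nouns = 0,
              plural_nouns = 0, third_person_verbs = 0, past_verbs = 0)
  for (rec in corpus) {
    tokens <- if (is.list(rec)) rec$tokens else rec
    if (length(tokens) == 0) next
    u <- .dp_units(tokens, lex)
    is_verb <- u$head_category %in% verb_cats
    is_noun <- u$head_category %in% noun_cats
    nxt <- c(u$head_category[-1L], NA)
    has <- function(tok) vapply(u$members, function(m) tok %in% m, logical(1))
    counts["verb_units"] <- counts["verb_units"] + sum(is_verb)
    counts["verb_det"] <- counts["verb_det"] +
      sum(is_verb & nxt %in% "determiner")
    counts["verb_particle"] <- counts["verb_particle"] +
      sum(is_verb & nxt %in% "particle")
    counts["nouns"] <- counts["nouns"] + sum(is_noun)
    counts["plural_nouns"] <- counts["plural_nouns"] + sum(is_noun & has("-z"))
    counts["third_person_verbs"] <- counts["third_person_verbs"] +
      sum(is_verb & has("-ss"))
    counts["past_verbs"] <- counts["past_verbs"] + sum(is_verb & has("-ed"))
  }
  out <- as.list(counts)
  class(out) <- c("dp_rule_counts", "list")
  out
}

#' Forward conditional probability of one rule
#'
#' DET = verb_det / verb_units, PL = plural_nouns / nouns,
#' PAR = verb_particle / verb_units, 3PS = third_person_verbs / verb_units,
#' PST = past_verbs / verb_units.
#'
#' @param counts A `dp_rule_counts` object (or compatible named list).
#' @param rule One of `"DET"`, `"PL"`, `"PAR"`, `"3PS"`, `"PST"`.
#' @return `list(rule, numerator, denominator, cp)`.
#' @export
rule_cp <- function(counts, rule) {
  rule <- match.arg(rule, .dp_rules)
  num <- switch(rule, DET = counts$verb_det, PL = counts$plural_nouns,
                PAR = counts$verb_particle, `3PS` = counts$third_person_verbs,
                PST = counts$past_verbs)
  den <- if (rule == "PL") counts$nouns else counts$verb_units
  if (is.null(den) || den == 0)
    stop("zero denominator for rule ", rule, call. = FALSE)
  list(rule = rule, numerator = num, denominator = den, cp = num / den)
}

#' All five rule CPs as a tidy table
#'
#' @inheritParams rule_cp
#' @return A tibble with columns `rule`, `numerator`, `denominator`, `cp`.
#' @export
rule_cps <- function(counts) {
  rows <- lapply(.dp_rules, function(r) tibble::as_tibble(rule_cp(counts, r)))
  do.call(rbind, rows)
}

#' Pearson correlation between two rule-CP profiles
#'
#' Standard product-moment correlation with explicit validation (equal
#' length of at least 3, non-degenerate variance on both sides).
#'
#' @param xs,ys Numeric vectors.
#' @return Correlation in `[-1, 1]`.
#' @export
cp_pearson <- function(xs, ys) {
  if (length(xs) != length(ys) || length(xs) < 3)
    stop("need two sequences of equal length >= 3", call. = FALSE)
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0)
    stop("degenerate variance: correlation undefined", call. = FALSE)
  stats::cor(xs, ys)
}

#' Printed reference constants
#'
#' Transcriptions of the published raw CHILDES frequency counts, the
#' CHILDES/COCA rule conditional probabilities, and the corpora-vs-model CP
#' profile of the training grammar.
#'
#' @return A list with elements `table2` (named counts), `table3`
#'   (data frame: rule, childes, coca) and `table7` (data frame: rule,
#'   corpora, model).
#' @export
table_fixtures <- function() {
  list(
    table2 = c(DET = 159107, PL = 40171, PAR = 133958, `3PS` = 16570,
               PST = 6049, VERBDET = 42038, VERBPAR = 28571,
               VERB = 334191, NOUN = 320650),
    table3 = data.frame(
      rule = .dp_rules,
      childes = c(0.126, 0.125, 0.085, 0.05, 0.018),
      coca = c(0.14, 0.21, 0.13, 0.08, 0.11),
      stringsAsFactors = FALSE),
    table7 = data.frame(
      rule = .dp_rules,
      corpora = c(0.126, 0.125, 0.085, 0.05, 0.018),
      model = c(0.47, 0.4, 0.22, 0.16, 0.11),
      stringsAsFactors = FALSE)
  )
}
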