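# Corpus, test-set and judgment-item generation.

#' Generate a message-sentence training corpus
#'
#' Draws `n` messages from the grammar and realizes each one in the
#' requested language.  A fixed fraction of records (default 0.25) have
#' their message removed after realization — the token sequence stays, the
#' meaning is withheld — with the exact count `round(n * fraction)` chosen
#' by sampling without replacement.  In `"bilingual"` mode each record is
#' English or Korean with probability 1/2 and every surviving message
#' carries exactly one language feature (`LANG_EN`/`LANG_KO`) in its event
#' semantics.
#'
#' @param params A [grammar_params()] object.
#' @param n Number of message-sentence pairs.
#' @param messageless_fraction Fraction of records whose message is absent.
#' @param language `"en"`, `"ko"` or `"bilingual"`.
#' @return A list of class `dp_corpus`; each record is
#'   `list(tokens, language, message)` with `message = NULL` when absent.
#' @export
generate_corpus <- function(params, n, messageless_fraction = 0.25,
                            language = c("en", "ko", "bilingual")) {
  language <- match.arg(language)
  stopifnot(n >= 1)
  if (messageless_fraction < 0 || messageless_fraction >= 1)
    stop("messageless_fraction must be in [0, 1)", call. = FALSE)
  langs <- if (language == "bilingual") {
    c("en", "ko")[1L + (stats::runif(n) < 0.5)]
  } else rep(language, n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    msg <- sample_message(params)
    if (language == "bilingual")
      msg$event <- c(msg$event, if (langs[i] == "en") "LANG_EN" else "LANG_KO")
    out[[i]] <- list(tokens = .dp_realize(msg, langs[i]),
                     language = langs[i], message = msg)
  }
  drop <- sample.int(n, round(n * messageless_fraction))
  for (i in drop) out[[i]]$message <- NULL
  class(out) <- c("dp_corpus", "list")
  out
}

#' Generate grammatical test sentences with messages
#'
#' As [generate_corpus()] but messages are always present; used for
#' word-prediction accuracy.
#'
#' @inheritParams generate_corpus
#' @param lang_feature If `TRUE`, stamp the matching `LANG_*` event feature
#'   on every message (for models trained on bilingual input).
#' @return A `dp_corpus` list; empty when `n = 0`.
#' @export
generate_test_sentences <- function(params, n, language = c("en", "ko"),
                                    lang_feature = FALSE) {
  language <- match.arg(language)
  if (n == 0) {
    out <- list()
    class(out) <- c("dp_corpus", "list")
    return(out)
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    msg <- sample_message(params)
    if (lang_feature)
      msg$event <- c(msg$event, if (language == "en") "LANG_EN" else "LANG_KO")
    out[[i]] <- list(tokens = .dp_realize(msg, language),
                     language = language, message = msg)
  }
  class(out) <- c("dp_corpus", "list")
  out
}

#' Generate matched grammaticality-judgment item pairs
#'
#' Builds `n_items` grammatical/ungrammatical sentence pairs for one rule
#' from canonical transitive English frames ("a boy touch -ed the apple",
#' "two boy -z touch -ed the apple", "a boy break -ss down the apple",
#' ...), varying the content words.  The ungrammatical version omits exactly
#' one rule-specific token: the object determiner (DET), the plural `-z` on
#' the subject noun (PL), the particle of a phrasal verb (PAR), the
#' third-person `-ss` (3PS) or the past-tense `-ed` (PST).  The SSE-based
#' rule-proportion metric is evaluated at the first position where the two
#' versions diverge: the grammatical target is the omitted token and the
#' ungrammatical target is the token that follows it in the pruned
#' sentence.
#'
#' @param rule One of `"DET"`, `"PL"`, `"PAR"`, `"3PS"`, `"PST"`.
#' @param n_items Number of item pairs.
#' @param params Grammar parameters (the canonical frames do not depend on
#'   the distributional parameters; accepted for interface symmetry).
#' @return List of items: `list(rule, grammatical, ungrammatical,
#'   divergence, target_gram, target_ungram, message)` where `divergence`
#'   is the 0-based index of the first differing token and `message` is
#'   the meaning the frame was generated from (installed during
#'   evaluation, production-style).
#' @export
generate_judgment_items <- function(rule, n_items,
                                    params = grammar_params("table7-tuned")) {
  rule <- match.arg(rule, c("DET", "PL", "PAR", "3PS", "PST"))
  animate <- toupper(.dp_animate)
  count_nouns <- toupper(c(.dp_animate, setdiff(.dp_inanimate, .dp_mass)))
  out <- vector("list", n_items)
  for (i in seq_len(n_items)) {
    # canonical transitive frame, varying only the content words:
    # "a boy touch -ed the apple" — indefinite singular subject, plain
    # transitive verb, definite singular count-noun object, simple tense
    action <- if (rule == "PAR") {
      .dp_sample1(c("TURNDOWN", "BREAKDOWN"), NULL)
    } else {
      .dp_sample1(toupper(.dp_trans), NULL)
    }
    X <- .dp_arg(.dp_sample1(animate, NULL), "INDEF", "SING")
    Y <- .dp_arg(.dp_sample1(count_nouns, NULL), "DEF", "SING")
    # simple past for DET/PL/PST frames, simple present (third-person
    # -ss) for PAR/3PS frames
    event <- if (rule %in% c("PAR", "3PS")) c("XX", "YY")
             else c("PAST", "XX", "YY")
    if (rule == "PL") {
      # subject carries the plural suffix: "two boy -z ..."
      X$kind <- "DEF"
      X$number <- .dp_sample1(c("TWO", "THREE"), NULL)
    }
    msg <- list(action = action, args = list(X = X, Y = Y), event = event)
    subj <- .dp_np_en(msg$args$X)
    vb <- .dp_verb_en(msg)
    obj <- .dp_np_en(msg$args$Y)
    gram <- c(subj, vb, obj, .dp_eos)
    # 1-based index of the token the rule omission removes
    omit <- switch(rule,
      DET = length(subj) + length(vb) + 1L,
      PL = which(gram == "-z")[1L],
      PAR = length(subj) + length(vb),
      `3PS` = length(subj) + which(vb == "-ss")[1L],
      PST = length(subj) + which(vb == "-ed")[1L])
    ungram <- gram[-omit]
    out[[i]] <- list(rule = rule, grammatical = gram, ungrammatical = ungram,
                     divergence = omit - 1L,
                     target_gram = gram[omit], target_ungram = gram[omit + 1L],
                     message = msg)
  }
  class(out) <- c("dp_items", "list")
  out
}

# ---- JSON Lines I/O --------------------------------------------------------

#' Write a corpus as JSON Lines
#'
#' One record per line:
#' `{"tokens": [...], "language": "en"|"ko", "message": {...}|null}` with the
#' message serialized as `{"A": ..., "X": {...}, ..., "event": [...]}`.
#'
#' @param corpus A `dp_corpus` list.
#' @param path Output file.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  lines <- vapply(corpus, function(rec) {
    msg <- if (is.null(rec$message)) NULL else {
      m <- list(A = rec$message$action)
      for (r in names(rec$message$args)) m[[r]] <- rec$message$args[[r]]
      m$event <- as.list(rec$message$event)
      m
    }
    jsonlite::toJSON(list(tokens = rec$tokens, language = rec$language,
                          message = msg),
                     auto_unbox = TRUE, null = "null")
  }, character(1))
  writeLines(lines, path)
}

#' Read a JSON Lines corpus
#'
#' @param path File written by [write_corpus_jsonl()].
#' @return A `dp_corpus` list.
#' @export
read_corpus_jsonl <- function(path) {
  out <- lapply(readLines(path), function(line) {
    rec <- jsonlite::fromJSON(line, simplifyVector = FALSE)
    msg <- if (is.null(rec$message)) NULL else {
      roles <- intersect(c("X", "Y", "Z"), names(rec$message))
      list(action = rec$message$A,
           args = lapply(stats::setNames(roles, roles), function(r)
             list(concept = rec$message[[r]]$concept,
                  kind = rec$message[[r]]$kind,
                  number = rec$message[[r]]$number)),
           event = unlist(rec$message$event) %||% character(0))
    }
    list(tokens = unlist(rec$tokens), language = rec$language, message = msg)
  })
  class(out) <- c("dp_corpus", "list")
  out
}
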