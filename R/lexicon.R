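# Lexicon of the two miniature languages.
#
# Content inventory per language: 8 animate nouns, 8 inanimate nouns (four of
# which are mass nouns), 6 intransitive, 6 transitive and 6 dative verbs.
# Korean content forms mirror the English ones with a "k" prefix; the labels
# play no role in the model's behaviour.  Phrasal actions exist as concepts:
# GIVEUP/SHOWUP (intransitive, dative base verb + "up") and
# TURNDOWN/BREAKDOWN (transitive, intransitive base verb + "down").  English
# realizes them as base verb + particle; Korean has dedicated single verbs.

.dp_animate <- c("cat", "dog", "boy", "girl", "man", "elk", "owl", "horse")
.dp_inanimate <- c("apple", "ball", "book", "cup",
                   "sugar", "milk", "water", "coffee")
.dp_mass <- c("sugar", "milk", "water", "coffee")
.dp_vowel_initial <- c("elk", "owl", "apple")
.dp_intrans <- c("dance", "sit", "jump", "run", "turn", "break")
.dp_trans <- c("carry", "touch", "push", "kick", "hit", "pull")
.dp_dative <- c("give", "show", "send", "throw", "bring", "hand")

# phrasal actions: concept, English base verb, particle, structure they head
.dp_phrasal <- data.frame(
  concept = c("TURNDOWN", "BREAKDOWN", "GIVEUP", "SHOWUP"),
  base = c("turn", "break", "give", "show"),
  particle = c("down", "down", "up", "up"),
  structure = c("transitive", "transitive", "intransitive", "intransitive"),
  stringsAsFactors = FALSE
)

.dp_en_determiners <- c("a", "an", "the", "this", "that", "these", "those",
                        "two", "three", "many", "several")
.dp_en_morphemes <- c("-ed", "-ing", "-ss", "-z")
.dp_en_aux <- c("is", "was", "are", "were")
.dp_particles <- c("up", "down")
.dp_ko_case <- c("ka", "ul", "eykey")
.dp_ko_endings <- c("-da", "-eoss", "-iss")
.dp_ko_det <- c("kthis", "kthat", "ktwo", "kthree")

.dp_eos <- "."
.dp_start <- "<s>"

.dp_env <- new.env(parent = emptyenv())

#' Lexicon of the miniature English and Korean languages
#'
#' Returns the full word-token inventory of both languages as a data frame.
#' Every token belongs to exactly one language (the sentence boundary tokens
#' `"."` and `"<s>"` are shared and carry language `"xx"`); content words map
#' to exactly one concept shared between the languages.
#'
#' @return A data frame with columns `token`, `language` (`"en"`, `"ko"` or
#'   `"xx"`), `category`, `vowel_initial`, `mass_noun` and `concept` (`NA`
#'   for function words).
#' @export
dp_lexicon <- function() {
  if (!is.null(.dp_env$lexicon)) return(.dp_env$lexicon)
  row <- function(token, language, category, vowel = FALSE, mass = FALSE,
                  concept = NA_character_) {
    data.frame(token = token, language = language, category = category,
               vowel_initial = vowel, mass_noun = mass, concept = concept,
               stringsAsFactors = FALSE)
  }
  en <- rbind(
    row(.dp_animate, "en", "animate-noun", .dp_animate %in% .dp_vowel_initial,
        FALSE, toupper(.dp_animate)),
    row(.dp_inanimate, "en", "inanimate-noun",
        .dp_inanimate %in% .dp_vowel_initial,
        .dp_inanimate %in% .dp_mass, toupper(.dp_inanimate)),
    row(.dp_intrans, "en", "intransitive-verb", concept = toupper(.dp_intrans)),
    row(.dp_trans, "en", "transitive-verb", concept = toupper(.dp_trans)),
    row(.dp_dative, "en", "dative-verb", concept = toupper(.dp_dative)),
    row(.dp_en_determiners, "en", "determiner"),
    row(.dp_en_morphemes, "en", "morpheme"),
    row(.dp_en_aux, "en", "auxiliary"),
    row(.dp_particles, "en", "particle"),
    row("to", "en", "preposition")
  )
  ko <- rbind(
    row(paste0("k", .dp_animate), "ko", "animate-noun",
        concept = toupper(.dp_animate)),
    row(paste0("k", .dp_inanimate), "ko", "inanimate-noun",
        mass = .dp_inanimate %in% .dp_mass, concept = toupper(.dp_inanimate)),
    row(paste0("k", .dp_intrans), "ko", "intransitive-verb",
        concept = toupper(.dp_intrans)),
    row(paste0("k", .dp_trans), "ko", "transitive-verb",
        concept = toupper(.dp_trans)),
    row(paste0("k", .dp_dative), "ko", "dative-verb",
        concept = toupper(.dp_dative)),
    row(paste0("k", tolower(.dp_phrasal$concept)), "ko",
        ifelse(.dp_phrasal$structure == "transitive",
               "transitive-verb", "intransitive-verb"),
        concept = .dp_phrasal$concept),
    row(.dp_ko_case, "ko", "case-marker"),
    row(.dp_ko_endings, "ko", "verb-ending"),
    row(.dp_ko_det, "ko", "determiner")
  )
  special <- rbind(row(.dp_eos, "xx", "boundary"),
                   row(.dp_start, "xx", "boundary"))
  lex <- rbind(en, ko, special)
  rownames(lex) <- NULL
  stopifnot(!anyDuplicated(lex$token))
  .dp_env$lexicon <- lex
  lex
}

#' Concept inventory
#'
#' All concept identifiers shared between the two languages: one per content
#' word, the four phrasal action concepts, and the noun feature units
#' (kind features DEF/INDEF/PROX/DIST and number features
#' SING/TWO/THREE/PLUR, printed explicitly in the message notation of the
#' grammar tables; only tense and aspect are absence-coded defaults).
#' Feature units live in the same layer as content concepts and are bound
#' to their role by the fast message weights.
#'
#' @return Character vector of concept ids.
#' @export
dp_concepts <- function() {
  c(toupper(c(.dp_animate, .dp_inanimate, .dp_intrans, .dp_trans, .dp_dative)),
    .dp_phrasal$concept,
    "DEF", "INDEF", "PROX", "DIST", "SING", "TWO", "THREE", "PLUR")
}

# tokens belonging to one language (excludes shared boundary tokens)
dp_language_tokens <- function(language) {
  lex <- dp_lexicon()
  lex$token[lex$language == language]
}

# concept -> English surface token (phrasal concepts map to their base verb)
.dp_concept_token_en <- function(concept) {
  i <- match(concept, .dp_phrasal$concept)
  ifelse(is.na(i), tolower(concept), .dp_phrasal$base[i])
}

# concept -> Korean surface token (phrasal concepts are dedicated verbs)
.dp_concept_token_ko <- function(concept) {
  paste0("k", tolower(concept))
}
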