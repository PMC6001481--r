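# The miniature languages: lexicon closure, deterministic realization,
# corpus generation and judgment items.

test_that("lexicon has the stated inventory and unique language membership", {
  lex <- dp_lexicon()
  count <- function(lang, cat) sum(lex$language == lang & lex$category == cat)
  expect_equal(count("en", "animate-noun"), 8)
  expect_equal(count("en", "inanimate-noun"), 8)
  expect_equal(count("en", "transitive-verb"), 6)
  expect_equal(count("en", "intransitive-verb"), 6)
  expect_equal(count("en", "dative-verb"), 6)
  expect_setequal(lex$token[lex$language == "en" &
                              lex$category == "determiner"],
                  c("a", "an", "the", "this", "that", "these", "those",
                    "two", "three", "many", "several"))
  expect_setequal(lex$token[lex$language == "en" &
                              lex$category == "morpheme"],
                  c("-ed", "-ing", "-ss", "-z"))
  expect_setequal(lex$token[lex$category == "auxiliary"],
                  c("is", "was", "are", "were"))
  expect_setequal(lex$token[lex$category == "case-marker"],
                  c("ka", "ul", "eykey"))
  expect_setequal(lex$token[lex$category == "verb-ending"],
                  c("-da", "-eoss", "-iss"))
  expect_false(anyDuplicated(lex$token) > 0)
  # every content word maps to exactly one shared concept
  content <- lex[lex$category %in% c("animate-noun", "inanimate-noun",
                                     "intransitive-verb", "transitive-verb",
                                     "dative-verb"), ]
  expect_true(all(content$concept %in% dp_concepts()))
})

test_that("English noun phrases follow the full kind x number table", {
  np <- function(kind, number) {
    paste(dualpathL2:::.dp_np_en(list(concept = "DOG", kind = kind,
                                      number = number)), collapse = " ")
  }
  expect_equal(np("DEF", "SING"), "the dog")
  expect_equal(np("INDEF", "SING"), "a dog")
  expect_equal(np("PROX", "SING"), "this dog")
  expect_equal(np("DIST", "SING"), "that dog")
  expect_equal(np("DEF", "TWO"), "two dog -z")
  expect_equal(np("INDEF", "TWO"), "several dog -z")
  expect_equal(np("PROX", "TWO"), "these dog -z")
  expect_equal(np("DIST", "TWO"), "those dog -z")
  expect_equal(np("DEF", "THREE"), "three dog -z")
  expect_equal(np("INDEF", "THREE"), "many dog -z")
  expect_equal(np("PROX", "THREE"), "these dog -z")
  expect_equal(np("DIST", "THREE"), "those dog -z")
  expect_equal(np("DEF", "PLUR"), "the dog -z")
  expect_equal(np("INDEF", "PLUR"), "dog -z")
  expect_equal(np("PROX", "PLUR"), "these dog -z")
  expect_equal(np("DIST", "PLUR"), "those dog -z")
  # vowel-initial noun switches the indefinite article
  expect_equal(paste(dualpathL2:::.dp_np_en(
    list(concept = "APPLE", kind = "INDEF", number = "SING")),
    collapse = " "), "an apple")
})

test_that("Korean noun phrases use demonstratives and number words only", {
  np <- function(kind, number) {
    paste(dualpathL2:::.dp_np_ko(list(concept = "DOG", kind = kind,
                                      number = number)), collapse = " ")
  }
  expect_equal(np("DEF", "SING"), "kdog")
  expect_equal(np("INDEF", "SING"), "kdog")
  expect_equal(np("PROX", "SING"), "kthis kdog")
  expect_equal(np("DIST", "SING"), "kthat kdog")
  expect_equal(np("DEF", "TWO"), "ktwo kdog")
  expect_equal(np("INDEF", "TWO"), "ktwo kdog")
  expect_equal(np("INDEF", "THREE"), "kthree kdog")
  expect_equal(np("PROX", "TWO"), "kthis kdog")
  expect_equal(np("DIST", "THREE"), "kthat kdog")
  expect_equal(np("DEF", "PLUR"), "kdog")
  expect_equal(np("INDEF", "PLUR"), "kdog")
})

test_that("worked sentence examples realize exactly", {
  m <- msg_dative_table5()
  expect_equal(realize_english(m),
               c("an", "elk", "give", "-ss", "sugar", "to", "the", "cat", "."))
  expect_equal(realize_korean(m),
               c("kelk", "ka", "kcat", "eykey", "ksugar", "ul", "kgive",
                 "-da", "."))
  m2 <- list(action = "DANCE",
             args = list(Y = list(concept = "CAT", kind = "DIST",
                                  number = "THREE")),
             event = c("PROG", "YY"))
  expect_equal(realize_english(m2),
               c("those", "cat", "-z", "are", "dance", "-ing", "."))
  m3 <- list(action = "CARRY",
             args = list(X = list(concept = "CAT", kind = "DEF",
                                  number = "SING"),
                         Y = list(concept = "APPLE", kind = "PROX",
                                  number = "SING")),
             event = c("PAST", "PROG", "XX", "YY"))
  expect_equal(realize_english(m3),
               c("the", "cat", "was", "carry", "-ing", "this", "apple", "."))
  expect_equal(realize_korean(m3),
               c("kcat", "ka", "kthis", "kapple", "ul", "kcarry", "-iss",
                 "-eoss", "-da", "."))
})

test_that("verb morphology covers phrasal, past, third person and plural", {
  vb <- function(action, event, xn = "SING") {
    m <- msg_transitive(event = event, xn = xn)
    m$action <- action
    paste(dualpathL2:::.dp_verb_en(m), collapse = " ")
  }
  expect_equal(vb("TURNDOWN", c("PAST", "XX", "YY")), "turn -ed down")
  expect_equal(vb("TURNDOWN", c("XX", "YY")), "turn -ss down")
  expect_equal(vb("CARRY", c("XX", "YY")), "carry -ss")
  expect_equal(vb("CARRY", c("XX", "YY"), xn = "PLUR"), "carry")
  expect_equal(vb("CARRY", c("PROG", "XX", "YY")), "is carry -ing")
  expect_equal(vb("CARRY", c("PROG", "XX", "YY"), xn = "TWO"),
               "are carry -ing")
  expect_equal(vb("CARRY", c("PAST", "PROG", "XX", "YY"), xn = "TWO"),
               "were carry -ing")
  # Korean endings
  kv <- function(event) {
    m <- msg_transitive(event = event); m$action <- "TURN"
    paste(dualpathL2:::.dp_verb_ko(m), collapse = " ")
  }
  expect_equal(kv(character(0)), "kturn -da")
  expect_equal(kv("PAST"), "kturn -eoss -da")
  expect_equal(kv("PROG"), "kturn -iss -da")
  expect_equal(kv(c("PAST", "PROG")), "kturn -iss -eoss -da")
})

test_that("sampled messages satisfy the role/feature invariants", {
  set.seed(7)
  p <- grammar_params("naive-defaults")
  for (i in 1:300) {
    m <- sample_message(p)
    roles <- sort(names(m$args))
    if (identical(roles, "Y")) {
      expect_true("YY" %in% m$event)
      expect_false(any(c("XX", "ZZ") %in% m$event))
    } else if (identical(roles, c("X", "Y"))) {
      expect_setequal(intersect(m$event, c("XX", "YY", "ZZ")), c("XX", "YY"))
    } else {
      expect_identical(roles, c("X", "Y", "Z"))
      expect_true(all(c("XX", "YY", "ZZ") %in% m$event))
    }
    # agents and goals animate
    for (r in intersect(c("X", "Z"), roles))
      expect_true(m$args[[r]]$concept %in% toupper(dualpathL2:::.dp_animate))
  }
})

test_that("singular dominates draws at the stated 8:1 bias", {
  set.seed(123)
  p <- grammar_params("naive-defaults")
  numbers <- replicate(10000, sample_message(p)$args$Y$number)
  expect_equal(mean(numbers == "SING"), 8 / 11, tolerance = 0.03)
})

test_that("generated corpora are reproducible, closed and exactly thinned", {
  p <- grammar_params("table7-tuned")
  set.seed(99)
  c1 <- generate_corpus(p, 400, 0.25, "en")
  set.seed(99)
  c2 <- generate_corpus(p, 400, 0.25, "en")
  expect_identical(c1, c2)
  expect_equal(sum(vapply(c1, function(r) is.null(r$message), logical(1))),
               100)
  en_tokens <- dp_lexicon()$token[dp_lexicon()$language %in% c("en", "xx")]
  expect_true(all(unlist(lapply(c1, `[[`, "tokens")) %in% en_tokens))
  # n = 1, fraction = 0: the single record keeps its message
  set.seed(1)
  one <- generate_corpus(p, 1, 0, "en")
  expect_length(one, 1)
  expect_false(is.null(one[[1]]$message))
  expect_error(generate_corpus(p, 10, 1.2), "fraction")
})

test_that("bilingual corpora interleave languages and stamp LANG features", {
  set.seed(11)
  p <- grammar_params("table7-tuned")
  corp <- generate_corpus(p, 2000, 0.25, "bilingual")
  langs <- vapply(corp, `[[`, character(1), "language")
  expect_gt(mean(langs == "en"), 0.45)
  expect_lt(mean(langs == "en"), 0.55)
  for (rec in corp) {
    if (is.null(rec$message)) next
    lang_feats <- intersect(rec$message$event, c("LANG_EN", "LANG_KO"))
    expect_length(lang_feats, 1)
    expect_equal(lang_feats, if (rec$language == "en") "LANG_EN"
                 else "LANG_KO")
  }
})

test_that("test sentences round-trip through their messages", {
  set.seed(21)
  p <- grammar_params("table7-tuned")
  pairs <- generate_test_sentences(p, 50, "en")
  for (pr in pairs)
    expect_identical(pr$tokens, realize_english(pr$message))
  pairs_ko <- generate_test_sentences(p, 20, "ko")
  for (pr in pairs_ko)
    expect_identical(pr$tokens, realize_korean(pr$message))
  expect_length(generate_test_sentences(p, 0, "en"), 0)
})

test_that("judgment items apply exactly one rule-specific omission", {
  set.seed(31)
  for (rule in c("DET", "PL", "PAR", "3PS", "PST")) {
    items <- generate_judgment_items(rule, 40)
    for (it in items) {
      g <- it$grammatical; u <- it$ungrammatical
      expect_length(u, length(g) - 1)
      d <- it$divergence + 1L            # 0-based -> 1-based
      expect_true(all(g[seq_len(d - 1)] == u[seq_len(d - 1)]))
      expect_false(g[d] == u[d])
      expect_identical(g[-d], u)         # omission only
      expect_identical(it$target_gram, g[d])
      expect_identical(it$target_ungram, u[d])
      omitted <- switch(rule, DET = NULL, PL = "-z", PAR = c("up", "down"),
                        `3PS` = "-ss", PST = "-ed")
      if (!is.null(omitted)) expect_true(g[d] %in% omitted)
      if (rule == "DET") {
        lex <- dp_lexicon()
        expect_equal(lex$category[match(g[d], lex$token)], "determiner")
      }
    }
  }
})

test_that("the worked determiner item appears with its stated targets", {
  # a boy touch -ed the apple  vs  a boy touch -ed apple
  it <- list(rule = "DET",
             grammatical = c("a", "boy", "touch", "-ed", "the", "apple", "."),
             ungrammatical = c("a", "boy", "touch", "-ed", "apple", "."),
             divergence = 4L, target_gram = "the", target_ungram = "apple")
  expect_identical(it$grammatical[it$divergence + 1L], "the")
  expect_identical(it$ungrammatical[it$divergence + 1L], "apple")
  # the generator builds items with the same geometry
  set.seed(4)
  gen <- generate_judgment_items("DET", 10)
  for (g in gen) {
    expect_equal(g$target_ungram,
                 g$grammatical[g$divergence + 2L])
  }
})

test_that("grammar presets validate and load from YAML", {
  expect_error(grammar_params(structure_mix = c(0.5, 0.2, 0.2)))
  expect_error(grammar_params(kind_weights = c(-1, 1, 1, 1)))
  path <- system.file("extdata", "presets", "table7-tuned.yaml",
                      package = "dualpathL2")
  p <- read_grammar_params(path)
  expect_s3_class(p, "dp_grammar_params")
  expect_equal(p$phrasal_verb_prob, 0.4)
})
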