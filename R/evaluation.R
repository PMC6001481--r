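# Outcome measures: word-prediction accuracy, SSE-based rule proportion,
# code-switching rate, and the effect-sign analysis over simulation output.

#' Word-prediction accuracy
#'
#' Fraction of word positions (end-of-sentence included, the start token
#' excluded) at which the argmax of the output activations equals the
#' target word, over a set of message-sentence pairs.
#'
#' @param net A `dp_network`.
#' @param test_pairs A `dp_corpus` of pairs with messages.
#' @return Proportion in `[0, 1]`.
#' @export
word_prediction_accuracy <- function(net, test_pairs) {
  if (length(test_pairs) == 0) stop("empty test set", call. = FALSE)
  cfg <- net$config
  enc <- .dp_encode_corpus(cfg, test_pairs)
  res <- cpp_process_batch(net$weights, enc$sents, enc$binds, enc$evs,
                           rep(0, length(enc$sents)),
                           rep(0, length(enc$sents)),
                           cfg$output_activation == "softmax",
                           cfg$binding_strength, cfg$start_index, TRUE,
                           0, net$velocity)
  hits <- 0L; total <- 0L
  for (i in seq_along(enc$sents)) {
    out <- res$outputs[[i]]
    out[, cfg$start_index] <- -1          # the start token is input-only
    pred <- max.col(out, ties.method = "first")
    hits <- hits + sum(pred == enc$sents[[i]])
    total <- total + length(pred)
  }
  hits / total
}

#' Rule proportion from matched judgment items
#'
#' For each item the output activations at the divergence point are scored
#' against the grammatical target (the omitted token) and against the
#' ungrammatical target (the token that follows it in the pruned
#' sentence); both versions share the same prefix, so the prediction is
#' made once.  Prediction is conditioned on the item's generating message
#' (the network is a production model: it predicts the next word given
#' the meaning it is expressing).  The rule proportion is the mean
#' ungrammatical
#' SSE divided by the sum of the mean grammatical and ungrammatical SSEs:
#' 0.5 means no discrimination, higher means better rule knowledge.
#'
#' @param net A `dp_network`.
#' @param items Items for a single rule from [generate_judgment_items()].
#' @return `list(rule, mean_sse_grammatical, mean_sse_ungrammatical,
#'   proportion)`.
#' @export
rule_proportion <- function(net, items) {
  if (length(items) == 0) stop("need at least one item", call. = FALSE)
  cfg <- net$config
  # predict up to and including the divergence position, with each item's
  # message installed
  sents <- lapply(items, function(it)
    .dp_encode_tokens(cfg, it$grammatical[seq_len(it$divergence + 1L)]))
  enc <- lapply(items, function(it) .dp_encode_message(cfg, it$message))
  n <- length(sents)
  res <- cpp_process_batch(net$weights, sents,
                           lapply(enc, `[[`, "bind"),
                           lapply(enc, `[[`, "ev"),
                           rep(0, n), rep(0, n),
                           cfg$output_activation == "softmax",
                           cfg$binding_strength, cfg$start_index, TRUE,
                           0, net$velocity)
  sse_g <- numeric(n); sse_u <- numeric(n)
  for (i in seq_len(n)) {
    it <- items[[i]]
    out <- res$outputs[[i]][it$divergence + 1L, ]
    tg <- match(it$target_gram, cfg$words)
    tu <- match(it$target_ungram, cfg$words)
    og <- out; og[tg] <- og[tg] - 1
    ou <- out; ou[tu] <- ou[tu] - 1
    sse_g[i] <- sum(og^2)
    sse_u[i] <- sum(ou^2)
  }
  mg <- mean(sse_g); mu <- mean(sse_u)
  if (mg + mu == 0)
    stop("both mean SSEs are zero; proportion undefined", call. = FALSE)
  list(rule = items[[1L]]$rule, mean_sse_grammatical = mg,
       mean_sse_ungrammatical = mu, proportion = mu / (mg + mu))
}

#' Code-switching rate in greedy production
#'
#' Produces a sentence for each (English) message and returns the
#' proportion of Korean-lexicon tokens among all produced word tokens
#' (boundary tokens excluded; morpheme tokens count for their language).
#'
#' @param net A `dp_network`.
#' @param messages List of messages.
#' @param max_len Maximum production length per sentence.
#' @return Proportion in `[0, 1]`.
#' @export
code_switch_rate <- function(net, messages, max_len = 20) {
  lex <- dp_lexicon()
  ko <- 0L; total <- 0L
  for (msg in messages) {
    toks <- produce_sentence(net, msg, max_len)
    lang <- lex$language[match(toks, lex$token)]
    ko <- ko + sum(lang == "ko")
    total <- total + sum(lang %in% c("en", "ko"))
  }
  if (total == 0) return(0)
  ko / total
}

#' Effect-sign analysis of a simulation results table
#'
#' Fits rule proportion on AoA, LoE and rule CP fully crossed, with a
#' per-subject random intercept (lme4).  Predictors (and only predictors)
#' are centered when `centered = TRUE`.  If the mixed fit fails or is
#' singular, falls back to least squares on subject-demeaned outcomes and
#' records that in the summary.
#'
#' @param results A results table from [run_simulation()] (columns
#'   `subject`, `aoa`, `loe`, `rule_cp`, `rule_proportion`).
#' @param centered Center the predictors before fitting (default `TRUE`).
#' @return An object of class `dp_effects`: a coefficient table
#'   (`term`, `estimate`, `se`) plus the estimation method used.
#' @export
fit_effects <- function(results, centered = TRUE) {
  d <- data.frame(subject = factor(results$subject),
                  aoa = as.numeric(results$aoa),
                  loe = as.numeric(results$loe),
                  cp = as.numeric(results$rule_cp),
                  y = as.numeric(results$rule_proportion))
  if (centered) {
    d$aoa <- d$aoa - mean(d$aoa)
    d$loe <- d$loe - mean(d$loe)
    d$cp <- d$cp - mean(d$cp)
  }
  X <- stats::model.matrix(~ aoa * loe * cp, d)
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient design; collinear terms: ",
         paste(colnames(X)[-seq_len(qr(X)$rank)], collapse = ", "),
         call. = FALSE)
  }
  method <- "lmer"
  fit <- tryCatch(
    lme4::lmer(y ~ aoa * loe * cp + (1 | subject), data = d, REML = FALSE),
    error = function(e) NULL)
  if (!is.null(fit) && lme4::isSingular(fit, tol = 1e-5)) {
    # keep the fit but note singularity; fixed effects remain interpretable
    method <- "lmer (singular random intercept)"
  }
  if (is.null(fit)) {
    method <- "subject-demeaned least squares"
    d$y <- d$y - stats::ave(d$y, d$subject) + mean(d$y)
    fit <- stats::lm(y ~ aoa * loe * cp, data = d)
  }
  coefs <- if (inherits(fit, "lm")) {
    s <- summary(fit)$coefficients
    data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    s <- summary(fit)$coefficients
    data.frame(term = rownames(s), estimate = s[, "Estimate"],
               se = s[, "Std. Error"], row.names = NULL,
               stringsAsFactors = FALSE)
  }
  out <- list(coefficients = coefs, method = method, model = fit)
  class(out) <- "dp_effects"
  out
}

#' Extract one coefficient from a dp_effects object
#'
#' @param effects A `dp_effects` object.
#' @param term Coefficient name, e.g. `"aoa"` or `"aoa:loe"`.
#' @return The estimate (numeric scalar).
#' @export
effect_estimate <- function(effects, term) {
  i <- match(term, effects$coefficients$term)
  if (is.na(i)) stop("no such term: ", term, call. = FALSE)
  effects$coefficients$estimate[i]
}

#' @export
print.dp_effects <- function(x, ...) {
  cat("effect estimates (", x$method, ")\n", sep = "")
  print(x$coefficients, digits = 3)
  invisible(x)
}
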