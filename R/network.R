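# The dual-path network: configuration, initialization, message binding and
# the R wrappers around the compiled training/prediction core.
#
# Weight matrices are updated in place by the compiled code for speed, so a
# dp_network behaves with reference semantics under training: use
# copy_network() (or a saved checkpoint) wherever an independent snapshot
# is needed.

.dp_roles <- c("A", "X", "Y", "Z")
.dp_event_features <- c("PAST", "PROG", "XX", "YY", "ZZ",
                        "LANG_EN", "LANG_KO")

#' Network configuration
#'
#' Layer sizes and numerical settings of the dual-path network.  The word
#' layer covers the full bilingual token inventory (plus sentence boundary
#' tokens); the concept layers cover the shared concept inventory; the role
#' layers have one unit per message role (A, X, Y, Z).
#'
#' @param hidden,compress,ccompress Sizes of the hidden layer and of the
#'   two category-compression layers.
#' @param output_activation `"softmax"` (winner-take-all bias,
#'   cross-entropy training loss) or `"logistic"` (per-unit sigmoid,
#'   squared-error training loss whose delta carries the o(1-o)
#'   entrenchment factor).
#' @param init_half_range Learned weights are initialized uniformly on
#'   `[-init_half_range, init_half_range]`; the default 0.25 gives a total
#'   range of 0.5.
#' @param binding_strength Value of the fast role-concept message weights
#'   (default 6).
#' @param momentum Classical momentum on the weight updates (default 0 =
#'   plain gradient descent; the squared-error logistic regime uses 0.9).
#' @return An object of class `dp_network_config`.
#' @export
network_config <- function(hidden = 160, compress = 60, ccompress = 20,
                           output_activation = c("softmax", "logistic"),
                           init_half_range = 0.25, binding_strength = 6,
                           momentum = 0) {
  output_activation <- match.arg(output_activation)
  stopifnot(hidden >= 1, compress >= 1, ccompress >= 1,
            init_half_range > 0, binding_strength > 0,
            momentum >= 0, momentum < 1)
  lex <- dp_lexicon()
  cfg <- list(words = lex$token, concepts = dp_concepts(), roles = .dp_roles,
              event_features = .dp_event_features,
              hidden = as.integer(hidden), compress = as.integer(compress),
              ccompress = as.integer(ccompress),
              output_activation = output_activation,
              init_half_range = init_half_range,
              binding_strength = binding_strength,
              start_index = match(.dp_start, lex$token),
              eos_index = match(.dp_eos, lex$token),
              momentum = momentum)
  class(cfg) <- "dp_network_config"
  cfg
}

.dp_runif_mat <- function(nr, nc, half) {
  matrix(stats::runif(nr * nc, -half, half), nr, nc)
}

# Names of the learned weight groups in the lexical subset; everything else
# learned is syntactic.  The two subsets partition the learned weights.
.dp_lexical_groups <- c("concept_word", "hidden_compress", "compress_word",
                        "bias_word")

#' Initialize a dual-path network
#'
#' Every learned weight (including biases) is drawn uniformly from
#' `[-init_half_range, init_half_range]`.  Fast message weights start at
#' zero.  Uses the R random number stream.
#'
#' @param config A [network_config()] object.
#' @return An object of class `dp_network` holding the weight set.
#' @export
init_network <- function(config = network_config()) {
  stopifnot(inherits(config, "dp_network_config"))
  W <- length(config$words); C <- length(config$concepts)
  H <- config$hidden; P <- config$compress; CC <- config$ccompress
  R <- length(config$roles); E <- length(config$event_features)
  h <- config$init_half_range
  weights <- list(
    prev_cconcept = .dp_runif_mat(C, W, h),
    prev_ccompress = .dp_runif_mat(CC, W, h),
    ccompress_hidden = .dp_runif_mat(H, CC, h),
    context_hidden = .dp_runif_mat(H, H, h),
    eventsem_hidden = .dp_runif_mat(H, E, h),
    crole_hidden = .dp_runif_mat(H, R, h),
    crolecopy_hidden = .dp_runif_mat(H, R, h),
    hidden_role = .dp_runif_mat(R, H, h),
    hidden_compress = .dp_runif_mat(P, H, h),
    compress_word = .dp_runif_mat(W, P, h),
    concept_word = .dp_runif_mat(W, C, h),
    bias_hidden = stats::runif(H, -h, h),
    bias_compress = stats::runif(P, -h, h),
    bias_ccompress = stats::runif(CC, -h, h),
    bias_word = stats::runif(W, -h, h)
  )
  net <- list(config = config, weights = weights,
              velocity = lapply(weights, function(x) x * 0),
              binding = matrix(integer(0), 0, 2),
              eventsem = numeric(E))
  class(net) <- "dp_network"
  net
}

#' Deep-copy a network
#'
#' Training updates weight matrices in place; use this to take an
#' independent snapshot (e.g. an age checkpoint).
#'
#' @param net A `dp_network`.
#' @return A `dp_network` sharing no memory with `net`.
#' @export
copy_network <- function(net) {
  net$weights <- lapply(net$weights, function(x) x + 0)
  net$velocity <- lapply(net$velocity, function(x) x + 0)
  net
}

#' @export
print.dp_network <- function(x, ...) {
  cfg <- x$config
  cat("dual-path network:", length(cfg$words), "words,",
      length(cfg$concepts), "concepts, hidden", cfg$hidden,
      paste0("(", cfg$output_activation, " output)\n"))
  invisible(x)
}

# ---- encoding --------------------------------------------------------------

.dp_encode_tokens <- function(config, tokens) {
  idx <- match(tokens, config$words)
  if (anyNA(idx))
    stop("token outside inventory: '", tokens[which(is.na(idx))[1L]], "'",
         call. = FALSE)
  as.integer(idx)
}

# message -> (role, concept) binding index pairs + event-semantics vector.
# Each noun role binds to its concept plus its kind and number feature
# units (tense/aspect stay absence-coded in the event semantics).
.dp_encode_message <- function(config, message) {
  if (is.null(message)) {
    return(list(bind = matrix(integer(0), 0, 2),
                ev = numeric(length(config$event_features))))
  }
  roles <- "A"
  concepts <- message$action
  for (r in names(message$args)) {
    a <- message$args[[r]]
    feats <- c(a$concept, a$kind, a$number)
    roles <- c(roles, rep(r, length(feats)))
    concepts <- c(concepts, feats)
  }
  ri <- match(roles, config$roles)
  ci <- match(concepts, config$concepts)
  if (anyNA(ci))
    stop("unknown concept '", concepts[which(is.na(ci))[1L]], "'",
         call. = FALSE)
  ev <- as.numeric(config$event_features %in% message$event)
  list(bind = cbind(as.integer(ri), as.integer(ci)), ev = ev)
}

.dp_encode_corpus <- function(config, corpus) {
  sents <- lapply(corpus, function(rec) .dp_encode_tokens(config, rec$tokens))
  enc <- lapply(corpus, function(rec) .dp_encode_message(config, rec$message))
  list(sents = sents,
       binds = lapply(enc, `[[`, "bind"),
       evs = lapply(enc, `[[`, "ev"))
}

# ---- message binding -------------------------------------------------------

#' Install a message in the fast weights
#'
#' Sets the fast role-concept binding matrix (binding_strength at each
#' bound pair, zero elsewhere; the comprehension side uses the transpose)
#' and the event-semantics input vector.  A `NULL` message clears both.
#' A second call fully overwrites the first.
#'
#' @param net A `dp_network`.
#' @param message A message or `NULL`.
#' @return The network with the message installed.
#' @export
set_message <- function(net, message = NULL) {
  enc <- .dp_encode_message(net$config, message)
  net$binding <- enc$bind
  net$eventsem <- enc$ev
  net
}

#' Fast binding matrix currently installed
#'
#' @param net A `dp_network`.
#' @return A roles-by-concepts matrix of fast weights.
#' @export
binding_matrix <- function(net) {
  cfg <- net$config
  F <- matrix(0, length(cfg$roles), length(cfg$concepts),
              dimnames = list(cfg$roles, cfg$concepts))
  if (nrow(net$binding))
    F[net$binding] <- cfg$binding_strength
  F
}

# ---- stepwise API (reference R implementation) -----------------------------

#' Initial step state
#'
#' Context reset to 0.5 at sentence start; comprehension-role trace zero.
#'
#' @param net A `dp_network`.
#' @return `list(context, crole_copy)`.
#' @export
init_state <- function(net) {
  list(context = rep(0.5, net$config$hidden),
       crole_copy = rep(0, length(net$config$roles)))
}

#' One forward step
#'
#' Pure R reference implementation of a single prediction step (the
#' compiled batch path is numerically identical).  Uses the message
#' currently installed via [set_message()].
#'
#' @param net A `dp_network`.
#' @param state A step state from [init_state()] or a previous step.
#' @param prev_word The previous word token (use the start token `"<s>"`
#'   sentence-initially).
#' @return `list(output, state)`: the activation vector over the word
#'   inventory and the updated state.
#' @export
forward_step <- function(net, state, prev_word) {
  cfg <- net$config
  w <- net$weights
  p <- .dp_encode_tokens(cfg, prev_word)
  sig <- function(x) 1 / (1 + exp(-x))
  F <- binding_matrix(net)
  cconcept <- sig(w$prev_cconcept[, p])
  ccompress <- sig(w$prev_ccompress[, p] + w$bias_ccompress)
  crole <- sig(drop(F %*% cconcept))
  hidden <- sig(drop(w$ccompress_hidden %*% ccompress +
                     w$context_hidden %*% state$context +
                     w$eventsem_hidden %*% net$eventsem +
                     w$crole_hidden %*% crole +
                     w$crolecopy_hidden %*% state$crole_copy) + w$bias_hidden)
  role <- sig(drop(w$hidden_role %*% hidden))
  concept <- sig(drop(t(F) %*% role))
  compress <- sig(drop(w$hidden_compress %*% hidden) + w$bias_compress)
  net_out <- drop(w$compress_word %*% compress + w$concept_word %*% concept) +
    w$bias_word
  out <- if (cfg$output_activation == "softmax") {
    e <- exp(net_out - max(net_out)); e / sum(e)
  } else sig(net_out)
  names(out) <- cfg$words
  list(output = out,
       state = list(context = hidden,
                    crole_copy = pmax(state$crole_copy, crole)))
}

# ---- sentence-level operations --------------------------------------------

#' Train on one message-sentence pair
#'
#' Processes the token sequence left to right, predicting each next word
#' and backpropagating the prediction error at every step (context treated
#' as a fixed input).  Lexical weight groups (concept-to-word and the
#' hidden-compress-word route, plus output biases) are updated with
#' `lr_lexical`; all other learned groups with `lr_syntactic`.  The fast
#' message weights are installed from the pair's message before the first
#' step and cleared afterwards.
#'
#' @param net A `dp_network` (modified in place).
#' @param pair `list(tokens, message)`; `message` may be `NULL`.
#' @param lr_lexical,lr_syntactic Learning rates (>= 0).
#' @return `list(network, errors)`: the updated network and the summed
#'   squared error at each word position.
#' @export
train_sentence <- function(net, pair, lr_lexical, lr_syntactic) {
  stopifnot(lr_lexical >= 0, lr_syntactic >= 0)
  cfg <- net$config
  enc <- .dp_encode_message(cfg, pair$message)
  res <- cpp_process_batch(net$weights,
                           list(.dp_encode_tokens(cfg, pair$tokens)),
                           list(enc$bind), list(enc$ev),
                           lr_lexical, lr_syntactic,
                           cfg$output_activation == "softmax",
                           cfg$binding_strength, cfg$start_index,
                           FALSE, cfg$momentum, net$velocity)
  list(network = net, errors = res$sse[[1L]])
}

#' Train on a corpus with per-sentence learning rates
#'
#' @param net A `dp_network` (modified in place).
#' @param corpus A `dp_corpus` (or encoded corpus from the internal
#'   encoder).
#' @param lr_lexical,lr_syntactic Scalar rates or one rate per sentence.
#' @return `list(network, mean_sse)` where `mean_sse` is the mean per-word
#'   summed squared error over the corpus.
#' @export
train_network <- function(net, corpus, lr_lexical, lr_syntactic) {
  cfg <- net$config
  enc <- if (!is.null(corpus$sents)) corpus else .dp_encode_corpus(cfg, corpus)
  n <- length(enc$sents)
  res <- cpp_process_batch(net$weights, enc$sents, enc$binds, enc$evs,
                           rep_len(lr_lexical, n), rep_len(lr_syntactic, n),
                           cfg$output_activation == "softmax",
                           cfg$binding_strength, cfg$start_index,
                           FALSE, cfg$momentum, net$velocity)
  list(network = net,
       mean_sse = mean(unlist(res$sse, use.names = FALSE)))
}

#' Per-position output activations for a sentence
#'
#' Forward pass only (no weight change): installs the pair's message,
#' predicts each token position and returns the full activation vector at
#' each position.
#'
#' @param net A `dp_network`.
#' @param pair `list(tokens, message)`.
#' @return A positions-by-words matrix of output activations; row `p`
#'   predicts token `p`.
#' @export
predict_sentence <- function(net, pair) {
  cfg <- net$config
  enc <- .dp_encode_message(cfg, pair$message)
  res <- cpp_process_batch(net$weights,
                           list(.dp_encode_tokens(cfg, pair$tokens)),
                           list(enc$bind), list(enc$ev),
                           0, 0,
                           cfg$output_activation == "softmax",
                           cfg$binding_strength, cfg$start_index,
                           TRUE, 0, net$velocity)
  out <- res$outputs[[1L]]
  dimnames(out) <- list(pair$tokens, cfg$words)
  out
}

#' Produce a sentence from a message by greedy decoding
#'
#' The argmax output is fed back as the next previous word until the
#' end-of-sentence token or `max_len`; ties break to the lowest token
#' index, so production is deterministic.
#'
#' @param net A `dp_network`.
#' @param message A message (or `NULL` for unconditioned production).
#' @param max_len Maximum number of tokens.
#' @return Character vector of produced tokens.
#' @export
produce_sentence <- function(net, message, max_len = 20) {
  stopifnot(max_len >= 1)
  cfg <- net$config
  enc <- .dp_encode_message(cfg, message)
  idx <- cpp_produce(net$weights, enc$bind, enc$ev,
                     cfg$output_activation == "softmax",
                     cfg$binding_strength, cfg$start_index,
                     cfg$eos_index, as.integer(max_len))
  cfg$words[idx]
}

# ---- checkpoints -----------------------------------------------------------

#' Save a network checkpoint
#'
#' Serializes every weight group plus configuration and age metadata;
#' round-trips bit-exactly.
#'
#' @param net A `dp_network`.
#' @param path Output file.
#' @param age Model age in years to record with the checkpoint.
#' @export
save_checkpoint <- function(net, path, age = NA_real_) {
  net$age <- age
  saveRDS(net, path)
}

#' Load a network checkpoint
#'
#' @param path File written by [save_checkpoint()].
#' @return The `dp_network`, with its recorded `age` field.
#' @export
load_checkpoint <- function(path) {
  readRDS(path)
}
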