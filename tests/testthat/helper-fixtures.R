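# Shared fixtures: tiny networks, hand-built messages, and an analytic
# gradient extractor used by the finite-difference checks.

toy_config <- function(activation = "softmax") {
  network_config(hidden = 6, compress = 3, ccompress = 3,
                 output_activation = activation)
}

msg_transitive <- function(x = "DOG", y = "APPLE", xk = "DEF", xn = "SING",
                           yk = "PROX", yn = "SING", event = c("XX", "YY")) {
  list(action = "CARRY",
       args = list(X = list(concept = x, kind = xk, number = xn),
                   Y = list(concept = y, kind = yk, number = yn)),
       event = event)
}

msg_dative_table5 <- function() {
  list(action = "GIVE",
       args = list(X = list(concept = "ELK", kind = "INDEF", number = "SING"),
                   Y = list(concept = "SUGAR", kind = "PROX", number = "PLUR"),
                   Z = list(concept = "CAT", kind = "DEF", number = "SING")),
       event = c("XX", "YY", "ZZ"))
}

# Analytic single-step gradients for every weight group, extracted by
# running the compiled trainer for one step at unit learning rates from a
# frozen state (the weight change then equals the gradient).
analytic_gradients <- function(net, prev, target, context, crolecopy) {
  cfg <- net$config
  snap <- lapply(net$weights, function(x) x + 0)
  work <- copy_network(net)
  dualpathL2:::cpp_process_batch(
    work$weights,
    list(dualpathL2:::.dp_encode_tokens(cfg, target)),
    list(work$binding), list(work$eventsem),
    1, 1, cfg$output_activation == "softmax",
    cfg$binding_strength,
    dualpathL2:::.dp_encode_tokens(cfg, prev),
    FALSE, 0, work$velocity, context, crolecopy)
  mapply(function(a, b) a - b, snap, work$weights, SIMPLIFY = FALSE)
}

# Single-step loss via the pure-R forward pass: multinomial cross-entropy
# under softmax, half summed squared error under logistic.
step_loss <- function(net, prev, target, context, crolecopy) {
  st <- list(context = context, crole_copy = crolecopy)
  out <- forward_step(net, st, prev)$output
  if (net$config$output_activation == "softmax") {
    -log(out[[target]])
  } else {
    tgt <- as.numeric(net$config$words == target)
    0.5 * sum((out - tgt)^2)
  }
}
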