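# Shared fixtures built in code.

# evaluate a rule object through its text representation
eval_rule_for_test <- function(rule, state) {
  oracle_rule_eval(rule$text, state)
}

# two-node toggle switch: X = !Y, Y = !X
toggle_model <- function() {
  boolean_model(list(
    X = boolean_rule("X", inhibitors = "Y"),
    Y = boolean_rule("Y", inhibitors = "X")))
}

# Seven-node constructed instance with a planted knockout: hubs M (MES-like)
# and N (NPC-like) mutually inhibit; N activates T which inhibits F, and F in
# turn inhibits N; G and H mark the NPC side, J the MES side. Clamping T from
# the NPC basin releases F, which shuts N down and lands exactly on the MES
# fixed point. Verified by exhaustive enumeration in the tests.
constructed_instance <- function() {
  model <- boolean_model(list(
    M = boolean_rule("M", inhibitors = "N"),
    N = boolean_rule("N", inhibitors = c("M", "F"), inh_comb = "OR"),
    T = boolean_rule("T", activators = "N"),
    F = boolean_rule("F", inhibitors = "T"),
    G = boolean_rule("G", activators = "N"),
    H = boolean_rule("H", activators = "N"),
    J = boolean_rule("J", activators = "M")))
  profiles <- list(
    MES = c(M = 1L, N = 0L, T = 0L, F = 1L, G = 0L, H = 0L, J = 1L),
    NPC = c(M = 0L, N = 1L, T = 1L, F = 0L, G = 1L, H = 1L, J = 0L))
  list(model = model, profiles = profiles,
       network = network_from_model(model))
}

# 144-node binary profiles matching the merged-network scale
profsN <- function() {
  nodes <- sprintf("p%03d", 1:144)
  withr::with_seed(99, list(
    MES = stats::setNames(sample(0:1, 144, TRUE), nodes),
    NPC = stats::setNames(sample(0:1, 144, TRUE), nodes)))
}

# disjoint marker modules over a synthetic gene namespace
toy_modules <- function(states = state_order(), genes_per_module = 10) {
  mods <- lapply(seq_along(states), function(i) {
    sprintf("%s_g%02d", states[i], seq_len(genes_per_module))
  })
  names(mods) <- states
  mods
}

# simple reference-means matrix with state-specific marker blocks
toy_reference_means <- function(states = state_order(), genes_per_module = 10,
                                n_background = 20, elevation = 8) {
  mods <- toy_modules(states, genes_per_module)
  genes <- c(unlist(mods, use.names = FALSE),
             sprintf("bg%03d", seq_len(n_background)))
  ref <- matrix(1, length(genes), length(states),
                dimnames = list(genes, states))
  for (s in states) ref[mods[[s]], s] <- elevation
  ref
}
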