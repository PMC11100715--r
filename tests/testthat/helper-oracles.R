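# Independent oracles used by the test suite. These deliberately take a
# different computational route from the package code they check: rules are
# re-evaluated by parsing their text representation, attractors come from the
# exhaustive state-transition graph, hypergeometric tails from the explicit
# combinatorial sum, and Shapley values from brute-force subset enumeration.

# evaluate a rule by parsing its canonical text (independent of eval_rule)
oracle_rule_eval <- function(rule_text, state) {
  env <- as.list(stats::setNames(as.logical(state), names(state)))
  as.integer(as.logical(eval(parse(text = rule_text)[[1]], envir = env)))
}

oracle_update <- function(model, state) {
  out <- vapply(model$rules, function(r) oracle_rule_eval(r$text, state),
                integer(1))
  stats::setNames(out, model$nodes)
}

# index (1-based, little-endian) <-> state helpers over the full state space
oracle_state_from_index <- function(i, nodes) {
  stats::setNames(as.integer(bitwAnd(i - 1L, 2^(seq_along(nodes) - 1)) > 0),
                  nodes)
}
oracle_index_of_state <- function(state, nodes) {
  as.integer(1 + sum(state[nodes] * 2^(seq_along(nodes) - 1)))
}

# full synchronous successor table of a model via text-parsed rules
oracle_successors <- function(model) {
  n <- length(model$nodes)
  vapply(seq_len(2^n), function(i) {
    s <- oracle_state_from_index(i, model$nodes)
    oracle_index_of_state(oracle_update(model, s), model$nodes)
  }, integer(1))
}

# the attractor (sorted set of state indices) reached from state index i
oracle_attractor_from <- function(succ, i) {
  seen <- integer(0)
  while (!(i %in% seen)) {
    seen <- c(seen, i)
    i <- succ[i]
  }
  cyc_start <- match(i, seen)
  sort(seen[cyc_start:length(seen)])
}

# all fixed points of a model by exhaustive enumeration
oracle_fixed_points <- function(model) {
  succ <- oracle_successors(model)
  which(succ == seq_along(succ))
}

# exact upper-tail hypergeometric P(X >= k): |marker| draws from a universe
# of N genes containing K module genes
oracle_hyper_tail <- function(k, K, N, n) {
  if (k <= 0) return(1)
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# random sign-consistent gate model for oracle-equivalence checks
random_gate_model <- function(n, seed) {
  withr::with_seed(seed, {
    nodes <- sprintf("n%02d", seq_len(n))
    rules <- list()
    for (i in seq_len(n)) {
      k <- sample(1:min(3, n), 1)
      regs <- sample(nodes, k)
      sgn <- sample(c(1L, -1L), k, replace = TRUE)
      rules[[nodes[i]]] <- boolean_rule(
        nodes[i], activators = regs[sgn == 1L], inhibitors = regs[sgn == -1L],
        act_comb = sample(c("OR", "AND"), 1),
        inh_comb = sample(c("OR", "AND"), 1))
    }
    boolean_model(rules)
  })
}

# ---- brute-force tree-Shapley oracle ----------------------------------------

# expected prediction of one tree given only the features in subset S,
# marginalizing unseen splits by cover weights (tree-conditional expectation)
oracle_tree_expect <- function(tree, x, S) {
  node_row <- function(id) tree[tree$ID == id, , drop = FALSE]
  rec <- function(id) {
    r <- node_row(id)
    if (r$Feature == "Leaf") return(r$Gain)
    if (r$Feature %in% S) {
      branch <- if (x[[r$Feature]] < r$Split) r$Yes else r$No
      return(rec(branch))
    }
    wy <- node_row(r$Yes)$Cover
    wn <- node_row(r$No)$Cover
    (wy * rec(r$Yes) + wn * rec(r$No)) / (wy + wn)
  }
  rec(tree$ID[1])
}

# per-class per-feature Shapley values of an xgboost multiclass model by
# enumerating all feature subsets
oracle_shap <- function(xgb_model, x, n_class) {
  stopifnot(requireNamespace("data.table", quietly = TRUE))
  dump <- as.data.frame(xgboost::xgb.model.dt.tree(model = xgb_model))
  feats <- names(x)
  p <- length(feats)
  subsets <- lapply(0:(2^p - 1), function(m) feats[bitwAnd(m, 2^(seq_len(p) - 1)) > 0])
  class_of_tree <- dump$Tree %% n_class
  v <- function(S, cls) {
    trees <- unique(dump$Tree[class_of_tree == cls])
    sum(vapply(trees, function(t)
      oracle_tree_expect(dump[dump$Tree == t, , drop = FALSE], x, S),
      numeric(1)))
  }
  key <- function(S) paste0("{", paste(sort(S), collapse = ","), "}")
  out <- matrix(0, n_class, p, dimnames = list(NULL, feats))
  for (cls in 0:(n_class - 1)) {
    vals <- vapply(subsets, v, numeric(1), cls = cls)
    names(vals) <- vapply(subsets, key, character(1))
    for (j in feats) {
      phi <- 0
      for (S in subsets) {
        if (j %in% S) next
        w <- factorial(length(S)) * factorial(p - length(S) - 1) / factorial(p)
        phi <- phi + w * (vals[[key(c(S, j))]] - vals[[key(S)]])
      }
      out[cls + 1, j] <- phi
    }
  }
  out
}
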