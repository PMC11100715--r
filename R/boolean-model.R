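#' Boolean rules and models
#'
#' A Boolean model assigns one logic rule to every node. Rules come in four
#' flavours:
#' \describe{
#'   \item{gate}{`combine(activators) AND NOT combine(inhibitors)`, with each
#'     combinator OR or AND; degenerate forms when one side is empty.}
#'   \item{table}{an explicit truth table over the node's regulators (used as
#'     the sign-monotone fallback of rule synthesis and by the rule parser).}
#'   \item{input}{identity: an input node (no incoming edges) holds whatever
#'     value it is given at time zero, i.e. it acts as a self-clamp.}
#'   \item{const}{a constant 0/1, used for knockouts and clamps.}
#' }
#'
#' @param target Node name.
#' @param activators,inhibitors Character vectors of regulator names.
#' @param act_comb,inh_comb "OR" or "AND".
#' @return A `boolean_rule` object.
#' @export
boolean_rule <- function(target, activators = character(),
                         inhibitors = character(),
                         act_comb = "OR", inh_comb = "OR") {
  stopifnot(act_comb %in% c("OR", "AND"), inh_comb %in% c("OR", "AND"))
  r <- structure(list(target = target, type = "gate",
                      activators = activators, inhibitors = inhibitors,
                      act_comb = act_comb, inh_comb = inh_comb),
                 class = "boolean_rule")
  r$text <- rule_text(r)
  r
}

#' @rdname boolean_rule
#' @param regulators Ordered character vector of regulator names.
#' @param output Integer 0/1 vector of length `2^length(regulators)`; entry
#'   `i` is the output for the pattern whose bit `j` (1-based, little-endian)
#'   is `bitwAnd(i - 1, 2^(j-1)) > 0`.
#' @export
table_rule <- function(target, regulators, output) {
  stopifnot(length(output) == 2^length(regulators),
            all(output %in% c(0L, 1L)))
  r <- structure(list(target = target, type = "table",
                      regulators = regulators,
                      output = as.integer(output),
                      bitw = if (length(regulators)) 2^(seq_along(regulators) - 1) else numeric()),
                 class = "boolean_rule")
  r$text <- rule_text(r)
  r
}

#' @rdname boolean_rule
#' @export
input_rule <- function(target) {
  structure(list(target = target, type = "input", text = target),
            class = "boolean_rule")
}

#' @rdname boolean_rule
#' @param value Constant 0 or 1.
#' @export
const_rule <- function(target, value) {
  structure(list(target = target, type = "const", value = as.integer(value),
                 text = as.character(as.integer(value))),
            class = "boolean_rule")
}

# canonical BoolNet-style text for a rule; parseable by read_rules()
rule_text <- function(rule) {
  switch(rule$type,
    input = rule$target,
    const = as.character(rule$value),
    gate = {
      wrap <- function(x, op) {
        if (length(x) == 1) x else paste0("(", paste(x, collapse = op), ")")
      }
      op <- c(OR = " | ", AND = " & ")
      act <- if (length(rule$activators))
        wrap(rule$activators, op[[rule$act_comb]]) else NULL
      inh <- if (length(rule$inhibitors)) {
        if (length(rule$inhibitors) == 1) paste0("!", rule$inhibitors)
        else paste0("!(", paste(rule$inhibitors, collapse = op[[rule$inh_comb]]), ")")
      } else NULL
      paste(c(act, inh), collapse = " & ")
    },
    table = {
      ones <- which(rule$output == 1L)
      if (length(ones) == 0) return("0")
      if (length(ones) == 2^length(rule$regulators)) return("1")
      terms <- vapply(ones, function(i) {
        bits <- as.integer(bitwAnd(i - 1L, rule$bitw) > 0)
        lits <- ifelse(bits == 1L, rule$regulators,
                       paste0("!", rule$regulators))
        if (length(lits) == 1) lits else paste0("(", paste(lits, collapse = " & "), ")")
      }, character(1))
      paste(terms, collapse = " | ")
    })
}

rule_regulators <- function(rule) {
  switch(rule$type,
         gate = unique(c(rule$activators, rule$inhibitors)),
         table = rule$regulators,
         character())
}

# evaluate one rule on a named 0/1 state vector
eval_rule <- function(rule, state) {
  switch(rule$type,
    input = state[[rule$target]],
    const = rule$value,
    gate = {
      act <- if (length(rule$activators) == 0) TRUE else {
        v <- state[rule$activators] == 1
        if (rule$act_comb == "OR") any(v) else all(v)
      }
      inh <- if (length(rule$inhibitors) == 0) FALSE else {
        v <- state[rule$inhibitors] == 1
        if (rule$inh_comb == "OR") any(v) else all(v)
      }
      as.integer(act && !inh)
    },
    table = {
      idx <- if (length(rule$regulators) == 0) 1L
             else 1L + sum(state[rule$regulators] * rule$bitw)
      rule$output[idx]
    })
}

#' Assemble a Boolean model
#'
#' @param rules Named list of `boolean_rule` objects (names = node names; each
#'   rule's `target` must match its name). Nodes whose rule is of type
#'   `input` are the model's input nodes.
#' @return A `boolean_model` with elements `nodes`, `rules`, `inputs`.
#' @export
boolean_model <- function(rules) {
  stopifnot(length(rules) > 0)
  tg <- vapply(rules, function(r) r$target, character(1))
  if (is.null(names(rules))) names(rules) <- tg
  stopifnot(identical(unname(tg), names(rules)))
  nodes <- names(rules)
  regs <- unique(unlist(lapply(rules, rule_regulators)))
  missing <- setdiff(regs, nodes)
  if (length(missing)) {
    stop_ctx("rules reference undeclared node(s): %s",
             paste(missing, collapse = ", "))
  }
  inputs <- nodes[vapply(rules, function(r) r$type == "input", logical(1))]
  structure(list(nodes = nodes, rules = rules, inputs = inputs),
            class = "boolean_model")
}

#' @export
print.boolean_model <- function(x, ...) {
  cat(sprintf("boolean_model: %d nodes (%d inputs)\n",
              length(x$nodes), length(x$inputs)))
  for (r in x$rules) cat(sprintf("  %s, %s\n", r$target, r$text))
  invisible(x)
}

#' One synchronous update of a Boolean model
#'
#' @param model A `boolean_model`.
#' @param state Named 0/1 vector covering all nodes.
#' @return The next state (same names, model node order).
#' @export
update_state <- function(model, state) {
  state <- state[model$nodes]
  vapply(model$rules, eval_rule, integer(1), state = state)
}

apply_clamps <- function(model, clamps) {
  if (is.null(clamps) || length(clamps) == 0) return(model)
  stopifnot(all(names(clamps) %in% model$nodes))
  for (nm in names(clamps)) {
    model$rules[[nm]] <- const_rule(nm, clamps[[nm]])
  }
  model$inputs <- setdiff(model$inputs, names(clamps))
  model
}

state_key <- function(state) paste(state, collapse = "")

#' Run a Boolean model to its attractor
#'
#' Synchronous mode iterates the deterministic full-vector update with
#' trajectory hashing and returns the fixed point or limit cycle reached.
#' Asynchronous mode (`async_gillespie`) is a continuous-time single-node-flip
#' simulation: every unstable node (one whose rule output differs from its
#' current value) flips with unit rate; the node to flip is chosen uniformly
#' and the dwell time is exponential with rate = number of unstable nodes.
#' It returns the time-weighted empirical state distribution after burn-in,
#' plus the absorbing fixed point if one is reached.
#'
#' @param model A `boolean_model`.
#' @param initial Named 0/1 vector covering all nodes.
#' @param mode `"synchronous"` or `"async_gillespie"`.
#' @param clamps Optional named 0/1 vector; clamped nodes' rules are replaced
#'   by constants for the whole run (a knockout is `clamps = c(node = 0)`).
#' @param max_steps Maximum number of updates/flip events.
#' @param seed RNG seed (asynchronous mode only).
#' @param burn_in Events discarded before accumulating the distribution
#'   (asynchronous mode; default `max_steps %/% 5`).
#' @return An `attractor` object: list with `type` ("fixed", "cycle" or
#'   "distribution"), `state` (fixed point, if any), `states` (cycle matrix,
#'   one row per state), `period`, `steps`, `distribution` (data.frame of
#'   state keys and weights, async mode) and `mode`.
#' @export
steady_state <- function(model, initial, mode = c("synchronous", "async_gillespie"),
                         clamps = NULL, max_steps = 10000, seed = 1,
                         burn_in = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(model$nodes %in% names(initial)))
  model <- apply_clamps(model, clamps)
  state <- as.integer(initial[model$nodes])
  names(state) <- model$nodes
  if (!is.null(clamps)) state[names(clamps)] <- as.integer(clamps)

  if (mode == "synchronous") {
    seen <- new.env(hash = TRUE, parent = emptyenv())
    traj <- vector("list", 64)
    t <- 0L
    repeat {
      key <- state_key(state)
      prev <- seen[[key]]
      if (!is.null(prev)) {
        cyc <- traj[prev:t]
        period <- length(cyc)
        if (period == 1L) {
          return(structure(list(type = "fixed", state = cyc[[1]],
                                period = 1L, steps = t, mode = mode),
                           class = "attractor"))
        }
        states <- do.call(rbind, cyc)
        return(structure(list(type = "cycle", states = states,
                              period = period, steps = t, mode = mode),
                         class = "attractor"))
      }
      if (t >= max_steps) {
        stop_ctx("no attractor within max_steps = %d updates (check clamps)",
                 max_steps)
      }
      t <- t + 1L
      if (t > length(traj)) traj <- c(traj, vector("list", length(traj)))
      seen[[key]] <- t
      traj[[t]] <- state
      state <- update_state(model, state)
    }
  }

  # async_gillespie
  burn_in <- burn_in %||% (max_steps %/% 5L)
  local_seed(seed, {
    weights <- new.env(hash = TRUE, parent = emptyenv())
    reps <- new.env(hash = TRUE, parent = emptyenv())
    for (ev in seq_len(max_steps)) {
      nxt <- update_state(model, state)
      unstable <- which(nxt != state)
      if (length(unstable) == 0) {
        return(structure(list(type = "fixed", state = state, period = 1L,
                              steps = ev - 1L, mode = mode,
                              distribution = env_to_dist(weights)),
                         class = "attractor"))
      }
      dwell <- stats::rexp(1, rate = length(unstable))
      if (ev > burn_in) {
        key <- state_key(state)
        weights[[key]] <- (weights[[key]] %||% 0) + dwell
        if (is.null(reps[[key]])) reps[[key]] <- state
      }
      flip <- if (length(unstable) == 1) unstable else sample(unstable, 1)
      state[flip] <- nxt[flip]
    }
    d <- env_to_dist(weights)
    top <- reps[[d$state[which.max(d$weight)]]]
    structure(list(type = "distribution", state = top, distribution = d,
                   steps = max_steps, mode = mode),
              class = "attractor")
  })
}

env_to_dist <- function(weights) {
  keys <- ls(weights)
  if (length(keys) == 0) {
    return(data.frame(state = character(), weight = numeric()))
  }
  w <- vapply(keys, function(k) weights[[k]], numeric(1))
  d <- data.frame(state = keys, weight = w / sum(w),
                  stringsAsFactors = FALSE)
  d[order(-d$weight, d$state), , drop = FALSE]
}

#' @export
print.attractor <- function(x, ...) {
  cat(sprintf("attractor (%s, %s): ", x$mode, x$type))
  if (x$type == "fixed") cat(state_key(x$state), "\n")
  else if (x$type == "cycle") cat("period", x$period, "\n")
  else cat(nrow(x$distribution), "states visited\n")
  invisible(x)
}

# single representative state of an attractor: fixed point; the most-visited
# state of an async distribution; or (synchronous cycle, all states visited
# equally) the first state of the cycle in trajectory order, flagged upstream.
attractor_representative <- function(att) {
  if (att$type == "fixed") return(att$state)
  if (att$type == "cycle") {
    s <- att$states[1, ]
    names(s) <- colnames(att$states)
    return(s)
  }
  att$state
}

#' Similarity of steady states across cell-state initial conditions
#'
#' Runs the model to steady state from each profile and reports, for each
#' (start i, reference j) pair, the fraction of nodes whose steady value from
#' start i equals profile j's time-zero value. The matrix need not be
#' symmetric: basins can overlap asymmetrically.
#'
#' @param model A `boolean_model`.
#' @param profiles Named list of named 0/1 vectors (one per cell state).
#' @return Numeric matrix, rows = start profile, columns = reference profile,
#'   with attribute `"cycle_flagged"` naming starts that reached a limit
#'   cycle (similarity then uses the cycle's representative state).
#' @export
cross_state_similarity <- function(model, profiles) {
  stopifnot(length(profiles) >= 1, !is.null(names(profiles)))
  n <- length(model$nodes)
  flagged <- character()
  sim <- matrix(NA_real_, length(profiles), length(profiles),
                dimnames = list(names(profiles), names(profiles)))
  for (i in names(profiles)) {
    att <- steady_state(model, profiles[[i]])
    if (att$type != "fixed") flagged <- c(flagged, i)
    s <- attractor_representative(att)
    for (j in names(profiles)) {
      sim[i, j] <- 1 - hamming(s, profiles[[j]][model$nodes]) / n
    }
  }
  attr(sim, "cycle_flagged") <- flagged
  sim
}

#' Single in-silico knockout
#'
#' Clamps `ko_node` to 0 for the whole simulation (rule replaced by the
#' constant 0) and re-runs the model to steady state from the given baseline.
#'
#' @param model A `boolean_model`.
#' @param start_steady Named 0/1 baseline steady state; `ko_node` must be ON
#'   in it and must not already be clamped.
#' @param ko_node Node to force OFF.
#' @param clamps Optional additional clamps already in force.
#' @return The post-knockout `attractor`.
#' @export
knockout <- function(model, start_steady, ko_node, clamps = NULL) {
  stopifnot(ko_node %in% model$nodes)
  if (start_steady[[ko_node]] != 1) {
    stop_ctx("knockout of '%s' rejected: node is OFF in the starting steady state",
             ko_node)
  }
  if (!is.null(clamps) && ko_node %in% names(clamps)) {
    stop_ctx("knockout of '%s' rejected: node is already clamped", ko_node)
  }
  ko <- c(clamps, stats::setNames(0L, ko_node))
  steady_state(model, start_steady, clamps = ko)
}

#' Systematic knockout screen over all cell states
#'
#' For each cell-state profile, the model is first run to its baseline steady
#' state; every node ON in that steady state is then knocked out one
#' simulation at a time and the model re-run. Each post-knockout steady state
#' is compared to all reference steady states by Hamming distance and
#' similarity (1 - distance/n); per (start state, reference) column the
#' similarities are z-normalized across that start's knockouts, so a positive
#' z means the knockout shifted the network toward that reference state. Each
#' knockout is assigned the reference of maximal similarity, with ties broken
#' by profile order.
#'
#' @param model A `boolean_model` synthesized against `profiles`.
#' @param profiles Named list of named 0/1 vectors in the fixed state order.
#' @return A `ko_screen` object: `table` (one row per simulation with
#'   `start_state`, `ko_node`, `assigned` and per-reference `hamming_*`,
#'   `similarity_*`, `z_*` columns), `steady` (matrix of post-KO steady
#'   states, rows aligned with `table`), `references` (matrix of baseline
#'   steady states) and `nodes`.
#' @export
knockout_screen <- function(model, profiles) {
  stopifnot(length(profiles) >= 2, !is.null(names(profiles)))
  states <- names(profiles)
  n <- length(model$nodes)
  flagged <- character()

  base <- list()
  for (s in states) {
    att <- steady_state(model, profiles[[s]])
    if (att$type != "fixed") flagged <- c(flagged, s)
    base[[s]] <- attractor_representative(att)
  }
  refs <- do.call(rbind, base)

  rows <- list(); steadies <- list()
  for (s in states) {
    on_nodes <- model$nodes[base[[s]] == 1]
    for (ko in on_nodes) {
      att <- knockout(model, base[[s]], ko)
      if (att$type != "fixed") flagged <- c(flagged, paste(s, ko, sep = ":"))
      st <- attractor_representative(att)
      hd <- vapply(states, function(r) hamming(st, refs[r, ]), numeric(1))
      sim <- 1 - hd / n
      rows[[length(rows) + 1L]] <- data.frame(
        start_state = s, ko_node = ko,
        assigned = argmax_name(sim),
        t(stats::setNames(hd, paste0("hamming_", states))),
        t(stats::setNames(sim, paste0("similarity_", states))),
        stringsAsFactors = FALSE)
      steadies[[length(steadies) + 1L]] <- st
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  for (r in states) {
    z <- rep(NA_real_, nrow(tab))
    for (s in states) {
      idx <- tab$start_state == s
      v <- tab[[paste0("similarity_", r)]][idx]
      sdv <- stats::sd(v)
      z[idx] <- if (length(v) < 2 || is.na(sdv) || sdv == 0) 0 else (v - mean(v)) / sdv
    }
    tab[[paste0("z_", r)]] <- z
  }
  steady <- do.call(rbind, steadies)
  rownames(steady) <- paste(tab$start_state, tab$ko_node, sep = ":")
  structure(list(table = tab, steady = steady, references = refs,
                 nodes = model$nodes, states = states,
                 cycle_flagged = flagged),
            class = "ko_screen")
}

#' @export
print.ko_screen <- function(x, ...) {
  cat(sprintf("ko_screen: %d simulations over %d start states (%d nodes)\n",
              nrow(x$table), length(x$states), length(x$nodes)))
  invisible(x)
}
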