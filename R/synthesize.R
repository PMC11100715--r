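#' Synthesize Boolean rules whose fixed points match the cell-state profiles
#'
#' For every non-input node the synthesis problem is: find a sign-monotone
#' logic rule over the node's network regulators such that, for each
#' cell-state profile, evaluating the rule on the profile returns the node's
#' own profile value. A model in which every node satisfies this makes every
#' profile a synchronous fixed point, mirroring the requirement that the
#' steady state of the simulation fully match each phenotype.
#'
#' The search is deterministic: candidate gates of the form
#' `act_comb(activators) AND NOT inh_comb(inhibitors)` are tried in the fixed
#' order (OR,OR), (OR,AND), (AND,OR), (AND,AND) and the first gate satisfying
#' all profiles is kept. If no simple gate works, an exhaustive sign-monotone
#' truth-table search over the node's regulators is run (regulator count
#' capped at `max_regulators`): the unique monotone table with the minimal
#' number of 1-outputs satisfying all constraints is the up-closure, in the
#' signed partial order, of the patterns constrained to 1. If the constraints
#' are contradictory (the same regulator pattern demands both outputs, or a
#' 0-constraint dominates a 1-constraint in the signed order so no monotone
#' table exists), the node is reported infeasible and the simple gate
#' satisfying the most profiles is used (ties broken toward earlier profiles
#' in the fixed state order, then earlier gate order). Input nodes receive
#' identity rules and are held at their profile values.
#'
#' @param net A `signed_network` whose nodes the profiles cover. Nodes missing
#'   from a profile default to 0 (OFF) and are flagged in the report.
#' @param profiles Named list of named 0/1 vectors, in the fixed state order.
#' @param max_regulators Cap on regulator count for the truth-table fallback.
#' @return List with `model` (a `boolean_model`), and `report` (a
#'   data.frame: node, rule, n_satisfied, satisfied, feasible, method) plus
#'   `filled` — profile/node pairs that were defaulted to 0.
#' @export
synthesize_rules <- function(net, profiles, max_regulators = 10) {
  stopifnot(inherits(net, "signed_network"), length(profiles) >= 1,
            !is.null(names(profiles)))
  filled <- character()
  for (s in names(profiles)) {
    missing <- setdiff(net$nodes, names(profiles[[s]]))
    if (length(missing)) {
      filled <- c(filled, paste(s, missing, sep = ":"))
      profiles[[s]][missing] <- 0L
    }
    profiles[[s]] <- as.integer(profiles[[s]][net$nodes])
    names(profiles[[s]]) <- net$nodes
  }

  inputs <- input_nodes(net)
  rules <- list()
  rep_rows <- list()
  for (node in net$nodes) {
    if (node %in% inputs) {
      rules[[node]] <- input_rule(node)
      rep_rows[[node]] <- data.frame(
        node = node, rule = node, n_satisfied = length(profiles),
        satisfied = paste(names(profiles), collapse = ","),
        feasible = TRUE, method = "input", stringsAsFactors = FALSE)
      next
    }
    reg <- regulators_of(net, node)
    res <- synthesize_node(node, reg$activators, reg$inhibitors, profiles,
                           max_regulators)
    rules[[node]] <- res$rule
    rep_rows[[node]] <- res$report
  }
  report <- do.call(rbind, rep_rows)
  rownames(report) <- NULL
  list(model = boolean_model(rules), report = report, filled = filled)
}

# candidate simple gates in the deterministic enumeration order, with
# semantically redundant combinator choices collapsed (first occurrence kept)
candidate_gates <- function(node, activators, inhibitors) {
  combos <- list(c("OR", "OR"), c("OR", "AND"), c("AND", "OR"), c("AND", "AND"))
  gates <- list(); seen <- character()
  for (cb in combos) {
    g <- boolean_rule(node, activators, inhibitors, cb[1], cb[2])
    if (!(g$text %in% seen)) {
      seen <- c(seen, g$text)
      gates[[length(gates) + 1L]] <- g
    }
  }
  gates
}

synthesize_node <- function(node, activators, inhibitors, profiles,
                            max_regulators) {
  regs <- sort(unique(c(activators, inhibitors)))
  gates <- candidate_gates(node, activators, inhibitors)
  sat <- lapply(gates, function(g) {
    vapply(profiles, function(p) eval_rule(g, p) == p[[node]], logical(1))
  })
  n_sat <- vapply(sat, sum, numeric(1))
  full <- which(n_sat == length(profiles))
  if (length(full)) {
    g <- gates[[full[1]]]
    return(list(rule = g, report = data.frame(
      node = node, rule = g$text, n_satisfied = length(profiles),
      satisfied = paste(names(profiles), collapse = ","),
      feasible = TRUE, method = "gate", stringsAsFactors = FALSE)))
  }

  # truth-table fallback
  if (length(regs) <= max_regulators) {
    tt <- monotone_table(node, regs, activators, inhibitors, profiles)
    if (!is.null(tt)) {
      satisfied <- vapply(profiles, function(p) eval_rule(tt, p) == p[[node]],
                          logical(1))
      return(list(rule = tt, report = data.frame(
        node = node, rule = tt$text, n_satisfied = sum(satisfied),
        satisfied = paste(names(profiles)[satisfied], collapse = ","),
        feasible = TRUE, method = "table", stringsAsFactors = FALSE)))
    }
  } else {
    stop_ctx("node '%s' has %d regulators (cap %d) and no feasible simple gate",
             node, length(regs), max_regulators)
  }

  # contradictory constraints: best-effort gate
  best <- order(-n_sat,
                -vapply(sat, function(s) sum(s * rev(2^(seq_along(s) - 1))), numeric(1)))[1]
  g <- gates[[best]]
  list(rule = g, report = data.frame(
    node = node, rule = g$text, n_satisfied = n_sat[best],
    satisfied = paste(names(profiles)[sat[[best]]], collapse = ","),
    feasible = FALSE, method = "infeasible", stringsAsFactors = FALSE))
}

# minimal sign-monotone truth table satisfying the per-profile constraints,
# or NULL when the constraints are contradictory. Orientation per regulator:
# +1 pure activator, -1 pure inhibitor, 0 dual-sign (no monotonicity; the
# closure requires equality on that coordinate).
monotone_table <- function(node, regs, activators, inhibitors, profiles) {
  k <- length(regs)
  orient <- ifelse(regs %in% activators & regs %in% inhibitors, 0L,
                   ifelse(regs %in% activators, 1L, -1L))
  pats <- vapply(profiles, function(p) {
    as.integer(1 + sum(p[regs] * 2^(seq_len(k) - 1)))
  }, integer(1))
  outs <- vapply(profiles, function(p) p[[node]], integer(1))
  # same pattern demanding both outputs -> contradiction
  for (u in unique(pats)) {
    if (length(unique(outs[pats == u])) > 1) return(NULL)
  }
  bits <- function(i) as.integer(bitwAnd(i - 1L, 2^(seq_len(k) - 1)) > 0)
  dominates <- function(q, p) {  # q >= p in the signed order
    all((orient == 1L & q >= p) | (orient == -1L & q <= p) |
          (orient == 0L & q == p))
  }
  n_pat <- 2^k
  output <- integer(n_pat)
  ones <- unique(pats[outs == 1L])
  if (length(ones)) {
    one_bits <- lapply(ones, bits)
    for (i in seq_len(n_pat)) {
      b <- bits(i)
      if (any(vapply(one_bits, function(p) dominates(b, p), logical(1)))) {
        output[i] <- 1L
      }
    }
  }
  zeros <- unique(pats[outs == 0L])
  if (any(output[zeros] == 1L)) return(NULL)  # monotone-infeasible
  table_rule(node, regs, output)
}

#' Derive the signed dependency network of a Boolean model
#'
#' Edges are exactly the regulator-to-target dependencies of the rules, signed
#' by the direction of each regulator's monotone influence (a regulator with
#' both increasing and decreasing influence in a truth-table rule yields two
#' edges).
#'
#' @param model A `boolean_model`.
#' @param node_states Optional per-state annotations to attach.
#' @return A `signed_network`.
#' @export
network_from_model <- function(model, node_states = NULL) {
  edges <- list()
  add <- function(src, tgt, sign) {
    edges[[length(edges) + 1L]] <<- data.frame(
      source = src, target = tgt, sign = sign, stringsAsFactors = FALSE)
  }
  for (r in model$rules) {
    if (r$type == "gate") {
      for (a in r$activators) add(a, r$target, 1L)
      for (i in r$inhibitors) add(i, r$target, -1L)
    } else if (r$type == "table") {
      k <- length(r$regulators)
      for (j in seq_len(k)) {
        lo <- which(bitwAnd(seq_len(2^k) - 1L, 2^(j - 1)) == 0)
        hi <- lo + 2^(j - 1)
        inc <- any(r$output[hi] > r$output[lo])
        dec <- any(r$output[hi] < r$output[lo])
        if (inc) add(r$regulators[j], r$target, 1L)
        if (dec) add(r$regulators[j], r$target, -1L)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(source = character(), target = character(), sign = integer())
  signed_network(edges, nodes = model$nodes, node_states = node_states)
}
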