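#' Construct a signed, directed interaction network
#'
#' A signed network is the static scaffold of the Boolean model: nodes are
#' proteins, edges are directed activating (+1) or inhibiting (-1)
#' interactions, and optional per-state annotations record whether each node
#' is up (1) or down (0) in a given cell state.
#'
#' @param edges data.frame with columns `source`, `target`, `sign`
#'   (sign coerced to +1/-1). Duplicate identical triples are removed.
#' @param nodes Optional character vector of node names; defaults to the union
#'   of edge endpoints. Extra isolated nodes may be listed here.
#' @param node_states Optional named list: one named 0/1 vector per cell
#'   state giving node annotations.
#' @return An object of class `signed_network` with elements `nodes`,
#'   `edges` and `node_states`.
#' @export
signed_network <- function(edges, nodes = NULL, node_states = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0) {
    stopifnot(all(c("source", "target", "sign") %in% names(edges)))
    edges$source <- as.character(edges$source)
    edges$target <- as.character(edges$target)
    edges$sign <- as.integer(edges$sign)
    if (!all(edges$sign %in% c(-1L, 1L))) {
      stop_ctx("edge signs must be +1 or -1")
    }
    edges <- unique(edges[, c("source", "target", "sign")])
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(source = character(), target = character(),
                        sign = integer(), stringsAsFactors = FALSE)
  }
  nodes <- unique(c(as.character(nodes %||% character()),
                    edges$source, edges$target))
  structure(list(nodes = nodes, edges = edges, node_states = node_states),
            class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  cat(sprintf("signed_network: %d nodes, %d signed edges\n",
              length(x$nodes), nrow(x$edges)))
  if (!is.null(x$node_states)) {
    cat("  state annotations:", paste(names(x$node_states), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Merge cell-state networks into one integrated network
#'
#' The integrated protein-interaction network keeps every unique
#' (source, target, sign) interaction found in any of the per-state networks;
#' the same ordered pair may appear with both signs as two distinct edges.
#' Per-state node annotations of the inputs are carried along.
#'
#' @param nets List of `signed_network` objects (at least one).
#' @return A single merged `signed_network`.
#' @export
merge_networks <- function(nets) {
  if (inherits(nets, "signed_network")) nets <- list(nets)
  stopifnot(length(nets) >= 1)
  lapply(nets, function(n) stopifnot(inherits(n, "signed_network")))
  edges <- unique(do.call(rbind, lapply(nets, function(n) n$edges)))
  rownames(edges) <- NULL
  nodes <- unique(unlist(lapply(nets, function(n) n$nodes)))
  node_states <- do.call(c, lapply(nets, function(n) n$node_states))
  if (length(node_states) == 0) node_states <- NULL
  signed_network(edges, nodes = nodes, node_states = node_states)
}

# regulators of each node, split by sign; a dual-sign pair lands in both sets
regulators_of <- function(net, node) {
  e <- net$edges[net$edges$target == node, , drop = FALSE]
  list(activators = sort(unique(e$source[e$sign == 1L])),
       inhibitors = sort(unique(e$source[e$sign == -1L])))
}

input_nodes <- function(net) {
  setdiff(net$nodes, unique(net$edges$target))
}
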