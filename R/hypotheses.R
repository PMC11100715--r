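#' Mechanistic hypotheses for an observed cell-state transition
#'
#' Combines the three evidence streams for a paired primary/recurrent tumor:
#' (1) features whose booleanized state flipped between the pair AND whose
#' Shapley attribution toward the recurrent-state class increased; (2)
#' knockout-screen simulations that start from the primary predicted state,
#' are assigned to the recurrent predicted state, and whose post-knockout
#' steady state matches the recurrent value of at least one flipped feature;
#' (3) for each such knockout, all simple directed paths (up to
#' `max_path_len` edges) from the knocked-out node to the flipped feature in
#' the signed network, with the cumulative path sign. Hypotheses are ranked
#' by the number of flipped features they explain, then by shortest path.
#'
#' @param pair List with named 0/1 vectors `primary` and `recurrent`.
#' @param predictions Character vector of length 2: predicted states of the
#'   primary and recurrent member. If equal, the result is empty.
#' @param attributions Attribution table from [attribute()] covering both
#'   members (samples named "primary" and "recurrent").
#' @param screen A `ko_screen`.
#' @param net The merged `signed_network`.
#' @param max_path_len Maximum path length in edges (default 4).
#' @param delta_threshold Minimum increase of the recurrent-class attribution
#'   for a flipped feature to count (default 0).
#' @return A `transition_hypotheses` object: list with `from`, `to`,
#'   `flipped_features` and `candidates` (data.frame: ko_node, feature, path,
#'   path_sign, path_len, n_explained), ranked.
#' @export
transition_hypotheses <- function(pair, predictions, attributions, screen,
                                  net, max_path_len = 4,
                                  delta_threshold = 0) {
  stopifnot(length(predictions) == 2, inherits(screen, "ko_screen"),
            inherits(net, "signed_network"))
  from <- predictions[1]; to <- predictions[2]
  empty <- structure(list(from = from, to = to,
                          flipped_features = character(),
                          candidates = data.frame()),
                     class = "transition_hypotheses")
  if (from == to) return(empty)

  nodes <- intersect(names(pair$primary), names(pair$recurrent))
  flipped <- nodes[pair$primary[nodes] != pair$recurrent[nodes]]
  # attribution toward the recurrent class must have increased
  a_to <- attributions[attributions$class == to, , drop = FALSE]
  delta <- function(f) {
    pv <- a_to$value[a_to$sample == "primary" & a_to$feature == f]
    rv <- a_to$value[a_to$sample == "recurrent" & a_to$feature == f]
    if (length(pv) == 0 || length(rv) == 0) return(-Inf)
    rv - pv
  }
  flipped <- flipped[vapply(flipped, delta, numeric(1)) > delta_threshold]
  if (length(flipped) == 0) return(empty)

  cand_rows <- screen$table$start_state == from & screen$table$assigned == to
  if (!any(cand_rows)) {
    empty$flipped_features <- flipped
    return(empty)
  }
  g <- igraph::graph_from_data_frame(
    net$edges[, c("source", "target", "sign")], directed = TRUE,
    vertices = net$nodes)

  out <- list()
  for (ri in which(cand_rows)) {
    ko <- screen$table$ko_node[ri]
    steady <- screen$steady[ri, ]
    explained <- flipped[steady[flipped] == pair$recurrent[flipped]]
    if (length(explained) == 0) next
    for (f in explained) {
      if (!(ko %in% net$nodes) || !(f %in% net$nodes) || ko == f) next
      paths <- igraph::all_simple_paths(g, from = ko, to = f,
                                        mode = "out", cutoff = max_path_len)
      for (p in paths) {
        vp <- names(p)
        sg <- path_sign(net, vp)
        out[[length(out) + 1L]] <- data.frame(
          ko_node = ko, feature = f,
          path = paste(vp, collapse = " -> "),
          path_sign = sg, path_len = length(vp) - 1L,
          n_explained = length(explained), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    empty$flipped_features <- flipped
    return(empty)
  }
  candidates <- do.call(rbind, out)
  candidates <- candidates[order(-candidates$n_explained,
                                 candidates$path_len,
                                 candidates$ko_node, candidates$feature), ,
                           drop = FALSE]
  rownames(candidates) <- NULL
  structure(list(from = from, to = to, flipped_features = flipped,
                 candidates = candidates),
            class = "transition_hypotheses")
}

# cumulative sign along a node path; NA when an edge carries both signs
path_sign <- function(net, path_nodes) {
  sg <- 1L
  for (i in seq_len(length(path_nodes) - 1)) {
    e <- net$edges[net$edges$source == path_nodes[i] &
                     net$edges$target == path_nodes[i + 1], , drop = FALSE]
    s <- unique(e$sign)
    if (length(s) != 1) return(NA_integer_)
    sg <- sg * s
  }
  sg
}

#' @export
print.transition_hypotheses <- function(x, ...) {
  cat(sprintf("transition_hypotheses: %s -> %s; %d flipped feature(s), %d candidate path(s)\n",
              x$from, x$to, length(x$flipped_features), nrow(x$candidates)))
  if (nrow(x$candidates) > 0) print(utils::head(x$candidates, 10))
  invisible(x)
}
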