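#' Generate a ground-truth Boolean model with planted cell-state attractors
#'
#' Constructs a model whose fixed points are known by design, so every
#' downstream stage (rule synthesis, knockout screening, classification) can
#' be validated against planted truth. The construction plants a backbone of
#' `n_states` mutually inhibiting hub nodes — each hub's rule is
#' `NOT (OR of the other hubs)` — so each "own hub ON, others OFF"
#' configuration is self-consistent. Every downstream node draws its first
#' regulator from the hubs and any further regulators from strictly earlier
#' nodes (an acyclic downstream layer) with a random sign-consistent gate, so
#' each hub configuration extends deterministically to a full fixed point.
#'
#' @param n_nodes Total node count (must be at least `2 * n_states`).
#' @param n_states Number of planted cell states (at least 2).
#' @param seed Integer seed; identical seeds give identical ground truths.
#' @param states Optional state names; defaults to MES/AC/NPC/OPC order,
#'   extended as S5, S6, ... beyond four.
#' @param max_extra_regulators Extra non-hub regulators per downstream node.
#' @return A `ground_truth` object: `model`, `network` (derived from the
#'   rules), `profiles` (named list of planted fixed points), `seed`.
#' @export
generate_ground_truth_model <- function(n_nodes, n_states, seed,
                                        states = NULL,
                                        max_extra_regulators = 2) {
  if (n_states < 2) stop_ctx("n_states must be >= 2")
  if (n_nodes < 2 * n_states) {
    stop_ctx("infeasible sizes: n_nodes (%d) must be >= 2 * n_states (%d)",
             n_nodes, n_states)
  }
  states <- states %||% {
    base <- state_order()
    if (n_states <= 4) base[seq_len(n_states)]
    else c(base, paste0("S", 5:n_states))
  }
  stopifnot(length(states) == n_states)
  hubs <- paste0("hub_", states)
  extra <- if (n_nodes > n_states) {
    sprintf("g%02d", seq_len(n_nodes - n_states))
  } else character()
  nodes <- c(hubs, extra)

  local_seed(seed, {
    rules <- list()
    for (i in seq_len(n_states)) {
      rules[[hubs[i]]] <- boolean_rule(hubs[i], inhibitors = hubs[-i],
                                       inh_comb = "OR")
    }
    for (j in seq_along(extra)) {
      node <- extra[j]
      prior <- nodes[seq_len(n_states + j - 1)]
      first <- sample(hubs, 1)
      n_more <- sample(0:min(max_extra_regulators, length(prior) - 1), 1)
      more <- if (n_more > 0) sample(setdiff(prior, first), n_more) else character()
      regs <- c(first, more)
      sign <- sample(c(1L, -1L), length(regs), replace = TRUE)
      if (all(sign == -1L)) sign[1] <- 1L  # keep at least one activator
      rules[[node]] <- boolean_rule(
        node,
        activators = regs[sign == 1L], inhibitors = regs[sign == -1L],
        act_comb = sample(c("OR", "AND"), 1),
        inh_comb = sample(c("OR", "AND"), 1))
    }
    model <- boolean_model(rules)

    profiles <- list()
    for (i in seq_len(n_states)) {
      p <- stats::setNames(integer(length(nodes)), nodes)
      p[hubs[i]] <- 1L
      for (node in extra) p[node] <- eval_rule(rules[[node]], p)
      profiles[[states[i]]] <- p
    }
    for (s in states) {
      if (!identical(unname(update_state(model, profiles[[s]])),
                     unname(profiles[[s]]))) {
        stop_ctx("internal error: planted profile '%s' is not a fixed point", s)
      }
    }
    node_states <- profiles
    structure(list(model = model,
                   network = network_from_model(model, node_states),
                   profiles = profiles, states = states, seed = seed),
              class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d nodes, %d planted states (%s), seed %d\n",
              length(x$model$nodes), length(x$profiles),
              paste(x$states, collapse = ", "), x$seed))
  invisible(x)
}

#' Simulate a single-cell reference with state-specific module elevation
#'
#' Draws negative-binomial counts for `cells_per_type` cells of each cell
#' state. Genes in a state's module have their mean elevated `elevation`-fold
#' over baseline in cells of that state, emulating the marker structure that
#' hypergeometric cluster labeling relies on.
#'
#' @param profiles Named list of cell-state profiles (names define the
#'   states).
#' @param gene_modules Named list (state -> character vector of genes);
#'   modules must be pairwise disjoint and non-empty.
#' @param cells_per_type Cells simulated per state (>= 1).
#' @param depth Expected total counts per cell.
#' @param seed Integer seed.
#' @param elevation Fold-elevation of module genes in their own state
#'   (default 4, the minimum the generator guarantees).
#' @param dispersion Negative-binomial size parameter (default 2).
#' @param n_background Baseline genes shared by all states.
#' @return List with `counts` (gene-by-cell integer matrix), `labels`
#'   (per-cell state), `gene_modules`, `seed`.
#' @export
generate_sc_reference <- function(profiles, gene_modules, cells_per_type,
                                  depth = 1e5, seed = 1, elevation = 4,
                                  dispersion = 2, n_background = 100) {
  states <- names(profiles)
  stopifnot(!is.null(states), cells_per_type >= 1)
  stopifnot(setequal(names(gene_modules), states))
  if (any(lengths(gene_modules) == 0)) stop_ctx("empty gene module")
  all_mod <- unlist(gene_modules, use.names = FALSE)
  if (anyDuplicated(all_mod)) stop_ctx("gene modules must be pairwise disjoint")
  genes <- c(all_mod,
             if (n_background > 0) sprintf("bg%04d", seq_len(n_background)))

  local_seed(seed, {
    n_cells <- cells_per_type * length(states)
    labels <- rep(states, each = cells_per_type)
    counts <- matrix(0L, length(genes), n_cells,
                     dimnames = list(genes, sprintf("cell%04d", seq_len(n_cells))))
    for (ci in seq_len(n_cells)) {
      w <- stats::setNames(rep(1, length(genes)), genes)
      w[gene_modules[[labels[ci]]]] <- elevation
      mu <- w / sum(w) * depth
      counts[, ci] <- stats::rnbinom(length(genes), mu = mu, size = dispersion)
    }
    list(counts = counts, labels = labels, gene_modules = gene_modules,
         seed = seed)
  })
}

#' Simulate bulk mixtures with known cell-state proportions
#'
#' The expected expression of each sample is the reference profile matrix
#' times its proportion vector, rescaled to the target depth. With
#' `noise = "none"` the expectation is returned rounded to integers; with
#' `noise = "negbin"` counts are drawn negative-binomial around it.
#'
#' @param reference_means Nonnegative gene-by-state matrix.
#' @param proportions Sample-by-state matrix; every row must lie on the
#'   simplex (nonnegative, summing to 1 within 1e-9).
#' @param depth Target total counts per sample.
#' @param noise `"none"` or `"negbin"`.
#' @param seed Integer seed.
#' @param dispersion Negative-binomial size parameter (default 20, i.e. a
#'   biological-replicate dispersion of 0.05 — bulk tissue averages over
#'   millions of cells and is far less overdispersed than single cells).
#' @return Gene-by-sample count matrix; `attr(,"true_proportions")` carries
#'   the proportions used.
#' @export
generate_bulk_mixtures <- function(reference_means, proportions, depth = 1e6,
                                   noise = c("none", "negbin"), seed = 1,
                                   dispersion = 20) {
  noise <- match.arg(noise)
  reference_means <- as.matrix(reference_means)
  proportions <- as.matrix(proportions)
  if (any(reference_means < 0)) stop_ctx("negative reference means rejected")
  stopifnot(ncol(reference_means) == ncol(proportions))
  if (any(proportions < 0) || any(abs(rowSums(proportions) - 1) > 1e-9)) {
    stop_ctx("each proportions row must lie on the simplex")
  }
  expected <- reference_means %*% t(proportions)  # genes x samples
  expected <- sweep(expected, 2, colSums(expected), "/") * depth
  if (is.null(colnames(expected))) {
    colnames(expected) <- sprintf("sample%03d", seq_len(ncol(expected)))
  }
  out <- if (noise == "none") round(expected) else {
    local_seed(seed, {
      matrix(stats::rnbinom(length(expected), mu = expected, size = dispersion),
             nrow(expected), ncol(expected), dimnames = dimnames(expected))
    })
  }
  attr(out, "true_proportions") <- proportions
  out
}

#' Simulate per-gene statistics with planted regulator activities
#'
#' Each gene's statistic is the sum, over all regulons containing it, of the
#' mode-of-regulation weight times the planted activity of the regulator,
#' plus Gaussian noise — the additive signal model under which the WMEAN
#' footprint score is an unbiased estimator of planted activity.
#'
#' @param regulons data.frame with columns `source`, `target`, `mor` (and
#'   optionally `confidence`).
#' @param planted_activity Named numeric vector (regulator -> activity);
#'   every named regulator must have at least one target in `regulons`.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @param genes Optional gene universe; defaults to all regulon targets.
#' @return Named numeric vector of per-gene statistics.
#' @export
generate_activity_stats <- function(regulons, planted_activity, noise_sd,
                                    seed = 1, genes = NULL) {
  stopifnot(noise_sd >= 0)
  regulons <- as.data.frame(regulons)
  missing <- setdiff(names(planted_activity), regulons$source)
  if (length(missing)) {
    stop_ctx("regulator(s) without targets rejected: %s",
             paste(missing, collapse = ", "))
  }
  genes <- genes %||% sort(unique(regulons$target))
  stat <- stats::setNames(numeric(length(genes)), genes)
  act <- regulons$source %in% names(planted_activity)
  if (any(act)) {
    r <- regulons[act, , drop = FALSE]
    contrib <- r$mor * planted_activity[r$source]
    agg <- tapply(contrib, r$target, sum)
    stat[names(agg)] <- stat[names(agg)] + as.numeric(agg)
  }
  local_seed(seed, stat + stats::rnorm(length(stat), 0, noise_sd))
}

#' Simulate a paired primary/recurrent booleanized activity profile
#'
#' Each member of the pair equals the named cell-state profile with
#' independent per-node bit flips at `flip_rate`, emulating the noisy
#' booleanized activity vectors derived from paired clinical tumors.
#'
#' @param profiles Named list of cell-state profiles.
#' @param primary_state,recurrent_state Names of the planted states.
#' @param flip_rate Per-node flip probability in `[0, 0.5)`.
#' @param seed Integer seed.
#' @return List with `primary` and `recurrent` named 0/1 vectors and the
#'   planted state names.
#' @export
generate_patient_pair <- function(profiles, primary_state, recurrent_state,
                                  flip_rate, seed = 1) {
  stopifnot(flip_rate >= 0, flip_rate < 0.5)
  for (s in c(primary_state, recurrent_state)) {
    if (!s %in% names(profiles)) stop_ctx("unknown state name '%s'", s)
  }
  local_seed(seed, {
    flip <- function(p) {
      f <- stats::runif(length(p)) < flip_rate
      out <- ifelse(f, 1L - p, p)
      stats::setNames(as.integer(out), names(p))
    }
    list(primary = flip(profiles[[primary_state]]),
         recurrent = flip(profiles[[recurrent_state]]),
         primary_state = primary_state, recurrent_state = recurrent_state,
         seed = seed)
  })
}
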