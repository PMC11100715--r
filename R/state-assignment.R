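#' Marker genes per cluster by one-vs-rest Wilcoxon rank-sum test
#'
#' For each cluster, every gene is tested for upregulation against all other
#' cells (rank-sum, one-sided) and p-values are Benjamini-Hochberg adjusted
#' within the cluster; genes with adjusted p below `alpha` are that cluster's
#' markers.
#'
#' @param expr Gene-by-cell expression matrix (counts or normalized).
#' @param cluster_labels Per-cell cluster identifier.
#' @param alpha Adjusted-p threshold in (0, 1); default 0.05.
#' @return Named list (cluster -> character vector of marker genes). Clusters
#'   with fewer than 3 cells are skipped with a warning.
#' @export
cluster_markers <- function(expr, cluster_labels, alpha = 0.05) {
  expr <- as.matrix(expr)
  stopifnot(ncol(expr) == length(cluster_labels), alpha > 0, alpha < 1)
  clusters <- unique(as.character(cluster_labels))
  if (length(clusters) < 2) stop_ctx("need at least 2 clusters")
  out <- list()
  for (cl in clusters) {
    idx <- cluster_labels == cl
    if (sum(idx) < 3) {
      warn_ctx("cluster '%s' has fewer than 3 cells; skipped", cl)
      next
    }
    p <- apply(expr, 1, function(g) {
      if (all(g[idx] == g[idx][1]) && all(g[!idx] == g[idx][1])) return(1)
      stats::wilcox.test(g[idx], g[!idx], alternative = "greater",
                         exact = FALSE)$p.value
    })
    padj <- stats::p.adjust(p, method = "BH")
    out[[cl]] <- rownames(expr)[!is.na(padj) & padj < alpha]
  }
  out
}

#' Label clusters by hypergeometric gene-module enrichment
#'
#' Tests each cluster's marker set for overrepresentation of each gene module
#' with the upper-tail hypergeometric probability `P(X >= k)`, where `k` is
#' the marker/module overlap, drawing `|markers|` genes from a universe
#' containing `|module|` successes. Each cluster is labeled with the most
#' overrepresented module (largest -log10 p; ties broken by module order).
#'
#' @param marker_sets Named list (cluster -> marker genes).
#' @param module_sets Named list (module -> module genes).
#' @param universe Character vector of all genes; marker and module sets must
#'   be subsets of it.
#' @return data.frame with one row per cluster: `cluster`, `label`, and one
#'   `neglogp_<module>` column per module.
#' @export
label_clusters_hypergeometric <- function(marker_sets, module_sets, universe) {
  if (length(universe) == 0) stop_ctx("empty universe rejected")
  stopifnot(length(module_sets) >= 1)
  universe <- unique(universe)
  for (m in names(module_sets)) {
    if (!all(module_sets[[m]] %in% universe)) {
      stop_ctx("module '%s' not contained in universe", m)
    }
  }
  rows <- lapply(names(marker_sets), function(cl) {
    markers <- intersect(marker_sets[[cl]], universe)
    if (!all(marker_sets[[cl]] %in% universe)) {
      stop_ctx("marker set '%s' not contained in universe", cl)
    }
    nlp <- vapply(module_sets, function(mod) {
      k <- length(intersect(markers, mod))
      p <- stats::phyper(k - 1, length(mod), length(universe) - length(mod),
                         length(markers), lower.tail = FALSE)
      -log10(p)
    }, numeric(1))
    df <- data.frame(cluster = cl, label = argmax_name(nlp),
                     stringsAsFactors = FALSE)
    for (m in names(nlp)) df[[paste0("neglogp_", m)]] <- nlp[[m]]
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reference-based bulk deconvolution onto cell-state proportions
#'
#' Bisque-style chain: (1) CPM-normalize single cells and bulk; (2) build the
#' reference matrix as the mean CPM per cell state; (3) when overlap
#' individuals (profiled by both assays) are given, compute their single-cell
#' pseudobulk (mean CPM over the individual's cells) and fit a per-gene
#' ordinary least squares of pseudobulk on observed bulk, whose slope
#' (clipped to be nonnegative) and intercept transform all bulk samples onto
#' the single-cell scale; with no overlap the transform is the identity;
#' (4) solve a nonnegative least squares per sample against the reference;
#' (5) clip negatives and renormalize onto the simplex.
#'
#' @param bulk Gene-by-sample count matrix.
#' @param sc_counts Gene-by-cell count matrix.
#' @param cell_type_labels Per-cell state name.
#' @param overlap_ids Sample names present in both assays (may be NULL).
#' @param cell_individuals Per-cell individual id, required when
#'   `overlap_ids` is nonempty.
#' @param states Optional state order for the output columns.
#' @return data.frame: `sample`, one proportion column per state, `dominant`.
#' @export
deconvolve <- function(bulk, sc_counts, cell_type_labels, overlap_ids = NULL,
                       cell_individuals = NULL, states = NULL) {
  bulk <- as.matrix(bulk); sc_counts <- as.matrix(sc_counts)
  stopifnot(ncol(sc_counts) == length(cell_type_labels))
  states <- states %||% unique(as.character(cell_type_labels))
  if (length(states) < 2) stop_ctx("need at least 2 cell states")
  genes <- intersect(rownames(bulk), rownames(sc_counts))
  if (length(genes) < 1) stop_ctx("no shared genes between bulk and reference")
  bulk_cpm <- cpm(bulk[genes, , drop = FALSE])
  sc_cpm <- cpm(sc_counts[genes, , drop = FALSE])

  ref <- vapply(states, function(s) {
    cells <- cell_type_labels == s
    if (!any(cells)) stop_ctx("state '%s' has no cells in the reference", s)
    rowMeans(sc_cpm[, cells, drop = FALSE])
  }, numeric(length(genes)))
  if (any(colSums(ref) == 0)) stop_ctx("reference has an all-zero state column")

  trans <- bulk_cpm
  if (!is.null(overlap_ids) && length(overlap_ids) > 0) {
    if (is.null(cell_individuals)) {
      stop_ctx("cell_individuals required when overlap_ids are given")
    }
    stopifnot(all(overlap_ids %in% colnames(bulk_cpm)),
              all(overlap_ids %in% cell_individuals))
    pseudo <- vapply(overlap_ids, function(id) {
      rowMeans(sc_cpm[, cell_individuals == id, drop = FALSE])
    }, numeric(length(genes)))
    obs <- bulk_cpm[, overlap_ids, drop = FALSE]
    for (g in seq_along(genes)) {
      x <- obs[g, ]; y <- pseudo[g, ]
      if (stats::var(x) == 0) next  # identity fallback for flat genes
      fit <- stats::lm.fit(cbind(1, x), y)$coefficients
      slope <- max(fit[2], 0)
      trans[g, ] <- fit[1] + slope * bulk_cpm[g, ]
    }
  }

  props <- t(apply(trans, 2, function(b) {
    p <- pracma::lsqnonneg(ref, b)$x
    p[p < 0] <- 0
    if (sum(p) > 0) p / sum(p) else rep(1 / length(p), length(p))
  }))
  colnames(props) <- states
  out <- data.frame(sample = colnames(bulk), props, stringsAsFactors = FALSE,
                    row.names = NULL, check.names = FALSE)
  out$dominant <- apply(props, 1, function(p)
    assign_dominant_state(stats::setNames(p, states)))
  out
}

#' Dominant malignant cell state of a proportion vector
#'
#' Argmax over the four malignant states only (healthy cell types present in
#' the proportions are ignored), with ties broken by the fixed state order.
#'
#' @param proportions Named numeric vector of proportions.
#' @param states Candidate states in tie-break order; defaults to the
#'   malignant states found in `proportions`, ordered per [state_order()].
#' @return The dominant state name.
#' @export
assign_dominant_state <- function(proportions, states = NULL) {
  if (is.null(names(proportions)) && !is.null(states)) {
    names(proportions) <- states
  }
  if (is.null(states)) {
    states <- intersect(state_order(), names(proportions))
    if (length(states) == 0) states <- names(proportions)
  }
  states <- states[states %in% names(proportions)]
  if (length(states) == 0) stop_ctx("no candidate states in proportions")
  p <- proportions[states]
  if (all(p == 0)) stop_ctx("all-zero proportions rejected")
  argmax_name(p)
}
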