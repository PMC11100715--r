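#' Per-sample log2 fold change against a healthy reference
#'
#' Computes `log2((CPM_sample + pseudocount) / (mean healthy CPM +
#' pseudocount))` per gene; the pseudocount keeps dropout genes finite.
#'
#' @param sample_expr Named vector of gene counts for one sample.
#' @param healthy_ref Gene-by-sample count matrix of healthy tissue.
#' @param pseudocount Positive pseudocount (default 1).
#' @return Named per-gene log2 fold-change vector over the shared genes.
#' @export
sample_logfc <- function(sample_expr, healthy_ref, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  healthy_ref <- as.matrix(healthy_ref)
  if (ncol(healthy_ref) == 0) stop_ctx("empty healthy reference rejected")
  genes <- intersect(names(sample_expr), rownames(healthy_ref))
  if (length(genes) == 0) stop_ctx("no shared genes with healthy reference")
  s_cpm <- sample_expr[genes] / sum(sample_expr[genes]) * 1e6
  h_cpm <- rowMeans(cpm(healthy_ref[genes, , drop = FALSE]))
  log2((s_cpm + pseudocount) / (h_cpm + pseudocount))
}

#' Filter a regulon table to usable interactions
#'
#' Keeps confidence grades A-C (when a confidence column is present) and
#' drops duplicated (source, target) pairs.
#'
#' @param regulons data.frame with columns `source`, `target`, `mor` and
#'   optionally `confidence`.
#' @param confidence Grades to retain.
#' @return Filtered regulon data.frame.
#' @export
filter_regulons <- function(regulons, confidence = c("A", "B", "C")) {
  regulons <- as.data.frame(regulons)
  stopifnot(all(c("source", "target", "mor") %in% names(regulons)))
  if ("confidence" %in% names(regulons)) {
    regulons <- regulons[regulons$confidence %in% confidence, , drop = FALSE]
  }
  regulons[!duplicated(regulons[, c("source", "target")]), , drop = FALSE]
}

#' Footprint activity scores by weighted mean with a permutation null
#'
#' The raw WMEAN score of a regulator is the weighted mean of its measured
#' targets' statistics, `sum(w * x) / sum(|w|)`, with mode-of-regulation
#' weights `w`. The null distribution is obtained by permuting the gene
#' labels of the statistic vector `n_perm` times; the reported activity is
#' the z-score of the raw score against that null.
#'
#' @param stats_vec Named per-gene statistic vector (e.g. log2 fold changes
#'   or differential test statistics).
#' @param regulons Regulon data.frame (`source`, `target`, `mor`).
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param min_targets Minimum measured targets per regulator (default 5);
#'   regulators below it are dropped with a message.
#' @param seed Integer seed for the permutations.
#' @return data.frame: `source`, `score` (permutation z), `raw`, `n_targets`,
#'   `flag` ("" or "zero_sd" when the null is degenerate and the score is set
#'   to 0).
#' @export
wmean_activity <- function(stats_vec, regulons, n_perm = 1000,
                           min_targets = 5, seed = 1) {
  stopifnot(n_perm >= 100, min_targets >= 2, !is.null(names(stats_vec)))
  regulons <- as.data.frame(regulons)
  genes <- names(stats_vec)
  reg <- regulons[regulons$target %in% genes, , drop = FALSE]
  n_tgt <- table(reg$source)
  drop <- names(n_tgt)[n_tgt < min_targets]
  if (length(drop)) {
    message(sprintf("wmean_activity: dropping %d regulator(s) with < %d measured targets: %s",
                    length(drop), min_targets, paste(drop, collapse = ", ")))
    reg <- reg[!reg$source %in% drop, , drop = FALSE]
  }
  sources <- sort(unique(reg$source))
  if (length(sources) == 0) {
    return(data.frame(source = character(), score = numeric(),
                      raw = numeric(), n_targets = integer(),
                      flag = character(), stringsAsFactors = FALSE))
  }
  W <- matrix(0, length(sources), length(genes),
              dimnames = list(sources, genes))
  W[cbind(match(reg$source, sources), match(reg$target, genes))] <- reg$mor
  denom <- rowSums(abs(W))
  raw <- as.numeric(W %*% stats_vec) / denom

  null_scores <- local_seed(seed, {
    P <- vapply(seq_len(n_perm), function(i) stats_vec[sample.int(length(genes))],
                numeric(length(genes)))
    (W %*% P) / denom
  })
  mu <- rowMeans(null_scores)
  sdv <- apply(null_scores, 1, stats::sd)
  flag <- ifelse(sdv == 0, "zero_sd", "")
  if (any(sdv == 0)) {
    warn_ctx("degenerate permutation null (sd = 0) for: %s",
             paste(sources[sdv == 0], collapse = ", "))
  }
  score <- ifelse(sdv == 0, 0, (raw - mu) / ifelse(sdv == 0, 1, sdv))
  data.frame(source = sources, score = score, raw = raw,
             n_targets = as.integer(n_tgt[sources]), flag = flag,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Impute phospho-level activities from RNA-level activities
#'
#' For cohorts without phosphoproteomics, a regulator's phospho activity is
#' imputed from its RNA activity via the ratio observed in a reference cohort
#' profiled with both assays: `phos = rna * ref_phos / ref_rna`. Reference
#' denominators smaller than `epsilon` in magnitude are replaced by a
#' sign-preserving `epsilon`; regulators missing a reference value pass
#' through unchanged and are flagged.
#'
#' @param rna_act Named numeric vector of RNA-level activity scores.
#' @param ref_rna_act,ref_phos_act Named reference activities (regulator ->
#'   score) from the dual-assay cohort.
#' @param epsilon Positive denominator floor (default 1e-6).
#' @param invert Use the inverse reference ratio instead (config option for
#'   the opposite reading of the ratio rule).
#' @return Named numeric vector of imputed scores with attribute
#'   `"flags"` (named character: "missing_reference" or "epsilon_denominator").
#' @export
impute_phospho_activity <- function(rna_act, ref_rna_act, ref_phos_act,
                                    epsilon = 1e-6, invert = FALSE) {
  stopifnot(epsilon > 0)
  out <- rna_act
  flags <- stats::setNames(character(length(rna_act)), names(rna_act))
  for (r in names(rna_act)) {
    if (!(r %in% names(ref_rna_act)) || !(r %in% names(ref_phos_act))) {
      flags[r] <- "missing_reference"
      next
    }
    num <- if (invert) ref_rna_act[[r]] else ref_phos_act[[r]]
    den <- if (invert) ref_phos_act[[r]] else ref_rna_act[[r]]
    if (abs(den) < epsilon) {
      den <- if (den < 0) -epsilon else epsilon
      flags[r] <- "epsilon_denominator"
    }
    out[[r]] <- rna_act[[r]] * num / den
  }
  flags <- flags[flags != ""]
  if (length(flags)) attr(out, "flags") <- flags
  out
}

#' Booleanize activity scores
#'
#' Positive activity maps to 1, negative (and exactly zero) activity to 0 —
#' the convention used to match simulation states to clinical activity
#' profiles.
#'
#' @param scores Named numeric vector of activity scores.
#' @return Named integer 0/1 vector.
#' @export
booleanize <- function(scores) {
  stats::setNames(as.integer(scores > 0), names(scores))
}
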