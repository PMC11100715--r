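#' Canonical malignant cell-state order
#'
#' Fixed tie-break order used everywhere a deterministic choice among the four
#' malignant glioblastoma cell states is needed: mesenchymal-like (MES),
#' astrocyte-like (AC), neural-progenitor-like (NPC) and
#' oligodendrocyte-progenitor-like (OPC).
#'
#' @return Character vector of the four state names in fixed order.
#' @export
state_order <- function() c("MES", "AC", "NPC", "OPC")

#' Counts-per-million normalization
#'
#' @param counts Numeric matrix, genes in rows, samples/cells in columns.
#' @return Matrix of the same shape with each column scaled to sum to 1e6.
#'   All-zero columns are left at zero.
#' @export
cpm <- function(counts) {
  counts <- as.matrix(counts)
  libsize <- colSums(counts)
  libsize[libsize == 0] <- 1
  sweep(counts, 2, libsize, "/") * 1e6
}

# Run expr with a locally seeded RNG, restoring global state afterwards.
local_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# argmax with deterministic tie-break by the order of `names(x)`
argmax_name <- function(x) {
  names(x)[which.max(x)]
}

hamming <- function(a, b) {
  stopifnot(length(a) == length(b))
  sum(a != b)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ctx <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_ctx <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
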