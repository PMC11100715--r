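#' Read a signed network from a SIF-like TSV file
#'
#' Expected format: three tab-separated columns `source`, `sign`, `target`
#' (an optional header line is detected and skipped). Recognized sign tokens:
#' `+1`, `1`, `+`, `activate`, and `-1`, `−1`, `-`, `inhibit`.
#' Duplicate identical triples are dropped with a message; an unknown sign
#' token is an error naming the offending line.
#'
#' @param path File path.
#' @return A `signed_network`.
#' @export
read_signed_network <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(signed_network(data.frame(source = character(), target = character(),
                                     sign = integer())))
  }
  first <- tolower(strsplit(lines[1], "\t", fixed = TRUE)[[1]])
  start <- if (identical(first, c("source", "sign", "target"))) 2L else 1L
  sign_map <- c("+1" = 1L, "1" = 1L, "+" = 1L, "activate" = 1L,
                "-1" = -1L, "−1" = -1L, "-" = -1L, "inhibit" = -1L)
  rows <- list()
  for (i in seq(start, length(lines))) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 3) stop_ctx("%s line %d: expected 3 tab-separated fields",
                                 path, i)
    tok <- trimws(f[2])
    if (!tok %in% names(sign_map)) {
      stop_ctx("%s line %d: unknown sign token '%s'", path, i, tok)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      source = trimws(f[1]), target = trimws(f[3]),
      sign = sign_map[[tok]], stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, rows)
  n_dup <- nrow(edges) - nrow(unique(edges))
  if (n_dup > 0) message(sprintf("read_signed_network: %d duplicate edge(s) removed", n_dup))
  signed_network(edges)
}

#' @rdname read_signed_network
#' @param net A `signed_network` to write.
#' @export
write_signed_network <- function(net, path) {
  e <- net$edges[order(net$edges$source, net$edges$target, net$edges$sign), ,
                 drop = FALSE]
  lines <- c("source\tsign\ttarget",
             sprintf("%s\t%+d\t%s", e$source, e$sign, e$target))
  writeLines(lines, path)
  invisible(path)
}

# tokenizer for BoolNet-style rule expressions
tokenize_expr <- function(expr, where) {
  pat <- "[A-Za-z_.][A-Za-z0-9_.]*|[01]|!|&|\\||\\(|\\)"
  toks <- regmatches(expr, gregexpr(pat, expr))[[1]]
  residue <- gsub(pat, "", expr)
  residue <- gsub("[[:space:]]", "", residue)
  if (nzchar(residue)) {
    stop_ctx("%s: unparseable characters '%s' in expression '%s'",
             where, residue, expr)
  }
  toks
}

# spaces around binary operators, none after '!' or just inside parentheses
normalize_expr <- function(toks) {
  s <- paste(toks, collapse = " ")
  s <- gsub("( ", "(", s, fixed = TRUE)
  s <- gsub(" )", ")", s, fixed = TRUE)
  gsub("! ", "!", s, fixed = TRUE)
}

#' Read and write Boolean rule files (BoolNet dialect)
#'
#' One rule per line, `target, factor-expression`, with operators `!`, `&`,
#' `|`, parentheses and the constants 0/1, after a `targets, factors` header.
#' A rule whose expression is the target itself is an input (identity) node.
#' Reading then writing preserves rule text; writing then reading preserves
#' evaluated truth tables.
#'
#' @param path File path.
#' @param max_regulators Cap on regulator count per parsed rule.
#' @return `read_rules()`: a `boolean_model`.
#' @export
read_rules <- function(path, max_regulators = 16) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  idx <- which(keep)
  if (length(idx) == 0) stop_ctx("%s: no rules found", path)
  first <- tolower(gsub("[[:space:]]", "", lines[idx[1]]))
  if (first == "targets,factors") idx <- idx[-1]
  rules <- list()
  for (i in idx) {
    parts <- regmatches(lines[i], regexpr(",", lines[i]), invert = TRUE)[[1]]
    if (length(parts) != 2) {
      stop_ctx("%s line %d: expected 'target, expression'", path, i)
    }
    target <- trimws(parts[1])
    toks <- tokenize_expr(trimws(parts[2]), sprintf("%s line %d", path, i))
    if (length(toks) == 0) stop_ctx("%s line %d: empty expression", path, i)
    text <- normalize_expr(toks)
    regs <- unique(toks[grepl("^[A-Za-z_.]", toks)])
    rule <- if (identical(toks, target)) {
      input_rule(target)
    } else if (length(regs) == 0) {
      const_rule(target, as.integer(text == "1"))
    } else {
      if (length(regs) > max_regulators) {
        stop_ctx("%s line %d: rule for '%s' has %d regulators (cap %d)",
                 path, i, target, length(regs), max_regulators)
      }
      parsed <- tryCatch(parse(text = text)[[1]],
                         error = function(e) stop_ctx(
                           "%s line %d: cannot parse expression '%s'",
                           path, i, text))
      k <- length(regs)
      output <- integer(2^k)
      for (pat in seq_len(2^k)) {
        env <- as.list(stats::setNames(
          as.logical(bitwAnd(pat - 1L, 2^(seq_len(k) - 1)) > 0), regs))
        output[pat] <- as.integer(as.logical(eval(parsed, envir = env)))
      }
      tr <- table_rule(target, regs, output)
      tr$text <- text  # preserve the file's (normalized) rule text
      tr
    }
    if (target %in% names(rules)) {
      stop_ctx("%s line %d: duplicate rule for '%s'", path, i, target)
    }
    rules[[target]] <- rule
  }
  boolean_model(rules)
}

#' @rdname read_rules
#' @param model A `boolean_model` to write.
#' @export
write_rules <- function(model, path) {
  lines <- c("targets, factors",
             vapply(model$rules, function(r) sprintf("%s, %s", r$target, r$text),
                    character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write GMT gene-set files
#'
#' @param path File path.
#' @return `read_gmt()`: named list of gene vectors (descriptions dropped).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop_ctx("%s line %d: GMT needs name, description, >=1 gene",
                                path, i)
    out[[f[1]]] <- f[-(1:2)]
  }
  out
}

#' @rdname read_gmt
#' @param sets Named list of gene vectors to write.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write gene-by-sample TSV matrices
#'
#' Genes in rows (first column), sample/cell ids in the header.
#'
#' @param path File path.
#' @return `read_matrix_tsv()`: numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_ctx("%s: expected gene column plus >=1 sample", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop_ctx("%s: non-numeric matrix entries", path)
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_matrix_tsv
#' @param m Matrix to write; `id_col` names the gene column.
#' @param id_col Header of the first (gene id) column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sparse count matrix stored as MTX triplet with name sidecars
#'
#' @param mtx_path MatrixMarket file; `rows_path`/`cols_path` are plain-text
#'   files with one row (gene) / column (cell) name per line.
#' @param rows_path,cols_path Sidecar file paths.
#' @return Dense numeric matrix with dimnames.
#' @export
read_mtx_triplet <- function(mtx_path, rows_path, cols_path) {
  m <- as.matrix(Matrix::readMM(mtx_path))
  rn <- readLines(rows_path); cn <- readLines(cols_path)
  if (nrow(m) != length(rn) || ncol(m) != length(cn)) {
    stop_ctx("MTX dimensions (%d x %d) do not match sidecars (%d x %d)",
             nrow(m), ncol(m), length(rn), length(cn))
  }
  dimnames(m) <- list(rn, cn)
  m
}

#' Write a knockout screen as TSV (wide and heatmap-ready long format)
#'
#' @param screen A `ko_screen`.
#' @param path Output TSV path for the wide table.
#' @param long_path Optional path for the long-format export
#'   (start_state, ko_node, reference, hamming, similarity, z).
#' @export
write_screen_tsv <- function(screen, path, long_path = NULL) {
  utils::write.table(screen$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(long_path)) {
    long <- do.call(rbind, lapply(screen$states, function(r) {
      data.frame(start_state = screen$table$start_state,
                 ko_node = screen$table$ko_node, reference = r,
                 hamming = screen$table[[paste0("hamming_", r)]],
                 similarity = screen$table[[paste0("similarity_", r)]],
                 z = screen$table[[paste0("z_", r)]],
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(long, long_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
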