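# Readers and writers for the standard plain-text formats the pipeline
# touches: Matrix Market triplets with gene/cell id sidecars, dense TSV
# count tables, TF->target edge lists, and GMT gene-set annotations.
# Readers validate strictly and fail with the offending id or line number
# rather than silently coercing.

#' Read a count matrix from disk
#'
#' Supports two layouts: a dense TSV with gene ids in the first column and
#' column ids in the header, or a Matrix Market triplet file accompanied by
#' one-id-per-line `genes` and `cells` files.
#'
#' @param path path to the `.tsv` or `.mtx` file.
#' @param format `"tsv"` or `"mtx"`.
#' @param genes,cells for `format = "mtx"`, paths to the row and column id
#'   files; default to `genes.tsv` / `cells.tsv` next to the matrix.
#' @return a base dense matrix (genes x columns) with dimnames.
#' @export
read_counts <- function(path, format = c("tsv", "mtx"),
                        genes = NULL, cells = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "tsv") {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(tab[[1L]])
    if (anyDuplicated(ids)) {
      dup <- ids[duplicated(ids)][1L]
      stop("duplicate gene id '", dup, "' in ", path,
           " (line ", which(ids == dup)[2L] + 1L, ")", call. = FALSE)
    }
    m <- as.matrix(tab[, -1L, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric entries in ", path, call. = FALSE)
    rownames(m) <- ids
  } else {
    dir <- dirname(path)
    if (is.null(genes)) genes <- file.path(dir, "genes.tsv")
    if (is.null(cells)) cells <- file.path(dir, "cells.tsv")
    for (f in c(genes, cells))
      if (!file.exists(f)) stop("id file not found: ", f, call. = FALSE)
    sp <- Matrix::readMM(path)
    gid <- readLines(genes)
    cid <- readLines(cells)
    if (nrow(sp) != length(gid))
      stop("gene id file has ", length(gid), " ids but matrix has ",
           nrow(sp), " rows", call. = FALSE)
    if (ncol(sp) != length(cid))
      stop("cell id file has ", length(cid), " ids but matrix has ",
           ncol(sp), " columns", call. = FALSE)
    m <- as.matrix(sp)
    dimnames(m) <- list(gid, cid)
  }
  check_count_matrix(m, paste0("counts (", path, ")"))
  m
}

#' Write a count matrix to disk
#'
#' @param counts genes x columns matrix with dimnames.
#' @param path output path (`.tsv`, or `.mtx` with id sidecars).
#' @param format `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  check_count_matrix(counts)
  if (format == "tsv") {
    tab <- data.frame(gene = rownames(counts), counts,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    dir <- dirname(path)
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), file.path(dir, "genes.tsv"))
    writeLines(colnames(counts), file.path(dir, "cells.tsv"))
  }
  invisible(path)
}

#' Read a directed TF->target edge list
#'
#' Expects a headerless TSV whose first two columns are source and target
#' gene ids.  Duplicate edges are collapsed (with a message giving the
#' count) and self-loops are retained but flagged.
#'
#' @param path path to the edge-list TSV.
#' @return data.frame with columns `source`, `target`; attribute
#'   `self_loops` holds the flagged self-loop rows.
#' @export
read_edges <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad))
    stop("malformed edge line ", bad[1L], ": '", lines[bad[1L]], "'",
         call. = FALSE)
  df <- data.frame(source = vapply(fields, `[[`, "", 1L),
                   target = vapply(fields, `[[`, "", 2L),
                   stringsAsFactors = FALSE)
  ndup <- sum(duplicated(df))
  if (ndup > 0) {
    message("read_edges: collapsed ", ndup, " duplicate edge(s)")
    df <- unique(df)
  }
  rownames(df) <- NULL
  loops <- which(df$source == df$target)
  if (length(loops))
    message("read_edges: ", length(loops), " self-loop(s) retained")
  attr(df, "self_loops") <- loops
  df
}

#' Write an edge list as a headerless two-column TSV
#' @param edges data.frame with columns `source`, `target`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(edges, path) {
  stopifnot(all(c("source", "target") %in% names(edges)))
  utils::write.table(edges[, c("source", "target")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene-set annotations in GMT format
#'
#' Each line is `term<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path path to the GMT file.
#' @return named list mapping each term to its character vector of genes;
#'   descriptions kept in the `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 3L)
  if (length(bad))
    stop("malformed GMT line ", bad[1L], " (needs >= 3 fields): '",
         lines[bad[1L]], "'", call. = FALSE)
  terms <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(terms))
    stop("duplicate term '", terms[duplicated(terms)][1L], "' in ", path,
         call. = FALSE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- terms
  attr(sets, "descriptions") <-
    stats::setNames(vapply(fields, `[[`, "", 2L), terms)
  sets
}

#' Write gene-set annotations in GMT format
#' @param sets named list of gene vectors.
#' @param path output path.
#' @param descriptions optional named descriptions; defaults to the term.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a result table as TSV with a deterministic layout
#'
#' Numeric columns are rounded to 6 significant digits; matrices are
#' written with their rownames in a leading `id` column so that the file
#' round-trips through [utils::read.delim()].
#'
#' @param x matrix or data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  if (is.matrix(x)) {
    x <- data.frame(id = rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE)
  }
  num <- vapply(x, is.numeric, TRUE)
  x[num] <- lapply(x[num], signif, digits = 6L)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Report gene ids present in one id set but not another
#'
#' Cross-input id matching is exact-string and case-sensitive; this helper
#' logs the discrepancy between two inputs.
#'
#' @param a,b character vectors of gene ids.
#' @param names length-2 labels for the two inputs.
#' @return list with `only_a`, `only_b`, `shared` id vectors.
#' @export
match_report <- function(a, b, names = c("first", "second")) {
  out <- list(only_a = setdiff(a, b), only_b = setdiff(b, a),
              shared = intersect(a, b))
  message("id match: ", length(out$shared), " shared, ",
          length(out$only_a), " only in ", names[1L], ", ",
          length(out$only_b), " only in ", names[2L])
  out
}
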