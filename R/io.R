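#' Read and write the pipeline's plain-text formats
#'
#' Expression matrices and tissue profiles travel as TSV with the gene id in
#' the first column and sample/tissue ids in the header; single-cell counts as
#' MatrixMarket plus `genes.tsv` and `cells.tsv` (cell id, cluster label);
#' gene sets as GMT (set name, description, tab-separated member ids).
#'
#' @param x gene x sample numeric matrix with row names.
#' @param path file path.
#' @param digits significant digits written (keeps TSVs diff-stable).
#' @return `read_expression_tsv` returns a numeric matrix with gene row names;
#'   writers return the path invisibly.
#' @name expression_io
NULL

#' @rdname expression_io
#' @export
write_expression_tsv <- function(x, path, digits = 6L) {
  check_matrix(x, "x")
  df <- data.frame(gene_id = rownames(x),
                   apply(x, 2, format_signif, digits = digits),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname expression_io
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_input(sprintf("'%s' has no sample columns", path))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  if (anyDuplicated(rownames(m)))
    stop_input(sprintf("duplicate gene ids in '%s'", path))
  if (anyNA(m)) stop_input(sprintf("missing values in '%s'", path))
  m
}

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then member gene ids, tab-separated.
#' Blank lines are tolerated; lines with fewer than three fields raise an
#' error naming the line.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of gene ids (the description is
#'   kept in `attr(, "description")`).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) {
    warning(sprintf("GMT file '%s' contains no gene sets", path))
    return(structure(list(), description = character(0)))
  }
  sets <- list()
  desc <- character(0)
  for (i in keep) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop_input(sprintf("malformed GMT line %d in '%s': expected at least 3 tab-separated fields", i, path))
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    sets[[fields[1]]] <- members
    desc[fields[1]] <- fields[2]
  }
  attr(sets, "description") <- desc
  sets
}

#' Write gene sets as GMT
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param description optional per-set description (recycled).
#' @return The path, invisibly.
#' @export
write_gmt <- function(sets, path, description = "synthetic gene set") {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop_input("every gene set must be named")
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a single-cell dataset (MatrixMarket + metadata TSVs)
#'
#' @param counts cells x genes count matrix (dense or `Matrix` sparse).
#' @param cells data.frame with columns `cell_id` and `cluster`.
#' @param dir directory receiving `matrix.mtx`, `genes.tsv`, `cells.tsv`.
#' @return `read_single_cell` returns `list(counts, cells)` with a sparse
#'   counts matrix; the writer returns `dir` invisibly.
#' @name single_cell_io
#' @export
write_single_cell <- function(counts, cells, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (nrow(cells) != nrow(counts))
    stop_input("cells metadata and counts matrix disagree on cell number")
  Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(dir, "genes.tsv"))
  utils::write.table(cells[, c("cell_id", "cluster")],
                     file.path(dir, "cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname single_cell_io
#' @export
read_single_cell <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- utils::read.delim(file.path(dir, "cells.tsv"),
                             stringsAsFactors = FALSE)
  if (!all(c("cell_id", "cluster") %in% colnames(cells)))
    stop_input("cells.tsv must have 'cell_id' and 'cluster' columns")
  if (nrow(cells) != nrow(counts) || length(genes) != ncol(counts))
    stop_input("matrix.mtx dimensions disagree with genes.tsv/cells.tsv")
  dimnames(counts) <- list(cells$cell_id, genes)
  list(counts = counts, cells = cells)
}

#' Read a response dataset written as genotype_condition_rep TSV
#'
#' Column names must follow `genotype_condition_replicate`, e.g.
#' `CTL_fasting_1`, `KO_refeeding_3`.
#'
#' @param path TSV path (format of [write_expression_tsv()]).
#' @return `list(values, samples)` matching the layout of [sim_response()].
#' @export
read_response_tsv <- function(path) {
  values <- read_expression_tsv(path)
  parts <- strsplit(colnames(values), "_", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop_input(sprintf("sample column '%s' is not genotype_condition_rep",
                       colnames(values)[bad[1]]))
  samples <- data.frame(sample = colnames(values),
                        genotype = vapply(parts, `[`, "", 1L),
                        condition = vapply(parts, `[`, "", 2L),
                        replicate = as.integer(vapply(parts, `[`, "", 3L)),
                        stringsAsFactors = FALSE)
  list(values = values, samples = samples)
}

#' Write a planted-truth table as TSV
#'
#' @param truth a `synthetic_truth` data.frame.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(as.data.frame(truth), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
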