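#' Rank genes within each cell by expression
#'
#' For every cell, genes are ordered by descending count with ties broken by
#' ascending gene index (column order), so rank 1 is the most highly expressed
#' gene and the ranking is fully deterministic. This within-cell ranking is
#' scale-free: no prior normalization is applied.
#'
#' @param counts cells x genes count matrix (dense or `Matrix` sparse) with
#'   at least one gene.
#' @return Integer cells x genes matrix of ranks (1 = highest count).
#' @examples
#' rank_genes_per_cell(rbind(cellA = c(g1 = 5, g2 = 3, g3 = 3, g4 = 0)))
#' @export
rank_genes_per_cell <- function(counts) {
  if (is.null(dim(counts)) || ncol(counts) < 1L)
    stop_input("'counts' must be a cells x genes matrix with >= 1 gene")
  x <- as.matrix(counts)
  G <- ncol(x)
  ranks <- matrix(0L, nrow(x), G, dimnames = dimnames(x))
  idx <- seq_len(G)
  for (i in seq_len(nrow(x))) {
    ord <- order(-x[i, ], idx)
    ranks[i, ord] <- idx
  }
  ranks
}

#' Recovery-curve AUC of a gene set along one cell's ranking
#'
#' The AUCell-style score: walk down the cell's ranked gene list to the top
#' `ceil(top_fraction * G)` positions, accumulate the running count of
#' gene-set members recovered, and normalize the area under this staircase by
#' its maximum (the `min(x, |S|)` staircase attained when the whole set sits
#' at the top of the list). Scores are therefore in \[0, 1\] and comparable
#' across set sizes. Gene-set ids absent from the universe are dropped with a
#' warning; an empty set scores 0.
#'
#' @param ranking integer vector of per-gene ranks for one cell (as one row of
#'   [rank_genes_per_cell()]), named by gene id, or a cells x genes rank
#'   matrix (scored row-wise).
#' @param gene_set character vector of member gene ids.
#' @param top_fraction fraction of the ranking examined, in (0, 1\];
#'   default 0.05.
#' @return A single score, or a named vector of per-cell scores for a matrix
#'   input.
#' @examples
#' ranks <- setNames(1:10, paste0("g", 1:10))
#' gene_set_auc(ranks, c("g2", "g4"), top_fraction = 0.5) # 6/9
#' @export
gene_set_auc <- function(ranking, gene_set, top_fraction = 0.05) {
  check_scalar_number(top_fraction, "top_fraction", lower = 0, upper = 1,
                      strict_lower = TRUE)
  if (is.matrix(ranking)) {
    gs <- intersect_set(gene_set, colnames(ranking))
    return(vapply(seq_len(nrow(ranking)), function(i)
      auc_from_ranks(ranking[i, gs], ncol(ranking), top_fraction),
      numeric(1), USE.NAMES = FALSE) |>
        stats::setNames(rownames(ranking)))
  }
  if (is.null(names(ranking)))
    stop_input("'ranking' must be named by gene id")
  gs <- intersect_set(gene_set, names(ranking))
  auc_from_ranks(ranking[gs], length(ranking), top_fraction)
}

intersect_set <- function(gene_set, universe) {
  gene_set <- unique(gene_set)
  unknown <- setdiff(gene_set, universe)
  if (length(unknown))
    warning(sprintf("%d gene-set id(s) absent from the universe were dropped",
                    length(unknown)))
  intersect(gene_set, universe)
}

auc_from_ranks <- function(set_ranks, G, top_fraction) {
  S <- length(set_ranks)
  if (S == 0L) return(0)
  T <- ceiling(top_fraction * G)
  r <- set_ranks[set_ranks <= T]
  raw <- sum(T - r + 1)
  max_raw <- sum(pmin(seq_len(T), S))
  raw / max_raw
}

#' Score a gene set across all cells and summarize per cluster
#'
#' @param counts cells x genes count matrix.
#' @param clusters per-cell cluster labels (length = cells).
#' @param gene_set character vector of member gene ids.
#' @param top_fraction see [gene_set_auc()].
#' @param gene_set_id label stored with the result.
#' @return Object of class `gene_set_score`: `auc` (per-cell), `cluster_mean`
#'   (named per-cluster mean AUC), `gene_set_id`, `top_fraction`.
#' @export
score_cells <- function(counts, clusters, gene_set, top_fraction = 0.05,
                        gene_set_id = "gene_set") {
  if (length(clusters) != nrow(counts))
    stop_input("'clusters' must have one label per cell")
  ranks <- rank_genes_per_cell(counts)
  auc <- gene_set_auc(ranks, gene_set, top_fraction)
  cluster_mean <- tapply(auc, clusters, mean)
  structure(list(auc = auc,
                 cluster_mean = cluster_mean[sort(names(cluster_mean))],
                 gene_set_id = gene_set_id, top_fraction = top_fraction),
            class = "gene_set_score")
}

#' @export
print.gene_set_score <- function(x, ...) {
  cat(sprintf("Gene-set recovery AUC '%s' (top fraction %.3g, %d cells)\n",
              x$gene_set_id, x$top_fraction, length(x$auc)))
  cat("  per-cluster mean:\n")
  for (nm in names(x$cluster_mean))
    cat(sprintf("    %s: %.4f\n", nm, x$cluster_mean[[nm]]))
  invisible(x)
}

#' Per-cluster expression summary with small-cluster exclusion
#'
#' For each requested gene and each cluster with at least `min_cells` cells:
#' the percentage of cells with a nonzero count, the mean count, the
#' min-max-normalized mean across included clusters (dot-plot color scale),
#' and the relative percentage (a cluster's share of all expressing cells).
#' Clusters below `min_cells` are excluded from every statistic and reported,
#' mirroring the exclusion of undersized clusters (n < 10) from cell-type
#' summaries to avoid statistical bias.
#'
#' @param counts cells x genes count matrix.
#' @param clusters per-cell cluster labels.
#' @param genes gene ids to summarize (default all).
#' @param min_cells minimum cluster size; default 10.
#' @return Object of class `cluster_summary`: matrices `pct_expressing`,
#'   `mean_expr`, `normalized_mean`, `relative_pct` (gene x cluster over the
#'   included clusters), plus `excluded` (data.frame cluster/n_cells) and
#'   `cluster_sizes`.
#' @export
cluster_summary <- function(counts, clusters, genes = colnames(counts),
                            min_cells = 10L) {
  if (length(clusters) != nrow(counts))
    stop_input("'clusters' must have one label per cell")
  missing_genes <- setdiff(genes, colnames(counts))
  if (length(missing_genes))
    stop_input(sprintf("gene(s) absent from counts: %s",
                       paste(utils::head(missing_genes, 5), collapse = ", ")))
  sizes <- table(clusters)
  keep <- names(sizes)[sizes >= min_cells]
  if (length(keep) == 0L)
    stop_input("all clusters fall below min_cells; nothing to summarize")
  excluded <- data.frame(cluster = names(sizes)[sizes < min_cells],
                         n_cells = as.integer(sizes[sizes < min_cells]),
                         stringsAsFactors = FALSE)
  keep <- sort(keep)
  x <- counts[, genes, drop = FALSE]
  pct <- mean_expr <- matrix(
    0, length(genes), length(keep), dimnames = list(genes, keep))
  for (cl in keep) {
    rows <- which(clusters == cl)
    sub <- x[rows, , drop = FALSE]
    pct[, cl] <- 100 * Matrix::colSums(sub > 0) / length(rows)
    mean_expr[, cl] <- Matrix::colMeans(sub)
  }
  rng <- t(apply(mean_expr, 1L, range))
  span <- rng[, 2] - rng[, 1]
  norm_mean <- (mean_expr - rng[, 1]) / ifelse(span == 0, 1, span)
  norm_mean[span == 0, ] <- 0
  expressing <- pct * rep(as.integer(table(clusters)[keep]),
                          each = length(genes)) / 100
  tot <- rowSums(expressing)
  rel <- 100 * expressing / ifelse(tot == 0, 1, tot)
  structure(list(pct_expressing = pct, mean_expr = mean_expr,
                 normalized_mean = norm_mean, relative_pct = rel,
                 excluded = excluded,
                 cluster_sizes = as.integer(sizes[keep]) |>
                   stats::setNames(keep),
                 min_cells = as.integer(min_cells)),
            class = "cluster_summary")
}

#' @export
print.cluster_summary <- function(x, ...) {
  cat(sprintf("Per-cluster summary: %d genes x %d clusters (min_cells = %d)\n",
              nrow(x$pct_expressing), ncol(x$pct_expressing), x$min_cells))
  if (nrow(x$excluded))
    cat("  excluded clusters:",
        paste(sprintf("%s (n = %d)", x$excluded$cluster, x$excluded$n_cells),
              collapse = ", "), "\n")
  invisible(x)
}

#' Flag cluster-restricted genes
#'
#' Operationalizes "expressed in one cell type with negligible levels
#' elsewhere": a gene is flagged when its top cluster holds at least
#' `mean_share` of its proportionally normalized mean expression and no other
#' cluster expresses it in more than `max_offtarget_pct` percent of cells.
#'
#' @param summary a [cluster_summary()] result.
#' @param mean_share minimum share of total mean expression in the top
#'   cluster; default 0.9.
#' @param max_offtarget_pct maximum percent of expressing cells tolerated in
#'   any non-top cluster; default 10.
#' @return Character vector of flagged gene ids.
#' @export
restricted_genes <- function(summary, mean_share = 0.9,
                             max_offtarget_pct = 10) {
  stopifnot(inherits(summary, "cluster_summary"))
  check_scalar_number(mean_share, "mean_share", lower = 0, upper = 1)
  check_scalar_number(max_offtarget_pct, "max_offtarget_pct",
                      lower = 0, upper = 100)
  me <- summary$mean_expr
  tot <- rowSums(me)
  flagged <- vapply(seq_len(nrow(me)), function(i) {
    if (tot[i] <= 0) return(FALSE)
    share <- me[i, ] / tot[i]
    top <- which.max(share)
    share[top] >= mean_share &&
      all(summary$pct_expressing[i, -top] <= max_offtarget_pct)
  }, logical(1))
  rownames(me)[flagged]
}
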