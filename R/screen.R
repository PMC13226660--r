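#' Pearson correlation of two expression vectors
#'
#' Thin, strictly-validated wrapper around the sample Pearson coefficient used
#' throughout the screen: equal lengths of at least 3, finite values, and an
#' explicit error (never a silent 0) when either vector is constant, where the
#' coefficient is undefined.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return The correlation coefficient, in \[-1, 1\].
#' @examples
#' pearson_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4)) # 0.8
#' @export
pearson_correlation <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) stop_input("inputs must be numeric")
  if (length(x) != length(y)) stop_input("x and y must have equal length")
  if (length(x) < 3L) stop_input("at least 3 paired observations are required")
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y)))
    stop_input("inputs must be finite and complete")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_input("correlation undefined for a constant vector")
  r <- stats::cor(x, y)
  min(1, max(-1, r))
}

#' Correlate every gene with a set of anchor genes
#'
#' For one tissue's gene x sample matrix, computes the Pearson correlation of
#' every gene against each anchor, by default on `log2(x + 1)`-transformed
#' values (the robust choice for TPM-like units; the raw scale is available
#' via `transform = "identity"`). Genes that are constant across samples after
#' transformation have no defined correlation; they are dropped with a warning
#' and their ids recorded, rather than being assigned 0.
#'
#' @param matrix gene x sample numeric matrix with unique row names.
#' @param anchors character vector of anchor gene ids, all present in
#'   `matrix`.
#' @param transform `"log2p1"` (default) or `"identity"`.
#' @return An object of class `anchor_cor`: list with `r` (gene x anchor
#'   correlation matrix over the retained genes), `is_self` (logical matrix
#'   flagging anchor-vs-itself entries, reported as 1), `dropped` (ids of
#'   constant genes), `tissue` and `transform`.
#' @examples
#' sim <- sim_coexpression(sim_config(seed = 1, n_genes = 100,
#'                                    n_samples_per_tissue = 20,
#'                                    module_size = 10))
#' ac <- anchor_correlations(sim$tissue_a, attr(sim$truth, "anchor_ids"))
#' head(ac$r)
#' @export
anchor_correlations <- function(matrix, anchors,
                                transform = c("log2p1", "identity")) {
  check_matrix(matrix, "matrix")
  transform <- match.arg(transform)
  if (ncol(matrix) < 3L) stop_input("at least 3 samples are required")
  missing_anchor <- setdiff(anchors, rownames(matrix))
  if (length(missing_anchor))
    stop_input(sprintf("anchor gene(s) not in matrix: %s",
                       paste(missing_anchor, collapse = ", ")))
  x <- if (transform == "log2p1") log2(matrix + 1) else matrix
  sds <- apply(x, 1L, stats::sd)
  constant <- sds == 0
  if (any(constant[anchors]))
    stop_input("anchor gene has constant expression; correlation undefined")
  if (any(constant))
    warning(sprintf("%d constant gene(s) dropped from the correlation screen",
                    sum(constant)))
  keep <- x[!constant, , drop = FALSE]
  r <- stats::cor(t(keep), t(x[anchors, , drop = FALSE]))
  r[r > 1] <- 1; r[r < -1] <- -1
  colnames(r) <- anchors
  is_self <- outer(rownames(r), anchors, `==`)
  r[is_self] <- 1
  structure(list(r = r, is_self = is_self,
                 dropped = rownames(matrix)[constant],
                 tissue = attr(matrix, "tissue"), transform = transform),
            class = "anchor_cor")
}

#' Intersect thresholded anchor correlations across tissues
#'
#' The screening rule: a gene is a candidate when its correlation exceeds the
#' threshold (strictly, r > threshold) for every (anchor, tissue) pair — with
#' two anchors and two tissues, the four-set intersection summarised by the
#' classic Venn diagram. Anchors themselves are excluded from the candidate
#' list. The screen operates on the intersection of the gene universes
#' retained in each tissue; genes missing from any tissue are counted in
#' `n_universe_dropped`.
#'
#' @param tables named list of [anchor_correlations()] results, one per
#'   tissue (two tissues x two anchors is the canonical case; any k x m is
#'   accepted).
#' @param threshold correlation cutoff in (-1, 1); default 0.6.
#' @return An object of class `anchor_screen`: `candidates` (data.frame of
#'   gene, per-pair r, `min_r`, ordered as by [rank_candidates()]),
#'   `candidate_set`, `pass_counts` per pair, `venn` (per-membership-pattern
#'   counts over all non-empty combinations), `threshold`, `anchors`,
#'   `universe`, `n_universe_dropped`.
#' @export
candidate_intersection <- function(tables, threshold = 0.6) {
  if (!is.list(tables) || length(tables) < 1L ||
      !all(vapply(tables, inherits, TRUE, "anchor_cor")))
    stop_input("'tables' must be a list of anchor_correlations() results")
  check_scalar_number(threshold, "threshold", lower = -1, upper = 1,
                      strict_lower = TRUE, strict_upper = TRUE)
  if (is.null(names(tables)))
    names(tables) <- sprintf("tissue%d", seq_along(tables))
  anchors <- colnames(tables[[1]]$r)
  for (tb in tables)
    if (!identical(colnames(tb$r), anchors))
      stop_input("all tables must use the same anchors")
  universes <- lapply(tables, function(tb) rownames(tb$r))
  universe <- Reduce(intersect, universes)
  if (length(universe) == 0L)
    stop_input("gene universes of the tissues are disjoint")
  n_dropped <- length(Reduce(union, universes)) - length(universe)

  rmat <- do.call(cbind, lapply(names(tables), function(tn) {
    m <- tables[[tn]]$r[universe, , drop = FALSE]
    colnames(m) <- paste(tn, anchors, sep = ".")
    m
  }))
  pass <- rmat > threshold
  non_anchor <- !(universe %in% anchors)
  candidate <- rowSums(pass) == ncol(pass) & non_anchor
  min_r <- apply(rmat, 1L, min)

  candidates <- data.frame(gene_id = universe, rmat, min_r = min_r,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           row.names = NULL)[candidate, , drop = FALSE]
  candidates <- candidates[order(-candidates$min_r, candidates$gene_id), ,
                           drop = FALSE]
  rownames(candidates) <- NULL

  # Venn region counts over the non-anchor universe (all non-empty patterns)
  pat <- apply(pass[non_anchor, , drop = FALSE], 1L,
               function(z) paste(ifelse(z, "1", "0"), collapse = ""))
  combos <- expand.grid(rep(list(c("0", "1")), ncol(pass)))[-1, , drop = FALSE]
  pattern <- apply(combos, 1L, paste, collapse = "")
  venn <- data.frame(pattern = pattern,
                     count = as.integer(table(factor(pat, levels = pattern))),
                     stringsAsFactors = FALSE)

  structure(list(candidates = candidates,
                 candidate_set = candidates$gene_id,
                 pass_counts = colSums(pass[non_anchor, , drop = FALSE]),
                 venn = venn, sets = colnames(pass),
                 threshold = threshold, anchors = anchors,
                 universe = universe, n_universe_dropped = n_dropped),
            class = "anchor_screen")
}

#' Rank screen candidates
#'
#' Orders candidates by descending minimum correlation over the
#' (anchor, tissue) pairs, breaking ties lexicographically by gene id.
#'
#' @param result an `anchor_screen` object.
#' @return Character vector of gene ids (empty when no candidate passed).
#' @export
rank_candidates <- function(result) {
  stopifnot(inherits(result, "anchor_screen"))
  result$candidates$gene_id
}

#' Run the full two-tissue anchor screen
#'
#' Convenience wrapper: [anchor_correlations()] per tissue followed by
#' [candidate_intersection()].
#'
#' @param tissues named list of gene x sample matrices.
#' @inheritParams anchor_correlations
#' @inheritParams candidate_intersection
#' @return An `anchor_screen` object.
#' @examples
#' sim <- sim_coexpression(sim_config(seed = 1, n_genes = 200,
#'                                    n_samples_per_tissue = 30,
#'                                    module_size = 10))
#' scr <- screen_anchors(list(liver = sim$tissue_a, intestine = sim$tissue_b),
#'                       anchors = attr(sim$truth, "anchor_ids"))
#' scr
#' @export
screen_anchors <- function(tissues, anchors, threshold = 0.6,
                           transform = c("log2p1", "identity")) {
  transform <- match.arg(transform)
  tables <- lapply(tissues, anchor_correlations, anchors = anchors,
                   transform = transform)
  candidate_intersection(tables, threshold = threshold)
}

#' @export
print.anchor_screen <- function(x, ...) {
  cat("Anchor co-expression screen\n")
  cat(sprintf("  anchors: %s | threshold: r > %g\n",
              paste(x$anchors, collapse = ", "), x$threshold))
  cat(sprintf("  universe: %d genes (%d dropped at union/intersection)\n",
              length(x$universe), x$n_universe_dropped))
  cat("  per-pair pass counts:\n")
  for (nm in names(x$pass_counts))
    cat(sprintf("    %s: %d\n", nm, x$pass_counts[[nm]]))
  cat(sprintf("  candidates (all pairs): %d\n", length(x$candidate_set)))
  if (length(x$candidate_set))
    cat("  top:", paste(utils::head(x$candidate_set, 5), collapse = ", "), "\n")
  invisible(x)
}
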