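#' Min-max scale a gene-by-tissue profile
#'
#' Rescales each gene's row to \[0, 1\]: `(x - min) / (max - min)`. Rows with
#' no spread carry no distributional information; they are mapped to all-zero
#' and flagged in `attr(, "constant_rows")` (with a warning) so they can be
#' excluded before correlation.
#'
#' @param profile gene x tissue numeric matrix (>= 2 tissues).
#' @return The scaled matrix, same dimnames, with `attr(, "constant_rows")`.
#' @examples
#' minmax_scale(rbind(g1 = c(5, 10, 15), g2 = c(3, 3, 3)))
#' @export
minmax_scale <- function(profile) {
  check_matrix(profile, "profile")
  if (ncol(profile) < 2L) stop_input("at least 2 tissues are required")
  rmin <- apply(profile, 1L, min)
  rmax <- apply(profile, 1L, max)
  span <- rmax - rmin
  constant <- span == 0
  span[constant] <- 1 # avoid 0/0; constant rows are zeroed below
  out <- (profile - rmin) / span
  out[constant, ] <- 0
  if (any(constant))
    warning(sprintf("%d constant row(s) mapped to zero in min-max scaling",
                    sum(constant)))
  attr(out, "constant_rows") <- rownames(profile)[constant]
  out
}

#' Proportionally normalize a gene-by-tissue profile
#'
#' Divides each row by its sum so the values become tissue shares summing
#' to 1 — the normalization used for tissue-distribution heatmaps.
#'
#' @param profile gene x tissue numeric matrix with non-negative rows; an
#'   all-zero row is an error naming the gene.
#' @return Matrix of row-wise shares.
#' @export
proportional_normalize <- function(profile) {
  check_matrix(profile, "profile")
  rs <- rowSums(profile)
  zero <- rs <= 0
  if (any(zero))
    stop_input(sprintf("all-zero row(s): %s",
                       paste(rownames(profile)[zero], collapse = ", ")))
  profile / rs
}

#' Pairwise gene-gene Pearson correlation of a scaled profile
#'
#' @param scaled gene x tissue matrix, typically the output of
#'   [minmax_scale()] with constant rows removed; >= 3 tissues; an error is
#'   raised if any row is constant (correlation undefined).
#' @return Symmetric gene x gene correlation matrix with unit diagonal.
#' @export
pairwise_gene_correlation <- function(scaled) {
  check_matrix(scaled, "scaled")
  if (ncol(scaled) < 3L) stop_input("at least 3 tissues are required")
  sds <- apply(scaled, 1L, stats::sd)
  if (any(sds == 0))
    stop_input(sprintf("constant row(s) must be excluded before correlation: %s",
                       paste(rownames(scaled)[sds == 0], collapse = ", ")))
  r <- stats::cor(t(scaled))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r[r > 1] <- 1; r[r < -1] <- -1
  r
}

#' Cut a correlation matrix into gene modules by hierarchical clustering
#'
#' Agglomerative clustering on the distance `d = 1 - r` (so perfectly
#' correlated genes are at distance 0 and anti-correlated genes at 2), average
#' linkage by default, with the tree cut to exactly `n_modules` groups.
#' `stats::hclust` is deterministic for a fixed input ordering; distance ties
#' are resolved by its documented lowest-index merge rule.
#'
#' @param corr symmetric gene x gene correlation matrix with unit diagonal.
#' @param n_modules number of modules to cut, between 2 and the gene count.
#' @param linkage linkage method passed to [stats::hclust()].
#' @return An object of class `cluster_modules`: list with `membership`
#'   (named integer vector), `modules` (list of `module_id`, `members`,
#'   `contains_anchors` placeholder, `linkage_method`, `n_modules`), and the
#'   `hclust` tree.
#' @export
hierarchical_modules <- function(corr, n_modules, linkage = "average") {
  check_matrix(corr, "corr")
  if (nrow(corr) != ncol(corr) ||
      max(abs(corr - t(corr))) > 1e-8 ||
      max(abs(diag(corr) - 1)) > 1e-8)
    stop_input("'corr' must be symmetric with unit diagonal")
  check_scalar_number(n_modules, "n_modules", lower = 2, upper = nrow(corr))
  d <- stats::as.dist(1 - corr)
  tree <- stats::hclust(d, method = linkage)
  membership <- stats::cutree(tree, k = n_modules)
  modules <- lapply(sort(unique(membership)), function(k) {
    list(module_id = k, members = names(membership)[membership == k],
         contains_anchors = NA, linkage_method = linkage,
         n_modules = as.integer(n_modules))
  })
  structure(list(membership = membership, modules = modules, tree = tree,
                 linkage = linkage, n_modules = as.integer(n_modules)),
            class = "cluster_modules")
}

#' @export
print.cluster_modules <- function(x, ...) {
  sizes <- table(x$membership)
  cat(sprintf("Hierarchical gene modules: %d modules (%s linkage, d = 1 - r)\n",
              x$n_modules, x$linkage))
  cat("  sizes:", paste(sprintf("%s:%d", names(sizes), sizes), collapse = " "),
      "\n")
  invisible(x)
}

#' Extract the module containing the anchor genes
#'
#' Returns the module holding all anchors; when the anchors are split across
#' modules, returns the module holding the majority (ties resolved toward the
#' lower module index) with `contains_anchors = FALSE` and a warning.
#'
#' @param modules a [hierarchical_modules()] result.
#' @param anchors anchor gene ids, all present in the clustered universe.
#' @return A list: `module_id`, `members`, `contains_anchors`.
#' @export
anchor_module <- function(modules, anchors) {
  stopifnot(inherits(modules, "cluster_modules"))
  missing_anchor <- setdiff(anchors, names(modules$membership))
  if (length(missing_anchor))
    stop_input(sprintf("anchor(s) absent from the clustered genes: %s",
                       paste(missing_anchor, collapse = ", ")))
  hits <- modules$membership[anchors]
  ids <- sort(unique(hits))
  counts <- vapply(ids, function(k) sum(hits == k), integer(1))
  best <- ids[which.max(counts)] # ties -> lowest module index
  all_in_one <- length(unique(hits)) == 1L
  if (!all_in_one)
    warning("anchors are split across modules; returning the majority module")
  list(module_id = best,
       members = names(modules$membership)[modules$membership == best],
       contains_anchors = all_in_one)
}
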