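#' Simulate a labelled single-cell count matrix
#'
#' Negative-binomial counts per gene per cluster, emulating a liver atlas in
#' which the first cluster plays the hepatocyte role. Planted gene classes:
#' \describe{
#'   \item{celltype_restricted}{mean `mu_marker` in cluster 1, `mu_ambient`
#'     elsewhere (genes 1..module_size; includes the anchors).}
#'   \item{broad}{mean `mu_marker` in every cluster (next module_size genes).}
#'   \item{null}{mean `mu_null` everywhere (remaining genes).}
#' }
#' All counts share the `nb_dispersion` size parameter
#' (variance = mu + mu^2/size). The configured cluster sizes must include
#' exactly one cluster below 10 cells so the downstream small-cluster
#' exclusion rule is exercised.
#'
#' @param config a [sim_config()] with at least two clusters.
#' @param mu_marker,mu_ambient,mu_null negative-binomial means (counts per
#'   cell) for marker expression, off-target leakage of restricted genes, and
#'   unexpressed background genes.
#' @return A list with `counts` (sparse cells x genes `dgCMatrix`), `cells`
#'   (data.frame of `cell_id`, `cluster`) and `truth`.
#' @examples
#' sim <- sim_single_cell(sim_config(seed = 2, n_genes = 50, module_size = 5,
#'                                   n_cells_per_cluster = c(50, 20, 8)))
#' table(sim$cells$cluster)
#' @export
sim_single_cell <- function(config, mu_marker = 5, mu_ambient = 0.05,
                            mu_null = 0.2) {
  stopifnot(inherits(config, "sim_config"))
  sizes <- config$n_cells_per_cluster
  if (length(sizes) < 2L) stop_input("at least two clusters are required")
  if (sum(sizes < 10L) != 1L)
    stop_input("exactly one cluster must have fewer than 10 cells")
  n <- config$n_genes
  m <- config$module_size
  if (2L * m > n) stop_input("n_genes must be at least 2 * module_size")
  ids <- gene_ids(n)
  cls <- rep("null", n)
  cls[seq_len(m)] <- "celltype_restricted"
  cls[m + seq_len(m)] <- "broad"
  k <- length(sizes)
  clusters <- sprintf("cluster%d", seq_len(k))
  cell_cluster <- rep(clusters, sizes)
  cell_ids <- sprintf("cell%05d", seq_along(cell_cluster))

  # per-gene x cluster mean matrix
  mu <- matrix(mu_null, n, k)
  mu[cls == "celltype_restricted", ] <- mu_ambient
  mu[cls == "celltype_restricted", 1L] <- mu_marker
  mu[cls == "broad", ] <- mu_marker

  with_seed(offset_seed(config$seed, 2L), {
    counts <- matrix(0L, length(cell_ids), n,
                     dimnames = list(cell_ids, ids))
    for (j in seq_len(k)) {
      rows <- which(cell_cluster == clusters[j])
      counts[rows, ] <- matrix(
        stats::rnbinom(length(rows) * n, size = config$nb_dispersion,
                       mu = rep(mu[, j], each = length(rows))),
        length(rows), n)
    }
    list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
         cells = data.frame(cell_id = cell_ids, cluster = cell_cluster,
                            stringsAsFactors = FALSE),
         truth = make_truth(ids, cls, ids[1:2], config))
  })
}
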