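#' Simulate a gene-by-tissue consensus expression profile
#'
#' Emulates an HPA/GTEx-style consensus table (nTPM-like) with three planted
#' modules of `module_size` genes each:
#' \describe{
#'   \item{module 1}{restricted to the designated tissue pair (the first two
#'     tissues, labelled "liver" and "intestine"); contains the two anchors.}
#'   \item{module 2}{restricted to a second, disjoint tissue pair — a control
#'     pattern the clustering must separate from the anchors' module.}
#'   \item{module 3}{broad: expressed in every tissue, modulated by a shared
#'     tissue-depth factor (tissues differ in overall transcriptional
#'     output), so broad genes form a coherent third cluster.}
#' }
#' Restricted genes take value `baseline * (1 + tissue_noise * z)` in their
#' designated tissues and `baseline * tissue_noise * u` (u uniform on
#' \[0, 1\]) elsewhere, so at `tissue_noise = 0` the off-target value is
#' exactly 0 and proportional normalization puts 1/2 in each designated
#' tissue. Broad genes take `baseline * depth_j * exp(tissue_noise * z)` with
#' `depth_j = exp(3 * tissue_noise * z_j)` shared across genes; at
#' `tissue_noise = 0` every tissue gets the identical value.
#'
#' @param config a [sim_config()]; requires `n_tissues >= 3` (>= 5 for the
#'   second restricted pair to be disjoint; with 3 or 4 tissues module 2 is
#'   restricted to the last tissue only).
#' @return A list with `profile` (gene x tissue matrix) and `truth`
#'   (planted classes `tissue_restricted` / `broad` plus a `module_id`
#'   column and `attr(, "restricted_tissues")`, the designated tissue set per
#'   restricted module).
#' @examples
#' sim <- sim_tissue_profiles(sim_config(seed = 3, n_tissues = 10,
#'                                       module_size = 5))
#' dim(sim$profile)
#' @export
sim_tissue_profiles <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  nt <- config$n_tissues
  if (nt < 3L) stop_input("n_tissues must be at least 3")
  m <- config$module_size
  n <- 3L * m
  ids <- gene_ids(n)
  anchors <- ids[1:2]
  tissues <- c("liver", "intestine",
               sprintf("tissue%02d", seq_len(max(nt - 2L, 0L)) + 2L))[seq_len(nt)]
  pair1 <- 1:2
  pair2 <- if (nt >= 5L) 3:4 else nt
  module_id <- rep(1:3, each = m)
  cls <- c(rep("tissue_restricted", 2L * m), rep("broad", m))

  with_seed(offset_seed(config$seed, 1L), {
    baseline <- config$base_expression_scale * stats::rlnorm(n, 0, 0.5)
    tn <- config$tissue_noise
    depth <- exp(3 * tn * stats::rnorm(nt))
    prof <- matrix(0, n, nt, dimnames = list(ids, tissues))
    fill_restricted <- function(rows, pair) {
      on_t <- baseline[rows] *
        (1 + tn * matrix(stats::rnorm(length(rows) * length(pair)),
                         length(rows), length(pair)))
      off <- setdiff(seq_len(nt), pair)
      off_t <- baseline[rows] * tn *
        matrix(stats::runif(length(rows) * length(off)), length(rows), length(off))
      prof[rows, pair] <<- pmax(on_t, 0)
      prof[rows, off] <<- off_t
    }
    fill_restricted(which(module_id == 1L), pair1)
    fill_restricted(which(module_id == 2L), pair2)
    rows3 <- which(module_id == 3L)
    prof[rows3, ] <- baseline[rows3] *
      matrix(depth, length(rows3), nt, byrow = TRUE) *
      exp(tn * matrix(stats::rnorm(length(rows3) * nt), length(rows3), nt))

    truth <- make_truth(ids, cls, anchors, config, module_id = module_id)
    attr(truth, "restricted_tissues") <-
      list(`1` = tissues[pair1], `2` = tissues[pair2])
    list(profile = prof, truth = truth)
  })
}
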