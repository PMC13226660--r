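test_that("per-cell ranking orders by count with index tie-break", {
  m <- rbind(cellA = c(g1 = 5, g2 = 3, g3 = 3, g4 = 0))
  expect_equal(unname(rank_genes_per_cell(m)[1, ]), c(1L, 2L, 3L, 4L))
  zero <- rbind(cellB = c(g1 = 0, g2 = 0, g3 = 0))
  expect_equal(unname(rank_genes_per_cell(zero)[1, ]), 1:3)
})

test_that("per-cell ranking equals a naive stable sort on random cells", {
  set.seed(21)
  counts <- matrix(rpois(100 * 30, 2), 100, 30,
                   dimnames = list(sprintf("c%03d", 1:100),
                                   sprintf("g%02d", 1:30)))
  ranks <- rank_genes_per_cell(counts)
  for (i in seq_len(nrow(counts))) {
    ord <- sort.list(-counts[i, ], method = "radix") # stable, index ties
    oracle <- integer(30)
    oracle[ord] <- 1:30
    expect_equal(unname(ranks[i, ]), oracle)
  }
})

test_that("gene_set_auc reproduces the worked staircase and its edge cases", {
  ranks <- stats::setNames(1:10, paste0("g", 1:10))
  # set at ranks {2, 4}, T = 5: raw = 0+1+1+2+2 = 6, max = 1+2+2+2+2 = 9
  expect_equal(gene_set_auc(ranks, c("g2", "g4"), top_fraction = 0.5), 6 / 9)
  # whole set at the top -> maximal recovery
  expect_equal(gene_set_auc(ranks, c("g1", "g2"), top_fraction = 0.5), 1.0)
  # no member inside the window -> 0
  expect_equal(gene_set_auc(ranks, c("g9", "g10"), top_fraction = 0.5), 0)
  # empty set after filtering -> 0, with a warning about unknown ids
  expect_warning(s <- gene_set_auc(ranks, c("zz1", "zz2"), top_fraction = 0.5),
                 "absent")
  expect_equal(s, 0)
  expect_error(gene_set_auc(ranks, "g1", top_fraction = 0), "top_fraction")
  expect_error(gene_set_auc(ranks, "g1", top_fraction = 1.5), "top_fraction")
})

test_that("gene_set_auc matches exhaustive enumeration on random instances", {
  set.seed(31)
  for (i in 1:200) {
    G <- sample(5:50, 1)
    ranking <- stats::setNames(sample(G), sprintf("g%02d", 1:G))
    set_size <- sample(1:min(8, G), 1)
    gene_set <- sample(names(ranking), set_size)
    tf <- runif(1, 0.05, 1)
    expect_equal(gene_set_auc(ranking, gene_set, tf),
                 auc_oracle(ranking, gene_set, tf))
  }
})

test_that("the score ignores relabelling outside the set and rewards top ranks", {
  ranks <- stats::setNames(c(3L, 1L, 7L, 2L, 5L, 4L, 6L, 8L, 9L, 10L),
                           paste0("g", 1:10))
  base <- gene_set_auc(ranks, c("g1", "g4"), 0.5)
  relabelled <- ranks
  names(relabelled)[c(5, 7)] <- c("x1", "x2") # non-members renamed
  expect_equal(gene_set_auc(relabelled, c("g1", "g4"), 0.5), base)
  # moving a member to rank 1 never decreases the score
  better <- stats::setNames(ranks, names(ranks))
  swap <- names(better)[better == 1L]
  better[swap] <- better["g4"]
  better["g4"] <- 1L
  expect_gte(gene_set_auc(better, c("g1", "g4"), 0.5), base)
})

test_that("cluster_summary applies the definitional rules and the n<10 exclusion", {
  counts <- rbind(
    matrix(c(rep(1, 3), rep(0, 9)), 12, 1), # 3 of 12 cells expressing
    matrix(1, 9, 1))                        # a 9-cell cluster
  colnames(counts) <- "gA"
  rownames(counts) <- sprintf("c%02d", 1:21)
  clusters <- c(rep("big", 12), rep("tiny", 9))
  cs <- cluster_summary(counts, clusters, min_cells = 10)
  expect_equal(unname(cs$pct_expressing["gA", "big"]), 25.0)
  expect_equal(cs$excluded$cluster, "tiny")
  expect_equal(cs$excluded$n_cells, 9L)
  expect_false("tiny" %in% colnames(cs$pct_expressing))
  expect_error(cluster_summary(counts, clusters, min_cells = 30), "min_cells")
})

test_that("noise-free restricted genes min-max to 1 in their cluster, 0 elsewhere", {
  sim <- sim_single_cell(small_config(seed = 2), mu_ambient = 0, mu_null = 0)
  cs <- cluster_summary(sim$counts, sim$cells$cluster)
  restricted <- sim$truth$gene_id[sim$truth$planted_class == "celltype_restricted"]
  nm <- cs$normalized_mean[restricted, ]
  expect_true(all(nm[, "cluster1"] == 1))
  expect_true(all(nm[, colnames(nm) != "cluster1"] == 0))
})

test_that("restricted-gene calling recovers the planted markers (F1 >= 0.9)", {
  sim <- sim_single_cell(sim_config(seed = 9, n_genes = 400))
  cs <- cluster_summary(sim$counts, sim$cells$cluster)
  called <- restricted_genes(cs)
  planted <- sim$truth$gene_id[sim$truth$planted_class == "celltype_restricted"]
  expect_gte(f1_score(called, planted), 0.9)
  # a uniformly expressed gene is never flagged
  broad <- sim$truth$gene_id[sim$truth$planted_class == "broad"]
  expect_length(intersect(called, broad), 0)
})

test_that("the planted marker set scores highest in its home cluster", {
  sim <- sim_single_cell(small_config(seed = 12))
  planted <- sim$truth$gene_id[sim$truth$planted_class == "celltype_restricted"]
  sc <- score_cells(sim$counts, sim$cells$cluster, planted)
  expect_equal(names(which.max(sc$cluster_mean)), "cluster1")
  expect_true(all(sc$auc >= 0 & sc$auc <= 1))
  expect_gt(min(sc$cluster_mean[["cluster1"]] -
                  sc$cluster_mean[names(sc$cluster_mean) != "cluster1"]), 0)
})
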