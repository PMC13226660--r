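test_that("pearson_correlation matches hand-computed and degenerate cases", {
  expect_equal(pearson_correlation(c(1, 2, 3, 4), c(2, 4, 6, 8)), 1.0)
  expect_equal(pearson_correlation(c(1, 2, 3), c(3, 2, 1)), -1.0)
  expect_equal(pearson_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_correlation(1:4, 1:3), "equal length")
  expect_error(pearson_correlation(1:2, 2:3), "at least 3")
})

test_that("pearson_correlation agrees with the two-pass oracle on random pairs", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(3:40, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(pearson_correlation(x, y), pearson_oracle(x, y),
                 tolerance = 1e-10)
  }
})

test_that("anchor_correlations validates inputs and flags self-correlation", {
  sim <- sim_coexpression(small_config(seed = 1))
  anchors <- attr(sim$truth, "anchor_ids")
  ac <- anchor_correlations(sim$tissue_a, anchors)
  expect_equal(unname(ac$r[anchors[1], anchors[1]]), 1.0)
  expect_true(ac$is_self[match(anchors[1], rownames(ac$r)), 1])
  expect_error(anchor_correlations(sim$tissue_a, c(anchors, "nope")), "nope")
  expect_error(anchor_correlations(sim$tissue_a[, 1:2], anchors),
               "at least 3 samples")
  # constant genes dropped with a warning, never scored as 0
  m <- sim$tissue_a
  m["gene00150", ] <- 7
  expect_warning(ac2 <- anchor_correlations(m, anchors), "constant")
  expect_false("gene00150" %in% rownames(ac2$r))
  expect_identical(ac2$dropped, "gene00150")
})

test_that("anchor correlation of a module gene matches the factor-model closed form", {
  cfg <- sim_config(seed = 1, n_genes = 500, module_size = 20,
                    module_loading = 0.9, n_samples_per_tissue = 60)
  sim <- sim_coexpression(cfg)
  anchors <- attr(sim$truth, "anchor_ids")
  ac <- anchor_correlations(sim$tissue_a, anchors)
  members <- setdiff(
    sim$truth$gene_id[sim$truth$planted_class == "both_tissue_module"], anchors)
  analytic <- cfg$module_loading^2 / (cfg$module_loading^2 + cfg$noise_sd^2)
  expect_lt(abs(mean(ac$r[members, 1]) - analytic), 0.15)
})

test_that("candidate_intersection applies the strict all-pairs rule", {
  # hand-built tables: one gene passing all four pairs, one failing a single
  # pair at 0.59, anchors excluded
  mk <- function(vals, tissue) {
    r <- rbind(a1 = c(1, 0.9), a2 = c(0.9, 1), g1 = vals[1:2], g2 = vals[3:4])
    colnames(r) <- c("a1", "a2")
    structure(list(r = r, is_self = outer(rownames(r), colnames(r), `==`),
                   dropped = character(0), tissue = tissue,
                   transform = "log2p1"),
              class = "anchor_cor")
  }
  tabs <- list(liver = mk(c(0.9, 0.8, 0.9, 0.9), "liver"),
               gut = mk(c(0.7, 0.65, 0.9, 0.59), "gut"))
  res <- candidate_intersection(tabs, threshold = 0.6)
  expect_identical(res$candidate_set, "g1")
  expect_equal(res$candidates$min_r, 0.65)
  expect_false("a1" %in% res$candidate_set)
  expect_equal(nrow(res$venn), 15L)
  expect_equal(sum(res$venn$count[res$venn$pattern == "1111"]), 1L)
  expect_error(candidate_intersection(tabs, threshold = 1), "threshold")
})

test_that("raising the threshold never enlarges the candidate set", {
  sim <- sim_coexpression(small_config(seed = 6))
  anchors <- attr(sim$truth, "anchor_ids")
  tissues <- list(liver = sim$tissue_a, intestine = sim$tissue_b)
  prev <- NULL
  for (th in c(0.2, 0.4, 0.6, 0.8)) {
    cand <- screen_anchors(tissues, anchors, threshold = th)$candidate_set
    if (!is.null(prev)) expect_true(all(cand %in% prev))
    prev <- cand
  }
})

test_that("threshold near -1 admits the whole non-anchor universe", {
  sim <- sim_coexpression(small_config(seed = 2))
  anchors <- attr(sim$truth, "anchor_ids")
  res <- screen_anchors(list(a = sim$tissue_a, b = sim$tissue_b), anchors,
                        threshold = -0.999999)
  expect_setequal(res$candidate_set, setdiff(rownames(sim$tissue_a), anchors))
})

test_that("candidates are ranked by descending min r with lexicographic ties", {
  set.seed(7)
  n <- 20
  ids <- sprintf("g%02d", sample(n))
  r <- matrix(runif(n * 2, 0.61, 0.99), n, 2,
              dimnames = list(ids, c("a1", "a2")))
  r <- rbind(r, a1 = c(1, 0.95), a2 = c(0.95, 1))
  r["g05", ] <- r["g11", ] <- c(0.7, 0.8) # forced min-r tie
  mk <- structure(list(r = r, is_self = outer(rownames(r), colnames(r), `==`),
                       dropped = character(0), tissue = "t",
                       transform = "log2p1"), class = "anchor_cor")
  res <- candidate_intersection(list(t1 = mk, t2 = mk), threshold = 0.6)
  ranked <- rank_candidates(res)
  minr <- apply(cbind(r[ranked, ], r[ranked, ]), 1, min)
  oracle <- ranked[order(-minr, ranked)]
  expect_identical(ranked, oracle)
  expect_lt(which(ranked == "g05"), which(ranked == "g11"))
})

test_that("noise-free screen recovers exactly the planted both-tissue module", {
  cfg <- small_config(seed = 5, module_loading = 1, noise_sd = 1e-7)
  sim <- sim_coexpression(cfg)
  anchors <- attr(sim$truth, "anchor_ids")
  res <- screen_anchors(list(a = sim$tissue_a, b = sim$tissue_b), anchors)
  planted <- setdiff(
    sim$truth$gene_id[sim$truth$planted_class == "both_tissue_module"], anchors)
  expect_setequal(res$candidate_set, planted)
})
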