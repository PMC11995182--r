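test_that("self-synteny gives full retention in every window", {
  g <- simulate_ancestor(2, 60, seed = 12)
  blocks <- chain_anchors(build_anchors(self_pairs(g), g, g))
  prof <- retention_profile(g, blocks, window_size = 20, step = 20)
  expect_true(all(prof$fraction == 1))
  expect_equal(attr(prof, "overall"), 1)
  expect_equal(overall_retention(g, blocks), 1)
  # and zero retention without blocks
  none <- structure(list(), class = "collinear_blocks")
  expect_equal(overall_retention(g, none), 0)
})

test_that("windows tile chromosomes with the stated step", {
  g <- simulate_ancestor(1, 100, seed = 5)
  blocks <- chain_anchors(build_anchors(self_pairs(g), g, g))
  prof <- retention_profile(g, blocks, window_size = 30, step = 30)
  expect_equal(prof$start_rank, c(0L, 30L, 60L, 90L))
  expect_equal(prof$end_rank, c(30L, 60L, 90L, 100L))
  expect_error(retention_profile(g, blocks, window_size = 3), "unstable")
})

test_that("uniform 30% gene loss yields ~70% retention within binomial bounds", {
  ref <- simulate_ancestor(8, 100, seed = 41, species = "ref")
  set.seed(42)
  keep <- runif(800) >= 0.3
  tgt_genes <- ref$genes[keep, ]
  tgt_genes$gene_id <- paste0("t_", tgt_genes$gene_id)
  tgt <- genome("tgt", tgt_genes)
  pairs <- data.frame(gene_a = ref$genes$gene_id[keep],
                      gene_b = tgt_genes$gene_id)
  blocks <- chain_anchors(build_anchors(pairs, ref, tgt))
  rho <- overall_retention(ref, blocks)
  ci <- qbinom(c(0.005, 0.995), 800, 0.7) / 800
  expect_gte(rho, ci[1L])
  expect_lte(rho, ci[2L])
  # profile/overall consistency: weighted mean of window fractions equals
  # the overall fraction exactly when windows partition the chromosomes
  prof <- retention_profile(ref, blocks, window_size = 50, step = 50)
  expect_equal(sum(prof$n_retained) / sum(prof$n_reference_genes), rho,
               tolerance = 1e-12)
  expect_equal(stats::weighted.mean(prof$fraction,
                                    prof$n_reference_genes), rho,
               tolerance = 1e-12)
})

test_that("adding blocks never decreases any window's retention", {
  g <- simulate_ancestor(1, 80, seed = 77)
  blocks <- chain_anchors(build_anchors(self_pairs(g), g, g))
  half <- structure(blocks[1L], class = "collinear_blocks")
  # restrict the single self-block to the first 40 genes
  half[[1L]]$anchors <- half[[1L]]$anchors[half[[1L]]$anchors$rank_a < 40, ]
  p1 <- retention_profile(g, half, window_size = 20, step = 20)
  p2 <- retention_profile(g, blocks, window_size = 20, step = 20)
  expect_true(all(p2$fraction >= p1$fraction))
  expect_gte(attr(p2, "overall"), attr(p1, "overall"))
})

test_that("post-WGT fractionation matches 1 - (1-q)^3 reference retention", {
  q <- 0.45
  anc <- simulate_ancestor(4, 100, seed = 90)
  set.seed(91)
  # target keeps each of 3 subgenome copies of each gene with prob q
  w <- apply_wgt(anc, retention = 1, seed = 92)
  keep <- runif(nrow(w$genome$genes)) < q
  tgt_genes <- w$genome$genes[keep, ]
  tgt_genes$gene_id <- paste0("t_", tgt_genes$gene_id)
  tgt <- genome("tgt", tgt_genes)
  all_pairs <- wgt_pairs(anc, w)
  all_pairs$gene_b <- paste0("t_", all_pairs$gene_b)
  all_pairs <- all_pairs[all_pairs$gene_b %in% tgt_genes$gene_id, ]
  blocks <- chain_anchors(build_anchors(all_pairs, anc, tgt))
  rho <- overall_retention(anc, blocks)
  expected <- 1 - (1 - q)^3
  expect_lt(abs(rho - expected), 0.05)
})
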