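test_that("anchors carry rank coordinates and strand agreement", {
  ga <- genome("A", data.frame(gene_id = c("g1", "g2"), chrom = "chrA",
                               start = c(0, 100), end = c(50, 150),
                               strand = c("+", "+")))
  gb <- genome("B", data.frame(gene_id = c("h1", "h2"), chrom = "chrB",
                               start = c(0, 100), end = c(50, 150),
                               strand = c("-", "+")))
  p <- data.frame(gene_a = c("g1", "g2"), gene_b = c("h1", "h2"))
  a <- build_anchors(p, ga, gb)
  expect_equal(nrow(a), 2L)
  expect_equal(a$strand_match[a$gene_a == "g1"], "opposite")
  expect_equal(a$strand_match[a$gene_a == "g2"], "same")
  expect_equal(a$rank_a, c(0L, 1L))
  # permuting pair order leaves the anchor set identical
  a2 <- build_anchors(p[2:1, ], ga, gb)
  expect_identical(a, a2)
  # unresolvable pairs are rejected, not fatal
  p3 <- rbind(p, data.frame(gene_a = "gX", gene_b = "h1"))
  a3 <- build_anchors(p3, ga, gb)
  expect_equal(nrow(a3), 2L)
  expect_equal(nrow(attr(a3, "rejects")), 1L)
})

test_that("diagonals chain into single oriented blocks", {
  mk <- function(rb) data.frame(
    gene_a = sprintf("a%d", 0:9), gene_b = sprintf("b%d", 0:9),
    chr_a = "c1", rank_a = 0:9, chr_b = "c2", rank_b = rb,
    strand_match = "same", score = 1, stringsAsFactors = FALSE)
  plus <- chain_anchors(mk(0:9), max_gap = 5, min_block_size = 5)
  expect_length(plus, 1L)
  expect_equal(plus[[1L]]$orientation, "+")
  expect_equal(nrow(plus[[1L]]$anchors), 10L)
  minus <- chain_anchors(mk(9:0), max_gap = 5, min_block_size = 5)
  expect_length(minus, 1L)
  expect_equal(minus[[1L]]$orientation, "-")
  expect_equal(nrow(minus[[1L]]$anchors), 10L)
})

test_that("top chain score matches exhaustive enumeration on seeded instances", {
  for (seed in 1:25) {
    anchors <- random_anchor_set(n_anchors = sample(10:30, 1L), grid = 50L,
                                 seed = seed)
    for (gp in c(0.05, 1)) {
      blocks <- chain_anchors(anchors, max_gap = 10L, min_block_size = 1L,
                              gap_penalty = gp)
      top <- max(vapply(blocks, `[[`, 1, "score"))
      expect_equal(top, oracle_best_over_orientations(anchors, 10L, gp))
    }
  }
})

test_that("chaining responds monotonically to its parameters", {
  for (seed in 1:10) {
    anchors <- random_anchor_set(40L, grid = 40L, seed = seed)
    n_prev <- Inf
    for (mbs in c(2L, 4L, 6L)) {
      n <- length(chain_anchors(anchors, min_block_size = mbs))
      expect_lte(n, n_prev)
      n_prev <- n
    }
    top_prev <- -Inf
    for (mg in c(3L, 10L, 25L)) {
      b <- chain_anchors(anchors, max_gap = mg, min_block_size = 1L)
      top <- max(vapply(b, `[[`, 1, "score"))
      expect_gte(top, top_prev)
      top_prev <- top
    }
  }
})

test_that("swapping genomes transposes blocks with identical anchor sets", {
  b <- simulate_clade(sim_config(seed = 19, n_chromosomes = 2,
                                 genes_per_chromosome = 50,
                                 tips = c("u", "v")))
  pr <- b$ortholog_pairs[["u|v"]]
  fwd <- chain_anchors(build_anchors(pr, b$tips$u, b$tips$v))
  rev_pairs <- data.frame(gene_a = pr$gene_b, gene_b = pr$gene_a)
  bwd <- chain_anchors(build_anchors(rev_pairs, b$tips$v, b$tips$u))
  expect_equal(length(fwd), length(bwd))
  shape <- function(bl, flip) {
    s <- blocks_summary(bl)
    if (flip) {
      tmp <- s$chr_a; s$chr_a <- s$chr_b; s$chr_b <- tmp
    }
    sort(paste(s$chr_a, s$chr_b, s$orientation, s$n_anchors))
  }
  expect_identical(shape(fwd, FALSE), shape(bwd, TRUE))
  pairs_of <- function(bl, flip) sort(unlist(lapply(bl, function(b) {
    a <- b$anchors
    if (flip) paste(a$gene_b, a$gene_a) else paste(a$gene_a, a$gene_b)
  })))
  expect_identical(pairs_of(fwd, FALSE), pairs_of(bwd, TRUE))
})

test_that("depth ratios read 1:1 for sister tips and 1:3 after a triplication", {
  b <- simulate_clade(sim_config(seed = 29, n_chromosomes = 3,
                                 genes_per_chromosome = 70,
                                 tips = c("s1", "s2")))
  blocks <- clade_blocks(b)[["s2"]]
  expect_equal(estimate_depth_ratio(blocks, b$tips$s1, b$tips$s2)$ratio,
               "1:1")
  anc <- simulate_ancestor(3, 70, seed = 30)
  w <- apply_wgt(anc, retention = 1, seed = 31)
  wb <- chain_anchors(build_anchors(wgt_pairs(anc, w), anc, w$genome))
  expect_equal(estimate_depth_ratio(wb, anc, w$genome)$ratio, "1:3")
  expect_warning(out <- estimate_depth_ratio(
    structure(list(), class = "collinear_blocks"), anc, w$genome), "empty")
  expect_equal(out$ratio, "0:0")
})

test_that("block classification recovers simulated rearrangement labels", {
  g <- simulate_ancestor(2, 80, seed = 51, species = "ref")
  evs <- list(list(type = "inversion", chrom = "chr1", from = 20L, to = 40L),
              list(type = "translocation", chrom_a = "chr1",
                   chrom_b = "chr2", len_a = 15L, len_b = 12L))
  der <- apply_rearrangements(g, evs)$genome
  der$species <- "der"
  blocks <- classify_blocks(chain_anchors(build_anchors(self_pairs(g), g,
                                                        der)))
  smry <- blocks_summary(blocks)
  expect_true(any(smry$classification == "inversion" &
                    smry$orientation == "-"))
  # the inverted interval 20..40 is recovered up to boundary anchors that a
  # flanking collinear chain may absorb
  inv <- smry[smry$classification == "inversion", ]
  expect_true(any(inv$a_start <= 23 & inv$a_end >= 37))
  expect_true(any(smry$classification == "translocation" &
                    smry$chr_a != smry$chr_b))
  expect_true(any(smry$classification == "syntenic"))
})

test_that("a single collinear comparison is labeled syntenic", {
  g <- simulate_ancestor(1, 40, seed = 3)
  blocks <- classify_blocks(chain_anchors(build_anchors(self_pairs(g), g, g)))
  expect_length(blocks, 1L)
  expect_equal(blocks[[1L]]$classification, "syntenic")
})

test_that("overlapping lower-scoring blocks are labeled duplication", {
  g <- simulate_ancestor(1, 60, seed = 71, species = "ref")
  # duplicate a segment: genes 10..29 copied onto a second chromosome of a
  # derived genome, so two blocks overlap on the reference interval
  seg <- g$genes[g$genes$rank %in% 10:29, ]
  cols <- c("gene_id", "chrom", "start", "end", "strand")
  der_genes <- rbind(
    transform(g$genes[cols], gene_id = paste0("d_", gene_id)),
    data.frame(gene_id = paste0("dup_", seg$gene_id), chrom = "chr_extra",
               start = seq_len(nrow(seg)) * 1000L,
               end = seq_len(nrow(seg)) * 1000L + 500L,
               strand = seg$strand))
  der <- genome("der", der_genes)
  pairs <- rbind(
    data.frame(gene_a = g$genes$gene_id,
               gene_b = paste0("d_", g$genes$gene_id)),
    data.frame(gene_a = seg$gene_id, gene_b = paste0("dup_", seg$gene_id)))
  blocks <- classify_blocks(chain_anchors(build_anchors(pairs, g, der)))
  smry <- blocks_summary(blocks)
  expect_true("duplication" %in% smry$classification)
  dup <- smry[smry$classification == "duplication", ]
  expect_true(all(dup$score < max(smry$score)))
})
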