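test_that("NG86 worked examples match hand enumeration", {
  expect_equal(ks_ng86(c("ATGGCT", "ATGGCT"))$ks, 0)
  expect_equal(ks_ng86(c("ATGGCT", "ATGGCT"))$ka, 0)

  est <- ks_ng86(c("ATGGCTGCT", "ATGGCCGCT"))
  expect_equal(est$S, 2)
  expect_equal(est$N, 7)
  expect_equal(est$Sd, 1)
  expect_equal(est$Nd, 0)
  expect_equal(est$pS, 0.5)
  expect_equal(est$ks, -0.75 * log(1 / 3), tolerance = 1e-12)

  sat <- ks_ng86(c("ATGTTT", "ATGTTC"))
  expect_true(sat$saturated)
  expect_true(is.na(sat$ks))
  expect_equal(sat$pS, 3)  # Sd/S = 1 / (1/3)
})

test_that("NG86 matches the enumeration oracle exactly on random pairs", {
  set.seed(202)
  for (i in 1:120) {
    n <- sample(5:40, 1L)
    a <- random_codon_seq(n)
    b <- random_codon_seq(n)
    est <- ks_ng86(c(a, b))
    orc <- oracle_ng86(a, b)
    expect_equal(est$S, orc$S, tolerance = 1e-10)
    expect_equal(est$N, orc$N, tolerance = 1e-10)
    expect_equal(est$Sd, orc$Sd, tolerance = 1e-10)
    expect_equal(est$Nd, orc$Nd, tolerance = 1e-10)
    expect_equal(est$S + est$N, 3 * n)
  }
})

test_that("ks is monotonically increasing in pS below saturation", {
  ps <- seq(0.01, 0.74, by = 0.01)
  ks <- -0.75 * log(1 - 4 * ps / 3)
  expect_true(all(diff(ks) > 0))
})

test_that("codon alignment handles identity, deletions and internal stops", {
  a <- "ATGGCTACTGGTAAA"
  aln <- align_codons(a, a)
  expect_equal(aln$n_codons_ungapped, 5L)
  expect_false(any(aln$codons_a == "---"))

  b <- "ATGGCTGGTAAA"  # ACT codon deleted
  aln2 <- align_codons(a, b)
  expect_equal(sum(aln2$codons_b == "---"), 1L)
  expect_equal(aln2$n_codons_ungapped, 4L)

  expect_error(align_codons("ATGTAAGCT", a), "internal stop")
})

test_that("protein alignment score equals the DP oracle on toy sequences", {
  # linear-gap scoring: custom match/mismatch matrix, zero gap opening
  aas <- c("A", "R", "N", "D", "C", "G", "H", "I", "L", "M")
  subm <- matrix(-1, 10, 10, dimnames = list(aas, aas))
  diag(subm) <- 2
  set.seed(31)
  codon_of <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
                G = "GGT", H = "CAT", I = "ATT", L = "CTT", M = "ATG")
  for (i in 1:15) {
    pa <- paste0(sample(aas, sample(4:10, 1), replace = TRUE), collapse = "")
    pb <- paste0(sample(aas, sample(4:10, 1), replace = TRUE), collapse = "")
    ca <- paste0(codon_of[strsplit(pa, "")[[1L]]], collapse = "")
    cb <- paste0(codon_of[strsplit(pb, "")[[1L]]], collapse = "")
    aln <- align_codons(ca, cb, substitution_matrix = subm,
                        gap_opening = 0, gap_extension = 3)
    expect_equal(aln$score, oracle_nw_score(pa, pb, 2, -1, 3))
  }
})

test_that("block median Ks summarises anchors and ignores saturated pairs", {
  blk <- list(anchors = data.frame(gene_a = c("a1", "a2", "a3"),
                                   gene_b = c("b1", "b2", "b3")))
  ks <- c("a1|b1" = 0.1, "a2|b2" = 0.2, "a3|b3" = 0.3)
  expect_equal(block_median_ks(blk, ks), 0.2)
  expect_true(is.na(block_median_ks(blk, c("a1|b1" = NA, "a2|b2" = NA,
                                           "a3|b3" = NA))))
  # median equals a sort-based oracle on random blocks
  set.seed(404)
  for (i in 1:200) {
    n <- sample(1:20, 1L)
    v <- stats::setNames(runif(n, 0, 3), paste0("a", 1:n, "|b", 1:n))
    blk <- list(anchors = data.frame(gene_a = paste0("a", 1:n),
                                     gene_b = paste0("b", 1:n)))
    srt <- sort(v)
    manual <- if (n %% 2L) srt[(n + 1L) / 2L] else
      (srt[n / 2L] + srt[n / 2L + 1L]) / 2
    expect_equal(block_median_ks(blk, v), unname(manual))
  }
})

test_that("per-anchor Ks propagates to block medians", {
  cfg <- sim_config(seed = 61, n_chromosomes = 1, genes_per_chromosome = 30,
                    tips = c("p", "q"), with_cds = TRUE, n_codons = 60,
                    ks_tip = 0.15, n_inversions = 0, n_translocations = 0)
  b <- simulate_clade(cfg)
  blocks <- clade_blocks(b, "p")[["q"]]
  res <- compute_block_ks(blocks, b$tips$p$cds, b$tips$q$cds)
  expect_true(all(!is.na(vapply(res$blocks, `[[`, 1, "median_ks"))))
  expect_gt(stats::median(res$pairs$ks, na.rm = TRUE), 0.1)
  expect_lt(stats::median(res$pairs$ks, na.rm = TRUE), 0.6)
})
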