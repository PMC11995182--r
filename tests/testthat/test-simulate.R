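test_that("ancestor simulation is deterministic with the expected layout", {
  g <- simulate_ancestor(8, 100, seed = 1)
  expect_equal(length(g$chromosomes), 8L)
  expect_equal(nrow(g$genes), 800L)
  expect_true(all(table(g$genes$chrom) == 100L))
  # dense ranks
  expect_equal(sort(g$genes$rank[g$genes$chrom == "chr1"]), 0:99)
  expect_identical(g, simulate_ancestor(8, 100, seed = 1))
  g2 <- simulate_ancestor(8, 100, seed = 2)
  expect_false(identical(g$genes$strand, g2$genes$strand))
})

test_that("whole-genome triplication bookkeeping and retention are correct", {
  anc <- simulate_ancestor(8, 100, seed = 1)
  w <- apply_wgt(anc, retention = 1, seed = 2)
  expect_equal(nrow(w$genome$genes), 2400L)
  expect_equal(length(w$genome$chromosomes), 24L)
  expect_equal(nrow(w$truth_pairs), 1600L)
  # every duplicate maps back to a copy-1 gene that exists
  expect_true(all(w$truth_pairs$gene_a %in% anc$genes$gene_id))
  expect_true(all(w$truth_pairs$gene_b %in% w$genome$genes$gene_id))
  # retention 0.3: kept duplicates within the 99% binomial interval of
  # Binomial(1600, 0.3)
  w3 <- apply_wgt(anc, retention = 0.3, seed = 5)
  kept <- nrow(w3$truth_pairs)
  ci <- qbinom(c(0.005, 0.995), 1600, 0.3)
  expect_gte(kept, ci[1L])
  expect_lte(kept, ci[2L])
})

test_that("rearrangements conserve gene content and replay exactly", {
  g <- simulate_ancestor(4, 60, seed = 3)
  inv <- list(type = "inversion", chrom = "chr2", from = 10L, to = 20L)
  out <- apply_rearrangements(g, list(inv))$genome
  seg_old <- g$genes[g$genes$chrom == "chr2" & g$genes$rank %in% 10:20, ]
  seg_new <- out$genes[out$genes$chrom == "chr2" & out$genes$rank %in% 10:20, ]
  expect_equal(seg_new$gene_id[order(seg_new$rank)],
               rev(seg_old$gene_id[order(seg_old$rank)]))
  expect_true(all(seg_new$strand[match(seg_old$gene_id, seg_new$gene_id)] !=
                    seg_old$strand))
  untouched_old <- g$genes[!(g$genes$chrom == "chr2" &
                               g$genes$rank %in% 10:20), ]
  untouched_new <- out$genes[match(untouched_old$gene_id,
                                   out$genes$gene_id), ]
  expect_equal(untouched_old$rank, untouched_new$rank)

  tr <- list(type = "translocation", chrom_a = "chr1", chrom_b = "chr3",
             len_a = 12L, len_b = 7L)
  out2 <- apply_rearrangements(g, list(tr))$genome
  expect_equal(length(out2$chromosomes), length(g$chromosomes))
  expect_equal(sum(out2$genes$chrom == "chr1"), 60L - 12L + 7L)
  expect_equal(sum(out2$genes$chrom == "chr3"), 60L - 7L + 12L)
  expect_setequal(out2$genes$gene_id, g$genes$gene_id)

  # replaying the emitted log reproduces the output genome exactly
  evs <- list(inv, tr, list(type = "fission", chrom = "chr4", at = 30L))
  res <- apply_rearrangements(g, evs)
  expect_identical(replay_events(g, res$log)$genes, res$genome$genes)
})

test_that("fusion and fission change chromosome counts by one", {
  g <- simulate_ancestor(3, 30, seed = 8)
  fu <- apply_rearrangements(g, list(list(type = "fusion", chrom_a = "chr1",
                                          chrom_b = "chr2")))$genome
  expect_equal(length(fu$chromosomes), 2L)
  expect_equal(nrow(fu$genes), nrow(g$genes))
  fi <- apply_rearrangements(g, list(list(type = "fission", chrom = "chr1",
                                          at = 10L)))$genome
  expect_equal(length(fi$chromosomes), 4L)
  expect_equal(sum(fi$genes$chrom == "chr1"), 10L)
})

test_that("invalid events are rejected before any change", {
  g <- simulate_ancestor(2, 20, seed = 1)
  expect_error(apply_rearrangements(g, list(
    list(type = "inversion", chrom = "chr1", from = 5L, to = 25L))),
    "out of range")
  expect_error(apply_rearrangements(g, list(
    list(type = "translocation", chrom_a = "chr1", chrom_b = "chr1",
         len_a = 3L, len_b = 3L))), "distinct")
})

test_that("clade simulation is deterministic and truth pairs resolve", {
  cfg <- sim_config(seed = 33, n_chromosomes = 3, genes_per_chromosome = 50,
                    tips = c("x", "y"), wgt = TRUE, wgt_retention = 0.6)
  b1 <- simulate_clade(cfg)
  b2 <- simulate_clade(cfg)
  expect_identical(b1$tips$x$genes, b2$tips$x$genes)
  expect_identical(b1$event_log, b2$event_log)
  for (key in names(b1$ortholog_pairs)) {
    p <- b1$ortholog_pairs[[key]]
    sp <- strsplit(key, "|", fixed = TRUE)[[1L]]
    expect_true(all(p$gene_a %in% b1$tips[[sp[1L]]]$genes$gene_id))
    expect_true(all(p$gene_b %in% b1$tips[[sp[2L]]]$genes$gene_id))
  }
})

test_that("fixture emission is complete, deterministic, and round-trips", {
  cfg <- sim_config(seed = 44, n_chromosomes = 2, genes_per_chromosome = 30,
                    tips = c("t1", "t2", "t3"), wgt = TRUE,
                    wgt_retention = 0.7, with_cds = TRUE, n_codons = 60,
                    ks_tip = 0.05)
  b <- simulate_clade(cfg)
  d1 <- withr::local_tempdir()
  paths <- emit_fixtures(b, d1)
  expect_length(paths, 3L * 3L + 1L)  # bed + fasta + pairs per tip + truth
  # byte-identical on re-simulation + re-emission
  d2 <- withr::local_tempdir()
  emit_fixtures(simulate_clade(cfg), d2)
  for (p in paths) {
    q <- file.path(d2, basename(p))
    expect_identical(readLines(p), readLines(q))
  }
  # round-trip through the package readers
  g <- read_gene_positions(file.path(d1, "t2.bed"), species = "t2")
  cols <- c("gene_id", "chrom", "start", "end", "strand", "rank")
  expect_identical(g$genes[cols], b$tips$t2$genes[cols])
  expect_identical(read_cds_fasta(file.path(d1, "t2.cds.fasta")),
                   b$tips$t2$cds)
})
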