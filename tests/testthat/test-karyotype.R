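test_that("identical genomes give one ancestral block per chromosome", {
  b <- simulate_clade(sim_config(seed = 2, n_chromosomes = 3,
                                 genes_per_chromosome = 40,
                                 tips = c("r", "s"), n_inversions = 0,
                                 n_translocations = 0))
  bl <- clade_blocks(b, "r")
  bs <- partition_ancestral_blocks(bl, b$tips$r)
  expect_equal(nrow(bs$blocks), 3L)
  expect_equal(sort(unique(bs$blocks$chrom)), c("chr1", "chr2", "chr3"))
  kar <- linearize_cars(score_adjacencies(bs),
                        block_ids = bs$blocks$block_id)
  expect_equal(kar$n_chromosomes, 3L)
  for (p in bs$projections) {
    ev <- classify_rearrangements(kar, p)
    expect_equal(unlist(ev[c("fusion", "fission", "translocation",
                             "inversion")]),
                 c(fusion = 0L, fission = 0L, translocation = 0L,
                   inversion = 0L))
  }
})

test_that("translocation-only tips reproduce the true breakpoint segmentation", {
  cfg <- sim_config(seed = 62, tips = c("r", "s", "t"), n_inversions = 0,
                    n_translocations = 1)
  b <- simulate_clade(cfg)
  bl <- clade_blocks(b, "r")
  bs <- partition_ancestral_blocks(bl, b$tips$r)
  # every breakpoint stems from one of the 3 reciprocal translocations:
  # 8 chromosomes + 2 extra segments per translocation-affected chromosome
  n_affected <- length(unique(unlist(lapply(b$event_log[c("r", "s", "t")],
    function(evs) unlist(lapply(evs, function(e)
      c(e$chrom_a, e$chrom_b)))))))
  expect_gte(nrow(bs$blocks), 8L)
  expect_lte(nrow(bs$blocks), 8L + 2L * n_affected)
  # dropping one species never refines the segmentation
  bs2 <- partition_ancestral_blocks(bl["s"], b$tips$r)
  expect_lte(nrow(bs2$blocks), nrow(bs$blocks))
})

test_that("adjacency weights equal per-species counts and honor Dollo", {
  b <- simulate_clade(sim_config(seed = 3, n_chromosomes = 2,
                                 genes_per_chromosome = 60,
                                 tips = c("r", "s", "t"), n_inversions = 0,
                                 n_translocations = 0))
  bl <- clade_blocks(b, "r")
  bs <- partition_ancestral_blocks(bl, b$tips$r)
  adj <- score_adjacencies(bs)
  # identical genomes: every adjacency is present in all three species
  expect_true(all(adj$weight == 3))
  # brute-force recount from the projections
  for (i in seq_len(nrow(adj))) {
    n <- 0L
    for (sp in names(bs$projections)) {
      d <- bs$projections[[sp]]
      for (j in seq_len(nrow(d) - 1L)) {
        if (d$chrom[j] != d$chrom[j + 1L]) next
        k <- syntevo:::adjacency_key(d$block_id[j], d$orientation[j],
                                     d$block_id[j + 1L],
                                     d$orientation[j + 1L])
        if (k == paste(adj$end1[i], adj$end2[i], sep = "--")) n <- n + 1L
      }
    }
    expect_equal(adj$weight[i], n)
  }
  # Dollo: an adjacency private to one side of the root gets weight 0
  tree <- ape::read.tree(text = "((r,s),t);")
  fused <- apply_rearrangements(b$tips$s,
    list(list(type = "fusion", chrom_a = "chr1", chrom_b = "chr2")))$genome
  pr <- b$ortholog_pairs[["r|s"]]
  bl2 <- bl
  bl2[["s"]] <- chain_anchors(build_anchors(pr, b$tips$r, fused),
                              species_a = "r", species_b = "s")
  bs2 <- partition_ancestral_blocks(bl2, b$tips$r)
  adj2 <- score_adjacencies(bs2, species_tree = tree)
  private <- adj2[adj2$species == "s", ]
  expect_true(all(private$weight == 0))
  shared <- adj2[grepl("r", adj2$species) & grepl("t", adj2$species), ]
  expect_true(all(shared$weight > 0))
})

test_that("greedy linearization respects weights and path structure", {
  # 8 disjoint two-block chains -> 8 CARs
  adj <- data.frame(end1 = sprintf("b%02d:H", 1:8),
                    end2 = sprintf("c%02d:T", 1:8),
                    weight = 2, species = "x,y",
                    stringsAsFactors = FALSE)
  kar <- linearize_cars(structure(adj,
                                  class = c("adjacency_graph", "data.frame")))
  expect_equal(kar$n_chromosomes, 8L)
  expect_true(all(vapply(kar$cars, nrow, 1L) == 2L))
  # conflicting extremity: the weight-3 edge wins over weight-1
  adj2 <- data.frame(end1 = c("x:H", "x:H"), end2 = c("y:T", "z:T"),
                     weight = c(3, 1), species = c("a,b,c", "a"),
                     stringsAsFactors = FALSE)
  kar2 <- linearize_cars(structure(adj2,
                                   class = c("adjacency_graph", "data.frame")),
                         min_weight = 1)
  joined <- vapply(kar2$cars, function(d) paste(d$block_id, collapse = "-"),
                   character(1L))
  expect_true(any(grepl("^x-y$|^y-x$", joined)))
  expect_true("z" %in% unlist(lapply(kar2$cars, `[[`, "block_id")))
})

test_that("simulated clades recover the ancestral chromosome number and events", {
  recovered <- 0L
  for (seed in 1:8) {
    cfg <- sim_config(seed = 300 + seed, tips = c("r", "s", "t"),
                      n_inversions = 1, n_translocations = 1)
    b <- simulate_clade(cfg)
    bl <- clade_blocks(b, "r")
    bs <- partition_ancestral_blocks(bl, b$tips$r)
    kar <- linearize_cars(score_adjacencies(bs),
                          block_ids = bs$blocks$block_id)
    if (kar$n_chromosomes == 8L) recovered <- recovered + 1L
    for (sp in names(bs$projections)) {
      ev <- classify_rearrangements(kar, bs$projections[[sp]])
      expect_equal(ev$fusion, 0L)
      expect_equal(ev$fission, 0L)
      expect_equal(ev$translocation, 1L)
      expect_equal(ev$inversion, 1L)
    }
  }
  expect_gte(recovered, 7L)
})

test_that("a fused descendant is classified as one fusion", {
  cfg <- sim_config(seed = 5, tips = c("r", "s", "t"), n_inversions = 0,
                    n_translocations = 0)
  b <- simulate_clade(cfg)
  fused <- apply_rearrangements(b$tips$s,
    list(list(type = "fusion", chrom_a = "chr1", chrom_b = "chr2")))$genome
  bl <- clade_blocks(b, "r")
  bl[["s"]] <- chain_anchors(build_anchors(b$ortholog_pairs[["r|s"]],
                                           b$tips$r, fused),
                             species_a = "r", species_b = "s")
  bs <- partition_ancestral_blocks(bl, b$tips$r)
  kar <- linearize_cars(score_adjacencies(bs),
                        block_ids = bs$blocks$block_id)
  expect_equal(kar$n_chromosomes, 8L)
  ev <- classify_rearrangements(kar, bs$projections$s)
  expect_equal(ev$fusion, 1L)
  expect_equal(ev$fission, 0L)
  evr <- classify_rearrangements(kar, bs$projections$r)
  expect_equal(evr$fusion + evr$fission, 0L)
})
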