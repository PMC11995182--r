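# Small fixture builders shared across test files.

# identity homolog pairs of a genome against itself (or a renamed copy)
self_pairs <- function(g) {
  data.frame(gene_a = g$genes$gene_id, gene_b = g$genes$gene_id,
             stringsAsFactors = FALSE)
}

# homolog pairs between an ancestor and a post-WGT genome: copy-1 genes keep
# ancestral ids; duplicated copies come from the truth pairs
wgt_pairs <- function(ancestor, wgt) {
  rbind(self_pairs(ancestor),
        stats::setNames(wgt$truth_pairs, c("gene_a", "gene_b")))
}

# random anchor set on an n x n rank grid (single chromosome pair)
random_anchor_set <- function(n_anchors, grid = 50L, seed = 1L) {
  set.seed(seed)
  cells <- sample(grid * grid, n_anchors)
  data.frame(gene_a = sprintf("a%03d", seq_len(n_anchors)),
             gene_b = sprintf("b%03d", seq_len(n_anchors)),
             chr_a = "chrA", rank_a = (cells - 1L) %/% grid,
             chr_b = "chrB", rank_b = (cells - 1L) %% grid,
             strand_match = "same", score = 1,
             stringsAsFactors = FALSE)
}

# blocks between a reference tip and the other tips of a clade bundle
clade_blocks <- function(bundle, ref_name = names(bundle$tips)[1L], ...) {
  ref <- bundle$tips[[ref_name]]
  others <- setdiff(names(bundle$tips), ref_name)
  out <- lapply(others, function(tn) {
    pr <- bundle$ortholog_pairs[[paste(ref_name, tn, sep = "|")]]
    chain_anchors(build_anchors(pr, ref, bundle$tips[[tn]]),
                  species_a = ref_name, species_b = tn, ...)
  })
  names(out) <- others
  out
}
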