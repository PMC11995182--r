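#' Collinear gene retention along a reference genome
#'
#' A reference gene counts as retained iff it is an anchor in at least one
#' collinear block (blocks must have been computed with the reference as
#' genome_a). Retention is reported overall and in sliding rank windows
#' along every reference chromosome.
#'
#' @param reference the reference [genome].
#' @param blocks a \code{collinear_blocks} object with the reference as
#'   genome_a.
#' @param window_size window size in ranks (default 100; refuse below 5).
#' @param step window step in ranks (default 50). With \code{step ==
#'   window_size} the windows partition each chromosome and the weighted
#'   mean of window fractions equals the overall fraction exactly.
#' @return A \code{retention_profile}: data.frame with chrom, start_rank,
#'   end_rank (half-open), n_reference_genes, n_retained and fraction;
#'   attributes \code{overall}, \code{window_size}, \code{step}.
#' @export
retention_profile <- function(reference, blocks, window_size = 100L,
                              step = 50L) {
  if (window_size < 5L)
    stop("window_size < 5 gives unstable retention estimates; refusing")
  if (step < 1L) stop("step must be >= 1")
  retained_ids <- unique(unlist(lapply(blocks, function(b) b$anchors$gene_a)))
  genes <- reference$genes
  genes$retained <- genes$gene_id %in% retained_ids
  rows <- list()
  for (ch in reference$chromosomes) {
    sub <- genes[genes$chrom == ch, , drop = FALSE]
    n <- nrow(sub)
    if (!n) next
    starts <- seq.int(0L, max(0L, n - 1L), by = step)
    starts <- starts[starts < n]
    ends <- pmin(starts + window_size, n)
    for (i in seq_along(starts)) {
      sel <- sub$rank >= starts[i] & sub$rank < ends[i]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start_rank = starts[i], end_rank = ends[i],
        n_reference_genes = sum(sel), n_retained = sum(sub$retained[sel]),
        stringsAsFactors = FALSE)
    }
  }
  prof <- do.call(rbind, rows)
  prof$fraction <- ifelse(prof$n_reference_genes > 0,
                          prof$n_retained / prof$n_reference_genes, NA_real_)
  structure(prof, class = c("retention_profile", "data.frame"),
            overall = mean(genes$retained),
            window_size = window_size, step = step)
}

#' Overall collinear retention fraction
#'
#' Retained reference genes (anchors in >= 1 block) divided by all reference
#' genes. The denominator deliberately includes genes outside every block;
#' set \code{in_block_only = TRUE} to restrict it to genes lying inside the
#' rank span of at least one block.
#'
#' @param reference the reference [genome].
#' @param blocks a \code{collinear_blocks} object with the reference as
#'   genome_a.
#' @param in_block_only restrict the denominator to in-block genes.
#' @return retention fraction in [0, 1].
#' @export
overall_retention <- function(reference, blocks, in_block_only = FALSE) {
  retained_ids <- unique(unlist(lapply(blocks, function(b) b$anchors$gene_a)))
  genes <- reference$genes
  if (in_block_only) {
    covered <- rep(FALSE, nrow(genes))
    for (b in blocks) {
      covered <- covered | (genes$chrom == b$chr_a &
                              genes$rank >= min(b$anchors$rank_a) &
                              genes$rank <= max(b$anchors$rank_a))
    }
    genes <- genes[covered, , drop = FALSE]
  }
  if (!nrow(genes)) return(NA_real_)
  mean(genes$gene_id %in% retained_ids)
}
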