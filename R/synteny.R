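#' @title Collinear block detection in gene-rank space
#' @name synteny
#' @description Homolog pairs are lifted to rank coordinates (anchors), chained
#'   into collinear blocks per chromosome pair and orientation by dynamic
#'   programming, and classified against the dominant chromosome
#'   correspondence. Chaining in rank space matches gene-order dot plots and
#'   removes assembly-scale effects.
NULL

new_block <- function(block_id, chr_a, chr_b, orientation, score,
                      anchors, classification = "unassigned",
                      median_ks = NA_real_) {
  list(block_id = as.character(block_id), chr_a = chr_a, chr_b = chr_b,
       orientation = orientation, score = score,
       classification = classification, median_ks = median_ks,
       anchors = anchors)
}

#' Build rank-space anchors from homolog pairs
#'
#' @param pairs data.frame(gene_a, gene_b[, score]); unresolvable pairs are
#'   dropped and reported in the \code{rejects} attribute.
#' @param genome_a,genome_b the two [genome]s.
#' @return data.frame(gene_a, gene_b, chr_a, rank_a, chr_b, rank_b,
#'   strand_match, score); anchors with missing input score get score 1.
#' @export
build_anchors <- function(pairs, genome_a, genome_b) {
  ia <- gene_index(genome_a)
  ib <- gene_index(genome_b)
  ok <- pairs$gene_a %in% names(ia) & pairs$gene_b %in% names(ib)
  rejects <- pairs[!ok, , drop = FALSE]
  p <- pairs[ok, , drop = FALSE]
  ga <- genome_a$genes[ia[p$gene_a], ]
  gb <- genome_b$genes[ib[p$gene_b], ]
  score <- if ("score" %in% names(p)) p$score else rep(NA_real_, nrow(p))
  score[is.na(score)] <- 1
  anchors <- data.frame(
    gene_a = p$gene_a, gene_b = p$gene_b,
    chr_a = ga$chrom, rank_a = ga$rank,
    chr_b = gb$chrom, rank_b = gb$rank,
    strand_match = ifelse(ga$strand == gb$strand, "same", "opposite"),
    score = score, stringsAsFactors = FALSE)
  anchors <- anchors[order(anchors$chr_a, anchors$chr_b,
                           anchors$rank_a, anchors$rank_b), , drop = FALSE]
  rownames(anchors) <- NULL
  attr(anchors, "rejects") <- rejects
  anchors
}

# Best chain by DP over anchors sorted by rank_a (then rank_b): predecessors
# must be strictly smaller in both ranks with both rank gaps <= max_gap.
# Chain score = sum(anchor score) - gap_penalty * sum((da - 1) + (db - 1)).
# Returns list(idx, score) for the best chain, or NULL.
best_chain <- function(ra, rb, sc, max_gap, gap_penalty) {
  n <- length(ra)
  if (n == 0L) return(NULL)
  ord <- order(ra, rb)
  ra <- ra[ord]; rb <- rb[ord]; sc <- sc[ord]
  dp <- sc
  len <- rep(1L, n)
  prev <- rep(0L, n)
  for (j in seq_len(n)) {
    if (j == 1L) next
    for (i in seq_len(j - 1L)) {
      da <- ra[j] - ra[i]
      db <- rb[j] - rb[i]
      if (da <= 0L || db <= 0L) next
      if (da - 1L > max_gap || db - 1L > max_gap) next
      cand <- dp[i] + sc[j] - gap_penalty * ((da - 1L) + (db - 1L))
      if (cand > dp[j] + 1e-12 ||
          (abs(cand - dp[j]) <= 1e-12 && len[i] + 1L > len[j])) {
        dp[j] <- cand
        len[j] <- len[i] + 1L
        prev[j] <- i
      }
    }
  }
  best <- which.max(dp + 1e-9 * len)  # favour longer chains on score ties
  idx <- integer(0L)
  j <- best
  while (j != 0L) {
    idx <- c(j, idx)
    j <- prev[j]
  }
  list(idx = ord[idx], score = dp[best])
}

#' Chain anchors into collinear blocks
#'
#' Chaining runs separately per (chr_a, chr_b) pair and per orientation
#' ("+": rank_b ascending; "-": rank_b descending). Within a group anchors are
#' partitioned greedily: the maximal-scoring chain is extracted, its anchors
#' removed, and the search repeated; an anchor joins at most one block.
#' Chains shorter than \code{min_block_size} are discarded.
#'
#' @param anchors output of [build_anchors].
#' @param max_gap maximum rank gap (ranks skipped) between consecutive
#'   anchors, in each genome (default 25).
#' @param min_block_size minimum anchors per block (default 5).
#' @param gap_penalty score penalty per rank of gap (default 0.05, a
#'   match:gap ratio in line with common collinearity chaining practice).
#' @param species_a,species_b labels stored on the result.
#' @return A \code{collinear_blocks} object: list of blocks, each with
#'   \code{block_id}, \code{chr_a}, \code{chr_b}, \code{orientation},
#'   \code{score}, \code{classification}, \code{median_ks} and an
#'   \code{anchors} data.frame ordered by ascending rank_a.
#' @export
chain_anchors <- function(anchors, max_gap = 25L, min_block_size = 5L,
                          gap_penalty = 0.05, species_a = "a", species_b = "b") {
  groups <- split(seq_len(nrow(anchors)),
                  paste(anchors$chr_a, anchors$chr_b, sep = "\r"))
  groups <- groups[order(names(groups))]
  blocks <- list()
  for (gi in groups) {
    sub <- anchors[gi, , drop = FALSE]
    avail <- rep(TRUE, nrow(sub))  # an anchor joins at most one block
    repeat {
      idx_avail <- which(avail)
      if (length(idx_avail) < min_block_size) break
      cand <- list()
      for (orientation in c("+", "-")) {
        rb <- if (orientation == "+") sub$rank_b else -sub$rank_b
        ch <- best_chain(sub$rank_a[idx_avail], rb[idx_avail],
                         sub$score[idx_avail], max_gap, gap_penalty)
        if (!is.null(ch) && length(ch$idx) >= min_block_size)
          cand[[orientation]] <- ch
      }
      if (!length(cand)) break
      scores <- vapply(cand, `[[`, numeric(1L), "score")
      sizes <- vapply(cand, function(c) length(c$idx), integer(1L))
      pick <- names(cand)[order(-scores, -sizes, names(cand))][1L]
      ch <- cand[[pick]]
      sel <- idx_avail[ch$idx]
      avail[sel] <- FALSE
      banchors <- sub[sel, , drop = FALSE]
      banchors <- banchors[order(banchors$rank_a), , drop = FALSE]
      rownames(banchors) <- NULL
      attr(banchors, "rejects") <- NULL
      blocks[[length(blocks) + 1L]] <-
        new_block(block_id = "", chr_a = banchors$chr_a[1L],
                  chr_b = banchors$chr_b[1L], orientation = pick,
                  score = ch$score, anchors = banchors)
    }
  }
  # deterministic order and ids: by descending score, anchor count, names
  if (length(blocks)) {
    keys <- vapply(blocks, function(b)
      sprintf("%020.6f|%06d|%s|%s|%s", 1e9 - b$score, 1e6 - nrow(b$anchors),
              b$chr_a, b$chr_b, b$orientation), character(1L))
    blocks <- blocks[order(keys)]
    for (i in seq_along(blocks)) blocks[[i]]$block_id <- sprintf("b%04d", i)
  }
  structure(blocks, class = "collinear_blocks",
            species_a = species_a, species_b = species_b)
}

#' @export
print.collinear_blocks <- function(x, ...) {
  cat(sprintf("collinear_blocks: %d block(s), %d anchors (%s vs %s)\n",
              length(x), sum(vapply(x, function(b) nrow(b$anchors), 1L)),
              attr(x, "species_a") %||% "a", attr(x, "species_b") %||% "b"))
  invisible(x)
}

#' Summarise collinear blocks as a data.frame
#' @param blocks a \code{collinear_blocks} object.
#' @return one row per block with span and classification columns.
#' @export
blocks_summary <- function(blocks) {
  if (!length(blocks))
    return(data.frame(block_id = character(0L), chr_a = character(0L),
                      chr_b = character(0L), orientation = character(0L),
                      n_anchors = integer(0L), score = numeric(0L),
                      a_start = integer(0L), a_end = integer(0L),
                      b_start = integer(0L), b_end = integer(0L),
                      classification = character(0L), median_ks = numeric(0L)))
  do.call(rbind, lapply(blocks, function(b) data.frame(
    block_id = b$block_id, chr_a = b$chr_a, chr_b = b$chr_b,
    orientation = b$orientation, n_anchors = nrow(b$anchors),
    score = b$score,
    a_start = min(b$anchors$rank_a), a_end = max(b$anchors$rank_a),
    b_start = min(b$anchors$rank_b), b_end = max(b$anchors$rank_b),
    classification = b$classification, median_ks = b$median_ks,
    stringsAsFactors = FALSE)))
}

# Maximum-weight one-to-one chromosome correspondence, solved exactly with
# igraph's bipartite matching on the summed-anchor weight matrix.
dominant_pairs <- function(blocks) {
  if (!length(blocks)) return(character(0L))
  smry <- blocks_summary(blocks)
  w <- stats::aggregate(n_anchors ~ chr_a + chr_b, data = smry, FUN = sum)
  va <- paste0("A\r", sort(unique(w$chr_a)))
  vb <- paste0("B\r", sort(unique(w$chr_b)))
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(c(va, vb), type = c(rep(FALSE, length(va)),
                                         rep(TRUE, length(vb))))
  edges <- as.vector(rbind(paste0("A\r", w$chr_a), paste0("B\r", w$chr_b)))
  g <- igraph::add_edges(g, edges, weight = w$n_anchors)
  m <- igraph::max_bipartite_match(g, weights = igraph::E(g)$weight)
  mt <- m$matching[va]
  ok <- !is.na(mt)
  paste(sub("^A\r", "", va[ok]), sub("^B\r", "", mt[ok]), sep = "\r")
}

#' Classify collinear blocks at gene-order resolution
#'
#' A dominant one-to-one chromosome correspondence is computed first by
#' maximum-weight bipartite matching on summed block anchors. Blocks are then
#' labeled: \emph{syntenic} ("+" orientation on a dominant pair),
#' \emph{inversion} ("-" on a dominant pair), \emph{translocation} (any
#' orientation on a non-dominant pair), and \emph{duplication} (a block whose
#' rank interval on either genome overlaps a higher-scoring block's interval
#' by more than \code{overlap_frac}).
#'
#' @param blocks a \code{collinear_blocks} object.
#' @param overlap_frac overlap fraction above which the lower-scoring block is
#'   a duplication (default 0.5).
#' @return the blocks with \code{classification} filled in.
#' @export
classify_blocks <- function(blocks, overlap_frac = 0.5) {
  if (!length(blocks)) return(blocks)
  dom <- dominant_pairs(blocks)
  smry <- blocks_summary(blocks)
  n <- length(blocks)
  cls <- character(n)
  for (i in seq_len(n)) {
    key <- paste(smry$chr_a[i], smry$chr_b[i], sep = "\r")
    cls[i] <- if (key %in% dom) {
      if (smry$orientation[i] == "+") "syntenic" else "inversion"
    } else "translocation"
  }
  # duplication override: > overlap_frac rank-interval overlap with a
  # higher-scoring block on exactly one genome side. Overlap on both sides
  # is the same region pair seen twice (e.g. an inverted segment nested in
  # a syntenic span), not a duplication.
  ord <- order(-smry$score, -smry$n_anchors)
  ovl <- function(s1, e1, s2, e2) {
    inter <- min(e1, e2) - max(s1, s2) + 1L
    if (inter <= 0L) return(0)
    inter / (e1 - s1 + 1L)
  }
  for (pos in seq_along(ord)) {
    i <- ord[pos]
    if (pos == 1L) next
    for (qos in seq_len(pos - 1L)) {
      j <- ord[qos]
      dup_a <- smry$chr_a[i] == smry$chr_a[j] &&
        ovl(smry$a_start[i], smry$a_end[i],
            smry$a_start[j], smry$a_end[j]) > overlap_frac
      dup_b <- smry$chr_b[i] == smry$chr_b[j] &&
        ovl(smry$b_start[i], smry$b_end[i],
            smry$b_start[j], smry$b_end[j]) > overlap_frac
      if (xor(dup_a, dup_b)) {
        cls[i] <- "duplication"
        break
      }
    }
  }
  for (i in seq_len(n)) blocks[[i]]$classification <- cls[i]
  blocks
}

#' Estimate the syntenic depth ratio between two genomes
#'
#' Counts, for every gene, the number of blocks whose rank span on that
#' genome covers the gene, and reports the modal nonzero coverage on each
#' side as a ratio string "m:n": a typical genome_a gene lies in n blocks
#' (n matching regions in b per a region is m... see Details).
#'
#' @details The ratio is printed as \code{modal_b:modal_a} where
#'   \code{modal_a} is the modal nonzero number of blocks covering a
#'   genome_a gene and \code{modal_b} the same for genome_b. After an
#'   unshared triplication in genome_b, every genome_a gene is covered by 3
#'   blocks and every genome_b gene by 1, giving "1:3".
#'
#' @param blocks a \code{collinear_blocks} object.
#' @param genome_a,genome_b the two [genome]s.
#' @return list with \code{ratio} (string), \code{modal_a}, \code{modal_b},
#'   and per-genome coverage histograms (fractions of genes covered by
#'   0, 1, 2, 3+ blocks).
#' @export
estimate_depth_ratio <- function(blocks, genome_a, genome_b) {
  cov_a <- integer(nrow(genome_a$genes))
  cov_b <- integer(nrow(genome_b$genes))
  if (!length(blocks)) {
    warning("empty block list: depth ratio undefined, reporting 0:0")
    return(list(ratio = "0:0", modal_a = 0L, modal_b = 0L,
                hist_a = c(`0` = 1), hist_b = c(`0` = 1)))
  }
  for (b in blocks) {
    sel_a <- genome_a$genes$chrom == b$chr_a &
      genome_a$genes$rank >= min(b$anchors$rank_a) &
      genome_a$genes$rank <= max(b$anchors$rank_a)
    sel_b <- genome_b$genes$chrom == b$chr_b &
      genome_b$genes$rank >= min(b$anchors$rank_b) &
      genome_b$genes$rank <= max(b$anchors$rank_b)
    cov_a[sel_a] <- cov_a[sel_a] + 1L
    cov_b[sel_b] <- cov_b[sel_b] + 1L
  }
  modal <- function(cv) {
    cv <- cv[cv > 0L]
    if (!length(cv)) return(0L)
    tab <- table(cv)
    as.integer(names(tab)[which.max(tab)])
  }
  hist_frac <- function(cv) {
    capped <- pmin(cv, 3L)
    tab <- table(factor(capped, levels = 0:3))
    out <- as.numeric(tab) / length(cv)
    names(out) <- c("0", "1", "2", "3+")
    out
  }
  ma <- modal(cov_a)
  mb <- modal(cov_b)
  list(ratio = paste0(mb, ":", ma), modal_a = ma, modal_b = mb,
       hist_a = hist_frac(cov_a), hist_b = hist_frac(cov_b))
}
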