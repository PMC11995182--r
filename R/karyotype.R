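#' @title Ancestral karyotype reconstruction by adjacency consensus
#' @name karyotype
#' @description Cross-species collinear blocks are reduced to a common
#'   segmentation of a reference genome (ancestral blocks), block
#'   adjacencies observed in the extant genomes are scored by consensus
#'   (optionally Dollo-filtered on a species tree), and contiguous ancestral
#'   regions (CARs) are assembled by greedy maximum-weight matching of block
#'   extremities. Per-branch rearrangements (fusion, fission, translocation,
#'   inversion) are then classified against the reconstruction.
NULL

#' Partition genomes into ancestral blocks via a reference segmentation
#'
#' The reference gene order is cut at the union of all block boundaries
#' from the pairwise comparisons; the resulting minimal segments become
#' candidate ancestral blocks. Each segment is projected into every other
#' species through the block anchors; segments supported by fewer than two
#' species (the reference plus at least one other) or shorter than
#' \code{min_block_genes} are dropped and reported.
#'
#' @param blocks_list named list (by species) of \code{collinear_blocks},
#'   each computed with the reference as genome_a.
#' @param reference the reference [genome].
#' @param min_block_genes minimum segment length in genes (default 10;
#'   micro-blocks inflate breakpoints).
#' @param min_cover minimum fraction of a segment a species block must
#'   cover to support it (default 0.8).
#' @return An \code{ancestral_block_set}: \code{blocks} (data.frame
#'   block_id, chrom, start_rank, end_rank half-open, n_genes),
#'   \code{projections} (named list of data.frames block_id, chrom, start,
#'   end, orientation, ordered along each genome; includes the reference),
#'   and \code{dropped} (segments without dual support).
#' @export
partition_ancestral_blocks <- function(blocks_list, reference,
                                       min_block_genes = 10L,
                                       min_cover = 0.8) {
  stopifnot(length(blocks_list) >= 1L, !is.null(names(blocks_list)))
  genes <- reference$genes
  cuts <- lapply(reference$chromosomes, function(ch)
    c(0L, sum(genes$chrom == ch)))
  names(cuts) <- reference$chromosomes
  for (sp in names(blocks_list)) {
    for (b in blocks_list[[sp]]) {
      ch <- b$chr_a
      if (!ch %in% names(cuts)) next
      cuts[[ch]] <- c(cuts[[ch]], min(b$anchors$rank_a),
                      max(b$anchors$rank_a) + 1L)
    }
  }
  segs <- list()
  for (ch in reference$chromosomes) {
    cp <- sort(unique(cuts[[ch]]))
    if (length(cp) < 2L) next
    for (i in seq_len(length(cp) - 1L)) {
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = ch, start_rank = cp[i], end_rank = cp[i + 1L],
        stringsAsFactors = FALSE)
    }
  }
  segs <- do.call(rbind, segs)
  segs$n_genes <- segs$end_rank - segs$start_rank
  too_short <- segs$n_genes < min_block_genes
  dropped <- segs[too_short, , drop = FALSE]
  segs <- segs[!too_short, , drop = FALSE]
  if (!nrow(segs)) stop("no segments of at least ", min_block_genes,
                        " genes; relax min_block_genes")
  segs$block_id <- sprintf("ab%03d", seq_len(nrow(segs)))
  # project every segment into each species through its best covering block
  projections <- list()
  support <- matrix(FALSE, nrow(segs), length(blocks_list),
                    dimnames = list(segs$block_id, names(blocks_list)))
  proj_rows <- list()
  for (sp in names(blocks_list)) {
    for (b in blocks_list[[sp]]) {
      a <- b$anchors
      lo <- min(a$rank_a); hi <- max(a$rank_a)
      hit <- which(segs$chrom == b$chr_a &
                     pmin(segs$end_rank - 1L, hi) -
                     pmax(segs$start_rank, lo) + 1L >=
                     min_cover * segs$n_genes)
      for (i in hit) {
        inside <- a$rank_a >= segs$start_rank[i] &
          a$rank_a < segs$end_rank[i]
        if (sum(inside) < 2L) next
        proj_rows[[length(proj_rows) + 1L]] <- data.frame(
          species = sp, block_id = segs$block_id[i], chrom = b$chr_b,
          start = min(a$rank_b[inside]), end = max(a$rank_b[inside]),
          orientation = b$orientation, n_anchors = sum(inside),
          stringsAsFactors = FALSE)
        support[i, sp] <- TRUE
      }
    }
  }
  proj <- if (length(proj_rows)) do.call(rbind, proj_rows) else
    stop("no segment is supported by any species block")
  # keep the best-supported projection per (species, segment)
  proj <- proj[order(proj$species, proj$block_id, -proj$n_anchors), ]
  proj <- proj[!duplicated(proj[, c("species", "block_id")]), ]
  supported <- rowSums(support) >= 1L  # reference + >= 1 species
  dropped <- rbind(dropped[, c("chrom", "start_rank", "end_rank", "n_genes")],
                   segs[!supported,
                        c("chrom", "start_rank", "end_rank", "n_genes")])
  segs <- segs[supported, , drop = FALSE]
  proj <- proj[proj$block_id %in% segs$block_id, , drop = FALSE]
  projections <- lapply(split(proj, proj$species), function(d) {
    d <- d[order(d$chrom, d$start), c("block_id", "chrom", "start", "end",
                                      "orientation")]
    rownames(d) <- NULL
    d
  })
  ref_proj <- data.frame(block_id = segs$block_id, chrom = segs$chrom,
                         start = segs$start_rank,
                         end = segs$end_rank - 1L, orientation = "+",
                         stringsAsFactors = FALSE)
  ref_proj <- ref_proj[order(ref_proj$chrom, ref_proj$start), ]
  rownames(ref_proj) <- NULL
  projections[[reference$species]] <- ref_proj
  rownames(segs) <- NULL
  structure(list(blocks = segs[, c("block_id", "chrom", "start_rank",
                                   "end_rank", "n_genes")],
                 projections = projections, dropped = dropped,
                 reference = reference$species),
            class = "ancestral_block_set")
}

# Oriented extremities: traversing a block in "+" orientation enters at T
# (tail) and exits at H (head).
adjacency_key <- function(x, ox, y, oy) {
  left <- paste0(x, ":", if (ox == "+") "H" else "T")
  right <- paste0(y, ":", if (oy == "+") "T" else "H")
  paste(sort(c(left, right)), collapse = "--")
}

#' Score block adjacencies across species
#'
#' Each species contributes one adjacency per pair of consecutive oriented
#' blocks on a chromosome; the weight of an adjacency is the number of
#' species exhibiting it. With a rooted species tree, an adjacency is an
#' ancestral candidate only if observed in species on both sides of the
#' root (Dollo criterion); others get weight 0.
#'
#' @param block_set an \code{ancestral_block_set}.
#' @param species_tree optional rooted \code{ape::phylo} whose tip labels
#'   are the projection species names.
#' @return An \code{adjacency_graph} data.frame: end1, end2, weight,
#'   species (comma-separated).
#' @export
score_adjacencies <- function(block_set, species_tree = NULL) {
  tallies <- new.env(parent = emptyenv())
  for (sp in names(block_set$projections)) {
    d <- block_set$projections[[sp]]
    if (nrow(d) < 2L) next
    for (i in seq_len(nrow(d) - 1L)) {
      if (d$chrom[i] != d$chrom[i + 1L]) next
      key <- adjacency_key(d$block_id[i], d$orientation[i],
                           d$block_id[i + 1L], d$orientation[i + 1L])
      tallies[[key]] <- c(tallies[[key]], sp)
    }
  }
  keys <- ls(tallies)
  if (!length(keys))
    return(structure(data.frame(end1 = character(0L), end2 = character(0L),
                                weight = numeric(0L),
                                species = character(0L)),
                     class = c("adjacency_graph", "data.frame")))
  ends <- strsplit(keys, "--", fixed = TRUE)
  df <- data.frame(end1 = vapply(ends, `[[`, character(1L), 1L),
                   end2 = vapply(ends, `[[`, character(1L), 2L),
                   weight = vapply(keys, function(k)
                     length(unique(tallies[[k]])), numeric(1L)),
                   species = vapply(keys, function(k)
                     paste(sort(unique(tallies[[k]])), collapse = ","),
                     character(1L)),
                   stringsAsFactors = FALSE)
  if (!is.null(species_tree)) {
    root_children <- species_sides(species_tree)
    dollo_ok <- vapply(keys, function(k) {
      sps <- unique(tallies[[k]])
      any(sps %in% root_children$left) && any(sps %in% root_children$right)
    }, logical(1L))
    df$weight[!dollo_ok] <- 0
  }
  rownames(df) <- NULL
  structure(df, class = c("adjacency_graph", "data.frame"))
}

# tip labels on each side of the root of a rooted binary (or multifurcating)
# tree; for multifurcations, the first child clade vs the rest.
species_sides <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  root <- length(tree$tip.label) + 1L
  kids <- tree$edge[tree$edge[, 1L] == root, 2L]
  clade_tips <- function(node) {
    if (node <= length(tree$tip.label)) return(tree$tip.label[node])
    ape::extract.clade(tree, node)$tip.label
  }
  left <- clade_tips(kids[1L])
  list(left = left,
       right = setdiff(tree$tip.label, left))
}

#' Assemble contiguous ancestral regions from scored adjacencies
#'
#' Greedy maximum-weight matching on block extremities subject to linearity:
#' each extremity is used at most once and cycle-closing edges are rejected.
#' Connected paths are emitted as CARs; isolated blocks become singleton
#' CARs. Ties break on (weight, extremity names) so output is reproducible.
#'
#' @param adjacency_graph an \code{adjacency_graph} from
#'   [score_adjacencies].
#' @param block_ids all block ids (defaults to those present in the graph);
#'   supply the full \code{block_set$blocks$block_id} so isolated blocks
#'   are kept.
#' @param min_weight minimum adjacency weight to be an ancestral candidate
#'   (default 2: a junction seen in a single genome cannot be polarized
#'   without a tree and would otherwise bake branch-private fusions into
#'   the ancestor; under Dollo filtering weights are already polarized and
#'   \code{min_weight = 1} is appropriate).
#' @return An \code{ancestral_karyotype}: \code{cars} (list of data.frames
#'   block_id, orientation), \code{n_chromosomes}.
#' @export
linearize_cars <- function(adjacency_graph, block_ids = NULL,
                           min_weight = 2) {
  df <- adjacency_graph[adjacency_graph$weight >= min_weight, ,
                        drop = FALSE]
  if (is.null(block_ids)) {
    block_ids <- sort(unique(sub(":[HT]$", "", c(df$end1, df$end2))))
  }
  df <- df[order(-df$weight, df$end1, df$end2), , drop = FALSE]
  parent <- stats::setNames(block_ids, block_ids)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  deg <- new.env(parent = emptyenv())
  link <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(df))) {
    e1 <- df$end1[i]; e2 <- df$end2[i]
    if (!is.null(deg[[e1]]) || !is.null(deg[[e2]])) next
    b1 <- sub(":[HT]$", "", e1)
    b2 <- sub(":[HT]$", "", e2)
    if (!(b1 %in% block_ids) || !(b2 %in% block_ids)) next
    r1 <- find(b1); r2 <- find(b2)
    if (r1 == r2) next  # would close a cycle
    parent[[r1]] <- r2
    deg[[e1]] <- 1L
    deg[[e2]] <- 1L
    link[[e1]] <- e2
    link[[e2]] <- e1
  }
  other_end <- function(ext) {
    if (endsWith(ext, ":H")) sub(":H$", ":T", ext) else sub(":T$", ":H", ext)
  }
  visited <- character(0L)
  cars <- list()
  free_start <- function(b) {
    # start extremity for a path walk: a T or H not used by any kept edge
    for (ext in c(paste0(b, ":T"), paste0(b, ":H")))
      if (is.null(link[[ext]])) return(ext)
    NULL
  }
  for (b in block_ids) {
    if (b %in% visited) next
    start <- free_start(b)
    if (is.null(start)) next  # interior block; reached from a path end
    ids <- character(0L)
    ors <- character(0L)
    ext <- start
    repeat {
      blk <- sub(":[HT]$", "", ext)
      ids <- c(ids, blk)
      ors <- c(ors, if (endsWith(ext, ":T")) "+" else "-")
      visited <- c(visited, blk)
      exit <- other_end(ext)
      nxt <- link[[exit]]
      if (is.null(nxt)) break
      ext <- nxt
    }
    cars[[length(cars) + 1L]] <- data.frame(block_id = ids,
                                            orientation = ors,
                                            stringsAsFactors = FALSE)
  }
  # canonical orientation: lexicographically smaller of the two readings
  cars <- lapply(cars, function(d) {
    rev_d <- data.frame(block_id = rev(d$block_id),
                        orientation = ifelse(rev(d$orientation) == "+",
                                             "-", "+"),
                        stringsAsFactors = FALSE)
    k1 <- paste(d$block_id, d$orientation, collapse = ";")
    k2 <- paste(rev_d$block_id, rev_d$orientation, collapse = ";")
    if (k2 < k1) rev_d else d
  })
  cars <- cars[order(vapply(cars, function(d) d$block_id[1L], character(1L)))]
  structure(list(cars = cars, n_chromosomes = length(cars)),
            class = "ancestral_karyotype")
}

#' @export
print.ancestral_karyotype <- function(x, ...) {
  cat(sprintf("ancestral karyotype: %d CAR(s)\n", x$n_chromosomes))
  for (i in seq_along(x$cars)) {
    d <- x$cars[[i]]
    cat(sprintf("  CAR%d: %s\n", i,
                paste0(d$block_id, d$orientation, collapse = " ")))
  }
  invisible(x)
}

#' Classify rearrangements between an ancestral karyotype and a descendant
#'
#' Fusions/fissions come from chromosome-count bookkeeping (CARs present in
#' the descendant vs descendant chromosomes carrying classified blocks).
#' An inversion is counted per maximal run of blocks from a chromosome's
#' dominant CAR whose orientation is flipped relative to that CAR (the
#' majority relative orientation defines the unflipped state, so CAR global
#' orientation does not matter). Segments from a non-dominant CAR are moved
#' segments; reciprocal pairs between two chromosomes count as one
#' translocation each, unpaired moved segments as one each.
#'
#' @param karyotype an \code{ancestral_karyotype}.
#' @param descendant_projection a projection data.frame for one species
#'   (from \code{ancestral_block_set$projections}).
#' @return A list: \code{fusion}, \code{fission}, \code{translocation},
#'   \code{inversion} counts plus \code{unclassifiable} (blocks absent from
#'   the ancestor, excluded).
#' @export
classify_rearrangements <- function(karyotype, descendant_projection) {
  car_of <- character(0L)
  car_orient <- character(0L)
  for (i in seq_along(karyotype$cars)) {
    d <- karyotype$cars[[i]]
    car_of[d$block_id] <- sprintf("CAR%d", i)
    car_orient[d$block_id] <- d$orientation
  }
  proj <- descendant_projection
  known <- proj$block_id %in% names(car_of)
  unclassifiable <- sum(!known)
  proj <- proj[known, , drop = FALSE]
  counts <- list(fusion = 0L, fission = 0L, translocation = 0L,
                 inversion = 0L, unclassifiable = unclassifiable)
  if (!nrow(proj)) return(counts)
  proj <- proj[order(proj$chrom, proj$start), , drop = FALSE]
  proj$car <- unname(car_of[proj$block_id])
  chroms <- unique(proj$chrom)
  cars_present <- unique(proj$car)
  # dominant chromosome <-> CAR assignment by shared block count
  w <- stats::aggregate(cbind(n = rep(1L, nrow(proj))) ~ chrom + car,
                        data = proj, FUN = sum)
  vc <- paste0("C\r", sort(unique(w$chrom)))
  vk <- paste0("K\r", sort(unique(w$car)))
  gr <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(c(vc, vk), type = c(rep(FALSE, length(vc)),
                                         rep(TRUE, length(vk))))
  gr <- igraph::add_edges(gr, as.vector(rbind(paste0("C\r", w$chrom),
                                              paste0("K\r", w$car))),
                          weight = w$n)
  m <- igraph::max_bipartite_match(gr, weights = igraph::E(gr)$weight)
  dom <- sub("^K\r", "", m$matching[vc])
  names(dom) <- sub("^C\r", "", vc)
  counts$fusion <- max(0L, length(cars_present) - length(chroms))
  counts$fission <- max(0L, length(chroms) - length(cars_present))
  for (ch in chroms) {
    d <- proj[proj$chrom == ch, , drop = FALSE]
    dc <- dom[[ch]]
    if (is.na(dc)) dc <- names(sort(-table(d$car)))[1L]
    # inversions: flipped-orientation runs among dominant-CAR blocks
    dd <- d[d$car == dc, , drop = FALSE]
    if (nrow(dd)) {
      rel <- ifelse(dd$orientation == car_orient[dd$block_id], 1L, -1L)
      maj <- if (sum(rel) >= 0) 1L else -1L
      runs <- rle(rel)
      counts$inversion <- counts$inversion +
        sum(runs$values != maj)
    }
  }
  # moved segments: maximal runs of non-dominant-CAR blocks per chromosome
  moves <- list()
  for (ch in chroms) {
    d <- proj[proj$chrom == ch, , drop = FALSE]
    dc <- dom[[ch]]
    if (is.na(dc)) next
    is_foreign <- d$car != dc
    if (!any(is_foreign)) next
    runs <- rle(is_foreign)
    idx_end <- cumsum(runs$lengths)
    idx_start <- idx_end - runs$lengths + 1L
    for (r in which(runs$values)) {
      seg_cars <- unique(d$car[idx_start[r]:idx_end[r]])
      for (sc in seg_cars)
        moves[[length(moves) + 1L]] <- c(from_car = sc, to_chrom = ch)
    }
  }
  if (length(moves)) {
    mv <- as.data.frame(do.call(rbind, moves), stringsAsFactors = FALSE)
    chrom_of_car <- stats::setNames(names(dom), unname(dom))
    paired <- rep(FALSE, nrow(mv))
    n_trans <- 0L
    for (i in seq_len(nrow(mv))) {
      if (paired[i]) next
      # reciprocal partner: a move of this chromosome's own CAR onto the
      # chromosome that the moved CAR dominates
      home <- if (mv$from_car[i] %in% names(chrom_of_car))
        chrom_of_car[[mv$from_car[i]]] else NA_character_
      own_car <- dom[[mv$to_chrom[i]]]
      j <- which(!paired & mv$from_car == own_car & mv$to_chrom == home)
      j <- setdiff(j, i)
      if (!is.na(home) && length(j)) {
        paired[i] <- TRUE
        paired[j[1L]] <- TRUE
      } else {
        paired[i] <- TRUE
      }
      n_trans <- n_trans + 1L
    }
    counts$translocation <- n_trans
  }
  counts
}
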