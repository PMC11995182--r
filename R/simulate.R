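#' @title Genome evolution simulation with known truth
#' @name synthetic_data
#' @description Simulates an ancestral genome and its descendants under
#'   whole-genome triplication, fractionation, rearrangement and sequence
#'   divergence, keeping a replayable event log and true homology so that
#'   every pipeline stage has a parameter-recovery test. A fixed seed makes
#'   the entire output deterministic.
NULL

#' Simulate an ancestral genome
#'
#' Genes are placed at uniform spacing with strands drawn at random from a
#' seeded generator; ranks are dense along each chromosome.
#'
#' @param n_chromosomes number of chromosomes (default 8, the inferred
#'   ancestral chromosome number of the clade the package targets).
#' @param genes_per_chromosome genes per chromosome (>= 2).
#' @param seed integer seed.
#' @param species species label.
#' @param with_cds attach a random CDS per gene.
#' @param n_codons codons per CDS when \code{with_cds} (default 150).
#' @return a [genome].
#' @export
simulate_ancestor <- function(n_chromosomes = 8L, genes_per_chromosome = 100L,
                              seed = 1L, species = "ancestor",
                              with_cds = FALSE, n_codons = 150L) {
  stopifnot(n_chromosomes >= 1L, genes_per_chromosome >= 2L)
  set.seed(seed)
  chroms <- sprintf("chr%d", seq_len(n_chromosomes))
  genes <- do.call(rbind, lapply(chroms, function(ch) {
    idx <- seq_len(genes_per_chromosome) - 1L
    data.frame(gene_id = sprintf("%s_%s_g%04d", species, ch, idx),
               chrom = ch, start = idx * 1500L, end = idx * 1500L + 900L,
               strand = sample(c("+", "-"), genes_per_chromosome,
                               replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  genes$source_id <- genes$gene_id
  cds <- NULL
  if (with_cds) {
    cds <- vapply(seq_len(nrow(genes)), function(i) random_cds(n_codons),
                  character(1L))
    names(cds) <- genes$gene_id
  }
  genome(species, genes, chromosomes = chroms, cds = cds)
}

# genome <-> ordered per-chromosome gene id lists
chrom_order <- function(g) {
  split(g$genes$gene_id,
        factor(g$genes$chrom, levels = g$chromosomes))
}

rebuild_genome <- function(g, order_list, strand = NULL) {
  strand_map <- if (is.null(strand)) {
    s <- g$genes$strand
    names(s) <- g$genes$gene_id
    s
  } else strand
  src <- g$genes$source_id
  names(src) <- g$genes$gene_id
  chroms <- names(order_list)
  genes <- do.call(rbind, lapply(chroms, function(ch) {
    ids <- order_list[[ch]]
    if (!length(ids)) return(NULL)
    idx <- seq_along(ids) - 1L
    data.frame(gene_id = ids, chrom = ch, start = idx * 1500L,
               end = idx * 1500L + 900L, strand = unname(strand_map[ids]),
               source_id = unname(src[ids]), stringsAsFactors = FALSE)
  }))
  out <- genome(g$species, genes, chromosomes = chroms, cds = g$cds)
  out
}

#' Apply a whole-genome triplication
#'
#' Every chromosome is triplicated into three subgenome copies. The first
#' copy keeps all genes; in each of the two duplicated copies every gene is
#' kept independently with probability \code{retention}. Copy-of relations
#' are recorded as truth pairs.
#'
#' @param g a [genome].
#' @param retention per-gene retention probability in each duplicated copy,
#'   in (0, 1].
#' @param seed optional integer seed.
#' @return list with \code{genome}, \code{event} (log entry) and
#'   \code{truth_pairs} (data.frame gene_a = source gene in copy 1,
#'   gene_b = surviving duplicate).
#' @export
apply_wgt <- function(g, retention = 1, seed = NULL) {
  stopifnot(retention > 0, retention <= 1)
  if (!is.null(seed)) set.seed(seed)
  ord <- chrom_order(g)
  strand <- g$genes$strand
  names(strand) <- g$genes$gene_id
  src <- g$genes$source_id
  names(src) <- g$genes$gene_id
  new_ord <- list()
  new_strand <- character(0L)
  new_src <- character(0L)
  pairs <- list()
  cds <- g$cds
  for (ch in names(ord)) {
    ids <- ord[[ch]]
    for (copy in 1:3) {
      cname <- sprintf("%s_%d", ch, copy)
      if (copy == 1L) {
        new_ord[[cname]] <- ids
        new_strand[ids] <- strand[ids]
        new_src[ids] <- src[ids]
      } else {
        keep <- stats::runif(length(ids)) < retention
        kept <- ids[keep]
        dup <- sprintf("%s_d%d", kept, copy)
        new_ord[[cname]] <- dup
        new_strand[dup] <- strand[kept]
        new_src[dup] <- src[kept]
        if (length(kept))
          pairs[[length(pairs) + 1L]] <-
            data.frame(gene_a = kept, gene_b = dup, stringsAsFactors = FALSE)
        if (!is.null(cds)) {
          add <- cds[kept]
          names(add) <- dup
          cds <- c(cds, add)
        }
      }
    }
  }
  genes <- do.call(rbind, lapply(names(new_ord), function(cn) {
    ids <- new_ord[[cn]]
    if (!length(ids)) return(NULL)
    idx <- seq_along(ids) - 1L
    data.frame(gene_id = ids, chrom = cn, start = idx * 1500L,
               end = idx * 1500L + 900L, strand = unname(new_strand[ids]),
               source_id = unname(new_src[ids]), stringsAsFactors = FALSE)
  }))
  out <- genome(g$species, genes, chromosomes = names(new_ord), cds = cds)
  truth_pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(gene_a = character(0L), gene_b = character(0L))
  list(genome = out,
       event = list(type = "WGT", retention = retention),
       truth_pairs = truth_pairs)
}

validate_event <- function(ev, ord) {
  n_of <- function(ch) {
    if (!ch %in% names(ord)) stop("event on unknown chromosome ", ch)
    length(ord[[ch]])
  }
  switch(ev$type,
    inversion = {
      n <- n_of(ev$chrom)
      if (ev$from < 0L || ev$to >= n || ev$from > ev$to)
        stop("inversion segment out of range on ", ev$chrom)
    },
    translocation = {
      na <- n_of(ev$chrom_a); nb <- n_of(ev$chrom_b)
      if (ev$chrom_a == ev$chrom_b)
        stop("translocation needs two distinct chromosomes")
      if (ev$len_a < 1L || ev$len_a >= na || ev$len_b < 1L || ev$len_b >= nb)
        stop("translocation segment out of range")
    },
    fusion = {
      n_of(ev$chrom_a); n_of(ev$chrom_b)
      if (ev$chrom_a == ev$chrom_b) stop("fusion needs distinct chromosomes")
    },
    fission = {
      n <- n_of(ev$chrom)
      if (ev$at < 1L || ev$at >= n) stop("fission point out of range")
    },
    stop("unknown event type: ", ev$type))
  invisible(TRUE)
}

#' Apply rearrangement events to a genome
#'
#' Supported events (rank units, inclusive bounds): \emph{inversion}
#' (\code{chrom}, \code{from}, \code{to}): reversal of the rank interval
#' with strand flip; \emph{translocation} (\code{chrom_a}, \code{chrom_b},
#' \code{len_a}, \code{len_b}): reciprocal exchange of the two terminal
#' segments; \emph{fusion} (\code{chrom_a}, \code{chrom_b}): concatenation;
#' \emph{fission} (\code{chrom}, \code{at}): split before rank \code{at},
#' the distal part becoming \code{<chrom>_f}. Gene content is conserved by
#' every event; ranks and bp coordinates are recomputed.
#'
#' @param g a [genome].
#' @param events list of event lists, applied in order.
#' @return list with \code{genome} and \code{log} (the normalized events).
#' @export
apply_rearrangements <- function(g, events) {
  ord <- chrom_order(g)
  strand <- g$genes$strand
  names(strand) <- g$genes$gene_id
  for (ev in events) {
    validate_event(ev, ord)
    if (ev$type == "inversion") {
      ids <- ord[[ev$chrom]]
      seg <- (ev$from:ev$to) + 1L
      ids[seg] <- rev(ids[seg])
      strand[ids[seg]] <- ifelse(strand[ids[seg]] == "+", "-", "+")
      ord[[ev$chrom]] <- ids
    } else if (ev$type == "translocation") {
      a <- ord[[ev$chrom_a]]; b <- ord[[ev$chrom_b]]
      na <- length(a); nb <- length(b)
      tail_a <- a[(na - ev$len_a + 1L):na]
      tail_b <- b[(nb - ev$len_b + 1L):nb]
      ord[[ev$chrom_a]] <- c(a[seq_len(na - ev$len_a)], tail_b)
      ord[[ev$chrom_b]] <- c(b[seq_len(nb - ev$len_b)], tail_a)
    } else if (ev$type == "fusion") {
      ord[[ev$chrom_a]] <- c(ord[[ev$chrom_a]], ord[[ev$chrom_b]])
      ord[[ev$chrom_b]] <- NULL
    } else if (ev$type == "fission") {
      ids <- ord[[ev$chrom]]
      new_name <- paste0(ev$chrom, "_f")
      while (new_name %in% names(ord)) new_name <- paste0(new_name, "f")
      second <- ids[(ev$at + 1L):length(ids)]
      ord[[ev$chrom]] <- ids[seq_len(ev$at)]
      # insert the new chromosome right after its parent
      pos <- match(ev$chrom, names(ord))
      nm <- append(names(ord), new_name, after = pos)
      ord <- append(ord, list(second), after = pos)
      names(ord) <- nm
    }
  }
  list(genome = rebuild_genome(g, ord, strand), log = events)
}

#' Replay an event log from a starting genome
#'
#' @param g the starting [genome].
#' @param log list of events as produced by [apply_rearrangements] /
#'   [apply_wgt] (WGT entries need a \code{seed} to be replayable and are
#'   not supported here; replay covers rearrangement logs).
#' @return the resulting [genome].
#' @export
replay_events <- function(g, log) {
  apply_rearrangements(g, log)$genome
}

#' Draw a random, non-overlapping set of rearrangement events
#'
#' Samples inversions of interior rank intervals and reciprocal terminal
#' translocations whose segments do not overlap each other, so that each
#' event remains individually identifiable in downstream classification
#' (breakpoint reuse is deliberately avoided).
#'
#' @param g a [genome].
#' @param n_inversions,n_translocations event counts.
#' @param min_seg,max_seg segment length bounds in ranks (defaults 12, 30:
#'   the minimum sits above the 10-gene ancestral-block resolution so every
#'   simulated event remains recoverable even when a boundary anchor is
#'   absorbed by a flanking chain).
#' @param seed optional integer seed.
#' @param buffer ranks reserved around every event's breakpoints (default
#'   \code{min_seg}) so that breakpoints of distinct events stay at least a
#'   block-length apart and each event remains resolvable at block
#'   resolution.
#' @param used optional named list of per-chromosome logical vectors marking
#'   ranks already consumed by earlier events (e.g. on sibling branches);
#'   the updated mask is returned as the \code{used} attribute. Sharing the
#'   mask across the branches of a clade keeps every event's breakpoints
#'   private to one branch, so each event stays individually recoverable.
#' @return list of events suitable for [apply_rearrangements], with the
#'   updated mask in \code{attr(, "used")}.
#' @export
random_events <- function(g, n_inversions = 1L, n_translocations = 1L,
                          min_seg = 12L, max_seg = 30L, seed = NULL,
                          buffer = min_seg, used = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ord <- chrom_order(g)
  sizes <- lengths(ord)
  events <- list()
  if (is.null(used))
    used <- lapply(ord, function(x) logical(length(x)))
  reserve <- function(ch, from, to) {
    idx <- max(1L, from + 1L - buffer):min(sizes[[ch]], to + 1L + buffer)
    used[[ch]][idx] <<- TRUE
  }
  blocked <- function(ch, from, to) {
    idx <- max(1L, from + 1L - buffer):min(sizes[[ch]], to + 1L + buffer)
    any(used[[ch]][idx])
  }
  for (i in seq_len(n_inversions)) {
    for (try in 1:200) {
      ch <- sample(names(ord), 1L)
      n <- sizes[[ch]]
      lo <- 2L
      hi <- n - max_seg - 2L
      if (hi - lo < min_seg) next
      len <- sample(min_seg:min(max_seg, hi - lo), 1L)
      from <- sample(lo:(hi - len), 1L)
      if (blocked(ch, from, from + len - 1L)) next
      reserve(ch, from, from + len - 1L)
      events[[length(events) + 1L]] <-
        list(type = "inversion", chrom = ch, from = from,
             to = from + len - 1L)
      break
    }
  }
  pool <- names(ord)
  for (i in seq_len(n_translocations)) {
    for (try in 1:200) {
      if (length(pool) < 2L) break
      chs <- sample(pool, 2L)
      la <- sample(min_seg:max_seg, 1L)
      lb <- sample(min_seg:max_seg, 1L)
      na <- sizes[[chs[1L]]]; nb <- sizes[[chs[2L]]]
      if (la >= na - 1L || lb >= nb - 1L) next
      if (blocked(chs[1L], na - la, na - 1L) ||
            blocked(chs[2L], nb - lb, nb - 1L)) next
      reserve(chs[1L], na - la, na - 1L)
      reserve(chs[2L], nb - lb, nb - 1L)
      # one reciprocal exchange per chromosome pair keeps events separable
      pool <- setdiff(pool, chs)
      events[[length(events) + 1L]] <-
        list(type = "translocation", chrom_a = chs[1L], chrom_b = chs[2L],
             len_a = la, len_b = lb)
      break
    }
  }
  attr(events, "used") <- used
  events
}

rename_tip <- function(g, species) {
  map <- sprintf("%s_%s", species, g$genes$gene_id)
  names(map) <- g$genes$gene_id
  genes <- g$genes
  genes$source_id <- genes$gene_id
  genes$gene_id <- unname(map[genes$gene_id])
  cds <- g$cds
  if (!is.null(cds)) names(cds) <- unname(map[names(cds)])
  genome(species, genes, chromosomes = g$chromosomes, cds = cds)
}

#' Simulation configuration for a clade
#'
#' @param seed master seed; fixes the entire simulation output.
#' @param n_chromosomes,genes_per_chromosome ancestor dimensions (defaults
#'   8 x 100, the ancestral karyotype scale the package targets).
#' @param tips tip species labels.
#' @param rate_multipliers named per-tip synonymous-rate multipliers
#'   (default 1 for every tip).
#' @param wgt apply a shared whole-genome triplication on the stem.
#' @param wgt_retention per-copy gene retention after the triplication.
#' @param n_inversions,n_translocations per-tip event counts.
#' @param with_cds simulate coding sequences.
#' @param n_codons codons per gene.
#' @param kappa transition/transversion ratio.
#' @param ks_wgt true synonymous distance between triplication-derived
#'   paralog copies at rate multiplier 1 (default 1.22).
#' @param ks_tip true synonymous distance between a tip and the ancestor at
#'   rate multiplier 1 (default 0.1).
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(seed = 1L, n_chromosomes = 8L,
                       genes_per_chromosome = 100L,
                       tips = c("spA", "spB", "spC"),
                       rate_multipliers = NULL, wgt = FALSE,
                       wgt_retention = 0.5, n_inversions = 1L,
                       n_translocations = 1L, with_cds = FALSE,
                       n_codons = 150L, kappa = 2, ks_wgt = 1.22,
                       ks_tip = 0.1) {
  if (is.null(rate_multipliers)) {
    rate_multipliers <- rep(1, length(tips))
    names(rate_multipliers) <- tips
  }
  stopifnot(all(tips %in% names(rate_multipliers)),
            all(rate_multipliers > 0),
            wgt_retention > 0, wgt_retention <= 1)
  structure(list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
                 genes_per_chromosome = genes_per_chromosome, tips = tips,
                 rate_multipliers = rate_multipliers, wgt = wgt,
                 wgt_retention = wgt_retention, n_inversions = n_inversions,
                 n_translocations = n_translocations, with_cds = with_cds,
                 n_codons = n_codons, kappa = kappa, ks_wgt = ks_wgt,
                 ks_tip = ks_tip),
            class = "sim_config")
}

#' Simulate a clade with known truth
#'
#' Builds an ancestor, optionally applies a shared whole-genome triplication
#' on the stem, then derives each tip by seeded rearrangements (and CDS
#' divergence scaled by its rate multiplier). Everything is deterministic
#' under the config seed.
#'
#' @param config a [sim_config].
#' @return A \code{truth_bundle}: \code{ancestor} (pre-WGT),
#'   \code{stem} (post-WGT ancestor the tips descend from), \code{tips}
#'   (named list of genomes), \code{event_log} (named per-tip event lists,
#'   plus \code{stem} entries), \code{ortholog_pairs} (named list per tip
#'   pair), \code{paralog_pairs} (named list per tip; triplication-derived),
#'   and \code{config}.
#' @export
simulate_clade <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  anc <- simulate_ancestor(config$n_chromosomes, config$genes_per_chromosome,
                           seed = config$seed, species = "ancestor",
                           with_cds = config$with_cds,
                           n_codons = config$n_codons)
  stem <- anc
  stem_pairs <- NULL
  event_log <- list(stem = list())
  if (config$wgt) {
    w <- apply_wgt(anc, retention = config$wgt_retention,
                   seed = config$seed + 1L)
    stem <- w$genome
    stem_pairs <- w$truth_pairs
    event_log$stem <- list(w$event)
    if (config$with_cds && nrow(stem_pairs)) {
      # diverge the duplicated copies on the stem so that, after the tip
      # branches are added, within-tip paralog pairs sit near ks_wgt
      stem_ks <- max(0, config$ks_wgt - 2 * config$ks_tip)
      if (stem_ks > 0) {
        dup_ids <- stem_pairs$gene_b
        stem$cds[dup_ids] <- evolve_tip_cds(stem$cds[dup_ids], stem_ks,
                                            config$kappa,
                                            seed = config$seed + 2L)
      }
    }
  }
  tips <- list()
  paralog_pairs <- list()
  used_mask <- NULL  # shared across branches: no cross-branch breakpoint reuse
  for (ti in seq_along(config$tips)) {
    tip_name <- config$tips[ti]
    tip <- rename_tip(stem, tip_name)
    ev <- random_events(tip, n_inversions = config$n_inversions,
                        n_translocations = config$n_translocations,
                        seed = config$seed * 131L + ti, used = used_mask)
    used_mask <- attr(ev, "used")
    attr(ev, "used") <- NULL
    res <- apply_rearrangements(tip, ev)
    tip <- res$genome
    event_log[[tip_name]] <- res$log
    if (config$with_cds) {
      mult <- config$rate_multipliers[[tip_name]]
      tip$cds <- evolve_tip_cds(tip$cds, config$ks_tip * mult,
                                config$kappa,
                                seed = config$seed * 977L + ti)
    }
    if (!is.null(stem_pairs) && nrow(stem_pairs)) {
      paralog_pairs[[tip_name]] <- data.frame(
        gene_a = sprintf("%s_%s", tip_name, stem_pairs$gene_a),
        gene_b = sprintf("%s_%s", tip_name, stem_pairs$gene_b),
        stringsAsFactors = FALSE)
    }
    tips[[tip_name]] <- tip
  }
  ortholog_pairs <- list()
  if (length(tips) > 1L) {
    combos <- utils::combn(names(tips), 2L)
    for (k in seq_len(ncol(combos))) {
      s1 <- combos[1L, k]; s2 <- combos[2L, k]
      g1 <- tips[[s1]]$genes; g2 <- tips[[s2]]$genes
      m <- merge(g1[, c("gene_id", "source_id")],
                 g2[, c("gene_id", "source_id")], by = "source_id")
      ortholog_pairs[[paste(s1, s2, sep = "|")]] <-
        data.frame(gene_a = m$gene_id.x, gene_b = m$gene_id.y,
                   stringsAsFactors = FALSE)
    }
  }
  structure(list(ancestor = anc, stem = stem, tips = tips,
                 event_log = event_log, ortholog_pairs = ortholog_pairs,
                 paralog_pairs = paralog_pairs, stem_pairs = stem_pairs,
                 config = config),
            class = "truth_bundle")
}

# Evolve every CDS of a tip by the same branch-level synonymous distance.
# The Poisson event rate is calibrated once on a pooled sample of the
# sequences (composition differences between random CDS are negligible),
# then applied gene by gene.
evolve_tip_cds <- function(cds, branch_ks, kappa, seed = NULL,
                           pool_codons = 400L) {
  if (!is.null(seed)) set.seed(seed)
  if (branch_ks == 0 || !length(cds)) return(cds)
  pool <- paste0(cds[seq_len(min(length(cds),
                                 ceiling(pool_codons * 3 / nchar(cds[[1L]]))))],
                 collapse = "")
  m <- calibrate_events(pool, branch_ks, kappa)
  out <- vapply(cds, function(s) {
    L <- nchar(s)
    res <- apply_events(strsplit(s, "")[[1L]],
                        stats::rpois(1L, m * L), kappa)
    paste0(res$seq, collapse = "")
  }, character(1L))
  names(out) <- names(cds)
  out
}

#' Write a truth bundle to fixture files
#'
#' Writes, per tip, a BED gene-position file, a CDS FASTA (when sequences
#' were simulated) and a homolog pair TSV (truth pairs against the first
#' tip, or paralog pairs for the first tip itself when a triplication was
#' simulated), plus a versioned \code{truth.json}. Re-reading the files
#' through the package readers reproduces the bundle.
#'
#' @param bundle a \code{truth_bundle} from [simulate_clade].
#' @param out_dir output directory (created if needed).
#' @return invisible character vector of written paths.
#' @export
emit_fixtures <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0L)
  tip_names <- names(bundle$tips)
  ref <- tip_names[1L]
  for (tn in tip_names) {
    g <- bundle$tips[[tn]]
    p <- file.path(out_dir, paste0(tn, ".bed"))
    write_gene_positions(g, p)
    paths <- c(paths, p)
    if (!is.null(g$cds)) {
      p <- file.path(out_dir, paste0(tn, ".cds.fasta"))
      write_cds_fasta(g$cds, p)
      paths <- c(paths, p)
    }
    pairs <- if (tn == ref) {
      bundle$paralog_pairs[[tn]] %||%
        data.frame(gene_a = character(0L), gene_b = character(0L))
    } else {
      bundle$ortholog_pairs[[paste(ref, tn, sep = "|")]]
    }
    p <- file.path(out_dir, paste0(tn, ".pairs.tsv"))
    write_homolog_pairs(pairs, p)
    paths <- c(paths, p)
  }
  truth <- list(schema_version = "1.0",
                species = tip_names,
                seed = bundle$config$seed,
                event_log = bundle$event_log,
                n_genes = lapply(bundle$tips, function(g) nrow(g$genes)))
  p <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth, p, auto_unbox = TRUE, pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
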