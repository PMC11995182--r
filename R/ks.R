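#' @title Synonymous and nonsynonymous divergence by NG86 counting
#' @name ksrates
#' @description Counting-method Ka/Ks: per-codon synonymous site fractions are
#'   derived from all single-nucleotide neighbours (averaged over the two
#'   sequences), differences between codons are averaged over all minimal
#'   substitution pathways, and proportions are corrected for multiple hits
#'   with the Jukes-Cantor formula. Codons containing N or alignment gaps are
#'   excluded from all site and difference counts.
NULL

ng86_env <- new.env(parent = emptyenv())

# Precompute the codon tables: amino acids, per-codon synonymous site counts,
# and 64x64 pathway-averaged synonymous/nonsynonymous difference counts.
# Pathways passing through a stop codon are excluded; if every minimal
# pathway does, all are used with equal weight.
ng86_tables <- function() {
  if (!is.null(ng86_env$codons)) return(ng86_env)
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases,
                              stringsAsFactors = FALSE)[, 3:1], 1L, paste0,
                  collapse = "")
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  names(aa) <- codons
  neighbour <- function(codon, pos, base) {
    s <- strsplit(codon, "")[[1L]]
    s[pos] <- base
    paste0(s, collapse = "")
  }
  syn_sites <- vapply(codons, function(cd) {
    tot <- 0
    for (pos in 1:3) {
      for (b in setdiff(bases, substr(cd, pos, pos))) {
        alt <- neighbour(cd, pos, b)
        if (aa[[alt]] == aa[[cd]]) tot <- tot + 1 / 3
      }
    }
    tot
  }, numeric(1L))
  perms <- list(`1` = list(1L), `2` = list(1:2, 2:1),
                `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                           c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  n <- length(codons)
  SdM <- matrix(0, n, n, dimnames = list(codons, codons))
  NdM <- matrix(0, n, n, dimnames = list(codons, codons))
  for (i in seq_len(n)) {
    ci <- strsplit(codons[i], "")[[1L]]
    for (j in seq_len(n)) {
      if (i == j) next
      cj <- strsplit(codons[j], "")[[1L]]
      diffpos <- which(ci != cj)
      d <- length(diffpos)
      paths <- perms[[as.character(d)]]
      acc <- matrix(NA_real_, length(paths), 3L)  # sd, nd, valid
      for (p in seq_along(paths)) {
        cur <- ci
        sd <- 0; nd <- 0; valid <- TRUE
        for (pos in diffpos[paths[[p]]]) {
          nxt <- cur
          nxt[pos] <- cj[pos]
          a1 <- aa[[paste0(cur, collapse = "")]]
          a2 <- aa[[paste0(nxt, collapse = "")]]
          if (a2 == "*" && !identical(nxt, cj)) valid <- FALSE
          if (a1 == a2) sd <- sd + 1 else nd <- nd + 1
          cur <- nxt
        }
        acc[p, ] <- c(sd, nd, valid)
      }
      use <- acc[, 3L] == 1
      if (!any(use)) use <- rep(TRUE, nrow(acc))
      SdM[i, j] <- mean(acc[use, 1L])
      NdM[i, j] <- mean(acc[use, 2L])
    }
  }
  ng86_env$codons <- codons
  ng86_env$aa <- aa
  ng86_env$syn_sites <- syn_sites
  ng86_env$SdM <- SdM
  ng86_env$NdM <- NdM
  ng86_env
}

split_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Estimate Ka and Ks by the NG86 counting method
#'
#' @param alignment a \code{codon_alignment} from [align_codons], or a
#'   character vector of two equal-length gapless CDS (lengths multiples
#'   of 3) which are treated as pre-aligned.
#' @return An object of class \code{ks_estimate}: synonymous (\code{S}) and
#'   nonsynonymous (\code{N}) site counts, observed synonymous
#'   (\code{Sd}) and nonsynonymous (\code{Nd}) differences, proportions
#'   \code{pS}, \code{pN}, Jukes-Cantor corrected distances \code{ks},
#'   \code{ka} (NA when saturated), saturation flags, the number of codon
#'   columns used, and the transition fraction among differing sites.
#' @examples
#' est <- ks_ng86(c("ATGGCTGCT", "ATGGCCGCT"))
#' est$ks  # -0.75 * log(1/3)
#' @export
ks_ng86 <- function(alignment) {
  tab <- ng86_tables()
  if (is.character(alignment)) {
    stopifnot(length(alignment) == 2L,
              nchar(alignment[1L]) == nchar(alignment[2L]),
              nchar(alignment[1L]) %% 3L == 0L)
    ca <- split_codons(toupper(alignment[1L]))
    cb <- split_codons(toupper(alignment[2L]))
  } else if (inherits(alignment, "codon_alignment")) {
    ca <- alignment$codons_a
    cb <- alignment$codons_b
  } else stop("alignment must be a codon_alignment or two CDS strings")
  keep <- !grepl("[-N]", ca) & !grepl("[-N]", cb)
  ca <- ca[keep]
  cb <- cb[keep]
  n_codons <- length(ca)
  if (n_codons < 1L) stop("no ungapped codon columns")
  S <- (sum(tab$syn_sites[ca]) + sum(tab$syn_sites[cb])) / 2
  N <- 3 * n_codons - S
  ia <- match(ca, tab$codons)
  ib <- match(cb, tab$codons)
  Sd <- sum(tab$SdM[cbind(ia, ib)])
  Nd <- sum(tab$NdM[cbind(ia, ib)])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  jc <- function(p) {
    if (is.na(p)) return(list(d = NA_real_, sat = TRUE))
    arg <- 1 - 4 * p / 3
    if (arg <= 0) return(list(d = NA_real_, sat = TRUE))
    list(d = -0.75 * log(arg) + 0, sat = FALSE)  # + 0 avoids IEEE -0
  }
  ks <- jc(pS)
  ka <- jc(pN)
  # transition fraction among differing aligned nucleotide positions
  na <- unlist(strsplit(ca, ""))
  nb <- unlist(strsplit(cb, ""))
  dif <- which(na != nb)
  ts <- c("AG", "GA", "CT", "TC")
  ts_frac <- if (length(dif))
    mean(paste0(na[dif], nb[dif]) %in% ts) else NA_real_
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 ks = ks$d, ka = ka$d, saturated = ks$sat,
                 ka_saturated = ka$sat, n_codons_ungapped = n_codons,
                 ts_fraction = ts_frac),
            class = "ks_estimate")
}

#' @export
print.ks_estimate <- function(x, ...) {
  cat(sprintf(paste0("NG86 estimate over %d codons: S=%.2f N=%.2f ",
                     "Sd=%.2f Nd=%.2f  Ks=%s Ka=%s%s\n"),
              x$n_codons_ungapped, x$S, x$N, x$Sd, x$Nd,
              ifelse(x$saturated, "saturated", sprintf("%.4f", x$ks)),
              ifelse(x$ka_saturated, "saturated", sprintf("%.4f", x$ka)),
              ""))
  invisible(x)
}

#' Protein-guided codon alignment of two CDS
#'
#' Both sequences are translated, globally aligned at the protein level
#' (Needleman-Wunsch with affine gaps) and the alignment is back-translated
#' to codon columns. A terminal stop codon is stripped; an internal stop is
#' an error.
#'
#' @param cds_a,cds_b CDS strings; lengths must be positive multiples of 3.
#' @param substitution_matrix protein scoring matrix name (default
#'   "BLOSUM62") or a numeric matrix.
#' @param gap_opening,gap_extension affine gap costs (defaults 10 and 4).
#' @return An object of class \code{codon_alignment}: codon columns
#'   \code{codons_a}, \code{codons_b} ("---" for a gap),
#'   \code{n_codons_ungapped}, and the protein alignment \code{score}.
#' @export
align_codons <- function(cds_a, cds_b, substitution_matrix = "BLOSUM62",
                         gap_opening = 10, gap_extension = 4) {
  prep <- function(s) {
    s <- toupper(s)
    if (nchar(s) %% 3L != 0L || nchar(s) == 0L)
      stop("CDS length must be a positive multiple of 3")
    aa <- strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(gsub("N", "A", s)), no.init.codon = TRUE)),
      "")[[1L]]
    # mask codons containing N back to X so they do not drive the alignment
    cods <- split_codons(s)
    aa[grepl("N", cods)] <- "X"
    if (aa[length(aa)] == "*") {
      aa <- aa[-length(aa)]
      cods <- cods[-length(cods)]
    }
    if (any(aa == "*"))
      stop("internal stop codon in CDS")
    list(aa = paste0(aa, collapse = ""), codons = cods)
  }
  a <- prep(cds_a)
  b <- prep(cds_b)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a$aa), Biostrings::AAString(b$aa),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_opening, gapExtension = gap_extension)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  sbj <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  back <- function(chars, codons) {
    out <- character(length(chars))
    k <- 0L
    for (i in seq_along(chars)) {
      if (chars[i] == "-") {
        out[i] <- "---"
      } else {
        k <- k + 1L
        out[i] <- codons[k]
      }
    }
    out
  }
  codons_a <- back(pat, a$codons)
  codons_b <- back(sbj, b$codons)
  structure(list(codons_a = codons_a, codons_b = codons_b,
                 n_codons_ungapped = sum(codons_a != "---" &
                                           codons_b != "---"),
                 score = Biostrings::score(aln)),
            class = "codon_alignment")
}

#' Median Ks of a collinear block
#'
#' @param block a single block from a \code{collinear_blocks} object.
#' @param ks_by_pair named numeric vector of Ks values keyed
#'   "gene_a|gene_b"; saturated/undefined values are NA.
#' @return the median over the block's anchors ignoring NA, or NA when no
#'   anchor has a defined Ks.
#' @export
block_median_ks <- function(block, ks_by_pair) {
  keys <- paste(block$anchors$gene_a, block$anchors$gene_b, sep = "|")
  v <- ks_by_pair[keys]
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  stats::median(v)
}

#' Compute per-anchor Ks for a block set and annotate block medians
#'
#' Aligns and estimates NG86 Ks for every distinct anchor gene pair with CDS
#' available in both genomes, then sets each block's \code{median_ks}.
#'
#' @param blocks a \code{collinear_blocks} object.
#' @param cds_a,cds_b named CDS vectors for the two genomes.
#' @param ... passed to [align_codons].
#' @return list with \code{blocks} (median_ks filled), \code{pairs}
#'   (data.frame gene_a, gene_b, ks, ka, saturated) and \code{ks_by_pair}.
#' @export
compute_block_ks <- function(blocks, cds_a, cds_b, ...) {
  keys <- unique(unlist(lapply(blocks, function(b)
    paste(b$anchors$gene_a, b$anchors$gene_b, sep = "|"))))
  if (is.null(keys)) keys <- character(0L)
  parts <- strsplit(keys, "|", fixed = TRUE)
  ga <- vapply(parts, `[[`, character(1L), 1L)
  gb <- vapply(parts, `[[`, character(1L), 2L)
  have <- ga %in% names(cds_a) & gb %in% names(cds_b)
  ks <- ka <- rep(NA_real_, length(keys))
  sat <- rep(NA, length(keys))
  for (i in which(have)) {
    est <- ks_ng86(align_codons(cds_a[[ga[i]]], cds_b[[gb[i]]], ...))
    ks[i] <- est$ks
    ka[i] <- est$ka
    sat[i] <- est$saturated
  }
  ks_by_pair <- ks
  names(ks_by_pair) <- keys
  for (i in seq_along(blocks))
    blocks[[i]]$median_ks <- block_median_ks(blocks[[i]], ks_by_pair)
  list(blocks = blocks,
       pairs = data.frame(gene_a = ga, gene_b = gb, ks = ks, ka = ka,
                          saturated = sat, stringsAsFactors = FALSE),
       ks_by_pair = ks_by_pair)
}
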