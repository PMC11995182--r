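#' Construct a genome object
#'
#' A \code{genome} is the coordinate system for all synteny work: an ordered
#' set of chromosomes, each carrying gene models ranked by start coordinate.
#' Coordinates are 0-based half-open throughout the package; ranks are dense
#' 0..n-1 along each chromosome in (start, end, gene_id) order.
#'
#' @param species species label (single string).
#' @param genes data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand} ("+" or "-"). An optional
#'   \code{source_id} column (ancestral gene of origin, used by the simulator)
#'   is carried along.
#' @param chromosomes chromosome names in display order; defaults to the
#'   sorted unique chromosome names found in \code{genes}.
#' @param cds optional named character vector of coding sequences
#'   (names are gene ids); each length must be a positive multiple of 3.
#' @return An object of class \code{genome}: a list with elements
#'   \code{species}, \code{chromosomes}, \code{genes} (with a \code{rank}
#'   column added) and \code{cds}.
#' @examples
#' g <- genome("toy", data.frame(
#'   gene_id = c("a", "b"), chrom = "chr1",
#'   start = c(0L, 500L), end = c(300L, 800L), strand = c("+", "-")))
#' g$genes$rank
#' @export
genome <- function(species, genes, chromosomes = NULL, cds = NULL) {
  stopifnot(is.character(species), length(species) == 1L)
  needed <- c("gene_id", "chrom", "start", "end", "strand")
  missing_cols <- setdiff(needed, names(genes))
  if (length(missing_cols))
    stop("genes is missing column(s): ", paste(missing_cols, collapse = ", "))
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  genes$strand <- as.character(genes$strand)
  if (anyDuplicated(genes$gene_id)) {
    dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
    stop("duplicate gene_id(s): ", paste(utils::head(dup, 5L), collapse = ", "))
  }
  if (any(genes$start >= genes$end))
    stop("all gene models must satisfy start < end (0-based half-open)")
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (is.null(chromosomes)) chromosomes <- sort(unique(genes$chrom))
  if (!all(genes$chrom %in% chromosomes))
    stop("gene chromosome(s) not listed in chromosomes")
  if (!"source_id" %in% names(genes)) genes$source_id <- NA_character_
  genes <- rank_genes(genes, chromosomes)
  if (!is.null(cds)) {
    cds <- validate_cds(cds)
    unknown <- setdiff(names(cds), genes$gene_id)
    if (length(unknown))
      stop("cds entries with no gene model: ",
           paste(utils::head(unknown, 5L), collapse = ", "))
  }
  structure(list(species = species, chromosomes = chromosomes,
                 genes = genes, cds = cds),
            class = "genome")
}

# Dense 0-based ranks per chromosome, deterministic (start, end, gene_id)
# tie-break; rows returned in (chromosome order, rank) order.
rank_genes <- function(genes, chromosomes) {
  genes$chrom <- factor(genes$chrom, levels = chromosomes)
  ord <- order(genes$chrom, genes$start, genes$end, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  genes$rank <- stats::ave(seq_len(nrow(genes)), genes$chrom,
                           FUN = seq_along) - 1L
  genes$chrom <- as.character(genes$chrom)
  rownames(genes) <- NULL
  genes
}

validate_cds <- function(cds) {
  cds <- vapply(cds, toupper, character(1L))
  bad_chr <- names(cds)[grepl("[^ACGTN]", cds)]
  if (length(bad_chr))
    stop("non-ACGTN characters in CDS of: ",
         paste(utils::head(bad_chr, 5L), collapse = ", "))
  bad_len <- names(cds)[nchar(cds) == 0L | nchar(cds) %% 3L != 0L]
  if (length(bad_len))
    stop("CDS length not a positive multiple of 3 for: ",
         paste(utils::head(bad_len, 5L), collapse = ", "))
  cds
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("genome '%s': %d genes on %d chromosome(s)%s\n",
              x$species, nrow(x$genes), length(x$chromosomes),
              if (is.null(x$cds)) "" else
                sprintf(", CDS for %d genes", length(x$cds))))
  invisible(x)
}

#' @export
summary.genome <- function(object, ...) {
  tab <- table(factor(object$genes$chrom, levels = object$chromosomes))
  out <- data.frame(chrom = names(tab), n_genes = as.integer(tab))
  print(out, row.names = FALSE)
  invisible(out)
}

n_genes <- function(g) nrow(g$genes)

# Fast lookup table gene_id -> row index.
gene_index <- function(g) {
  idx <- seq_len(nrow(g$genes))
  names(idx) <- g$genes$gene_id
  idx
}

# Rebuild bp coordinates from ranks after structural edits (uniform spacing),
# keeping the ledger of ranks authoritative. Used by the simulator.
respace_genome <- function(g, spacing = 1500L, width = 900L) {
  g$genes$start <- g$genes$rank * spacing
  g$genes$end <- g$genes$start + width
  g
}
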