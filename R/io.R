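#' Read gene positions from BED or GFF3
#'
#' BED input is 0-based half-open (columns chrom, start, end, name[, score,
#' strand]); GFF3 is 1-based inclusive and converted to the internal 0-based
#' half-open convention at the boundary. For GFF3 only records of the types in
#' \code{gff3_types} are used and the \code{ID} attribute is taken as the gene
#' id.
#'
#' @param path input file.
#' @param format "BED" or "GFF3"; default guessed from the file extension.
#' @param species species label for the resulting genome; defaults to the
#'   file base name.
#' @param gff3_types GFF3 feature types to keep (default gene and mRNA).
#' @return A [genome] with ranks assigned by start coordinate per chromosome.
#' @export
read_gene_positions <- function(path, format = NULL, species = NULL,
                                gff3_types = c("gene", "mRNA")) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE))
      "GFF3" else "BED"
  }
  format <- match.arg(toupper(format), c("BED", "GFF3"))
  if (is.null(species))
    species <- sub("\\.[^.]*$", "", basename(path))
  if (format == "BED") {
    genes <- parse_bed(path)
  } else {
    genes <- parse_gff3(path, gff3_types)
  }
  genome(species, genes)
}

parse_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 4L)
  if (length(bad))
    stop("malformed BED line ", lineno[bad[1L]],
         ": fewer than 4 tab-separated fields")
  chrom <- vapply(fields, `[[`, character(1L), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1L), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1L), 3L)))
  name <- vapply(fields, `[[`, character(1L), 4L)
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed BED line ", lineno[bad[1L]], ": non-integer coordinates")
  strand <- ifelse(nf >= 6L,
                   vapply(fields, function(f) if (length(f) >= 6L) f[[6L]] else "+",
                          character(1L)),
                   "+")
  strand[!strand %in% c("+", "-")] <- "+"
  data.frame(gene_id = name, chrom = chrom, start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

parse_gff3 <- function(path, types) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[as.character(gr$type) %in% types]
    ids <- as.character(gr$ID)
    if (anyNA(ids) || any(!nzchar(ids)))
      stop("GFF3 record of kept type lacks an ID attribute")
    # GFF3 1-based inclusive -> 0-based half-open
    data.frame(gene_id = ids,
               chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr),
               strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-",
                               "-", "+"),
               stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    keep <- !grepl("^#", lines) & nzchar(lines)
    lineno <- which(keep)
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 9L)
    if (length(bad))
      stop("malformed GFF3 line ", lineno[bad[1L]], ": fewer than 9 fields")
    type <- vapply(fields, `[[`, character(1L), 3L)
    sel <- type %in% types
    fields <- fields[sel]
    attr9 <- vapply(fields, `[[`, character(1L), 9L)
    ids <- sub(".*(?:^|;)ID=([^;]+).*", "\\1", attr9)
    no_id <- !grepl("(^|;)ID=", attr9)
    if (any(no_id))
      stop("GFF3 record of kept type lacks an ID attribute (line ",
           lineno[sel][which(no_id)[1L]], ")")
    data.frame(gene_id = ids,
               chrom = vapply(fields, `[[`, character(1L), 1L),
               start = as.integer(vapply(fields, `[[`, character(1L), 4L)) - 1L,
               end = as.integer(vapply(fields, `[[`, character(1L), 5L)),
               strand = ifelse(vapply(fields, `[[`, character(1L), 7L) == "-",
                               "-", "+"),
               stringsAsFactors = FALSE)
  }
}

#' Write gene positions as BED
#'
#' Emits 6-column BED (chrom, start, end, gene_id, score 0, strand) in
#' (chromosome, rank) order; round-trips bit-exactly through
#' [read_gene_positions].
#'
#' @param g a [genome].
#' @param path output file.
#' @export
write_gene_positions <- function(g, path) {
  genes <- g$genes
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   genes$chrom, genes$start, genes$end, genes$gene_id,
                   genes$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read coding sequences from FASTA
#'
#' The first whitespace-delimited token of each header is the gene id.
#' Sequences are uppercased; only A, C, G, T, N are accepted.
#'
#' @param path FASTA file.
#' @param strict if TRUE (default) a sequence whose length is not a positive
#'   multiple of 3 is an error; if FALSE it is dropped with a warning.
#' @return named character vector gene_id -> sequence.
#' @export
read_cds_fasta <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1L), 1L)
  seqs <- toupper(as.character(ss))
  names(seqs) <- ids
  bad_chr <- ids[grepl("[^ACGTN]", seqs)]
  if (length(bad_chr))
    stop("non-ACGTN characters in CDS of: ",
         paste(utils::head(bad_chr, 5L), collapse = ", "))
  bad_len <- nchar(seqs) == 0L | nchar(seqs) %% 3L != 0L
  if (any(bad_len)) {
    if (strict)
      stop("CDS length not a positive multiple of 3 for: ",
           paste(utils::head(ids[bad_len], 5L), collapse = ", "))
    warning("dropping ", sum(bad_len), " CDS with length not a multiple of 3")
    seqs <- seqs[!bad_len]
  }
  seqs
}

#' Write coding sequences as FASTA
#' @param cds named character vector gene_id -> sequence.
#' @param path output file.
#' @export
write_cds_fasta <- function(cds, path) {
  ss <- Biostrings::BStringSet(cds)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read a homologous gene-pair table
#'
#' Tab-delimited with at least two columns (gene_a, gene_b, optional score).
#' Pairs are deduplicated; with \code{unordered = TRUE} (a,b) and (b,a) are
#' collapsed. Pairs whose ids do not resolve in the supplied genomes are not
#' fatal: they are returned in the \code{rejects} attribute.
#'
#' @param path pairs file.
#' @param genome_a,genome_b optional genomes used to validate ids.
#' @param unordered collapse (a,b)/(b,a) duplicates (default TRUE).
#' @return data.frame(gene_a, gene_b, score) with attribute \code{rejects}.
#' @export
read_homolog_pairs <- function(path, genome_a = NULL, genome_b = NULL,
                               unordered = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          fill = TRUE, quote = "")
  if (ncol(df) < 2L) stop("homolog pair table needs >= 2 columns")
  pairs <- data.frame(gene_a = as.character(df[[1L]]),
                      gene_b = as.character(df[[2L]]),
                      score = if (ncol(df) >= 3L)
                        suppressWarnings(as.numeric(df[[3L]])) else NA_real_,
                      stringsAsFactors = FALSE)
  if (unordered) {
    key <- ifelse(pairs$gene_a <= pairs$gene_b,
                  paste(pairs$gene_a, pairs$gene_b, sep = "\r"),
                  paste(pairs$gene_b, pairs$gene_a, sep = "\r"))
  } else {
    key <- paste(pairs$gene_a, pairs$gene_b, sep = "\r")
  }
  pairs <- pairs[!duplicated(key), , drop = FALSE]
  rejects <- pairs[0L, ]
  if (!is.null(genome_a) && !is.null(genome_b)) {
    ok <- pairs$gene_a %in% genome_a$genes$gene_id &
      pairs$gene_b %in% genome_b$genes$gene_id
    rejects <- pairs[!ok, , drop = FALSE]
    pairs <- pairs[ok, , drop = FALSE]
  }
  rownames(pairs) <- NULL
  rownames(rejects) <- NULL
  attr(pairs, "rejects") <- rejects
  pairs
}

#' Write a homologous gene-pair table
#' @param pairs data.frame(gene_a, gene_b[, score]).
#' @param path output file.
#' @export
write_homolog_pairs <- function(pairs, path) {
  has_score <- "score" %in% names(pairs) && !all(is.na(pairs$score))
  lines <- if (has_score)
    sprintf("%s\t%s\t%s", pairs$gene_a, pairs$gene_b,
            format(pairs$score, trim = TRUE, scientific = FALSE))
  else sprintf("%s\t%s", pairs$gene_a, pairs$gene_b)
  writeLines(lines, path)
  invisible(path)
}

#' Write collinear blocks in an MCScanX-like text layout
#'
#' One header line per block (id, chromosome pair, orientation, score,
#' classification, anchor count) followed by one anchor pair per line.
#' Blocks with orientation "-" serialise anchors in descending rank_b,
#' i.e. in ascending rank_a as found. Re-reading with [read_collinearity]
#' reproduces the block set exactly.
#'
#' @param blocks a \code{collinear_blocks} object (see [chain_anchors]).
#' @param path output file.
#' @export
write_collinearity <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# collinearity: %s vs %s, %d block(s)",
                     attr(blocks, "species_a") %||% "a",
                     attr(blocks, "species_b") %||% "b",
                     length(blocks)), con)
  for (b in blocks) {
    writeLines(sprintf("## block %s %s %s %s %.12g %s %d",
                       b$block_id, b$chr_a, b$chr_b, b$orientation,
                       b$score, b$classification, nrow(b$anchors)), con)
    a <- b$anchors
    writeLines(sprintf("%s\t%s\t%d\t%d\t%s\t%.12g",
                       a$gene_a, a$gene_b, a$rank_a, a$rank_b,
                       a$strand_match, a$score), con)
  }
  invisible(path)
}

#' Read collinear blocks written by [write_collinearity]
#' @param path collinearity file.
#' @return a \code{collinear_blocks} object.
#' @export
read_collinearity <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- grep("^## block ", lines)
  blocks <- vector("list", length(hdr))
  bounds <- c(hdr, length(lines) + 1L)
  for (i in seq_along(hdr)) {
    h <- strsplit(sub("^## block ", "", lines[hdr[i]]), " ", fixed = TRUE)[[1L]]
    body <- lines[seq.int(hdr[i] + 1L, bounds[i + 1L] - 1L)]
    body <- body[nzchar(body) & !grepl("^#", body)]
    f <- strsplit(body, "\t", fixed = TRUE)
    anchors <- data.frame(
      gene_a = vapply(f, `[[`, character(1L), 1L),
      gene_b = vapply(f, `[[`, character(1L), 2L),
      chr_a = h[2L],
      rank_a = as.integer(vapply(f, `[[`, character(1L), 3L)),
      chr_b = h[3L],
      rank_b = as.integer(vapply(f, `[[`, character(1L), 4L)),
      strand_match = vapply(f, `[[`, character(1L), 5L),
      score = as.numeric(vapply(f, `[[`, character(1L), 6L)),
      stringsAsFactors = FALSE)
    blocks[[i]] <- new_block(block_id = h[1L], chr_a = h[2L], chr_b = h[3L],
                             orientation = h[4L], score = as.numeric(h[5L]),
                             classification = h[6L], anchors = anchors)
  }
  structure(blocks, class = "collinear_blocks")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
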