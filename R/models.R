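# ---- core interval models -------------------------------------------------
# All coordinates are 1-based closed genomic intervals, as in GTF.

#' Construct a transcript model
#'
#' A transcript is an ordered set of non-overlapping exons on one strand of
#' one chromosome, optionally carrying CDS anchors (genomic positions of the
#' outermost coding bases, ascending).
#'
#' @param transcript_id,gene_id Character scalars.
#' @param chrom Chromosome identifier.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix (start, end), 1-based closed; rows need not
#'   be pre-sorted, they are ordered by genomic start.
#' @param cds Optional length-2 numeric: genomic ascending (left, right)
#'   anchors of the annotated CDS including the stop codon, or `NULL`.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             cds = NULL) {
  exons <- matrix(as.numeric(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  t <- structure(
    list(transcript_id = as.character(transcript_id),
         gene_id = as.character(gene_id),
         chrom = as.character(chrom),
         strand = strand,
         exons = exons,
         cds = if (is.null(cds)) NULL else as.numeric(cds)),
    class = "transcript_model")
  validate_transcript(t)
  t
}

validate_transcript <- function(t) {
  if (!t$strand %in% c("+", "-"))
    stop("transcript ", t$transcript_id, ": strand must be '+' or '-'")
  ex <- t$exons
  if (nrow(ex) < 1L)
    stop("transcript ", t$transcript_id, ": needs at least one exon")
  if (any(ex[, 2] < ex[, 1]))
    stop("transcript ", t$transcript_id, ": exon with end < start")
  if (nrow(ex) > 1L) {
    # require a >=1 nt gap so every junction yields a well-formed intron
    if (any(ex[-1L, 1] <= ex[-nrow(ex), 2] + 1L))
      stop("transcript ", t$transcript_id,
           ": exons overlap or are adjacent (zero-length intron)")
  }
  if (!is.null(t$cds)) {
    if (length(t$cds) != 2L || t$cds[1] > t$cds[2])
      stop("transcript ", t$transcript_id, ": malformed CDS anchors")
    if (is.na(genomic_to_tx(t, t$cds[1])) || is.na(genomic_to_tx(t, t$cds[2])))
      stop("transcript ", t$transcript_id, ": CDS outside exon union")
  }
  invisible(t)
}

#' Construct a gene model
#'
#' @param gene_id Character scalar.
#' @param transcripts List of [transcript_model()] objects; all must share
#'   chromosome, strand, and this gene id.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, transcripts) {
  if (length(transcripts) < 1L) stop("gene ", gene_id, ": no transcripts")
  ids <- vapply(transcripts, function(t) t$transcript_id, character(1))
  if (anyDuplicated(ids))
    stop("gene ", gene_id, ": duplicate transcript id ",
         ids[duplicated(ids)][1])
  chroms <- unique(vapply(transcripts, function(t) t$chrom, character(1)))
  strands <- unique(vapply(transcripts, function(t) t$strand, character(1)))
  if (length(chroms) != 1L)
    stop("gene ", gene_id, ": transcripts on multiple chromosomes")
  if (length(strands) != 1L)
    stop("gene ", gene_id, ": transcripts on conflicting strands")
  bad <- vapply(transcripts, function(t) t$gene_id != gene_id, logical(1))
  if (any(bad))
    stop("gene ", gene_id, ": transcript ", ids[bad][1],
         " carries a different gene id")
  names(transcripts) <- ids
  structure(list(gene_id = as.character(gene_id), chrom = chroms,
                 strand = strands, transcripts = transcripts),
            class = "gene_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript %s (%s) %s:%s %d exon(s), span %d-%d%s>\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand, nrow(x$exons),
              min(x$exons[, 1]), max(x$exons[, 2]),
              if (is.null(x$cds)) "" else " +CDS"))
  invisible(x)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene %s %s:%s with %d transcript(s)>\n",
              x$gene_id, x$chrom, x$strand, length(x$transcripts)))
  invisible(x)
}

# ---- introns --------------------------------------------------------------

#' Introns of a transcript
#'
#' @param t A [transcript_model()].
#' @return Matrix with columns start, end: the `n_exons - 1` introns in
#'   genomic order; 0 rows for a single-exon transcript. Intron i spans
#'   `(exon_i end + 1, exon_{i+1} start - 1)`.
#' @export
introns_of <- function(t) {
  ex <- t$exons
  n <- nrow(ex)
  if (n < 2L)
    return(matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  cbind(start = ex[-n, 2] + 1, end = ex[-1L, 1] - 1)
}

# ---- genome sequences -----------------------------------------------------

#' Read a genome FASTA into a DNAStringSet
#'
#' Names are truncated at the first whitespace, matching the usual
#' chromosome-id convention of annotation files.
#'
#' @param path Path to a (possibly multi-record) FASTA file.
#' @return A [Biostrings::DNAStringSet] keyed by chromosome id.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write a genome FASTA
#' @param genome Named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @export
write_genome <- function(genome, path) {
  genome <- as_genome(genome)
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && !is.null(names(genome)))
    return(Biostrings::DNAStringSet(genome))
  stop("genome must be a named character vector or DNAStringSet")
}

genome_fetch <- function(genome, chrom, start, end) {
  genome <- as_genome(genome)
  if (!chrom %in% names(genome))
    stop("chromosome '", chrom, "' not present in genome")
  len <- length(genome[[chrom]])
  if (start < 1 || end > len)
    stop("interval ", start, "-", end, " out of bounds for chromosome '",
         chrom, "' (length ", len, ")")
  as.character(Biostrings::subseq(genome[[chrom]], start, end))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Spliced (mature) sequence of a transcript
#'
#' Exon substrings concatenated in genomic order, reverse-complemented for
#' minus-strand transcripts, so the result reads 5' to 3' in transcript
#' orientation.
#'
#' @param t A [transcript_model()].
#' @param genome Genome sequences (named character or DNAStringSet).
#' @return Single nucleotide string of length `sum(exon widths)`.
#' @export
spliced_sequence <- function(t, genome) {
  parts <- apply(t$exons, 1L, function(e)
    genome_fetch(genome, t$chrom, e[1], e[2]))
  s <- paste0(parts, collapse = "")
  if (t$strand == "-") s <- revcomp(s)
  s
}

# ---- coordinate mapping ---------------------------------------------------
# Transcript coordinates are 1-based along the spliced sequence, 5'->3'.

tx_length <- function(t) sum(t$exons[, 2] - t$exons[, 1] + 1)

# genomic position -> transcript coordinate (NA when intronic / outside)
genomic_to_tx <- function(t, gpos) {
  ex <- t$exons
  w <- ex[, 2] - ex[, 1] + 1
  offs <- cumsum(c(0, w[-length(w)]))       # plus-strand prefix lengths
  hit <- which(gpos >= ex[, 1] & gpos <= ex[, 2])
  if (length(hit) != 1L) return(NA_real_)
  plus_pos <- unname(offs[hit] + (gpos - ex[hit, 1] + 1))
  if (t$strand == "+") plus_pos else tx_length(t) - plus_pos + 1
}

# transcript coordinate -> genomic position
tx_to_genomic <- function(t, tpos) {
  L <- tx_length(t)
  if (tpos < 1 || tpos > L) return(NA_real_)
  plus_pos <- if (t$strand == "+") tpos else L - tpos + 1
  ex <- t$exons
  w <- ex[, 2] - ex[, 1] + 1
  ends <- cumsum(w)
  hit <- which(plus_pos <= ends)[1L]
  unname(ex[hit, 1] + (plus_pos - (ends[hit] - w[hit]) - 1))
}

# transcript coordinate of the last base of exon i (genomic order), used for
# locating exon-exon junctions in transcript orientation
tx_junctions <- function(t) {
  n <- nrow(t$exons)
  if (n < 2L) return(numeric(0))
  w <- t$exons[, 2] - t$exons[, 1] + 1
  plus_ends <- cumsum(w)[-n]
  j <- if (t$strand == "+") plus_ends else sort(tx_length(t) - plus_ends)
  j
}
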