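# PTC classification of intron-retaining transcripts.
#
# The PTC criterion is positional: the retained transcript is translated
# from the gene's reference start codon, and the call is PTC+ iff its first
# in-frame stop maps genomically upstream (in transcript orientation) of the
# reference stop codon. The 50-nt last-junction NMD rule is reported as an
# auxiliary flag, not as the verdict.

STOP_CODONS <- c("TAA", "TAG", "TGA")

codon_at <- function(seq, i) substr(seq, i, i + 2L)

# first in-frame stop at or after transcript position `from` (1-based);
# returns the position of the stop's first base or NA
first_stop_from <- function(seq, from) {
  n <- nchar(seq)
  i <- from
  while (i + 2L <= n) {
    if (codon_at(seq, i) %in% STOP_CODONS) return(i)
    i <- i + 3L
  }
  NA_integer_
}

# longest ATG-initiated ORF in a nucleotide string; open-ended ORFs (no stop
# before the sequence end) count with their truncated length.
# Returns list(start, n_codons) — n_codons excludes the stop — or NULL.
longest_orf <- function(seq) {
  n <- nchar(seq)
  best <- NULL
  starts <- gregexpr("ATG", seq, fixed = TRUE)[[1L]]
  if (starts[1L] == -1L) return(NULL)
  claimed <- logical(3L)  # per frame: positions already inside a scanned ORF
  frame_next <- c(1L, 1L, 1L)
  for (s in starts) {
    fr <- ((s - 1L) %% 3L) + 1L
    if (s < frame_next[fr]) next   # nested in an already-scanned ORF
    stop_at <- first_stop_from(seq, s)
    len <- if (is.na(stop_at)) (n - s + 1L) %/% 3L else (stop_at - s) %/% 3L
    if (is.null(best) || len > best$n_codons) best <- list(start = s,
                                                           n_codons = len)
    frame_next[fr] <- if (is.na(stop_at)) n + 1L else stop_at + 3L
  }
  best
}

#' Resolve a gene's reference ORF
#'
#' If any transcript carries an annotated CDS, the longest annotated CDS is
#' the reference; otherwise the longest ATG-initiated ORF across transcripts
#' (at least `min_codons` codons) is used.
#'
#' @param g A [gene_model()].
#' @param genome Genome sequences.
#' @param min_codons Minimum ORF length in codons for the ORF fallback
#'   (default 100).
#' @return List with `transcript_id`, `start_genomic` (first base of the
#'   start codon), `stop_genomic` (first base of the stop codon, genomic
#'   coordinates, transcript orientation), and `source` ("cds" or "orf");
#'   or `NULL` when undetermined.
#' @export
reference_orf <- function(g, genome, min_codons = 100) {
  with_cds <- Filter(function(t) !is.null(t$cds), g$transcripts)
  if (length(with_cds)) {
    # CDS length in spliced coordinates; anchors are genomic ascending
    lens <- vapply(with_cds, function(t) {
      a <- genomic_to_tx(t, t$cds[1]); b <- genomic_to_tx(t, t$cds[2])
      abs(b - a) + 1
    }, numeric(1))
    ord <- order(-lens, names(with_cds))
    t <- with_cds[[ord[1L]]]
    # transcript-oriented: start codon at the 5' anchor, stop at the 3' end
    a <- genomic_to_tx(t, t$cds[1]); b <- genomic_to_tx(t, t$cds[2])
    start_tx <- min(a, b); stop_tx <- max(a, b) - 2L
    return(list(transcript_id = t$transcript_id,
                start_genomic = tx_to_genomic(t, start_tx),
                stop_genomic = tx_to_genomic(t, stop_tx),
                source = "cds"))
  }
  best <- NULL
  for (t in g$transcripts) {
    orf <- longest_orf(spliced_sequence(t, genome))
    if (!is.null(orf) && orf$n_codons >= min_codons &&
        (is.null(best) || orf$n_codons > best$orf$n_codons))
      best <- list(t = t, orf = orf)
  }
  if (is.null(best)) return(NULL)
  t <- best$t
  stop_tx <- best$orf$start + 3L * best$orf$n_codons
  list(transcript_id = t$transcript_id,
       start_genomic = tx_to_genomic(t, best$orf$start),
       stop_genomic = if (stop_tx + 2L <= tx_length(t))
         tx_to_genomic(t, stop_tx) else NA_real_,
       source = "orf")
}

#' Classify an intron-retaining transcript as PTC+/PTC-
#'
#' The reference start codon is mapped into the retaining transcript, which
#' is then translated codon-by-codon. PTC+ iff the first in-frame stop maps
#' genomically upstream, in transcript orientation, of the reference stop
#' codon. Undetermined when the reference start does not map into the
#' transcript (or no reference was resolvable).
#'
#' @param t_ir The retaining [transcript_model()]; the retained intron must
#'   lie inside one of its exons together with both flanks.
#' @param ref Reference anchors from [reference_orf()] (or `NULL`).
#' @param genome Genome sequences.
#' @param retained_intron Length-2 numeric (start, end) of the retained
#'   intron, genomic coordinates.
#' @return A one-row data.frame: `transcript_id`, `gene_id`, `intron_start`,
#'   `intron_end`, `orf_start_tx`, `first_stop_tx`, `status`
#'   (`"PTC+"`, `"PTC-"` or `"undetermined"`), `nmd_50nt_flag` (stop more
#'   than 50 nt upstream of the last exon-exon junction).
#' @export
classify_ptc <- function(t_ir, ref, genome, retained_intron) {
  ri <- as.numeric(retained_intron)
  host <- which(t_ir$exons[, 1] <= ri[1] - 1 & t_ir$exons[, 2] >= ri[2] + 1)
  if (!length(host))
    stop("transcript ", t_ir$transcript_id,
         " does not retain intron ", ri[1], "-", ri[2])
  res <- data.frame(transcript_id = t_ir$transcript_id,
                    gene_id = t_ir$gene_id,
                    intron_start = ri[1], intron_end = ri[2],
                    orf_start_tx = NA_real_, first_stop_tx = NA_real_,
                    status = "undetermined", nmd_50nt_flag = NA,
                    stringsAsFactors = FALSE)
  if (is.null(ref) || is.na(ref$start_genomic)) return(res)
  start_tx <- genomic_to_tx(t_ir, ref$start_genomic)
  if (is.na(start_tx)) return(res)
  seq <- spliced_sequence(t_ir, genome)
  res$orf_start_tx <- start_tx
  stop_tx <- first_stop_from(seq, start_tx)
  if (is.na(stop_tx)) {                      # runs off the end: no premature stop
    res$status <- "PTC-"
    res$nmd_50nt_flag <- FALSE
    return(res)
  }
  res$first_stop_tx <- stop_tx
  stop_genomic <- tx_to_genomic(t_ir, stop_tx)
  upstream <- if (is.na(ref$stop_genomic)) FALSE
    else if (t_ir$strand == "+") stop_genomic < ref$stop_genomic
    else stop_genomic > ref$stop_genomic
  res$status <- if (upstream) "PTC+" else "PTC-"
  j <- tx_junctions(t_ir)
  res$nmd_50nt_flag <- upstream && length(j) > 0 &&
    (max(j) - (stop_tx + 2L)) > 50
  res
}

#' Expression filter for intron-retaining transcripts
#'
#' Keeps a transcript iff its FPKM presence rule (mean replicate FPKM at or
#' above `min_fpkm`) holds in at least one tissue; transcripts below the
#' threshold in every tissue are removed.
#'
#' @param transcript_ids Character vector of transcript ids.
#' @param expr An [expression_matrix()] covering all queried transcripts.
#' @param min_fpkm Threshold (default 1).
#' @return Character vector of retained transcript ids.
#' @export
expression_filter <- function(transcript_ids, expr, min_fpkm = 1) {
  miss <- setdiff(transcript_ids, rownames(expr$values))
  if (length(miss))
    stop("no expression row for transcript ", miss[1])
  pres <- tissue_presence(expr, min_fpkm = min_fpkm)
  transcript_ids[rowSums(pres[transcript_ids, , drop = FALSE]) >= 1L]
}

#' Per-tissue PTC census
#'
#' @param calls Row-bound [classify_ptc()] results (resolved calls only are
#'   tallied; undetermined rows are ignored).
#' @param expr Transcript-level [expression_matrix()].
#' @param min_fpkm Presence threshold (default 1).
#' @return List with `per_tissue` (data.frame tissue, n_ptc_plus,
#'   n_ptc_minus), `shared` and `specific` counts per status, totals, and
#'   `ratio` (total PTC+ / total PTC-).
#' @export
ptc_census <- function(calls, expr, min_fpkm = 1) {
  calls <- calls[calls$status %in% c("PTC+", "PTC-"), , drop = FALSE]
  tissues <- unique(unname(expr$tissues))
  if (nrow(calls) == 0L) {
    per_tissue <- data.frame(tissue = tissues, n_ptc_plus = 0L,
                             n_ptc_minus = 0L, stringsAsFactors = FALSE)
    return(list(per_tissue = per_tissue,
                shared = c("PTC+" = 0L, "PTC-" = 0L),
                specific = c("PTC+" = 0L, "PTC-" = 0L),
                total = c("PTC+" = 0L, "PTC-" = 0L), ratio = NaN))
  }
  pres <- tissue_presence(expr, min_fpkm = min_fpkm)
  pres <- pres[calls$transcript_id, , drop = FALSE]
  plus <- calls$status == "PTC+"
  per_tissue <- data.frame(
    tissue = colnames(pres),
    n_ptc_plus = colSums(pres[plus, , drop = FALSE]),
    n_ptc_minus = colSums(pres[!plus, , drop = FALSE]),
    stringsAsFactors = FALSE)
  rownames(per_tissue) <- NULL
  n_tis <- rowSums(pres)
  tally <- function(sel) c("PTC+" = sum(sel & plus),
                           "PTC-" = sum(sel & !plus))
  total <- tally(n_tis >= 1L)
  list(per_tissue = per_tissue,
       shared = tally(n_tis == ncol(pres)),
       specific = tally(n_tis == 1L),
       total = total,
       ratio = unname(total["PTC+"] / total["PTC-"]))
}

#' Write PTC calls as TSV
#' @param calls Row-bound [classify_ptc()] results.
#' @param path Output path.
#' @export
write_ptc_table <- function(calls, path) {
  utils::write.table(
    calls[, c("transcript_id", "gene_id", "intron_start", "intron_end",
              "status", "nmd_50nt_flag")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
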