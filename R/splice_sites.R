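# Intron terminal-dinucleotide extraction and AS/non-AS splice-site
# composition profiles.

#' Terminal dinucleotides of a transcript's introns
#'
#' For each intron, the first two (donor) and last two (acceptor) intron
#' bases in transcript orientation: on the minus strand the genomic-forward
#' intron sequence is reverse-complemented, so the donor is the genomic
#' right end. Introns shorter than 4 nt are reported as the degenerate pair
#' ("NN", "NN").
#'
#' @param t A [transcript_model()].
#' @param genome Genome sequences.
#' @return data.frame `intron_start`, `intron_end`, `donor`, `acceptor`;
#'   zero rows for a single-exon transcript.
#' @export
terminal_dinucleotides <- function(t, genome) {
  ins <- introns_of(t)
  out <- data.frame(intron_start = numeric(0), intron_end = numeric(0),
                    donor = character(0), acceptor = character(0),
                    stringsAsFactors = FALSE)
  if (!nrow(ins)) return(out)
  for (i in seq_len(nrow(ins))) {
    s <- ins[i, 1]; e <- ins[i, 2]
    if (e - s + 1 < 4) {
      donor <- "NN"; acceptor <- "NN"
    } else {
      left <- genome_fetch(genome, t$chrom, s, s + 1)
      right <- genome_fetch(genome, t$chrom, e - 1, e)
      if (t$strand == "+") {
        donor <- left; acceptor <- right
      } else {
        donor <- revcomp(right); acceptor <- revcomp(left)
      }
    }
    out[i, ] <- list(s, e, donor, acceptor)
  }
  out
}

#' Splice-site composition profiles for AS and non-AS genes
#'
#' Introns are pooled per transcript (an intron shared by two isoforms
#' counts once per isoform) unless `unique_introns = TRUE`, in which case
#' each distinct genomic intron of a gene counts once.
#'
#' @param genes List of [gene_model()] objects.
#' @param as_flags Named logical (from [classify_genes()]`$flags`).
#' @param genome Genome sequences.
#' @param unique_introns Deduplicate introns within each gene first?
#' @return Object of class `splice_site_profile`: data.frame `group`
#'   (`"AS"`/`"non-AS"`), `donor`, `acceptor`, `count`, `percent` (of the
#'   group total), ordered by group then count descending; attribute
#'   `totals` holds per-group intron totals.
#' @export
site_proportions <- function(genes, as_flags, genome,
                             unique_introns = FALSE) {
  rows <- list()
  for (g in genes) {
    grp <- if (isTRUE(as_flags[[g$gene_id]])) "AS" else "non-AS"
    dts <- lapply(g$transcripts, terminal_dinucleotides, genome = genome)
    dt <- do.call(rbind, dts)
    if (is.null(dt) || !nrow(dt)) next
    if (unique_introns)
      dt <- dt[!duplicated(dt[, c("intron_start", "intron_end")]), ,
               drop = FALSE]
    dt$group <- grp
    rows[[length(rows) + 1L]] <- dt
  }
  if (!length(rows)) {
    out <- data.frame(group = character(0), donor = character(0),
                      acceptor = character(0), count = numeric(0),
                      percent = numeric(0), stringsAsFactors = FALSE)
    return(structure(out, totals = c("AS" = 0, "non-AS" = 0),
                     class = c("splice_site_profile", "data.frame")))
  }
  all <- do.call(rbind, rows)
  agg <- stats::aggregate(list(count = rep(1L, nrow(all))),
                          by = all[, c("group", "donor", "acceptor")],
                          FUN = sum)
  totals <- tapply(agg$count, agg$group, sum)
  agg$percent <- round(100 * agg$count / totals[agg$group], 2)
  agg <- agg[order(agg$group, -agg$count, agg$donor, agg$acceptor), ]
  rownames(agg) <- NULL
  structure(agg, totals = totals,
            class = c("splice_site_profile", "data.frame"))
}

#' @export
print.splice_site_profile <- function(x, top = 5L, ...) {
  totals <- attr(x, "totals")
  for (grp in unique(x$group)) {
    cat(sprintf("%s genes (%d introns), top %d splice sites:\n",
                grp, totals[[grp]], top))
    sub <- x[x$group == grp, , drop = FALSE]
    print.data.frame(utils::head(sub, top), row.names = FALSE)
  }
  invisible(x)
}

#' Write a splice-site profile as TSV
#' @param profile A `splice_site_profile`.
#' @param path Output path.
#' @export
write_site_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
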