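# Gene-structure statistics and their relationships with AS status,
# AS-event frequency and event type; plus the ORF-based noncoding flag.

#' Per-gene structure feature table
#'
#' The representative structure of a gene is its transcript with the most
#' exons (ties broken by spliced length, then transcript id): exon counts,
#' lengths and intron lengths are taken from it. Averages undefined for
#' single-exon representatives (intron metrics) are reported as `NA`, not 0.
#'
#' @param genes List of [gene_model()] objects.
#' @param events Event table from [enumerate_events_all()].
#' @return data.frame, one row per gene: `gene_id`, `n_transcripts`,
#'   `exon_count`, `transcript_length`, `total_exon_length`,
#'   `total_intron_length`, `avg_exon_length`, `avg_intron_length`,
#'   `as_flag`, `event_count`, `event_types` (comma list).
#' @export
feature_table <- function(genes, events) {
  ev_by_gene <- split(events$type, events$gene_id)
  rows <- lapply(genes, function(g) {
    nex <- vapply(g$transcripts, function(t) nrow(t$exons), integer(1))
    lens <- vapply(g$transcripts, tx_length, numeric(1))
    ord <- order(-nex, -lens, names(g$transcripts))
    rep_t <- g$transcripts[[ord[1L]]]
    ins <- introns_of(rep_t)
    exon_w <- rep_t$exons[, 2] - rep_t$exons[, 1] + 1
    intron_w <- if (nrow(ins)) ins[, 2] - ins[, 1] + 1 else numeric(0)
    types <- ev_by_gene[[g$gene_id]]
    data.frame(
      gene_id = g$gene_id,
      n_transcripts = length(g$transcripts),
      exon_count = nrow(rep_t$exons),
      transcript_length = sum(exon_w),
      total_exon_length = sum(exon_w),
      total_intron_length = if (length(intron_w)) sum(intron_w) else NA_real_,
      avg_exon_length = mean(exon_w),
      avg_intron_length = if (length(intron_w)) mean(intron_w) else NA_real_,
      as_flag = !is.null(types),
      event_count = length(types),
      event_types = if (is.null(types)) "" else
        paste(sort(unique(types)), collapse = ","),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

FEATURE_METRICS <- c("transcript_length", "exon_count", "total_exon_length",
                     "total_intron_length", "avg_exon_length",
                     "avg_intron_length")

#' Group summaries of structure metrics (AS vs non-AS)
#'
#' Quantiles use linear interpolation (`stats::quantile` type 7) and are
#' computed over defined values only (NA intron metrics of single-exon
#' genes are excluded, not zero-filled).
#'
#' @param records Output of [feature_table()].
#' @return data.frame `group`, `metric`, `n`, `p5`, `q1`, `median`, `q3`,
#'   `p95`; attribute `quantile_type = 7`.
#' @export
compare_groups <- function(records) {
  groups <- list("AS" = records[records$as_flag, , drop = FALSE],
                 "non-AS" = records[!records$as_flag, , drop = FALSE])
  if (any(vapply(groups, nrow, integer(1)) == 0L))
    stop("both AS and non-AS groups must be non-empty")
  rows <- list()
  for (grp in names(groups)) {
    for (m in FEATURE_METRICS) {
      v <- groups[[grp]][[m]]
      v <- v[!is.na(v)]
      q <- stats::quantile(v, probs = c(.05, .25, .5, .75, .95), type = 7,
                           names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        group = grp, metric = m, n = length(v), p5 = q[1], q1 = q[2],
        median = q[3], q3 = q[4], p95 = q[5], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "quantile_type") <- 7L
  out
}

#' Structure metrics by AS-event-count bin
#'
#' AS genes are binned by event count (1, 2, ..., >= `max_bin`); per-bin
#' means of the structure metrics are reported.
#'
#' @param records Output of [feature_table()]; non-AS genes are dropped.
#' @param max_bin Events at or above this count share the top bin
#'   (default 5).
#' @return data.frame `bin` (label), `n`, and `mean_<metric>` columns.
#' @export
events_vs_structure <- function(records, max_bin = 5L) {
  rec <- records[records$as_flag & records$event_count >= 1L, , drop = FALSE]
  bin <- pmin(rec$event_count, max_bin)
  labs <- c(as.character(seq_len(max_bin - 1L)), paste0(">=", max_bin))
  rows <- lapply(sort(unique(bin)), function(b) {
    sub <- rec[bin == b, , drop = FALSE]
    means <- vapply(FEATURE_METRICS, function(m)
      mean(sub[[m]], na.rm = TRUE), numeric(1))
    cbind(data.frame(bin = labs[b], n = nrow(sub), stringsAsFactors = FALSE),
          as.data.frame(as.list(stats::setNames(means,
                                                paste0("mean_",
                                                       FEATURE_METRICS)))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Structure metrics by event type
#'
#' A gene contributes to every event type it exhibits.
#'
#' @param records Output of [feature_table()].
#' @param events Event table.
#' @return data.frame `type`, `n_genes`, and mean/median of average exon
#'   length, average intron length and exon count.
#' @export
features_by_event_type <- function(records, events) {
  rows <- list()
  for (ty in EVENT_TYPES) {
    gids <- unique(events$gene_id[events$type == ty])
    if (!length(gids)) next
    sub <- records[records$gene_id %in% gids, , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      type = ty, n_genes = nrow(sub),
      mean_avg_exon_length = mean(sub$avg_exon_length, na.rm = TRUE),
      median_avg_exon_length = stats::median(sub$avg_exon_length,
                                             na.rm = TRUE),
      mean_avg_intron_length = mean(sub$avg_intron_length, na.rm = TRUE),
      median_avg_intron_length = stats::median(sub$avg_intron_length,
                                               na.rm = TRUE),
      mean_exon_count = mean(sub$exon_count),
      median_exon_count = stats::median(sub$exon_count),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flag a transcript as putatively noncoding
#'
#' A transcript is flagged noncoding iff its spliced length is at least
#' `min_len` nucleotides and its longest ATG-initiated ORF is shorter than
#' `max_orf_codons` codons — the conventional lncRNA length/ORF screen.
#'
#' @param t A [transcript_model()].
#' @param genome Genome sequences.
#' @param min_len Minimum length in nt (default 200).
#' @param max_orf_codons ORF-length cutoff in codons (default 100).
#' @return Logical scalar.
#' @export
flag_noncoding <- function(t, genome, min_len = 200, max_orf_codons = 100) {
  seq <- spliced_sequence(t, genome)
  if (nchar(seq) < min_len) return(FALSE)
  orf <- longest_orf(seq)
  is.null(orf) || orf$n_codons < max_orf_codons
}
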