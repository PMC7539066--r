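# Annotation reading/writing. Parsing is delegated to rtracklayer; a light
# pre-scan gives line-numbered errors for structurally broken files, which
# the GFF parser does not report.

#' Read a GTF/GFF3 annotation into gene models
#'
#' Transcripts are reconstructed from `exon` features; `CDS` features, when
#' present, set the transcript's CDS anchors (outermost coding coordinates).
#' GFF3 files are supported through their `ID`/`Parent` attributes.
#'
#' @param path GTF (2.2) or GFF3 file.
#' @param genome Optional genome; when supplied, every referenced chromosome
#'   must exist and all exons must be within bounds.
#' @return Named list of [gene_model()] objects, ordered by
#'   (chromosome, gene start, gene id).
#' @export
read_annotation <- function(path, genome = NULL) {
  n_content <- prescan_annotation(path)
  if (n_content == 0L)
    return(structure(list(), class = "gene_model_list"))
  gr <- rtracklayer::import(path)
  if (length(gr) == 0L) return(structure(list(), class = "gene_model_list"))
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  if (is.null(df$type)) stop("annotation lacks a feature-type column")
  df$type <- as.character(df$type)

  if (is.null(df$transcript_id) || all(is.na(df$transcript_id))) {
    # GFF3 route: map exon Parent -> transcript, transcript Parent -> gene
    df <- gff3_assign_ids(df)
  }
  ex <- df[df$type == "exon", , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]
  if (nrow(ex) == 0L) return(structure(list(), class = "gene_model_list"))
  if (any(is.na(ex$transcript_id)) || any(is.na(ex$gene_id)))
    stop("exon feature without transcript/gene attributes in ", path)

  genes <- list()
  for (gid in unique(ex$gene_id)) {
    gex <- ex[ex$gene_id == gid, , drop = FALSE]
    txs <- lapply(unique(gex$transcript_id), function(tid) {
      tex <- gex[gex$transcript_id == tid, , drop = FALSE]
      chrom <- unique(tex$seqnames); strand <- unique(tex$strand)
      if (length(chrom) > 1L)
        stop("transcript ", tid, " spans multiple chromosomes")
      if (length(strand) > 1L)
        stop("transcript ", tid, " spans both strands")
      tcds <- cds[!is.na(cds$transcript_id) & cds$transcript_id == tid, ,
                  drop = FALSE]
      anchors <- if (nrow(tcds)) c(min(tcds$start), max(tcds$end)) else NULL
      transcript_model(tid, gid, chrom, strand,
                       cbind(tex$start, tex$end), cds = anchors)
    })
    genes[[gid]] <- gene_model(gid, txs)
  }
  if (!is.null(genome)) validate_against_genome(genes, genome)
  ord <- order(vapply(genes, function(g) g$chrom, character(1)),
               vapply(genes, function(g) min(g$transcripts[[1]]$exons[, 1]),
                      numeric(1)),
               vapply(genes, function(g) g$gene_id, character(1)))
  structure(genes[ord], class = "gene_model_list")
}

prescan_annotation <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n_content <- 0L
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    n_content <- n_content + 1L
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L)
      stop("malformed annotation line ", i, " in ", path,
           " (fewer than 8 tab-separated fields)")
    if (is.na(suppressWarnings(as.numeric(f[4]))) ||
        is.na(suppressWarnings(as.numeric(f[5]))))
      stop("malformed annotation line ", i, " in ", path,
           " (non-numeric coordinates)")
  }
  n_content
}

gff3_assign_ids <- function(df) {
  id <- if (!is.null(df$ID)) as.character(df$ID) else rep(NA_character_,
                                                          nrow(df))
  parent <- df$Parent
  parent <- if (is.null(parent)) rep(NA_character_, nrow(df)) else
    vapply(as.list(parent), function(p)
      if (length(p)) as.character(p[[1]]) else NA_character_, character(1))
  is_tx <- df$type %in% c("mRNA", "transcript", "lnc_RNA", "ncRNA")
  tx2gene <- stats::setNames(parent[is_tx], id[is_tx])
  df$transcript_id <- ifelse(df$type %in% c("exon", "CDS"), parent, id)
  df$gene_id <- ifelse(df$type %in% c("exon", "CDS"),
                       tx2gene[df$transcript_id],
                       ifelse(is_tx, parent, id))
  df
}

validate_against_genome <- function(genes, genome) {
  genome <- as_genome(genome)
  for (g in genes) {
    if (!g$chrom %in% names(genome))
      stop("gene ", g$gene_id, " references unknown chromosome '",
           g$chrom, "'")
    len <- length(genome[[g$chrom]])
    for (t in g$transcripts)
      if (max(t$exons[, 2]) > len || min(t$exons[, 1]) < 1)
        stop("transcript ", t$transcript_id, " out of bounds for '",
             g$chrom, "'")
  }
  invisible(TRUE)
}

#' Write gene models as GTF
#'
#' Emits one `exon` row per exon and one `CDS` row per annotated CDS span,
#' with `gene_id`/`transcript_id` attributes, sorted by
#' (chromosome, start, gene, transcript).
#'
#' @param genes List of [gene_model()] objects.
#' @param path Output GTF path.
#' @export
write_annotation <- function(genes, path) {
  rows <- list()
  for (g in genes) {
    for (t in g$transcripts) {
      for (i in seq_len(nrow(t$exons))) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = t$chrom, start = t$exons[i, 1], end = t$exons[i, 2],
          strand = t$strand, type = "exon", gene_id = g$gene_id,
          transcript_id = t$transcript_id, stringsAsFactors = FALSE)
      }
      if (!is.null(t$cds)) {
        # one CDS row per overlapped exon segment
        for (i in seq_len(nrow(t$exons))) {
          s <- max(t$exons[i, 1], t$cds[1]); e <- min(t$exons[i, 2], t$cds[2])
          if (s <= e)
            rows[[length(rows) + 1L]] <- data.frame(
              chrom = t$chrom, start = s, end = e, strand = t$strand,
              type = "CDS", gene_id = g$gene_id,
              transcript_id = t$transcript_id, stringsAsFactors = FALSE)
        }
      }
    }
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$chrom, df$start, df$gene_id, df$transcript_id), ]
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$source <- "splicescape"
  S4Vectors::mcols(gr)$gene_id <- df$gene_id
  S4Vectors::mcols(gr)$transcript_id <- df$transcript_id
  # CDS rows carry no phase (anchors suffice for this package's needs)
  suppressWarnings(rtracklayer::export(gr, path, format = "gtf"))
  invisible(path)
}
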