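# Seven-type AS event enumeration by pairwise isoform comparison.
#
# Event definitions (strand-aware; 5'/3' refer to transcript orientation):
#   IR — an intron of the spliced form lies inside a single exon of the
#        retaining form whose outer boundaries equal the spliced form's
#        flanking-exon outer boundaries.
#   ES — an internal exon of one form lies strictly inside an intron of the
#        other whose boundaries match the flanking splice sites.
#   A5/A3 — two introns share one boundary and differ at the other; the exons
#        flanking the differing boundary must overlap (this separates the
#        alternative-site types from terminal-exon and MX configurations).
#        A5 when the differing boundary is the donor side, A3 the acceptor.
#   MX — exactly one internal exon per form between a shared donor and a
#        shared acceptor, the two internal exons non-overlapping.
#   AF/AL — non-overlapping first (AF) or last (AL) exons, in transcript
#        orientation, whose adjacent introns share the internal-side boundary.
#
# Events are deduplicated per gene by (type, signature); signatures are the
# sorted genomic coordinate tuples defining the event (arity: IR 2, ES 4,
# A5/A3 3, MX 6, AF/AL 5).

EVENT_TYPES <- c("IR", "ES", "A3", "A5", "AF", "AL", "MX")

.overlaps <- function(a1, a2, b1, b2) a1 <= b2 && b1 <= a2

# accumulate one event occurrence into the dedup store
.ev_add <- function(store, type, sig, incl, excl) {
  key <- paste(type, paste(sig, collapse = ":"), sep = "|")
  cur <- store[[key]]
  if (is.null(cur)) {
    store[[key]] <- list(type = type, sig = sig, incl = incl, excl = excl)
  } else {
    store[[key]]$incl <- union(cur$incl, incl)
    store[[key]]$excl <- union(cur$excl, excl)
  }
  invisible(NULL)
}

# all events between one ordered pair of transcripts (x, y); symmetric types
# are emitted once, directional types in this direction only
.pair_events <- function(store, x, y, strand) {
  ex <- x$exons; ey <- y$exons
  nx <- nrow(ex); ny <- nrow(ey)
  ix <- introns_of(x); iy <- introns_of(y)

  # IR: intron of x retained inside a single exon of y
  if (nx >= 2L) for (k in seq_len(nx - 1L)) {
    for (f in seq_len(ny)) {
      if (ey[f, 1] == ex[k, 1] && ey[f, 2] == ex[k + 1L, 2]) {
        .ev_add(store, "IR", c(ex[k, 2], ex[k + 1L, 1]),
                incl = y$transcript_id, excl = x$transcript_id)
      }
    }
  }

  # ES: internal exon of x skipped by an intron of y
  if (nx >= 3L && ny >= 2L) for (m in 2:(nx - 1L)) {
    prev_end <- ex[m - 1L, 2]; next_start <- ex[m + 1L, 1]
    for (j in seq_len(nrow(iy))) {
      if (iy[j, 1] == prev_end + 1 && iy[j, 2] == next_start - 1) {
        .ev_add(store, "ES", c(prev_end, ex[m, 1], ex[m, 2], next_start),
                incl = x$transcript_id, excl = y$transcript_id)
      }
    }
  }

  # A5/A3: introns sharing one boundary, overlapping flank at the other
  if (nrow(ix) && nrow(iy)) for (i in seq_len(nrow(ix))) {
    for (j in seq_len(nrow(iy))) {
      if (ix[i, 2] == iy[j, 2] && ix[i, 1] != iy[j, 1]) {
        # differ at genomic-left boundary; flanking exons end at start-1
        fx <- ex[which(ex[, 2] == ix[i, 1] - 1)[1L], ]
        fy <- ey[which(ey[, 2] == iy[j, 1] - 1)[1L], ]
        if (.overlaps(fx[1], fx[2], fy[1], fy[2])) {
          type <- if (strand == "+") "A5" else "A3"
          sig <- c(sort(c(ix[i, 1], iy[j, 1])), ix[i, 2])
          shorter <- if (ix[i, 1] > iy[j, 1]) x else y  # larger start = shorter intron
          longer <- if (ix[i, 1] > iy[j, 1]) y else x
          .ev_add(store, type, sig, incl = shorter$transcript_id,
                  excl = longer$transcript_id)
        }
      } else if (ix[i, 1] == iy[j, 1] && ix[i, 2] != iy[j, 2]) {
        fx <- ex[which(ex[, 1] == ix[i, 2] + 1)[1L], ]
        fy <- ey[which(ey[, 1] == iy[j, 2] + 1)[1L], ]
        if (.overlaps(fx[1], fx[2], fy[1], fy[2])) {
          type <- if (strand == "+") "A3" else "A5"
          sig <- c(ix[i, 1], sort(c(ix[i, 2], iy[j, 2])))
          shorter <- if (ix[i, 2] < iy[j, 2]) x else y
          longer <- if (ix[i, 2] < iy[j, 2]) y else x
          .ev_add(store, type, sig, incl = shorter$transcript_id,
                  excl = longer$transcript_id)
        }
      }
    }
  }

  # MX: shared donor + shared acceptor, one non-overlapping internal exon each
  if (nx >= 3L && ny >= 3L) for (u in seq_len(nx - 2L)) {
    for (v in seq_len(ny - 2L)) {
      if (ex[u, 2] == ey[v, 2] && ex[u + 2L, 1] == ey[v + 2L, 1]) {
        mx <- ex[u + 1L, ]; my <- ey[v + 1L, ]
        if (!.overlaps(mx[1], mx[2], my[1], my[2])) {
          left_is_x <- mx[1] < my[1]
          mL <- if (left_is_x) mx else my
          mR <- if (left_is_x) my else mx
          sig <- c(ex[u, 2], mL[1], mL[2], mR[1], mR[2], ex[u + 2L, 1])
          .ev_add(store, "MX", sig,
                  incl = (if (left_is_x) x else y)$transcript_id,
                  excl = (if (left_is_x) y else x)$transcript_id)
        }
      }
    }
  }

  # AF/AL: alternative terminal exons with shared internal-side boundary
  if (nx >= 2L && ny >= 2L) {
    # genomic-left terminal exons (first on '+', last on '-')
    if (ix[1, 2] == iy[1, 2] &&
        !.overlaps(ex[1, 1], ex[1, 2], ey[1, 1], ey[1, 2])) {
      type <- if (strand == "+") "AF" else "AL"
      sig <- sort(c(ex[1, ], ey[1, ], ix[1, 2] + 1))
      distal_is_x <- ex[1, 1] < ey[1, 1]    # farther from the anchor
      .ev_add(store, type, sig,
              incl = (if (distal_is_x) x else y)$transcript_id,
              excl = (if (distal_is_x) y else x)$transcript_id)
    }
    # genomic-right terminal exons (last on '+', first on '-')
    if (ix[nrow(ix), 1] == iy[nrow(iy), 1] &&
        !.overlaps(ex[nx, 1], ex[nx, 2], ey[ny, 1], ey[ny, 2])) {
      type <- if (strand == "+") "AL" else "AF"
      sig <- sort(c(ex[nx, ], ey[ny, ], ix[nrow(ix), 1] - 1))
      distal_is_x <- ex[nx, 2] > ey[ny, 2]
      .ev_add(store, type, sig,
              incl = (if (distal_is_x) x else y)$transcript_id,
              excl = (if (distal_is_x) y else x)$transcript_id)
    }
  }
  invisible(NULL)
}

#' Enumerate AS events of one gene
#'
#' All unordered transcript pairs are compared; matches of the seven event
#' definitions are collected and deduplicated by (type, signature), with the
#' inclusion/exclusion transcript sets of merged duplicates unioned. Output
#' order is deterministic (type, then signature), independent of transcript
#' input order.
#'
#' @param g A [gene_model()].
#' @return A data.frame with columns `gene_id`, `type`, `signature`
#'   (colon-joined ascending genomic coordinates), `event_id`
#'   (`gene:TYPE:signature:strand`), `inclusion`, `exclusion` (comma-joined
#'   sorted transcript ids), `chrom`, `strand`. Zero rows for a
#'   single-transcript gene.
#' @export
enumerate_events <- function(g) {
  store <- new.env(parent = emptyenv())
  txs <- g$transcripts
  n <- length(txs)
  if (n >= 2L) for (a in 1:(n - 1L)) for (b in (a + 1L):n) {
    .pair_events(store, txs[[a]], txs[[b]], g$strand)
    .pair_events(store, txs[[b]], txs[[a]], g$strand)
  }
  evs <- as.list(store)
  if (!length(evs)) return(empty_event_table())
  df <- do.call(rbind, lapply(evs, function(e) data.frame(
    gene_id = g$gene_id, type = e$type,
    signature = paste(e$sig, collapse = ":"),
    inclusion = paste(sort(e$incl), collapse = ","),
    exclusion = paste(sort(e$excl), collapse = ","),
    chrom = g$chrom, strand = g$strand, stringsAsFactors = FALSE)))
  df$event_id <- paste(df$gene_id, df$type, df$signature, df$strand, sep = ":")
  df <- df[order(df$type, df$signature), ]
  rownames(df) <- NULL
  df[, c("gene_id", "event_id", "type", "signature", "inclusion",
         "exclusion", "chrom", "strand")]
}

empty_event_table <- function() {
  data.frame(gene_id = character(0), event_id = character(0),
             type = character(0), signature = character(0),
             inclusion = character(0), exclusion = character(0),
             chrom = character(0), strand = character(0),
             stringsAsFactors = FALSE)
}

#' Enumerate AS events across a gene collection
#' @param genes List of [gene_model()] objects.
#' @return Row-bound event table (see [enumerate_events()]).
#' @export
enumerate_events_all <- function(genes) {
  tabs <- lapply(genes, enumerate_events)
  out <- do.call(rbind, c(tabs, list(empty_event_table())))
  rownames(out) <- NULL
  out
}

#' Flag AS genes and compute the AS-gene proportion
#'
#' A gene is alternatively spliced iff at least one event references it.
#'
#' @param genes List of [gene_model()] objects.
#' @param events Event table from [enumerate_events_all()].
#' @return List with `flags` (named logical over genes), `n_as`, `n_genes`,
#'   and `percent` (AS genes / all genes x 100, rounded to 2 decimals).
#' @export
classify_genes <- function(genes, events) {
  gids <- vapply(genes, function(g) g$gene_id, character(1))
  unknown <- setdiff(unique(events$gene_id), gids)
  if (length(unknown))
    stop("event references unknown gene: ", unknown[1])
  flags <- stats::setNames(gids %in% events$gene_id, gids)
  list(flags = flags, n_as = sum(flags), n_genes = length(flags),
       percent = round(100 * sum(flags) / length(flags), 2))
}

#' Summarize event counts and proportions
#'
#' @param x Either an event table (rows counted per type) or a named numeric
#'   vector of per-type counts.
#' @return Object of class `event_summary`: data.frame `type`, `count`,
#'   `percent` (count/total x 100, 2 decimals, ordered by count descending),
#'   with attribute `total`. Zero total yields the defined "no events" state
#'   (empty table, total 0).
#' @export
event_summary <- function(x) {
  counts <- if (is.data.frame(x)) {
    tab <- table(factor(x$type, levels = EVENT_TYPES))
    stats::setNames(as.numeric(tab), names(tab))
  } else {
    bad <- setdiff(names(x), EVENT_TYPES)
    if (length(bad)) stop("unknown event type: ", bad[1])
    full <- stats::setNames(numeric(length(EVENT_TYPES)), EVENT_TYPES)
    full[names(x)] <- as.numeric(x)
    full
  }
  if (any(counts < 0)) stop("negative event count")
  total <- sum(counts)
  if (total == 0) {
    out <- data.frame(type = character(0), count = numeric(0),
                      percent = numeric(0), stringsAsFactors = FALSE)
  } else {
    out <- data.frame(type = names(counts), count = as.numeric(counts),
                      percent = round(100 * counts / total, 2),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$count, out$type), ]
    rownames(out) <- NULL
  }
  structure(out, total = total, class = c("event_summary", "data.frame"))
}

#' @export
print.event_summary <- function(x, ...) {
  total <- attr(x, "total")
  if (total == 0) {
    cat("AS event summary: no events\n")
    return(invisible(x))
  }
  cat("AS event summary (", format(total, big.mark = ","), " events):\n",
      sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Tissue-specific AS genes and transcripts
#'
#' An item is tissue-specific iff it is present (mean replicate FPKM at or
#' above `min_fpkm`) in exactly one tissue.
#'
#' @param events Event table.
#' @param genes Gene models the events refer to.
#' @param expr An [expression_matrix()] (transcript-level rows for
#'   transcripts, gene-level rows for genes; rows are looked up by id).
#' @param min_fpkm Presence threshold (default 1).
#' @return List of two data.frames (`genes`, `transcripts`) with columns
#'   `id` and `tissue`.
#' @export
tissue_specific_sets <- function(events, genes, expr, min_fpkm = 1) {
  as_genes <- unique(events$gene_id)
  as_tx <- unique(unlist(strsplit(
    c(events$inclusion, events$exclusion), ",", fixed = TRUE)))
  pres <- tissue_presence(expr, min_fpkm = min_fpkm)
  pick_specific <- function(ids) {
    ids <- intersect(ids, rownames(pres))
    sub <- pres[ids, , drop = FALSE]
    spec <- rowSums(sub) == 1L
    data.frame(
      id = ids[spec],
      tissue = colnames(sub)[apply(sub[spec, , drop = FALSE], 1L, which.max)],
      stringsAsFactors = FALSE)
  }
  list(genes = pick_specific(as_genes), transcripts = pick_specific(as_tx))
}

#' Write an event table as TSV
#'
#' Columns follow the SUPPA ioe flavor: `gene_id`, `event_id`
#' (`gene:TYPE:signature:strand`), `inclusion_transcripts`,
#' `total_transcripts`.
#'
#' @param events Event table.
#' @param genes Gene models (for the per-gene transcript totals).
#' @param path Output path.
#' @export
write_event_table <- function(events, genes, path) {
  totals <- vapply(genes, function(g) length(g$transcripts), integer(1))
  names(totals) <- vapply(genes, function(g) g$gene_id, character(1))
  out <- data.frame(gene_id = events$gene_id, event_id = events$event_id,
                    inclusion_transcripts = events$inclusion,
                    total_transcripts = totals[events$gene_id],
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
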