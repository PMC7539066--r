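# Independent brute-force oracles, written from the event/PTC/TOM
# definitions without reusing the package's internals.

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# brute-force seven-type enumerator over ordered transcript pairs,
# returning the same table shape as enumerate_events()
oracle_enumerate <- function(g) {
  txs <- g$transcripts
  strand <- g$strand
  bag <- list()
  put <- function(type, sig, incl, excl) {
    key <- paste(type, paste(sig, collapse = ":"))
    prev <- bag[[key]]
    if (is.null(prev))
      bag[[key]] <<- list(type = type, sig = sig, incl = incl, excl = excl)
    else {
      bag[[key]]$incl <<- union(prev$incl, incl)
      bag[[key]]$excl <<- union(prev$excl, excl)
    }
  }
  intervals_overlap <- function(a, b) !(a[2] < b[1] || b[2] < a[1])
  intr_list <- function(e) {
    if (nrow(e) < 2) return(list())
    lapply(seq_len(nrow(e) - 1), function(i) c(e[i, 2] + 1, e[i + 1, 1] - 1))
  }
  ids <- names(txs)
  for (xi in ids) for (yi in ids) {
    if (xi == yi) next
    X <- txs[[xi]]; Y <- txs[[yi]]
    eX <- X$exons; eY <- Y$exons
    iX <- intr_list(eX); iY <- intr_list(eY)

    # IR
    for (k in seq_along(iX)) for (f in seq_len(nrow(eY))) {
      flank_l <- eX[k, ]; flank_r <- eX[k + 1, ]
      if (eY[f, 1] == flank_l[1] && eY[f, 2] == flank_r[2])
        put("IR", c(flank_l[2], flank_r[1]), yi, xi)
    }

    # ES: internal exon of X inside an intron of Y matching X's flanks
    if (nrow(eX) >= 3) for (m in 2:(nrow(eX) - 1)) {
      want <- c(eX[m - 1, 2] + 1, eX[m + 1, 1] - 1)
      for (j in iY) if (all(j == want))
        put("ES", c(eX[m - 1, 2], eX[m, 1], eX[m, 2], eX[m + 1, 1]), xi, yi)
    }

    # A5/A3 with the overlapping-flank requirement
    for (a in iX) for (b in iY) {
      if (a[2] == b[2] && a[1] != b[1]) {
        fl_x <- eX[eX[, 2] == a[1] - 1, ][1:2]
        fl_y <- eY[eY[, 2] == b[1] - 1, ][1:2]
        if (intervals_overlap(fl_x, fl_y)) {
          ty <- if (strand == "+") "A5" else "A3"
          who_short <- if (a[1] > b[1]) xi else yi
          who_long <- if (a[1] > b[1]) yi else xi
          put(ty, c(sort(c(a[1], b[1])), a[2]), who_short, who_long)
        }
      }
      if (a[1] == b[1] && a[2] != b[2]) {
        fr_x <- eX[eX[, 1] == a[2] + 1, ][1:2]
        fr_y <- eY[eY[, 1] == b[2] + 1, ][1:2]
        if (intervals_overlap(fr_x, fr_y)) {
          ty <- if (strand == "+") "A3" else "A5"
          who_short <- if (a[2] < b[2]) xi else yi
          who_long <- if (a[2] < b[2]) yi else xi
          put(ty, c(a[1], sort(c(a[2], b[2]))), who_short, who_long)
        }
      }
    }

    # MX: consecutive triples with shared outer junctions, middle exons
    # disjoint
    if (nrow(eX) >= 3 && nrow(eY) >= 3)
      for (u in 1:(nrow(eX) - 2)) for (v in 1:(nrow(eY) - 2)) {
        if (eX[u, 2] == eY[v, 2] && eX[u + 2, 1] == eY[v + 2, 1] &&
            !intervals_overlap(eX[u + 1, ], eY[v + 1, ])) {
          xm <- eX[u + 1, ]; ym <- eY[v + 1, ]
          left_x <- xm[1] < ym[1]
          pair <- if (left_x) c(xm, ym) else c(ym, xm)
          put("MX", c(eX[u, 2], pair, eX[u + 2, 1]),
              if (left_x) xi else yi, if (left_x) yi else xi)
        }
      }

    # AF/AL (terminal exons in transcript orientation)
    if (length(iX) && length(iY)) {
      # genomic-left terminal exon pair
      if (iX[[1]][2] == iY[[1]][2] &&
          !intervals_overlap(eX[1, ], eY[1, ])) {
        ty <- if (strand == "+") "AF" else "AL"
        dist_x <- eX[1, 1] < eY[1, 1]
        put(ty, sort(c(eX[1, ], eY[1, ], iX[[1]][2] + 1)),
            if (dist_x) xi else yi, if (dist_x) yi else xi)
      }
      # genomic-right terminal exon pair
      lx <- iX[[length(iX)]]; ly <- iY[[length(iY)]]
      if (lx[1] == ly[1] &&
          !intervals_overlap(eX[nrow(eX), ], eY[nrow(eY), ])) {
        ty <- if (strand == "+") "AL" else "AF"
        dist_x <- eX[nrow(eX), 2] > eY[nrow(eY), 2]
        put(ty, sort(c(eX[nrow(eX), ], eY[nrow(eY), ], lx[1] - 1)),
            if (dist_x) xi else yi, if (dist_x) yi else xi)
      }
    }
  }
  if (!length(bag))
    return(splicescape:::empty_event_table())
  df <- do.call(rbind, lapply(unname(bag), function(e) data.frame(
    gene_id = g$gene_id, type = e$type,
    signature = paste(e$sig, collapse = ":"),
    inclusion = paste(sort(e$incl), collapse = ","),
    exclusion = paste(sort(e$excl), collapse = ","),
    chrom = g$chrom, strand = g$strand, stringsAsFactors = FALSE)))
  df$event_id <- paste(df$gene_id, df$type, df$signature, df$strand,
                       sep = ":")
  df <- df[order(df$type, df$signature), ]
  rownames(df) <- NULL
  df[, c("gene_id", "event_id", "type", "signature", "inclusion",
         "exclusion", "chrom", "strand")]
}

# double-loop TOM oracle from the formula
oracle_tom <- function(a) {
  n <- nrow(a)
  out <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) { out[i, j] <- 1; next }
    s <- 0
    for (u in 1:n) if (u != i && u != j) s <- s + a[i, u] * a[u, j]
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    out[i, j] <- (s + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  dimnames(out) <- dimnames(a)
  out
}

# mirror a whole gene fixture to the opposite strand across position `L`
mirror_gene <- function(g, L) {
  txs <- lapply(g$transcripts, function(t) {
    e2 <- cbind(L - t$exons[, 2] + 1, L - t$exons[, 1] + 1)
    cds2 <- if (is.null(t$cds)) NULL else sort(L - t$cds + 1)
    transcript_model(t$transcript_id, t$gene_id, t$chrom,
                     if (t$strand == "+") "-" else "+",
                     e2[order(e2[, 1]), , drop = FALSE], cds = cds2)
  })
  gene_model(g$gene_id, txs)
}

mirror_genome_seq <- function(s) oracle_revcomp(s)
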