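# Quick builders for toy gene models and genomes used across tests.

tx <- function(id, gid, exons, strand = "+", chrom = "chr1", cds = NULL) {
  transcript_model(id, gid, chrom, strand, exons, cds = cds)
}

gene <- function(gid, exon_sets, strand = "+", chrom = "chr1") {
  txs <- lapply(seq_along(exon_sets), function(i)
    tx(paste0(gid, ".t", i), gid, exon_sets[[i]], strand, chrom))
  gene_model(gid, txs)
}

ex <- function(...) {
  v <- c(...)
  matrix(v, ncol = 2, byrow = TRUE)
}

# random genome covering every locus referenced by `genes`
random_genome <- function(genes, seed = 1) {
  set.seed(seed)
  chroms <- unique(vapply(genes, function(g) g$chrom, character(1)))
  lens <- vapply(chroms, function(ch) {
    mx <- max(unlist(lapply(genes, function(g)
      if (g$chrom == ch) lapply(g$transcripts, function(t) t$exons[, 2])
      else 0)))
    mx + 10
  }, numeric(1))
  stats::setNames(vapply(lens, function(L)
    paste0(sample(c("A", "C", "G", "T"), L, replace = TRUE),
           collapse = ""), character(1)), chroms)
}

# random multi-isoform gene: a base exon chain plus derived/novel isoforms,
# exercising shared and shifted boundaries
random_gene_model <- function(gid, max_tx = 4, max_exons = 8) {
  n_ex <- sample(1:max_exons, 1)
  w <- sample(20:80, n_ex, replace = TRUE)
  gaps <- if (n_ex > 1) sample(15:60, n_ex - 1, replace = TRUE) else integer(0)
  starts <- 1 + cumsum(c(0, w[-n_ex] + gaps))
  base <- cbind(starts, starts + w - 1)
  strand <- sample(c("+", "-"), 1)
  n_tx <- sample(1:max_tx, 1)
  sets <- list(base)
  tries <- 0
  while (length(sets) < n_tx && tries < 50) {
    tries <- tries + 1
    e <- base
    op <- sample(c("retain", "skip", "shift", "first", "last", "swap",
                   "copy", "fresh"), 1)
    e2 <- try(switch(op,
      retain = {
        if (nrow(e) < 2) stop("no")
        j <- sample(nrow(e) - 1, 1)
        e[j, 2] <- e[j + 1, 2]
        e[-(j + 1), , drop = FALSE]
      },
      skip = {
        if (nrow(e) < 3) stop("no")
        e[-sample(2:(nrow(e) - 1), 1), , drop = FALSE]
      },
      shift = {
        if (nrow(e) < 2) stop("no")
        j <- sample(nrow(e) - 1, 1)
        d <- sample(3:12, 1)
        if (sample(2, 1) == 1) e[j, 2] <- e[j, 2] + d
        else e[j + 1, 1] <- e[j + 1, 1] - d
        e
      },
      first = {
        if (nrow(e) < 2 || e[1, 1] < 30) stop("no")
        f <- c(max(1, e[1, 1] - 25), e[1, 1] - 10)
        rbind(f, e[-1, , drop = FALSE])
      },
      last = {
        if (nrow(e) < 2) stop("no")
        g2 <- c(e[nrow(e), 2] + 10, e[nrow(e), 2] + 25)
        rbind(e[-nrow(e), , drop = FALSE], g2)
      },
      swap = {
        if (nrow(e) < 3) stop("no")
        j <- sample(2:(nrow(e) - 1), 1)
        gap_lo <- e[j, 2] + 2; gap_hi <- e[j + 1, 1] - 2
        if (gap_hi - gap_lo < 12) stop("no")
        m2 <- c(gap_hi - 10, gap_hi - 1)
        rbind(e[1:(j - 1), , drop = FALSE], m2,
              e[(j + 1):nrow(e), , drop = FALSE])
      },
      copy = e,
      fresh = {
        k <- sample(1:4, 1)
        w2 <- sample(20:60, k, replace = TRUE)
        g2 <- if (k > 1) sample(10:50, k - 1, replace = TRUE) else integer(0)
        s2 <- sample(1:40, 1) + cumsum(c(0, w2[-k] + g2))
        cbind(s2, s2 + w2 - 1)
      }), silent = TRUE)
    if (inherits(e2, "try-error")) next
    e2 <- e2[order(e2[, 1]), , drop = FALSE]
    if (nrow(e2) > 1 && any(e2[-1, 1] <= e2[-nrow(e2), 2] + 1)) next
    sets[[length(sets) + 1]] <- e2
  }
  gene(gid, sets, strand = strand)
}

# coding gene with one intron and a retaining isoform, built base-by-base:
# exon1 = 6 nt UTR5 + ATG + 17 GCC codons (60 nt, 54 coding nt precede the
# intron, a codon boundary); exon2 = 51 coding nt + TAA + 6 nt UTR3.
# Returns the gene (base + retained transcript) and its genome.
make_ptc_fixture <- function(intron_seq,
                             exon2_core = paste(rep("GCC", 17),
                                                collapse = "")) {
  stopifnot(nchar(exon2_core) == 51)
  exon1 <- paste0("CCCCCC", "ATG", paste(rep("GCC", 17), collapse = ""))
  exon2 <- paste0(exon2_core, "TAA", "CCCCCC")
  ilen <- nchar(intron_seq)
  chr <- paste0(exon1, intron_seq, exon2, "CCCC")
  base <- tx("g.t1", "g", ex(1, 60, 61 + ilen, 120 + ilen),
             cds = c(7, 114 + ilen))
  ret <- tx("g.t2", "g", ex(1, 120 + ilen))
  list(gene = gene_model("g", list(base, ret)),
       genome = c(chr1 = chr),
       intron = c(61, 60 + ilen))
}

# {C,G} intron body with GT/AG termini; optionally an in-frame TAA given
# 54 coding nt precede the intron (frame offset 0)
ir_intron <- function(len, taa_at = NA) {
  v <- rep("C", len)
  v[1:2] <- c("G", "T")
  v[(len - 1):len] <- c("A", "G")
  if (!is.na(taa_at)) v[taa_at:(taa_at + 2)] <- c("T", "A", "A")
  paste(v, collapse = "")
}
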