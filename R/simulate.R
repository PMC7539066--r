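# Synthetic multi-isoform transcriptome generator with planted truth.
#
# Design notes (details in the methods vignette):
#  * Event types are allocated over AS genes by largest-remainder rounding,
#    so realized proportions are deterministic, not multinomially sampled.
#  * Each AS gene carries a base isoform plus one alternative isoform
#    realizing its planted event by a coordinate edit.
#  * Genes are built in transcript-forward local coordinates and mirrored
#    onto the genome for minus-strand genes, so all downstream strand logic
#    is exercised.
#  * Coding sequences use T-free filler codons; planted retained introns use
#    a {C,G} body with forced GT/AG termini (and an in-frame TAA for PTC+),
#    which makes PTC truth statuses exact by construction.
#  * Splice-site dinucleotides are allocated exactly (largest remainder)
#    over the unique introns; introns of AS genes are kept canonical since
#    isoforms share boundary positions there.

#' Simulation configuration
#'
#' Defaults mirror the study conditions: seven tissues x three replicates,
#' event-type proportions as observed in the published tally, 90% canonical
#' GT-AG splice sites, and a 1:2 PTC+ : PTC- target among retained-intron
#' transcripts.
#'
#' @param seed Integer RNG seed; fixed seed implies byte-identical output.
#' @param n_genes Number of genes (default 500).
#' @param as_fraction Fraction of genes that are alternatively spliced
#'   (default 0.1756, the published AS-gene rate).
#' @param event_props Named per-type proportions over AS genes; must sum
#'   to 1.
#' @param canonical_fraction Fraction of unique introns with GT-AG termini
#'   (default 0.90).
#' @param ptc_props PTC+ and PTC- proportions among coding retained-intron
#'   transcripts (default 1/3, 2/3).
#' @param lnc_fraction Fraction of AS genes built as noncoding (no ORF,
#'   length over 200 nt).
#' @param tissues Tissue labels (default the seven study tissues).
#' @param n_reps Replicates per tissue (default 3).
#' @param exon_count_range_as,exon_count_range_non Exon-count ranges for AS
#'   and non-AS multi-exon genes.
#' @param single_exon_fraction Fraction of non-AS genes with a single exon.
#' @param exon_len_range Exon length range (nt).
#' @param intron_len_range Intron length range; `ir_intron_len_range` is
#'   used for IR genes (shorter, mirroring the observation that retained
#'   introns tend to be short).
#' @param n_tissue_specific Number of planted tissue-specific transcripts.
#' @param modules Planted coexpression design: `count`, `size`,
#'   `within_cor` (default 0.8), `hub_cor` (hub loading; default 1, i.e.
#'   the planted hub follows the module consensus profile exactly and is
#'   the most-connected member by construction).
#' @param noise_sd Replicate noise SD on the log10 scale.
#' @param baseline_floor FPKM floor applied to all non-tissue-specific
#'   transcripts so presence calls match the planted truth exactly.
#' @param minus_strand_fraction Fraction of genes on the minus strand.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_genes = 500L,
                              as_fraction = 0.1756,
                              event_props = c(IR = 0.2839, A3 = 0.2029,
                                              ES = 0.1668, A5 = 0.1527,
                                              AF = 0.1166, AL = 0.0634,
                                              MX = 0.0137),
                              canonical_fraction = 0.90,
                              ptc_props = c(`PTC+` = 1 / 3, `PTC-` = 2 / 3),
                              lnc_fraction = 0.05,
                              tissues = c("leaf", "stamen", "pistil",
                                          "petal", "sepal", "bract",
                                          "shoot_apex"),
                              n_reps = 3L,
                              exon_count_range_as = c(4L, 8L),
                              exon_count_range_non = c(2L, 6L),
                              single_exon_fraction = 0.25,
                              exon_len_range = c(90L, 240L),
                              intron_len_range = c(81L, 180L),
                              ir_intron_len_range = c(60L, 90L),
                              n_tissue_specific = 30L,
                              modules = list(count = 3L, size = 60L,
                                             within_cor = 0.8,
                                             hub_cor = 1),
                              noise_sd = 0.15,
                              baseline_floor = 1.5,
                              minus_strand_fraction = 0.5) {
  if (abs(sum(event_props) - 1) > 1e-9)
    stop("event_props must sum to 1")
  fracs <- c(as_fraction, canonical_fraction, lnc_fraction,
             single_exon_fraction, minus_strand_fraction)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must be in [0, 1]")
  if (abs(sum(ptc_props) - 1) > 1e-9) stop("ptc_props must sum to 1")
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              as_fraction = as_fraction, event_props = event_props,
              canonical_fraction = canonical_fraction,
              ptc_props = ptc_props, lnc_fraction = lnc_fraction,
              tissues = tissues, n_reps = as.integer(n_reps),
              exon_count_range_as = exon_count_range_as,
              exon_count_range_non = exon_count_range_non,
              single_exon_fraction = single_exon_fraction,
              exon_len_range = exon_len_range,
              intron_len_range = intron_len_range,
              ir_intron_len_range = ir_intron_len_range,
              n_tissue_specific = as.integer(n_tissue_specific),
              modules = modules, noise_sd = noise_sd,
              baseline_floor = baseline_floor,
              minus_strand_fraction = minus_strand_fraction)
  structure(cfg, class = "simulation_config")
}

#' Largest-remainder integer allocation
#'
#' Splits `n` items over proportions exactly: floors of `n * props` plus one
#' extra for the largest fractional remainders (ties broken by position).
#'
#' @param n Total count.
#' @param props Proportions (need not be named); must sum to 1.
#' @return Integer vector summing to `n`.
#' @export
largest_remainder <- function(n, props) {
  if (abs(sum(props) - 1) > 1e-9) stop("proportions must sum to 1")
  exact <- n * props
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- exact - base
    ord <- order(-frac, seq_along(frac))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  out <- as.integer(base)
  names(out) <- names(props)
  out
}

T_FREE_CODONS <- apply(expand.grid(c("A", "C", "G"), c("A", "C", "G"),
                                   c("A", "C", "G")), 1L, paste0,
                       collapse = "")

.rand_bases <- function(n, alphabet = c("A", "C", "G", "T")) {
  sample(alphabet, n, replace = TRUE)
}

# retained-intron body: GT + {C,G} filler + AG, position 3 fixed to C;
# for PTC+ a TAA is placed in frame given `cds_before` coding nt upstream
.ir_intron_seq <- function(len, ptc_plus, cds_before) {
  v <- .rand_bases(len, c("C", "G"))
  v[1:2] <- c("G", "T"); v[3] <- "C"
  v[(len - 1):len] <- c("A", "G")
  if (ptc_plus) {
    p <- 7L
    while ((cds_before + p - 1L) %% 3L != 0L) p <- p + 1L
    v[p:(p + 2L)] <- c("T", "A", "A")
  }
  v
}

# local transcript position -> local genomic position for an exon matrix
.local_tx_to_genomic <- function(exl, p) {
  w <- exl[, 2] - exl[, 1] + 1
  cum <- cumsum(w)
  i <- which(p <= cum)[1L]
  exl[i, 1] + (p - (cum[i] - w[i]) - 1)
}

# single-gene plan in local (transcript-forward) coordinates
.plan_gene <- function(gid, type, lnc, single_exon, cfg) {
  rng <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)
  is_as <- !is.na(type)
  E <- if (!is_as && single_exon) 1L
    else if (is_as) max(rng(cfg$exon_count_range_as),
                        if (type %in% c("ES", "MX")) 3L else 2L)
    else rng(cfg$exon_count_range_non)
  w <- vapply(seq_len(E), function(i) rng(cfg$exon_len_range), numeric(1))
  irange <- if (is_as && type == "IR") cfg$ir_intron_len_range
    else cfg$intron_len_range
  l <- if (E > 1L) vapply(seq_len(E - 1L), function(i) rng(irange),
                          numeric(1)) else numeric(0)
  coding <- !lnc
  if (coding) {
    if (sum(w) < 120) w[E] <- w[E] + (120 - sum(w))  # room for UTRs + CDS
    w[E] <- w[E] + (3 - (sum(w) - 105) %% 3) %% 3
  } else if (sum(w) < 210) {
    w[E] <- w[E] + (210 - sum(w))
  }
  j <- if (is_as && type == "IR") max(1L, (E - 1L) %/% 2L) else NA_integer_
  if (!is.na(j)) l[j] <- l[j] + (3 - l[j] %% 3) %% 3
  buf <- 300L
  starts <- buf + 1 + cumsum(c(0, w[-E] + l))
  exl <- cbind(start = starts, end = starts + w - 1)
  span_end <- exl[E, 2]
  L <- span_end + buf

  alt <- NULL
  if (is_as) {
    alt <- switch(type,
      IR = {
        merged <- exl
        merged[j, 2] <- merged[j + 1L, 2]
        merged[-(j + 1L), , drop = FALSE]
      },
      ES = exl[-2L, , drop = FALSE],
      A5 = { a <- exl; a[1, 2] <- a[1, 2] + 18; a },
      A3 = { a <- exl; a[2, 1] <- a[2, 1] - 18; a },
      AF = rbind(c(121, 180), exl[-1L, , drop = FALSE]),
      AL = rbind(exl[-E, , drop = FALSE],
                 c(span_end + 121, span_end + 180)),
      MX = rbind(exl[1L, , drop = FALSE],
                 c(exl[3L, 1] - 71, exl[3L, 1] - 12),
                 exl[-c(1L, 2L), , drop = FALSE]))
    rownames(alt) <- NULL
    colnames(alt) <- c("start", "end")
  }

  # local truth signature + inclusion role (alt unless ES/MX)
  sig <- NULL; incl_alt <- TRUE
  if (is_as) {
    sig <- switch(type,
      IR = c(exl[j, 2], exl[j + 1L, 1]),
      ES = { incl_alt <- FALSE
             c(exl[1, 2], exl[2, 1], exl[2, 2], exl[3, 1]) },
      A5 = c(exl[1, 2] + 1, exl[1, 2] + 19, exl[2, 1] - 1),
      A3 = c(exl[1, 2] + 1, exl[2, 1] - 19, exl[2, 1] - 1),
      MX = { incl_alt <- FALSE
             c(exl[1, 2], exl[2, 1], exl[2, 2], exl[3, 1] - 71,
               exl[3, 1] - 12, exl[3, 1]) },
      AF = sort(c(121, 180, exl[1, ], exl[2, 1])),
      AL = sort(c(exl[E - 1L, 2], exl[E, ], span_end + 121,
                  span_end + 180)))
  }

  cds_tx <- if (coding) c(46, sum(w) - 60) else NULL
  list(gid = gid, type = type, lnc = lnc, E = E, w = w, l = l,
       exl = exl, alt = alt, L = L, j = j, coding = coding,
       cds_tx = cds_tx, sig = sig, incl_alt = incl_alt)
}

#' Simulate a genome, annotation and truth tables
#'
#' @param config A [simulation_config()].
#' @return List of class `simulation` with `genome` (DNAStringSet), `genes`
#'   (gene models), `truth` (list of data.frames: `genes`, `events`,
#'   `splice_sites`, `ptc`), and `config`.
#' @export
simulate_annotation <- function(config = simulation_config()) {
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_genes
  n_as <- largest_remainder(n, c(cfg$as_fraction, 1 - cfg$as_fraction))[1L]
  type_counts <- largest_remainder(n_as, cfg$event_props)
  if (n_as > 0 && type_counts[["MX"]] > 0 && cfg$exon_count_range_as[2] < 3)
    stop("MX events require genes with at least 3 exons")
  types <- rep(names(type_counts), type_counts)
  gids <- sprintf("G%04d", seq_len(n))
  as_idx <- if (n_as) sort(sample.int(n, n_as)) else integer(0)
  gene_type <- rep(NA_character_, n)
  gene_type[as_idx] <- sample(types)
  n_lnc <- largest_remainder(n_as, c(cfg$lnc_fraction,
                                     1 - cfg$lnc_fraction))[1L]
  lnc <- logical(n)
  if (n_lnc) lnc[sample(as_idx, n_lnc)] <- TRUE
  single <- logical(n)
  non_idx <- setdiff(seq_len(n), as_idx)
  n_single <- largest_remainder(length(non_idx),
                                c(cfg$single_exon_fraction,
                                  1 - cfg$single_exon_fraction))[1L]
  if (n_single) single[sample(non_idx, n_single)] <- TRUE
  strands <- rep("+", n)
  n_minus <- largest_remainder(n, c(cfg$minus_strand_fraction,
                                    1 - cfg$minus_strand_fraction))[1L]
  if (n_minus) strands[sample.int(n, n_minus)] <- "-"
  chroms <- rep(c("chr1", "chr2"), length.out = n)

  plans <- lapply(seq_len(n), function(i)
    .plan_gene(gids[i], gene_type[i], lnc[i], single[i], cfg))

  # PTC allocation over coding IR genes
  ir_coding <- which(!is.na(gene_type) & gene_type == "IR" & !lnc)
  ptc_counts <- largest_remainder(length(ir_coding), cfg$ptc_props)
  ptc_status <- rep(NA_character_, n)
  if (length(ir_coding))
    ptc_status[ir_coding] <- sample(rep(names(ptc_counts), ptc_counts))
  ptc_status[!is.na(gene_type) & gene_type == "IR" & lnc] <- "undetermined"

  # build local sequences + collect unique introns per gene
  seqs <- vector("list", n)
  intron_tabs <- vector("list", n)
  for (i in seq_len(n)) {
    p <- plans[[i]]
    alphabet <- if (p$lnc) c("C", "G", "T") else c("A", "C", "G", "T")
    v <- .rand_bases(p$L, alphabet)
    if (p$coding) {
      cdslen <- sum(p$w) - 105
      content <- c(.rand_bases(45),
                   c("A", "T", "G"),
                   strsplit(paste0(sample(T_FREE_CODONS,
                                          (cdslen - 6) / 3,
                                          replace = TRUE),
                                   collapse = ""), "")[[1L]],
                   c("T", "A", "A"),
                   .rand_bases(60))
      pos <- unlist(lapply(seq_len(p$E), function(k)
        p$exl[k, 1]:p$exl[k, 2]))
      v[pos] <- content
    }
    if (!is.na(p$j) && !p$lnc) {
      s <- p$exl[p$j, 2] + 1; e <- p$exl[p$j + 1L, 1] - 1
      cds_before <- sum(p$w[seq_len(p$j)]) - 45
      v[s:e] <- .ir_intron_seq(e - s + 1, ptc_status[i] == "PTC+",
                               cds_before)
    }
    seqs[[i]] <- v
    ins <- introns_from_exons(p$exl)
    if (!is.null(p$alt)) ins <- rbind(ins, introns_from_exons(p$alt))
    ins <- ins[!duplicated(ins), , drop = FALSE]
    retained <- if (!is.na(p$j))
      ins[, 1] == p$exl[p$j, 2] + 1 & ins[, 2] == p$exl[p$j + 1L, 1] - 1
      else rep(FALSE, nrow(ins))
    intron_tabs[[i]] <- if (nrow(ins))
      data.frame(gene_idx = i, start = ins[, 1], end = ins[, 2],
                 retained = retained, as_gene = !is.na(p$type))
      else NULL
  }

  # splice-site allocation over unique introns (exact, largest remainder);
  # AS-gene introns stay canonical because isoforms share boundaries there
  introns <- do.call(rbind, intron_tabs)
  n_introns <- nrow(introns)
  alloc <- largest_remainder(n_introns, c(cfg$canonical_fraction,
                                          1 - cfg$canonical_fraction))
  n_noncan <- alloc[2L]
  free <- which(!introns$as_gene)
  if (n_noncan > length(free))
    stop("canonical_fraction too low: not enough non-AS introns to carry ",
         "the non-canonical quota")
  noncan_idx <- if (n_noncan) sort(sample(free, n_noncan)) else integer(0)
  NONCANONICAL <- list(c("AA", "AG"), c("GT", "TG"), c("GT", "TT"),
                       c("GC", "AG"))
  introns$donor <- "GT"; introns$acceptor <- "AG"
  if (length(noncan_idx)) {
    picks <- sample(length(NONCANONICAL), length(noncan_idx),
                    replace = TRUE)
    introns$donor[noncan_idx] <-
      vapply(picks, function(k) NONCANONICAL[[k]][1], character(1))
    introns$acceptor[noncan_idx] <-
      vapply(picks, function(k) NONCANONICAL[[k]][2], character(1))
  }
  for (r in seq_len(n_introns)) {
    i <- introns$gene_idx[r]
    s <- introns$start[r]; e <- introns$end[r]
    seqs[[i]][s:(s + 1)] <- strsplit(introns$donor[r], "")[[1L]]
    seqs[[i]][(e - 1):e] <- strsplit(introns$acceptor[r], "")[[1L]]
  }

  # assemble chromosomes; mirror minus-strand genes
  offsets <- numeric(n)
  chrom_parts <- list(chr1 = character(0), chr2 = character(0))
  chrom_len <- c(chr1 = 0, chr2 = 0)
  gap <- strrep("N", 100)
  for (i in seq_len(n)) {
    ch <- chroms[i]
    v <- seqs[[i]]
    s <- paste0(v, collapse = "")
    if (strands[i] == "-") s <- revcomp(s)
    offsets[i] <- chrom_len[ch] + 100
    chrom_parts[[ch]] <- c(chrom_parts[[ch]], gap, s)
    chrom_len[ch] <- chrom_len[ch] + 100 + nchar(s)
  }
  genome <- Biostrings::DNAStringSet(vapply(chrom_parts, paste0,
                                            character(1), collapse = ""))

  map_pos <- function(i, p) {
    L <- plans[[i]]$L
    if (strands[i] == "+") offsets[i] + p else offsets[i] + (L - p + 1)
  }
  map_iv <- function(i, iv) {
    a <- map_pos(i, iv[, 1]); b <- map_pos(i, iv[, 2])
    cbind(start = pmin(a, b), end = pmax(a, b))
  }

  genes <- vector("list", n)
  ev_rows <- list(); ptc_rows <- list()
  for (i in seq_len(n)) {
    p <- plans[[i]]
    t1 <- paste0(p$gid, ".t1")
    cds <- if (p$coding)
      sort(c(map_pos(i, .local_tx_to_genomic(p$exl, p$cds_tx[1])),
             map_pos(i, .local_tx_to_genomic(p$exl, p$cds_tx[2]))))
      else NULL
    txs <- list(transcript_model(t1, p$gid, chroms[i], strands[i],
                                 map_iv(i, p$exl), cds = cds))
    if (!is.null(p$alt)) {
      t2 <- paste0(p$gid, ".t2")
      txs <- c(txs, list(transcript_model(t2, p$gid, chroms[i],
                                          strands[i], map_iv(i, p$alt))))
      sig_g <- sort(map_pos(i, p$sig))
      incl_alt <- p$incl_alt
      # MX inclusion follows the genomic-left internal exon; mirroring a
      # minus-strand gene puts the alternative exon on the left
      if (p$type == "MX" && strands[i] == "-") incl_alt <- !incl_alt
      ev_rows[[length(ev_rows) + 1L]] <- data.frame(
        gene_id = p$gid, type = p$type,
        signature = paste(sig_g, collapse = ":"),
        inclusion = if (incl_alt) t2 else t1,
        exclusion = if (incl_alt) t1 else t2,
        stringsAsFactors = FALSE)
      if (p$type == "IR") {
        ri <- map_iv(i, cbind(p$exl[p$j, 2] + 1, p$exl[p$j + 1L, 1] - 1))
        ptc_rows[[length(ptc_rows) + 1L]] <- data.frame(
          transcript_id = t2, gene_id = p$gid,
          intron_start = ri[1, 1], intron_end = ri[1, 2],
          status = ptc_status[i], stringsAsFactors = FALSE)
      }
    }
    genes[[i]] <- gene_model(p$gid, txs)
  }
  names(genes) <- gids

  ss <- introns
  ss_iv <- t(vapply(seq_len(nrow(ss)), function(r)
    map_iv(ss$gene_idx[r], cbind(ss$start[r], ss$end[r]))[1, ],
    numeric(2)))
  truth_sites <- data.frame(
    gene_id = gids[ss$gene_idx], chrom = chroms[ss$gene_idx],
    intron_start = ss_iv[, 1], intron_end = ss_iv[, 2],
    donor = ss$donor, acceptor = ss$acceptor,
    canonical = ss$donor == "GT" & ss$acceptor == "AG",
    stringsAsFactors = FALSE)

  truth_genes <- data.frame(
    gene_id = gids, chrom = chroms, strand = strands,
    as_gene = !is.na(gene_type), event_type = gene_type,
    lnc = lnc, single_exon = single, stringsAsFactors = FALSE)

  structure(list(
    genome = genome,
    genes = structure(genes, class = "gene_model_list"),
    truth = list(genes = truth_genes,
                 events = do.call(rbind, c(ev_rows, list(data.frame()))),
                 splice_sites = truth_sites,
                 ptc = do.call(rbind, c(ptc_rows, list(data.frame())))),
    config = cfg), class = "simulation")
}

introns_from_exons <- function(ex) {
  n <- nrow(ex)
  if (n < 2L) return(matrix(numeric(0), ncol = 2))
  cbind(ex[-n, 2] + 1, ex[-1L, 1] - 1)
}

#' @export
print.simulation <- function(x, ...) {
  cat(sprintf(
    "<simulation: %d genes (%d AS), %d chromosome(s), seed %d%s>\n",
    nrow(x$truth$genes), sum(x$truth$genes$as_gene), length(x$genome),
    x$config$seed,
    if (is.null(x$expr_transcripts)) "" else ", with expression"))
  invisible(x)
}

# ---- expression simulation ------------------------------------------------

#' Planted module score matrix
#'
#' Factor-model scores on the log scale: member genes of module m follow
#' `sqrt(rho) * z_m + sqrt(1 - rho) * noise` with `z_m` a standardized
#' tissue-structured sample profile, giving within-module correlation about
#' `rho` and near-zero between modules. The first gene of each module is
#' the planted hub (loading `sqrt(hub_cor)`).
#'
#' @param n_genes Total genes (unassigned genes get iid noise of amplitude
#'   `background_amp`; label 0).
#' @param modules List with `count`, `size`, `within_cor`, `hub_cor`.
#' @param tissues Tissue labels.
#' @param n_reps Replicates per tissue.
#' @param background_amp SD of unassigned genes' scores (default 0.6, below
#'   the unit module amplitude, so a variance ranking prefers networked
#'   genes as in the study's pre-filter).
#' @return List with `scores` (genes x samples, log scale), `labels`
#'   (planted module per gene, 0 = none), `hubs` (planted hub gene indices).
#' @export
simulate_module_scores <- function(n_genes, modules, tissues, n_reps,
                                   background_amp = 0.6) {
  n_samples <- length(tissues) * n_reps
  sample_tissue <- rep(tissues, each = n_reps)
  scores <- matrix(stats::rnorm(n_genes * n_samples, sd = background_amp),
                   nrow = n_genes)
  labels <- integer(n_genes)
  hubs <- integer(0)
  total_member <- modules$count * modules$size
  if (total_member > n_genes)
    stop("module sizes exceed gene count")
  g <- 1L
  for (m in seq_len(modules$count)) {
    profile <- stats::rnorm(length(tissues))
    z <- profile[match(sample_tissue, tissues)] +
      stats::rnorm(n_samples, sd = 0.5)
    z <- as.numeric(scale(z))
    members <- g:(g + modules$size - 1L)
    for (k in seq_along(members)) {
      rho <- if (k == 1L) modules$hub_cor else modules$within_cor
      scores[members[k], ] <- sqrt(rho) * z +
        sqrt(1 - rho) * stats::rnorm(n_samples)
    }
    labels[members] <- m
    hubs <- c(hubs, members[1L])
    g <- g + modules$size
  }
  list(scores = scores, labels = labels, hubs = hubs)
}

#' Simulate tissue-structured FPKM matrices
#'
#' Log-normal FPKM with planted coexpression modules at the gene level,
#' planted tissue-specific transcripts (high in one tissue, exactly zero
#' elsewhere), a presence floor for all other transcripts, and a guaranteed
#' floor for retained-intron transcripts so the PTC census sees every call.
#'
#' @param sim A `simulation` from [simulate_annotation()].
#' @return The simulation with `expr_transcripts` and `expr_genes`
#'   ([expression_matrix()] objects) and truth tables `modules`, `hubs`
#'   and `tissue_specific` added.
#' @export
simulate_expression <- function(sim) {
  cfg <- sim$config
  set.seed(cfg$seed + 1L)
  tg <- sim$truth$genes
  n <- nrow(tg)
  samples <- paste(rep(cfg$tissues, each = cfg$n_reps),
                   rep(seq_len(cfg$n_reps), length(cfg$tissues)),
                   sep = "_rep")
  tissue_map <- stats::setNames(rep(cfg$tissues, each = cfg$n_reps),
                                samples)

  # modules planted on AS genes first (the study networked AS genes), then
  # padded with non-AS genes when the design is larger than the AS set
  ord <- order(!tg$as_gene, tg$gene_id)
  ms <- simulate_module_scores(n, cfg$modules, cfg$tissues, cfg$n_reps)
  scores <- matrix(0, nrow = n, ncol = length(samples))
  scores[ord, ] <- ms$scores
  labels <- integer(n); labels[ord] <- ms$labels
  hub_idx <- ord[ms$hubs]

  gene_fpkm <- 10^(0.6 * scores + 0.8 +
                     matrix(stats::rnorm(length(scores),
                                         sd = cfg$noise_sd), nrow = n))
  rownames(gene_fpkm) <- tg$gene_id
  colnames(gene_fpkm) <- samples

  # transcript split: base 0.7 / alt 0.3 for two-isoform genes
  tx_ids <- list(); tx_rows <- list()
  for (i in seq_len(n)) {
    gid <- tg$gene_id[i]
    if (tg$as_gene[i]) {
      tx_ids[[i]] <- paste0(gid, c(".t1", ".t2"))
      tx_rows[[i]] <- rbind(0.7 * gene_fpkm[i, ], 0.3 * gene_fpkm[i, ])
    } else {
      tx_ids[[i]] <- paste0(gid, ".t1")
      tx_rows[[i]] <- gene_fpkm[i, , drop = FALSE]
    }
  }
  tx_fpkm <- do.call(rbind, tx_rows)
  rownames(tx_fpkm) <- unlist(tx_ids)
  colnames(tx_fpkm) <- samples

  # presence floor for every transcript, then carve out planted
  # tissue-specific transcripts among non-IR alternative isoforms
  tx_fpkm <- pmax(tx_fpkm, cfg$baseline_floor)
  alt_pool <- paste0(tg$gene_id[tg$as_gene &
                                  tg$event_type != "IR"], ".t2")
  n_ts <- min(cfg$n_tissue_specific, length(alt_pool))
  ts_ids <- if (n_ts) sort(sample(alt_pool, n_ts)) else character(0)
  ts_tissue <- rep(cfg$tissues, length.out = n_ts)
  for (k in seq_len(n_ts)) {
    row <- numeric(length(samples))
    sel <- tissue_map == ts_tissue[k]
    row[sel] <- 10^stats::runif(sum(sel), 0.7, 1.2)
    tx_fpkm[ts_ids[k], ] <- row
  }

  # gene matrix = sum of its transcripts (kept consistent after overrides)
  gene_fpkm <- do.call(rbind, lapply(seq_len(n), function(i)
    colSums(tx_fpkm[tx_ids[[i]], , drop = FALSE])))
  rownames(gene_fpkm) <- tg$gene_id

  sim$expr_transcripts <- expression_matrix(tx_fpkm, tissue_map)
  sim$expr_genes <- expression_matrix(gene_fpkm, tissue_map)
  sim$truth$modules <- data.frame(gene_id = tg$gene_id, module = labels,
                                  stringsAsFactors = FALSE)
  sim$truth$hubs <- data.frame(gene_id = tg$gene_id[hub_idx],
                               module = labels[hub_idx],
                               stringsAsFactors = FALSE)
  sim$truth$tissue_specific <- data.frame(
    transcript_id = ts_ids,
    tissue = if (n_ts) ts_tissue else character(0),
    stringsAsFactors = FALSE)
  sim
}

#' Write a simulation to disk
#'
#' Emits `genome.fa`, `annotation.gtf`, `fpkm_transcripts.tsv`,
#' `fpkm_genes.tsv` and `truth/*.tsv`.
#'
#' @param sim A `simulation` (run [simulate_expression()] first for the
#'   FPKM files).
#' @param dir Output directory (created if needed).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  write_genome(sim$genome, file.path(dir, "genome.fa"))
  write_annotation(sim$genes, file.path(dir, "annotation.gtf"))
  if (!is.null(sim$expr_transcripts)) {
    write_fpkm(sim$expr_transcripts, file.path(dir, "fpkm_transcripts.tsv"))
    write_fpkm(sim$expr_genes, file.path(dir, "fpkm_genes.tsv"))
  }
  for (nm in names(sim$truth)) {
    df <- sim$truth[[nm]]
    if (is.data.frame(df) && nrow(df))
      utils::write.table(df, file.path(dir, "truth", paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
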