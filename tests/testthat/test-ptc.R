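test_that("reference_orf prefers the longest annotated CDS, else longest ORF", {
  fx <- make_ptc_fixture(ir_intron(30))
  ref <- reference_orf(fx$gene, fx$genome)
  expect_equal(ref$source, "cds")
  expect_equal(ref$transcript_id, "g.t1")
  expect_equal(ref$start_genomic, 7)
  expect_equal(ref$stop_genomic, 142)      # first base of the TAA (tx 112)

  # two CDS transcripts: the longer one wins
  g2 <- gene_model("g", list(
    tx("g.a", "g", ex(1, 300), cds = c(1, 300)),
    tx("g.b", "g", ex(1, 300), cds = c(1, 150))))
  expect_equal(reference_orf(g2, c(chr1 = strrep("A", 300)))$transcript_id,
               "g.a")

  # ORF fallback on an unannotated gene
  seq <- paste0("CCCCCC", "ATG", strrep("GCA", 120), "TAA", "CCC")
  g3 <- gene_model("g", list(tx("g.t1", "g", ex(1, nchar(seq)))))
  ref3 <- reference_orf(g3, c(chr1 = seq))
  expect_equal(ref3$source, "orf")
  expect_equal(ref3$start_genomic, 7)
  expect_equal(ref3$stop_genomic, 7 + 3 + 360)

  # nothing long enough -> undetermined
  g4 <- gene_model("g", list(tx("g.t1", "g", ex(1, 50))))
  expect_null(reference_orf(g4, c(chr1 = strrep("C", 50))))
})

test_that("retained introns are classified PTC+/PTC- by stop position", {
  # 3n, stop-free {C,G} intron: frame preserved, no premature stop
  fx <- make_ptc_fixture(ir_intron(30))
  ref <- reference_orf(fx$gene, fx$genome)
  call <- classify_ptc(fx$gene$transcripts[["g.t2"]], ref, fx$genome,
                       fx$intron)
  expect_equal(call$status, "PTC-")

  # in-frame TAA inside the intron (offset 7: 54 coding nt precede)
  fx2 <- make_ptc_fixture(ir_intron(30, taa_at = 7))
  ref2 <- reference_orf(fx2$gene, fx2$genome)
  call2 <- classify_ptc(fx2$gene$transcripts[["g.t2"]], ref2, fx2$genome,
                        fx2$intron)
  expect_equal(call2$status, "PTC+")
  expect_equal(call2$first_stop_tx, 60 + 7)  # intron offset 7 in tx coords

  # 31 nt frameshifting intron with a stop in the shifted frame downstream:
  # shifted reading hits TAA at exon2 offset 6 (hand-derived)
  core <- paste0("GCC", "CCT", "AAC", strrep("GCC", 14))
  fx3 <- make_ptc_fixture(ir_intron(31), exon2_core = core)
  ref3 <- reference_orf(fx3$gene, fx3$genome)
  call3 <- classify_ptc(fx3$gene$transcripts[["g.t2"]], ref3, fx3$genome,
                        fx3$intron)
  expect_equal(call3$status, "PTC+")
  # and the base (properly spliced) isoform is stop-free until its own stop
  base_call <- classify_ptc(
    tx("g.t1b", "g", ex(1, 120 + 31)), ref3, fx3$genome, fx3$intron)
  expect_equal(base_call$status, "PTC+")  # same retained form, sanity

  # intron entirely in the 3' UTR can never precede the stop
  seq <- paste0("CCCCCC", "ATG", strrep("GCC", 15), "TAA",  # CDS tx 7..57
                strrep("C", 43),                            # UTR3 in exon1
                ir_intron(30), strrep("C", 60))
  gutr <- gene_model("g", list(
    tx("g.t1", "g", ex(1, 100, 131, 190), cds = c(7, 57)),
    tx("g.t2", "g", ex(1, 190))))
  refu <- reference_orf(gutr, c(chr1 = seq))
  callu <- classify_ptc(gutr$transcripts[["g.t2"]], refu, c(chr1 = seq),
                        c(101, 130))
  expect_equal(callu$status, "PTC-")

  # non-retaining transcript -> error
  expect_error(classify_ptc(fx$gene$transcripts[["g.t1"]], ref, fx$genome,
                            fx$intron), "does not retain")
})

test_that("PTC calls are invariant under a whole-fixture strand mirror", {
  cases <- list(ir_intron(30), ir_intron(30, taa_at = 7), ir_intron(31))
  for (intr in cases) {
    fx <- make_ptc_fixture(intr)
    ref <- reference_orf(fx$gene, fx$genome)
    fwd <- classify_ptc(fx$gene$transcripts[["g.t2"]], ref, fx$genome,
                        fx$intron)
    L <- nchar(fx$genome[["chr1"]])
    mg <- mirror_gene(fx$gene, L)
    mgenome <- c(chr1 = mirror_genome_seq(fx$genome[["chr1"]]))
    mref <- reference_orf(mg, mgenome)
    mint <- sort(L - fx$intron + 1)
    rev <- classify_ptc(mg$transcripts[["g.t2"]], mref, mgenome, mint)
    expect_equal(rev$status, fwd$status, label = substr(intr, 1, 12))
  }
})

test_that("3n stop-free introns never and in-frame stops always flip the call", {
  set.seed(31)
  for (i in 1:15) {
    len <- 3 * sample(5:40, 1)
    fx <- make_ptc_fixture(ir_intron(len))
    ref <- reference_orf(fx$gene, fx$genome)
    expect_equal(classify_ptc(fx$gene$transcripts[["g.t2"]], ref,
                              fx$genome, fx$intron)$status, "PTC-")
    p <- 3 * sample(2:(len / 3 - 2), 1) + 1   # in-frame offset
    fx2 <- make_ptc_fixture(ir_intron(len, taa_at = p))
    ref2 <- reference_orf(fx2$gene, fx2$genome)
    expect_equal(classify_ptc(fx2$gene$transcripts[["g.t2"]], ref2,
                              fx2$genome, fx2$intron)$status, "PTC+")
  }
})

test_that("expression_filter keeps transcripts present in some tissue", {
  vals <- rbind(a = rep(0.5, 6), b = c(1.2, 1.2, 1.2, 0, 0, 0),
                c = c(0.9, 1.0, 1.1, 0, 0, 0),
                d = rep(0, 6), e = rep(3, 6))
  colnames(vals) <- paste0(rep(c("leaf", "stamen"), each = 3), "_rep", 1:3)
  tm <- stats::setNames(rep(c("leaf", "stamen"), each = 3), colnames(vals))
  expr <- expression_matrix(vals, tm)
  expect_equal(expression_filter(rownames(vals), expr),
               c("b", "c", "e"))   # c: mean(0.9,1,1.1) = 1.0 passes
  expect_equal(expression_filter(rownames(vals), expr, min_fpkm = 2), "e")
  expect_error(expression_filter(c("a", "zz"), expr), "zz")
})

test_that("ptc_census tallies per-tissue, shared, specific and the ratio", {
  calls <- data.frame(
    transcript_id = paste0("t", 1:6), gene_id = paste0("g", 1:6),
    intron_start = 1, intron_end = 10,
    status = c("PTC+", "PTC+", "PTC-", "PTC-", "PTC-", "PTC-"),
    nmd_50nt_flag = FALSE, stringsAsFactors = FALSE)
  vals <- matrix(5, nrow = 6, ncol = 6,
                 dimnames = list(paste0("t", 1:6),
                                 paste0(rep(c("leaf", "stamen"), each = 3),
                                        "_rep", 1:3)))
  tm <- stats::setNames(rep(c("leaf", "stamen"), each = 3), colnames(vals))
  cen <- ptc_census(calls, expression_matrix(vals, tm))
  expect_equal(unname(cen$ratio), 0.5)
  expect_equal(unname(cen$shared), c(2L, 4L))
  expect_equal(unname(cen$specific), c(0L, 0L))
  expect_equal(cen$per_tissue$n_ptc_plus, c(2L, 2L))

  empty <- ptc_census(calls[0, ], expression_matrix(vals, tm))
  expect_equal(unname(empty$total), c(0L, 0L))
})

test_that("simulated retained introns recover their planted PTC statuses", {
  cfg <- simulation_config(seed = 13, n_genes = 250,
                           modules = list(count = 2, size = 30,
                                          within_cor = 0.8, hub_cor = 1))
  sim <- simulate_expression(simulate_annotation(cfg))
  tp <- sim$truth$ptc
  expect_gt(nrow(tp), 5)
  calls <- do.call(rbind, lapply(seq_len(nrow(tp)), function(r) {
    g <- sim$genes[[tp$gene_id[r]]]
    classify_ptc(g$transcripts[[tp$transcript_id[r]]],
                 reference_orf(g, sim$genome), sim$genome,
                 c(tp$intron_start[r], tp$intron_end[r]))
  }))
  expect_equal(calls$status, tp$status)
  # planted 1:2 allocation shows up in the census of expressed transcripts
  cen <- ptc_census(calls, sim$expr_transcripts)
  alloc <- largest_remainder(sum(tp$status %in% c("PTC+", "PTC-")),
                             c(1, 2) / 3)
  expect_equal(unname(cen$total), alloc)
})
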