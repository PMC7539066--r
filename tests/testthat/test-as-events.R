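test_that("each event type is called on its defining configuration", {
  # IR: retained intron with matching outer flanks
  ir <- enumerate_events(gene("g", list(ex(1, 100, 201, 300), ex(1, 300))))
  expect_equal(ir$type, "IR")
  expect_equal(ir$signature, "100:201")
  expect_equal(ir$inclusion, "g.t2")   # the retaining form
  expect_equal(ir$exclusion, "g.t1")

  # ES: internal exon inside a flank-matched intron
  es <- enumerate_events(gene("g", list(
    ex(1, 100, 201, 300, 401, 500), ex(1, 100, 401, 500))))
  expect_equal(es$type, "ES")
  expect_equal(es$signature, "100:201:300:401")
  expect_equal(es$inclusion, "g.t1")

  # A5 on + strand: donors differ, acceptor shared, flanks overlap
  a5 <- enumerate_events(gene("g", list(
    ex(1, 100, 201, 300), ex(1, 120, 201, 300))))
  expect_equal(a5$type, "A5")
  expect_equal(a5$signature, "101:121:200")
  expect_equal(a5$inclusion, "g.t2")   # shorter intron
  # mirroring the whole fixture to the minus strand preserves the
  # transcript-orientation semantics: still A5
  a5m <- enumerate_events(mirror_gene(
    gene("g", list(ex(1, 100, 201, 300), ex(1, 120, 201, 300))), 300))
  expect_equal(a5m$type, "A5")

  # A3 on + strand: acceptors differ
  a3 <- enumerate_events(gene("g", list(
    ex(1, 100, 201, 300), ex(1, 100, 231, 300))))
  expect_equal(a3$type, "A3")
  expect_equal(a3$inclusion, "g.t1")

  # MX: shared outer junctions, disjoint middle exons
  mx <- enumerate_events(gene("g", list(
    ex(1, 100, 201, 250, 401, 500), ex(1, 100, 301, 350, 401, 500))))
  expect_equal(mx$type, "MX")
  expect_equal(mx$signature, "100:201:250:301:350:401")
  expect_equal(mx$inclusion, "g.t1")   # carries the genomic-left exon

  # AF: disjoint first exons sharing the downstream acceptor
  af <- enumerate_events(gene("g", list(
    ex(101, 160, 301, 400), ex(1, 60, 301, 400))))
  expect_equal(af$type, "AF")
  expect_equal(af$inclusion, "g.t2")   # distal first exon
  expect_equal(enumerate_events(mirror_gene(gene("g", list(
    ex(101, 160, 301, 400), ex(1, 60, 301, 400))), 400))$type, "AF")

  # AL: disjoint last exons sharing the upstream donor
  al <- enumerate_events(gene("g", list(
    ex(1, 100, 201, 260), ex(1, 100, 301, 360))))
  expect_equal(al$type, "AL")
  expect_equal(al$inclusion, "g.t2")

  # single-transcript gene: no pair, no events
  expect_equal(nrow(enumerate_events(gene("g", list(ex(1, 100, 201, 300))))),
               0L)
  # identical isoforms: no events
  expect_equal(nrow(enumerate_events(gene("g", list(
    ex(1, 100, 201, 300), ex(1, 100, 201, 300))))), 0L)
})

test_that("terminal-exon and MX configurations are not double-called as A5/A3", {
  # the ES configuration shares boundaries with the skipping intron but the
  # differing-side flanks do not overlap
  es <- enumerate_events(gene("g", list(
    ex(1, 100, 201, 300, 401, 500), ex(1, 100, 401, 500))))
  expect_equal(es$type, "ES")
  mx <- enumerate_events(gene("g", list(
    ex(1, 100, 201, 250, 401, 500), ex(1, 100, 301, 350, 401, 500))))
  expect_equal(mx$type, "MX")
  af <- enumerate_events(gene("g", list(
    ex(101, 160, 301, 400), ex(1, 60, 301, 400))))
  expect_equal(af$type, "AF")
})

test_that("enumeration is order-independent and deduplicates across pairs", {
  sets <- list(ex(1, 100, 201, 300, 401, 500),
               ex(1, 300, 401, 500),
               ex(1, 100, 201, 300))
  g1 <- gene("g", sets)
  g2 <- gene("g", sets[c(3, 1, 2)])
  e1 <- enumerate_events(g1)
  e2 <- enumerate_events(g2)
  # same events regardless of transcript input order (ids permuted with the
  # order, so compare by type+signature and set sizes)
  expect_equal(e1[, c("type", "signature")], e2[, c("type", "signature")])
  # the retained intron 101-200 is shared by two spliced isoforms: one IR
  # event with both in the exclusion set
  ir <- e1[e1$type == "IR" & e1$signature == "100:201", ]
  expect_equal(nrow(ir), 1L)
  expect_length(strsplit(ir$exclusion, ",")[[1]], 2L)
})

test_that("enumerate_events matches the brute-force oracle on random genes", {
  set.seed(101)
  for (i in 1:150) {
    g <- random_gene_model(paste0("g", i))
    expect_identical(enumerate_events(g), oracle_enumerate(g),
                     label = paste("gene", i))
  }
})

test_that("classify_genes computes the AS proportion and rejects unknowns", {
  genes <- lapply(1:10, function(i)
    gene(paste0("g", i), list(ex(1, 100, 201, 300))))
  ev <- rbind(
    data.frame(gene_id = "g1", event_id = "e1", type = "IR",
               signature = "s", inclusion = "a", exclusion = "b",
               chrom = "chr1", strand = "+", stringsAsFactors = FALSE),
    data.frame(gene_id = "g2", event_id = "e2", type = "ES",
               signature = "s", inclusion = "a", exclusion = "b",
               chrom = "chr1", strand = "+", stringsAsFactors = FALSE))
  cls <- classify_genes(genes, ev)
  expect_equal(cls$percent, 20)
  expect_equal(cls$n_as, 2L)
  expect_equal(classify_genes(genes, splicescape:::empty_event_table())$percent,
               0)
  ev$gene_id[1] <- "nope"
  expect_error(classify_genes(genes, ev), "unknown gene: nope")
})

test_that("event_summary reports counts and two-decimal proportions", {
  s <- event_summary(c(IR = 10743, A3 = 7679, ES = 6312, A5 = 5780,
                       AF = 4413, AL = 2399, MX = 518))
  expect_equal(attr(s, "total"), 37844)
  expect_equal(s$percent[s$type == "IR"], 28.39)
  expect_equal(s$percent[s$type == "MX"], 1.37)
  expect_equal(s$percent[s$type == "A3"], 20.29)

  one <- event_summary(c(IR = 1))
  expect_equal(one$percent[one$type == "IR"], 100)
  zero <- event_summary(c(IR = 0))
  expect_equal(attr(zero, "total"), 0)
  expect_equal(nrow(zero), 0L)
  expect_error(event_summary(c(XX = 3)), "unknown event type")

  # proportions always sum to 100 within rounding slack
  set.seed(5)
  for (i in 1:50) {
    counts <- stats::setNames(sample(0:500, 7, replace = TRUE),
                              c("IR", "ES", "A3", "A5", "AF", "AL", "MX"))
    if (sum(counts) == 0) next
    expect_lt(abs(sum(event_summary(counts)$percent) - 100), 0.05)
  }
})

test_that("tissue-specific AS sets follow the single-tissue presence rule", {
  genes <- list(gene("g1", list(ex(1, 100, 201, 300), ex(1, 300))))
  ev <- enumerate_events_all(genes)
  vals <- rbind(
    g1.t1 = c(5, 5, 5, 0, 0, 0),    # leaf only -> specific
    g1.t2 = c(2, 2, 2, 3, 3, 3))    # two tissues -> not specific
  colnames(vals) <- c("leaf_rep1", "leaf_rep2", "leaf_rep3",
                      "stamen_rep1", "stamen_rep2", "stamen_rep3")
  tm <- stats::setNames(rep(c("leaf", "stamen"), each = 3), colnames(vals))
  gvals <- rbind(g1 = colSums(vals))
  expr_tx <- expression_matrix(vals, tm)
  sets <- tissue_specific_sets(ev, genes, expr_tx)
  expect_equal(sets$transcripts$id, "g1.t1")
  expect_equal(sets$transcripts$tissue, "leaf")

  # planted specificity in the simulator is recovered exactly
  cfg <- simulation_config(seed = 21, n_genes = 120, n_tissue_specific = 12,
                           modules = list(count = 2, size = 25,
                                          within_cor = 0.8, hub_cor = 1))
  sim <- simulate_expression(simulate_annotation(cfg))
  ev2 <- enumerate_events_all(sim$genes)
  sets2 <- tissue_specific_sets(ev2, sim$genes, sim$expr_transcripts)
  expect_setequal(sets2$transcripts$id,
                  sim$truth$tissue_specific$transcript_id)
})
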