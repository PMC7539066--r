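# End-to-end orchestration: events -> PTC -> splice sites -> features ->
# expression -> coexpression, with per-stage TSV outputs, a combined
# summary and a machine-readable manifest.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full AS characterization pipeline
#'
#' Either supply input files (`gtf`, `fasta`, `fpkm_transcripts`,
#' `fpkm_genes`) or a [simulation_config()], in which case the inputs are
#' generated first and written alongside the results.
#'
#' @param out_dir Output directory.
#' @param gtf,fasta,fpkm_transcripts,fpkm_genes Input paths (ignored when
#'   `sim_config` is given).
#' @param sim_config Optional [simulation_config()]; when set, inputs are
#'   simulated.
#' @param min_fpkm Presence/IR-filter threshold (default 1).
#' @param power Coexpression soft-threshold power (default 16; the study's
#'   choice). `NULL` selects by scale-free fit.
#' @param min_module_size Minimum module size (default 300; use far less at
#'   desk scale).
#' @param hub_fraction Top-degree hub fraction (default 0.10).
#' @param variance_fraction Variance pre-filter for the network
#'   (default 0.60).
#' @param max_event_bin Top bin for the event-count/structure table.
#' @return List of class `pipeline_result` with the per-stage tables, the
#'   `summary` list, and the paths written.
#' @export
run_pipeline <- function(out_dir,
                         gtf = NULL, fasta = NULL,
                         fpkm_transcripts = NULL, fpkm_genes = NULL,
                         sim_config = NULL,
                         min_fpkm = 1, power = 16,
                         min_module_size = 300, hub_fraction = 0.10,
                         variance_fraction = 0.60, max_event_bin = 5L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(sim_config)) {
    sim <- .stage("simulate", {
      s <- simulate_annotation(sim_config)
      simulate_expression(s)
    })
    write_simulation(sim, file.path(out_dir, "inputs"))
    genes <- sim$genes; genome <- sim$genome
    expr_tx <- sim$expr_transcripts; expr_gene <- sim$expr_genes
  } else {
    genome <- .stage("read_genome", read_genome(fasta))
    genes <- .stage("read_annotation", read_annotation(gtf, genome))
    expr_tx <- if (is.null(fpkm_transcripts)) NULL else
      .stage("read_fpkm", read_fpkm(fpkm_transcripts))
    expr_gene <- if (is.null(fpkm_genes)) NULL else
      .stage("read_fpkm", read_fpkm(fpkm_genes))
  }

  events <- .stage("events", enumerate_events_all(genes))
  cls <- .stage("events", classify_genes(genes, events))
  summ <- .stage("events", event_summary(events))
  utils::write.table(events, file.path(out_dir, "events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(summ),
                     file.path(out_dir, "event_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # PTC stage needs transcript expression
  ptc <- NULL; census <- NULL
  ir_events <- events[events$type == "IR", , drop = FALSE]
  if (nrow(ir_events)) {
    if (is.null(expr_tx))
      .stage("ptc", stop("transcript FPKM input is required"))
    ptc <- .stage("ptc", {
      calls <- list()
      for (r in seq_len(nrow(ir_events))) {
        g <- genes[[ir_events$gene_id[r]]]
        sig <- as.numeric(strsplit(ir_events$signature[r], ":")[[1]])
        intron <- c(sig[1] + 1, sig[2] - 1)
        retainers <- strsplit(ir_events$inclusion[r], ",")[[1]]
        retainers <- expression_filter(retainers, expr_tx, min_fpkm)
        ref <- reference_orf(g, genome)
        for (tid in retainers)
          calls[[length(calls) + 1L]] <-
            classify_ptc(g$transcripts[[tid]], ref, genome, intron)
      }
      if (length(calls)) do.call(rbind, calls) else NULL
    })
    if (!is.null(ptc)) {
      census <- .stage("ptc", ptc_census(ptc, expr_tx, min_fpkm))
      write_ptc_table(ptc, file.path(out_dir, "ptc_calls.tsv"))
    }
  }

  sites <- .stage("splice_sites",
                  site_proportions(genes, cls$flags, genome))
  write_site_profile(sites, file.path(out_dir, "splice_sites.tsv"))

  feats <- .stage("features", feature_table(genes, events))
  utils::write.table(feats, file.path(out_dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  groups <- .stage("features",
                   if (any(feats$as_flag) && any(!feats$as_flag))
                     compare_groups(feats) else NULL)
  if (!is.null(groups))
    utils::write.table(groups, file.path(out_dir, "group_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  # AS lncRNAs: every isoform of an AS gene noncoding
  lnc <- .stage("lncRNA", {
    as_gids <- unique(events$gene_id)
    vapply(as_gids, function(gid) {
      all(vapply(genes[[gid]]$transcripts, flag_noncoding, logical(1),
                 genome = genome))
    }, logical(1))
  })

  coex <- NULL
  if (!is.null(expr_gene)) {
    coex <- .stage("coexpression",
                   coexpression_network(expr_gene, power = power,
                                        min_module_size = min_module_size,
                                        hub_fraction = hub_fraction,
                                        variance_fraction =
                                          variance_fraction))
    utils::write.table(
      data.frame(gene = names(coex$labels), module = coex$labels,
                 stringsAsFactors = FALSE),
      file.path(out_dir, "modules.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(coex$hubs, file.path(out_dir, "hubs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  top_sites <- utils::head(sites[sites$group == "AS", ], 5)
  summary <- list(
    n_genes = length(genes),
    n_as_genes = cls$n_as,
    as_gene_percent = cls$percent,
    n_events = attr(summ, "total"),
    event_percent = stats::setNames(summ$percent, summ$type),
    ptc_counts = if (!is.null(census)) census$total else NULL,
    ptc_ratio = if (!is.null(census)) census$ratio else NULL,
    n_as_lncRNA = sum(lnc),
    top_as_splice_sites = paste0(top_sites$donor, "-", top_sites$acceptor,
                                 " (", top_sites$percent, "%)"),
    n_modules = if (!is.null(coex)) length(unique(
      coex$labels[coex$labels > 0])) else NULL,
    n_hubs = if (!is.null(coex)) sum(coex$hubs$hub) else NULL)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    package = "splicescape",
    version = as.character(utils::packageVersion("splicescape")),
    seed = if (!is.null(sim_config)) sim_config$seed else NULL,
    parameters = list(min_fpkm = min_fpkm, power = power,
                      min_module_size = min_module_size,
                      hub_fraction = hub_fraction,
                      variance_fraction = variance_fraction),
    sim_config = if (!is.null(sim_config))
      unclass(sim_config)[c("n_genes", "as_fraction", "canonical_fraction",
                            "lnc_fraction", "n_tissue_specific")]
      else NULL)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(list(genes = genes, events = events, classification = cls,
                 event_summary = summ, ptc = ptc, census = census,
                 sites = sites, features = feats, groups = groups,
                 coexpression = coex, summary = summary,
                 out_dir = out_dir),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("splicescape pipeline result\n")
  cat(sprintf("  genes: %d (%s%% AS)\n", s$n_genes, s$as_gene_percent))
  cat(sprintf("  events: %d\n", s$n_events))
  if (!is.null(s$ptc_ratio))
    cat(sprintf("  PTC+/PTC-: %d/%d (ratio %.2f)\n",
                s$ptc_counts[["PTC+"]], s$ptc_counts[["PTC-"]],
                s$ptc_ratio))
  if (!is.null(s$n_modules))
    cat(sprintf("  modules: %d, hubs: %d\n", s$n_modules, s$n_hubs))
  cat("  outputs in: ", x$out_dir, "\n", sep = "")
  invisible(x)
}

#' Event tallies reported for the Liriodendron chinense isoform catalog
#'
#' Published per-type AS event counts for the seven-tissue L. chinense
#' transcriptome (37,844 events over 8,503 AS genes among 48,408 genes),
#' usable as worked-example input to [event_summary()].
#'
#' @return Named numeric vector of event counts by type.
#' @export
lchinense_event_counts <- function() {
  c(IR = 10743, A3 = 7679, ES = 6312, A5 = 5780, AF = 4413, AL = 2399,
    MX = 518)
}

#' Gene tallies for the L. chinense isoform catalog
#' @return Named numeric vector with `as_genes` and `total_genes`.
#' @export
lchinense_gene_counts <- function() {
  c(as_genes = 8503, total_genes = 48408)
}

#' PTC tallies for the L. chinense retained-intron transcripts
#' @return Named numeric vector with `ptc_plus` and `ptc_minus`.
#' @export
lchinense_ptc_counts <- function() {
  c(ptc_plus = 1656, ptc_minus = 3310)
}
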