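# FPKM matrix container and the transforms/presence/variance/clustering
# operations shared across the pipeline stages.

#' Construct an expression matrix
#'
#' @param values Numeric matrix, rows = transcripts or genes, columns =
#'   samples (tissue x replicate). FPKM scale, all values >= 0.
#' @param tissue_map Named character vector mapping each column name to its
#'   tissue label.
#' @return Object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, tissue_map) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("FPKM values must be non-negative")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs row and column names")
  miss <- setdiff(colnames(values), names(tissue_map))
  if (length(miss))
    stop("sample '", miss[1], "' has no tissue assignment")
  structure(list(values = values,
                 tissues = tissue_map[colnames(values)]),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix %d rows x %d samples, %d tissues>\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$tissues))))
  invisible(x)
}

#' Read an FPKM TSV (rows x samples, header = sample ids)
#'
#' @param path TSV file; first column = row ids.
#' @param tissue_map Named character vector sample -> tissue, or `NULL` to
#'   derive tissues by stripping a trailing replicate suffix (`_rep<k>` or
#'   `_<k>`) from the sample names.
#' @return An [expression_matrix()].
#' @export
read_fpkm <- function(path, tissue_map = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
  m <- as.matrix(df)
  if (is.null(tissue_map)) {
    tissue_map <- stats::setNames(sub("_(rep)?[0-9]+$", "", colnames(m)),
                                  colnames(m))
  }
  expression_matrix(m, tissue_map)
}

#' Write an expression matrix as TSV
#' @param expr An [expression_matrix()].
#' @param path Output path.
#' @export
write_fpkm <- function(expr, path) {
  df <- data.frame(id = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' log10(FPKM + 1) transform
#' @param expr An [expression_matrix()] or non-negative numeric matrix.
#' @return Transformed matrix (same shape).
#' @export
log_transform <- function(expr) {
  m <- if (inherits(expr, "expression_matrix")) expr$values else as.matrix(expr)
  if (any(m < 0)) stop("negative value in FPKM matrix")
  log10(m + 1)
}

#' Per-tissue presence calls
#'
#' A row is present in a tissue iff its mean FPKM over that tissue's
#' replicates is at least `min_fpkm`.
#'
#' @param expr An [expression_matrix()].
#' @param min_fpkm Presence threshold (default 1).
#' @return Logical matrix rows x tissues.
#' @export
tissue_presence <- function(expr, min_fpkm = 1) {
  stopifnot(inherits(expr, "expression_matrix"))
  tissues <- unique(unname(expr$tissues))
  means <- sapply(tissues, function(ts)
    rowMeans(expr$values[, expr$tissues == ts, drop = FALSE]))
  means <- matrix(means, nrow = nrow(expr$values),
                  dimnames = list(rownames(expr$values), tissues))
  means >= min_fpkm
}

#' Keep the most variable rows
#'
#' Rows are ranked by variance across all samples; the top
#' `ceiling(fraction * n)` are retained. Ties are broken by row id so the
#' retained set is deterministic.
#'
#' @param expr An [expression_matrix()] or numeric matrix.
#' @param fraction Fraction of rows to keep, in (0, 1] (default 0.60).
#' @return Character vector of retained row ids (original row order).
#' @export
variance_top_fraction <- function(expr, fraction = 0.60) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  m <- if (inherits(expr, "expression_matrix")) expr$values else as.matrix(expr)
  if (ncol(m) < 2L) stop("need at least two samples to rank by variance")
  v <- apply(m, 1L, stats::var)
  keep_n <- ceiling(fraction * nrow(m))
  ord <- order(-v, rownames(m))
  keep <- sort(ord[seq_len(keep_n)])
  rownames(m)[keep]
}

#' Hierarchical clustering of expression rows
#'
#' Average-linkage clustering on a 1 - Pearson correlation distance of the
#' log10(FPKM + 1) rows; the heatmap convention. Zero-variance rows have no
#' defined correlation and are assigned distance 1 to all others (warned).
#'
#' @param expr An [expression_matrix()] or numeric FPKM matrix.
#' @return List with `tree` (an [stats::hclust] object), `order` (row ids in
#'   leaf order), `distance` ("1-pearson") and `linkage` ("average").
#' @export
hierarchical_cluster <- function(expr) {
  m <- log_transform(expr)
  if (nrow(m) < 2L) stop("need at least two rows to cluster")
  sds <- apply(m, 1L, stats::sd)
  cc <- suppressWarnings(stats::cor(t(m)))
  if (any(sds == 0)) {
    warning("zero-variance row(s): distance to all others set to 1")
    cc[sds == 0, ] <- 0
    cc[, sds == 0] <- 0
  }
  diag(cc) <- 1
  d <- stats::as.dist(1 - cc)
  tree <- stats::hclust(d, method = "average")
  list(tree = tree, order = rownames(m)[tree$order],
       distance = "1-pearson", linkage = "average")
}
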