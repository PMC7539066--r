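# Simplified signed weighted coexpression network: soft threshold, signed
# adjacency, topological overlap, static-cut module detection and
# top-degree hub calling.

#' Signed soft-thresholded adjacency
#'
#' `a_ij = ((1 + cor(x_i, x_j)) / 2) ^ beta`, unit diagonal. Zero-variance
#' rows have no defined correlation and are excluded with a warning.
#'
#' @param m Numeric matrix, rows = genes, columns = samples.
#' @param beta Soft-threshold power.
#' @return Symmetric adjacency matrix with values in \[0, 1\].
#' @export
signed_adjacency <- function(m, beta) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least two rows")
  sds <- apply(m, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance row(s) excluded from network")
    m <- m[sds > 0, , drop = FALSE]
  }
  cc <- stats::cor(t(m))
  a <- ((1 + cc) / 2)^beta
  diag(a) <- 1
  a
}

#' Scale-free-topology soft-threshold selection
#'
#' For each candidate power the signed adjacency is built, connectivities
#' `k_i = sum_j a_ij - 1` are binned (`n_bins` equal-width bins) and the
#' scale-free fit is the R-squared of `log10(frequency) ~ log10(mean k)`,
#' signed negative when the slope is positive. The chosen power is the
#' smallest candidate with fit at least `r2_cut`, else the argmax; an
#' explicit `override` short-circuits the scan.
#'
#' @param m Expression matrix (genes x samples), typically log-transformed.
#' @param powers Candidate powers (default 1:10, 12, 14, 16, 18, 20).
#' @param r2_cut Fit threshold (default 0.80).
#' @param n_bins Histogram bins for the degree distribution (default 10).
#' @param override If not `NULL`, returned as the chosen power regardless of
#'   fit (the study fixed 16).
#' @return List with `beta` and `fit_table` (power, r_squared, slope,
#'   mean_k).
#' @export
pick_soft_threshold <- function(m, powers = c(1:10, seq(12, 20, 2)),
                                r2_cut = 0.80, n_bins = 10L,
                                override = NULL) {
  if (length(powers) < 2L) stop("need at least two candidate powers")
  fit <- data.frame(power = powers, r_squared = NA_real_, slope = NA_real_,
                    mean_k = NA_real_)
  for (i in seq_along(powers)) {
    a <- signed_adjacency(m, powers[i])
    k <- rowSums(a) - 1
    fit$mean_k[i] <- mean(k)
    sf <- scale_free_fit(k, n_bins)
    fit$r_squared[i] <- sf$r_squared
    fit$slope[i] <- sf$slope
  }
  if (!is.null(override))
    return(list(beta = override, fit_table = fit))
  signed_r2 <- ifelse(fit$slope < 0, fit$r_squared, -fit$r_squared)
  ok <- which(signed_r2 >= r2_cut)
  beta <- if (length(ok)) powers[ok[1L]] else powers[which.max(signed_r2)]
  list(beta = beta, fit_table = fit)
}

scale_free_fit <- function(k, n_bins = 10L) {
  brks <- seq(min(k), max(k), length.out = n_bins + 1L)
  if (brks[1] == brks[n_bins + 1L]) return(list(r_squared = 0, slope = 0))
  bin <- cut(k, brks, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  mids <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0 & !is.na(mids) & mids > 0
  if (sum(keep) < 3L) return(list(r_squared = 0, slope = 0))
  fitlm <- stats::lm(log10(freq[keep]) ~ log10(mids[keep]))
  list(r_squared = summary(fitlm)$r.squared,
       slope = unname(stats::coef(fitlm)[2L]))
}

#' Topological overlap similarity
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k_i = sum_{u != i} a_iu` and the shared-neighbor sum over `u != i, j`;
#' unit diagonal.
#'
#' @param a Adjacency from [signed_adjacency()].
#' @return Symmetric TOM matrix with values in \[0, 1\].
#' @export
tom_similarity <- function(a) {
  a <- as.matrix(a)
  n <- nrow(a)
  a0 <- a
  diag(a0) <- 0
  shared <- a0 %*% a0            # sum over all u != i (and != j via diag 0)
  k <- rowSums(a0)
  kmin <- outer(k, k, pmin)
  tom <- (shared + a0) / (kmin + 1 - a0)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect coexpression modules from a TOM
#'
#' Average-linkage hierarchical clustering on `1 - TOM`; the tree is cut at
#' `cut_height` (default: midpoint of the largest gap in the upper half of
#' the merge-height sequence, a deterministic static stand-in for dynamic
#' tree cutting);
#' clusters smaller than `min_size` are relabeled 0 (unassigned) and the
#' remaining modules renumbered by size, largest first.
#'
#' @param tom TOM matrix with row/column names.
#' @param min_size Minimum module size (the study used 300; desk-scale
#'   analyses will want far less).
#' @param cut_height Optional explicit cut height on the 1 - TOM scale.
#' @return Named integer vector of module labels (0 = unassigned).
#' @export
detect_modules <- function(tom, min_size, cut_height = NULL) {
  if (min_size < 2L) stop("min_size must be at least 2")
  d <- stats::as.dist(1 - tom)
  tree <- stats::hclust(d, method = "average")
  if (is.null(cut_height)) {
    # largest gap among the upper half of merge heights: the low half is
    # within-cluster structure, the module/background transition sits above
    h <- sort(tree$height)
    top <- h[h >= stats::median(h)]
    if (length(top) > 1L) {
      gaps <- diff(top)
      g <- which.max(gaps)
      cut_height <- top[g] + gaps[g] / 2
    } else cut_height <- h[length(h)]
  }
  raw <- stats::cutree(tree, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_size]
  labels <- integer(length(raw))
  names(labels) <- names(raw)
  if (length(keep)) {
    kept_sizes <- sort(sizes[keep], decreasing = TRUE)
    for (i in seq_along(kept_sizes)) {
      labels[raw == as.integer(names(kept_sizes)[i])] <- i
    }
  }
  labels
}

#' Top-degree hub genes per module
#'
#' Degree is the weighted within-module connectivity (sum of adjacency to
#' same-module genes, self excluded); per module the top
#' `ceiling(fraction * size)` genes by degree are hubs, ties broken by gene
#' id.
#'
#' @param labels Module labels from [detect_modules()].
#' @param a Adjacency matrix.
#' @param fraction Hub fraction (default 0.10).
#' @return data.frame `gene`, `module`, `degree`, `hub`, ordered by module
#'   then degree descending.
#' @export
hub_genes <- function(labels, a, fraction = 0.10) {
  stopifnot(!is.null(names(labels)))
  rows <- list()
  for (mod in sort(unique(labels[labels > 0]))) {
    members <- names(labels)[labels == mod]
    sub <- a[members, members, drop = FALSE]
    deg <- rowSums(sub) - 1     # exclude the unit self-adjacency
    ord <- order(-deg, members)
    n_hub <- ceiling(fraction * length(members))
    hub <- logical(length(members))
    hub[ord[seq_len(n_hub)]] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      gene = members, module = mod, degree = unname(deg), hub = hub,
      stringsAsFactors = FALSE)[ord, ]
  }
  if (!length(rows))
    return(data.frame(gene = character(0), module = integer(0),
                      degree = numeric(0), hub = logical(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full coexpression analysis
#'
#' Variance filter, soft threshold, signed adjacency, TOM, modules and hubs
#' in one call.
#'
#' @param expr An [expression_matrix()] (gene level).
#' @param power Soft-threshold power; `NULL` to select by scale-free fit
#'   (the study fixed 16).
#' @param min_module_size Minimum module size (default 300, per the study).
#' @param hub_fraction Hub fraction (default 0.10).
#' @param variance_fraction Variance pre-filter fraction (default 0.60).
#' @param cut_height Passed to [detect_modules()].
#' @return Object of class `coexpression_result`: list with `beta`,
#'   `fit_table`, `adjacency`, `tom`, `labels`, `hubs`, `kept_genes`.
#' @export
coexpression_network <- function(expr, power = 16, min_module_size = 300,
                                 hub_fraction = 0.10,
                                 variance_fraction = 0.60,
                                 cut_height = NULL) {
  keep <- variance_top_fraction(expr, variance_fraction)
  m <- log_transform(expr)[keep, , drop = FALSE]
  picked <- if (is.null(power)) pick_soft_threshold(m)
    else list(beta = power, fit_table = NULL)
  a <- signed_adjacency(m, picked$beta)
  tom <- tom_similarity(a)
  labels <- detect_modules(tom, min_size = min_module_size,
                           cut_height = cut_height)
  hubs <- hub_genes(labels, a, fraction = hub_fraction)
  structure(list(beta = picked$beta, fit_table = picked$fit_table,
                 adjacency = a, tom = tom, labels = labels, hubs = hubs,
                 kept_genes = keep),
            class = "coexpression_result")
}

#' @export
print.coexpression_result <- function(x, ...) {
  sizes <- table(x$labels[x$labels > 0])
  cat(sprintf(
    "<coexpression_result: beta=%s, %d genes, %d module(s)%s, %d hub(s)>\n",
    format(x$beta), length(x$labels), length(sizes),
    if (length(sizes)) paste0(" [", paste(sizes, collapse = ", "), "]")
    else "", sum(x$hubs$hub)))
  invisible(x)
}

#' Export a weighted edge list
#'
#' @param a Adjacency matrix.
#' @param path Output TSV (`gene1`, `gene2`, `weight`).
#' @param min_weight Drop edges lighter than this (default 0).
#' @export
write_edge_list <- function(a, path, min_weight = 0) {
  idx <- which(upper.tri(a) & a >= min_weight, arr.ind = TRUE)
  out <- data.frame(gene1 = rownames(a)[idx[, 1]],
                    gene2 = colnames(a)[idx[, 2]],
                    weight = a[idx], stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
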