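test_that("signed adjacency follows the ((1 + r)/2)^beta closed forms", {
  x <- c(1, 2, 3, 4, 5, 6)
  m <- rbind(a = x, b = 2 * x + 1,           # r = 1
             c = -x,                         # r = -1 with a
             d = c(1, -1, 0, 0, -1, 1))      # orthogonal: r = 0 with a
  a6 <- signed_adjacency(m, 6)
  expect_equal(a6["a", "b"], 1)
  expect_equal(a6["a", "c"], 0)
  expect_equal(a6["a", "d"], 0.5^6, tolerance = 1e-12)
  expect_true(isSymmetric(a6))
  expect_true(all(a6 >= 0 & a6 <= 1))
  expect_equal(unname(diag(a6)), rep(1, 4))
  # zero-variance rows are excluded with a warning
  m2 <- rbind(m, e = rep(3, 6))
  expect_warning(a2 <- signed_adjacency(m2, 6), "zero-variance")
  expect_equal(nrow(a2), 4L)
  expect_error(signed_adjacency(m[1, , drop = FALSE], 6), "two rows")
})

test_that("TOM similarity matches the brute-force formula", {
  # 2-gene network: empty shared-neighbor sum, TOM_12 = a/(1 - a + 1)... the
  # formula evaluated directly
  a2 <- matrix(c(1, 0.4, 0.4, 1), 2, 2)
  t2 <- tom_similarity(a2)
  expect_equal(t2[1, 2], 0.4 / (0.4 + 1 - 0.4))
  # complete graph: TOM = 1 everywhere
  a1 <- matrix(1, 4, 4)
  expect_true(all(tom_similarity(a1) == 1))
  # random 5-gene adjacency vs the double-loop oracle
  set.seed(77)
  for (i in 1:5) {
    r <- matrix(runif(25, 0, 0.9), 5, 5)
    a <- (r + t(r)) / 2
    diag(a) <- 1
    tom <- tom_similarity(a)
    expect_equal(tom, oracle_tom(a), tolerance = 1e-12)
    expect_true(isSymmetric(tom))
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  }
})

test_that("soft-threshold selection honors the override and the fit rule", {
  set.seed(88)
  ms <- simulate_module_scores(60, list(count = 3, size = 20,
                                        within_cor = 0.8, hub_cor = 1),
                               paste0("T", 1:7), 3)
  rownames(ms$scores) <- paste0("g", 1:60)
  pick <- pick_soft_threshold(ms$scores, powers = c(2, 4, 6, 8),
                              override = 16)
  expect_equal(pick$beta, 16)
  expect_equal(pick$fit_table$power, c(2, 4, 6, 8))
  expect_true(all(is.finite(pick$fit_table$r_squared)))
  expect_error(pick_soft_threshold(ms$scores, powers = 7), "two candidate")
  # without override the chosen beta is the smallest passing candidate or
  # the argmax of the signed fit
  free <- pick_soft_threshold(ms$scores, powers = c(2, 4, 6, 8))
  expect_true(free$beta %in% c(2, 4, 6, 8))
  # fit statistic agrees with a direct regression on the binned degrees
  a <- signed_adjacency(ms$scores, 4)
  k <- rowSums(a) - 1
  sf <- splicescape:::scale_free_fit(k, 10)
  brks <- seq(min(k), max(k), length.out = 11)
  bin <- cut(k, brks, include.lowest = TRUE)
  freq <- tapply(k, bin, length); mids <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0 & mids > 0
  ref <- summary(stats::lm(log10(freq[keep]) ~ log10(mids[keep])))
  expect_equal(sf$r_squared, ref$r.squared)
})

test_that("module detection recovers planted blocks and handles edge cases", {
  set.seed(99)
  ms <- simulate_module_scores(60, list(count = 2, size = 30,
                                        within_cor = 0.85, hub_cor = 1),
                               paste0("T", 1:7), 3)
  rownames(ms$scores) <- paste0("g", 1:60)
  tom <- tom_similarity(signed_adjacency(ms$scores, 12))
  lab <- detect_modules(tom, min_size = 10)
  expect_gte(mclust::adjustedRandIndex(lab, ms$labels), 0.9)
  # labels renumbered by size descending
  sizes <- table(lab[lab > 0])
  expect_true(all(diff(as.numeric(sizes)) <= 0))
  # permuting rows yields the same partition up to names
  perm <- sample(nrow(tom))
  lab2 <- detect_modules(tom[perm, perm], min_size = 10)
  expect_gte(mclust::adjustedRandIndex(lab2[names(lab)], lab), 0.999)
  # all-identical rows form a single module
  ident <- matrix(1, 5, 5, dimnames = list(paste0("g", 1:5),
                                           paste0("g", 1:5)))
  expect_equal(unname(detect_modules(ident, min_size = 2)), rep(1L, 5))
  # min_size above n unassigns everything
  expect_true(all(detect_modules(tom, min_size = 100) == 0))
  expect_error(detect_modules(tom, min_size = 1), "min_size")
})

test_that("hub calling takes the ceiling top fraction by degree", {
  set.seed(123)
  n <- 20
  m <- matrix(runif(n * n, 0.1, 0.5), n, n)
  a <- (m + t(m)) / 2
  diag(a) <- 1
  rownames(a) <- colnames(a) <- sprintf("g%02d", 1:n)
  a["g01", -1] <- a[-1, "g01"] <- 0.95    # clear max-degree gene
  labels <- stats::setNames(rep(1L, n), rownames(a))
  h <- hub_genes(labels, a, fraction = 0.10)
  expect_equal(sum(h$hub), 2L)             # ceiling(0.1 * 20)
  expect_true(h$hub[h$gene == "g01"])
  # module of 10 with fraction 0.10: exactly one hub
  lab10 <- stats::setNames(c(rep(1L, 10), rep(0L, 10)), rownames(a))
  h10 <- hub_genes(lab10, a, fraction = 0.10)
  expect_equal(sum(h10$hub), 1L)
  # ties break deterministically by gene id
  aeq <- matrix(0.5, 4, 4); diag(aeq) <- 1
  rownames(aeq) <- colnames(aeq) <- c("d", "c", "b", "a")
  he <- hub_genes(stats::setNames(rep(1L, 4), rownames(aeq)), aeq, 0.25)
  expect_equal(he$gene[he$hub], "a")
})

test_that("coexpression_network runs the full stack on simulated input", {
  cfg <- simulation_config(seed = 41, n_genes = 150,
                           modules = list(count = 2, size = 35,
                                          within_cor = 0.8, hub_cor = 1))
  sim <- simulate_expression(simulate_annotation(cfg))
  res <- coexpression_network(sim$expr_genes, power = 12,
                              min_module_size = 15)
  expect_s3_class(res, "coexpression_result")
  expect_equal(res$beta, 12)
  truth <- sim$truth$modules
  tl <- truth$module[match(names(res$labels), truth$gene_id)]
  expect_gte(mclust::adjustedRandIndex(res$labels, tl), 0.85)
  expect_true(all(res$hubs$gene[res$hubs$hub] %in% names(res$labels)))
})
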