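test_that("CYT score is the geometric mean of the effector genes", {
  expr <- rbind(GZMA = c(s1 = 4, s2 = 1, s3 = 0),
                PRF1 = c(s1 = 4, s2 = 100, s3 = 50))
  expect_equal(unname(cyt_score(expr[, 1:2])), c(4, 10))
  expect_error(cyt_score(expr), class = "tcaflux_domain_error")
  expect_equal(unname(cyt_score(expr, pseudocount = 0.01)[3]),
               sqrt(0.01 * 50.01))
  expect_error(cyt_score(expr[1, , drop = FALSE]), "PRF1",
               class = "tcaflux_lookup_error")

  # scale equivariance
  set.seed(2)
  e2 <- rbind(GZMA = runif(10, 1, 5), PRF1 = runif(10, 1, 5))
  colnames(e2) <- paste0("s", 1:10)
  expect_equal(cyt_score(e2 * 3), 3 * cyt_score(e2))
})

test_that("correlation screen classifies planted genes and nulls", {
  co <- planted_cohort()
  cv <- setNames(co$covariate$leukocyte_fraction, co$covariate$sample_id)
  scr <- correlate_genes(co$expr, cv)
  cls <- setNames(scr$class, scr$gene)
  expect_equal(unname(cls["SLC7A7"]), "positive")
  expect_equal(unname(cls["SLC7A5"]), "negative")
  # deterministic |r|-descending order
  expect_true(all(diff(abs(scr$r)) <= 1e-12))

  # permuted covariate: null screen mostly non-significant
  set.seed(31)
  perm <- setNames(sample(cv), names(cv))
  scr0 <- correlate_genes(co$expr, perm)
  expect_gte(mean(scr0$class == "ns"), 0.9)

  expect_equal(nrow(correlate_genes(co$expr, cv, gene_set = character())), 0L)
  bad <- cv
  names(bad)[1] <- "NOT_A_SAMPLE"
  expect_error(correlate_genes(co$expr, bad),
               class = "tcaflux_alignment_error")
})

test_that("DE gating applies BH then fold-change thresholds", {
  one <- classify_de(data.frame(gene = "A", log2fc = 3, pvalue = 1e-6))
  expect_equal(one$class, "up")

  # strong p but modest fold change fails the fold-change gate
  weak <- classify_de(data.frame(gene = "A", log2fc = 1.5, pvalue = 1e-9))
  expect_equal(weak$class, "not_significant")

  ten <- data.frame(gene = paste0("G", 1:10),
                    log2fc = rep(c(3, -3), 5), pvalue = rep(0.001, 10))
  res <- classify_de(ten)
  expect_equal(unname(attr(res, "counts")[c("up", "down")]), c(5L, 5L))

  # class counts invariant to row order
  perm <- ten[sample(10), ]
  expect_equal(attr(classify_de(perm), "counts"), attr(res, "counts"))

  expect_error(classify_de(data.frame(gene = c("A", "a"), log2fc = 1:2,
                                      pvalue = c(0.1, 0.2))),
               class = "tcaflux_validation_error")
})

test_that("Z-score/p conversions anchor at the prognostic threshold", {
  expect_equal(z_to_p(0), 0.5)
  expect_equal(signif(z_to_p(3.09), 1), 0.001)
  expect_equal(p_to_z(0.001), 3.09, tolerance = 1e-3)
  for (x in c(-2, 0, 1.5))
    expect_equal(p_to_z(z_to_p(x)), x, tolerance = 1e-10)
  z <- seq(-4, 4, 0.5)
  expect_true(all(diff(z_to_p(z)) < 0))
  expect_error(p_to_z(0), class = "tcaflux_domain_error")
  expect_error(p_to_z(1), class = "tcaflux_domain_error")
})

test_that("prognostic classification partitions by the Z cut", {
  zt <- data.frame(gene = c("d", "b", "n1", "n2"),
                   zscore = c(3.2, -3.2, 0, 3.05))
  res <- classify_prognostic(zt)
  expect_equal(res$class, c("detrimental", "beneficial", "neutral",
                            "neutral"))
  expect_equal(sum(attr(res, "counts")), 4L)
  # partition is disjoint and exhaustive on random scores
  set.seed(12)
  rnd <- data.frame(gene = paste0("g", 1:200), zscore = rnorm(200, 0, 3))
  rc <- classify_prognostic(rnd)
  expect_true(all(rc$class %in% c("detrimental", "beneficial", "neutral")))
  expect_equal(sum(attr(rc, "counts")), 200L)
  expect_error(classify_prognostic(data.frame(gene = "a", zscore = "x")),
               class = "tcaflux_validation_error")
})

test_that("PCA variance fractions behave on structured and null data", {
  rank1 <- outer(1:6, seq(0.5, 2, length.out = 5))
  dimnames(rank1) <- list(paste0("g", 1:6), paste0("s", 1:5))
  v <- pca_variance_explained(rank1)
  expect_equal(v[1], 1, tolerance = 1e-9)

  set.seed(19)
  k <- 50
  iso <- matrix(runif(k * 1000), k, 1000,
                dimnames = list(paste0("g", 1:k), paste0("s", 1:1000)))
  v2 <- pca_variance_explained(iso)
  expect_equal(sum(v2), 1, tolerance = 1e-9)
  expect_lt(v2[1], 2 / k)

  expect_error(pca_variance_explained(rank1[, 1, drop = FALSE]),
               class = "tcaflux_data_error")
})

test_that("row clustering standardizes, merges duplicates, drops constants", {
  set.seed(23)
  block_a <- matrix(rnorm(5 * 10, mean = rep(c(2, -2), each = 5)), 5, 10)
  block_b <- -block_a + matrix(rnorm(50, 0, 0.1), 5, 10)
  mat <- rbind(block_a, block_b)
  rownames(mat) <- c(paste0("a", 1:5), paste0("b", 1:5))
  res <- cluster_rows(mat)
  expect_true(all(abs(rowMeans(res$zmat)) < 1e-12))
  expect_true(all(abs(apply(res$zmat, 1, sd) - 1) < 1e-12))
  # the two anti-correlated blocks come out contiguous in leaf order
  grp <- substr(res$order, 1, 1)
  expect_equal(length(rle(grp)$values), 2L)

  dup <- rbind(x = c(1, 2, 3, 4), y = c(1, 2, 3, 4), z = c(4, 1, 0, 9))
  rdup <- cluster_rows(dup)
  expect_equal(rdup$hclust$height[1], 0)
  first_pair <- rownames(dup)[abs(rdup$hclust$merge[1, ])]
  expect_setequal(first_pair, c("x", "y"))

  withcst <- rbind(dup, w = c(5, 5, 5, 5))
  expect_warning(rc <- cluster_rows(withcst), "constant")
  expect_equal(rc$dropped, "w")
  expect_error(cluster_rows(rbind(a = rep(1, 4), b = rep(2, 4))),
               class = "tcaflux_data_error")
})
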