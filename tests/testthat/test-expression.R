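test_that("size factors reproduce the hand-checked 2x2 case", {
  m <- matrix(c(10, 100, 20, 200), ncol = 2)
  sf <- computeSizeFactors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-10)
  expect_equal(unname(sf), c(0.7071, 1.4142), tolerance = 1e-4)
})

test_that("size factors scale with per-sample depth", {
  set.seed(1)
  m <- matrix(rpois(300, 50) + 1, ncol = 3)
  sf <- computeSizeFactors(m)
  m2 <- sweep(m, 2, c(1, 2, 4), "*")
  sf2 <- computeSizeFactors(m2)
  expect_equal(sf2 / sf, c(1, 2, 4) / prod(c(1, 2, 4))^(1 / 3),
    tolerance = 1e-10
  )
  expect_error(computeSizeFactors(matrix(c(0, 1, 1, 0), 2)), "no gene")
})

test_that("bhAdjust matches stats and the step-up oracle", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(2)
  for (i in 1:10) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    expect_equal(bhAdjust(p), bhOracle(p))
  }
  expect_equal(bhAdjust(0.5), 0.5)
  expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bhAdjust(numeric()), "empty")
})

test_that("differentialExpression reproduces a hand-computed fold change", {
  ## ten stable genes pin the size factors at 1; one gene moves 10 -> 40
  counts <- rbind(
    matrix(100, nrow = 10, ncol = 4),
    g_de = c(10, 10, 40, 40)
  )
  rownames(counts)[1:10] <- paste0("stable", 1:10)
  de <- differentialExpression(
    counts, c("c", "c", "t", "t"), "c", "t"
  )
  expect_equal(unname(S4Vectors::metadata(de)$size_factors), rep(1, 4))
  row <- de[de$gene_id == "g_de", ]
  expect_equal(row$log2fc, log2(40.5 / 10.5), tolerance = 1e-12)
  expect_equal(row$base_mean, mean(c(10, 10, 40, 40)))
  ## identical groups: p-value 1, no flag
  expect_true(all(de$pvalue[de$gene_id != "g_de"] == 1))
  expect_false(any(de$flag_de[de$gene_id != "g_de"]))
})

test_that("swapping the contrast negates the fold changes", {
  set.seed(3)
  counts <- matrix(rpois(600, 60) + 1, ncol = 6,
    dimnames = list(paste0("g", 1:100), paste0("s", 1:6))
  )
  cond <- rep(c("a", "b"), each = 3)
  ab <- differentialExpression(counts, cond, "a", "b")
  ba <- differentialExpression(counts, cond, "b", "a")
  expect_equal(ab$log2fc, -ba$log2fc)
  expect_equal(ab$pvalue, ba$pvalue)
  expect_equal(ab$padj, ba$padj)
})

test_that("the Welch test agrees with stats::t.test gene by gene", {
  set.seed(4)
  counts <- matrix(rpois(120, 80) + 1, ncol = 6,
    dimnames = list(paste0("g", 1:20), paste0("s", 1:6))
  )
  cond <- rep(c("a", "b"), each = 3)
  de <- differentialExpression(counts, cond, "a", "b")
  sf <- computeSizeFactors(counts)
  l <- log2(sweep(counts, 2, sf, "/") + 0.5)
  for (i in 1:20) {
    tt <- t.test(l[i, 4:6], l[i, 1:3])
    expect_equal(de$pvalue[i], tt$p.value, tolerance = 1e-12)
    expect_equal(de$log2fc[i], unname(diff(rev(tt$estimate))),
      tolerance = 1e-12
    )
  }
})

test_that("group sizes below two replicates are rejected", {
  counts <- matrix(10, nrow = 3, ncol = 3,
    dimnames = list(paste0("g", 1:3), paste0("s", 1:3))
  )
  expect_error(
    differentialExpression(counts, c("a", "a", "b"), "a", "b"),
    "at least 2 replicates"
  )
})

test_that("external DE tables are imported with flexible column names", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(
    data.frame(
      gene = c("g1", "g2"), baseMean = c(100, 30),
      log2FoldChange = c(2.5, 0.2), pvalue = c(1e-6, 0.4),
      padj = c(1e-5, 0.6)
    ),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  de <- importExternalDE(path)
  expect_equal(de$gene_id, c("g1", "g2"))
  expect_equal(de$log2fc, c(2.5, 0.2))
  expect_equal(de$flag_de, c(TRUE, FALSE))
})

test_that("genesetSummary pairs genes and flags degenerate contrasts", {
  a <- fakeDE(paste0("g", 1:5), log2fc = c(1, 2, 3, 4, 5))
  b <- fakeDE(paste0("g", 1:5), log2fc = c(1, 2, 3, 4, 5) + 2)
  gs <- genesetSummary(list(A = a, B = b), paste0("g", 1:5))
  expect_equal(nrow(gs$values), 10L)
  expect_equal(gs$tests$mean_difference, 2)
  expect_true(gs$tests$degenerate) # constant difference, zero variance
  expect_true(is.na(gs$tests$p_value))
  b2 <- fakeDE(paste0("g", 1:5), log2fc = c(2, 2.5, 4, 6, 6.5))
  gs2 <- genesetSummary(list(A = a, B = b2), paste0("g", 1:5))
  expect_false(gs2$tests$degenerate)
  d <- b2$log2fc - a$log2fc
  expect_equal(gs2$tests$p_value, t.test(d)$p.value)
  expect_error(
    genesetSummary(list(A = a, B = b), c("g1", "g2")),
    "fewer than 3"
  )
})

test_that("correlateChanges recovers exact linear relations", {
  genes <- paste0("g", 1:20)
  set.seed(6)
  x <- rnorm(20, 0, 2)
  a <- fakeDE(genes, log2fc = x, flag_de = abs(x) > 1)
  b <- fakeDE(genes, log2fc = 2 * x + 1, flag_de = abs(x) > 1)
  res <- correlateChanges(a, b, selection = "de_in_A")
  expect_equal(res$r, 1)
  expect_equal(res$r_squared, 1)
  expect_equal(res$n, sum(abs(x) > 1))
  bneg <- fakeDE(genes, log2fc = -x, flag_de = abs(x) > 1)
  expect_equal(correlateChanges(a, bneg, "de_in_either")$r, -1)
  ## independent changes: weak correlation on a large null set
  set.seed(7)
  genes2 <- paste0("h", 1:2000)
  an <- fakeDE(genes2, log2fc = rnorm(2000), flag_de = TRUE)
  bn <- fakeDE(genes2, log2fc = rnorm(2000), flag_de = TRUE)
  expect_lt(abs(correlateChanges(an, bn, "de_in_A")$r), 0.1)
  expect_error(
    correlateChanges(a[1:2, ], b[1:2, ], "de_in_A"),
    "fewer than 3"
  )
})
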