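test_that("aggregate UTR:ORF ratios are sums over passing genes", {
  utr3 <- rbind(g1 = c(5), g2 = c(15), g3 = c(100))
  cds <- rbind(g1 = c(100), g2 = c(300), g3 = c(0.5))
  colnames(utr3) <- colnames(cds) <- "s1"
  rpm <- makeRegionMatrix(utr5 = cds * 0, cds = cds, utr3 = utr3)
  agg <- utrOrfRatio(rpm, "utr3", "aggregate", minCdsRpm = 1)
  ## g3 fails the 1-rpm CDS filter; ratio = (5 + 15) / (100 + 300)
  expect_equal(agg$ratio, 0.05)
  expect_equal(agg$genes_used, 2L)
  per <- utrOrfRatio(rpm, "utr3", "per_gene", minCdsRpm = 1)
  expect_equal(setNames(per$ratio, per$gene_id), c(g1 = 0.05, g2 = 0.05))
})

test_that("the 5'UTR ratio reproduces a hand sum", {
  utr5 <- rbind(g1 = c(20))
  cds <- rbind(g1 = c(200))
  colnames(utr5) <- colnames(cds) <- "s1"
  rpm <- makeRegionMatrix(utr5 = utr5, cds = cds, utr3 = cds * 0)
  res <- utrOrfRatio(rpm, "utr5", "aggregate")
  expect_equal(res$ratio, 0.1)
  expect_equal(res$which, "utr5")
})

test_that("ratios are invariant to uniform rescaling of a sample", {
  set.seed(11)
  utr3 <- matrix(runif(12, 0, 10), 6,
    dimnames = list(paste0("g", 1:6), c("a", "b"))
  )
  cds <- matrix(runif(12, 2, 50), 6,
    dimnames = list(paste0("g", 1:6), c("a", "b"))
  )
  r1 <- utrOrfRatio(makeRegionMatrix(cds * 0, cds, utr3), "utr3")
  r2 <- utrOrfRatio(makeRegionMatrix(cds * 0, cds * 5, utr3 * 5), "utr3")
  expect_equal(r2$ratio, r1$ratio)
})

test_that("per-gene scope requires a positive CDS filter", {
  cds <- rbind(g1 = 1)
  colnames(cds) <- "s1"
  rpm <- makeRegionMatrix(cds * 0, cds, cds * 0)
  expect_error(utrOrfRatio(rpm, "utr3", "per_gene", minCdsRpm = 0), "> 0")
  expect_error(
    utrOrfRatio(
      makeRegionMatrix(cds * 0, cds, cds * 0, units = "counts"), "utr3"
    ),
    "rpm"
  )
})

test_that("uniform occupancy gives a flat metagene of height 1", {
  ts <- tinyTxSet()
  tr <- makeTrack(data.frame(
    transcript_id = "tx1", pos = 0:299, count = 3
  ))
  prof <- metageneProfile(tr, ts,
    anchor = "stop_codon", window = c(30L, 40L),
    minCdsDensity = 1
  )
  expect_equal(prof$offset, -30:40)
  expect_equal(prof$mean_occupancy, rep(1, 71))
  expect_equal(unique(prof$n_genes), 1L)
})

test_that("metagene anchors sit on the start and stop codons", {
  ts <- tinyTxSet()
  ## single P-site spikes at tx1's start codon and stop codon
  tr <- makeTrack(data.frame(
    transcript_id = "tx1", pos = c(100L, 247L), count = c(60, 60)
  ))
  start_prof <- metageneProfile(tr, ts,
    anchor = "start_codon",
    window = c(20L, 20L), minCdsDensity = 0.5
  )
  expect_equal(
    start_prof$offset[start_prof$mean_occupancy > 0], 0L
  )
  stop_prof <- metageneProfile(tr, ts,
    anchor = "stop_codon",
    window = c(20L, 20L), minCdsDensity = 0.5
  )
  ## stop codon occupies cds_end - 3 = 247
  expect_equal(stop_prof$offset[stop_prof$mean_occupancy > 0], 0L)
})

test_that("genes enter the metagene with equal weight regardless of depth", {
  ts <- TranscriptomeSet(data.frame(
    transcript_id = c("tx1", "tx2"), gene_id = c("g1", "g2"),
    length = 300L, cds_start = 100L, cds_end = 250L
  ))
  base <- data.frame(transcript_id = "tx1", pos = 80:260, count = 2)
  deep <- transform(base, transcript_id = "tx2", count = 20)
  one <- metageneProfile(makeTrack(base), ts,
    anchor = "start_codon",
    window = c(10L, 10L), minCdsDensity = 0.5
  )
  both <- metageneProfile(makeTrack(rbind(base, deep)), ts,
    anchor = "start_codon", window = c(10L, 10L), minCdsDensity = 0.5
  )
  ## tx2 is 10x deeper but identically shaped: the average is unchanged
  expect_equal(both$mean_occupancy, one$mean_occupancy)
  expect_equal(unique(both$n_genes), 2L)
})

test_that("an empty metagene is an error, not a silent zero", {
  ts <- tinyTxSet()
  tr <- makeTrack(data.frame(transcript_id = "tx1", pos = 1L, count = 1))
  expect_error(
    metageneProfile(tr, ts, minCdsDensity = 10),
    "empty metagene"
  )
})
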