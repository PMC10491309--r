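## Transcript with a single AUG candidate in an otherwise A-only 5'UTR.
peakTxSet <- function() {
  s <- strsplit(paste(rep("A", 150), collapse = ""), "")[[1]]
  s[21:23] <- c("A", "T", "G") # candidate start at position 20 (0-based)
  TranscriptomeSet(
    data.frame(
      transcript_id = "tx1", gene_id = "g1", length = 150L,
      cds_start = 60L, cds_end = 120L
    ),
    sequences = c(tx1 = paste(s, collapse = ""))
  )
}

test_that("flat 5'UTR coverage scores a candidate near 1 and is not called", {
  ts <- peakTxSet()
  tr <- makeTrack(data.frame(
    transcript_id = "tx1", pos = 0:59, count = 2
  ))
  res <- detectUorfPeaks(tr, ts)
  expect_equal(nrow(res), 1L)
  expect_equal(res$start, 20L)
  expect_equal(res$peak_score, 1)
  expect_false(res$called)
})

test_that("a concentrated start-codon peak is called", {
  ts <- peakTxSet()
  tr <- makeTrack(data.frame(
    transcript_id = "tx1", pos = c(20L, 5L, 40L), count = c(30, 1, 1)
  ))
  res <- detectUorfPeaks(tr, ts)
  ## background: 2 reads over the 51 non-window 5'UTR positions
  expect_equal(res$local_background, 2 / 51)
  expect_equal(res$start_peak_count, 30)
  expect_equal(res$peak_score, 30 / (2 / 51 * 9))
  expect_true(res$called)
  ## with an empty background the score is infinite
  tr2 <- makeTrack(data.frame(transcript_id = "tx1", pos = 20L, count = 30))
  res2 <- detectUorfPeaks(tr2, ts)
  expect_true(is.infinite(res2$peak_score))
  expect_true(res2$called)
})

test_that("transcripts without reads or without candidates are absent", {
  ts <- peakTxSet()
  tr <- makeTrack(data.frame(
    transcript_id = character(), pos = integer(), count = numeric()
  ))
  expect_equal(nrow(detectUorfPeaks(tr, ts)), 0L)
})

test_that("detectUorfPeaks matches a direct reimplementation", {
  set.seed(10)
  seqs <- vapply(1:4, function(i) randomTx(60, 90, 30, seed = 100 + i), "")
  names(seqs) <- paste0("tx", 1:4)
  ts <- TranscriptomeSet(
    data.frame(
      transcript_id = names(seqs), gene_id = paste0("g", 1:4),
      length = 180L, cds_start = 60L, cds_end = 150L
    ),
    sequences = seqs
  )
  cnt <- data.frame(
    transcript_id = rep(names(seqs), each = 40),
    pos = sample(0:179, 160, replace = TRUE),
    count = sample(1:6, 160, replace = TRUE)
  )
  cnt <- aggregate(count ~ transcript_id + pos, cnt, sum)
  tr <- makeTrack(cnt)
  res <- detectUorfPeaks(tr, ts, scoreThreshold = 3, minReads = 5)
  for (id in unique(res$transcript_id)) {
    v <- trackVector(tr, ts, id)
    cands <- scanOrfs(seqs[[id]])
    cands <- cands[cands$start < 60, , drop = FALSE]
    lo <- pmax(cands$start - 3L, 0L)
    hi <- pmin(cands$start + 5L, 59L)
    inwin <- logical(60)
    for (k in seq_len(nrow(cands))) inwin[(lo[k] + 1):(hi[k] + 1)] <- TRUE
    bg <- mean(v[1:60][!inwin])
    for (k in seq_len(nrow(cands))) {
      peak <- sum(v[(lo[k] + 1):(hi[k] + 1)])
      want <- if (bg > 0) peak / (bg * (hi[k] - lo[k] + 1)) else {
        if (peak > 0) Inf else 0
      }
      row <- res[res$transcript_id == id & res$start == cands$start[k], ]
      expect_equal(row$peak_score, want, info = paste(id, cands$start[k]))
      expect_equal(row$called, want >= 3 && peak >= 5)
    }
  }
})

test_that("utr5MainShift reproduces a hand-built ratio change", {
  ## two genes, 2 + 2 samples; gene g1 drops its 5'UTR:CDS ratio 4-fold
  utr5 <- rbind(
    g1 = c(40, 40, 10, 10),
    g2 = c(20, 20, 20, 20)
  )
  cds <- rbind(
    g1 = c(100, 100, 100, 100),
    g2 = c(100, 100, 100, 100)
  )
  colnames(utr5) <- colnames(cds) <- c("c1", "c2", "t1", "t2")
  rpm <- makeRegionMatrix(utr5, cds, utr3 = cds * 0)
  res <- utr5MainShift(rpm, c("c1", "c2"), c("t1", "t2"))
  g1 <- res[res$gene_id == "g1", ]
  expect_equal(g1$mean_ratio_control, 0.4)
  expect_equal(g1$mean_ratio_treated, 0.1)
  expect_equal(g1$log2_shift, -2)
  expect_equal(res$log2_shift[res$gene_id == "g2"], 0)
  ## swapping the conditions negates the shift exactly
  swapped <- utr5MainShift(rpm, c("t1", "t2"), c("c1", "c2"))
  expect_equal(swapped$log2_shift, -res$log2_shift)
})

test_that("genes with zero CDS signal are excluded, not divided by zero", {
  utr5 <- rbind(g1 = c(5, 5, 5, 5), g2 = c(5, 5, 5, 5))
  cds <- rbind(g1 = c(10, 10, 10, 10), g2 = c(10, 0, 10, 10))
  colnames(utr5) <- colnames(cds) <- c("c1", "c2", "t1", "t2")
  rpm <- makeRegionMatrix(utr5, cds, utr3 = cds * 0)
  res <- utr5MainShift(rpm, c("c1", "c2"), c("t1", "t2"))
  expect_equal(res$gene_id, "g1")
  expect_equal(attr(res, "excluded"), "g2")
})

test_that("utr5MainShift insists on rpm units and known samples", {
  utr5 <- rbind(g1 = c(1, 1, 1, 1))
  cds <- rbind(g1 = c(2, 2, 2, 2))
  colnames(utr5) <- colnames(cds) <- c("c1", "c2", "t1", "t2")
  counts <- makeRegionMatrix(utr5, cds, utr3 = cds * 0, units = "counts")
  expect_error(
    utr5MainShift(counts, c("c1", "c2"), c("t1", "t2")),
    "rpm"
  )
  rpm <- makeRegionMatrix(utr5, cds, utr3 = cds * 0)
  expect_error(utr5MainShift(rpm, c("c1", "zz"), c("t1", "t2")), "unknown")
})
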