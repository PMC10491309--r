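test_that("TranscriptomeSet validates CDS intervals and uORFs", {
  expect_error(
    TranscriptomeSet(data.frame(
      transcript_id = "tx1", gene_id = "g1",
      length = 100L, cds_start = 50L, cds_end = 40L
    )),
    "invalid CDS"
  )
  expect_error(
    TranscriptomeSet(
      data.frame(
        transcript_id = "tx1", gene_id = "g1",
        length = 300L, cds_start = 100L, cds_end = 250L
      ),
      uorfs = data.frame(
        transcript_id = "tx1", start = 10L, end = 20L,
        start_codon = "AUG"
      )
    ),
    "multiple of 3"
  )
  expect_error(
    TranscriptomeSet(data.frame(
      transcript_id = c("a", "b"), gene_id = c("g", "g"),
      length = c(100L, 100L), cds_start = c(0L, 0L), cds_end = c(99L, 99L)
    )),
    "single-isoform"
  )
})

test_that("partitionRegions tiles every transcript exactly", {
  ts <- tinyTxSet()
  pr <- partitionRegions(ts)
  tx <- as.data.frame(transcripts(ts))
  for (id in tx$transcript_id) {
    sub <- pr[pr$transcript_id == id, ]
    expect_equal(sub$region, c("utr5", "cds", "utr3"))
    expect_equal(sub$start[1], 0L)
    expect_equal(sub$end[3], tx$length[tx$transcript_id == id])
    ## contiguity: each region starts where the previous ended
    expect_equal(sub$start[-1], sub$end[-3])
    expect_equal(sum(sub$end - sub$start), tx$length[tx$transcript_id == id])
  }
})

test_that("transcript table round-trips through write and load", {
  ts <- tinyTxSet()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeTranscriptTable(ts, path)
  ts2 <- loadAnnotation(path, format = "transcript_table")
  expect_equal(
    as.data.frame(transcripts(ts2)),
    as.data.frame(transcripts(ts))
  )
  expect_equal(as.data.frame(uorfs(ts2)), as.data.frame(uorfs(ts)))
})

test_that("transcript table parse errors report the offending line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "transcript_id\tgene_id\tlength\tcds_start\tcds_end",
    "tx1\tg1\t300\t100\t250",
    "tx2\tg2\toops\t30\t180"
  ), path)
  expect_error(loadAnnotation(path), "line 3")
})

test_that("GTF projection handles both strands and isoform preference", {
  gtf <- c(
    ## plus strand, two exons; CDS split across them
    "chr1\ttest\texon\t101\t200\t.\t+\t.\tgene_id \"gA\"; transcript_id \"tA\";",
    "chr1\ttest\texon\t301\t400\t.\t+\t.\tgene_id \"gA\"; transcript_id \"tA\";",
    "chr1\ttest\tCDS\t151\t200\t.\t+\t0\tgene_id \"gA\"; transcript_id \"tA\";",
    "chr1\ttest\tCDS\t301\t360\t.\t+\t0\tgene_id \"gA\"; transcript_id \"tA\";",
    ## minus strand, two exons
    "chr1\ttest\texon\t1001\t1100\t.\t-\t.\tgene_id \"gB\"; transcript_id \"tB\";",
    "chr1\ttest\texon\t1201\t1300\t.\t-\t.\tgene_id \"gB\"; transcript_id \"tB\";",
    "chr1\ttest\tCDS\t1051\t1080\t.\t-\t0\tgene_id \"gB\"; transcript_id \"tB\";",
    "chr1\ttest\tCDS\t1251\t1260\t.\t-\t0\tgene_id \"gB\"; transcript_id \"tB\";",
    ## two isoforms of gC: the MANE-tagged one has the shorter CDS
    "chr2\ttest\texon\t1\t300\t.\t+\t.\tgene_id \"gC\"; transcript_id \"tC1\"; tag \"MANE_Select\";",
    "chr2\ttest\tCDS\t31\t90\t.\t+\t0\tgene_id \"gC\"; transcript_id \"tC1\"; tag \"MANE_Select\";",
    "chr2\ttest\texon\t1\t300\t.\t+\t.\tgene_id \"gC\"; transcript_id \"tC2\";",
    "chr2\ttest\tCDS\t31\t240\t.\t+\t0\tgene_id \"gC\"; transcript_id \"tC2\";"
  )
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(gtf, path)
  ts <- loadAnnotation(path, format = "gtf")
  tx <- as.data.frame(transcripts(ts))
  a <- tx[tx$transcript_id == "tA", ]
  expect_equal(a$length, 200L)
  expect_equal(a$cds_start, 50L)
  expect_equal(a$cds_end, 160L)
  b <- tx[tx$transcript_id == "tB", ]
  expect_equal(b$length, 200L)
  expect_equal(b$cds_start, 40L)
  expect_equal(b$cds_end, 150L)
  ## single-isoform reduction prefers the MANE tag over CDS length
  expect_true("tC1" %in% tx$transcript_id)
  expect_false("tC2" %in% tx$transcript_id)
})

test_that("sequences attached at load must match annotated lengths", {
  ts <- tinyTxSet()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeTranscriptTable(ts, path)
  seqs <- Biostrings::DNAStringSet(c(
    tx1 = paste(rep("A", 300), collapse = ""),
    tx2 = paste(rep("A", 150), collapse = "") # wrong length
  ))
  expect_error(
    loadAnnotation(path, sequences = seqs),
    "widths disagree"
  )
})
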