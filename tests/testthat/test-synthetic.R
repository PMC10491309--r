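test_that("findCleavageSites places cuts immediately 3' of motifs", {
  rl <- cleavageModel("rnasel_like")
  ## UA at 0-1 cuts at 2; UU at 2-3 cuts at 4
  s <- findCleavageSites("UAUU", rl)
  expect_equal(s$pos, c(2L, 4L))
  expect_equal(sort(s$motif), c("TA", "TT"))
  ## overlapping UU matches both count
  expect_equal(findCleavageSites("UUU", rl)$pos, c(2L, 3L))
  ## pyrimidine model: single-base motifs C and U
  ra <- cleavageModel("rnasea_like")
  s <- findCleavageSites("ACAU", ra)
  expect_equal(s$pos, c(2L, 4L))
  ## no motif, no sites
  expect_equal(nrow(findCleavageSites("AAAA", rl)), 0L)
  expect_equal(nrow(findCleavageSites("GGG", rl)), 0L)
})

test_that("custom motif weights are normalised to the strongest motif", {
  m <- cleavageModel("custom", motifWeights = c(TT = 2, TA = 1))
  s <- findCleavageSites("UUAUU", m)
  expect_equal(s$weight[s$motif == "TT"], rep(1, sum(s$motif == "TT")))
  expect_equal(s$weight[s$motif == "TA"], rep(0.5, sum(s$motif == "TA")))
})

## A transcriptome with one transcript of known site count: each AATTGG
## block carries exactly one UU site.
blockTxSet <- function(blocks = 10L) {
  s <- strrep("AATTGG", blocks)
  TranscriptomeSet(
    data.frame(
      transcript_id = "tx1", gene_id = "g1",
      length = nchar(s), cds_start = 0L, cds_end = nchar(s)
    ),
    sequences = c(tx1 = s)
  )
}

test_that("fragmentation conserves nucleotide mass exactly before decay", {
  ts <- blockTxSet(10L)
  set.seed(42)
  pool <- simulateFragmentation(ts, c(tx1 = 500), cleavageModel("rnasel_like",
    perSiteProbability = 0.1
  ), survival = 0.5)
  mass <- poolMass(pool, ts, predecay = TRUE)
  expect_identical(unname(mass["tx1"]), 500 * 60)
  expect_true(nrow(pool@fragments) > 0)
  expect_true(all(pool@fragments$copies <= pool@fragments$copies_predecay))
})

test_that("intact fraction matches the analytic expectation", {
  ts <- blockTxSet(10L) # exactly 10 equal-weight sites
  n <- 20000
  p <- 0.05
  set.seed(7)
  pool <- simulateFragmentation(ts, c(tx1 = n),
    cleavageModel("rnasel_like", perSiteProbability = p),
    survival = 1
  )
  q <- (1 - p)^10
  se <- sqrt(q * (1 - q) / n)
  expect_lt(abs(pool@intact[["tx1"]] / n - q), 3 * se)
  ## survival 1: no decay
  expect_identical(pool@fragments$copies, pool@fragments$copies_predecay)
})

test_that("zero cut probability and resistance leave every copy intact", {
  ts <- blockTxSet(5L)
  pool <- simulateFragmentation(ts, c(tx1 = 100),
    cleavageModel("rnasel_like", perSiteProbability = 0))
  expect_equal(pool@intact[["tx1"]], 100)
  expect_equal(nrow(pool@fragments), 0L)
  set.seed(1)
  pool <- simulateFragmentation(ts, c(tx1 = 100),
    cleavageModel("rnasel_like", perSiteProbability = 0.5),
    resistant = "tx1"
  )
  expect_equal(pool@intact[["tx1"]], 100)
  expect_equal(nrow(pool@fragments), 0L)
})

test_that("a certain cut splits copies into the two expected fragments", {
  ## one UU site: cut at pos 4 of an 8-nt transcript, p = 1
  ts <- TranscriptomeSet(
    data.frame(
      transcript_id = "tx1", gene_id = "g1", length = 8L,
      cds_start = 0L, cds_end = 8L
    ),
    sequences = c(tx1 = "AATTGGGG")
  )
  set.seed(1)
  pool <- simulateFragmentation(ts, c(tx1 = 10),
    cleavageModel("rnasel_like", perSiteProbability = 1))
  expect_equal(pool@intact[["tx1"]], 0)
  fr <- pool@fragments[order(pool@fragments$start), ]
  expect_equal(fr$start, c(0L, 4L))
  expect_equal(fr$end, c(4L, 8L))
  expect_equal(fr$copies_predecay, c(10L, 10L))
})

test_that("RNA-seq counts follow the CDS-mass multinomial expectation", {
  ts <- TranscriptomeSet(data.frame(
    transcript_id = c("tx1", "tx2"), gene_id = c("g1", "g2"),
    length = c(200L, 100L), cds_start = c(0L, 0L), cds_end = c(150L, 50L)
  ))
  ## intact mass: 10 x 150 = 1500 vs 30 x 50 = 1500 -> equal expectation
  pool <- methods::new("FragmentPool",
    intact = c(tx1 = 10, tx2 = 30),
    fragments = data.frame(
      transcript_id = character(), start = integer(), end = integer(),
      copies_predecay = integer(), copies = integer()
    ),
    survival = 1
  )
  set.seed(3)
  depth <- 1e5
  counts <- simulateRnaseq(pool, ts, depth = depth)
  se <- sqrt(0.5 * 0.5 / depth)
  expect_lt(abs(counts[["g1"]] / depth - 0.5), 4 * se)
  expect_equal(sum(counts), depth)
})

test_that("the generated experiment is deterministic under a seed", {
  cfg <- simulationConfig(
    nGenes = 20, footprintDepth = 5e3, rnaseqDepth = 5e3, seed = 11
  )
  e1 <- generateExperiment(cfg)
  e2 <- generateExperiment(cfg)
  expect_identical(e1$footprints, e2$footprints)
  expect_identical(e1$rnaseq, e2$rnaseq)
  expect_identical(
    as.data.frame(truthGenes(e1$truth)),
    as.data.frame(truthGenes(e2$truth))
  )
})

test_that("written experiment bundles are byte-identical across runs", {
  cfg <- simulationConfig(
    nGenes = 15, footprintDepth = 2e3, rnaseqDepth = 2e3, seed = 4
  )
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generateExperiment(cfg, outDir = d1)
  generateExperiment(cfg, outDir = d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in f1) {
    expect_identical(
      readLines(file.path(d1, f)), readLines(file.path(d2, f)),
      info = f
    )
  }
})

test_that("non-control abundances reflect loss and induction in truth", {
  cfg <- simulationConfig(
    nGenes = 200, footprintDepth = 1e3, rnaseqDepth = 1e3,
    globalLossFraction = 0.9, inducedGeneFraction = 0.1,
    inductionFactor = 20, seed = 2
  )
  exp <- generateExperiment(cfg)
  g <- as.data.frame(truthGenes(exp$truth))
  ab <- exp$truth@abundance
  expect_equal(
    ab[, "treated"],
    round(g$baseline_abundance * 0.1 * g$induction_mult),
    ignore_attr = TRUE
  )
  expect_equal(ab[, "control"], round(g$baseline_abundance),
    ignore_attr = TRUE
  )
  ## bulk absolute abundance drops despite induction of a gene subset
  expect_lt(sum(ab[, "treated"]), sum(ab[, "control"]))
})

test_that("configuration invariants are enforced", {
  expect_error(simulationConfig(nGenes = 5), "nGenes")
  expect_error(simulationConfig(globalLossFraction = 1), "globalLossFraction")
  expect_error(simulationConfig(frameWeights = c(0.5, 0.5)), "frameWeights")
  expect_error(
    simulationConfig(pFragmentReinitiation = 1.2),
    "pFragmentReinitiation"
  )
  expect_error(
    simulationConfig(
      conditions = c("control", "drug"),
      pUorfInitiation = c(control = 0.8)
    ),
    "drug"
  )
})
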