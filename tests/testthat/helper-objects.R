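## Shared fixtures and brute-force oracles for the test suite.

## Two-transcript annotation: tx1 carries a uORF overlapping the CDS.
tinyTxSet <- function() {
  TranscriptomeSet(
    data.frame(
      transcript_id = c("tx1", "tx2"), gene_id = c("g1", "g2"),
      length = c(300L, 200L), cds_start = c(100L, 30L),
      cds_end = c(250L, 180L)
    ),
    uorfs = data.frame(
      transcript_id = "tx1", start = 82L, end = 130L, start_codon = "AUG"
    )
  )
}

makeTrack <- function(counts, sampleId = "s1", offset = 12L) {
  methods::new("PSiteTrackSet",
    sampleId = sampleId, counts = as.data.frame(counts),
    discarded = 0, offset = as.integer(offset)
  )
}

## Region matrix built directly from per-layer matrices (for metric tests).
makeRegionMatrix <- function(utr5, cds, utr3, uorf = NULL,
                             library_size = NULL, condition = NA_character_,
                             units = "rpm") {
  if (is.null(uorf)) uorf <- utr5 * 0
  if (is.null(library_size)) library_size <- rep(1e6, ncol(cds))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(utr5 = utr5, cds = cds, utr3 = utr3, uorf = uorf),
    colData = S4Vectors::DataFrame(
      library_size = library_size,
      condition = rep(condition, length.out = ncol(cds)),
      row.names = colnames(cds)
    ),
    metadata = list(units = units, uorf_overlap_policy = "overlap_to_utr")
  )
  methods::new("RegionCountMatrix", se)
}

## Minimal DE-shaped table for classification tests.
fakeDE <- function(gene_id, log2fc, padj = 1e-4, base_mean = 100,
                   flag_de = NULL) {
  if (is.null(flag_de)) flag_de <- padj < 0.05 & abs(log2fc) > 1
  S4Vectors::DataFrame(
    gene_id = gene_id, base_mean = rep(base_mean, length.out = length(gene_id)),
    log2fc = log2fc, pvalue = rep(padj, length.out = length(gene_id)),
    padj = rep(padj, length.out = length(gene_id)),
    flag_de = rep(flag_de, length.out = length(gene_id))
  )
}

## Exhaustive ORF enumeration oracle (codon-by-codon walk).
bruteOrfs <- function(s, startCodons = c("AUG", "CUG", "GUG"),
                      minCodons = 2L) {
  s0 <- chartr("U", "T", toupper(as.character(s)))
  n <- nchar(s0)
  starts <- chartr("U", "T", toupper(startCodons))
  stops <- c("TAA", "TAG", "TGA")
  res <- list()
  for (i in 0:(n - 3L)) {
    if (!(substr(s0, i + 1L, i + 3L) %in% starts)) next
    j <- i + 3L
    end <- NA_integer_
    while (j + 3L <= n) {
      if (substr(s0, j + 1L, j + 3L) %in% stops) {
        end <- j + 3L
        break
      }
      j <- j + 3L
    }
    open <- is.na(end)
    if (open) end <- i + 3L * ((n - i) %/% 3L)
    nc <- if (open) (end - i) %/% 3L else (end - i) %/% 3L - 1L
    if (nc >= minCodons) {
      res[[length(res) + 1L]] <- data.frame(
        start = i, end = end, open_ended = open, n_codons = nc
      )
    }
  }
  if (!length(res)) {
    return(data.frame(
      start = integer(), end = integer(),
      open_ended = logical(), n_codons = integer()
    ))
  }
  do.call(rbind, res)
}

## Step-up BH oracle over sorted thresholds.
bhOracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- n * p[o] / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

## Random sequence with a guaranteed main-ORF architecture.
randomTx <- function(utr5, cds_nt, utr3, seed) {
  set.seed(seed)
  n <- utr5 + cds_nt + utr3
  s <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  s[(utr5 + 1L):(utr5 + 3L)] <- c("A", "T", "G")
  s[(utr5 + cds_nt - 2L):(utr5 + cds_nt)] <- c("T", "A", "A")
  paste(s, collapse = "")
}
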