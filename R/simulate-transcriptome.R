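#' Generate a synthetic single-isoform transcriptome
#'
#' Draws one transcript per gene with uniform-random 5'UTR, CDS and 3'UTR
#' lengths (per the config ranges), random sequence, a canonical AUG/stop
#' pair implanted at the CDS boundaries, and — for a configured fraction
#' of genes — one uORF implanted in the 5'UTR. uORF start codons are
#' sampled from AUG/CUG/GUG (near-cognate starts included); a configured
#' fraction of uORFs extends past the main start codon into the CDS, the
#' ATF4-like overlap geometry. A configured fraction of genes is labelled
#' with the "MT-" prefix for mitochondrial stratification.
#'
#' Uses the current RNG state; seed upstream (see [generateExperiment()]).
#'
#' @param config a [simulationConfig()].
#' @return A [TranscriptomeSet] with sequences and uORF annotations.
#' @export
simulateTranscriptome <- function(config) {
  n <- config$nGenes
  utr5 <- sample(config$utr5Range[1]:config$utr5Range[2], n, replace = TRUE)
  cds_cod <- sample(config$cdsCodonsRange[1]:config$cdsCodonsRange[2], n,
    replace = TRUE
  )
  utr3 <- sample(config$utr3Range[1]:config$utr3Range[2], n, replace = TRUE)
  cds_len <- 3L * cds_cod
  len <- utr5 + cds_len + utr3
  gene_id <- sprintf("gene%05d", seq_len(n))
  n_mito <- round(config$mitoGeneFraction * n)
  if (n_mito > 0) {
    mito_idx <- sample.int(n, n_mito)
    gene_id[mito_idx] <- paste0("MT-", gene_id[mito_idx])
  }
  tx_id <- sprintf("tx%05d", seq_len(n))

  bases <- c("A", "C", "G", "T")
  seqs <- vapply(len, function(L) {
    paste(sample(bases, L, replace = TRUE), collapse = "")
  }, "")

  implant <- function(s, at0, what) { # at0 is 0-based
    paste0(substr(s, 1L, at0), what, substr(s, at0 + nchar(what) + 1L, nchar(s)))
  }
  for (i in seq_len(n)) {
    seqs[i] <- implant(seqs[i], utr5[i], "ATG")
    seqs[i] <- implant(seqs[i], utr5[i] + cds_len[i] - 3L, "TAA")
  }

  ## uORFs: start codon + clean in-frame body + stop as the final codon
  n_uorf <- round(config$uorfGeneFraction * n)
  uo <- NULL
  if (n_uorf > 0) {
    eligible <- which(utr5 >= 45L) # room for a uORF plus flanks
    cand <- sample(eligible, min(n_uorf, length(eligible)))
    rows <- lapply(cand, function(i) {
      codons <- sample(4:10, 1L)
      ulen <- 3L * codons
      overlap <- runif(1) < config$uorfCdsOverlapFraction &&
        utr5[i] >= ulen # keep start in the 5'UTR
      if (overlap) {
        ## overlap depth capped so the uORF stop stays clear of the main AUG
        ustart <- utr5[i] - sample.int(min(ulen - 6L, utr5[i] - 6L), 1L)
      } else {
        hi <- utr5[i] - ulen - 3L
        if (hi < 3L) {
          return(NULL)
        }
        ustart <- sample(3:hi, 1L)
      }
      codon <- sample(c("ATG", "CTG", "GTG"), 1L, prob = c(0.5, 0.25, 0.25))
      list(i = i, start = ustart, end = ustart + ulen, codon = codon)
    })
    rows <- Filter(Negate(is.null), rows)
    for (r in rows) {
      i <- r$i
      seqs[i] <- implant(seqs[i], r$start, r$codon)
      ## scrub premature in-frame stops inside the uORF body
      for (p in seq(r$start + 3L, r$end - 6L, by = 3L)) {
        if (substr(seqs[i], p + 1L, p + 3L) %in% .STOP_CODONS) {
          seqs[i] <- implant(seqs[i], p, "AAA")
        }
      }
      seqs[i] <- implant(seqs[i], r$end - 3L, "TAA")
    }
    if (length(rows)) {
      uo <- data.frame(
        transcript_id = tx_id[vapply(rows, `[[`, 0L, "i")],
        start = vapply(rows, `[[`, 0L, "start"),
        end = vapply(rows, `[[`, 0L, "end"),
        start_codon = vapply(rows, `[[`, "", "codon")
      )
    }
  }

  TranscriptomeSet(
    data.frame(
      transcript_id = tx_id, gene_id = gene_id, length = len,
      cds_start = utr5, cds_end = utr5 + cds_len
    ),
    uorfs = uo,
    sequences = setNames(Biostrings::DNAStringSet(seqs), tx_id)
  )
}
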