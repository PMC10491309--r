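#' Generate a complete synthetic experiment with ground truth
#'
#' Runs the whole generative model under a single seed: transcriptome,
#' per-gene truth (baseline abundance, induction, TE and injected TE
#' shifts, uORF status, cleavage resistance), per-condition copy numbers
#' (rounded expectations; non-control conditions are scaled by
#' `1 - globalLossFraction` and multiplied by the induction factors),
#' per-condition fragment pools, and per-sample footprint
#' alignments and RNA-seq counts. With `outDir` set, the bundle is
#' written to disk: `transcriptome.fa`, `transcripts.tsv`, one
#' `footprints_<sample>.bed` per sample, `rnaseq_counts.tsv`,
#' `samples.tsv`, `truth.json` and `config.yaml`. The same seed
#' reproduces the bundle byte-identically.
#'
#' @param config a [simulationConfig()].
#' @param outDir optional output directory (created if missing).
#' @return list with `txset`, `truth` ([SimulationTruth]), `footprints`
#'   (named list of alignment data.tables), `rnaseq` (gene x sample count
#'   matrix), `samples` (data.frame sample/condition/replicate) and,
#'   when written, `paths`.
#' @export
generateExperiment <- function(config, outDir = NULL) {
  validateSimulationConfig(config)
  set.seed(config$seed)
  txset <- simulateTranscriptome(config)
  tx <- as.data.frame(transcripts(txset))
  n <- nrow(tx)

  baseline <- rlnorm(n, config$abundanceMeanlog, config$abundanceSdlog)
  induced <- runif(n) < config$inducedGeneFraction
  te <- rlnorm(n, 0, 0.5)
  te_shift <- numeric(n)
  if (config$nTeShiftGenes > 0) {
    pool_idx <- which(baseline >= median(baseline))
    pick <- sample(pool_idx, min(config$nTeShiftGenes, length(pool_idx)))
    half <- length(pick) %/% 2L
    te_shift[pick[seq_len(half)]] <- config$teShiftLog2
    te_shift[pick[(half + 1L):length(pick)]] <- -config$teShiftLog2
  }
  resistant <- runif(n) < config$resistantGeneFraction
  induction_mult <- ifelse(induced, config$inductionFactor, 1) *
    ifelse(te_shift != 0, config$teShiftInductionFactor, 1)
  has_uorf <- tx$transcript_id %in% uorfs(txset)$transcript_id

  genes <- S4Vectors::DataFrame(
    gene_id = tx$gene_id, transcript_id = tx$transcript_id,
    baseline_abundance = baseline, induced = induced,
    induction_mult = induction_mult, te = te, te_shift_log2 = te_shift,
    has_uorf = has_uorf, mito = startsWith(tx$gene_id, "MT-"),
    resistant = resistant
  )

  abundance <- matrix(0,
    nrow = n, ncol = length(config$conditions),
    dimnames = list(tx$gene_id, config$conditions)
  )
  for (cond in config$conditions) {
    mu <- if (.isControl(config, cond)) {
      baseline
    } else {
      baseline * (1 - config$globalLossFraction) * induction_mult
    }
    ## deterministic expectations: identical configurations give identical
    ## pools, so null conditions are exchangeable by construction
    abundance[, cond] <- round(mu)
  }

  pools <- lapply(config$conditions, function(cond) {
    ab <- setNames(abundance[, cond], tx$transcript_id)
    if (cond %in% config$cleavageConditions &&
      config$cleavage@perSiteProbability > 0) {
      simulateFragmentation(txset, ab, config$cleavage,
        survival = config$fragmentSurvival,
        resistant = tx$transcript_id[resistant]
      )
    } else {
      methods::new("FragmentPool",
        intact = ab,
        fragments = data.frame(
          transcript_id = character(), start = integer(), end = integer(),
          copies_predecay = integer(), copies = integer()
        ),
        survival = 1
      )
    }
  })
  names(pools) <- config$conditions

  truth <- methods::new("SimulationTruth",
    config = config, genes = genes,
    abundance = abundance, pools = pools
  )

  samples <- data.frame(
    sample_id = paste0(
      rep(config$conditions, each = config$replicates), "_rep",
      rep(seq_len(config$replicates), length(config$conditions))
    ),
    condition = rep(config$conditions, each = config$replicates),
    replicate = rep(seq_len(config$replicates), length(config$conditions))
  )

  footprints <- vector("list", nrow(samples))
  names(footprints) <- samples$sample_id
  rnaseq <- matrix(0,
    nrow = n, ncol = nrow(samples),
    dimnames = list(tx$gene_id, samples$sample_id)
  )
  for (cond in config$conditions) {
    units <- .footprintUnits(pools[[cond]], txset, truth, cond)
    for (s in samples$sample_id[samples$condition == cond]) {
      footprints[[s]] <- simulateFootprints(pools[[cond]], txset, truth,
        cond,
        nReads = config$footprintDepth, units = units
      )
      rnaseq[, s] <- simulateRnaseq(pools[[cond]], txset,
        depth = config$rnaseqDepth,
        replicateNoiseSd = config$replicateNoiseSd
      )
    }
  }

  out <- list(
    txset = txset, truth = truth, footprints = footprints,
    rnaseq = rnaseq, samples = samples
  )
  if (!is.null(outDir)) {
    out$paths <- .writeExperiment(out, config, outDir)
  }
  out
}

.writeExperiment <- function(exp, config, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  paths <- list(
    fasta = file.path(outDir, "transcriptome.fa"),
    transcripts = file.path(outDir, "transcripts.tsv"),
    rnaseq = file.path(outDir, "rnaseq_counts.tsv"),
    samples = file.path(outDir, "samples.tsv"),
    truth = file.path(outDir, "truth.json"),
    config = file.path(outDir, "config.yaml")
  )
  writeXStringSet(txSequences(exp$txset), paths$fasta)
  writeTranscriptTable(exp$txset, paths$transcripts)
  rn <- data.frame(gene_id = rownames(exp$rnaseq), exp$rnaseq,
    check.names = FALSE
  )
  write.table(rn, paths$rnaseq, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(exp$samples, paths$samples,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  paths$footprints <- character(0)
  for (s in exp$samples$sample_id) {
    p <- file.path(outDir, paste0("footprints_", s, ".bed"))
    writeFootprintsBed(exp$footprints[[s]], exp$txset, p)
    paths$footprints[s] <- p
  }
  writeTruth(exp$truth, paths$truth)
  yaml::write_yaml(.configAsList(config), paths$config)
  paths
}

#' Write footprint alignments as transcript-space BED6
#'
#' Columns: transcript_id, start (read 5' end), end (clipped at the
#' transcript end), read id, weight, strand (+; transcript space).
#'
#' @param fp alignment data.table from [simulateFootprints()] or
#'   [readFootprints()].
#' @param txset the matching [TranscriptomeSet] (for end clipping).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFootprintsBed <- function(fp, txset, path) {
  tx <- transcripts(txset)
  lens <- setNames(tx$length, tx$transcript_id)
  bed <- data.table(
    chrom = fp$transcript_id,
    start = fp$five_prime,
    end = pmin(fp$five_prime + fp$read_length, lens[fp$transcript_id]),
    name = paste0("read", seq_len(nrow(fp))),
    score = fp$weight,
    strand = "+"
  )
  fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Serialize simulation ground truth as JSON
#'
#' Writes the config, the per-gene truth table, realised per-condition
#' copy numbers and per-condition pool summaries (intact copies/mass and
#' surviving fragment counts), sufficient to recompute every expected
#' pipeline statistic.
#'
#' @param truth a [SimulationTruth].
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
writeTruth <- function(truth, path) {
  pools <- lapply(truth@pools, function(p) {
    list(
      total_intact_copies = sum(p@intact),
      n_fragment_species = nrow(p@fragments),
      total_fragment_copies = sum(p@fragments$copies),
      survival = p@survival
    )
  })
  obj <- list(
    config = .configAsList(truth@config),
    genes = as.data.frame(truth@genes),
    abundance = as.data.frame(truth@abundance),
    pools = pools
  )
  jsonlite::write_json(obj, path,
    auto_unbox = TRUE, digits = 10,
    dataframe = "columns"
  )
  invisible(path)
}
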