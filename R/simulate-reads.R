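## Footprint and RNA-seq read sampling from a fragment pool.
##
## Loading model: intact copies load ribosomes on the main ORF (and on the
## uORF with the condition's initiation probability) proportional to
## copies x TE; 3' fragments carrying CDS or 3'UTR sequence are loaded on
## their first available ORF with probability pFragmentReinitiation; a
## stall fraction of fragment footprints sits at the last complete codon
## before the fragment 3' end when the ORF is truncated by the cut. A
## small positionally uniform background is added per transcript.
##
## Footprint emission is proportional to initiation flux x ORF length:
## at steady state the number of elongating ribosomes on an ORF (and
## hence its footprint count) scales with the transit time, so each
## loading unit's sampling weight carries a factor of its ORF length.

.isControl <- function(cfg, condition) {
  identical(condition, cfg$conditions[1L])
}

.conditionTe <- function(truth, condition) {
  g <- truth@genes
  cfg <- truth@config
  if (.isControl(cfg, condition)) g$te else g$te * 2^g$te_shift_log2
}

## One row per "loading unit": a (transcript, ORF-interval, kind) with a
## sampling weight. Built once per condition and reused across replicates.
.footprintUnits <- function(pool, txset, truth, condition) {
  cfg <- truth@config
  tx <- as.data.frame(transcripts(txset))
  g <- as.data.frame(truth@genes)
  g <- g[match(tx$transcript_id, g$transcript_id), ]
  te <- .conditionTe(truth, condition)[match(g$gene_id, truth@genes$gene_id)]
  p_uorf <- if (condition %in% names(cfg$pUorfInitiation)) {
    cfg$pUorfInitiation[[condition]]
  } else {
    0
  }
  intact <- pool@intact[tx$transcript_id]
  intact[is.na(intact)] <- 0

  main_frac <- ifelse(g$has_uorf, 1 - p_uorf, 1)
  units <- list(data.table(
    transcript_id = tx$transcript_id, gene_id = g$gene_id, kind = "main",
    orf_start = tx$cds_start, orf_end = tx$cds_end,
    stall_pos = NA_integer_, tx_len = tx$length,
    weight = as.numeric(intact) * te * main_frac *
      (tx$cds_end - tx$cds_start)
  ))

  uo <- as.data.frame(uorfs(txset))
  if (nrow(uo) && p_uorf > 0) {
    m <- match(uo$transcript_id, tx$transcript_id)
    n_per <- table(uo$transcript_id)
    units <- c(units, list(data.table(
      transcript_id = uo$transcript_id, gene_id = g$gene_id[m],
      kind = "uorf", orf_start = uo$start, orf_end = uo$end,
      stall_pos = NA_integer_, tx_len = tx$length[m],
      weight = as.numeric(intact[m]) * te[m] * p_uorf /
        as.numeric(n_per[uo$transcript_id]) * (uo$end - uo$start)
    )))
  }

  fr <- pool@fragments
  if (nrow(fr) && cfg$pFragmentReinitiation > 0) {
    fr <- as.data.table(fr)
    m <- match(fr$transcript_id, tx$transcript_id)
    fr[, `:=`(cds_start = tx$cds_start[m], tx_len = tx$length[m],
      gene_id = g$gene_id[m], te = te[m]
    )]
    ## 3' fragments that carry CDS or 3'UTR sequence
    fr <- fr[copies > 0 & start > 0 & end > cds_start]
    if (nrow(fr)) {
      seqs <- as.character(txSequences(txset))
      starts_set <- .normCodons(c("AUG", "CUG", "GUG"))
      orf_rows <- vector("list", length(unique(fr$transcript_id)))
      spl <- split(seq_len(nrow(fr)), fr$transcript_id)
      for (ii in seq_along(spl)) {
        id <- names(spl)[ii]
        rows <- spl[[ii]]
        idx <- .orfIndex(.normSeq(seqs[[id]]), starts_set)
        fs <- fr$start[rows]
        fe <- fr$end[rows]
        if (!length(idx$starts)) next
        qi <- findInterval(fs - 0.5, idx$starts) + 1L
        ok <- qi <= length(idx$starts)
        q <- rep(NA_integer_, length(rows))
        q[ok] <- idx$starts[qi[ok]]
        se <- rep(NA_integer_, length(rows))
        se[ok] <- idx$stop_end[qi[ok]]
        ok <- ok & !is.na(q) & (q + 3L) <= fe
        trunc_end <- q + 3L * ((fe - q) %/% 3L)
        orf_end <- ifelse(is.na(se) | se > fe, trunc_end, se)
        truncated <- is.na(se) | se > fe
        stall <- ifelse(truncated & orf_end - 3L >= q, orf_end - 3L,
          NA_integer_
        )
        keep <- which(ok & orf_end > q)
        if (length(keep)) {
          orf_rows[[ii]] <- data.table(
            transcript_id = id, gene_id = fr$gene_id[rows[keep]],
            kind = "frag", orf_start = q[keep], orf_end = orf_end[keep],
            stall_pos = as.integer(stall[keep]),
            tx_len = fr$tx_len[rows[keep]],
            weight = fr$copies[rows[keep]] * cfg$pFragmentReinitiation *
              fr$te[rows[keep]] * (orf_end[keep] - q[keep])
          )
        }
      }
      units <- c(units, orf_rows)
    }
  }

  units <- rbindlist(units, use.names = TRUE)
  units <- units[weight > 0]
  if (cfg$backgroundFraction > 0 && nrow(units)) {
    bg <- units[, .(w = sum(weight)), by = .(transcript_id, gene_id)]
    m <- match(bg$transcript_id, tx$transcript_id)
    units <- rbind(units, data.table(
      transcript_id = bg$transcript_id, gene_id = bg$gene_id, kind = "bg",
      orf_start = 0L, orf_end = 0L, stall_pos = NA_integer_,
      tx_len = tx$length[m],
      weight = bg$w * cfg$backgroundFraction
    ))
  }
  units
}

#' Simulate ribosome footprint alignments for one sample
#'
#' Draws `nReads` footprints from the loading model of a fragment pool
#' (see the package vignette): P-sites are placed at in-frame codon
#' positions with 3-nt periodicity weights, a stall fraction of
#' fragment-borne footprints sits at the last complete codon before the
#' fragment 3' end, and each record's 5' end is `P-site - psiteOffset`,
#' clipped at 0. Per-gene replicate noise (log-normal) is drawn fresh on
#' every call, so repeated calls give biological replicates.
#'
#' @param pool a [FragmentPool] for the condition.
#' @param txset the [TranscriptomeSet].
#' @param truth the [SimulationTruth] (carries config and per-gene TE).
#' @param condition condition name (must be in the config).
#' @param nReads footprints to draw (default: config `footprintDepth`).
#' @param units precomputed unit table (internal reuse across replicates).
#' @return data.table of footprint alignments: `transcript_id`,
#'   `five_prime` (0-based), `read_length`, `weight`.
#' @export
simulateFootprints <- function(pool, txset, truth, condition, nReads = NULL,
                               units = NULL) {
  cfg <- truth@config
  if (!condition %in% cfg$conditions) {
    stop("unknown condition: ", condition)
  }
  if (is.null(nReads)) nReads <- cfg$footprintDepth
  if (is.null(units)) units <- .footprintUnits(pool, txset, truth, condition)
  if (!nrow(units) || sum(units$weight) <= 0) stop("empty footprint pool")

  genes <- unique(units$gene_id)
  jit <- setNames(2^rnorm(length(genes), 0, cfg$replicateNoiseSd), genes)
  w <- units$weight * jit[units$gene_id]
  counts <- as.vector(rmultinom(1L, size = nReads, prob = w))
  idx <- rep(seq_len(nrow(units)), counts)
  N <- length(idx)
  kind <- units$kind[idx]
  orf_start <- units$orf_start[idx]
  ncod <- (units$orf_end[idx] - orf_start) %/% 3L
  codon <- as.integer(floor(runif(N) * pmax(ncod, 1L)))
  frame <- sample(0:2, N, replace = TRUE, prob = cfg$frameWeights)
  psite <- orf_start + 3L * codon + frame
  is_bg <- kind == "bg"
  if (any(is_bg)) {
    psite[is_bg] <- as.integer(floor(runif(sum(is_bg)) *
      units$tx_len[idx][is_bg]))
  }
  stall_pos <- units$stall_pos[idx]
  stall <- kind == "frag" & !is.na(stall_pos) &
    runif(N) < cfg$stallFraction
  psite[stall] <- stall_pos[stall]

  data.table(
    transcript_id = units$transcript_id[idx],
    five_prime = pmax(psite - cfg$psiteOffset, 0L),
    read_length = sample(cfg$readLengths, N,
      replace = TRUE,
      prob = cfg$readLengthProbs
    ),
    weight = 1
  )
}

#' Simulate a per-gene RNA-seq count vector
#'
#' Counts are drawn multinomially over genes with weights equal to the
#' pool's CDS nucleotide mass: intact copies contribute the full CDS
#' length, surviving fragments their overlap with the CDS (emulating
#' CDS-restricted fragment counting). Per-gene replicate noise is drawn
#' fresh on every call.
#'
#' @param pool a [FragmentPool].
#' @param txset the [TranscriptomeSet].
#' @param depth total counts for the sample.
#' @param replicateNoiseSd sd (log2) of per-gene replicate noise.
#' @return named numeric vector of counts, one entry per gene.
#' @export
simulateRnaseq <- function(pool, txset, depth, replicateNoiseSd = 0) {
  if (depth <= 0) stop("depth must be positive")
  tx <- as.data.frame(transcripts(txset))
  cds_len <- tx$cds_end - tx$cds_start
  mass <- setNames(pool@intact[tx$transcript_id] * cds_len, tx$transcript_id)
  mass[is.na(mass)] <- 0
  fr <- pool@fragments
  if (nrow(fr)) {
    m <- match(fr$transcript_id, tx$transcript_id)
    ov <- pmax(
      0,
      pmin(fr$end, tx$cds_end[m]) - pmax(fr$start, tx$cds_start[m])
    )
    add <- tapply(ov * fr$copies, fr$transcript_id, sum)
    mass[names(add)] <- mass[names(add)] + add
  }
  if (sum(mass) <= 0) stop("empty library")
  gene <- setNames(tx$gene_id, tx$transcript_id)
  w <- mass * 2^rnorm(length(mass), 0, replicateNoiseSd)
  counts <- as.vector(rmultinom(1L, size = depth, prob = w))
  setNames(counts, gene[names(mass)])
}
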