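#' Detect translated uORFs from P-site peaks at candidate start codons
#'
#' Every candidate start codon (AUG and near-cognate CUG/GUG by default)
#' in a transcript's 5'UTR is scored by the P-site count in a window of
#' one codon either side of the start codon (9 nt), relative to the mean
#' 5'UTR P-site density computed with all candidate windows excluded. A
#' candidate is called translated when its peak score (peak count over
#' the background expectation for the window) reaches `scoreThreshold`
#' and the raw peak count reaches `minReads`. Transcripts whose 5'UTR is
#' shorter than the peak window are skipped and listed in the `skipped`
#' attribute.
#'
#' @param track a [PSiteTrackSet] (one sample).
#' @param txset a [TranscriptomeSet] with sequences.
#' @param startCodons candidate start codons.
#' @param scoreThreshold minimum peak/background ratio (default 5).
#' @param minReads minimum raw P-site count in the peak window.
#' @param minCodons minimum candidate ORF length in codons.
#' @return data.frame sorted by decreasing score: `transcript_id`,
#'   `gene_id`, `start`, `end`, `start_codon`, `start_peak_count`,
#'   `local_background`, `peak_score`, `called`; attribute `skipped`.
#' @export
detectUorfPeaks <- function(track, txset,
                            startCodons = c("AUG", "CUG", "GUG"),
                            scoreThreshold = 5, minReads = 10,
                            minCodons = 2L) {
  stopifnot(methods::is(track, "PSiteTrackSet"))
  if (is.null(txSequences(txset))) stop("txset must carry sequences")
  tx <- as.data.frame(transcripts(txset))
  seqs <- txSequences(txset)
  width <- 9L # start codon +/- one codon
  out <- list()
  skipped <- character()
  with_counts <- unique(track@counts$transcript_id)
  for (id in intersect(tx$transcript_id, with_counts)) {
    i <- match(id, tx$transcript_id)
    cs <- tx$cds_start[i]
    orfs <- scanOrfs(seqs[[id]],
      startCodons = startCodons,
      minCodons = minCodons
    )
    orfs <- orfs[orfs$start < cs, , drop = FALSE]
    if (!nrow(orfs)) next
    if (cs < width) {
      skipped <- c(skipped, id)
      next
    }
    v <- trackVector(track, txset, id)
    utr5 <- v[seq_len(cs)]
    win_lo <- pmax(orfs$start - 3L, 0L)
    win_hi <- pmin(orfs$start + 5L, cs - 1L)
    in_window <- logical(cs)
    for (k in seq_len(nrow(orfs))) {
      in_window[(win_lo[k] + 1L):(win_hi[k] + 1L)] <- TRUE
    }
    bg_pos <- which(!in_window)
    bg <- if (length(bg_pos)) mean(utr5[bg_pos]) else 0
    peak <- vapply(seq_len(nrow(orfs)), function(k) {
      sum(utr5[(win_lo[k] + 1L):(win_hi[k] + 1L)])
    }, numeric(1))
    expected <- bg * (win_hi - win_lo + 1L)
    score <- ifelse(expected > 0, peak / expected,
      ifelse(peak > 0, Inf, 0)
    )
    out[[id]] <- data.frame(
      transcript_id = id, gene_id = tx$gene_id[i],
      start = orfs$start, end = orfs$end, start_codon = orfs$start_codon,
      start_peak_count = peak, local_background = bg,
      peak_score = score,
      called = score >= scoreThreshold & peak >= minReads
    )
  }
  res <- if (length(out)) {
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  } else {
    data.frame(
      transcript_id = character(), gene_id = character(),
      start = integer(), end = integer(), start_codon = character(),
      start_peak_count = numeric(), local_background = numeric(),
      peak_score = numeric(), called = logical()
    )
  }
  res <- res[order(-res$peak_score), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

#' 5'UTR : main-ORF translation shift between conditions
#'
#' For each gene, the per-sample ratio of 5'UTR footprint rpm to CDS
#' footprint rpm (uORF/CDS overlap positions assigned per the policy used
#' when counting regions) is compared between conditions:
#' `log2_shift = log2(mean treated ratio / mean control ratio)`, with a
#' two-sided Welch t-test on per-replicate log2 ratios. A negative shift
#' is the ISR signature of initiation moving from uORFs to the main ORF.
#' Genes with zero CDS rpm in any considered sample are excluded and
#' listed in the `excluded` attribute; the t-test is NA when a zero
#' 5'UTR ratio makes the log undefined in any replicate.
#'
#' @param rpm a [RegionCountMatrix] in rpm units.
#' @param controlSamples,treatedSamples column names of the two groups.
#' @param genes optional gene subset (default: all genes).
#' @return data.frame: `gene_id`, `mean_ratio_control`,
#'   `mean_ratio_treated`, `log2_shift`, `p_value`; attributes `ratios`
#'   (per-sample long table) and `excluded`.
#' @export
utr5MainShift <- function(rpm, controlSamples, treatedSamples,
                          genes = NULL) {
  stopifnot(methods::is(rpm, "RegionCountMatrix"))
  if (!identical(metadata(rpm)$units, "rpm")) {
    stop("utr5MainShift expects rpm units; call toRpm() first")
  }
  all_s <- c(controlSamples, treatedSamples)
  if (!all(all_s %in% colnames(rpm))) stop("unknown sample name(s)")
  utr5 <- assay(rpm, "utr5")[, all_s, drop = FALSE]
  cds <- assay(rpm, "cds")[, all_s, drop = FALSE]
  if (is.null(genes)) genes <- rownames(rpm)
  utr5 <- utr5[genes, , drop = FALSE]
  cds <- cds[genes, , drop = FALSE]
  ok <- rowSums(cds > 0) == ncol(cds)
  excluded <- genes[!ok]
  ratio <- utr5[ok, , drop = FALSE] / cds[ok, , drop = FALSE]
  is_c <- all_s %in% controlSamples
  mc <- rowMeans(ratio[, is_c, drop = FALSE])
  mt <- rowMeans(ratio[, !is_c, drop = FALSE])
  lr <- log2(ratio)
  pv <- vapply(seq_len(nrow(ratio)), function(i) {
    a <- lr[i, is_c]
    b <- lr[i, !is_c]
    if (any(!is.finite(c(a, b))) || length(a) < 2L || length(b) < 2L ||
      (var(a) == 0 && var(b) == 0)) {
      return(NA_real_)
    }
    t.test(b, a)$p.value
  }, numeric(1))
  res <- data.frame(
    gene_id = genes[ok],
    mean_ratio_control = mc, mean_ratio_treated = mt,
    log2_shift = log2(mt / mc), p_value = pv
  )
  rownames(res) <- NULL
  ratios_long <- data.frame(
    gene_id = rep(genes[ok], times = ncol(ratio)),
    sample_id = rep(all_s, each = sum(ok)),
    condition = rep(
      ifelse(is_c, "control", "treated"),
      each = sum(ok)
    ),
    ratio = as.vector(ratio)
  )
  attr(res, "ratios") <- ratios_long
  attr(res, "excluded") <- excluded
  res
}
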