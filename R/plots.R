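#' Plot a metagene occupancy profile
#'
#' @param profile output of [metageneProfile()].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `profile`.
#' @export
plotMetagene <- function(profile, ...) {
  graphics::plot(profile$offset, profile$mean_occupancy,
    type = "l",
    xlab = "offset from anchor (nt)",
    ylab = "mean normalised occupancy", ...
  )
  graphics::abline(v = 0, lty = 2, col = "grey50")
  invisible(profile)
}

#' TE scatter: RNA-seq vs footprint log2 fold changes
#'
#' Scatter of per-gene log2 fold changes with the diagonal TE-change
#' gates drawn as dotted lines; mitochondrially encoded genes in orange,
#' TE calls coloured.
#'
#' @param teClasses output of [classifyTEChanges()].
#' @param teFoldGate fold-change gate used for the diagonals.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `teClasses`.
#' @export
plotTEScatter <- function(teClasses, teFoldGate = 2, ...) {
  x <- teClasses$log2fc_rna
  y <- teClasses$log2fc_ribo
  col <- rep("grey60", length(x))
  col[teClasses$category == "te_up"] <- "firebrick"
  col[teClasses$category == "te_down"] <- "steelblue"
  col[teClasses$mito] <- "orange"
  graphics::plot(x, y,
    col = col, pch = 16, cex = 0.6,
    xlab = "RNA-seq log2 fold change",
    ylab = "footprint log2 fold change", ...
  )
  graphics::abline(0, 1, lty = 3)
  graphics::abline(log2(teFoldGate), 1, lty = 3)
  graphics::abline(-log2(teFoldGate), 1, lty = 3)
  invisible(teClasses)
}

#' Plot one transcript's P-site track with start-codon markers
#'
#' Track of P-site counts along a transcript with the CDS shaded, the
#' main start codon marked in red and annotated uORF starts in green
#' (near-cognate starts dashed).
#'
#' @param track a [PSiteTrackSet].
#' @param txset the [TranscriptomeSet].
#' @param transcript_id transcript to draw.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the dense track vector.
#' @export
plotGeneTrack <- function(track, txset, transcript_id, ...) {
  v <- trackVector(track, txset, transcript_id)
  tx <- as.data.frame(transcripts(txset))
  i <- match(transcript_id, tx$transcript_id)
  graphics::plot(seq_along(v) - 1L, v,
    type = "h", col = "grey30",
    xlab = "transcript position (nt)", ylab = "P-site count",
    main = transcript_id, ...
  )
  graphics::rect(tx$cds_start[i], 0, tx$cds_end[i], max(v) * 1.02,
    border = NA, col = grDevices::adjustcolor("grey80", 0.3)
  )
  graphics::abline(v = tx$cds_start[i], col = "red")
  uo <- as.data.frame(uorfs(txset))
  uo <- uo[uo$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(uo)) {
    graphics::abline(
      v = uo$start, col = "forestgreen",
      lty = ifelse(uo$start_codon == "AUG", 1, 2)
    )
  }
  invisible(v)
}
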