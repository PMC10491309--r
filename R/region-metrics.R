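#' UTR:ORF occupancy ratios
#'
#' The headline altORF-translation statistic: the ratio of footprint rpm
#' mapping to a UTR to that mapping to the main ORF. `scope =
#' "aggregate"` (the single-bar-per-sample statistic) divides the summed
#' UTR rpm by the summed CDS rpm over all genes passing the expression
#' filter; `scope = "per_gene"` reports one ratio per passing gene.
#' Elevated 3'UTR:ORF ratios indicate translation of 3' cleavage
#' fragments; elevated 5'UTR:ORF ratios indicate uORF/altORF initiation.
#'
#' @param rpm a [RegionCountMatrix] in rpm units (see [toRpm()]).
#' @param which `"utr3"` or `"utr5"`.
#' @param scope `"aggregate"` or `"per_gene"`.
#' @param minCdsRpm expression filter: genes with CDS rpm below this are
#'   omitted (must be > 0 for per-gene scope, as a division guard).
#' @return data.frame with columns `sample_id`, `scope`, `gene_id` (NA
#'   for aggregate rows), `which`, `ratio`, `genes_used`.
#' @export
utrOrfRatio <- function(rpm, which = c("utr3", "utr5"),
                        scope = c("aggregate", "per_gene"),
                        minCdsRpm = 1) {
  which <- match.arg(which)
  scope <- match.arg(scope)
  stopifnot(methods::is(rpm, "RegionCountMatrix"))
  if (!identical(metadata(rpm)$units, "rpm")) {
    stop("utrOrfRatio expects rpm units; call toRpm() first")
  }
  if (scope == "per_gene" && minCdsRpm <= 0) {
    stop("minCdsRpm must be > 0 for per-gene scope")
  }
  cds <- assay(rpm, "cds")
  utr <- assay(rpm, which)
  out <- vector("list", ncol(rpm))
  for (j in seq_len(ncol(rpm))) {
    pass <- cds[, j] >= minCdsRpm
    if (scope == "aggregate") {
      out[[j]] <- data.frame(
        sample_id = colnames(rpm)[j], scope = scope,
        gene_id = NA_character_, which = which,
        ratio = sum(utr[pass, j]) / sum(cds[pass, j]),
        genes_used = sum(pass)
      )
    } else {
      out[[j]] <- data.frame(
        sample_id = colnames(rpm)[j], scope = scope,
        gene_id = rownames(rpm)[pass], which = which,
        ratio = utr[pass, j] / cds[pass, j],
        genes_used = sum(pass)
      )
    }
  }
  do.call(rbind, out)
}

#' Metagene occupancy profile around the start or stop codon
#'
#' For every gene passing the CDS-density filter and whose window lies
#' fully inside the transcript, the positional P-site count vector around
#' the anchor is divided by that gene's mean CDS P-site density, and the
#' normalised vectors are averaged with equal gene weights. Offset 0 is
#' the P-site of the first CDS codon (`anchor = "start_codon"`) or of the
#' stop codon (`anchor = "stop_codon"`). Elevated occupancy downstream of
#' the stop codon is the metagene signature of 3'UTR (altORF)
#' translation.
#'
#' @param track a [PSiteTrackSet] (one sample).
#' @param txset the [TranscriptomeSet].
#' @param anchor `"start_codon"` or `"stop_codon"`.
#' @param window `c(upstream_nt, downstream_nt)`; offsets run from
#'   `-upstream` to `+downstream`.
#' @param minCdsDensity minimum mean CDS P-site density (reads/nt) for a
#'   gene to enter the average.
#' @return data.frame with columns `offset`, `mean_occupancy`, `n_genes`.
#' @export
metageneProfile <- function(track, txset,
                            anchor = c("start_codon", "stop_codon"),
                            window = c(50L, 100L), minCdsDensity = 0.5) {
  anchor <- match.arg(anchor)
  stopifnot(methods::is(track, "PSiteTrackSet"))
  tx <- as.data.frame(transcripts(txset))
  up <- as.integer(window[1L])
  down <- as.integer(window[2L])
  cnt <- as.data.table(psiteCounts(track))
  m <- match(cnt$transcript_id, tx$transcript_id)
  if (anyNA(m)) stop("track on unannotated transcript")
  ## per-transcript CDS density
  cds_cnt <- cnt[
    pos >= tx$cds_start[m] & pos < tx$cds_end[m],
    .(cds = sum(count)),
    by = transcript_id
  ]
  tx$anchor <- if (anchor == "start_codon") tx$cds_start else tx$cds_end - 3L
  tx$dens <- 0
  mm <- match(cds_cnt$transcript_id, tx$transcript_id)
  tx$dens[mm] <- cds_cnt$cds / (tx$cds_end[mm] - tx$cds_start[mm])
  pass <- tx$dens >= minCdsDensity &
    (tx$anchor - up) >= 0L & (tx$anchor + down) <= (tx$length - 1L)
  if (!any(pass)) stop("empty metagene: no gene passes the filters")
  ptx <- tx[pass, , drop = FALSE]
  sub <- cnt[transcript_id %in% ptx$transcript_id]
  i <- match(sub$transcript_id, ptx$transcript_id)
  sub[, `:=`(off = pos - ptx$anchor[i], dens = ptx$dens[i])]
  sub <- sub[off >= -up & off <= down]
  agg <- sub[, .(s = sum(count / dens)), by = off]
  offsets <- (-up):down
  prof <- setNames(numeric(length(offsets)), offsets)
  prof[as.character(agg$off)] <- agg$s
  data.frame(
    offset = offsets,
    mean_occupancy = unname(prof) / nrow(ptx),
    n_genes = nrow(ptx)
  )
}
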