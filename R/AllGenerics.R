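#' Accessors for riboclast classes
#'
#' `transcripts()` and `uorfs()` return the model tables of a
#' [TranscriptomeSet]; `txSequences()` its sequences. `psiteCounts()`
#' returns the sparse count table of a [PSiteTrackSet] and
#' `discardedReads()` its discard tally. `libSizes()` returns per-sample
#' total P-site counts of a [RegionCountMatrix]. `truthGenes()` returns
#' the per-gene truth table of a [SimulationTruth] and `truthAbundance()`
#' its per-gene, per-condition copy-number matrix.
#'
#' @param x the object.
#' @return See details per accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("transcripts", function(x) standardGeneric("transcripts"))

#' @rdname accessors
#' @export
setGeneric("uorfs", function(x) standardGeneric("uorfs"))

#' @rdname accessors
#' @export
setGeneric("txSequences", function(x) standardGeneric("txSequences"))

#' @rdname accessors
#' @export
setGeneric("psiteCounts", function(x) standardGeneric("psiteCounts"))

#' @rdname accessors
#' @export
setGeneric("discardedReads", function(x) standardGeneric("discardedReads"))

#' @rdname accessors
#' @export
setGeneric("libSizes", function(x) standardGeneric("libSizes"))

#' @rdname accessors
#' @export
setGeneric("truthGenes", function(x) standardGeneric("truthGenes"))

#' @rdname accessors
#' @export
setGeneric("truthAbundance", function(x) standardGeneric("truthAbundance"))

#' Partition a transcript into 5'UTR, CDS and 3'UTR intervals
#'
#' Returns the region intervals `utr5 = [0, cds_start)`,
#' `cds = [cds_start, cds_end)` and `utr3 = [cds_end, length)` in 0-based
#' half-open transcript coordinates. Empty intervals are permitted
#' (`cds_start = 0` gives an empty 5'UTR; `cds_end = length` an empty
#' 3'UTR). The three intervals tile `[0, length)` exactly.
#'
#' @param x a [TranscriptomeSet].
#' @return A data.frame with one row per transcript x region: columns
#'   `transcript_id`, `region` (utr5/cds/utr3), `start`, `end`.
#' @examples
#' ts <- TranscriptomeSet(data.frame(
#'   transcript_id = "tx1", gene_id = "g1",
#'   length = 300L, cds_start = 100L, cds_end = 250L
#' ))
#' partitionRegions(ts)
#' @export
setGeneric("partitionRegions", function(x) standardGeneric("partitionRegions"))

setMethod("transcripts", "TranscriptomeSet", function(x) x@tx)
setMethod("uorfs", "TranscriptomeSet", function(x) x@uorfs)
setMethod("txSequences", "TranscriptomeSet", function(x) x@seqs)
setMethod("psiteCounts", "PSiteTrackSet", function(x) x@counts)
setMethod("discardedReads", "PSiteTrackSet", function(x) x@discarded)
setMethod("libSizes", "RegionCountMatrix", function(x) {
  setNames(colData(x)$library_size, colnames(x))
})
setMethod("truthGenes", "SimulationTruth", function(x) x@genes)

#' @rdname accessors
#' @export
setMethod("truthAbundance", "SimulationTruth", function(x) x@abundance)

setMethod("partitionRegions", "TranscriptomeSet", function(x) {
  tx <- as.data.frame(x@tx)
  out <- rbind(
    data.frame(
      transcript_id = tx$transcript_id, region = "utr5",
      start = 0L, end = tx$cds_start
    ),
    data.frame(
      transcript_id = tx$transcript_id, region = "cds",
      start = tx$cds_start, end = tx$cds_end
    ),
    data.frame(
      transcript_id = tx$transcript_id, region = "utr3",
      start = tx$cds_end, end = tx$length
    )
  )
  out[order(match(out$transcript_id, tx$transcript_id)), , drop = FALSE]
})
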