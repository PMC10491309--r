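## Central S4 containers. Coordinates are 0-based, half-open, transcript
## space throughout; the CDS interval includes the stop codon, so the 3'UTR
## starts immediately after the stop.

setClassUnion("DNAStringSetOrNULL", c("DNAStringSet", "NULL"))

setOldClass(c("SimulationConfig", "list"))

#' TranscriptomeSet: transcript models with optional sequences
#'
#' Holds one model per transcript: gene assignment, transcript length and
#' the CDS interval in 0-based half-open transcript coordinates (the CDS
#' includes the stop codon), plus upstream ORF (uORF) annotations and,
#' optionally, the transcript sequences as a [Biostrings::DNAStringSet].
#'
#' @slot tx `DataFrame` with columns `transcript_id`, `gene_id`, `length`,
#'   `cds_start`, `cds_end`.
#' @slot uorfs `DataFrame` with columns `transcript_id`, `start`, `end`,
#'   `start_codon`. uORFs begin in the 5'UTR and may extend into the CDS.
#' @slot seqs transcript sequences (`DNAStringSet`) or `NULL`.
#' @slot singleIsoform logical; when `TRUE` at most one transcript per gene
#'   is allowed (reduced-transcriptome convention).
#'
#' @seealso [loadAnnotation()], [partitionRegions()], [simulateTranscriptome()]
#' @export
setClass("TranscriptomeSet",
  slots = c(
    tx = "DataFrame",
    uorfs = "DataFrame",
    seqs = "DNAStringSetOrNULL",
    singleIsoform = "logical"
  ),
  prototype = list(
    uorfs = S4Vectors::DataFrame(
      transcript_id = character(), start = integer(),
      end = integer(), start_codon = character()
    ),
    seqs = NULL,
    singleIsoform = TRUE
  )
)

setValidity("TranscriptomeSet", function(object) {
  tx <- object@tx
  need <- c("transcript_id", "gene_id", "length", "cds_start", "cds_end")
  if (!all(need %in% colnames(tx))) {
    return(paste("tx must have columns:", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(tx$transcript_id)) {
    return("duplicate transcript_id")
  }
  if (isTRUE(object@singleIsoform) && anyDuplicated(tx$gene_id)) {
    return("more than one transcript per gene in a single-isoform set")
  }
  bad <- !(tx$cds_start >= 0 & tx$cds_start < tx$cds_end &
    tx$cds_end <= tx$length)
  if (any(bad)) {
    return(sprintf(
      "invalid CDS interval for transcript(s): %s",
      paste(head(tx$transcript_id[bad], 5), collapse = ", ")
    ))
  }
  uo <- object@uorfs
  if (nrow(uo)) {
    if (!all(uo$transcript_id %in% tx$transcript_id)) {
      return("uORF annotation refers to unknown transcript")
    }
    if (any(uo$start >= uo$end)) return("uORF start must be < end")
    if (any((uo$end - uo$start) %% 3L != 0L)) {
      return("uORF length must be a multiple of 3")
    }
    cs <- tx$cds_start[match(uo$transcript_id, tx$transcript_id)]
    if (any(uo$start >= cs)) {
      return("uORF must start in the 5'UTR (start < cds_start)")
    }
  }
  if (!is.null(object@seqs)) {
    common <- intersect(names(object@seqs), tx$transcript_id)
    wl <- Biostrings::width(object@seqs[common])
    tl <- tx$length[match(common, tx$transcript_id)]
    if (any(wl != tl)) {
      return("sequence widths disagree with annotated transcript lengths")
    }
  }
  TRUE
})

#' Construct a TranscriptomeSet
#'
#' @param tx data.frame or DataFrame of transcript models (columns
#'   `transcript_id`, `gene_id`, `length`, `cds_start`, `cds_end`).
#' @param uorfs optional data.frame of uORF annotations (columns
#'   `transcript_id`, `start`, `end`, `start_codon`).
#' @param sequences optional named `DNAStringSet` (or named character) of
#'   transcript sequences.
#' @param singleIsoform enforce at most one transcript per gene.
#' @return A `TranscriptomeSet`.
#' @examples
#' ts <- TranscriptomeSet(data.frame(
#'   transcript_id = "tx1", gene_id = "g1",
#'   length = 300L, cds_start = 100L, cds_end = 250L
#' ))
#' transcripts(ts)
#' @export
TranscriptomeSet <- function(tx, uorfs = NULL, sequences = NULL,
                             singleIsoform = TRUE) {
  tx <- S4Vectors::DataFrame(as.data.frame(tx))
  tx$length <- as.integer(tx$length)
  tx$cds_start <- as.integer(tx$cds_start)
  tx$cds_end <- as.integer(tx$cds_end)
  if (is.null(uorfs)) {
    uorfs <- S4Vectors::DataFrame(
      transcript_id = character(), start = integer(),
      end = integer(), start_codon = character()
    )
  } else {
    uorfs <- S4Vectors::DataFrame(as.data.frame(uorfs))
    uorfs$start <- as.integer(uorfs$start)
    uorfs$end <- as.integer(uorfs$end)
    uorfs$start_codon <- toupper(chartr("u", "U", uorfs$start_codon))
  }
  if (!is.null(sequences)) {
    if (!methods::is(sequences, "DNAStringSet")) {
      nm <- names(sequences)
      sequences <- Biostrings::DNAStringSet(
        chartr("Uu", "Tt", as.character(sequences))
      )
      names(sequences) <- nm
    }
    if (is.null(names(sequences))) {
      stop("sequences must be named by transcript_id")
    }
  }
  methods::new("TranscriptomeSet",
    tx = tx, uorfs = uorfs, seqs = sequences,
    singleIsoform = singleIsoform
  )
}

#' CleavageModel: sequence specificity of an endonuclease
#'
#' Relative cleavage propensities for short (k <= 2) motifs plus a global
#' per-site cut probability. The cut point is immediately 3' of the
#' matched motif. Presets: `"rnasel_like"` cleaves 3' of UU and UA
#' dinucleotides (RNase L specificity); `"rnasea_like"` cleaves 3' of
#' pyrimidines (U and C; RNase A specificity).
#'
#' @slot name model name.
#' @slot motifWeights named non-negative numeric; names are DNA-alphabet
#'   motifs of length 1 or 2 (U is stored as T).
#' @slot perSiteProbability probability that any one candidate site in one
#'   transcript copy is cut (scaled by normalised motif weight).
#' @seealso [cleavageModel()], [findCleavageSites()]
#' @export
setClass("CleavageModel",
  slots = c(
    name = "character",
    motifWeights = "numeric",
    perSiteProbability = "numeric"
  )
)

setValidity("CleavageModel", function(object) {
  w <- object@motifWeights
  if (length(w) == 0L || is.null(names(w))) {
    return("motifWeights must be a named numeric vector")
  }
  if (any(w < 0) || !any(w > 0)) {
    return("motif weights must be >= 0 with at least one positive")
  }
  if (any(!nchar(names(w)) %in% 1:2)) {
    return("motifs must have length 1 or 2")
  }
  p <- object@perSiteProbability
  if (length(p) != 1L || p < 0 || p > 1) {
    return("perSiteProbability must be a single value in [0, 1]")
  }
  TRUE
})

#' FragmentPool: outcome of simulated endonucleolytic fragmentation
#'
#' Per transcript: the number of copies left intact and the surviving
#' cleavage fragments in transcript coordinates. `copies_predecay` keeps
#' the pre-decay fragment counts so that nucleotide mass conservation can
#' be verified exactly.
#'
#' @slot intact named numeric; intact copies per transcript.
#' @slot fragments data.frame with columns `transcript_id`, `start`, `end`,
#'   `copies_predecay`, `copies` (post-decay).
#' @slot survival fragment survival probability used for decay.
#' @seealso [simulateFragmentation()]
#' @export
setClass("FragmentPool",
  slots = c(
    intact = "numeric",
    fragments = "data.frame",
    survival = "numeric"
  )
)

#' PSiteTrackSet: per-position ribosome P-site counts for one sample
#'
#' Sparse representation of one sample's P-site tracks: only positions
#' with non-zero counts are stored. Positions are 0-based transcript
#' coordinates of the inferred P-site (read 5' end + offset).
#'
#' @slot sampleId sample identifier.
#' @slot counts data.frame with columns `transcript_id`, `pos`, `count`.
#' @slot discarded total weight of reads whose shifted P-site fell off the
#'   transcript end (discarded, not clamped).
#' @slot offset the P-site offset (nt) that was applied.
#' @seealso [assignPsites()], [trackVector()]
#' @export
setClass("PSiteTrackSet",
  slots = c(
    sampleId = "character",
    counts = "data.frame",
    discarded = "numeric",
    offset = "integer"
  )
)

setValidity("PSiteTrackSet", function(object) {
  cc <- object@counts
  if (!all(c("transcript_id", "pos", "count") %in% colnames(cc))) {
    return("counts needs columns transcript_id, pos, count")
  }
  if (nrow(cc) && any(cc$count < 0)) return("negative P-site counts")
  if (object@discarded < 0) return("negative discard tally")
  TRUE
})

#' RegionCountMatrix: gene x sample P-site counts split by region
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one assay per
#' transcript region: `utr5`, `cds`, `utr3` and `uorf`. The first three
#' tile the transcript, so per gene and sample `utr5 + cds + utr3` equals
#' the total transcript P-site count; the `uorf` layer overlaps `utr5`
#' (and possibly `cds`) and is excluded from that identity. Column data
#' carry `library_size` (total P-sites per sample) and `condition`;
#' `metadata()$units` is `"counts"` or `"rpm"`.
#'
#' @seealso [countRegions()], [toRpm()], [libSizes()]
#' @export
setClass("RegionCountMatrix", contains = "SummarizedExperiment")

setValidity("RegionCountMatrix", function(object) {
  need <- c("utr5", "cds", "utr3", "uorf")
  if (!all(need %in% assayNames(object))) {
    return(paste("assays required:", paste(need, collapse = ", ")))
  }
  if (!all(c("library_size", "condition") %in% colnames(colData(object)))) {
    return("colData needs library_size and condition")
  }
  for (a in need) {
    if (any(assay(object, a) < 0)) return(sprintf("negative values in %s", a))
  }
  TRUE
})

#' SimulationTruth: ground truth of a generated experiment
#'
#' Everything needed to recompute the expected value of every pipeline
#' statistic: the configuration, per-gene parameters (baseline abundance,
#' induction flag, translation efficiency and injected TE shift, uORF
#' status), realised per-condition copy numbers and the fragment pools.
#'
#' @slot config the [SimulationConfig] used.
#' @slot genes `DataFrame`: `gene_id`, `transcript_id`,
#'   `baseline_abundance`, `induced`, `te`, `te_shift_log2`, `has_uorf`,
#'   `mito`.
#' @slot abundance matrix of realised pre-cleavage copy numbers,
#'   genes x conditions.
#' @slot pools named list of [FragmentPool], one per condition.
#' @seealso [generateExperiment()], [writeTruth()]
#' @export
setClass("SimulationTruth",
  slots = c(
    config = "list",
    genes = "DataFrame",
    abundance = "matrix",
    pools = "list"
  )
)

## ---- show methods -------------------------------------------------------

setMethod("show", "TranscriptomeSet", function(object) {
  cat(sprintf(
    "TranscriptomeSet with %d transcripts (%d genes), %d uORFs, sequences: %s\n",
    nrow(object@tx), length(unique(object@tx$gene_id)),
    nrow(object@uorfs), if (is.null(object@seqs)) "no" else "yes"
  ))
})

setMethod("show", "CleavageModel", function(object) {
  cat(sprintf(
    "CleavageModel '%s': per-site p = %g; motifs: %s\n",
    object@name, object@perSiteProbability,
    paste(sprintf("%s=%g", names(object@motifWeights), object@motifWeights),
      collapse = ", "
    )
  ))
})

setMethod("show", "FragmentPool", function(object) {
  cat(sprintf(
    "FragmentPool: %d transcripts, %.0f intact copies, %d fragment species (%.0f surviving copies)\n",
    length(object@intact), sum(object@intact),
    nrow(object@fragments), sum(object@fragments$copies)
  ))
})

setMethod("show", "PSiteTrackSet", function(object) {
  cat(sprintf(
    "PSiteTrackSet '%s': %.0f P-sites on %d transcripts (offset %d nt, %.0f discarded)\n",
    object@sampleId, sum(object@counts$count),
    length(unique(object@counts$transcript_id)),
    object@offset, object@discarded
  ))
})

setMethod("show", "SimulationTruth", function(object) {
  cat(sprintf(
    "SimulationTruth: %d genes x %d conditions (%s)\n",
    nrow(object@genes), ncol(object@abundance),
    paste(colnames(object@abundance), collapse = ", ")
  ))
})
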