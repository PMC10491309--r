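#' Count P-sites per region per gene
#'
#' Sums each sample's P-site track over the 5'UTR, CDS and 3'UTR
#' intervals of every transcript, plus a uORF layer covering annotated
#' uORF intervals. The three tiling layers always sum to the per-gene
#' track total; the uORF layer overlaps them and is excluded from that
#' identity. Where a uORF extends into the CDS, the overlap positions are
#' assigned per `uorfOverlapPolicy`: `"overlap_to_utr"` (default; the
#' convention used for ATF4-type genes) moves them to the `utr5` layer,
#' `"overlap_to_cds"` leaves them in `cds`. Library sizes are each
#' sample's total transcriptome-mapped P-site count.
#'
#' @param tracks a [PSiteTrackSet] or list of them (one per sample).
#' @param txset the [TranscriptomeSet]; every track transcript must be
#'   annotated.
#' @param uorfOverlapPolicy see above.
#' @param conditions optional named character vector mapping sample ids to
#'   condition labels (stored in `colData`).
#' @return A [RegionCountMatrix] (genes x samples).
#' @export
countRegions <- function(tracks, txset,
                         uorfOverlapPolicy = c(
                           "overlap_to_utr",
                           "overlap_to_cds"
                         ),
                         conditions = NULL) {
  uorfOverlapPolicy <- match.arg(uorfOverlapPolicy)
  if (methods::is(tracks, "PSiteTrackSet")) tracks <- list(tracks)
  tx <- as.data.frame(transcripts(txset))
  uo <- as.data.table(as.data.frame(uorfs(txset)))
  genes <- unique(tx$gene_id)
  sample_ids <- vapply(tracks, function(t) t@sampleId, "")
  if (anyDuplicated(sample_ids)) {
    sample_ids <- make.unique(sample_ids)
  }

  layer <- function() {
    matrix(0,
      nrow = length(genes), ncol = length(tracks),
      dimnames = list(genes, sample_ids)
    )
  }
  assaysL <- list(utr5 = layer(), cds = layer(), utr3 = layer(), uorf = layer())
  lib <- numeric(length(tracks))

  for (j in seq_along(tracks)) {
    cnt <- as.data.table(psiteCounts(tracks[[j]]))
    unknown <- setdiff(unique(cnt$transcript_id), tx$transcript_id)
    if (length(unknown)) {
      stop(
        "track on unannotated transcript(s): ",
        paste(head(unknown, 5), collapse = ", ")
      )
    }
    if (!nrow(cnt)) next
    m <- match(cnt$transcript_id, tx$transcript_id)
    cnt[, `:=`(
      gene_id = tx$gene_id[m],
      region = fifelse(pos < tx$cds_start[m], "utr5",
        fifelse(pos < tx$cds_end[m], "cds", "utr3")
      )
    )]
    cnt[, in_uorf := FALSE]
    if (nrow(uo)) {
      hit <- uo[cnt,
        on = .(transcript_id, start <= pos, end > pos),
        which = TRUE, nomatch = NA, mult = "first"
      ]
      cnt[, in_uorf := !is.na(hit)]
    }
    if (uorfOverlapPolicy == "overlap_to_utr") {
      cnt[in_uorf & region == "cds", region := "utr5"]
    }
    tot <- cnt[, .(count = sum(count)), by = .(gene_id, region)]
    for (r in c("utr5", "cds", "utr3")) {
      sub <- tot[region == r]
      assaysL[[r]][match(sub$gene_id, genes), j] <- sub$count
    }
    usub <- cnt[in_uorf == TRUE, .(count = sum(count)), by = gene_id]
    if (nrow(usub)) {
      assaysL$uorf[match(usub$gene_id, genes), j] <- usub$count
    }
    lib[j] <- cnt[, sum(count)]
  }

  cd <- S4Vectors::DataFrame(
    library_size = lib,
    condition = if (is.null(conditions)) {
      rep(NA_character_, length(tracks))
    } else {
      unname(conditions[sample_ids])
    },
    row.names = sample_ids
  )
  se <- SummarizedExperiment(
    assays = assaysL, colData = cd,
    metadata = list(
      units = "counts",
      uorf_overlap_policy = uorfOverlapPolicy
    )
  )
  methods::new("RegionCountMatrix", se)
}

#' Convert a RegionCountMatrix to reads-per-million
#'
#' Scales every region layer by `1e6 / library_size` of its sample, where
#' the library size is the sample's total transcriptome-mapped P-site
#' count. RPM values are invariant under uniform scaling of a sample's
#' counts.
#'
#' @param x a [RegionCountMatrix] in count units.
#' @return A [RegionCountMatrix] with `metadata()$units == "rpm"`.
#' @export
toRpm <- function(x) {
  stopifnot(methods::is(x, "RegionCountMatrix"))
  ls <- libSizes(x)
  if (any(ls <= 0)) stop("zero library size; cannot convert to rpm")
  a <- assays(x)
  for (nm in names(a)) {
    a[[nm]] <- sweep(a[[nm]], 2L, ls / 1e6, "/")
  }
  se <- SummarizedExperiment(
    assays = a, colData = colData(x),
    metadata = c(
      metadata(x)[setdiff(names(metadata(x)), "units")],
      list(units = "rpm")
    )
  )
  methods::new("RegionCountMatrix", se)
}
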