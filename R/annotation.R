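#' Load transcript models from a GTF or transcript-table file
#'
#' Two input formats are supported. `format = "transcript_table"` reads a
#' TSV with header columns `transcript_id`, `gene_id`, `length`,
#' `cds_start`, `cds_end` and optional comma-separated uORF columns
#' `uorf_starts`, `uorf_ends`, `uorf_codons` (all coordinates 0-based
#' half-open transcript space; the CDS interval includes the stop codon).
#' `format = "gtf"` reads an Ensembl-dialect GTF (1-based inclusive
#' genomic coordinates), concatenates exons per transcript and projects
#' the CDS to transcript coordinates on either strand. For multi-isoform
#' GTFs the isoform tagged MANE/RefSeq Select is kept when present,
#' otherwise the longest CDS per gene.
#'
#' @param path input file.
#' @param format `"transcript_table"` or `"gtf"`.
#' @param sequences optional transcript FASTA path or named
#'   `DNAStringSet`.
#' @param singleIsoform keep one transcript per gene (default TRUE).
#' @return A validated [TranscriptomeSet].
#' @seealso [writeTranscriptTable()]
#' @export
loadAnnotation <- function(path, format = c("transcript_table", "gtf"),
                           sequences = NULL, singleIsoform = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (!is.null(sequences) && is.character(sequences) && length(sequences) == 1L) {
    sequences <- readDNAStringSet(sequences)
    names(sequences) <- sub("\\s.*$", "", names(sequences))
  }
  if (format == "transcript_table") {
    out <- .loadTranscriptTable(path, singleIsoform)
  } else {
    out <- .loadGtf(path, singleIsoform)
  }
  if (!is.null(sequences)) {
    out@seqs <- sequences
    methods::validObject(out)
  }
  out
}

.loadTranscriptTable <- function(path, singleIsoform) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("transcript_id", "gene_id", "length", "cds_start", "cds_end")
  if (!all(need %in% colnames(tab))) {
    stop(
      "transcript table must have columns: ",
      paste(need, collapse = ", ")
    )
  }
  for (col in c("length", "cds_start", "cds_end")) {
    v <- suppressWarnings(as.integer(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]))
    if (length(bad)) {
      stop(sprintf(
        "parse error in column '%s' at line %d of %s",
        col, bad[1L] + 1L, path
      ))
    }
    tab[[col]] <- v
  }
  uo <- NULL
  if (all(c("uorf_starts", "uorf_ends") %in% colnames(tab))) {
    rows <- which(!is.na(tab$uorf_starts) & nzchar(tab$uorf_starts))
    if (length(rows)) {
      parse_list <- function(x) lapply(strsplit(as.character(x), ","), as.integer)
      st <- parse_list(tab$uorf_starts[rows])
      en <- parse_list(tab$uorf_ends[rows])
      cod <- if ("uorf_codons" %in% colnames(tab)) {
        strsplit(as.character(tab$uorf_codons[rows]), ",")
      } else {
        lapply(lengths(st), function(k) rep("AUG", k))
      }
      if (any(lengths(st) != lengths(en))) {
        stop("uorf_starts and uorf_ends disagree in length")
      }
      uo <- data.frame(
        transcript_id = rep(tab$transcript_id[rows], lengths(st)),
        start = unlist(st), end = unlist(en),
        start_codon = unlist(cod)
      )
    }
  }
  TranscriptomeSet(tab[, need], uorfs = uo, singleIsoform = singleIsoform)
}

.loadGtf <- function(path, singleIsoform) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  if (!all(c("type", "transcript_id", "gene_id") %in% colnames(md))) {
    stop("GTF must carry type, transcript_id and gene_id attributes")
  }
  exons <- gr[md$type == "exon"]
  cds <- gr[md$type == "CDS"]
  if (!length(exons) || !length(cds)) {
    stop("GTF must contain exon and CDS features")
  }
  ex_by <- split(exons, S4Vectors::mcols(exons)$transcript_id)
  cds_by <- split(cds, S4Vectors::mcols(cds)$transcript_id)
  ids <- intersect(names(ex_by), names(cds_by))
  rows <- lapply(ids, function(id) {
    ex <- ex_by[[id]]
    strand <- as.character(BiocGenerics::strand(ex))[1L]
    ord <- order(BiocGenerics::start(ex),
      decreasing = (strand == "-")
    )
    ex <- ex[ord]
    ws <- BiocGenerics::width(ex)
    offs <- cumsum(c(0L, ws[-length(ws)]))
    proj <- function(g) { # genomic (1-based) -> transcript 0-based
      i <- which(g >= BiocGenerics::start(ex) & g <= BiocGenerics::end(ex))
      if (!length(i)) stop("CDS coordinate outside exons for ", id)
      i <- i[1L]
      if (strand == "-") {
        offs[i] + (BiocGenerics::end(ex)[i] - g)
      } else {
        offs[i] + (g - BiocGenerics::start(ex)[i])
      }
    }
    cg <- cds_by[[id]]
    glo <- min(BiocGenerics::start(cg))
    ghi <- max(BiocGenerics::end(cg))
    if (strand == "-") {
      cs <- proj(ghi)
      ce <- proj(glo) + 1L
    } else {
      cs <- proj(glo)
      ce <- proj(ghi) + 1L
    }
    data.frame(
      transcript_id = id,
      gene_id = as.character(S4Vectors::mcols(ex)$gene_id[1L]),
      length = sum(ws), cds_start = cs, cds_end = ce,
      tag = if ("tag" %in% colnames(S4Vectors::mcols(ex))) {
        paste(unlist(S4Vectors::mcols(ex)$tag), collapse = ";")
      } else {
        ""
      }
    )
  })
  tab <- do.call(rbind, rows)
  if (singleIsoform && anyDuplicated(tab$gene_id)) {
    preferred <- grepl("MANE|RefSeq Select", tab$tag)
    tab$cds_len <- tab$cds_end - tab$cds_start
    tab <- tab[order(tab$gene_id, -preferred, -tab$cds_len), , drop = FALSE]
    tab <- tab[!duplicated(tab$gene_id), , drop = FALSE]
  }
  TranscriptomeSet(
    tab[, c("transcript_id", "gene_id", "length", "cds_start", "cds_end")],
    singleIsoform = singleIsoform
  )
}

#' Write a TranscriptomeSet as a transcript-table TSV
#'
#' Inverse of `loadAnnotation(format = "transcript_table")`: writes the
#' model table with comma-list uORF columns.
#'
#' @param x a [TranscriptomeSet].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTranscriptTable <- function(x, path) {
  tab <- as.data.frame(transcripts(x))
  uo <- as.data.frame(uorfs(x))
  tab$uorf_starts <- ""
  tab$uorf_ends <- ""
  tab$uorf_codons <- ""
  if (nrow(uo)) {
    agg <- function(v, ids) {
      vapply(
        split(v, factor(ids, levels = tab$transcript_id)),
        function(z) paste(z, collapse = ","), ""
      )
    }
    tab$uorf_starts <- agg(uo$start, uo$transcript_id)
    tab$uorf_ends <- agg(uo$end, uo$transcript_id)
    tab$uorf_codons <- agg(uo$start_codon, uo$transcript_id)
  }
  write.table(tab, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
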