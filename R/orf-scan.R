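## ORF scanning over transcript/fragment sequences. T and U are treated as
## equivalent on input; coordinates are 0-based half-open.

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.normSeq <- function(sequence) {
  if (methods::is(sequence, "XString") || methods::is(sequence, "XStringSet")) {
    sequence <- as.character(sequence)
  }
  chartr("U", "T", toupper(sequence))
}

.normCodons <- function(codons) chartr("U", "T", toupper(codons))

## All codon 3-mers of a sequence string (1-based start positions).
.codonStrings <- function(s) {
  n <- nchar(s)
  if (n < 3L) {
    return(character())
  }
  substring(s, seq_len(n - 2L), seq_len(n - 2L) + 2L)
}

## Per-transcript ORF index: every start-codon position (0-based) with the
## end of its first in-frame stop (NA if the transcript has none in frame).
.orfIndex <- function(s, startCodons) {
  cods <- .codonStrings(s)
  starts0 <- which(cods %in% startCodons) - 1L
  stops0 <- which(cods %in% .STOP_CODONS) - 1L
  if (!length(starts0)) {
    return(list(starts = integer(), stop_end = integer()))
  }
  stop_end <- rep(NA_integer_, length(starts0))
  for (f in 0:2) {
    sf <- sort(stops0[stops0 %% 3L == f])
    sel <- which(starts0 %% 3L == f)
    if (!length(sel) || !length(sf)) next
    ## first stop strictly downstream of the start codon
    idx <- findInterval(starts0[sel], sf) + 1L
    ok <- idx <= length(sf)
    stop_end[sel[ok]] <- sf[idx[ok]] + 3L
  }
  list(starts = starts0, stop_end = stop_end)
}

#' Scan a sequence for open reading frames
#'
#' Finds every ORF that begins with one of `startCodons` and ends at the
#' first in-frame stop codon (UAA/UAG/UGA). An ORF without an in-frame
#' stop runs to the last complete codon of the sequence and is flagged
#' open-ended. Overlapping ORFs are all reported. T and U are equivalent.
#'
#' @param sequence character, `DNAString` or `RNAString`.
#' @param startCodons character vector of accepted start codons. The
#'   default includes the near-cognate starts CUG and GUG used by
#'   ISR-regulated uORFs alongside AUG.
#' @param minCodons minimum ORF length in codons, not counting the stop
#'   codon (start codon counts as one). Default 2.
#' @return data.frame with columns `start`, `end` (0-based half-open,
#'   `end` includes the stop codon when present), `start_codon` (as
#'   spelled in the input), `open_ended`, `n_codons`; sorted by `start`.
#' @examples
#' scanOrfs("AUGAAAUAA", startCodons = "AUG", minCodons = 1)
#' scanOrfs("CUGAAAUAA", startCodons = c("AUG", "CUG", "GUG"), minCodons = 1)
#' @export
scanOrfs <- function(sequence, startCodons = c("AUG", "CUG", "GUG"),
                     minCodons = 2L) {
  if (!length(startCodons)) stop("startCodons must be non-empty")
  if (minCodons < 1L) stop("minCodons must be >= 1")
  orig <- toupper(as.character(if (methods::is(sequence, "XString")) {
    as.character(sequence)
  } else {
    sequence
  }))
  s <- chartr("U", "T", orig)
  n <- nchar(s)
  if (n < 3L) stop("sequence must be at least 3 nt")
  idx <- .orfIndex(s, .normCodons(startCodons))
  if (!length(idx$starts)) {
    return(data.frame(
      start = integer(), end = integer(), start_codon = character(),
      open_ended = logical(), n_codons = integer()
    ))
  }
  start <- idx$starts
  open_ended <- is.na(idx$stop_end)
  end <- ifelse(open_ended, start + 3L * ((n - start) %/% 3L), idx$stop_end)
  n_codons <- ifelse(open_ended, (end - start) %/% 3L,
    (end - start) %/% 3L - 1L
  )
  keep <- which(n_codons >= minCodons)
  if (!length(keep)) {
    return(data.frame(
      start = integer(), end = integer(), start_codon = character(),
      open_ended = logical(), n_codons = integer()
    ))
  }
  out <- data.frame(
    start = as.integer(start[keep]), end = as.integer(end[keep]),
    start_codon = substring(orig, start[keep] + 1L, start[keep] + 3L),
    open_ended = open_ended[keep], n_codons = as.integer(n_codons[keep])
  )
  out[order(out$start), , drop = FALSE]
}

#' First available ORF on a 3' cleavage fragment
#'
#' Under the altORF-translation model, ribosomes loading onto a 3'
#' cleavage fragment initiate at the first available start codon. This
#' returns the ORF with the minimal start position among [scanOrfs()]
#' results (minimum length 1 codon), or `NULL` when the fragment carries
#' no start codon.
#'
#' @inheritParams scanOrfs
#' @return One-row data.frame as in [scanOrfs()], or `NULL`.
#' @examples
#' firstOrfOnFragment("GGAUGAAAUAGCUGCCCUAA")
#' @export
firstOrfOnFragment <- function(sequence, startCodons = c("AUG", "CUG", "GUG")) {
  orfs <- scanOrfs(sequence, startCodons = startCodons, minCodons = 1L)
  if (!nrow(orfs)) {
    return(NULL)
  }
  orfs[1L, , drop = FALSE]
}
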