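#' Construct a cleavage-specificity model
#'
#' @param preset `"rnasel_like"` (cuts 3' of UU and UA dinucleotides, the
#'   RNase L motifs), `"rnasea_like"` (cuts 3' of the pyrimidines U and C,
#'   RNase A specificity) or `"custom"` (supply `motifWeights`).
#' @param perSiteProbability probability that a candidate site in a single
#'   transcript copy is cut (for the motif of maximal weight; lesser
#'   motifs are scaled down proportionally).
#' @param motifWeights named non-negative numeric for `preset = "custom"`;
#'   motif names over A/C/G/T (or U), length 1 or 2.
#' @param name model name (defaults to the preset).
#' @return A [CleavageModel].
#' @examples
#' cleavageModel("rnasel_like", perSiteProbability = 0.02)
#' @export
cleavageModel <- function(preset = c("rnasel_like", "rnasea_like", "custom"),
                          perSiteProbability = 0.02, motifWeights = NULL,
                          name = NULL) {
  preset <- match.arg(preset)
  if (preset == "rnasel_like") {
    w <- c(TT = 1, TA = 1)
  } else if (preset == "rnasea_like") {
    w <- c(T = 1, C = 1)
  } else {
    if (is.null(motifWeights)) stop("custom preset requires motifWeights")
    w <- motifWeights
  }
  names(w) <- chartr("U", "T", toupper(names(w)))
  methods::new("CleavageModel",
    name = if (is.null(name)) preset else name,
    motifWeights = w, perSiteProbability = perSiteProbability
  )
}

#' Candidate endonucleolytic cleavage sites in a sequence
#'
#' Enumerates every motif match of a [CleavageModel] in a transcript
#' sequence. The cut point of a match is immediately 3' of the motif, so
#' a cut at position `c` (0-based) splits `[0, L)` into `[0, c)` and
#' `[c, L)`. Overlapping matches all count (UUU carries two UU sites).
#' Deterministic given sequence and model.
#'
#' @param sequence character, `DNAString` or `RNAString`.
#' @param model a [CleavageModel].
#' @return data.frame with columns `pos` (0-based cut point, in
#'   `1..nchar(sequence)`), `motif`, `weight` (normalised so the maximal
#'   motif weight is 1), sorted by `pos`.
#' @examples
#' findCleavageSites("UAUU", cleavageModel("rnasel_like"))
#' @export
findCleavageSites <- function(sequence, model) {
  stopifnot(methods::is(model, "CleavageModel"))
  s <- .normSeq(sequence)
  n <- nchar(s)
  if (n == 0L) stop("sequence must be non-empty")
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  w <- model@motifWeights / max(model@motifWeights)
  out <- vector("list", length(w))
  for (i in seq_along(w)) {
    m <- names(w)[i]
    if (w[i] == 0) next
    if (nchar(m) == 1L) {
      hit <- which(chars == m) # cut 3' of the base
      pos <- hit
    } else {
      m1 <- substr(m, 1L, 1L)
      m2 <- substr(m, 2L, 2L)
      hit <- which(chars[-n] == m1 & chars[-1L] == m2)
      pos <- hit + 1L
    }
    if (length(pos)) {
      out[[i]] <- data.frame(pos = pos, motif = m, weight = unname(w[i]))
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(data.frame(pos = integer(), motif = character(), weight = numeric()))
  }
  ## a position reachable via two motifs keeps the strongest one
  out <- out[order(out$pos, -out$weight), , drop = FALSE]
  out <- out[!duplicated(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
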