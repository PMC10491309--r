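#' Simulate motif-specific endonucleolytic fragmentation
#'
#' Each transcript copy is cut independently at every candidate motif site
#' (see [findCleavageSites()]) with probability
#' `perSiteProbability x normalised motif weight`. Consecutive cut points
#' partition a cut copy into fragments that inherit transcript
#' coordinates. Before decay, nucleotide mass is conserved exactly: the
#' summed fragment lengths plus intact mass equal `length x copies` per
#' transcript. Each fragment then survives decay independently with
#' probability `survival`.
#'
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param txset a [TranscriptomeSet] with sequences.
#' @param abundances named numeric: copies per transcript (names are
#'   transcript ids; integer-valued, >= 0).
#' @param model a [CleavageModel]. `perSiteProbability = 0` leaves every
#'   copy intact.
#' @param survival per-fragment survival probability (1 = no decay).
#' @param resistant transcript ids whose motifs are ignored
#'   (cleavage-resistant transcripts).
#' @return A [FragmentPool].
#' @export
simulateFragmentation <- function(txset, abundances, model, survival = 1,
                                  resistant = character()) {
  stopifnot(methods::is(txset, "TranscriptomeSet"))
  if (is.null(txSequences(txset))) stop("txset must carry sequences")
  if (any(abundances < 0)) stop("abundances must be >= 0")
  tx <- transcripts(txset)
  ids <- tx$transcript_id
  ab <- setNames(numeric(length(ids)), ids)
  ab[names(abundances)] <- abundances
  seqs <- as.character(txSequences(txset)[ids])
  lens <- setNames(tx$length, ids)

  intact <- ab
  frag_list <- vector("list", length(ids))
  p0 <- model@perSiteProbability
  for (j in seq_along(ids)) {
    id <- ids[j]
    n <- as.integer(round(ab[[id]]))
    if (n == 0L || p0 == 0 || id %in% resistant) next
    sites <- findCleavageSites(seqs[[id]], model)
    k <- nrow(sites)
    if (k == 0L) next
    L <- lens[[id]]
    p_site <- p0 * sites$weight
    ## copy x site Bernoulli cuts, laid out site-major
    hits <- which(runif(n * k) < rep(p_site, each = n))
    if (!length(hits)) next
    cp <- (hits - 1L) %% n + 1L
    si <- (hits - 1L) %/% n + 1L
    cuts <- data.table(copy = cp, pos = sites$pos[si])
    setorder(cuts, copy, pos)
    intact[id] <- n - uniqueN(cuts$copy)
    fr <- cuts[, .(start = c(0L, pos), end = c(pos, L)), by = copy]
    fr <- fr[start < end, .(copies_predecay = .N), by = .(start, end)]
    fr[, transcript_id := id]
    frag_list[[j]] <- fr
  }
  frags <- rbindlist(frag_list)
  if (nrow(frags)) {
    frags[, copies := rbinom(.N, copies_predecay, survival)]
    frags <- as.data.frame(frags[, .(
      transcript_id, start, end,
      copies_predecay, copies
    )])
  } else {
    frags <- data.frame(
      transcript_id = character(), start = integer(), end = integer(),
      copies_predecay = integer(), copies = integer()
    )
  }
  methods::new("FragmentPool",
    intact = intact, fragments = frags,
    survival = survival
  )
}

#' Nucleotide mass of a fragment pool
#'
#' Total nucleotide mass per transcript, either before fragment decay
#' (which must equal `length x copies` exactly) or after.
#'
#' @param pool a [FragmentPool].
#' @param txset the matching [TranscriptomeSet].
#' @param predecay use pre-decay fragment copies (default) or surviving.
#' @return named numeric, nt mass per transcript.
#' @export
poolMass <- function(pool, txset, predecay = TRUE) {
  tx <- transcripts(txset)
  lens <- setNames(as.numeric(tx$length), tx$transcript_id)
  mass <- lens * 0
  mass[names(pool@intact)] <- pool@intact * lens[names(pool@intact)]
  fr <- pool@fragments
  if (nrow(fr)) {
    cp <- if (predecay) fr$copies_predecay else fr$copies
    add <- tapply((fr$end - fr$start) * cp, fr$transcript_id, sum)
    mass[names(add)] <- mass[names(add)] + add
  }
  mass
}
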