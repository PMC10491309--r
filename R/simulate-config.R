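#' Configuration for a synthetic cleavage experiment
#'
#' Bundles every parameter of the generative model. The defaults describe
#' a two-condition (control vs treated), three-replicate experiment in
#' which the treatment cleaves mRNAs at RNase L-type motifs (UU/UA) with
#' per-site probability 0.02, removes 90% of bulk mRNA (within the
#' reported 60% to >99% range of RNase L-driven loss), transcriptionally
#' induces 5% of genes 20-fold, and re-initiates ribosomes on 30% of 3'
#' cleavage fragments.
#'
#' @param nGenes number of genes (one transcript each); >= 10.
#' @param replicates replicates per condition.
#' @param conditions condition names; the first is the control (no
#'   cleavage, no loss, no induction).
#' @param footprintDepth ribosome footprints per sample.
#' @param rnaseqDepth RNA-seq fragments per sample.
#' @param abundanceMeanlog,abundanceSdlog log-normal parameters of
#'   baseline transcript copy numbers.
#' @param globalLossFraction fraction of bulk mRNA lost in non-control
#'   conditions before cleavage is applied (transcriptome-wide decay).
#' @param inducedGeneFraction,inductionFactor fraction of genes that are
#'   transcriptionally induced in non-control conditions and their
#'   pre-cleavage abundance multiplier.
#' @param nTeShiftGenes,teShiftLog2 number of genes receiving an injected
#'   translation-efficiency shift in non-control conditions (half up,
#'   half down by `teShiftLog2` log2 units). Drawn from genes with
#'   baseline abundance above the median so the shift is measurable.
#' @param teShiftInductionFactor additional transcriptional induction
#'   applied to TE-shift genes (strongly regulated genes are typically
#'   also transcriptionally induced; 1 = none).
#' @param uorfGeneFraction fraction of genes carrying an annotated uORF.
#' @param uorfCdsOverlapFraction fraction of uORFs that extend past the
#'   main start codon into the CDS (ATF4-like overlap).
#' @param pUorfInitiation named numeric per condition: probability that a
#'   ribosome loading onto an intact uORF-bearing transcript initiates at
#'   the uORF rather than the main ORF.
#' @param cleavage a [CleavageModel] applied in `cleavageConditions`.
#' @param cleavageConditions conditions in which cleavage is active.
#' @param resistantGeneFraction fraction of genes resistant to cleavage
#'   (their motifs are ignored), emulating motif underrepresentation.
#' @param pFragmentReinitiation probability that a 3' fragment carrying
#'   CDS or 3'UTR sequence is ribosome-loaded on its first available ORF.
#' @param stallFraction fraction of fragment-borne footprints placed with
#'   the P-site at the last complete codon before the fragment 3' end
#'   (ribosomes running into the truncated end).
#' @param fragmentSurvival probability that a cleavage fragment escapes
#'   decay and remains in the sampled pool.
#' @param frameWeights length-3 probabilities of the P-site frame relative
#'   to the ORF reading frame (3-nt periodicity).
#' @param readLengths,readLengthProbs footprint length distribution.
#' @param psiteOffset nt between a read 5' end and the ribosome P-site.
#' @param backgroundFraction relative weight of positionally uniform
#'   background footprints per transcript.
#' @param replicateNoiseSd sd (log2) of the per-gene, per-replicate
#'   abundance multiplier (biological replicate noise).
#' @param utr5Range,cdsCodonsRange,utr3Range transcript architecture:
#'   uniform ranges for 5'UTR length (nt), CDS length (codons incl. stop)
#'   and 3'UTR length (nt).
#' @param mitoGeneFraction fraction of genes labelled with the "MT-"
#'   prefix (mitochondrial stratification in TE scatter plots).
#' @param seed root random seed for [generateExperiment()].
#' @return A validated list of class `SimulationConfig`.
#' @examples
#' cfg <- simulationConfig(nGenes = 50, footprintDepth = 1e4, rnaseqDepth = 1e4)
#' @export
simulationConfig <- function(nGenes = 2000L,
                             replicates = 3L,
                             conditions = c("control", "treated"),
                             footprintDepth = 2e6,
                             rnaseqDepth = 2e6,
                             abundanceMeanlog = log(50),
                             abundanceSdlog = 1,
                             globalLossFraction = 0.9,
                             inducedGeneFraction = 0.05,
                             inductionFactor = 20,
                             nTeShiftGenes = 0L,
                             teShiftLog2 = 2,
                             teShiftInductionFactor = 1,
                             uorfGeneFraction = 0.15,
                             uorfCdsOverlapFraction = 0.25,
                             pUorfInitiation = c(control = 0.8, treated = 0.8),
                             cleavage = cleavageModel("rnasel_like",
                               perSiteProbability = 0.02
                             ),
                             cleavageConditions = "treated",
                             resistantGeneFraction = 0,
                             pFragmentReinitiation = 0.3,
                             stallFraction = 0.2,
                             fragmentSurvival = 0.2,
                             frameWeights = c(0.70, 0.15, 0.15),
                             readLengths = 26:32,
                             readLengthProbs = c(
                               0.05, 0.10, 0.20, 0.30,
                               0.20, 0.10, 0.05
                             ),
                             psiteOffset = 12L,
                             backgroundFraction = 0.01,
                             replicateNoiseSd = 0.1,
                             utr5Range = c(60L, 300L),
                             cdsCodonsRange = c(100L, 500L),
                             utr3Range = c(150L, 600L),
                             mitoGeneFraction = 0.01,
                             seed = 1L) {
  cfg <- list(
    nGenes = as.integer(nGenes), replicates = as.integer(replicates),
    conditions = conditions, footprintDepth = footprintDepth,
    rnaseqDepth = rnaseqDepth, abundanceMeanlog = abundanceMeanlog,
    abundanceSdlog = abundanceSdlog,
    globalLossFraction = globalLossFraction,
    inducedGeneFraction = inducedGeneFraction,
    inductionFactor = inductionFactor,
    nTeShiftGenes = as.integer(nTeShiftGenes), teShiftLog2 = teShiftLog2,
    teShiftInductionFactor = teShiftInductionFactor,
    uorfGeneFraction = uorfGeneFraction,
    uorfCdsOverlapFraction = uorfCdsOverlapFraction,
    pUorfInitiation = pUorfInitiation, cleavage = cleavage,
    cleavageConditions = cleavageConditions,
    resistantGeneFraction = resistantGeneFraction,
    pFragmentReinitiation = pFragmentReinitiation,
    stallFraction = stallFraction, fragmentSurvival = fragmentSurvival,
    frameWeights = frameWeights, readLengths = as.integer(readLengths),
    readLengthProbs = readLengthProbs, psiteOffset = as.integer(psiteOffset),
    backgroundFraction = backgroundFraction,
    replicateNoiseSd = replicateNoiseSd,
    utr5Range = as.integer(utr5Range),
    cdsCodonsRange = as.integer(cdsCodonsRange),
    utr3Range = as.integer(utr3Range),
    mitoGeneFraction = mitoGeneFraction, seed = as.integer(seed)
  )
  class(cfg) <- c("SimulationConfig", "list")
  validateSimulationConfig(cfg)
  cfg
}

#' Validate a SimulationConfig
#'
#' @param cfg a `SimulationConfig` (or plain list with the same fields).
#' @return `cfg`, invisibly; stops on the first violated invariant.
#' @export
validateSimulationConfig <- function(cfg) {
  stopifnot(methods::is(cfg$cleavage, "CleavageModel"))
  if (cfg$nGenes < 10L) stop("nGenes must be >= 10")
  if (cfg$footprintDepth <= 0 || cfg$rnaseqDepth <= 0) {
    stop("sequencing depths must be positive")
  }
  if (cfg$replicates < 1L) stop("replicates must be >= 1")
  probs <- c(
    globalLossFraction = cfg$globalLossFraction,
    inducedGeneFraction = cfg$inducedGeneFraction,
    uorfGeneFraction = cfg$uorfGeneFraction,
    uorfCdsOverlapFraction = cfg$uorfCdsOverlapFraction,
    pFragmentReinitiation = cfg$pFragmentReinitiation,
    stallFraction = cfg$stallFraction,
    fragmentSurvival = cfg$fragmentSurvival,
    backgroundFraction = cfg$backgroundFraction,
    resistantGeneFraction = cfg$resistantGeneFraction,
    mitoGeneFraction = cfg$mitoGeneFraction,
    cfg$pUorfInitiation
  )
  bad <- probs < 0 | probs > 1
  if (any(bad)) {
    stop(
      "probabilities out of [0, 1]: ",
      paste(names(probs)[bad], collapse = ", ")
    )
  }
  if (cfg$globalLossFraction >= 1) stop("globalLossFraction must be < 1")
  if (!all(cfg$conditions %in% c(names(cfg$pUorfInitiation), NA)) &&
    length(cfg$pUorfInitiation) > 0) {
    missing <- setdiff(cfg$conditions, names(cfg$pUorfInitiation))
    if (length(missing)) {
      stop(
        "pUorfInitiation missing for condition(s): ",
        paste(missing, collapse = ", ")
      )
    }
  }
  if (length(cfg$frameWeights) != 3L || abs(sum(cfg$frameWeights) - 1) > 1e-8) {
    stop("frameWeights must be 3 probabilities summing to 1")
  }
  if (length(cfg$readLengths) != length(cfg$readLengthProbs)) {
    stop("readLengths and readLengthProbs must align")
  }
  if (cfg$psiteOffset < 0L) stop("psiteOffset must be >= 0")
  invisible(cfg)
}

## Serializable (S4-free) view of a config, for YAML/JSON output.
.configAsList <- function(cfg) {
  out <- unclass(cfg)
  out$cleavage <- list(
    name = cfg$cleavage@name,
    motif_weights = as.list(cfg$cleavage@motifWeights),
    per_site_probability = cfg$cleavage@perSiteProbability
  )
  out$pUorfInitiation <- as.list(cfg$pUorfInitiation)
  out
}
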