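#' Per-gene, per-sample translation efficiency
#'
#' TE is the CDS footprint rpm divided by the CDS RNA-seq rpm of the same
#' sample pairing — ribosome loading per transcript. Samples must match
#' column-for-column between the two assays. Genes with RNA rpm 0 in a
#' sample get `NA` TE there (undefined; tallied in the
#' `n_undefined` attribute).
#'
#' @param riboCdsRpm,rnaCdsRpm genes x samples matrices of CDS rpm, or
#'   [RegionCountMatrix] objects in rpm units (their `cds` assay is
#'   used). Row and column structure must match.
#' @return genes x samples TE matrix with attribute `n_undefined`.
#' @export
computeTE <- function(riboCdsRpm, rnaCdsRpm) {
  getm <- function(x) {
    if (methods::is(x, "RegionCountMatrix")) {
      if (!identical(metadata(x)$units, "rpm")) {
        stop("RegionCountMatrix input must be in rpm units")
      }
      assay(x, "cds")
    } else {
      as.matrix(x)
    }
  }
  ribo <- getm(riboCdsRpm)
  rna <- getm(rnaCdsRpm)
  if (!identical(dim(ribo), dim(rna))) {
    stop("ribo and rna matrices must have matching replicate structure")
  }
  if (!is.null(rownames(ribo)) && !is.null(rownames(rna))) {
    rna <- rna[rownames(ribo), , drop = FALSE]
  }
  te <- ribo / rna
  te[rna == 0] <- NA_real_
  attr(te, "n_undefined") <- sum(rna == 0)
  te
}

#' Classify translation-efficiency changes between conditions
#'
#' Applies the filter cascade used for TE scatter classification: a gene
#' is considered when its |log2 fold change| exceeds `lfcGate` in the
#' ribosome profiling or the RNA-seq contrast with the corresponding
#' adjusted p-value below `padjGate`, and its mean normalised count
#' exceeds `basemeanGate` in both assays. Considered genes are called
#' `te_up` when `delta_log2_te = log2fc_ribo - log2fc_rna` exceeds
#' `log2(teFoldGate)` (TE fold change beyond the diagonal gates),
#' `te_down` symmetrically, else `no_te_change`. Removed genes carry the
#' failing gate in `filter_trace`. Defaults are the conventional gates:
#' log2FC > 4, padj < 0.01, mean counts > 50, TE change > 2-fold.
#'
#' @param deRibo,deRna DE tables for the same contrast
#'   ([differentialExpression()] output) on footprint CDS counts and
#'   RNA-seq counts respectively.
#' @param lfcGate log2 fold-change gate (literal log2 scale).
#' @param padjGate adjusted-p gate.
#' @param basemeanGate normalised mean-count gate (both assays).
#' @param teFoldGate TE fold-change gate; the category threshold is
#'   `log2(teFoldGate)` on `delta_log2_te`.
#' @param mitoPrefix gene-id prefix tagging mitochondrially encoded genes
#'   in the output (scatter stratification).
#' @return `DataFrame`: `gene_id`, `log2fc_rna`, `log2fc_ribo`,
#'   `delta_log2_te`, `base_mean_rna`, `base_mean_ribo`, `mito`,
#'   `category` (te_up/te_down/no_te_change/filtered_out),
#'   `filter_trace` (NA, "lfc_padj_gate" or "basemean_gate").
#' @export
classifyTEChanges <- function(deRibo, deRna, lfcGate = 4, padjGate = 0.01,
                              basemeanGate = 50, teFoldGate = 2,
                              mitoPrefix = "MT-") {
  common <- intersect(deRibo$gene_id, deRna$gene_id)
  ribo <- deRibo[match(common, deRibo$gene_id), ]
  rna <- deRna[match(common, deRna$gene_id), ]
  pass_ribo <- abs(ribo$log2fc) > lfcGate & !is.na(ribo$padj) &
    ribo$padj < padjGate
  pass_rna <- abs(rna$log2fc) > lfcGate & !is.na(rna$padj) &
    rna$padj < padjGate
  considered <- pass_ribo | pass_rna
  pass_bm <- ribo$base_mean > basemeanGate & rna$base_mean > basemeanGate
  delta <- ribo$log2fc - rna$log2fc
  thr <- log2(teFoldGate)
  category <- rep("filtered_out", length(common))
  trace <- rep(NA_character_, length(common))
  trace[!considered] <- "lfc_padj_gate"
  trace[considered & !pass_bm] <- "basemean_gate"
  keep <- considered & pass_bm
  category[keep] <- ifelse(delta[keep] > thr, "te_up",
    ifelse(delta[keep] < -thr, "te_down", "no_te_change")
  )
  S4Vectors::DataFrame(
    gene_id = common,
    log2fc_rna = rna$log2fc, log2fc_ribo = ribo$log2fc,
    delta_log2_te = delta,
    base_mean_rna = rna$base_mean, base_mean_ribo = ribo$base_mean,
    mito = startsWith(common, mitoPrefix),
    category = category, filter_trace = trace
  )
}
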