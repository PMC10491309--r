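#' Median-of-ratios size factors
#'
#' The count-normalisation convention of the differential-expression
#' literature: each sample's factor is the median, over genes with
#' non-zero counts in every sample, of that sample's count divided by the
#' gene's geometric mean across samples.
#'
#' @param counts non-negative numeric matrix, genes x samples.
#' @return positive numeric vector of per-sample size factors.
#' @examples
#' computeSizeFactors(matrix(c(10, 100, 20, 200), ncol = 2))
#' @export
computeSizeFactors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allpos)) {
    stop(
      "no gene has non-zero counts in all samples; ",
      "consider a pseudo-reference fallback"
    )
  }
  lg <- rowMeans(log(counts[allpos, , drop = FALSE]))
  apply(counts[allpos, , drop = FALSE], 2L, function(cc) {
    median(exp(log(cc) - lg))
  })
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (monotone-enforced, capped at 1), realised via
#' `stats::p.adjust(method = "BH")` after input validation.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bhAdjust <- function(pvalues) {
  if (!length(pvalues)) stop("empty p-value vector")
  if (any(!is.na(pvalues) & (pvalues < 0 | pvalues > 1))) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Simplified differential-expression statistics
#'
#' A documented light-weight stand-in for a negative-binomial DE stage:
#' counts are normalised by median-of-ratios size factors, log2 fold
#' changes are differences of mean `log2(normalised + pseudocount)`
#' between groups, p-values come from a two-sided Welch t-test across
#' replicates, and adjustment is Benjamini-Hochberg. Externally computed
#' DE tables can be imported with [importExternalDE()] instead. A gene is
#' flagged DE when `padj < alpha` and `|log2fc| > lfcThreshold` (defaults
#' 0.05 and 1, the conventional thresholds for "upregulated DE genes").
#'
#' @param counts genes x samples matrix (rownames = gene ids).
#' @param conditions character vector of condition labels, one per
#'   column.
#' @param controlLabel,treatedLabel the contrast; log2fc is treated minus
#'   control. Each group needs >= 2 replicates.
#' @param pseudocount added before log transform (keeps zeros finite).
#' @param alpha,lfcThreshold DE flag thresholds.
#' @return `DataFrame` with `gene_id`, `base_mean` (mean normalised
#'   count), `log2fc`, `pvalue`, `padj`, `flag_de`.
#' @export
differentialExpression <- function(counts, conditions, controlLabel,
                                   treatedLabel, pseudocount = 0.5,
                                   alpha = 0.05, lfcThreshold = 1) {
  counts <- as.matrix(counts)
  if (length(conditions) != ncol(counts)) {
    stop("conditions must have one label per sample column")
  }
  sel <- conditions %in% c(controlLabel, treatedLabel)
  counts <- counts[, sel, drop = FALSE]
  conditions <- conditions[sel]
  nc <- sum(conditions == controlLabel)
  nt <- sum(conditions == treatedLabel)
  if (nc < 2L || nt < 2L) {
    stop("each group needs at least 2 replicates")
  }
  sf <- computeSizeFactors(counts)
  norm <- sweep(counts, 2L, sf, "/")
  l <- log2(norm + pseudocount)
  lc <- l[, conditions == controlLabel, drop = FALSE]
  lt <- l[, conditions == treatedLabel, drop = FALSE]
  mc <- rowMeans(lc)
  mt <- rowMeans(lt)
  vc <- apply(lc, 1L, var)
  vt <- apply(lt, 1L, var)
  lfc <- mt - mc
  se2 <- vc / nc + vt / nt
  tstat <- lfc / sqrt(se2)
  df <- se2^2 / ((vc / nc)^2 / (nc - 1L) + (vt / nt)^2 / (nt - 1L))
  pvalue <- 2 * pt(-abs(tstat), df)
  ## degenerate variance: identical groups -> 1; exact separation -> 0
  zero_se <- se2 == 0
  pvalue[zero_se & lfc == 0] <- 1
  pvalue[zero_se & lfc != 0] <- 0
  padj <- bhAdjust(pvalue)
  res <- S4Vectors::DataFrame(
    gene_id = rownames(counts), base_mean = unname(rowMeans(norm)),
    log2fc = unname(lfc), pvalue = unname(pvalue), padj = unname(padj),
    flag_de = unname(padj < alpha & abs(lfc) > lfcThreshold)
  )
  metadata(res) <- list(
    control = controlLabel, treated = treatedLabel,
    alpha = alpha, lfc_threshold = lfcThreshold,
    pseudocount = pseudocount, size_factors = sf
  )
  res
}

#' Import an externally computed differential-expression table
#'
#' Reads a TSV with columns `gene_id` (or `gene`), `log2fc` (or
#' `log2FoldChange`), `pvalue` and `padj` (optionally `base_mean` /
#' `baseMean`), e.g. the output of a negative-binomial DE package run by
#' the user, and re-derives the DE flag under the configured thresholds.
#'
#' @param path TSV file.
#' @param alpha,lfcThreshold DE flag thresholds.
#' @return `DataFrame` shaped like [differentialExpression()] output.
#' @export
importExternalDE <- function(path, alpha = 0.05, lfcThreshold = 1) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  pick <- function(...) {
    nm <- intersect(c(...), colnames(tab))
    if (!length(nm)) stop("missing column: ", paste(c(...), collapse = "/"))
    tab[[nm[1L]]]
  }
  res <- S4Vectors::DataFrame(
    gene_id = as.character(pick("gene_id", "gene")),
    base_mean = if (any(c("base_mean", "baseMean") %in% colnames(tab))) {
      as.numeric(pick("base_mean", "baseMean"))
    } else {
      NA_real_
    },
    log2fc = as.numeric(pick("log2fc", "log2FoldChange")),
    pvalue = as.numeric(pick("pvalue")),
    padj = as.numeric(pick("padj"))
  )
  res$flag_de <- !is.na(res$padj) & res$padj < alpha &
    abs(res$log2fc) > lfcThreshold
  metadata(res) <- list(alpha = alpha, lfc_threshold = lfcThreshold)
  res
}

#' Gene-set fold-change summaries with paired tests
#'
#' Restricts each contrast's log2 fold changes to a gene set (the data
#' behind per-set violin plots) and runs a paired two-sided t-test on
#' every contrast pair, pairing by gene on the genes present in both.
#' Pairs whose differences have zero variance are flagged degenerate and
#' get no p-value.
#'
#' @param deList named list (>= 2) of DE result tables
#'   ([differentialExpression()] output).
#' @param geneSet character vector of gene ids; at least 3 must be
#'   measured in every contrast.
#' @return list with `values` (data.frame contrast/gene_id/log2fc) and
#'   `tests` (data.frame contrast_a, contrast_b, n, mean_difference,
#'   p_value, degenerate).
#' @export
genesetSummary <- function(deList, geneSet) {
  if (length(deList) < 2L || is.null(names(deList))) {
    stop("deList must be a named list of at least 2 contrasts")
  }
  vals <- lapply(names(deList), function(nm) {
    de <- deList[[nm]]
    sub <- de[de$gene_id %in% geneSet, , drop = FALSE]
    if (nrow(sub) < 3L) {
      stop("fewer than 3 gene-set genes measured in contrast ", nm)
    }
    data.frame(
      contrast = nm, gene_id = sub$gene_id,
      log2fc = sub$log2fc
    )
  })
  values <- do.call(rbind, vals)
  pairs <- utils::combn(names(deList), 2L)
  tests <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]
    b <- pairs[2L, k]
    va <- values[values$contrast == a, ]
    vb <- values[values$contrast == b, ]
    common <- intersect(va$gene_id, vb$gene_id)
    if (length(common) < 3L) {
      stop("fewer than 3 paired genes for ", a, " vs ", b)
    }
    d <- vb$log2fc[match(common, vb$gene_id)] -
      va$log2fc[match(common, va$gene_id)]
    degenerate <- isTRUE(all.equal(var(d), 0)) || var(d) == 0
    data.frame(
      contrast_a = a, contrast_b = b, n = length(common),
      mean_difference = mean(d),
      p_value = if (degenerate) NA_real_ else t.test(d)$p.value,
      degenerate = degenerate
    )
  })
  list(values = values, tests = do.call(rbind, tests))
}

#' Correlate log2 fold changes between two contrasts
#'
#' Pearson correlation of paired per-gene log2 fold changes on a gene
#' subset chosen by DE status, mirroring sequential-filtering comparisons
#' between treatments.
#'
#' @param deA,deB DE result tables sharing gene ids.
#' @param selection which genes enter: DE-flagged in A, in B, in either,
#'   or specifically not DE-flagged in A.
#' @return list with `r`, `r_squared`, `n`, `selection`.
#' @export
correlateChanges <- function(deA, deB,
                             selection = c(
                               "de_in_A", "de_in_B", "de_in_either",
                               "below_threshold_in_A"
                             )) {
  selection <- match.arg(selection)
  common <- intersect(deA$gene_id, deB$gene_id)
  a <- deA[match(common, deA$gene_id), ]
  b <- deB[match(common, deB$gene_id), ]
  keep <- switch(selection,
    de_in_A = a$flag_de,
    de_in_B = b$flag_de,
    de_in_either = a$flag_de | b$flag_de,
    below_threshold_in_A = !a$flag_de
  )
  keep <- keep & !is.na(a$log2fc) & !is.na(b$log2fc)
  if (sum(keep) < 3L) stop("fewer than 3 genes selected")
  r <- cor(a$log2fc[keep], b$log2fc[keep])
  list(r = r, r_squared = r^2, n = sum(keep), selection = selection)
}
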