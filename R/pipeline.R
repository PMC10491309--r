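#' Run the full analysis pipeline from one configuration
#'
#' Orchestrates simulate (or load) -> P-site assignment -> region
#' counting -> UTR:ORF ratios and metagene profiles -> differential
#' expression (RNA-seq and footprint CDS counts) -> TE classification ->
#' uORF shift analysis, and collects a machine-readable summary. Given
#' the same configuration and seed the summary is reproducible.
#'
#' The configuration is a YAML file path or an equivalent nested list
#' with either a `simulate` block (arguments to [simulationConfig()]) or
#' an `inputs` block (`transcripts` TSV, `fasta`, `samples` TSV with
#' sample_id/condition, `footprints` directory of
#' `footprints_<sample>.bed`, `rnaseq` counts TSV), plus optional
#' `contrast` (`control`/`treated` condition labels), `thresholds`
#' (`psite_offset`, `min_cds_rpm`, `min_cds_density`, `alpha`,
#' `lfc_threshold`, `te_lfc_gate`, `te_padj_gate`, `te_basemean_gate`,
#' `te_fold_gate`, `uorf_overlap_policy`), `seed` and `out_dir`.
#'
#' @param config YAML path or list (see details).
#' @return list with `txset`, `tracks`, `regions` (counts), `rpm`,
#'   `ratios`, `metagene`, `de_rna`, `de_ribo`, `te`, `te_classes`,
#'   `uorf_shift`, `summary` (list also written as JSON when `out_dir`
#'   is set), and `truth` for simulated runs.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  has_sim <- !is.null(config$simulate)
  has_inputs <- !is.null(config$inputs)
  if (!has_sim && !has_inputs) {
    stop("config must provide either a 'simulate' or an 'inputs' block")
  }
  thr <- config$thresholds
  thr_get <- function(nm, default) if (is.null(thr[[nm]])) default else thr[[nm]]
  offset <- thr_get("psite_offset", 12L)
  policy <- thr_get("uorf_overlap_policy", "overlap_to_utr")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  ## ---- data stage -------------------------------------------------------
  truth <- NULL
  if (has_sim) {
    sim <- config$simulate
    simcfg <- if (methods::is(sim, "SimulationConfig")) {
      sim
    } else {
      do.call(simulationConfig, c(sim, list(seed = seed)))
    }
    exp <- generateExperiment(simcfg)
    txset <- exp$txset
    truth <- exp$truth
    footprints <- exp$footprints
    rnaseq <- exp$rnaseq
    samples <- exp$samples
  } else {
    inp <- config$inputs
    txset <- loadAnnotation(inp$transcripts,
      format = "transcript_table",
      sequences = inp$fasta
    )
    samples <- read.delim(inp$samples, stringsAsFactors = FALSE)
    footprints <- lapply(samples$sample_id, function(s) {
      readFootprints(file.path(inp$footprints, paste0(
        "footprints_", s,
        ".bed"
      )))
    })
    names(footprints) <- samples$sample_id
    rn <- read.delim(inp$rnaseq, check.names = FALSE)
    rnaseq <- as.matrix(rn[, -1, drop = FALSE])
    rownames(rnaseq) <- rn[[1L]]
  }
  conditions <- setNames(samples$condition, samples$sample_id)
  contrast <- config$contrast
  control <- if (is.null(contrast$control)) {
    unique(samples$condition)[1L]
  } else {
    contrast$control
  }
  treated <- if (is.null(contrast$treated)) {
    setdiff(unique(samples$condition), control)[1L]
  } else {
    contrast$treated
  }

  ## ---- footprint processing --------------------------------------------
  tracks <- lapply(names(footprints), function(s) {
    assignPsites(footprints[[s]], txset, offset = offset, sampleId = s)
  })
  names(tracks) <- names(footprints)
  regions <- countRegions(tracks, txset,
    uorfOverlapPolicy = policy,
    conditions = conditions
  )
  rpm <- toRpm(regions)

  ## ---- altORF statistics -----------------------------------------------
  min_cds_rpm <- thr_get("min_cds_rpm", 1)
  ratios <- rbind(
    utrOrfRatio(rpm, "utr3", "aggregate", minCdsRpm = min_cds_rpm),
    utrOrfRatio(rpm, "utr5", "aggregate", minCdsRpm = min_cds_rpm)
  )
  metagene <- lapply(tracks, function(t) {
    tryCatch(
      metageneProfile(t, txset,
        anchor = "stop_codon",
        minCdsDensity = thr_get("min_cds_density", 0.5)
      ),
      error = function(e) NULL
    )
  })

  ## ---- differential expression and TE ----------------------------------
  alpha <- thr_get("alpha", 0.05)
  lfc_thr <- thr_get("lfc_threshold", 1)
  ribo_cds <- assay(regions, "cds")
  de_rna <- differentialExpression(rnaseq, conditions[colnames(rnaseq)],
    control, treated,
    alpha = alpha, lfcThreshold = lfc_thr
  )
  de_ribo <- differentialExpression(
    ribo_cds, conditions[colnames(ribo_cds)],
    control, treated,
    alpha = alpha, lfcThreshold = lfc_thr
  )
  rna_rpm <- sweep(rnaseq, 2L, colSums(rnaseq) / 1e6, "/")
  te <- computeTE(
    assay(rpm, "cds"),
    rna_rpm[rownames(rpm), colnames(rpm), drop = FALSE]
  )
  te_classes <- classifyTEChanges(de_ribo, de_rna,
    lfcGate = thr_get("te_lfc_gate", 4),
    padjGate = thr_get("te_padj_gate", 0.01),
    basemeanGate = thr_get("te_basemean_gate", 50),
    teFoldGate = thr_get("te_fold_gate", 2)
  )

  ## ---- uORF shift -------------------------------------------------------
  uorf_genes <- unique(transcripts(txset)$gene_id[
    transcripts(txset)$transcript_id %in% uorfs(txset)$transcript_id
  ])
  uorf_shift <- NULL
  cs <- names(conditions)[conditions == control]
  ts <- names(conditions)[conditions == treated]
  if (length(uorf_genes) && length(cs) >= 2L && length(ts) >= 2L) {
    uorf_shift <- utr5MainShift(rpm, cs, ts, genes = uorf_genes)
  }

  ## ---- summary ----------------------------------------------------------
  agg3 <- ratios[ratios$which == "utr3", ]
  summary <- list(
    seed = seed,
    n_genes = nrow(regions),
    samples = as.list(setNames(samples$condition, samples$sample_id)),
    discarded_reads = lapply(tracks, discardedReads),
    utr3_orf_ratio = as.list(setNames(agg3$ratio, agg3$sample_id)),
    utr3_orf_ratio_by_condition = lapply(
      split(agg3$ratio, conditions[agg3$sample_id]), mean
    ),
    de_genes_up = sum(de_rna$flag_de & de_rna$log2fc > 0, na.rm = TRUE),
    de_genes_down = sum(de_rna$flag_de & de_rna$log2fc < 0, na.rm = TRUE),
    te_categories = as.list(table(te_classes$category)),
    mean_uorf_log2_shift = if (is.null(uorf_shift)) {
      NA
    } else {
      mean(uorf_shift$log2_shift[is.finite(uorf_shift$log2_shift)])
    },
    thresholds = list(
      psite_offset = offset, min_cds_rpm = min_cds_rpm,
      alpha = alpha, lfc_threshold = lfc_thr,
      uorf_overlap_policy = policy
    )
  )

  out <- list(
    txset = txset, truth = truth, tracks = tracks, regions = regions,
    rpm = rpm, ratios = ratios, metagene = metagene, de_rna = de_rna,
    de_ribo = de_ribo, te = te, te_classes = te_classes,
    uorf_shift = uorf_shift, summary = summary
  )
  if (!is.null(config$out_dir)) {
    out$paths <- .writePipelineOutputs(out, config$out_dir)
  }
  out
}

.writePipelineOutputs <- function(out, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, nm) {
    p <- file.path(outDir, nm)
    write.table(as.data.frame(df), p,
      sep = "\t", quote = FALSE,
      row.names = FALSE
    )
    p
  }
  paths <- list(
    ratios = w(out$ratios, "utr_orf_ratios.tsv"),
    de_rna = w(out$de_rna, "de_rnaseq.tsv"),
    de_ribo = w(out$de_ribo, "de_ribo_cds.tsv"),
    te_classes = w(out$te_classes, "te_classification.tsv"),
    summary = file.path(outDir, "summary.json")
  )
  if (!is.null(out$uorf_shift)) {
    paths$uorf_shift <- w(out$uorf_shift, "uorf_shift.tsv")
  }
  mg <- Filter(Negate(is.null), out$metagene)
  if (length(mg)) {
    mgdf <- do.call(rbind, lapply(names(mg), function(s) {
      cbind(sample_id = s, mg[[s]])
    }))
    paths$metagene <- w(mgdf, "metagene_stop.tsv")
  }
  jsonlite::write_json(out$summary, paths$summary,
    auto_unbox = TRUE,
    digits = 10, pretty = TRUE
  )
  paths
}
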