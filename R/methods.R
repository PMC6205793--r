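#' @rdname MethylExperiment
#' @export
setMethod("betaValues", "MethylExperiment", function(x) assay(x, "beta"))

#' @rdname MethylExperiment
#' @export
setMethod("mValues", "MethylExperiment", function(x, eps = 1e-6) {
  betaToM(assay(x, "beta"), eps = eps)
})

#' @rdname MethylExperiment
#' @export
setMethod("sampleSheet", "MethylExperiment", function(x) {
  as.data.frame(colData(x))
})

#' @rdname MethylExperiment
#' @export
setMethod("probeAnnotation", "MethylExperiment", function(x) {
  if (ncol(rowData(x)) == 0L) return(NULL)
  as.data.frame(rowData(x))
})

setMethod("show", "MethylExperiment", function(object) {
  b <- assay(object, "beta")
  cat("MethylExperiment:", nrow(b), "CpGs x", ncol(b), "samples\n")
  tis <- colData(object)$tissue
  if (!is.null(tis)) {
    tab <- table(tis)
    cat("  tissues:", paste(sprintf("%s (%d)", names(tab), tab),
                            collapse = ", "), "\n")
  }
  aca <- colData(object)$aca_status
  if (!is.null(aca)) {
    tab <- table(aca, useNA = "ifany")
    cat("  aCA status:", paste(sprintf("%s (%d)", names(tab), tab),
                               collapse = ", "), "\n")
  }
  cat("  missing beta:", sum(is.na(b)), "entries\n")
})

#' @rdname DMResult
#' @export
setMethod("dmTable", "DMResult", function(x) x@results)

#' @rdname DMResult
#' @export
setMethod("dmCpGs", "DMResult", function(x) {
  x@results$cpg_id[which(x@results$dm_call)]
})

setMethod("show", "DMResult", function(object) {
  r <- object@results
  called <- which(r$dm_call)
  hyper <- sum(r$delta_beta[called] > 0)
  cat(sprintf(
    "DMResult: %d CpGs tested; %d DM at FDR < %g & |delta beta| > %g (%d hyper / %d hypo)\n",
    nrow(r), length(called), object@fdrMax, object@deltaBetaMin,
    hyper, length(called) - hyper))
  if (!is.null(object@design$moderation))
    cat("  moderation:", object@design$moderation, "\n")
})

#' @rdname CellSignature
#' @export
setMethod("signatureCpGs", "CellSignature", function(x) x@cpgIds)

setMethod("show", "CellSignature", function(object) {
  cat(sprintf(
    "CellSignature: %d CpGs specific to %s (FDR < %g, |delta beta| > %g, %d contrasts)\n",
    length(object@cpgIds), object@cellType,
    object@thresholds[["fdr_max"]], object@thresholds[["delta_beta_min"]],
    length(object@evidence)))
})

setMethod("show", "ClusterReport", function(object) {
  cat(sprintf("ClusterReport: %d samples, %d internal nodes\n",
              length(object@assignments), nrow(object@nodes)))
  cat(sprintf("  k = 2 split: %d vs %d samples, split p = %.4g\n",
              sum(object@assignments == 1L), sum(object@assignments == 2L),
              object@splitP))
  if (!is.null(object@enrichment$p))
    cat(sprintf("  phenotype enrichment (Fisher): p = %.4g\n",
                object@enrichment$p))
})

setMethod("show", "BatchModel", function(object) {
  cat(sprintf("BatchModel: '%s' with %d batches, %d features\n",
              object@batchVariable, length(object@batches),
              ncol(object@gammaStar)))
})

setMethod("show", "MdsResult", function(object) {
  cat(sprintf("MdsResult: %d samples, k = %d coordinates\n",
              nrow(object@coordinates), object@k))
})

setMethod("show", "OverlapTest", function(object) {
  cat(sprintf(
    "OverlapTest: %d/%d query CpGs DM in target (background %d, target DM %d)\n",
    object@kObs, object@m, object@N, object@K))
  cat(sprintf("  empirical p = %.4g (%d draws); hypergeometric p = %.4g\n",
              object@empiricalP, object@nDraws, object@hypergeomP))
})

setMethod("show", "ConcordanceResult", function(object) {
  cat(sprintf(
    "ConcordanceResult: %d/%d sites concordant (%.1f%%); binomial p = %.3g, empirical p = %.3g\n",
    object@nConcordant, object@nEvaluable, 100 * object@fraction,
    object@binomialP, object@empiricalP))
})
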