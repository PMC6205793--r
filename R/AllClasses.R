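#' MethylExperiment: CpG-by-sample methylation container
#'
#' An S4 container for array methylation data, extending
#' \linkS4class{SummarizedExperiment}. The `"beta"` assay holds beta values
#' (methylated fraction) in `[0, 1]` with `NA` for missing measurements;
#' `colData` is the sample sheet (tissue, aCA status, gestational age, fetal
#' sex, ancestry coordinates, chip and chip-row batch, optional
#' `replicate_group` / `individual_id`), and `rowData` carries the probe
#' annotation (chromosome, 1-based position, gene symbols, region class and
#' blocklist flags).
#'
#' @aliases MethylExperiment-class
#' @exportClass MethylExperiment
setClass("MethylExperiment", contains = "SummarizedExperiment")

.validate_methyl_experiment <- function(object) {
  msg <- character(0)
  if (!("beta" %in% names(assays(object))))
    msg <- c(msg, "assay 'beta' is required")
  else {
    b <- assay(object, "beta")
    bad <- which(!is.na(b) & (b < 0 | b > 1))
    if (length(bad)) {
      i <- arrayInd(bad[1L], dim(b))
      msg <- c(msg, sprintf(
        "beta values must lie in [0, 1] or be NA; first offender at CpG '%s', sample '%s' (value %g)",
        rownames(b)[i[1L]], colnames(b)[i[2L]], b[bad[1L]]))
    }
    if (is.null(rownames(b)) || anyDuplicated(rownames(b)))
      msg <- c(msg, "CpG ids (rownames) must be present and unique")
    if (is.null(colnames(b)) || anyDuplicated(colnames(b)))
      msg <- c(msg, "sample ids (colnames) must be present and unique")
  }
  if (length(msg)) msg else TRUE
}

setValidity("MethylExperiment", .validate_methyl_experiment)

#' Construct a MethylExperiment
#'
#' @param beta numeric matrix of beta values (CpGs in rows, samples in
#'   columns) with CpG ids as rownames and sample ids as colnames.
#' @param sampleSheet `data.frame` of per-sample covariates with a
#'   `sample_id` column matching `colnames(beta)` (order may differ; rows are
#'   aligned to the matrix).
#' @param probeAnnotation optional `data.frame` of probe annotation with a
#'   `cpg_id` column; aligned to `rownames(beta)`. CpGs absent from the
#'   annotation get `NA` rows.
#'
#' @return A [MethylExperiment-class] object.
#' @export
MethylExperiment <- function(beta, sampleSheet, probeAnnotation = NULL) {
  beta <- as.matrix(beta)
  if (is.null(colnames(beta)) || is.null(rownames(beta)))
    .stopf("beta matrix must carry CpG rownames and sample colnames")
  sampleSheet <- as.data.frame(sampleSheet)
  if (!"sample_id" %in% names(sampleSheet))
    .stopf("sampleSheet must have a 'sample_id' column")
  if (anyDuplicated(sampleSheet$sample_id))
    .stopf("duplicate sample_id in sample sheet: '%s'",
           sampleSheet$sample_id[duplicated(sampleSheet$sample_id)][1L])
  missing_in_sheet <- setdiff(colnames(beta), sampleSheet$sample_id)
  if (length(missing_in_sheet))
    .stopf("sample '%s' present in beta matrix but absent from sample sheet",
           missing_in_sheet[1L])
  extra_in_sheet <- setdiff(sampleSheet$sample_id, colnames(beta))
  if (length(extra_in_sheet))
    .stopf("sample '%s' present in sample sheet but absent from beta matrix",
           extra_in_sheet[1L])
  sampleSheet <- sampleSheet[match(colnames(beta), sampleSheet$sample_id), ,
                             drop = FALSE]
  rownames(sampleSheet) <- sampleSheet$sample_id
  rd <- NULL
  if (!is.null(probeAnnotation)) {
    probeAnnotation <- as.data.frame(probeAnnotation)
    if (!"cpg_id" %in% names(probeAnnotation))
      .stopf("probeAnnotation must have a 'cpg_id' column")
    if (anyDuplicated(probeAnnotation$cpg_id))
      .stopf("duplicate cpg_id in probe annotation: '%s'",
             probeAnnotation$cpg_id[duplicated(probeAnnotation$cpg_id)][1L])
    if (any(!is.na(probeAnnotation$position) & probeAnnotation$position < 1))
      .stopf("probe positions are 1-based and must be >= 1")
    rd <- probeAnnotation[match(rownames(beta), probeAnnotation$cpg_id), ,
                          drop = FALSE]
    rd$cpg_id <- rownames(beta)
    rownames(rd) <- rownames(beta)
  }
  se <- SummarizedExperiment(
    assays = list(beta = beta),
    colData = DataFrame(sampleSheet),
    rowData = if (is.null(rd)) NULL else DataFrame(rd))
  new("MethylExperiment", se)
}

#' Per-CpG differential methylation result
#'
#' Holds the per-CpG model output of an EWAS run: primary-term coefficient,
#' standard error, (possibly moderated) t statistic and degrees of freedom,
#' p value, BH-FDR q value, the group difference in mean beta (delta beta,
#' aCA minus non-aCA by convention) and the DM call at the recorded
#' thresholds (`dm_call` is true iff `q < fdrMax` and
#' `|delta_beta| > deltaBetaMin`).
#'
#' @slot results `data.frame` with columns `cpg_id`, `estimate`, `se`, `t`,
#'   `df`, `p`, `q`, `delta_beta`, `dm_call`.
#' @slot fdrMax,deltaBetaMin thresholds used for DM calling.
#' @slot design list describing the fitted design (primary term, covariates,
#'   response scale, moderation, shrinkage hyperparameters).
#' @aliases DMResult-class
#' @exportClass DMResult
setClass("DMResult", representation(
  results = "data.frame",
  fdrMax = "numeric",
  deltaBetaMin = "numeric",
  design = "list"))

setValidity("DMResult", function(object) {
  r <- object@results
  need <- c("cpg_id", "estimate", "se", "t", "df", "p", "q", "delta_beta",
            "dm_call")
  if (!all(need %in% names(r)))
    return(sprintf("results must have columns: %s",
                   paste(setdiff(need, names(r)), collapse = ", ")))
  q <- r$q[!is.na(r$q)]
  if (length(q) && (min(q) < 0 || max(q) > 1))
    return("q values must lie in [0, 1]")
  ok <- !is.na(r$q) & !is.na(r$delta_beta)
  expected <- r$q[ok] < object@fdrMax &
    abs(r$delta_beta[ok]) > object@deltaBetaMin
  if (!identical(as.logical(r$dm_call[ok]), as.logical(expected)))
    return("dm_call must equal (q < fdrMax & |delta_beta| > deltaBetaMin)")
  TRUE
})

#' Immune cell-type-specific CpG signature
#'
#' The CpG set specific to one immune cell type, derived as the intersection
#' of DM sets across all pairwise contrasts of that type against chorionic
#' villi and against every other immune class.
#'
#' @slot cellType target cell type (e.g. `"neutrophil"`).
#' @slot cpgIds character vector of signature CpG ids (possibly empty).
#' @slot evidence named list, one `data.frame` per contrast with columns
#'   `cpg_id`, `q`, `delta_beta` restricted to the signature CpGs.
#' @slot thresholds named numeric `c(fdr_max=, delta_beta_min=)`.
#' @aliases CellSignature-class
#' @exportClass CellSignature
setClass("CellSignature", representation(
  cellType = "character",
  cpgIds = "character",
  evidence = "list",
  thresholds = "numeric"))

#' Clustering report with bootstrap stability and enrichment
#'
#' @slot tree the `hclust` tree of samples.
#' @slot nodes `data.frame` of internal nodes with columns `node`,
#'   `n_leaves`, `members`, `bp`, `au`, `flag`.
#' @slot splitP Monte-Carlo p value for the k = 2 split (cluster-index null).
#' @slot assignments named integer vector of k = 2 cluster memberships.
#' @slot enrichment list with the 2 x 2 phenotype table, Fisher p and
#'   per-cluster demographic comparisons.
#' @aliases ClusterReport-class
#' @exportClass ClusterReport
setClass("ClusterReport", representation(
  tree = "ANY",
  nodes = "data.frame",
  splitP = "numeric",
  assignments = "integer",
  enrichment = "list"))

setValidity("ClusterReport", function(object) {
  nd <- object@nodes
  for (col in c("bp", "au")) {
    v <- nd[[col]][!is.na(nd[[col]])]
    if (length(v) && (min(v) < 0 || max(v) > 1))
      return(sprintf("%s values must lie in [0, 1]", toupper(col)))
  }
  if (length(object@assignments) &&
      !all(object@assignments %in% c(1L, 2L)))
    return("k = 2 assignments must partition all samples into clusters 1/2")
  TRUE
})

#' Empirical-Bayes batch adjustment model
#'
#' Per-feature batch location (gamma) and scale (delta) estimates with their
#' empirical-Bayes shrunken values and the method-of-moments hyperpriors
#' (normal for locations, inverse-gamma for squared scales).
#'
#' @slot batchVariable name of the batch column adjusted for.
#' @slot batches batch level names.
#' @slot gammaHat,gammaStar batch x feature location estimates (raw, EB).
#' @slot deltaHat,deltaStar batch x feature scale estimates (raw, EB).
#' @slot hyper list of per-batch hyperparameters
#'   (`gamma_bar`, `tau2`, `a_prior`, `b_prior`).
#' @aliases BatchModel-class
#' @exportClass BatchModel
setClass("BatchModel", representation(
  batchVariable = "character",
  batches = "character",
  gammaHat = "matrix",
  gammaStar = "matrix",
  deltaHat = "matrix",
  deltaStar = "matrix",
  hyper = "list"))

setValidity("BatchModel", function(object) {
  if (any(object@deltaStar <= 0)) return("delta estimates must be > 0")
  TRUE
})

#' Classical MDS result
#'
#' @slot coordinates samples x k coordinate matrix (columns scaled by the
#'   square root of the corresponding eigenvalue; column means ~ 0).
#' @slot eigenvalues eigenvalues of the double-centered squared-distance
#'   matrix, non-increasing.
#' @slot k number of coordinates retained.
#' @aliases MdsResult-class
#' @exportClass MdsResult
setClass("MdsResult", representation(
  coordinates = "matrix",
  eigenvalues = "numeric",
  k = "integer"))

#' DM-set overlap test against a resampling null
#'
#' @slot m query set size; @slot N background size; @slot K DM count in the
#'   target tissue; @slot kObs observed overlap; @slot nDraws random draws;
#'   @slot empiricalP add-one-corrected resampling p;
#'   @slot hypergeomP exact hypergeometric upper tail P(X >= kObs).
#' @aliases OverlapTest-class
#' @exportClass OverlapTest
setClass("OverlapTest", representation(
  m = "integer", N = "integer", K = "integer", kObs = "integer",
  nDraws = "integer", empiricalP = "numeric", hypergeomP = "numeric"))

setValidity("OverlapTest", function(object) {
  if (object@kObs > min(object@m, object@K))
    return("observed overlap cannot exceed min(query size, target DM count)")
  if (object@empiricalP <= 0 || object@empiricalP > 1)
    return("empirical p must lie in (0, 1]")
  TRUE
})

#' Trend-concordance result
#'
#' @slot nEvaluable sites with defined, nonzero directions in both datasets;
#'   @slot nConcordant sites whose aCA-vs-non-aCA and cell-vs-non-aCA
#'   directions agree; @slot fraction `nConcordant / nEvaluable`;
#'   @slot binomialP upper-tail binomial p under a 0.5 null;
#'   @slot empiricalP p from random same-size CpG sets;
#'   @slot directions per-site direction table.
#' @aliases ConcordanceResult-class
#' @exportClass ConcordanceResult
setClass("ConcordanceResult", representation(
  nEvaluable = "integer", nConcordant = "integer", fraction = "numeric",
  binomialP = "numeric", empiricalP = "numeric", directions = "data.frame"))

setValidity("ConcordanceResult", function(object) {
  if (object@nConcordant > object@nEvaluable)
    return("nConcordant cannot exceed nEvaluable")
  if (object@nEvaluable > 0 &&
      abs(object@fraction - object@nConcordant / object@nEvaluable) > 1e-12)
    return("fraction must equal nConcordant / nEvaluable")
  TRUE
})
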