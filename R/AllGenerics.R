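#' @rdname MethylExperiment
#' @param x,object a [MethylExperiment-class] (or result object, for the
#'   result accessors).
#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))

#' @rdname MethylExperiment
#' @param eps clipping epsilon applied before the logit when beta values hit
#'   0 or 1 exactly.
#' @export
setGeneric("mValues", function(x, eps = 1e-6) standardGeneric("mValues"))

#' @rdname MethylExperiment
#' @export
setGeneric("sampleSheet", function(x) standardGeneric("sampleSheet"))

#' @rdname MethylExperiment
#' @export
setGeneric("probeAnnotation", function(x) standardGeneric("probeAnnotation"))

#' @rdname DMResult
#' @param x a [DMResult-class].
#' @export
setGeneric("dmTable", function(x) standardGeneric("dmTable"))

#' @rdname DMResult
#' @export
setGeneric("dmCpGs", function(x) standardGeneric("dmCpGs"))

#' @rdname CellSignature
#' @param x a [CellSignature-class].
#' @export
setGeneric("signatureCpGs", function(x) standardGeneric("signatureCpGs"))

#' Write a result object to disk
#'
#' Tabular results are written as TSV with a stable column order; nested
#' reports as JSON. See the methods for [DMResult-class],
#' [ClusterReport-class], [OverlapTest-class], [ConcordanceResult-class]
#' and `data.frame`.
#'
#' @param x result object.
#' @param path output file path.
#' @param ... passed to methods.
#' @return `path`, invisibly.
#' @export
setGeneric("writeResults", function(x, path, ...) standardGeneric("writeResults"))
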