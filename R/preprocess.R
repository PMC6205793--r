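#' Beta / M value transforms
#'
#' `betaToM` computes `M = log2(beta / (1 - beta))`; `mToBeta` is its exact
#' inverse. Beta values of exactly 0 or 1 are clipped to `eps` / `1 - eps`
#' before the logit, with a warning reporting how many values were clipped.
#'
#' @param beta numeric vector or matrix of beta values in `[0, 1]` (`NA`
#'   allowed).
#' @param m numeric vector or matrix of M values.
#' @param eps clipping epsilon (default `1e-6`).
#' @return numeric object of the same shape.
#' @export
betaToM <- function(beta, eps = 1e-6) {
  if (any(!is.na(beta) & (beta < 0 | beta > 1)))
    .stopf("beta values must lie in [0, 1]")
  n_clip <- sum(!is.na(beta) & (beta <= 0 | beta >= 1))
  if (n_clip > 0)
    .warnf("%d beta value(s) at 0 or 1 clipped to epsilon %g", n_clip, eps)
  .logit2(.clip01(beta, eps))
}

#' @rdname betaToM
#' @export
mToBeta <- function(m) .ilogit2(m)

#' Probe filtering specification
#'
#' @param max_missing_fraction drop CpGs missing in more than this fraction
#'   of samples (in `[0, 1]`; 1 disables).
#' @param detection_p_threshold optional detection-p cut; a CpG is dropped
#'   when any sample fails `p < threshold` (requires a detection-p matrix at
#'   filter time).
#' @param drop_cross_reactive,drop_polymorphic,drop_sex_chromosomes flags
#'   keyed to the corresponding probe-annotation columns.
#' @param custom_blocklist character vector of CpG ids to drop.
#' @param keep_unannotated keep CpGs absent from the annotation (default) or
#'   drop them.
#' @return a `FilterSpec` list.
#' @export
filterSpec <- function(max_missing_fraction = 1,
                       detection_p_threshold = NULL,
                       drop_cross_reactive = FALSE,
                       drop_polymorphic = FALSE,
                       drop_sex_chromosomes = FALSE,
                       custom_blocklist = character(0),
                       keep_unannotated = TRUE) {
  if (max_missing_fraction < 0 || max_missing_fraction > 1)
    .stopf("max_missing_fraction must lie in [0, 1]")
  if (!is.null(detection_p_threshold) &&
      (detection_p_threshold < 0 || detection_p_threshold > 1))
    .stopf("detection_p_threshold must lie in [0, 1]")
  structure(list(
    max_missing_fraction = max_missing_fraction,
    detection_p_threshold = detection_p_threshold,
    drop_cross_reactive = drop_cross_reactive,
    drop_polymorphic = drop_polymorphic,
    drop_sex_chromosomes = drop_sex_chromosomes,
    custom_blocklist = custom_blocklist,
    keep_unannotated = keep_unannotated), class = "FilterSpec")
}

#' Filter probes by annotation flags, blocklists and missingness
#'
#' Applies the criteria of a [filterSpec()] in a fixed order
#' (cross-reactive, polymorphic, sex chromosomes, custom blocklist,
#' unannotated, missing fraction, detection p), removing each CpG at the
#' first criterion it fails, and reports the number removed per criterion
#' in application order. Filtering is idempotent.
#'
#' @param me a [MethylExperiment-class].
#' @param spec a [filterSpec()].
#' @param detection_p optional CpG x sample matrix of detection p values.
#' @return list with `me` (filtered) and `report` (`data.frame` with columns
#'   `order`, `criterion`, `n_removed`).
#' @export
filterProbes <- function(me, spec = filterSpec(), detection_p = NULL) {
  beta <- betaValues(me)
  anno <- probeAnnotation(me)
  keep <- rep(TRUE, nrow(beta))
  names(keep) <- rownames(beta)
  report <- data.frame(order = integer(0), criterion = character(0),
                       n_removed = integer(0), stringsAsFactors = FALSE)
  step <- 0L
  drop_by <- function(flag, criterion) {
    flag <- flag & keep
    step <<- step + 1L
    report <<- rbind(report, data.frame(
      order = step, criterion = criterion, n_removed = sum(flag),
      stringsAsFactors = FALSE))
    keep[flag] <<- FALSE
  }
  anno_flag <- function(col) {
    if (is.null(anno) || is.null(anno[[col]])) rep(FALSE, nrow(beta))
    else !is.na(anno[[col]]) & anno[[col]]
  }
  if (isTRUE(spec$drop_cross_reactive))
    drop_by(anno_flag("cross_reactive"), "cross_reactive")
  if (isTRUE(spec$drop_polymorphic))
    drop_by(anno_flag("polymorphic"), "polymorphic")
  if (isTRUE(spec$drop_sex_chromosomes))
    drop_by(anno_flag("sex_chromosome"), "sex_chromosome")
  if (length(spec$custom_blocklist))
    drop_by(rownames(beta) %in% spec$custom_blocklist, "custom_blocklist")
  if (!isTRUE(spec$keep_unannotated) && !is.null(anno))
    drop_by(is.na(anno$chromosome), "unannotated")
  if (spec$max_missing_fraction < 1)
    drop_by(rowMeans(is.na(beta)) > spec$max_missing_fraction,
            "missing_fraction")
  if (!is.null(spec$detection_p_threshold)) {
    if (is.null(detection_p))
      .stopf("detection_p_threshold set but no detection_p matrix supplied")
    dp <- detection_p[rownames(beta), colnames(beta), drop = FALSE]
    drop_by(apply(dp >= spec$detection_p_threshold, 1L, any, na.rm = TRUE),
            "detection_p")
  }
  if (!any(keep))
    .stopf("filter specification removes all CpGs")
  list(me = me[keep, ], report = report)
}

#' Sample quality control
#'
#' Reports pairwise M-value correlations within each `replicate_group`, and
#' per-sample mean inter-sample correlation within tissue; samples whose
#' mean correlation falls below `median - k * IQR` of their tissue are
#' flagged as outliers. Flags are advisory: removal is an explicit user
#' action.
#'
#' @param me a [MethylExperiment-class] with at least 2 samples.
#' @param k IQR multiplier for outlier flagging (default 3).
#' @return list with `replicates` (data.frame of pairwise replicate
#'   correlations, or a "no replicates" note), `samples` (per-sample mean
#'   within-tissue correlation and outlier flag) and `outliers` (flagged
#'   sample ids).
#' @export
sampleQC <- function(me, k = 3) {
  if (ncol(me) < 2L) .stopf("sample QC requires at least 2 samples")
  m <- mValues(me)
  sheet <- sampleSheet(me)
  reps <- NULL
  note <- NULL
  if (!is.null(sheet$replicate_group) && any(!is.na(sheet$replicate_group))) {
    for (g in unique(na.omit(sheet$replicate_group))) {
      ids <- sheet$sample_id[!is.na(sheet$replicate_group) &
                               sheet$replicate_group == g]
      if (length(ids) < 2L) next
      prs <- combn(ids, 2L)
      for (i in seq_len(ncol(prs))) {
        r <- cor(m[, prs[1L, i]], m[, prs[2L, i]],
                 use = "pairwise.complete.obs")
        reps <- rbind(reps, data.frame(
          replicate_group = g, sample_a = prs[1L, i], sample_b = prs[2L, i],
          correlation = r, stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(reps)) note <- "no replicates"
  tissue <- if (!is.null(sheet$tissue)) sheet$tissue
            else rep("all", ncol(me))
  samp <- data.frame(sample_id = sheet$sample_id, tissue = tissue,
                     mean_cor = NA_real_, outlier = FALSE,
                     stringsAsFactors = FALSE)
  for (t in unique(tissue)) {
    ids <- sheet$sample_id[tissue == t]
    if (length(ids) < 2L) next
    cc <- cor(m[, ids, drop = FALSE], use = "pairwise.complete.obs")
    diag(cc) <- NA
    mc <- rowMeans(cc, na.rm = TRUE)
    cut <- median(mc) - k * IQR(mc)
    samp$mean_cor[match(ids, samp$sample_id)] <- mc
    samp$outlier[match(ids, samp$sample_id)] <- mc < cut
  }
  list(replicates = reps, note = note, samples = samp,
       outliers = samp$sample_id[samp$outlier])
}

#' Quantile normalization across samples
#'
#' Forces every sample's value distribution onto the cross-sample mean of
#' sorted vectors, preserving within-sample ranks; ties share the mean of
#' their span. Implemented via [limma::normalizeQuantiles()].
#'
#' @param x numeric matrix (features x samples) or
#'   [MethylExperiment-class] (the beta assay is normalized).
#' @return object of the same type.
#' @export
quantileNormalize <- function(x) {
  if (is(x, "MethylExperiment")) {
    b <- normalizeQuantiles(betaValues(x), ties = TRUE)
    dimnames(b) <- dimnames(betaValues(x))
    assay(x, "beta") <- b
    return(x)
  }
  out <- normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}
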