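#' EWAS design specification
#'
#' Describes one differential-methylation run: the primary term (tested
#' coefficient), additive covariates, the response scale (M values by
#' default; beta for covariate-adjusted effect sizes), variance moderation,
#' and optional sample / CpG subsets (e.g. a candidate-gene CpG list, in
#' which BH correction is applied within the subset only, or a
#' fetal-sex-stratified sample filter).
#'
#' For a factor primary term the tested coefficient is the second level
#' versus the first, so order `primary_levels` as (reference, case) —
#' default `c("non-aCA", "aCA")`, making positive estimates hypermethylated
#' in aCA.
#'
#' @param primary sample-sheet column tested.
#' @param covariates additive covariate columns (those absent from the
#'   sheet at fit time are dropped with a warning).
#' @param primary_levels for a factor primary term, its (reference, case)
#'   levels.
#' @param response_scale `"M"` or `"beta"`.
#' @param moderation `"empirical_bayes"` (variance shrinkage across CpGs)
#'   or `"none"`.
#' @param sample_filter optional logical vector, character vector of sample
#'   ids, or predicate `function(sheet) -> logical`.
#' @param cpg_subset optional character vector of CpG ids.
#' @return a `DesignSpec` list.
#' @export
designSpec <- function(primary = "aca_status",
                       covariates = c("ga_weeks", "fetal_sex",
                                      "ancestry_1", "ancestry_2"),
                       primary_levels = c("non-aCA", "aCA"),
                       response_scale = c("M", "beta"),
                       moderation = c("empirical_bayes", "none"),
                       sample_filter = NULL,
                       cpg_subset = NULL) {
  structure(list(
    primary = primary,
    covariates = covariates,
    primary_levels = primary_levels,
    response_scale = match.arg(response_scale),
    moderation = match.arg(moderation),
    sample_filter = sample_filter,
    cpg_subset = cpg_subset), class = "DesignSpec")
}

.apply_sample_filter <- function(sheet, filter) {
  if (is.null(filter)) return(rep(TRUE, nrow(sheet)))
  if (is.function(filter)) return(filter(sheet))
  if (is.logical(filter)) return(filter)
  sheet$sample_id %in% filter
}

# model matrix + primary coefficient index for a design on a sheet subset
.build_design_matrix <- function(sheet, design) {
  covs <- design$covariates
  missing_cov <- setdiff(covs, names(sheet))
  if (length(missing_cov)) {
    .warnf("covariate(s) not in sheet dropped: %s",
           paste(missing_cov, collapse = ", "))
    covs <- setdiff(covs, missing_cov)
  }
  covs <- covs[vapply(covs, function(col)
    length(unique(na.omit(sheet[[col]]))) > 1L, logical(1L))]
  dat <- sheet[, unique(c(design$primary, covs)), drop = FALSE]
  pv <- dat[[design$primary]]
  if (is.character(pv) || is.factor(pv)) {
    lv <- design$primary_levels
    if (is.null(lv) || !all(unique(na.omit(pv)) %in% lv))
      lv <- sort(unique(na.omit(as.character(pv))))
    dat[[design$primary]] <- factor(pv, levels = lv)
  }
  if (length(unique(na.omit(dat[[design$primary]]))) < 2L)
    .stopf("primary term '%s' is constant within the analyzed subset",
           design$primary)
  for (col in covs)
    if (is.character(dat[[col]])) dat[[col]] <- factor(dat[[col]])
  cc <- complete.cases(dat)
  X <- model.matrix(reformulate(c(design$primary, covs)),
                    data = dat[cc, , drop = FALSE])
  jp <- grep(paste0("^", design$primary), colnames(X))[1L]
  if (is.na(jp)) .stopf("primary term column not found in design matrix")
  list(X = X, complete = cc, primary_col = jp)
}

# method-of-moments fit of the scaled inverse-chi-square prior on residual
# variances; returns d0 (prior df, possibly Inf) and s02 (prior variance)
.fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (sum(ok) < 2L) return(list(d0 = 0, s02 = NA_real_))
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  emean <- mean(e)
  evar <- var(e) - mean(trigamma(df[ok] / 2))
  if (is.na(evar) || evar <= 0) {
    d0 <- Inf
    s02 <- exp(emean)
  } else {
    d0 <- 2 * .trigammaInverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s02 = s02)
}

#' Per-CpG covariate-adjusted linear models
#'
#' Fits, for every CpG, an ordinary-least-squares regression of methylation
#' (M values by default) on the primary term plus additive covariates, and
#' returns the primary-term coefficient with its (optionally moderated)
#' t statistic and two-sided p value. With
#' `moderation = "empirical_bayes"`, residual variances are shrunk toward a
#' common prior, `s2_post = (d0 * s02 + d * s2) / (d0 + d)`, with `(d0,
#' s02)` estimated by method of moments on the log residual variances
#' across CpGs, and the t degrees of freedom augmented to `d + d0`.
#' Moderation changes only `se`/`t`/`df`/`p`; coefficients are identical to
#' the unmoderated fit. CpGs with missing values are fit on row-wise
#' complete cases with adjusted degrees of freedom.
#'
#' @param me a [MethylExperiment-class].
#' @param design a [designSpec()].
#' @param eps logit clipping epsilon for the beta-to-M transform.
#' @return `data.frame` with columns `cpg_id`, `estimate`, `se`, `t`, `df`,
#'   `p`; attributes `d0`, `s02` (shrinkage hyperparameters), `design` and
#'   `n_samples`.
#' @export
fitCpGModels <- function(me, design = designSpec(), eps = 1e-6) {
  sheet <- sampleSheet(me)
  sel <- .apply_sample_filter(sheet, design$sample_filter)
  sheet <- sheet[sel, , drop = FALSE]
  me_sub <- me[, sel]
  if (!is.null(design$cpg_subset)) {
    missing_cpg <- setdiff(design$cpg_subset, rownames(me_sub))
    if (length(missing_cpg))
      .stopf("cpg_subset contains unknown CpG '%s'", missing_cpg[1L])
    me_sub <- me_sub[design$cpg_subset, ]
  }
  Y <- if (design$response_scale == "M")
    betaToM(betaValues(me_sub), eps = eps) else betaValues(me_sub)
  dm <- .build_design_matrix(sheet, design)
  X <- dm$X
  jp <- dm$primary_col
  Y <- Y[, dm$complete, drop = FALSE]
  n <- ncol(Y)
  p <- ncol(X)
  if (n <= p + 1)
    .stopf("need more samples (%d) than design columns + 1 (%d)", n, p + 1)
  qx <- qr(X)
  if (qx$rank < p) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1L):p]]
    .stopf("rank-deficient design; aliased column(s): %s",
           paste(aliased, collapse = ", "))
  }
  xtxinv_jj <- solve(crossprod(X))[jp, jp]

  est <- rep(NA_real_, nrow(Y))
  s2 <- rep(NA_real_, nrow(Y))
  dfree <- rep(NA_real_, nrow(Y))
  vjj <- rep(xtxinv_jj, nrow(Y))

  has_na <- rowSums(is.na(Y)) > 0L
  if (any(!has_na)) {
    fit <- lm.fit(X, t(Y[!has_na, , drop = FALSE]))
    cf <- fit$coefficients
    res <- fit$residuals
    if (is.null(dim(cf))) cf <- matrix(cf, ncol = 1L)
    if (is.null(dim(res))) res <- matrix(res, ncol = 1L)
    est[!has_na] <- cf[jp, ]
    dfree[!has_na] <- n - p
    s2[!has_na] <- colSums(res^2) / (n - p)
  }
  for (i in which(has_na)) {
    ok <- !is.na(Y[i, ])
    Xi <- X[ok, , drop = FALSE]
    qi <- qr(Xi)
    if (sum(ok) <= p || qi$rank < p) next
    fi <- lm.fit(Xi, Y[i, ok])
    est[i] <- fi$coefficients[jp]
    dfree[i] <- sum(ok) - p
    s2[i] <- sum(fi$residuals^2) / dfree[i]
    vjj[i] <- solve(crossprod(Xi))[jp, jp]
  }

  d0 <- 0
  s02 <- NA_real_
  if (design$moderation == "empirical_bayes") {
    prior <- .fit_variance_prior(s2, dfree)
    d0 <- prior$d0
    s02 <- prior$s02
    if (is.finite(d0) && d0 > 0) {
      s2_post <- (d0 * s02 + dfree * s2) / (d0 + dfree)
      df_post <- dfree + d0
    } else if (is.infinite(d0)) {
      s2_post <- rep(s02, length(s2))
      df_post <- rep(Inf, length(s2))
    } else {
      s2_post <- s2
      df_post <- dfree
    }
  } else {
    s2_post <- s2
    df_post <- dfree
  }
  se <- sqrt(s2_post * vjj)
  tstat <- est / se
  pval <- 2 * pt(-abs(tstat), df_post)
  out <- data.frame(cpg_id = rownames(Y), estimate = est, se = se,
                    t = tstat, df = df_post, p = pval,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  attr(out, "design") <- design
  attr(out, "n_samples") <- n
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_(j >= i) p_(j) * n / j`, capped at 1 and mapped back to the
#' input order; missing p values propagate to missing q values and do not
#' count toward `n`.
#'
#' @param p numeric vector of p values in `[0, 1]` (NA allowed).
#' @return numeric vector of q values.
#' @export
bhAdjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    .stopf("p values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- p.adjust(p[ok], method = "BH")
  q
}

#' Per-CpG group difference in mean beta
#'
#' `delta beta = mean(beta | case) - mean(beta | reference)` per CpG
#' (default: aCA minus non-aCA, so positive values are hypermethylated in
#' aCA). A CpG with one group fully missing gets `NA`.
#'
#' @param me a [MethylExperiment-class].
#' @param group grouping column (default `"aca_status"`).
#' @param levels `(reference, case)` group levels.
#' @param sample_filter optional filter as in [designSpec()].
#' @return named numeric vector of delta beta, one per CpG.
#' @export
deltaBeta <- function(me, group = "aca_status",
                      levels = c("non-aCA", "aCA"), sample_filter = NULL) {
  sheet <- sampleSheet(me)
  sel <- .apply_sample_filter(sheet, sample_filter)
  beta <- betaValues(me)[, sel, drop = FALSE]
  g <- sheet[[group]][sel]
  case <- !is.na(g) & g == levels[2L]
  ref <- !is.na(g) & g == levels[1L]
  if (!any(case) || !any(ref))
    .stopf("both groups must be nonempty for delta beta")
  db <- rowMeans(beta[, case, drop = FALSE], na.rm = TRUE) -
    rowMeans(beta[, ref, drop = FALSE], na.rm = TRUE)
  db[is.nan(db)] <- NA_real_
  db
}

#' Call differentially methylated sites
#'
#' Applies BH correction to the fit p values (within the fitted CpG set,
#' so a candidate-gene run corrects within the candidate subset only) and
#' calls a CpG DM iff `q < fdr_max` and `|delta beta| > delta_beta_min`
#' (both directions).
#'
#' @param fit result of [fitCpGModels()].
#' @param delta_beta named vector from [deltaBeta()] (aligned by CpG id).
#' @param fdr_max,delta_beta_min calling thresholds in `[0, 1]`.
#' @return a [DMResult-class].
#' @export
callDMSites <- function(fit, delta_beta, fdr_max = 0.15,
                        delta_beta_min = 0.05) {
  if (fdr_max < 0 || fdr_max > 1 || delta_beta_min < 0 || delta_beta_min > 1)
    .stopf("thresholds must lie in [0, 1]")
  db <- delta_beta[match(fit$cpg_id, names(delta_beta))]
  if (anyNA(match(fit$cpg_id, names(delta_beta))))
    .stopf("delta beta is missing CpGs present in the fit table")
  q <- bhAdjust(fit$p)
  call <- !is.na(q) & !is.na(db) & q < fdr_max & abs(db) > delta_beta_min
  res <- data.frame(fit[, c("cpg_id", "estimate", "se", "t", "df", "p")],
                    q = q, delta_beta = unname(db), dm_call = call,
                    stringsAsFactors = FALSE)
  design <- attr(fit, "design")
  new("DMResult", results = res, fdrMax = fdr_max,
      deltaBetaMin = delta_beta_min,
      design = list(primary = design$primary,
                    covariates = design$covariates,
                    response_scale = design$response_scale,
                    moderation = design$moderation,
                    d0 = attr(fit, "d0"), s02 = attr(fit, "s02"),
                    n_samples = attr(fit, "n_samples")))
}

#' One-call EWAS
#'
#' Convenience wrapper chaining [fitCpGModels()], [deltaBeta()] and
#' [callDMSites()] on the same sample/CpG subsets. `delta_method = "raw"`
#' uses the unadjusted group-mean difference in beta;
#' `"covariate_adjusted"` instead refits the model on the beta scale and
#' uses the primary-term coefficient as the effect size.
#'
#' @inheritParams fitCpGModels
#' @inheritParams callDMSites
#' @param delta_method `"raw"` or `"covariate_adjusted"`.
#' @return a [DMResult-class].
#' @export
runEwas <- function(me, design = designSpec(), fdr_max = 0.15,
                    delta_beta_min = 0.05,
                    delta_method = c("raw", "covariate_adjusted")) {
  delta_method <- match.arg(delta_method)
  fit <- fitCpGModels(me, design)
  if (delta_method == "raw") {
    db <- deltaBeta(me, group = design$primary,
                    levels = design$primary_levels,
                    sample_filter = design$sample_filter)
    db <- db[match(fit$cpg_id, names(db))]
    names(db) <- fit$cpg_id
  } else {
    bdesign <- design
    bdesign$response_scale <- "beta"
    bfit <- fitCpGModels(me, bdesign)
    db <- setNames(bfit$estimate, bfit$cpg_id)
  }
  callDMSites(fit, db, fdr_max = fdr_max, delta_beta_min = delta_beta_min)
}

#' Volcano-plot-ready table
#'
#' @param dm a [DMResult-class].
#' @return `data.frame` with `cpg_id`, `delta_beta`, `neg_log10_q`,
#'   `dm_call` and `direction` (`hyper` / `hypo` for called sites).
#' @export
volcanoTable <- function(dm) {
  r <- dmTable(dm)
  data.frame(
    cpg_id = r$cpg_id, delta_beta = r$delta_beta,
    neg_log10_q = -log10(pmax(r$q, .Machine$double.xmin)),
    dm_call = r$dm_call,
    direction = ifelse(!r$dm_call, "",
                       ifelse(r$delta_beta > 0, "hyper", "hypo")),
    stringsAsFactors = FALSE)
}
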