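#' Matched-tissue per-CpG correlation with a shuffled-sample null
#'
#' Computes the per-CpG Spearman rank correlation of M values across
#' individuals matched between two tissues, and compares against a null
#' distribution built by shuffling the individual matching `n_shuffles`
#' times and pooling the resulting per-CpG correlations. Reports the count
#' of CpGs whose observed correlation exceeds the null 95th percentile and
#' a one-sided binomial test of whether that count exceeds the nominal 5%.
#'
#' CpGs with fewer than `min_pairs` complete matched pairs, or constant in
#' either tissue (correlation undefined), are excluded and counted.
#'
#' @param me_a,me_b [MethylExperiment-class] objects sharing CpG ids, with
#'   `individual_id` in their sample sheets; samples are matched on it
#'   (at least 3 matched individuals required).
#' @param n_shuffles number of shuffles pooled into the null.
#' @param seed RNG seed.
#' @param min_pairs minimum complete matched pairs per CpG (default 3).
#' @return list with `correlations` (named per-CpG observed Spearman r),
#'   `null_q95`, `n_above` / `n_tested` / `fraction_above`, `binomial_p`,
#'   `n_excluded`, and `n_pairs`.
#' @export
matchedTissueCorrelation <- function(me_a, me_b, n_shuffles = 100, seed = 1L,
                                     min_pairs = 3L) {
  common <- intersect(rownames(me_a), rownames(me_b))
  if (!length(common)) .stopf("the two matrices share no CpG ids")
  sheet_a <- sampleSheet(me_a)
  sheet_b <- sampleSheet(me_b)
  if (is.null(sheet_a$individual_id) || is.null(sheet_b$individual_id))
    .stopf("both sample sheets need an 'individual_id' column")
  ind <- intersect(na.omit(sheet_a$individual_id),
                   na.omit(sheet_b$individual_id))
  if (length(ind) < 3L) .stopf("need at least 3 matched individuals")
  ia <- match(ind, sheet_a$individual_id)
  ib <- match(ind, sheet_b$individual_id)
  A <- mValues(me_a)[common, ia, drop = FALSE]
  B <- mValues(me_b)[common, ib, drop = FALSE]
  n_pairs <- length(ind)

  row_spearman <- function(X, Y) {
    rx <- t(apply(X, 1L, rank, na.last = "keep"))
    ry <- t(apply(Y, 1L, rank, na.last = "keep"))
    rx <- rx - rowMeans(rx, na.rm = TRUE)
    ry <- ry - rowMeans(ry, na.rm = TRUE)
    num <- rowSums(rx * ry, na.rm = TRUE)
    den <- sqrt(rowSums(rx^2, na.rm = TRUE) * rowSums(ry^2, na.rm = TRUE))
    out <- num / den
    out[den == 0] <- NA_real_
    out
  }
  complete <- rowSums(!is.na(A) & !is.na(B))
  usable <- complete >= min_pairs
  r_obs <- rep(NA_real_, length(common))
  names(r_obs) <- common
  r_obs[usable] <- row_spearman(A[usable, , drop = FALSE],
                                B[usable, , drop = FALSE])
  tested <- !is.na(r_obs)

  set.seed(seed)
  null_pool <- vector("list", n_shuffles)
  for (s in seq_len(n_shuffles)) {
    perm <- sample.int(n_pairs)
    r_null <- row_spearman(A[tested, perm, drop = FALSE],
                           B[tested, , drop = FALSE])
    null_pool[[s]] <- r_null[!is.na(r_null)]
  }
  null_pool <- unlist(null_pool, use.names = FALSE)
  q95 <- quantile(null_pool, 0.95, names = FALSE)
  n_above <- sum(r_obs[tested] > q95)
  n_tested <- sum(tested)
  bt <- binom.test(n_above, n_tested, p = 0.05, alternative = "greater")
  list(correlations = r_obs, null_q95 = q95, n_above = n_above,
       n_tested = n_tested, fraction_above = n_above / n_tested,
       binomial_p = bt$p.value, n_excluded = sum(!tested),
       n_pairs = n_pairs)
}

#' Tissue-pair differential methylation
#'
#' Differential methylation between two tissues, delegating to the EWAS
#' engine with tissue as the primary term (positive delta beta = higher in
#' `tissue_a`). When both tissues carry `individual_id` and `paired = TRUE`,
#' matched samples are paired through an individual indicator in the
#' design. Calls use the strict tissue-contrast thresholds by default
#' (FDR < 0.01, |delta beta| > 0.20).
#'
#' @param me a [MethylExperiment-class] containing both tissues.
#' @param tissue_a,tissue_b tissue labels to contrast.
#' @param fdr_max,delta_beta_min calling thresholds.
#' @param paired pair by `individual_id` when available.
#' @param moderation passed to [designSpec()].
#' @return a [DMResult-class].
#' @export
tissuePairDM <- function(me, tissue_a, tissue_b, fdr_max = 0.01,
                         delta_beta_min = 0.20, paired = TRUE,
                         moderation = "empirical_bayes") {
  sheet <- sampleSheet(me)
  sel <- sheet$tissue %in% c(tissue_a, tissue_b)
  if (!any(sheet$tissue == tissue_a) || !any(sheet$tissue == tissue_b))
    .stopf("both tissues must be present in the experiment")
  covariates <- character(0)
  if (paired && !is.null(sheet$individual_id)) {
    sub <- sheet[sel, ]
    matched <- intersect(sub$individual_id[sub$tissue == tissue_a],
                         sub$individual_id[sub$tissue == tissue_b])
    if (length(matched) >= 2L) {
      # restrict to matched individuals so the pairing indicator is balanced
      sel <- sel & sheet$individual_id %in% matched
      covariates <- "individual_id"
    }
  }
  design <- designSpec(primary = "tissue", covariates = covariates,
                       primary_levels = c(tissue_b, tissue_a),
                       moderation = moderation,
                       sample_filter = sel)
  runEwas(me, design, fdr_max = fdr_max, delta_beta_min = delta_beta_min)
}

#' DM-set overlap test with a random-sampling null
#'
#' Tests whether a query CpG set overlaps a target tissue's DM set more
#' than expected by chance: `n_draws` random CpG sets of the query's size
#' are drawn from the background without replacement and the
#' add-one-corrected empirical p is
#' `(1 + #{draws with overlap >= k_obs}) / (n_draws + 1)`; the exact
#' hypergeometric upper tail `P(X >= k_obs)` is reported as a cross-check.
#'
#' @param query_cpgs character vector of query CpG ids (must be a subset of
#'   `background`).
#' @param target_dm_cpgs character vector of CpGs DM in the target tissue.
#' @param background character vector of all tested CpG ids.
#' @param n_draws number of random draws (>= 1000).
#' @param seed RNG seed.
#' @return an [OverlapTest-class].
#' @export
dmOverlapTest <- function(query_cpgs, target_dm_cpgs, background,
                          n_draws = 10000, seed = 1L) {
  if (n_draws < 1000) .stopf("n_draws must be at least 1000")
  if (length(setdiff(query_cpgs, background)))
    .stopf("query set must be a subset of the background")
  N <- length(background)
  m <- length(query_cpgs)
  if (m > N) .stopf("query set larger than background")
  is_dm <- background %in% target_dm_cpgs
  K <- sum(is_dm)
  k_obs <- sum(query_cpgs %in% background[is_dm])
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_draws)) {
    k <- sum(is_dm[sample.int(N, m)])
    if (k >= k_obs) hits <- hits + 1L
  }
  emp_p <- (1 + hits) / (n_draws + 1)
  hyper_p <- phyper(k_obs - 1L, K, N - K, m, lower.tail = FALSE)
  new("OverlapTest", m = as.integer(m), N = as.integer(N),
      K = as.integer(K), kObs = as.integer(k_obs),
      nDraws = as.integer(n_draws), empiricalP = emp_p,
      hypergeomP = hyper_p)
}
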