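#' Parametric empirical-Bayes batch adjustment
#'
#' Removes additive/multiplicative batch effects from a feature x sample
#' matrix (M values) while protecting biological covariates, by the
#' parametric empirical-Bayes procedure: (1) per-feature least-squares fit
#' of the protected design plus batch indicators under the
#' sample-size-weighted sum-to-zero constraint on batch effects;
#' (2) standardisation to residual scale; (3) method-of-moments
#' hyperpriors — normal across features for batch locations gamma,
#' inverse-gamma for batch scales delta^2; (4) fixed-point EB iteration to
#' convergence (tolerance `1e-4` on successive estimates); (5)
#' back-transformation with batch effects removed and protected effects
#' restored.
#'
#' @param m feature x sample numeric matrix (no missing values).
#' @param batch factor (or coercible) of batch labels, one per sample; every
#'   batch needs at least 2 samples.
#' @param mod optional protected-covariate model matrix (with intercept),
#'   e.g. `model.matrix(~ aca_status + ga_weeks + fetal_sex, sheet)`. Batch
#'   must not be perfectly confounded with a protected covariate.
#' @param tol convergence tolerance of the EB fixed-point iteration.
#' @return list with `adjusted` (matrix) and `model`
#'   (a [BatchModel-class]).
#' @export
combatAdjust <- function(m, batch, mod = NULL, tol = 1e-4) {
  m <- as.matrix(m)
  if (anyNA(m)) .stopf("batch adjustment requires complete data")
  batch <- droplevels(as.factor(batch))
  if (length(batch) != ncol(m))
    .stopf("batch must have one label per sample")
  n_array <- ncol(m)
  tab <- table(batch)
  if (any(tab < 2L))
    .stopf("batch '%s' has fewer than 2 samples", names(tab)[tab < 2L][1L])
  n_batch <- nlevels(batch)
  if (n_batch == 1L) {
    model <- new("BatchModel", batchVariable = "batch",
                 batches = levels(batch),
                 gammaHat = matrix(0, 1L, nrow(m)),
                 gammaStar = matrix(0, 1L, nrow(m)),
                 deltaHat = matrix(1, 1L, nrow(m)),
                 deltaStar = matrix(1, 1L, nrow(m)),
                 hyper = list())
    return(list(adjusted = m, model = model))
  }
  batchmod <- model.matrix(~ -1 + batch)
  design <- batchmod
  if (!is.null(mod)) {
    mod <- as.matrix(mod)
    # drop the intercept: it is absorbed by the batch indicators
    keep <- apply(mod, 2L, function(col) length(unique(col)) > 1L)
    mod_nc <- mod[, keep, drop = FALSE]
    design <- cbind(batchmod, mod_nc)
  }
  q <- qr(design)
  if (q$rank < ncol(design)) {
    aliased <- colnames(design)[q$pivot[(q$rank + 1L):ncol(design)]]
    .stopf("design is singular (batch confounded with protected covariate?): %s",
           paste(aliased, collapse = ", "))
  }

  n_batches <- as.numeric(tab)
  B_hat <- solve(crossprod(design), crossprod(design, t(m)))
  # weighted sum-to-zero constraint: the grand mean is the size-weighted
  # average of batch locations
  grand_mean <- crossprod(n_batches / n_array, B_hat[seq_len(n_batch), ,
                                                     drop = FALSE])
  var_pooled <- ((m - t(design %*% B_hat))^2) %*% rep(1 / n_array, n_array)
  if (any(var_pooled <= 0))
    .stopf("feature with zero pooled residual variance")
  stand_mean <- t(grand_mean) %*% t(rep(1, n_array))
  if (!is.null(mod)) {
    tmp <- design
    tmp[, seq_len(n_batch)] <- 0
    stand_mean <- stand_mean + t(tmp %*% B_hat)
  }
  s_data <- (m - stand_mean) / (sqrt(var_pooled) %*% t(rep(1, n_array)))

  gamma_hat <- solve(crossprod(batchmod), crossprod(batchmod, t(s_data)))
  delta_hat <- matrix(NA_real_, n_batch, nrow(m))
  for (i in seq_len(n_batch)) {
    sel <- batch == levels(batch)[i]
    delta_hat[i, ] <- apply(s_data[, sel, drop = FALSE], 1L, var)
  }
  gamma_bar <- rowMeans(gamma_hat)
  tau2 <- apply(gamma_hat, 1L, var)
  # inverse-gamma moments for the scale prior
  dmean <- rowMeans(delta_hat)
  dvar <- apply(delta_hat, 1L, var)
  a_prior <- (2 * dvar + dmean^2) / dvar
  b_prior <- (dmean * dvar + dmean^3) / dvar

  gamma_star <- matrix(NA_real_, n_batch, nrow(m))
  delta_star <- matrix(NA_real_, n_batch, nrow(m))
  for (i in seq_len(n_batch)) {
    sel <- batch == levels(batch)[i]
    sdat <- s_data[, sel, drop = FALSE]
    n_i <- ncol(sdat)
    g_old <- gamma_hat[i, ]
    d_old <- delta_hat[i, ]
    change <- 1
    while (change > tol) {
      g_new <- (n_i * tau2[i] * gamma_hat[i, ] + d_old * gamma_bar[i]) /
        (n_i * tau2[i] + d_old)
      sum2 <- rowSums((sdat - g_new %*% t(rep(1, n_i)))^2)
      d_new <- (0.5 * sum2 + b_prior[i]) / (n_i / 2 + a_prior[i] - 1)
      change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-8),
                    abs(d_new - d_old) / d_old, na.rm = TRUE)
      g_old <- g_new
      d_old <- d_new
    }
    gamma_star[i, ] <- g_old
    delta_star[i, ] <- d_old
  }

  bayes <- s_data
  for (i in seq_len(n_batch)) {
    sel <- batch == levels(batch)[i]
    n_i <- sum(sel)
    bayes[, sel] <- (s_data[, sel, drop = FALSE] -
                       gamma_star[i, ] %*% t(rep(1, n_i))) /
      (sqrt(delta_star[i, ]) %*% t(rep(1, n_i)))
  }
  adjusted <- bayes * (sqrt(var_pooled) %*% t(rep(1, n_array))) + stand_mean
  dimnames(adjusted) <- dimnames(m)

  model <- new("BatchModel",
               batchVariable = "batch", batches = levels(batch),
               gammaHat = gamma_hat, gammaStar = gamma_star,
               deltaHat = delta_hat, deltaStar = delta_star,
               hyper = list(gamma_bar = gamma_bar, tau2 = tau2,
                            a_prior = a_prior, b_prior = b_prior))
  list(adjusted = adjusted, model = model)
}

#' Sequential batch adjustment of a methylation experiment
#'
#' Transforms the beta assay to M values, applies [combatAdjust()] for each
#' batch variable in turn (chip row first, then chip id, by default) with
#' the protected biological design, and back-transforms to beta.
#'
#' @param me a [MethylExperiment-class].
#' @param batch_vars sample-sheet columns to adjust for, in order.
#' @param protect sample-sheet columns to protect (aCA status, GA, sex,
#'   ancestry by default; columns absent from the sheet are skipped).
#' @param eps logit clipping epsilon.
#' @return list with `me` (adjusted) and `models` (list of
#'   [BatchModel-class], one per batch variable).
#' @export
adjustBatchEffects <- function(me,
                               batch_vars = c("chip_row", "chip_id"),
                               protect = c("aca_status", "ga_weeks",
                                           "fetal_sex", "ancestry_1",
                                           "ancestry_2"),
                               eps = 1e-6) {
  sheet <- sampleSheet(me)
  protect <- intersect(protect, names(sheet))
  protect <- protect[vapply(protect, function(col) {
    v <- sheet[[col]]
    !anyNA(v) && length(unique(v)) > 1L
  }, logical(1L))]
  mod <- if (length(protect))
    model.matrix(reformulate(protect), data = sheet) else NULL
  m <- betaToM(betaValues(me), eps = eps)
  models <- list()
  for (bv in batch_vars) {
    if (is.null(sheet[[bv]])) .stopf("batch variable '%s' not in sheet", bv)
    res <- combatAdjust(m, sheet[[bv]], mod = mod)
    res$model@batchVariable <- bv
    m <- res$adjusted
    models[[bv]] <- res$model
  }
  assay(me, "beta") <- mToBeta(m)
  list(me = me, models = models)
}
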