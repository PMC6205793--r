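# tiny deterministic experiment where the truth is computable by hand
toy_design_me <- function(beta_mat, aca) {
  sheet <- data.frame(sample_id = colnames(beta_mat),
                      aca_status = aca, stringsAsFactors = FALSE)
  MethylExperiment(beta_mat, sheet)
}

test_that("the fit recovers a planted coefficient via the normal equations", {
  # 6 samples, no noise: M = 1 + 1.5 * aca, checked against solve(X'X) X'y
  aca <- c("aCA", "aCA", "aCA", "non-aCA", "non-aCA", "non-aCA")
  x <- as.integer(aca == "aCA")
  m_true <- 1 + 1.5 * x + c(0.01, -0.01, 0.02, -0.02, 0.01, -0.01)
  b <- matrix(mToBeta(m_true), 1, 6,
              dimnames = list("cg1", sprintf("s%d", 1:6)))
  me <- toy_design_me(b, aca)
  design <- designSpec(covariates = character(0), moderation = "none")
  fit <- fitCpGModels(me, design)
  X <- cbind(1, x)
  oracle <- solve(crossprod(X), crossprod(X, betaToM(b[1, ])))[2L]
  expect_equal(fit$estimate, oracle, tolerance = 1e-10)
  expect_equal(fit$estimate, 1.5, tolerance = 0.05)
})

test_that("identical group means with zero noise give t = 0, p = 1", {
  b <- matrix(rep(c(0.3, 0.6, 0.3, 0.6), 2), 2, 4, byrow = TRUE,
              dimnames = list(c("cg1", "cg2"), sprintf("s%d", 1:4)))
  me <- toy_design_me(b, c("aCA", "aCA", "non-aCA", "non-aCA"))
  fit <- fitCpGModels(me, designSpec(covariates = character(0),
                                     moderation = "none"))
  expect_equal(fit$t, c(0, 0))
  expect_equal(fit$p, c(1, 1))
})

test_that("moderation shrinks variances but never touches coefficients", {
  cfg <- villi_config(800, n_aca_effect = 40, seed = 61)
  coh <- generateCohort(cfg)
  f_mod <- fitCpGModels(coh$me, designSpec(moderation = "empirical_bayes"))
  f_none <- fitCpGModels(coh$me, designSpec(moderation = "none"))
  expect_equal(f_mod$estimate, f_none$estimate, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(f_mod$t, f_none$t)))
  d0 <- attr(f_mod, "d0")
  s02 <- attr(f_mod, "s02")
  expect_gt(d0, 0)
  # degrees of freedom are augmented by the prior df
  expect_equal(f_mod$df, f_none$df + d0, tolerance = 1e-8)
  # s2_post = (d0 s02 + d s2) / (d0 + d): with a common design,
  # se_mod^2 (d0 + d) - d se_none^2 = d0 s02 vjj, constant across CpGs
  const <- f_mod$se^2 * (d0 + f_none$df) - f_none$df * f_none$se^2
  expect_lt(diff(range(const)) / mean(const), 1e-8)
  expect_true(all(const > 0))
})

test_that("in the d0 -> Inf limit all posterior variances equal the prior", {
  # equal residual variance everywhere drives the prior weight to infinity
  set.seed(62)
  aca <- rep(c("aCA", "non-aCA"), each = 10)
  x <- as.integer(aca == "aCA")
  n_cpg <- 300
  noise <- matrix(rnorm(n_cpg * 20, 0, 0.5), n_cpg, 20)
  # force identical residual SS across CpGs by rescaling rows
  X <- cbind(1, x)
  H <- diag(20) - X %*% solve(crossprod(X), t(X))
  res <- noise %*% H
  rss <- rowSums(res^2)
  noise <- noise * sqrt(median(rss) / rss)
  m <- noise
  b <- mToBeta(m)
  dimnames(b) <- list(sprintf("cg%04d", 1:n_cpg), sprintf("s%02d", 1:20))
  me <- toy_design_me(b, aca)
  fit <- fitCpGModels(me, designSpec(covariates = character(0)))
  expect_true(is.infinite(attr(fit, "d0")))
  expect_true(all(is.infinite(fit$df)))
})

test_that("the moderated fit matches the established microarray pipeline", {
  skip_if_not_installed("limma")
  cfg <- villi_config(600, n_aca_effect = 30, seed = 63)
  coh <- generateCohort(cfg)
  design <- designSpec()
  fit <- fitCpGModels(coh$me, design)
  sheet <- sampleSheet(coh$me)
  X <- model.matrix(~ factor(aca_status, c("non-aCA", "aCA")) + ga_weeks +
                      factor(fetal_sex) + ancestry_1 + ancestry_2, sheet)
  lf <- limma::eBayes(limma::lmFit(mValues(coh$me), X))
  expect_equal(fit$estimate, unname(lf$coefficients[, 2L]),
               tolerance = 1e-9)
  expect_equal(attr(fit, "d0"), lf$df.prior, tolerance = 0.05)
  expect_equal(fit$t, unname(lf$t[, 2L]), tolerance = 1e-3)
  expect_equal(fit$p, unname(lf$p.value[, 2L]), tolerance = 1e-3)
})

test_that("BH adjustment matches the brute-force step-up on random vectors", {
  set.seed(64)
  for (i in 1:40) {
    p <- runif(sample(2:50, 1))
    expect_equal(bhAdjust(p), bh_stepup_oracle(p), tolerance = 1e-12)
  }
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.37), 0.37)
  expect_equal(bhAdjust(rep(0.5, 100)), rep(0.5, 100))
  expect_equal(bhAdjust(c(0.2, NA, 0.01)), c(0.2, NA, 0.02))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("delta beta is the aCA-minus-non-aCA difference of mean betas", {
  b <- matrix(c(0.60, 0.62, 0.50, 0.52,
                0.20, 0.20, 0.20, 0.20), 2, 4, byrow = TRUE,
              dimnames = list(c("cg1", "cg2"), sprintf("s%d", 1:4)))
  me <- toy_design_me(b, c("aCA", "aCA", "non-aCA", "non-aCA"))
  db <- deltaBeta(me)
  expect_equal(unname(db), c(0.10, 0))
  # one group fully missing -> NA
  b[1, 1:2] <- NA
  me2 <- toy_design_me(b, c("aCA", "aCA", "non-aCA", "non-aCA"))
  expect_true(is.na(deltaBeta(me2)["cg1"]))
})

test_that("DM calls respect both thresholds and direction labels match planted signs", {
  cfg <- villi_config(4000, n_aca_effect = 120, seed = 65)
  coh <- generateCohort(cfg)
  dm <- runEwas(coh$me)
  tab <- dmTable(dm)
  expect_true(all(tab$dm_call == (tab$q < 0.15 & abs(tab$delta_beta) > 0.05)))
  planted <- coh$truth$planted_cpg_sets$aca_effect
  called <- tab[tab$dm_call & tab$cpg_id %in% planted$cpg_id, ]
  signs <- sign(planted$effect[match(called$cpg_id, planted$cpg_id)])
  expect_true(all(sign(called$delta_beta) == signs))
  expect_gt(nrow(called), 0)
  # all q = 1 -> zero calls
  fake <- dmTable(dm)
  dm0 <- callDMSites(data.frame(cpg_id = fake$cpg_id, estimate = 0, se = 1,
                                t = 0, df = 10, p = 1),
                     setNames(fake$delta_beta, fake$cpg_id))
  expect_length(dmCpGs(dm0), 0)
})

test_that("results are invariant to sample and CpG order", {
  cfg <- villi_config(300, n_aca_effect = 30, seed = 66)
  coh <- generateCohort(cfg)
  me <- coh$me
  set.seed(1)
  me_perm <- me[sample(nrow(me)), sample(ncol(me))]
  dm1 <- dmTable(runEwas(me))
  dm2 <- dmTable(runEwas(me_perm))
  dm2 <- dm2[match(dm1$cpg_id, dm2$cpg_id), ]
  expect_equal(dm1$estimate, dm2$estimate, tolerance = 1e-9)
  expect_equal(dm1$p, dm2$p, tolerance = 1e-9)
  expect_equal(dm1$q, dm2$q, tolerance = 1e-9)
})

test_that("candidate-subset runs correct within the subset only", {
  cfg <- villi_config(2000, n_aca_effect = 60, seed = 67)
  coh <- generateCohort(cfg)
  subset_ids <- rownames(coh$me)[1:195]
  design <- designSpec(cpg_subset = subset_ids)
  dm_sub <- runEwas(coh$me, design)
  tab_sub <- dmTable(dm_sub)
  expect_identical(tab_sub$cpg_id, subset_ids)
  # q within the subset equals BH on the subset p values, not the full set
  expect_equal(tab_sub$q, bh_stepup_oracle(tab_sub$p), tolerance = 1e-12)
  # coefficients are per-CpG and unaffected by the subset; p values differ
  # because the shrinkage prior is estimated within the analyzed set
  dm_full <- runEwas(coh$me)
  tab_full <- dmTable(dm_full)
  expect_equal(tab_sub$estimate,
               tab_full$estimate[match(subset_ids, tab_full$cpg_id)],
               tolerance = 1e-12)
})

test_that("sex-stratified runs analyze the stated subset", {
  cfg <- villi_config(300, n_aca_effect = 30, seed = 68)
  coh <- generateCohort(cfg)
  design <- designSpec(covariates = c("ga_weeks", "ancestry_1", "ancestry_2"),
                       sample_filter = function(sheet) sheet$fetal_sex == "M")
  fit <- fitCpGModels(coh$me, design)
  expect_equal(attr(fit, "n_samples"),
               sum(sampleSheet(coh$me)$fetal_sex == "M"))
})

test_that("rank-deficient designs are rejected with the aliased column named", {
  cfg <- villi_config(50, seed = 69)
  coh <- generateCohort(cfg)
  sheet <- sampleSheet(coh$me)
  sheet$dup_ga <- sheet$ga_weeks
  me2 <- MethylExperiment(betaValues(coh$me), sheet)
  design <- designSpec(covariates = c("ga_weeks", "dup_ga"))
  expect_error(fitCpGModels(me2, design), "aliased|dup_ga")
})

test_that("CpGs with missing values are fit on complete cases with adjusted df", {
  cfg <- villi_config(60, n_aca_effect = 10, seed = 70)
  coh <- generateCohort(cfg)
  b <- betaValues(coh$me)
  set.seed(71)
  b[2, sample(ncol(b), 5)] <- NA
  me <- MethylExperiment(b, sampleSheet(coh$me))
  design <- designSpec(moderation = "none")
  fit <- fitCpGModels(me, design)
  # oracle: plain lm on the complete cases of that CpG
  sheet <- sampleSheet(me)
  sheet$aca_status <- factor(sheet$aca_status, c("non-aCA", "aCA"))
  sheet$m <- betaToM(b[2, ])
  lm_fit <- lm(m ~ aca_status + ga_weeks + factor(fetal_sex) + ancestry_1 +
                 ancestry_2, data = sheet)
  sm <- summary(lm_fit)$coefficients
  i <- which(fit$cpg_id == rownames(b)[2])
  expect_equal(fit$estimate[i], unname(sm["aca_statusaCA", "Estimate"]),
               tolerance = 1e-9)
  expect_equal(fit$t[i], unname(sm["aca_statusaCA", "t value"]),
               tolerance = 1e-9)
  expect_equal(fit$df[i], lm_fit$df.residual)
  # rows without missingness keep the full-sample df
  expect_equal(fit$df[1], ncol(b) - 6)
})
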