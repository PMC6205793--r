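test_that("config validation rejects impossible set sizes and ranges", {
  expect_error(simConfig(n_cpg = 100, n_tissue_specific = 200),
               "exceed n_cpg")
  expect_error(simConfig(mixture_fraction_range = c(0.5, 0.2)), "f_min")
  expect_error(simConfig(archetype_mix = c(0.5, 0.5, 0.5)), "summing to 1")
})

test_that("reference profiles separate planted cell-type CpGs from every other type", {
  cfg <- simConfig(n_cpg = 1000, n_tissue_specific = 30,
                   n_celltype_specific = 50,
                   effect_delta = c(celltype = 0.2), seed = 3)
  prof <- generateReferenceProfiles(cfg)
  neut <- prof$planted$neutrophil_specific
  idx <- match(neut$cpg_id, prof$cpg_ids)
  others <- setdiff(colnames(prof$profiles), "immune:neutrophil")
  gaps <- abs(prof$profiles[idx, "immune:neutrophil"] -
                prof$profiles[idx, others])
  expect_true(all(gaps >= 0.2 - 1e-9))
  expect_true(all(prof$profiles > 0 & prof$profiles < 1))
})

test_that("zero planted sets give identical profiles for all types", {
  cfg <- simConfig(n_cpg = 500, n_tissue_specific = 0,
                   n_celltype_specific = 0, n_aca_effect = 0,
                   n_ga_effect = 0, n_sex_effect = 0, seed = 4)
  prof <- generateReferenceProfiles(cfg)
  expect_true(all(prof$profiles == prof$profiles[, 1L]))
})

test_that("archetype mixture controls the intermediate fraction", {
  n <- 20000
  cfg <- simConfig(n_cpg = n, archetype_mix = c(low = 0.4,
                                                intermediate = 0.2,
                                                high = 0.4),
                   n_tissue_specific = 0, n_celltype_specific = 0,
                   n_ga_effect = 0, n_sex_effect = 0, seed = 5)
  prof <- generateReferenceProfiles(cfg)
  frac_mid <- mean(prof$archetype > 0.2 & prof$archetype < 0.8)
  expect_lt(abs(frac_mid - 0.2), 3 * sqrt(0.2 * 0.8 / n))
})

test_that("cohort bookkeeping: columns, sheet alignment, open-interval betas, GA ordering", {
  cfg <- simConfig(n_cpg = 600, n_tissue_specific = 30,
                   n_celltype_specific = 20, n_ga_effect = 20,
                   n_sex_effect = 10, seed = 6)
  coh <- generateCohort(cfg)
  sheet <- sampleSheet(coh$me)
  expect_identical(colnames(betaValues(coh$me)), sheet$sample_id)
  expect_equal(sum(sheet$tissue == "chorionic_villi"), 44L)
  b <- betaValues(coh$me)
  expect_true(all(b > 0 & b < 1))
  ga_aca <- mean(sheet$ga_weeks[sheet$tissue == "chorionic_villi" &
                                  sheet$aca_status == "aCA"])
  ga_non <- mean(sheet$ga_weeks[sheet$tissue == "chorionic_villi" &
                                  sheet$aca_status == "non-aCA"])
  expect_lt(ga_aca, ga_non)
  # every planted CpG exists in the emitted matrix, fractions in [0, 1]
  for (set in coh$truth$planted_cpg_sets)
    expect_true(all(set$cpg_id %in% rownames(b)))
  f <- coh$truth$sample_mixture_fractions
  expect_true(all(f >= 0 & f <= 1))
  aca_villi <- sheet$tissue == "chorionic_villi" & sheet$aca_status == "aCA"
  expect_true(all(f[aca_villi] >= 0.1 & f[aca_villi] <= 0.4))
  expect_true(all(f[!aca_villi] == 0))
})

test_that("same seed and config reproduce the cohort bit for bit", {
  cfg <- simConfig(n_cpg = 300, n_tissue_specific = 15,
                   n_celltype_specific = 10, n_ga_effect = 10,
                   n_sex_effect = 5, seed = 9)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(betaValues(a$me), betaValues(b$me))
  expect_identical(sampleSheet(a$me), sampleSheet(b$me))
  expect_identical(a$truth, b$truth)
})

test_that("mixture expectation: fixed f = 0.3 shifts neutrophil CpGs by 0.3 * (beta_neut - beta_villi)", {
  plan <- data.frame(tissue = "chorionic_villi",
                     aca_status = c("aCA", "non-aCA"), n = c(22L, 22L))
  cfg <- simConfig(n_cpg = 3000, sample_plan = plan, n_tissue_specific = 0,
                   n_celltype_specific = 100, n_aca_effect = 0,
                   n_ga_effect = 0, n_sex_effect = 0,
                   mixture_fraction_range = c(0.3, 0.3),
                   batch_effect_sd = 0, seed = 10)
  coh <- generateCohort(cfg)
  neut <- coh$truth$planted_cpg_sets$neutrophil_specific$cpg_id
  prof <- coh$truth$reference_profiles
  expected <- 0.3 * (prof[neut, "immune:neutrophil"] -
                       prof[neut, "chorionic_villi"])
  db <- deltaBeta(coh$me)[neut]
  # closed-form mixture expectation vs empirical mean over planted sites
  expect_lt(abs(mean(db - expected)), 0.02)
  expect_gt(cor(db, expected), 0.95)
})

test_that("mixture is monotone: larger f moves neutrophil CpGs further toward the neutrophil profile", {
  plan <- data.frame(tissue = "chorionic_villi", aca_status = "aCA", n = 20L)
  mean_gap <- function(fr) {
    cfg <- simConfig(n_cpg = 1500, sample_plan = plan, n_tissue_specific = 0,
                     n_celltype_specific = 80, n_aca_effect = 0,
                     n_ga_effect = 0, n_sex_effect = 0,
                     mixture_fraction_range = c(fr, fr),
                     batch_effect_sd = 0, seed = 11)
    coh <- generateCohort(cfg)
    neut <- coh$truth$planted_cpg_sets$neutrophil_specific$cpg_id
    prof <- coh$truth$reference_profiles
    mean(abs(rowMeans(betaValues(coh$me)[neut, ]) -
               prof[neut, "immune:neutrophil"]))
  }
  gaps <- vapply(c(0, 0.25, 0.5, 0.9), mean_gap, numeric(1L))
  expect_true(all(diff(gaps) < 0))
})

test_that("fully null cohort yields uniform EWAS p values and no BH calls", {
  cfg <- villi_config(8000, seed = 12, batch_effect_sd = 0)
  coh <- generateCohort(cfg)
  fit <- fitCpGModels(coh$me)
  expect_gt(ks.test(fit$p, "punif")$p.value, 0.01)
  expect_lte(sum(bhAdjust(fit$p) < 0.15), 2L)
  for (alpha in c(0.01, 0.05))
    expect_lt(abs(mean(fit$p < alpha) - alpha),
              3 * sqrt(alpha * (1 - alpha) / 8000))
})

test_that("genotype generator: shape, values, and population separation by MDS", {
  g <- generateGenotypes(40, 57, divergence = 0.6, seed = 13)
  expect_identical(dim(g$genotypes), c(40L, 57L))
  expect_true(all(g$genotypes %in% 0:2))
  mds <- ancestryMds(g$genotypes, k = 2)
  c1 <- mds@coordinates[, 1L]
  # midpoint threshold on coordinate 1 must recover the truth labels exactly
  thr <- mean(tapply(c1, g$population, mean))
  side <- as.integer(c1 > thr)
  err <- min(mean(side != g$population), mean(side != (1L - g$population)))
  expect_identical(err, 0)

  g0 <- generateGenotypes(40, 57, divergence = 0, seed = 14)
  mds0 <- ancestryMds(g0$genotypes, k = 2)
  c1 <- mds0@coordinates[, 1L]
  thr <- mean(tapply(c1, g0$population, mean))
  side <- as.integer(c1 > thr)
  err0 <- min(mean(side != g0$population), mean(side != (1L - g0$population)))
  expect_gt(err0, 0.2)
})
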