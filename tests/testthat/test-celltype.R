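ref_cohort <- function(n_cpg = 2000, n_celltype_specific = 60, seed = 81,
                       ...) {
  cfg <- reference_config(n_cpg, n_celltype_specific, seed = seed, ...)
  generateCohort(cfg)
}

test_that("signature derivation recovers planted cell-specific CpGs without cross-contamination", {
  coh <- ref_cohort(n_cpg = 2000, n_celltype_specific = 50, seed = 81)
  sig <- deriveCellSpecificCpGs(coh$me, "neutrophil")
  planted <- coh$truth$planted_cpg_sets$neutrophil_specific$cpg_id
  other <- unlist(lapply(c("eosinophil", "monocyte", "lymphoid"), function(ct)
    coh$truth$planted_cpg_sets[[paste0(ct, "_specific")]]$cpg_id))
  expect_gte(mean(planted %in% signatureCpGs(sig)), 0.9)
  expect_length(intersect(other, signatureCpGs(sig)), 0)
  expect_length(sig@evidence, 4L)
})

test_that("no planted cell-specific sites means an empty signature", {
  coh <- ref_cohort(n_cpg = 800, n_celltype_specific = 0, seed = 82)
  sig <- deriveCellSpecificCpGs(coh$me, "eosinophil")
  expect_length(signatureCpGs(sig), 0)
})

test_that("a missing contrast class is reported by name", {
  coh <- ref_cohort(n_cpg = 600, n_celltype_specific = 20, seed = 83)
  sheet <- sampleSheet(coh$me)
  no_mono <- coh$me[, sheet$tissue != "immune:monocyte"]
  expect_error(deriveCellSpecificCpGs(no_mono, "neutrophil"), "monocyte")
})

test_that("a hand-built intersection keeps only the CpG DM in all four contrasts", {
  # three CpGs: cg1 differs from everything, cg2 from all but monocytes,
  # cg3 from nothing
  classes <- c("chorionic_villi", "immune:neutrophil", "immune:eosinophil",
               "immune:monocyte", "immune:lymphoid")
  n_per <- 5L
  set.seed(84)
  build <- function(cls) {
    lev <- matrix(0.2, 3, n_per)
    if (cls == "immune:neutrophil") lev[1:2, ] <- 0.8
    if (cls == "immune:monocyte") lev[2, ] <- 0.8
    lev + matrix(rnorm(3 * n_per, 0, 0.01), 3, n_per)
  }
  beta <- do.call(cbind, lapply(classes, build))
  dimnames(beta) <- list(c("cg1", "cg2", "cg3"),
                         sprintf("s%02d", seq_len(ncol(beta))))
  sheet <- data.frame(sample_id = colnames(beta),
                      tissue = rep(classes, each = n_per))
  me <- MethylExperiment(beta, sheet)
  sig <- deriveCellSpecificCpGs(me, "neutrophil", fdr_max = 0.05,
                                delta_beta_min = 0.2)
  expect_identical(signatureCpGs(sig), "cg1")
})

test_that("tightening thresholds never grows a signature", {
  coh <- ref_cohort(n_cpg = 1200, n_celltype_specific = 40, seed = 85)
  loose <- signatureCpGs(deriveCellSpecificCpGs(coh$me, "neutrophil",
                                                fdr_max = 0.10,
                                                delta_beta_min = 0.10))
  tight <- signatureCpGs(deriveCellSpecificCpGs(coh$me, "neutrophil",
                                                fdr_max = 0.01,
                                                delta_beta_min = 0.30))
  expect_true(all(tight %in% loose))
})

test_that("trend concordance is perfect against a reference equal to the aCA means", {
  cfg <- villi_config(500, n_aca_effect = 80, seed = 86)
  coh <- generateCohort(cfg)
  sheet <- sampleSheet(coh$me)
  aca_means <- rowMeans(betaValues(coh$me)[, sheet$aca_status == "aCA"])
  ref_beta <- cbind(r1 = aca_means, r2 = aca_means)
  ref <- MethylExperiment(ref_beta, data.frame(sample_id = c("r1", "r2")))
  dm <- runEwas(coh$me)
  res <- trendConcordanceTest(dmCpGs(dm), coh$me, ref, n_draws = 1000,
                              seed = 8)
  expect_equal(res@fraction, 1)
  expect_lt(res@binomialP, 0.01)
})

test_that("an independent reference gives ~50% concordance", {
  cfg <- villi_config(2000, n_aca_effect = 0, seed = 87)
  coh <- generateCohort(cfg)
  set.seed(88)
  ref_beta <- matrix(runif(2000 * 4, 0.05, 0.95), 2000, 4,
                     dimnames = list(rownames(coh$me), paste0("r", 1:4)))
  ref <- MethylExperiment(ref_beta, data.frame(sample_id = paste0("r", 1:4)))
  sites <- sample(rownames(coh$me), 200)
  res <- trendConcordanceTest(sites, coh$me, ref, n_draws = 500, seed = 9)
  expect_lt(abs(res@fraction - 0.5), 0.12)
  expect_gt(res@binomialP, 0.01)
  # the fraction equals a brute-force per-site sign comparison
  sheet <- sampleSheet(coh$me)
  b <- betaValues(coh$me)
  da <- sign(rowMeans(b[sites, sheet$aca_status == "aCA"]) -
               rowMeans(b[sites, sheet$aca_status == "non-aCA"]))
  db <- sign(rowMeans(ref_beta[sites, ]) -
               rowMeans(b[sites, sheet$aca_status == "non-aCA"]))
  ok <- da != 0 & db != 0
  expect_equal(res@fraction, sum(da[ok] == db[ok]) / sum(ok))
})

test_that("a neutrophil-mixture cohort trends with the neutrophil reference", {
  fracs <- numeric(0)
  ps <- numeric(0)
  for (s in 1:3) {
    plan <- data.frame(tissue = "chorionic_villi",
                       aca_status = c("aCA", "non-aCA"), n = c(22L, 22L))
    cfg <- simConfig(n_cpg = 3000, sample_plan = plan, n_tissue_specific = 0,
                     n_celltype_specific = 100, n_aca_effect = 0,
                     n_ga_effect = 0, n_sex_effect = 0,
                     mixture_fraction_range = c(0.2, 0.4), seed = 88 + s)
    coh <- generateCohort(cfg)
    dm <- runEwas(coh$me)
    prof <- coh$truth$reference_profiles
    ref <- MethylExperiment(
      cbind(n1 = prof[, "immune:neutrophil"],
            n2 = prof[, "immune:neutrophil"]),
      data.frame(sample_id = c("n1", "n2")))
    if (length(dmCpGs(dm)) == 0) next
    res <- trendConcordanceTest(dmCpGs(dm), coh$me, ref, n_draws = 500,
                                seed = s)
    fracs <- c(fracs, res@fraction)
    ps <- c(ps, res@binomialP)
  }
  expect_gt(mean(fracs), 0.5)
  expect_lt(min(ps), 0.01)
})

test_that("hierarchical clustering handles the textbook small cases", {
  # two samples: a single merge at their distance
  b2 <- matrix(c(0.2, 0.2, 0.8, 0.8), 2, 2,
               dimnames = list(c("cg1", "cg2"), c("s1", "s2")))
  hc2 <- hierarchicalCluster(tiny_me(b2), c("cg1", "cg2"))
  expect_equal(length(hc2$tree$height), 1L)
  expect_equal(hc2$tree$height, sqrt(2 * 0.6^2), tolerance = 1e-12)

  # three collinear points 0, 1, 10 with average linkage
  b3 <- matrix(c(0, 1, 10) / 10, 1, 3,
               dimnames = list("cg1", c("a", "b", "c")))
  hc3 <- hierarchicalCluster(tiny_me(b3), "cg1")
  expect_equal(hc3$tree$merge[1, ], c(-1, -2))
  expect_equal(hc3$tree$height, c(1, 9.5) / 10, tolerance = 1e-12)

  # a duplicated sample merges first at height 0
  b4 <- cbind(b2, s3 = b2[, "s1"])
  hc4 <- hierarchicalCluster(tiny_me(b4), c("cg1", "cg2"))
  expect_equal(hc4$tree$height[1], 0)
  expect_setequal(-hc4$tree$merge[1, ], c(1, 3))
})

test_that("well-separated groups earn AU >= 0.95 and BP at scale 1 matches a plain bootstrap", {
  set.seed(91)
  b <- matrix(runif(300 * 20, 0.4, 0.6), 300, 20)
  b[1:150, 1:10] <- b[1:150, 1:10] + 0.35
  dimnames(b) <- list(sprintf("cg%03d", 1:300), sprintf("s%02d", 1:20))
  me <- tiny_me(b)
  boot <- multiscaleBootstrapAU(me, rownames(b), n_boot = 400, seed = 10)
  root <- nrow(boot$tree$merge)
  kids <- boot$tree$merge[root, ]
  kids <- kids[kids > 0]
  expect_true(all(boot$nodes$au[kids] >= 0.95))
  expect_true(auStableTwoClusters(boot))

  # BP at scale 1 is the plain bootstrap proportion, by definition
  plain <- local({
    X <- t(b)
    tree <- hclust(dist(X), method = "average")
    sets <- methylaCA:::.node_leaf_sets(tree)
    keys <- methylaCA:::.leaf_keys(sets, nrow(X))
    set.seed(99)
    cnt <- numeric(length(keys))
    for (i in 1:400) {
      idx <- sample.int(ncol(X), replace = TRUE)
      bt <- hclust(dist(X[, idx]), method = "average")
      bk <- methylaCA:::.leaf_keys(methylaCA:::.node_leaf_sets(bt), nrow(X))
      cnt <- cnt + !is.na(match(keys, bk))
    }
    cnt / 400
  })
  bp <- boot$nodes$bp
  se <- sqrt(pmax(plain * (1 - plain), 0.002) / 400)
  expect_true(all(abs(bp - plain) < 4 * se + 0.05))
})

test_that("split significance separates planted clusters and respects the degenerate case", {
  set.seed(92)
  b <- matrix(runif(200 * 16, 0.4, 0.6), 200, 16)
  b[1:100, 1:8] <- b[1:100, 1:8] + 0.35
  dimnames(b) <- list(sprintf("cg%03d", 1:200), sprintf("s%02d", 1:16))
  me <- tiny_me(b)
  cs <- clusterSignificance(me, rownames(b), n_sim = 500, seed = 11)
  expect_lte(cs$p, 0.01)

  # both sides identical point sets: CI = 1, p -> 1
  half <- matrix(runif(50 * 4, 0.3, 0.7), 50, 4)
  b_id <- cbind(half, half)
  dimnames(b_id) <- list(sprintf("cg%03d", 1:50), sprintf("s%02d", 1:8))
  me_id <- tiny_me(b_id)
  lab <- setNames(rep(c(1L, 2L), each = 4), colnames(b_id))
  cs_id <- clusterSignificance(me_id, rownames(b_id), assignments = lab,
                               n_sim = 200, seed = 12)
  expect_equal(cs_id$ci_observed, 1, tolerance = 1e-12)
  expect_gt(cs_id$p, 0.95)
})

test_that("cluster-phenotype enrichment reproduces the printed cluster table significance", {
  # 17/22 aCA in cluster 1 vs 5/20 in cluster 2
  assignments <- setNames(rep(c(1L, 2L), c(22, 20)), sprintf("s%02d", 1:42))
  phenotype <- setNames(c(rep("aCA", 17), rep("non-aCA", 5),
                          rep("aCA", 5), rep("non-aCA", 15)),
                        names(assignments))
  enr <- clusterPhenotypeEnrichment(assignments, phenotype)
  expect_lt(enr$p, 0.005)
  expect_equal(enr$p, fisher2x2_oracle(matrix(c(17, 5, 5, 15), 2,
                                              byrow = TRUE)),
               tolerance = 1e-9)

  balanced <- clusterPhenotypeEnrichment(
    setNames(c(1L, 1L, 2L, 2L), paste0("s", 1:4)),
    setNames(c("a", "b", "a", "b"), paste0("s", 1:4)))
  expect_equal(balanced$p, 1)
})

test_that("the full signature-clustering report separates mixture-driven aCA cases", {
  cfg <- simConfig(n_cpg = 1500, n_tissue_specific = 0,
                   n_celltype_specific = 60, n_aca_effect = 0,
                   n_ga_effect = 0, n_sex_effect = 0, seed = 93)
  coh <- generateCohort(cfg)
  sheet <- sampleSheet(coh$me)
  villi <- coh$me[, sheet$tissue == "chorionic_villi"]
  sig <- coh$truth$planted_cpg_sets$neutrophil_specific$cpg_id
  rep <- clusterCellSignature(villi, sig, n_boot = 200, n_sim = 200,
                              seed = 13)
  expect_lt(rep@enrichment$p, 0.005)
  expect_lt(rep@splitP, 0.05)
  expect_s4_class(rep, "ClusterReport")
  # the report writes as JSON + Newick
  path <- withr::local_tempfile(fileext = ".json")
  writeResults(rep, path)
  expect_true(file.exists(path))
  nwk <- readLines(paste0(path, ".nwk"))
  expect_match(nwk, "^\\(.*\\).*;$")
})
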