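.CELL_CLASSES <- c("neutrophil", "eosinophil", "monocyte", "lymphoid")

# tissue labels making up one immune class (lymphoid may be pooled T/B/NK)
.cell_class_tissues <- function(class) {
  if (class == "lymphoid")
    c("immune:lymphoid", "immune:tcell", "immune:bcell", "immune:nkcell")
  else paste0("immune:", class)
}

#' Derive a cell-type-specific CpG signature
#'
#' Runs one differential-methylation contrast of the target immune class
#' against chorionic villi and against each other immune class (lymphoid
#' pooled as T + B + NK when split), and takes the intersection of the DM
#' sets across all contrasts at the configured thresholds. The signature is
#' the set of CpGs DM in every contrast.
#'
#' @param ref a [MethylExperiment-class] containing reference samples:
#'   chorionic villi plus each immune class (>= 2 samples each).
#' @param cell_type one of `"neutrophil"`, `"eosinophil"`, `"monocyte"`,
#'   `"lymphoid"`.
#' @param fdr_max,delta_beta_min DM thresholds per contrast (defaults 0.05
#'   and 0.20).
#' @param moderation variance moderation for the contrast fits.
#' @return a [CellSignature-class].
#' @export
deriveCellSpecificCpGs <- function(ref, cell_type = "neutrophil",
                                   fdr_max = 0.05, delta_beta_min = 0.20,
                                   moderation = "empirical_bayes") {
  cell_type <- match.arg(cell_type, .CELL_CLASSES)
  sheet <- sampleSheet(ref)
  class_of <- function(tis) {
    for (cl in .CELL_CLASSES) if (tis %in% .cell_class_tissues(cl)) return(cl)
    if (tis == "chorionic_villi") return("chorionic_villi")
    NA_character_
  }
  cls <- vapply(sheet$tissue, class_of, character(1L))
  partners <- c("chorionic_villi", setdiff(.CELL_CLASSES, cell_type))
  missing_cls <- c(cell_type, partners)[
    !(c(cell_type, partners) %in% cls) |
      vapply(c(cell_type, partners), function(x) sum(cls == x, na.rm = TRUE),
             integer(1L)) < 2L]
  if (length(missing_cls))
    .stopf("contrast class(es) missing or with < 2 samples: %s",
           paste(unique(missing_cls), collapse = ", "))

  sets <- list()
  evidence <- list()
  for (partner in partners) {
    sel <- !is.na(cls) & cls %in% c(cell_type, partner)
    cls_sub <- factor(ifelse(cls[sel] == cell_type, "target", "other"),
                      levels = c("other", "target"))
    me_sub <- ref[, sel]
    sheet_sub <- sampleSheet(me_sub)
    sheet_sub$contrast_class <- cls_sub
    colData(me_sub) <- DataFrame(sheet_sub)
    design <- designSpec(primary = "contrast_class", covariates = character(0),
                         primary_levels = c("other", "target"),
                         moderation = moderation)
    dm <- runEwas(me_sub, design, fdr_max = fdr_max,
                  delta_beta_min = delta_beta_min)
    contrast <- sprintf("%s_vs_%s", cell_type, partner)
    sets[[contrast]] <- dmCpGs(dm)
    tab <- dmTable(dm)
    evidence[[contrast]] <- tab[, c("cpg_id", "q", "delta_beta")]
  }
  signature <- Reduce(intersect, sets)
  evidence <- lapply(evidence, function(tab)
    tab[match(signature, tab$cpg_id), , drop = FALSE])
  new("CellSignature", cellType = cell_type,
      cpgIds = as.character(signature), evidence = evidence,
      thresholds = c(fdr_max = fdr_max, delta_beta_min = delta_beta_min))
}

#' Trend concordance of DM sites with an immune cell reference
#'
#' For each DM site available on the reference platform, compares the
#' direction of the aCA-vs-non-aCA difference in villi with the direction
#' of the cell-reference-vs-non-aCA-villi difference; a site is concordant
#' when both signs agree and are nonzero (tied means are excluded from the
#' denominator). Reports the binomial upper-tail p under a 0.5 null and an
#' empirical p from random same-size CpG sets drawn from the tested
#' background.
#'
#' @param dm_cpgs character vector of DM CpG ids.
#' @param villi a [MethylExperiment-class] of chorionic villi with
#'   `aca_status`.
#' @param ref a [MethylExperiment-class] of reference samples for one cell
#'   type (its CpG set defines platform availability).
#' @param background CpG ids eligible for the random-set null (defaults to
#'   the villi/reference intersection).
#' @param n_draws random draws for the empirical null.
#' @param seed RNG seed.
#' @return a [ConcordanceResult-class].
#' @export
trendConcordanceTest <- function(dm_cpgs, villi, ref, background = NULL,
                                 n_draws = 10000, seed = 1L) {
  common_bg <- intersect(rownames(villi), rownames(ref))
  if (is.null(background)) background <- common_bg
  background <- intersect(background, common_bg)
  sites <- intersect(dm_cpgs, common_bg)
  n_dropped <- length(dm_cpgs) - length(sites)
  if (!length(sites)) .stopf("zero evaluable sites on the reference platform")

  sheet <- sampleSheet(villi)
  aca <- !is.na(sheet$aca_status) & sheet$aca_status == "aCA"
  non <- !is.na(sheet$aca_status) & sheet$aca_status == "non-aCA"
  if (!any(aca) || !any(non)) .stopf("villi must contain both aCA groups")
  beta_v <- betaValues(villi)
  beta_r <- betaValues(ref)
  mean_aca <- rowMeans(beta_v[, aca, drop = FALSE], na.rm = TRUE)
  mean_non <- rowMeans(beta_v[, non, drop = FALSE], na.rm = TRUE)
  mean_ref <- rowMeans(beta_r[, , drop = FALSE], na.rm = TRUE)

  concordance <- function(ids) {
    da <- sign(mean_aca[ids] - mean_non[ids])
    db <- sign(mean_ref[ids] - mean_non[ids])
    ok <- da != 0 & db != 0 & !is.na(da) & !is.na(db)
    c(n_eval = sum(ok), n_conc = sum(da[ok] == db[ok]))
  }
  obs <- concordance(sites)
  if (obs[["n_eval"]] == 0L) .stopf("zero evaluable sites (all directions tied)")
  frac <- obs[["n_conc"]] / obs[["n_eval"]]
  binom_p <- pbinom(obs[["n_conc"]] - 1L, obs[["n_eval"]], 0.5,
                    lower.tail = FALSE)

  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_draws)) {
    draw <- sample(background, length(sites))
    cc <- concordance(draw)
    f <- if (cc[["n_eval"]] > 0L) cc[["n_conc"]] / cc[["n_eval"]] else 0
    if (f >= frac) hits <- hits + 1L
  }
  emp_p <- (1 + hits) / (n_draws + 1)

  da <- sign(mean_aca[sites] - mean_non[sites])
  db <- sign(mean_ref[sites] - mean_non[sites])
  directions <- data.frame(
    cpg_id = sites,
    direction_aca = da, direction_cell = db,
    concordant = da != 0 & db != 0 & da == db,
    stringsAsFactors = FALSE, row.names = NULL)
  new("ConcordanceResult",
      nEvaluable = as.integer(obs[["n_eval"]]),
      nConcordant = as.integer(obs[["n_conc"]]),
      fraction = frac, binomialP = binom_p, empiricalP = emp_p,
      directions = directions)
}

# sample x feature data matrix for clustering on a signature
.cluster_data <- function(me, cpg_ids, scale = c("beta", "M")) {
  scale <- match.arg(scale)
  if (!length(cpg_ids)) .stopf("empty signature: nothing to cluster on")
  missing_cpg <- setdiff(cpg_ids, rownames(me))
  if (length(missing_cpg))
    .stopf("signature CpG '%s' absent from the experiment", missing_cpg[1L])
  x <- if (scale == "M") mValues(me)[cpg_ids, , drop = FALSE]
       else betaValues(me)[cpg_ids, , drop = FALSE]
  t(x)
}

#' Hierarchical clustering of samples on a CpG signature
#'
#' Deterministic agglomerative clustering of samples (Euclidean distance on
#' beta values by default). Heights are non-decreasing for monotone
#' linkages; merge-distance ties are broken by lowest pair index (the
#' behaviour of [stats::hclust()]).
#'
#' @param me a [MethylExperiment-class] (>= 2 samples).
#' @param cpg_ids signature CpG ids (>= 1).
#' @param scale cluster on `"beta"` (default) or `"M"` values.
#' @param linkage agglomeration method (default `"average"`).
#' @return list with `tree` (`hclust`) and `assignments` (named k = 2 cut).
#' @export
hierarchicalCluster <- function(me, cpg_ids, scale = "beta",
                                linkage = "average") {
  X <- .cluster_data(me, cpg_ids, scale)
  if (nrow(X) < 2L) .stopf("need at least 2 samples to cluster")
  tree <- hclust(dist(X), method = linkage)
  assignments <- cutree(tree, k = 2L)
  list(tree = tree, assignments = assignments)
}

#' Multiscale bootstrap cluster support (BP and AU)
#'
#' For each scale `r`, resamples the signature CpGs (features) with
#' replacement to size `round(r * n_cpg)`, reclusters the samples, and
#' records per original node the bootstrap probability `BP_r` — the
#' fraction of bootstrap trees containing the identical leaf set. The
#' approximately unbiased value fits `z_r = qnorm(1 - BP_r)` against
#' `(sqrt(r), 1/sqrt(r))` by weighted least squares with binomial-variance
#' weights, giving `AU = 1 - pnorm(v - c)` for fitted coefficients
#' `(v, c)`. The reported BP is the plain bootstrap proportion at scale
#' r = 1.
#'
#' Nodes observed at fewer than two scales with informative BP cannot be
#' extrapolated: a node with BP = 1 everywhere gets AU = 1, one never
#' observed gets AU = 0, both flagged `"degenerate"`.
#'
#' @param me a [MethylExperiment-class].
#' @param cpg_ids signature CpG ids.
#' @param scale,linkage as in [hierarchicalCluster()].
#' @param scales relative resampling sizes (>= 2 values; default 10 values
#'   in `[0.5, 1.4]`, including 1).
#' @param n_boot bootstrap replicates per scale (>= 100).
#' @param seed RNG seed.
#' @return list with `tree` and `nodes` (`data.frame`: `node`, `n_leaves`,
#'   `members`, `bp`, `au`, `flag`).
#' @export
multiscaleBootstrapAU <- function(me, cpg_ids, scale = "beta",
                                  linkage = "average",
                                  scales = seq(0.5, 1.4, by = 0.1),
                                  n_boot = 1000, seed = 1L) {
  if (length(scales) < 2L) .stopf("need at least 2 scales")
  if (n_boot < 100) .stopf("n_boot must be at least 100")
  X <- .cluster_data(me, cpg_ids, scale)
  n_samp <- nrow(X)
  n_cpg <- ncol(X)
  tree <- hclust(dist(X), method = linkage)
  leaf_sets <- .node_leaf_sets(tree)
  keys <- .leaf_keys(leaf_sets, n_samp)
  n_nodes <- length(keys)

  set.seed(seed)
  counts <- matrix(0L, nrow = n_nodes, ncol = length(scales))
  for (si in seq_along(scales)) {
    size <- max(2L, round(scales[si] * n_cpg))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n_cpg, size, replace = TRUE)
      bt <- hclust(dist(X[, idx, drop = FALSE]), method = linkage)
      bkeys <- .leaf_keys(.node_leaf_sets(bt), n_samp)
      hit <- match(keys, bkeys)
      counts[!is.na(hit), si] <- counts[!is.na(hit), si] + 1L
    }
  }
  bp_mat <- counts / n_boot
  r1 <- which.min(abs(scales - 1))

  au <- numeric(n_nodes)
  flag <- character(n_nodes)
  for (i in seq_len(n_nodes)) {
    bp <- bp_mat[i, ]
    if (all(bp == 0)) {
      au[i] <- 0
      flag[i] <- "degenerate"
      next
    }
    if (all(bp == 1)) {
      au[i] <- 1
      flag[i] <- "degenerate"
      next
    }
    use <- bp > 0 & bp < 1
    if (sum(use) < 2L) {
      au[i] <- bp_mat[i, r1]
      flag[i] <- "insufficient_scales"
      next
    }
    r <- scales[use]
    z <- qnorm(1 - bp[use])
    w <- n_boot * dnorm(z)^2 / (bp[use] * (1 - bp[use]))
    Xd <- cbind(v = sqrt(r), c = 1 / sqrt(r))
    cf <- tryCatch(
      solve(crossprod(Xd * sqrt(w)), crossprod(Xd * sqrt(w), z * sqrt(w))),
      error = function(e) NULL)
    if (is.null(cf)) {
      au[i] <- bp_mat[i, r1]
      flag[i] <- "fit_failed"
      next
    }
    au[i] <- 1 - pnorm(cf["v", 1L] - cf["c", 1L])
    flag[i] <- ""
  }
  members <- vapply(leaf_sets, function(ix)
    paste(tree$labels[sort(ix)], collapse = ","), character(1L))
  nodes <- data.frame(
    node = seq_len(n_nodes),
    n_leaves = lengths(leaf_sets),
    members = members,
    bp = bp_mat[, r1],
    au = au,
    flag = flag,
    stringsAsFactors = FALSE)
  list(tree = tree, nodes = nodes, scales = scales, n_boot = n_boot)
}

# cluster index: within-split sum of squares over total sum of squares
.cluster_index <- function(X, labels) {
  grand <- colMeans(X)
  tot <- sum(sweep(X, 2L, grand)^2)
  wss <- 0
  for (cl in unique(labels)) {
    Xi <- X[labels == cl, , drop = FALSE]
    wss <- wss + sum(sweep(Xi, 2L, colMeans(Xi))^2)
  }
  wss / tot
}

#' Monte-Carlo significance of a two-way cluster split
#'
#' The observed statistic is the cluster index CI of the k = 2 split:
#' within-cluster sum of squares divided by the total sum of squares about
#' the grand mean. The null clusters `n_sim` datasets drawn from a single
#' Gaussian with diagonal covariance equal to the per-CpG sample variances
#' the same way (same linkage, k = 2 cut) and records each best 2-split
#' CI; `p = (1 + #{null CI <= observed}) / (n_sim + 1)`. Small CI means
#' real two-group separation.
#'
#' @param me a [MethylExperiment-class].
#' @param cpg_ids signature CpG ids.
#' @param assignments k = 2 split to test (defaults to the tree's own
#'   k = 2 cut); both sides must be nonempty.
#' @param scale,linkage as in [hierarchicalCluster()].
#' @param n_sim null simulations (>= 100).
#' @param seed RNG seed.
#' @return list with `p`, `ci_observed` and `ci_null`.
#' @export
clusterSignificance <- function(me, cpg_ids, assignments = NULL,
                                scale = "beta", linkage = "average",
                                n_sim = 1000, seed = 1L) {
  if (n_sim < 100) .stopf("n_sim must be at least 100")
  X <- .cluster_data(me, cpg_ids, scale)
  if (is.null(assignments)) {
    assignments <- cutree(hclust(dist(X), method = linkage), k = 2L)
  }
  if (!is.null(names(assignments)))
    assignments <- assignments[rownames(X)]
  if (length(unique(assignments)) != 2L)
    .stopf("degenerate split: need two nonempty sides")
  ci_obs <- .cluster_index(X, assignments)
  n <- nrow(X)
  p_feat <- ncol(X)
  sds <- apply(X, 2L, sd)
  set.seed(seed)
  ci_null <- numeric(n_sim)
  for (s in seq_len(n_sim)) {
    X0 <- matrix(rnorm(n * p_feat, 0, rep(sds, each = n)), nrow = n)
    lab0 <- cutree(hclust(dist(X0), method = linkage), k = 2L)
    ci_null[s] <- .cluster_index(X0, lab0)
  }
  p <- (1 + sum(ci_null <= ci_obs)) / (n_sim + 1)
  list(p = p, ci_observed = ci_obs, ci_null = ci_null)
}

#' Cluster-phenotype enrichment
#'
#' Cross-tabulates the k = 2 cluster assignments against a two-level
#' phenotype and tests enrichment with a two-sided Fisher exact test
#' (hypergeometric enumeration); when a sample sheet is supplied, also
#' emits demographic comparisons of the two clusters (GA, maternal age,
#' birth weight, sex) via [compareGroupCovariates()].
#'
#' @param assignments named k = 2 cluster vector.
#' @param phenotype named phenotype vector (or sheet column values aligned
#'   to `assignments`).
#' @param sheet optional sample sheet for the demographic table.
#' @return list with `table` (2 x 2), `p`, and `demographics` (or `NULL`).
#' @export
clusterPhenotypeEnrichment <- function(assignments, phenotype,
                                       sheet = NULL) {
  if (!is.null(names(phenotype)))
    phenotype <- phenotype[names(assignments)]
  keep <- !is.na(phenotype)
  tab <- table(cluster = assignments[keep], phenotype = phenotype[keep])
  if (any(dim(tab) < 2L))
    .stopf("need two clusters and two phenotype levels (empty cluster?)")
  p <- fisher.test(tab)$p.value
  demo <- NULL
  if (!is.null(sheet)) {
    sheet <- sheet[match(names(assignments), sheet$sample_id), ,
                   drop = FALSE]
    sheet$cluster <- paste0("cluster", assignments)
    demo <- compareGroupCovariates(sheet, group = "cluster")
  }
  list(table = tab, p = p, demographics = demo)
}

#' Cluster samples on a cell signature, with stability and enrichment
#'
#' End-to-end clustering report for one cell-type signature: hierarchical
#' clustering of the samples on the signature CpGs, multiscale-bootstrap
#' AU/BP per node, Monte-Carlo significance of the k = 2 split, and
#' phenotype enrichment of the two clusters.
#'
#' @param me a [MethylExperiment-class] (e.g. the 44 chorionic villi).
#' @param signature a [CellSignature-class] or character vector of CpG ids.
#' @param phenotype sheet column for enrichment (default `"aca_status"`).
#' @param scale,linkage clustering options.
#' @param scales,n_boot multiscale bootstrap options.
#' @param n_sim split-significance simulations.
#' @param seed RNG seed (bootstrap and null simulations derive from it).
#' @return a [ClusterReport-class].
#' @export
clusterCellSignature <- function(me, signature, phenotype = "aca_status",
                                 scale = "beta", linkage = "average",
                                 scales = seq(0.5, 1.4, by = 0.1),
                                 n_boot = 1000, n_sim = 1000, seed = 1L) {
  cpg_ids <- if (is(signature, "CellSignature")) signatureCpGs(signature)
             else as.character(signature)
  boot <- multiscaleBootstrapAU(me, cpg_ids, scale = scale,
                                linkage = linkage, scales = scales,
                                n_boot = n_boot, seed = seed)
  assignments <- cutree(boot$tree, k = 2L)
  sig <- clusterSignificance(me, cpg_ids, assignments = assignments,
                             scale = scale, linkage = linkage,
                             n_sim = n_sim, seed = seed + 1L)
  sheet <- sampleSheet(me)
  enr <- clusterPhenotypeEnrichment(assignments,
                                    setNames(sheet[[phenotype]],
                                             sheet$sample_id),
                                    sheet = sheet)
  new("ClusterReport", tree = boot$tree, nodes = boot$nodes,
      splitP = sig$p, assignments = assignments, enrichment = enr)
}

#' Is there AU-stable two-cluster structure?
#'
#' TRUE iff the dendrogram root splits the samples into two clusters of at
#' least two samples each, both supported at `AU >= threshold`. A root
#' whose split peels off a single sample is an outlier, not two-cluster
#' structure (a one-sample side cannot carry cluster support, and no split
#' test accepts it), so it never qualifies.
#'
#' @param report a [ClusterReport-class] or the list from
#'   [multiscaleBootstrapAU()].
#' @param threshold AU support threshold (default 0.95).
#' @return logical.
#' @export
auStableTwoClusters <- function(report, threshold = 0.95) {
  tree <- if (is(report, "ClusterReport")) report@tree else report$tree
  nodes <- if (is(report, "ClusterReport")) report@nodes else report$nodes
  root <- nrow(tree$merge)
  children <- tree$merge[root, ]
  if (any(children < 0)) return(FALSE)  # singleton side: outlier, not a cluster
  all(nodes$au[children] >= threshold)
}
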