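#' Ancestry inference by classical multidimensional scaling
#'
#' Computes pairwise distances between samples from a 0/1/2 genotype matrix
#' (allele-sharing distance `mean(|g_i - g_j|) / 2`, or Euclidean) and
#' embeds them by classical (Torgerson) MDS: square the distances,
#' double-center, eigendecompose, and scale the top-k eigenvectors by the
#' square root of their eigenvalues. Missing genotypes are mean-imputed per
#' SNP before distances; SNPs with zero variance after imputation are
#' dropped with a warning. The result is deterministic up to sign; each
#' coordinate's sign is fixed so its largest-magnitude entry is positive.
#'
#' @param genotypes samples x SNP matrix of 0/1/2 (NA allowed).
#' @param k number of coordinates (`k < n_samples`).
#' @param distance `"allele_sharing"` or `"euclidean"`.
#' @return an [MdsResult-class].
#' @export
ancestryMds <- function(genotypes, k = 2,
                        distance = c("allele_sharing", "euclidean")) {
  distance <- match.arg(distance)
  g <- as.matrix(genotypes)
  n <- nrow(g)
  if (k >= n) .stopf("k must be smaller than the number of samples")
  snp_names <- colnames(g)
  if (is.null(snp_names)) snp_names <- paste0("snp", seq_len(ncol(g)))
  all_missing <- colSums(!is.na(g)) == 0L
  if (any(all_missing))
    .stopf("SNP '%s' is missing in every sample",
           snp_names[all_missing][1L])
  for (j in which(colSums(is.na(g)) > 0L)) {
    g[is.na(g[, j]), j] <- mean(g[, j], na.rm = TRUE)
  }
  v <- apply(g, 2L, var)
  if (any(v == 0))
    .warnf("%d SNP(s) with zero variance contribute nothing to distances",
           sum(v == 0))
  if (ncol(g) < 2L) .stopf("fewer than 2 usable SNPs")
  d <- if (distance == "allele_sharing") {
    # 1 - identity-by-state proportion
    dst <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      di <- colMeans(abs(t(g[(i + 1L):n, , drop = FALSE]) - g[i, ])) / 2
      dst[i, (i + 1L):n] <- di
      dst[(i + 1L):n, i] <- di
    }
    stats::as.dist(dst)
  } else {
    dist(g)
  }
  fit <- suppressWarnings(cmdscale(d, k = k, eig = TRUE))
  coords <- fit$points
  if (ncol(coords) < k)  # degenerate configurations span < k dimensions
    coords <- cbind(coords, matrix(0, n, k - ncol(coords)))
  # fix signs for reproducibility
  for (j in seq_len(ncol(coords))) {
    if (coords[which.max(abs(coords[, j])), j] < 0)
      coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("MDS", seq_len(ncol(coords)))
  rownames(coords) <- rownames(g)
  new("MdsResult", coordinates = coords, eigenvalues = fit$eig,
      k = as.integer(k))
}

#' Group-wise demographic comparisons
#'
#' Compares covariates between two groups in the layout of a cohort
#' demographics table: two-sided Wilcoxon-Mann-Whitney rank-sum tests for
#' continuous covariates (exact distribution when the combined sample size
#' is at most 30 and there are no ties, normal approximation with tie
#' correction otherwise), two-sided Fisher exact tests for categorical
#' covariates, and two-sample Kolmogorov-Smirnov tests for ancestry MDS
#' coordinates. A covariate constant in both groups is reported with p = 1
#' and a note.
#'
#' @param sheet sample sheet `data.frame`.
#' @param group name of the two-level grouping column (default
#'   `"aca_status"`).
#' @param continuous,categorical,ancestry covariate column names (absent
#'   columns are skipped; `ancestry = NULL` auto-detects columns starting
#'   with `"ancestry"`).
#' @return `data.frame` with columns `variable`, `test`,
#'   `summary_<group1>`, `summary_<group2>` (range and mean, or counts), `p`
#'   and `note`.
#' @export
compareGroupCovariates <- function(sheet, group = "aca_status",
                                   continuous = c("ga_weeks", "maternal_age",
                                                  "birth_weight_sd"),
                                   categorical = c("fetal_sex"),
                                   ancestry = NULL) {
  g <- sheet[[group]]
  if (is.null(g)) .stopf("grouping column '%s' not in sheet", group)
  keep <- !is.na(g)
  sheet <- sheet[keep, , drop = FALSE]
  g <- factor(g[keep])
  if (nlevels(g) != 2L) .stopf("grouping must have exactly two levels")
  lv <- levels(g)
  if (is.null(ancestry))
    ancestry <- grep("^ancestry", names(sheet), value = TRUE)
  continuous <- intersect(continuous, names(sheet))
  categorical <- intersect(categorical, names(sheet))
  ancestry <- intersect(ancestry, names(sheet))

  cont_summary <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return("NA")
    sprintf("%.3g-%.3g (%.4g)", min(x), max(x), mean(x))
  }
  rows <- list()
  add_row <- function(variable, test, s1, s2, p, note = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, test = test, summary_1 = s1, summary_2 = s2,
      p = p, note = note, stringsAsFactors = FALSE)
  }
  test_continuous <- function(col, x, test_name = "wilcoxon") {
    x1 <- x[g == lv[1L]]
    x2 <- x[g == lv[2L]]
    s1 <- cont_summary(x1)
    s2 <- cont_summary(x2)
    if (length(unique(na.omit(x))) <= 1L) {
      add_row(col, test_name, s1, s2, 1, "constant in both groups")
      return(invisible())
    }
    if (test_name == "wilcoxon") {
      n_tot <- sum(!is.na(x1)) + sum(!is.na(x2))
      exact <- n_tot <= 30 && !any(duplicated(na.omit(x)))
      p <- suppressWarnings(
        wilcox.test(x1, x2, exact = exact, correct = TRUE)$p.value)
    } else {
      p <- suppressWarnings(ks.test(x1[!is.na(x1)], x2[!is.na(x2)])$p.value)
    }
    add_row(col, test_name, s1, s2, p)
  }
  for (col in continuous) test_continuous(col, sheet[[col]])
  for (col in categorical) {
    x <- factor(sheet[[col]])
    if (nlevels(droplevels(x[!is.na(x)])) <= 1L) {
      add_row(col, "fisher", NA_character_, NA_character_, 1,
              "constant in both groups")
      next
    }
    tab <- table(x, g)
    s <- apply(tab, 2L, function(cnt)
      paste(sprintf("%s:%d", rownames(tab), cnt), collapse = " "))
    p <- fisher.test(tab)$p.value
    add_row(col, "fisher", s[1L], s[2L], p)
  }
  for (col in ancestry) test_continuous(col, sheet[[col]], "ks")
  out <- do.call(rbind, rows)
  names(out)[names(out) == "summary_1"] <- paste0("summary_", lv[1L])
  names(out)[names(out) == "summary_2"] <- paste0("summary_", lv[2L])
  out
}
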