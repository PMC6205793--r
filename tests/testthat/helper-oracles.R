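# independent oracles and small fixture builders used across test files

# brute-force Benjamini-Hochberg step-up: q_(i) = min_{j >= i} p_(j) * n / j
bh_stepup_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) {
    q[i] <- min(ps[i:n] * n / (i:n), 1)
  }
  out <- numeric(n)
  out[o] <- q
  out
}

# two-sided Fisher exact p for a 2x2 table by full hypergeometric enumeration:
# sum the probabilities of all tables (with the observed margins) whose
# probability does not exceed the observed table's
fisher2x2_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0, k - n)
  hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# minimal MethylExperiment from a bare beta matrix
tiny_me <- function(beta, sheet_extra = NULL) {
  if (is.null(rownames(beta)))
    rownames(beta) <- sprintf("cg%05d", seq_len(nrow(beta)))
  if (is.null(colnames(beta)))
    colnames(beta) <- sprintf("s%03d", seq_len(ncol(beta)))
  sheet <- data.frame(sample_id = colnames(beta), stringsAsFactors = FALSE)
  if (!is.null(sheet_extra)) sheet <- cbind(sheet, sheet_extra)
  MethylExperiment(beta, sheet)
}

# villi-only two-group simulation config used by several EWAS tests
villi_config <- function(n_cpg, n_aca_effect = 0, seed = 1L, ...) {
  plan <- data.frame(tissue = "chorionic_villi",
                     aca_status = c("aCA", "non-aCA"), n = c(22L, 22L),
                     stringsAsFactors = FALSE)
  simConfig(n_cpg = n_cpg, sample_plan = plan, n_tissue_specific = 0,
            n_celltype_specific = 0, n_aca_effect = n_aca_effect,
            n_ga_effect = 0, n_sex_effect = 0,
            mixture_fraction_range = c(0, 0), seed = seed, ...)
}

# reference panel config: villi controls plus the four immune classes
reference_config <- function(n_cpg, n_celltype_specific = 150, seed = 1L,
                             n_villi_ref = 15L, ...) {
  plan <- data.frame(
    tissue = c("chorionic_villi", "immune:neutrophil", "immune:eosinophil",
               "immune:monocyte", "immune:lymphoid"),
    aca_status = c("non-aCA", NA, NA, NA, NA),
    n = c(n_villi_ref, 6L, 6L, 6L, 6L), stringsAsFactors = FALSE)
  simConfig(n_cpg = n_cpg, sample_plan = plan, n_tissue_specific = 0,
            n_celltype_specific = n_celltype_specific, n_aca_effect = 0,
            n_ga_effect = 0, n_sex_effect = 0,
            mixture_fraction_range = c(0, 0), seed = seed, ...)
}
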