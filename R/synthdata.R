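#' Configuration for the synthetic methylation cohort generator
#'
#' Describes the statistical structure of a simulated array cohort: the
#' number of CpGs, the sample plan per (tissue, aCA) cell, the bimodal
#' archetype mixture, the planted CpG sets (tissue-specific,
#' cell-type-specific, direct aCA, gestational-age and fetal-sex effects)
#' with their beta-scale effect sizes, the neutrophil mixture fraction range
#' for aCA villi, chip/row batch-effect and residual noise SDs on the
#' M-value (logit) scale, and the seed.
#'
#' Defaults emulate the discovery cohort design: 22 aCA + 22 non-aCA
#' chorionic villi, 9 + 7 chorion, 8 + 7 amnion, and a six-donor reference
#' panel per immune class (neutrophil, eosinophil, monocyte, lymphoid) plus
#' whole blood; aCA villi are mixed with the neutrophil reference profile at
#' a fraction drawn uniformly from `mixture_fraction_range`, and direct
#' (non-mixture) aCA effects default to zero.
#'
#' @param n_cpg number of CpGs.
#' @param sample_plan `data.frame` with columns `tissue`, `aca_status`
#'   (`"aCA"`, `"non-aCA"` or `NA` for reference cells) and `n`.
#' @param archetype_mix named proportions `c(low=, intermediate=, high=)` of
#'   low-, intermediate- and high-methylation CpGs; must sum to 1.
#' @param n_tissue_specific total CpGs planted as tissue-specific (cycled
#'   over villi, chorion, amnion).
#' @param n_celltype_specific CpGs planted per immune class.
#' @param n_aca_effect,n_ga_effect,n_sex_effect planted direct-effect CpG
#'   counts.
#' @param effect_delta named beta-scale effect magnitudes
#'   `c(tissue=, celltype=, aca=, ga=, sex=)`; `ga` is the delta beta per
#'   5 weeks of gestational age.
#' @param mixture_fraction_range `c(f_min, f_max)` neutrophil fraction in
#'   aCA villi.
#' @param batch_effect_sd M-scale SD of per-chip and per-row additive batch
#'   effects.
#' @param noise_sd M-scale residual SD.
#' @param seed integer RNG seed.
#'
#' @return A validated `SimConfig` list.
#' @export
simConfig <- function(n_cpg = 20000,
                      sample_plan = defaultSamplePlan(),
                      archetype_mix = c(low = 0.4, intermediate = 0.2,
                                        high = 0.4),
                      n_tissue_specific = 300,
                      n_celltype_specific = 150,
                      n_aca_effect = 0,
                      n_ga_effect = 100,
                      n_sex_effect = 50,
                      effect_delta = c(tissue = 0.3, celltype = 0.4,
                                       aca = 0.15, ga = 0.05, sex = 0.1),
                      mixture_fraction_range = c(0.1, 0.4),
                      batch_effect_sd = 0.15,
                      noise_sd = 0.7,
                      seed = 1L) {
  delta_default <- c(tissue = 0.3, celltype = 0.4, aca = 0.15, ga = 0.05,
                     sex = 0.1)
  if (is.null(names(effect_delta)) && length(effect_delta) == 1L)
    effect_delta <- setNames(rep(effect_delta, 5L), names(delta_default))
  miss <- setdiff(names(delta_default), names(effect_delta))
  effect_delta <- c(effect_delta, delta_default[miss])[names(delta_default)]
  cfg <- list(
    n_cpg = as.integer(n_cpg),
    sample_plan = as.data.frame(sample_plan),
    archetype_mix = archetype_mix,
    n_tissue_specific = as.integer(n_tissue_specific),
    n_celltype_specific = as.integer(n_celltype_specific),
    n_aca_effect = as.integer(n_aca_effect),
    n_ga_effect = as.integer(n_ga_effect),
    n_sex_effect = as.integer(n_sex_effect),
    effect_delta = effect_delta,
    mixture_fraction_range = as.numeric(mixture_fraction_range),
    batch_effect_sd = as.numeric(batch_effect_sd),
    noise_sd = as.numeric(noise_sd),
    seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  validateSimConfig(cfg)
  cfg
}

#' @rdname simConfig
#' @export
defaultSamplePlan <- function() {
  data.frame(
    tissue = c("chorionic_villi", "chorionic_villi", "chorion", "chorion",
               "amnion", "amnion", "immune:neutrophil", "immune:eosinophil",
               "immune:monocyte", "immune:lymphoid", "whole_blood"),
    aca_status = c("aCA", "non-aCA", "aCA", "non-aCA", "aCA", "non-aCA",
                   NA, NA, NA, NA, NA),
    n = c(22L, 22L, 9L, 7L, 8L, 7L, 6L, 6L, 6L, 6L, 6L),
    stringsAsFactors = FALSE)
}

.IMMUNE_TYPES <- c("immune:neutrophil", "immune:eosinophil",
                   "immune:monocyte", "immune:lymphoid")
.PLACENTAL_TYPES <- c("chorionic_villi", "chorion", "amnion")
.ALL_TYPES <- c(.PLACENTAL_TYPES, .IMMUNE_TYPES, "whole_blood")

#' @rdname simConfig
#' @param config a `SimConfig`.
#' @export
validateSimConfig <- function(config) {
  cfg <- config
  counts <- c(cfg$n_cpg, cfg$n_tissue_specific, cfg$n_celltype_specific,
              cfg$n_aca_effect, cfg$n_ga_effect, cfg$n_sex_effect,
              cfg$sample_plan$n)
  if (any(is.na(counts)) || any(counts < 0))
    .stopf("all counts must be >= 0")
  planted <- cfg$n_tissue_specific + length(.IMMUNE_TYPES) *
    cfg$n_celltype_specific + cfg$n_aca_effect + cfg$n_ga_effect +
    cfg$n_sex_effect
  if (planted > cfg$n_cpg)
    .stopf("planted CpG sets (%d) exceed n_cpg (%d)", planted, cfg$n_cpg)
  mix <- cfg$archetype_mix
  if (length(mix) != 3L || abs(sum(mix) - 1) > 1e-8 || any(mix < 0))
    .stopf("archetype_mix must be three non-negative proportions summing to 1")
  f <- cfg$mixture_fraction_range
  if (length(f) != 2L || f[1L] < 0 || f[2L] > 1 || f[1L] > f[2L])
    .stopf("mixture_fraction_range must satisfy 0 <= f_min <= f_max <= 1")
  if (any(cfg$effect_delta < 0) || any(cfg$effect_delta >= 1))
    .stopf("effect_delta values must lie in [0, 1)")
  if (cfg$noise_sd < 0 || cfg$batch_effect_sd < 0)
    .stopf("noise_sd and batch_effect_sd must be >= 0")
  bad <- setdiff(cfg$sample_plan$tissue, .ALL_TYPES)
  if (length(bad)) .stopf("unknown tissue in sample plan: '%s'", bad[1L])
  invisible(TRUE)
}

# shift a base beta away from the nearer boundary by delta, staying in (0,1)
.shifted_beta <- function(base, delta, eps = 1e-6) {
  up <- base < 0.5
  out <- ifelse(up, base + delta, base - delta)
  .clip01(out, eps)
}

#' Generate per-tissue / per-cell-type archetype methylation profiles
#'
#' Draws a bimodal archetype beta per CpG (most CpGs near 0 or 1, an
#' `archetype_mix["intermediate"]` fraction in mid-range) shared across
#' types, then plants the configured tissue-specific and
#' cell-type-specific CpG sets so that the carrying type differs from every
#' other type by at least `effect_delta` on the beta scale (shifted away
#' from the nearer boundary). Direct aCA / GA / sex effect CpGs are
#' reserved here (disjoint index blocks) and applied in
#' [generateCohort()].
#'
#' @param config a [simConfig()] object.
#' @return A `ReferenceProfiles` list with elements `profiles` (CpG x type
#'   beta matrix), `cpg_ids`, `archetype` (base beta), `planted` (named list
#'   of data.frames with `cpg_id`, signed beta-scale `effect`, and the
#'   carrying `type` where applicable) and `config`.
#' @export
generateReferenceProfiles <- function(config) {
  validateSimConfig(config)
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_cpg
  cpg_ids <- sprintf("cg%08d", seq_len(n))
  cat_draw <- sample(c("low", "intermediate", "high"), n, replace = TRUE,
                     prob = cfg$archetype_mix[c("low", "intermediate", "high")])
  base <- numeric(n)
  base[cat_draw == "low"] <- runif(sum(cat_draw == "low"), 0.02, 0.15)
  base[cat_draw == "intermediate"] <-
    runif(sum(cat_draw == "intermediate"), 0.25, 0.75)
  base[cat_draw == "high"] <- runif(sum(cat_draw == "high"), 0.85, 0.98)
  base <- .clip01(base)

  profiles <- matrix(base, nrow = n, ncol = length(.ALL_TYPES),
                     dimnames = list(cpg_ids, .ALL_TYPES))
  planted <- list()
  cursor <- 0L

  take <- function(k) {
    idx <- cursor + seq_len(k)
    cursor <<- cursor + k
    idx
  }

  if (cfg$n_tissue_specific > 0L) {
    idx <- take(cfg$n_tissue_specific)
    tis <- rep(.PLACENTAL_TYPES, length.out = length(idx))
    shifted <- .shifted_beta(base[idx], cfg$effect_delta[["tissue"]])
    for (t in .PLACENTAL_TYPES) {
      sel <- tis == t
      profiles[idx[sel], t] <- shifted[sel]
    }
    planted$tissue_specific <- data.frame(
      cpg_id = cpg_ids[idx], type = tis,
      effect = shifted - base[idx], stringsAsFactors = FALSE)
  }
  if (cfg$n_celltype_specific > 0L) {
    for (ct in .IMMUNE_TYPES) {
      idx <- take(cfg$n_celltype_specific)
      shifted <- .shifted_beta(base[idx], cfg$effect_delta[["celltype"]])
      profiles[idx, ct] <- shifted
      nm <- paste0(sub("immune:", "", ct), "_specific")
      planted[[nm]] <- data.frame(
        cpg_id = cpg_ids[idx], type = ct,
        effect = shifted - base[idx], stringsAsFactors = FALSE)
    }
  }
  for (set in c("aca_effect", "ga_effect", "sex_effect")) {
    k <- cfg[[paste0("n_", set)]]
    if (k > 0L) {
      idx <- take(k)
      delta_name <- sub("_effect", "", set)
      shifted <- .shifted_beta(base[idx], cfg$effect_delta[[delta_name]])
      planted[[set]] <- data.frame(
        cpg_id = cpg_ids[idx],
        effect = shifted - base[idx], stringsAsFactors = FALSE)
    }
  }

  out <- list(profiles = profiles, cpg_ids = cpg_ids, archetype = base,
              planted = planted, config = cfg)
  class(out) <- "ReferenceProfiles"
  out
}

# individuals for one (aca status) stratum of the cohort
.make_individuals <- function(ids, aca) {
  n <- length(ids)
  ga <- if (is.na(aca)) rep(NA_real_, n)
        else if (aca == "aCA") runif(n, 28, 33.5) else runif(n, 28, 36.6)
  pop_p <- if (is.na(aca)) 0.5 else if (aca == "aCA") 0.65 else 0.4
  pop <- rbinom(n, 1L, pop_p)
  data.frame(
    individual_id = ids,
    ga_weeks = ga,
    fetal_sex = sample(c("M", "F"), n, replace = TRUE),
    population = pop,
    ancestry_1 = (pop - 0.5) + rnorm(n, 0, 0.25),
    ancestry_2 = rnorm(n, 0, 0.25),
    maternal_age = runif(n, 20, 44),
    birth_weight_sd = rnorm(n, 0, 0.8),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic methylation cohort with truth tables
#'
#' Builds per-sample beta values from the reference profiles on the M-value
#' scale: `M = logit2(mu_tissue) + aCA direct effects + GA slope + sex
#' effect + chip effect + row effect + N(0, noise_sd)`, back-transformed and
#' clipped to (0, 1). aCA chorionic villi are additionally mixed with the
#' neutrophil reference profile, `beta = (1 - f) * beta + f *
#' beta_neutrophil`, with `f ~ Uniform(f_min, f_max)` (non-aCA `f = 0`).
#' Gestational age is drawn so that the aCA group mean is lower than the
#' non-aCA mean. Chorion/amnion samples share `individual_id` (and its
#' covariates) with villi samples of the same aCA stratum; immune reference
#' samples share donors across cell classes.
#'
#' @param config a [simConfig()].
#' @param profiles result of [generateReferenceProfiles()]; pass the same
#'   object to several calls to generate cohorts on a common reference.
#' @param seed_offset integer added to `config$seed` for the cohort draws,
#'   so that several cohorts can be generated from one config/profile pair.
#' @return list with `me` (a [MethylExperiment-class] carrying beta values,
#'   sample sheet and probe annotation) and `truth` (planted CpG sets with
#'   signed effects, per-sample mixture fractions, batch assignments,
#'   population labels and the reference profiles).
#' @export
generateCohort <- function(config, profiles = generateReferenceProfiles(config),
                           seed_offset = 1L) {
  validateSimConfig(config)
  cfg <- config
  if (!identical(profiles$config$n_cpg, cfg$n_cpg))
    .stopf("profiles were generated for a different n_cpg")
  set.seed(cfg$seed + seed_offset)
  n <- cfg$n_cpg
  cpg_ids <- profiles$cpg_ids
  plan <- cfg$sample_plan

  # individuals: villi individuals are reused for matched membranes
  sheet <- NULL
  indiv_pool <- list()
  sample_counter <- 0L
  for (r in seq_len(nrow(plan))) {
    tis <- plan$tissue[r]
    aca <- plan$aca_status[r]
    k <- plan$n[r]
    if (k == 0L) next
    key <- if (is.na(aca)) "ref" else aca
    if (tis %in% c(.IMMUNE_TYPES, "whole_blood")) {
      # shared donors across immune classes
      pool <- indiv_pool[["ref"]]
      need <- k - NROW(pool)
      if (need > 0L) {
        new_ids <- sprintf("D%02d", NROW(pool) + seq_len(need))
        pool <- rbind(pool, .make_individuals(new_ids, NA))
        indiv_pool[["ref"]] <- pool
      }
      ind <- indiv_pool[["ref"]][seq_len(k), , drop = FALSE]
    } else if (tis == "chorionic_villi") {
      new_ids <- sprintf("P%s%02d", ifelse(aca == "aCA", "A", "N"), seq_len(k))
      ind <- .make_individuals(new_ids, aca)
      indiv_pool[[key]] <- rbind(indiv_pool[[key]], ind)
    } else {
      pool <- indiv_pool[[key]]
      need <- k - NROW(pool)
      if (need > 0L) {
        new_ids <- sprintf("P%sX%02d", ifelse(aca == "aCA", "A", "N"),
                           seq_len(need))
        extra <- .make_individuals(new_ids, aca)
        pool <- rbind(pool, extra)
        indiv_pool[[key]] <- pool
      }
      ind <- indiv_pool[[key]][seq_len(k), , drop = FALSE]
    }
    short <- c(chorionic_villi = "villi", chorion = "chor", amnion = "amn",
               `immune:neutrophil` = "neu", `immune:eosinophil` = "eos",
               `immune:monocyte` = "mono", `immune:lymphoid` = "lym",
               whole_blood = "wb")[[tis]]
    rows <- data.frame(
      sample_id = sprintf("%s_%s_%02d", short,
                          ifelse(is.na(aca), "ref",
                                 ifelse(aca == "aCA", "aCA", "non")),
                          seq_len(k)),
      tissue = tis, aca_status = aca, ind,
      stringsAsFactors = FALSE)
    sheet <- rbind(sheet, rows)
    sample_counter <- sample_counter + k
  }
  n_samp <- nrow(sheet)
  sheet$replicate_group <- NA_character_

  # chip / row assignment: chips of 8 in randomized sample order
  ord <- sample.int(n_samp)
  chip_idx <- integer(n_samp)
  row_idx <- integer(n_samp)
  chip_idx[ord] <- (seq_len(n_samp) - 1L) %/% 8L + 1L
  row_idx[ord] <- (seq_len(n_samp) - 1L) %% 8L + 1L
  n_chips <- max(chip_idx)
  sheet$chip_id <- sprintf("chip%02d", chip_idx)
  sheet$chip_row <- sprintf("R%02d", row_idx)

  chip_eff <- matrix(rnorm(n * n_chips, 0, cfg$batch_effect_sd), nrow = n)
  row_eff <- matrix(rnorm(n * 8L, 0, cfg$batch_effect_sd), nrow = n)

  # precomputed M-scale planted shifts
  base <- profiles$archetype
  m_shift <- function(set_name) {
    shift <- numeric(n)
    pl <- profiles$planted[[set_name]]
    if (!is.null(pl)) {
      idx <- match(pl$cpg_id, cpg_ids)
      shift[idx] <- .logit2(.clip01(base[idx] + pl$effect)) -
        .logit2(base[idx])
    }
    shift
  }
  aca_shift <- m_shift("aca_effect")
  ga_slope <- m_shift("ga_effect") / 5          # per week, delta per 5 weeks
  sex_shift <- m_shift("sex_effect")

  m_prof <- .logit2(profiles$profiles)
  neut_prof <- profiles$profiles[, "immune:neutrophil"]

  beta <- matrix(NA_real_, nrow = n, ncol = n_samp,
                 dimnames = list(cpg_ids, sheet$sample_id))
  f_vec <- setNames(numeric(n_samp), sheet$sample_id)
  for (j in seq_len(n_samp)) {
    tis <- sheet$tissue[j]
    m <- m_prof[, tis]
    is_aca <- !is.na(sheet$aca_status[j]) && sheet$aca_status[j] == "aCA"
    if (is_aca) m <- m + aca_shift
    if (!is.na(sheet$ga_weeks[j]))
      m <- m + ga_slope * (sheet$ga_weeks[j] - 32)
    if (sheet$fetal_sex[j] == "M") m <- m + sex_shift
    m <- m + chip_eff[, chip_idx[j]] + row_eff[, row_idx[j]] +
      rnorm(n, 0, cfg$noise_sd)
    b <- .ilogit2(m)
    if (is_aca && tis == "chorionic_villi") {
      f <- runif(1L, cfg$mixture_fraction_range[1L],
                 cfg$mixture_fraction_range[2L])
      b <- (1 - f) * b + f * neut_prof
      f_vec[j] <- f
    }
    beta[, j] <- .clip01(b)
  }

  anno <- .synth_annotation(cpg_ids, profiles$planted)
  me <- MethylExperiment(beta, sheet, anno)
  truth <- list(
    planted_cpg_sets = profiles$planted,
    sample_mixture_fractions = f_vec,
    batch_assignments = data.frame(sample_id = sheet$sample_id,
                                   chip_id = sheet$chip_id,
                                   chip_row = sheet$chip_row,
                                   stringsAsFactors = FALSE),
    population = setNames(sheet$population, sheet$sample_id),
    reference_profiles = profiles$profiles)
  list(me = me, truth = truth)
}

# probe annotation for the synthetic array; blocklist flags are planted only
# on CpGs outside the effect sets so that filtering never removes truth sites
.synth_annotation <- function(cpg_ids, planted) {
  n <- length(cpg_ids)
  planted_ids <- unlist(lapply(planted, `[[`, "cpg_id"), use.names = FALSE)
  free <- setdiff(seq_len(n), match(planted_ids, cpg_ids))
  n_sex <- min(length(free), max(0L, round(0.02 * n)))
  sex_idx <- free[seq_len(n_sex)]
  free <- setdiff(free, sex_idx)
  n_cr <- min(length(free), round(0.01 * n))
  cr_idx <- if (n_cr > 0) sample(free, n_cr) else integer(0)
  free <- setdiff(free, cr_idx)
  n_poly <- min(length(free), round(0.01 * n))
  poly_idx <- if (n_poly > 0) sample(free, n_poly) else integer(0)
  chrom <- sample(paste0("chr", 1:22), n, replace = TRUE)
  chrom[sex_idx] <- "chrX"
  data.frame(
    cpg_id = cpg_ids,
    chromosome = chrom,
    position = sample.int(2e8, n, replace = TRUE),
    gene_symbols = sprintf("GENE%04d", ((seq_len(n) - 1L) %/% 10L) + 1L),
    gene_region = sample(c("TSS200", "TSS1500", "body", "5'UTR", "3'UTR"),
                         n, replace = TRUE),
    cross_reactive = seq_len(n) %in% cr_idx,
    polymorphic = seq_len(n) %in% poly_idx,
    sex_chromosome = seq_len(n) %in% sex_idx,
    stringsAsFactors = FALSE)
}

#' Generate two-population AIM-SNP genotypes
#'
#' Simulates a biallelic genotype (0/1/2) matrix for samples drawn from two
#' latent populations with divergent allele frequencies: per SNP a midpoint
#' frequency is drawn uniformly and the two populations are placed
#' `divergence / 2` on either side, so `divergence` is the allele-frequency
#' gap between populations.
#'
#' @param n_samples,n_snp dimensions (`n_snp >= 2`).
#' @param divergence allele-frequency gap in `[0, 0.95]`.
#' @param seed RNG seed.
#' @param population optional 0/1 vector of population labels; defaults to a
#'   balanced split.
#' @return list with `genotypes` (samples x SNPs matrix of 0/1/2),
#'   `population` (truth labels) and `allele_freq` (2 x SNP matrix).
#' @export
generateGenotypes <- function(n_samples, n_snp, divergence = 0.3, seed = 1L,
                              population = NULL) {
  if (!.is_count(n_snp) || n_snp < 2) .stopf("n_snp must be a count >= 2")
  if (divergence < 0 || divergence > 0.95)
    .stopf("divergence must lie in [0, 0.95]")
  set.seed(seed)
  if (is.null(population))
    population <- rep(c(0L, 1L), length.out = n_samples)
  mid <- runif(n_snp, divergence / 2 + 0.025, 1 - divergence / 2 - 0.025)
  freq <- rbind(pop0 = mid - divergence / 2, pop1 = mid + divergence / 2)
  g <- matrix(rbinom(n_samples * n_snp, 2L, freq[population + 1L, ]),
              nrow = n_samples, ncol = n_snp)
  dimnames(g) <- list(sprintf("S%03d", seq_len(n_samples)),
                      sprintf("snp%03d", seq_len(n_snp)))
  list(genotypes = g, population = setNames(population, rownames(g)),
       allele_freq = freq)
}
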