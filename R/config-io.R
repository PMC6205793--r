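#' Read and write simulation configurations
#'
#' Serialises a [simConfig()] to a YAML key-value file (keys exactly the
#' `SimConfig` field names; the sample plan as a list of
#' tissue/aca_status/n records) and reads it back. Unknown keys are an
#' error; missing keys take their defaults. A written-then-read config
#' generates an identical cohort.
#'
#' @param config a `SimConfig`.
#' @param path file path.
#' @return `writeSimConfig` returns `path` invisibly; `readSimConfig`
#'   returns a validated `SimConfig`.
#' @export
writeSimConfig <- function(config, path) {
  cfg <- unclass(config)
  cfg$sample_plan <- lapply(seq_len(nrow(cfg$sample_plan)), function(i)
    list(tissue = cfg$sample_plan$tissue[i],
         aca_status = cfg$sample_plan$aca_status[i],
         n = cfg$sample_plan$n[i]))
  cfg$archetype_mix <- as.list(cfg$archetype_mix)
  cfg$effect_delta <- as.list(cfg$effect_delta)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname writeSimConfig
#' @export
readSimConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(simConfig))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    .stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  if (!is.null(raw$sample_plan)) {
    raw$sample_plan <- do.call(rbind, lapply(raw$sample_plan, function(r)
      data.frame(tissue = r$tissue,
                 aca_status = if (is.null(r$aca_status)) NA_character_
                              else r$aca_status,
                 n = as.integer(r$n), stringsAsFactors = FALSE)))
  }
  for (key in c("archetype_mix", "effect_delta"))
    if (!is.null(raw[[key]])) raw[[key]] <- unlist(raw[[key]])
  do.call(simConfig, raw)
}

#' Write truth tables to JSON
#'
#' Serialises the ground-truth component of [generateCohort()] (planted
#' CpG sets with signed effects, per-sample mixture fractions, batch
#' assignments and population labels; the reference-profile matrix is
#' summarised by its dimensions).
#'
#' @param truth the `truth` element of a [generateCohort()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeTruthTables <- function(truth, path) {
  out <- list(
    planted_cpg_sets = truth$planted_cpg_sets,
    sample_mixture_fractions = as.list(truth$sample_mixture_fractions),
    batch_assignments = truth$batch_assignments,
    population = as.list(truth$population),
    reference_profiles_dim = dim(truth$reference_profiles),
    reference_profile_types = colnames(truth$reference_profiles))
  write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
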