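#' Read a methylation dataset from disk
#'
#' Reads a beta-value matrix (TSV, first column `cpg_id`, remaining columns
#' one per sample), a sample sheet (CSV with a `sample_id` column) and an
#' optional probe annotation table (TSV with a `cpg_id` column), validates
#' their alignment and value ranges, and returns a
#' [MethylExperiment-class]. Empty fields and `NA` tokens are parsed to
#' missing values and carried as such (never imputed).
#'
#' @param beta_path,sheet_path,annotation_path file paths; `annotation_path`
#'   may be `NULL`.
#' @return a [MethylExperiment-class].
#' @export
readMethylDataset <- function(beta_path, sheet_path, annotation_path = NULL) {
  for (p in c(beta_path, sheet_path, annotation_path))
    if (!file.exists(p)) .stopf("file not found: '%s'", p)
  tab <- read.delim(beta_path, check.names = FALSE,
                    na.strings = c("NA", ""), stringsAsFactors = FALSE)
  if (names(tab)[1L] != "cpg_id")
    .stopf("beta matrix must have 'cpg_id' as its first column")
  if (anyDuplicated(tab$cpg_id))
    .stopf("duplicate cpg_id in beta matrix: '%s'",
           tab$cpg_id[duplicated(tab$cpg_id)][1L])
  beta <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(beta) <- tab$cpg_id
  storage.mode(beta) <- "double"
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(beta))
    .stopf("beta value out of [0, 1] at CpG '%s', sample '%s' (value %g)",
           rownames(beta)[i[1L]], colnames(beta)[i[2L]], beta[bad[1L]])
  }
  sheet <- read.csv(sheet_path, na.strings = c("NA", ""),
                    stringsAsFactors = FALSE)
  anno <- NULL
  if (!is.null(annotation_path))
    anno <- read.delim(annotation_path, na.strings = c("NA", ""),
                       stringsAsFactors = FALSE)
  MethylExperiment(beta, sheet, anno)
}

#' Write a methylation dataset to disk
#'
#' Writes the beta matrix as TSV (rows = CpG ids, columns = sample ids),
#' the sample sheet as CSV, and (when present) the probe annotation as TSV,
#' in the layout [readMethylDataset()] reads back.
#'
#' @param me a [MethylExperiment-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named character vector of the written paths, invisibly.
#' @export
writeMethylDataset <- function(me, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  beta <- betaValues(me)
  beta_path <- file.path(dir, paste0(prefix, "_beta.tsv"))
  out <- data.frame(cpg_id = rownames(beta), beta, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, beta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  sheet_path <- file.path(dir, paste0(prefix, "_samples.csv"))
  write.csv(sampleSheet(me), sheet_path, row.names = FALSE, quote = FALSE,
            na = "NA")
  paths <- c(beta = beta_path, sheet = sheet_path)
  anno <- probeAnnotation(me)
  if (!is.null(anno)) {
    anno_path <- file.path(dir, paste0(prefix, "_annotation.tsv"))
    write.table(anno, anno_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, annotation = anno_path)
  }
  invisible(paths)
}

#' Run manifest
#'
#' Emits a JSON manifest recording the configuration (and its MD5 hash),
#' the seed, package and R versions, and a timestamp, so that identical
#' (inputs, config, seed) invocations yield identical manifests up to the
#' timestamp field.
#'
#' @param path output JSON path.
#' @param config a configuration object (serialised into the manifest).
#' @param seed the seed used.
#' @return the manifest list, invisibly.
#' @export
runManifest <- function(path, config = NULL, seed = NULL) {
  cfg_json <- as.character(toJSON(config, auto_unbox = TRUE, digits = NA,
                                  null = "null", force = TRUE))
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest <- list(
    config = config,
    config_md5 = hash,
    seed = seed,
    package_version = as.character(packageVersion("methylaCA")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  write_json(manifest, path, auto_unbox = TRUE, digits = NA, null = "null",
             force = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' @describeIn writeResults DM result table as TSV with stable column order
#'   `(cpg_id, estimate, se, t, df, p, q, delta_beta, dm_call)`.
#' @export
setMethod("writeResults", "DMResult", function(x, path, ...) {
  cols <- c("cpg_id", "estimate", "se", "t", "df", "p", "q", "delta_beta",
            "dm_call")
  write.table(x@results[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
})

#' @describeIn writeResults cluster report as JSON (per-node AU/BP, split p,
#'   assignments, enrichment table) plus a Newick rendering of the
#'   dendrogram with `au|bp` node annotations at `<path>.nwk`.
#' @export
setMethod("writeResults", "ClusterReport", function(x, path, ...) {
  out <- list(
    nodes = x@nodes,
    split_p = x@splitP,
    assignments = as.list(x@assignments),
    enrichment = list(
      table = if (!is.null(x@enrichment$table))
        as.data.frame.matrix(x@enrichment$table) else NULL,
      p = x@enrichment$p))
  write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null",
             force = TRUE, pretty = TRUE)
  nwk <- clusterNewick(x)
  writeLines(nwk, paste0(path, ".nwk"))
  invisible(path)
})

#' @describeIn writeResults overlap test as JSON with all counts.
#' @export
setMethod("writeResults", "OverlapTest", function(x, path, ...) {
  write_json(list(m = x@m, N = x@N, K = x@K, k_obs = x@kObs,
                  n_draws = x@nDraws, empirical_p = x@empiricalP,
                  hypergeometric_p = x@hypergeomP),
             path, auto_unbox = TRUE, digits = NA)
  invisible(path)
})

#' @describeIn writeResults concordance result as JSON with the per-site
#'   direction table.
#' @export
setMethod("writeResults", "ConcordanceResult", function(x, path, ...) {
  write_json(list(n_evaluable = x@nEvaluable, n_concordant = x@nConcordant,
                  fraction = x@fraction, binomial_p = x@binomialP,
                  empirical_p = x@empiricalP, directions = x@directions),
             path, auto_unbox = TRUE, digits = NA)
  invisible(path)
})

#' @describeIn writeResults any data.frame as TSV.
#' @export
setMethod("writeResults", "data.frame", function(x, path, ...) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
})

#' Newick rendering of a clustering report
#'
#' Renders the dendrogram as a Newick string with internal nodes labelled
#' `au|bp` (rounded to 2 digits) and branch lengths taken from merge
#' heights.
#'
#' @param report a [ClusterReport-class].
#' @return a single Newick string.
#' @export
clusterNewick <- function(report) {
  tree <- report@tree
  nodes <- report@nodes
  merge <- tree$merge
  height <- tree$height
  labs <- tree$labels
  if (is.null(labs)) labs <- as.character(seq_len(nrow(merge) + 1L))
  node_lab <- setNames(sprintf("%.2f|%.2f", nodes$au, nodes$bp), nodes$node)
  render <- function(i, parent_h) {
    if (i < 0) {
      sprintf("%s:%.6g", labs[-i], parent_h)
    } else {
      lab <- if (as.character(i) %in% names(node_lab))
        node_lab[[as.character(i)]] else ""
      sprintf("(%s,%s)%s:%.6g",
              render(merge[i, 1L], height[i]),
              render(merge[i, 2L], height[i]),
              lab, max(parent_h - height[i], 0))
    }
  }
  root <- nrow(merge)
  lab <- if (as.character(root) %in% names(node_lab))
    node_lab[[as.character(root)]] else ""
  paste0("(", render(merge[root, 1L], height[root]), ",",
         render(merge[root, 2L], height[root]), ")", lab, ";")
}
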