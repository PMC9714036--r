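#' Read and write the long-format MID CSV dialect
#'
#' The package's on-disk exchange format for label time courses: UTF-8
#' CSV with a header row, "." decimal, no index column, and columns
#' `sample_id`, `condition`, `tracer`, `metabolite`, `time_min`,
#' `replicate`, `mass_shift` (integer, 0-based, `M0` = unlabeled) and
#' `fraction`. Leading `#` comment lines carry provenance and are
#' ignored on read. MIDs whose fractions sum within 1e-3 of 1 are
#' renormalized; larger deviations are rejected with the offending row.
#'
#' @param path file path.
#' @return a [label_timecourse()].
#' @export
read_mid_csv <- function(path) {
  if (!file.exists(path)) stop_data(paste("no such file:", path))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  label_timecourse(df)
}

#' @param tc a [label_timecourse()].
#' @param provenance optional named list echoed as `# key: value` comment
#'   lines (see [run_provenance()]).
#' @rdname read_mid_csv
#' @export
write_mid_csv <- function(tc, path, provenance = NULL) {
  stopifnot(inherits(tc, "label_timecourse"))
  write_csv_provenance(as.data.frame(tc), path, provenance)
}

write_csv_provenance <- function(df, path, provenance = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (k in names(provenance))
    writeLines(sprintf("# %s: %s", k, provenance[[k]]), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read and write expression matrices as TSV
#'
#' Genes x samples, first column the gene symbol, header row of sample
#' ids. Gene symbols are uppercased on read for TCGA-style matching.
#'
#' @param path file path.
#' @return a validated expression matrix.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop_data(paste("no such file:", path))
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_schema("expression TSV needs gene + sample columns")
  mat <- as.matrix(df[, -1L, drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- df[[1L]]
  as_expression_matrix(mat)
}

#' @param expr expression matrix.
#' @rdname read_expression_tsv
#' @export
write_expression_tsv <- function(expr, path) {
  expr <- as_expression_matrix(expr)
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read simple analysis tables
#'
#' `read_covariate_csv()` expects `sample_id` plus one value column;
#' `read_de_csv()` expects `gene`, `log2fc`, `pvalue`;
#' `read_z_csv()` expects `gene`, `zscore`. Gene symbols are uppercased.
#'
#' @param path file path.
#' @return a data.frame.
#' @export
read_covariate_csv <- function(path) {
  df <- read_checked_csv(path, c("sample_id"))
  if (ncol(df) < 2L) stop_schema("covariate CSV needs a value column")
  df
}

#' @rdname read_covariate_csv
#' @export
read_de_csv <- function(path) {
  df <- read_checked_csv(path, c("gene", "log2fc", "pvalue"))
  df$gene <- toupper(df$gene)
  df
}

#' @rdname read_covariate_csv
#' @export
read_z_csv <- function(path) {
  df <- read_checked_csv(path, c("gene", "zscore"))
  df$gene <- toupper(df$gene)
  df
}

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) stop_data(paste("no such file:", path))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop_schema(paste("missing column(s):", paste(miss, collapse = ", ")))
  df
}

#' Write a tidy results table with provenance
#'
#' @param df a data.frame.
#' @param path output path.
#' @param provenance optional named list echoed as comment lines.
#' @export
write_results_csv <- function(df, path, provenance = NULL) {
  write_csv_provenance(df, path, provenance)
}

#' Run configuration and provenance
#'
#' `read_run_config()` loads a structured YAML configuration (stage
#' parameters, paths, seeds) and validates the documented domains of the
#' thresholds it carries. `run_provenance()` derives the provenance block
#' (configuration hash, package version, seed) echoed into every output
#' file.
#'
#' @param path YAML file path.
#' @return `read_run_config()`: the configuration list with a
#'   `provenance` element; `run_provenance()`: a named list.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop_config("the 'yaml' package is required to read configurations")
  if (!file.exists(path)) stop_data(paste("no such file:", path))
  cfg <- yaml::read_yaml(path)
  chk <- function(name, lo, hi) {
    v <- cfg[[name]]
    if (!is.null(v) && (!is.numeric(v) || v < lo || v > hi))
      stop_config(sprintf("%s must lie in [%g, %g]", name, lo, hi))
  }
  chk("alpha", 0, 1)
  chk("p13", 0, 0.4999)
  chk("lfc_cut", 0, Inf)
  chk("z_cut", 0, Inf)
  chk("sd_mid", 0, Inf)
  cfg$provenance <- run_provenance(cfg)
  cfg
}

#' @param config a configuration list.
#' @param seed integer seed recorded whenever a stochastic stage runs.
#' @rdname read_run_config
#' @export
run_provenance <- function(config, seed = config$seed %||% NA) {
  list(config_hash = config_hash(config[setdiff(names(config), "provenance")]),
       package = paste0("tcaflux ",
                        as.character(utils::packageVersion("tcaflux"))),
       seed = seed)
}
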