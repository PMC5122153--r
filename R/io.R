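# Plain-text I/O for the pipeline's tabular formats.

#' Read and write pedigree CSV
#'
#' Columns `animal,sire,dam`; `0` codes an unknown parent on disk.
#'
#' @param pedigree Pedigree data frame.
#' @param path File path.
#' @return `read_pedigree()` returns a data frame with `NA` for unknown
#'   parents; `write_pedigree()` returns `path` invisibly.
#' @export
write_pedigree <- function(pedigree, path) {
  ped <- normalize_pedigree(pedigree)
  ped$sire[is.na(ped$sire)] <- "0"
  ped$dam[is.na(ped$dam)] <- "0"
  utils::write.csv(ped, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  normalize_pedigree(utils::read.csv(path, colClasses = "character"))
}

#' Read and write phenotype records CSV
#'
#' One row per AI record with the animal id, fixed-effect levels, age and
#' the binary outcome.
#'
#' @param records Records data frame (e.g. from [sim_records()]).
#' @param path File path.
#' @return `read_records()` returns the data frame with `parity`, `farm`
#'   and `ym` as factors.
#' @export
write_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in intersect(c("parity", "farm", "ym"), names(rec)))
    rec[[col]] <- factor(rec[[col]])
  rec
}

#' Read CNV calls from a BED-like TSV
#'
#' Tab-separated columns `chrom`, `start`, `end`, `animal`, `type`
#' (`loss`/`gain`) and optionally `cn`, with a header row.
#'
#' @param path File path.
#' @return Data frame suitable for [merge_cnvrs()].
#' @export
read_cnv_calls <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "animal", "type")
  if (!all(need %in% names(df)))
    stop_("CNV call table needs columns ", paste(need, collapse = ", "))
  df$chrom <- as.character(df$chrom)
  df
}

#' Read and write a simulation configuration as JSON
#'
#' @param config A [sim_config()] object.
#' @param path File path.
#' @return `read_sim_config()` returns a validated [sim_config()] object.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  raw <- unclass(config)
  # named atomic vectors serialize as bare arrays; keep the factor names
  raw$fixed_effect_levels <- as.list(raw$fixed_effect_levels)
  jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  pd <- raw$period_definitions
  raw$period_definitions <- if (is.matrix(pd))
    lapply(seq_len(nrow(pd)), function(i) as.numeric(pd[i, ]))
  else lapply(pd, as.numeric)
  raw$fixed_effect_levels <- unlist(raw$fixed_effect_levels)
  do.call(sim_config, raw)
}

#' Export a fitted threshold model
#'
#' Writes the stored chain as TSV (one row per stored cycle: variance
#' components plus fixed effects), the posterior variance-component
#' summary as JSON, and the breeding values as CSV.
#'
#' @param fit A [threshold_gibbs()] fit.
#' @param dir Output directory (created if needed).
#' @return Named vector of the three file paths, invisibly.
#' @export
write_gibbs_output <- function(fit, dir) {
  stopifnot(inherits(fit, "threshold_gibbs"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  samples <- data.frame(sigma2_a = fit$samples$sigma2_a,
                        sigma2_pe = fit$samples$sigma2_pe,
                        fit$samples$beta, check.names = FALSE)
  paths <- c(samples = file.path(dir, "samples.tsv"),
             summary = file.path(dir, "summary.json"),
             ebv = file.path(dir, "ebv.csv"))
  utils::write.table(samples, paths["samples"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  vc <- summarize_posterior(fit)
  jsonlite::write_json(cbind(parameter = rownames(vc), vc),
                       paths["summary"], dataframe = "rows", digits = NA)
  utils::write.csv(ebv(fit), paths["ebv"], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Read a qPCR Ct table
#'
#' CSV with columns `sample`, `replicate`, `target_ct`, `ref_ct`.
#'
#' @param path File path.
#' @return Data frame; split by `sample` to feed [ddct_copy_number()].
#' @export
read_qpcr <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "target_ct", "ref_ct")
  if (!all(need %in% names(df)))
    stop_("qPCR table needs columns ", paste(need, collapse = ", "))
  df
}
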