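#' Read a clone abundance table
#'
#' Tab-delimited text, two columns `clone_id<TAB>count`, UTF-8; lines
#' starting with `#` are comments. Zero-count rows are dropped (with a
#' message giving how many); duplicate clone ids are merged by summing their
#' counts, with a warning. A file left empty after filtering is an error.
#'
#' @param path file path.
#' @return named numeric vector of positive counts.
#' @export
read_abundance_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0)
    stop("no data rows in ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("malformed line ", lineno[bad[1]], " in ", path,
         ": expected 'clone_id<TAB>count'", call. = FALSE)
  ids <- vapply(parts, `[[`, "", 1L)
  cts <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  bad <- which(is.na(cts) | cts < 0)
  if (length(bad))
    stop("malformed count on line ", lineno[bad[1]], " in ", path,
         call. = FALSE)
  if (anyDuplicated(ids)) {
    warning("duplicate clone ids in ", path, " merged by summation",
            call. = FALSE)
    cts <- tapply(cts, factor(ids, levels = unique(ids)), sum)
    ids <- names(cts)
    cts <- as.numeric(cts)
  }
  n_zero <- sum(cts == 0)
  if (n_zero > 0)
    message("dropped ", n_zero, " zero-count clone(s) from ", path)
  keep <- cts > 0
  if (!any(keep))
    stop("sample in ", path, " is empty after dropping zero counts",
         call. = FALSE)
  stats::setNames(cts[keep], ids[keep])
}

#' Write a clone abundance table
#'
#' @param counts named numeric vector of counts.
#' @param path output path.
#' @export
write_abundance_table <- function(counts, path) {
  ids <- names(counts)
  if (is.null(ids)) ids <- as.character(seq_along(counts))
  writeLines(c("#clone_id\tcount",
               paste(ids, format(unname(counts), trim = TRUE), sep = "\t")),
             path)
  invisible(path)
}

#' Write a tidy result table
#'
#' Deterministic column order (as given), floats at 6 significant digits,
#' undefined sentinels as the literal `NA` token; tab-separated by default.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param sep field separator.
#' @export
write_tidy_table <- function(df, path, sep = "\t") {
  out <- df
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) signif(v, 6))
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a tidy result table written by [write_tidy_table()]
#'
#' @param path file path.
#' @param sep field separator.
#' @return data.frame; `NA` tokens parse back to `NA` sentinels.
#' @export
read_tidy_table <- function(path, sep = "\t") {
  utils::read.table(path, header = TRUE, sep = sep, na.strings = "NA",
                    stringsAsFactors = FALSE)
}

#' Read a longitudinal trial summary table
#'
#' CSV with header
#' `study,patient,time_months,cell_type,unique_is,shannon,log_base,event_flag`.
#' Records whose Shannon value exceeds the log_base-logarithm of their
#' richness by more than a rounding slack (1e-6) are internally inconsistent
#' (published values are rounded); they are flagged in a
#' `shannon_consistent` column and kept, not dropped.
#'
#' @param path file path.
#' @return data.frame with the input columns plus `shannon_consistent`.
#' @export
read_trial_table <- function(path) {
  req <- c("study", "patient", "time_months", "cell_type", "unique_is",
           "shannon", "log_base", "event_flag")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("trial table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(df$unique_is < 1)) stop("unique_is must be >= 1", call. = FALSE)
  if (any(df$shannon < 0)) stop("shannon must be >= 0", call. = FALSE)
  hmax <- log(df$unique_is) / log(df$log_base)
  df$shannon_consistent <- df$shannon <= hmax + 1e-6
  if (!all(df$shannon_consistent))
    warning(sum(!df$shannon_consistent),
            " record(s) with Shannon above log(richness); flagged",
            call. = FALSE)
  df
}

#' Write a trial evenness report
#'
#' @param df data.frame, typically the output of [classify_evenness()].
#' @param path output path (CSV).
#' @export
write_trial_report <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Write a run manifest beside an output
#'
#' Records the parameters, seed and software versions a result was produced
#' under, so any run can be reproduced from its manifest.
#'
#' @param path manifest path.
#' @param params named list of run parameters (must include the seed).
#' @export
write_manifest <- function(path, params) {
  stopifnot(is.list(params), "seed" %in% names(params))
  flat <- vapply(params, function(v) paste(format(v), collapse = ","), "")
  lines <- c(paste0("package: clonediv ",
                    as.character(utils::packageVersion("clonediv"))),
             paste0("r_version: ", R.version.string),
             paste(names(flat), flat, sep = ": "))
  writeLines(lines, path)
  invisible(path)
}
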