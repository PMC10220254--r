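#' Change the log base of a Shannon value
#'
#' Published Shannon indices mix log bases (base e and base 2 are both in
#' use); H' = H * ln(base_from) / ln(base_to) puts them on a common scale.
#'
#' @param h Shannon value(s), >= 0.
#' @param base_from base the value was reported in (> 1).
#' @param base_to target base (> 1).
#' @return converted Shannon value(s).
#' @examples
#' convert_log_base(1, 2, exp(1))   # 0.693
#' @export
convert_log_base <- function(h, base_from, base_to) {
  stopifnot(base_from > 1, base_to > 1)
  if (any(h < 0, na.rm = TRUE))
    stop("Shannon values must be non-negative", call. = FALSE)
  h * log(base_from) / log(base_to)
}

#' Pielou evenness from published (Shannon, richness) summaries
#'
#' J = H / log_base(S), computable directly from the two summary statistics
#' that trials report, without the underlying abundance table. The result is
#' independent of the base H was reported in, provided that base is passed.
#' S = 1 gives an `NA` sentinel (Hmax = 0). Published values are rounded, so
#' J can land marginally above 1; such values are clamped to 1 with a
#' warning.
#'
#' @param h reported Shannon value(s), >= 0.
#' @param s observed richness (unique insertion sites), >= 1.
#' @param base log base of `h` (default e).
#' @return evenness in \[0, 1\], `NA_real_` where S = 1.
#' @examples
#' pielou_from_summary(4.0, 1000)   # 0.579
#' @export
pielou_from_summary <- function(h, s, base = exp(1)) {
  stopifnot(base > 1)
  if (any(s < 1, na.rm = TRUE))
    stop("richness must be >= 1", call. = FALSE)
  if (any(h < 0, na.rm = TRUE))
    stop("Shannon values must be non-negative", call. = FALSE)
  j <- ifelse(s == 1, NA_real_, h / log(s, base = base))
  over <- !is.na(j) & j > 1
  if (any(over)) {
    warning(sum(over), " Pielou value(s) marginally above 1 ",
            "(published rounding); clamped to 1", call. = FALSE)
    j[over] <- 1
  }
  j
}

#' Default Pielou alert threshold separating low- and high-diversity samples
#' @export
PIELOU_ALERT_THRESHOLD <- 0.5

#' Label longitudinal trial records by evenness
#'
#' Derives Pielou evenness for each record from its (Shannon, richness, base)
#' triple and labels it `"low"` when strictly below the threshold, `"high"`
#' at or above it, and `"undefined"` where evenness cannot be computed
#' (single-clone samples). Evenness below 0.5 marks an increasingly high
#' probability of clinically relevant clonal dominance; the boundary itself
#' is labelled high. Records are ordered by study, patient and time so each
#' patient forms a longitudinal series.
#'
#' @param records data.frame with columns `unique_is`, `shannon`, `log_base`
#'   and ideally `study`, `patient`, `time_months` (see
#'   [read_trial_table()]).
#' @param threshold evenness alert level, default [PIELOU_ALERT_THRESHOLD].
#' @return the input with `pielou` and `label` columns appended.
#' @export
classify_evenness <- function(records, threshold = PIELOU_ALERT_THRESHOLD) {
  stopifnot(is.data.frame(records),
            all(c("unique_is", "shannon", "log_base") %in% names(records)))
  j <- mapply(pielou_from_summary, records$shannon, records$unique_is,
              records$log_base)
  records$pielou <- as.numeric(j)
  records$label <- ifelse(is.na(records$pielou), "undefined",
                          ifelse(records$pielou < threshold, "low", "high"))
  ord_cols <- intersect(c("study", "patient", "time_months"), names(records))
  if (length(ord_cols))
    records <- records[do.call(order, records[ord_cols]), , drop = FALSE]
  rownames(records) <- NULL
  records
}

#' Per-condition report for spiked-clone abundance series
#'
#' Summarises a series of abundance tables in which known clones were spiked
#' into a polyclonal background at increasing expected cumulative shares:
#' for each condition, the relative abundance of every major clone (above
#' `minor_cutoff`), the aggregate share of minor clones, and the evenness
#' indices that should react to the imposed dominance.
#'
#' @param tables named list of abundance vectors (named counts), one per
#'   condition.
#' @param expected_share optional numeric vector, the expected cumulative
#'   spiked share per condition; conditions are reported in increasing order
#'   of it.
#' @param minor_cutoff clones at or below this relative abundance are pooled
#'   as "minor" (default 1%).
#' @return list with
#'   \describe{
#'     \item{indices}{data.frame (condition, expected_share, S, pielou,
#'       simpson, uc50, dominant_fraction, minor_share).}
#'     \item{major_clones}{data.frame (condition, clone_id, share) for clones
#'       above the cutoff.}
#'   }
#' @export
spiked_condition_report <- function(tables, expected_share = NULL,
                                    minor_cutoff = 0.01) {
  stopifnot(is.list(tables), length(tables) > 0)
  if (is.null(names(tables)))
    names(tables) <- paste0("condition_", seq_along(tables))
  if (!is.null(expected_share)) {
    stopifnot(length(expected_share) == length(tables),
              all(expected_share < 1))
    ord <- order(expected_share)
    tables <- tables[ord]
    expected_share <- expected_share[ord]
  } else {
    expected_share <- rep(NA_real_, length(tables))
  }
  idx_rows <- vector("list", length(tables))
  major_rows <- vector("list", length(tables))
  for (i in seq_along(tables)) {
    x <- as_abundance(tables[[i]])
    p <- rel_abundance(x)
    ids <- if (is.null(names(x))) as.character(seq_along(p)) else names(x)
    major <- p > minor_cutoff
    idx_rows[[i]] <- data.frame(
      condition = names(tables)[i],
      expected_share = expected_share[i],
      S = length(p),
      pielou = pielou_index(x),
      simpson = simpson_index(x),
      uc50 = uc50(x),
      dominant_fraction = max(p),
      minor_share = sum(p[!major]))
    if (any(major)) {
      o <- order(p[major], decreasing = TRUE)
      major_rows[[i]] <- data.frame(
        condition = names(tables)[i],
        clone_id = ids[major][o],
        share = unname(p[major][o]))
    }
  }
  list(indices = do.call(rbind, idx_rows),
       major_clones = do.call(rbind, major_rows))
}
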