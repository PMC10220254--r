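#' Validate and normalise a clone abundance vector
#'
#' Clone abundances are per-clone counts from one sample: integer read or
#' fragment counts in real insertion-site data, or non-negative real
#' abundances from a simulation. Zero-count clones are dropped (observed
#' richness counts only clones actually seen); names, if any, are kept.
#'
#' @param counts numeric vector of non-negative abundances, optionally named
#'   by clone identifier.
#' @return numeric vector of strictly positive abundances, class
#'   `"abundance"`, with attribute `n_dropped` giving the number of
#'   zero-count entries removed.
#' @examples
#' as_abundance(c(a = 3, b = 1, c = 0))
#' @export
as_abundance <- function(counts) {
  if (inherits(counts, "abundance")) return(counts)
  if (!is.numeric(counts) || length(counts) == 0L)
    stop("'counts' must be a non-empty numeric vector", call. = FALSE)
  if (anyNA(counts))
    stop("'counts' contains NA", call. = FALSE)
  if (any(counts < 0))
    stop("'counts' contains negative abundances", call. = FALSE)
  keep <- counts > 0
  if (!any(keep))
    stop("sample is empty: no clone has positive abundance", call. = FALSE)
  out <- counts[keep]
  attr(out, "n_dropped") <- sum(!keep)
  class(out) <- "abundance"
  out
}

#' Relative clone abundances
#'
#' @param counts abundance vector (see [as_abundance()]).
#' @return vector of relative abundances p_i summing to 1.
#' @export
rel_abundance <- function(counts) {
  x <- as_abundance(counts)
  unclass(x) / sum(x)
}

.check_integer_counts <- function(x, what) {
  if (any(abs(x - round(x)) > 1e-9))
    stop(what, " requires integer counts (frequency-of-frequencies is ",
         "undefined for fractional abundances)", call. = FALSE)
  invisible(round(x))
}

#' Singleton/doubleton frequency counts
#'
#' Frequency-of-frequencies summary of an integer-count sample: the number of
#' clones seen exactly once (f1) and exactly twice (f2), the observed richness
#' S, and the total number of individuals sampled. These drive the Chao1
#' richness estimator and the coverage term of the corrected Shannon index.
#'
#' @param counts integer abundance vector.
#' @return list with elements `f1`, `f2`, `S`, `n_total`.
#' @export
clone_frequencies <- function(counts) {
  x <- as_abundance(counts)
  x <- .check_integer_counts(unclass(x), "clone_frequencies()")
  list(f1 = sum(x == 1L), f2 = sum(x == 2L),
       S = length(x), n_total = sum(x))
}
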