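#' Shannon diversity index
#'
#' Entropy of the clone relative-abundance distribution,
#' H = -sum(p_i * log(p_i)), in the requested log base. H confounds richness
#' and evenness: it grows with the number of clones sampled as well as with
#' how evenly they are represented.
#'
#' @param counts abundance vector (see [as_abundance()]); non-integer
#'   abundances are allowed.
#' @param base log base (> 1). Natural log by default; published trial values
#'   use base e or base 2.
#' @return Shannon entropy, 0 for a single clone, at most log(S) in `base`.
#' @examples
#' shannon_index(c(1, 1, 1, 1))        # log(4)
#' shannon_index(c(1, 1, 1, 1), base = 2)  # 2 bits
#' @export
shannon_index <- function(counts, base = exp(1)) {
  stopifnot(is.numeric(base), length(base) == 1L, base > 1)
  p <- rel_abundance(counts)
  -sum(p * log(p, base = base))
}

#' Pielou evenness index
#'
#' Shannon entropy normalised by its maximum log(S), giving a pure evenness
#' measure in \[0, 1\] that does not depend on the log base or (to first
#' order) on richness. Undefined for a single clone (Hmax = 0): returns
#' `NA_real_` rather than erroring, so panels and reports carry the sentinel
#' through.
#'
#' @inheritParams shannon_index
#' @return evenness J = H / log(S) in \[0, 1\], or `NA_real_` when S = 1.
#' @examples
#' pielou_index(c(10, 10, 10))  # 1: perfectly even
#' pielou_index(c(9999, 1))     # near 0: extreme dominance
#' @export
pielou_index <- function(counts, base = exp(1)) {
  x <- as_abundance(counts)
  S <- length(x)
  if (S == 1L) return(NA_real_)
  shannon_index(x, base = base) / log(S, base = base)
}

#' Simpson diversity index
#'
#' D = 1 - sum(p_i^2): one minus the probability that two cells drawn at
#' random belong to the same clone. 0 for a single clone, 1 - 1/S for a
#' perfectly even sample.
#'
#' @inheritParams pielou_index
#' @return diversity in \[0, 1 - 1/S\].
#' @export
simpson_index <- function(counts) {
  p <- rel_abundance(counts)
  1 - sum(p^2)
}

#' Gini inequality index (Brown's formula)
#'
#' Inequality of clone contributions, computed with Brown's formula on
#' abundances ranked in increasing order:
#' G = 2 * sum(i * y_i) / (n * sum(y_i)) - (n + 1) / n.
#' 0 when all clones contribute equally; approaches 1 under extreme dominance
#' with many clones.
#'
#' @inheritParams pielou_index
#' @return Gini coefficient in \[0, 1).
#' @examples
#' gini_brown(rep(10, 100))     # 0
#' gini_brown(c(1, 1, 1, 97))   # 0.72
#' @export
gini_brown <- function(counts) {
  y <- sort(unclass(as_abundance(counts)))
  n <- length(y)
  2 * sum(seq_len(n) * y) / (n * sum(y)) - (n + 1) / n
}

#' Chao1 richness estimator
#'
#' Nonparametric estimate of total (observed + unseen) richness from the
#' singleton and doubleton counts: S + f1 * (f1 - 1) / (2 * f2). When no
#' doubletons are observed the denominator uses f2 + 1 (the bias-corrected
#' convention), which avoids division by zero and reduces to the plain
#' formula whenever f2 > 0. Requires integer counts.
#'
#' @param counts integer abundance vector, or a frequency summary as returned
#'   by [clone_frequencies()].
#' @return estimated richness, always >= observed S.
#' @examples
#' chao1_richness(c(rep(3, 6), 1, 1, 1, 1, 2, 2))
#' @export
chao1_richness <- function(counts) {
  fr <- if (is.list(counts)) counts else clone_frequencies(counts)
  stopifnot(all(c("f1", "f2", "S") %in% names(fr)))
  f1 <- fr$f1; f2 <- fr$f2
  denom <- if (f2 > 0) 2 * f2 else 2 * (f2 + 1)
  fr$S + f1 * (f1 - 1) / denom
}

#' UC50: clones accounting for the top half of abundance
#'
#' The smallest number k of most-abundant clones whose cumulative relative
#' abundance reaches at least 50%. Drops to 1 as soon as one clone holds half
#' of the sample; equals S/2 for a perfectly even sample. Ties among equal
#' counts do not affect the result.
#'
#' @inheritParams pielou_index
#' @return integer in \[1, S\].
#' @examples
#' uc50(c(6, 2, 2))  # 1: the top clone already holds 60%
#' @export
uc50 <- function(counts) {
  p <- sort(rel_abundance(counts), decreasing = TRUE)
  as.integer(which(cumsum(p) >= 0.5 - 1e-12)[1L])
}

#' Fraction of the most abundant clone
#'
#' @inheritParams pielou_index
#' @return max p_i, the relative abundance of the largest clone.
#' @export
dominant_fraction <- function(counts) {
  max(rel_abundance(counts))
}

#' Coverage-corrected Shannon index (Horvitz-Thompson)
#'
#' Shannon entropy corrected for incomplete sampling: relative abundances are
#' shrunk by an estimated sample coverage c and each term is inflated by the
#' Horvitz-Thompson inclusion probability,
#' Hhat = -sum( c*p_i*log(c*p_i) / (1 - (1 - c*p_i)^k) ), natural log.
#'
#' Two dialects are provided. `"printed"` (default) uses coverage
#' c = 1 - f1/S and exponent k = S (observed richness) in the inclusion
#' probability. `"chao-shen"` is the standard Chao-Shen estimator with
#' c = 1 - f1/n and k = n, the total count. Both require integer counts.
#' When every clone is a singleton (f1 = S, printed dialect) the coverage is
#' zero or negative and the estimator is undefined: `NA_real_` is returned.
#'
#' @inheritParams chao1_richness
#' @param dialect `"printed"` or `"chao-shen"`.
#' @return corrected entropy (natural log), or `NA_real_` when coverage <= 0.
#' @export
shannon_corrected <- function(counts, dialect = c("printed", "chao-shen")) {
  dialect <- match.arg(dialect)
  x <- as_abundance(counts)
  .check_integer_counts(unclass(x), "shannon_corrected()")
  fr <- clone_frequencies(x)
  p <- rel_abundance(x)
  if (dialect == "printed") {
    cc <- 1 - fr$f1 / fr$S
    k <- fr$S
  } else {
    cc <- 1 - fr$f1 / fr$n_total
    k <- fr$n_total
  }
  if (cc <= 0) return(NA_real_)
  cp <- cc * p
  -sum(cp * log(cp) / (1 - (1 - cp)^k))
}

#' Full diversity-index panel for one sample
#'
#' Computes every index on one abundance vector and returns them as a
#' one-row data frame. Indices that are undefined for the sample (Pielou at
#' S = 1, corrected Shannon at zero coverage) or that require integer counts
#' the sample does not have (Chao1, corrected Shannon on fractional
#' abundances) are reported as `NA` sentinels; the rest of the panel is still
#' computed.
#'
#' @inheritParams shannon_index
#' @return one-row `data.frame` with columns `S`, `n_total`, `shannon`,
#'   `log_base`, `pielou`, `simpson`, `gini`, `chao1`, `uc50`,
#'   `shannon_corrected`, `dominant_fraction`.
#' @examples
#' diversity_panel(c(6, 2, 2))
#' @export
diversity_panel <- function(counts, base = exp(1)) {
  x <- as_abundance(counts)
  int_only <- function(f) tryCatch(f(x), error = function(e) NA_real_)
  data.frame(
    S = length(x),
    n_total = sum(x),
    shannon = shannon_index(x, base = base),
    log_base = base,
    pielou = pielou_index(x, base = base),
    simpson = simpson_index(x),
    gini = gini_brown(x),
    chao1 = int_only(chao1_richness),
    uc50 = uc50(x),
    shannon_corrected = int_only(shannon_corrected),
    dominant_fraction = dominant_fraction(x)
  )
}
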