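#' Population with one imposed dominant clone over a uniform-random background
#'
#' Builds the abundance vector used in the richness-by-dominance surface
#' study: one clone fixed at relative abundance `d`, and the remaining
#' S - 1 clones drawn from a uniform distribution on (0, 1) and rescaled to
#' sum 1 - d. With d = 0 the "dominant" clone has zero abundance and is
#' dropped, leaving a purely uniform-random population of S - 1 clones;
#' d = 1 degenerates to a single clone.
#'
#' @param S richness (>= 2).
#' @param d imposed dominant fraction in \[0, 1\].
#' @return numeric abundance vector summing to 1, dominant clone first
#'   (named `"dom"`), background clones named `"bg<i>"`.
#' @export
gradient_population <- function(S, d) {
  stopifnot(S >= 2, d >= 0, d <= 1)
  if (d == 1) return(c(dom = 1))
  bg <- stats::runif(S - 1)
  bg <- bg * (1 - d) / sum(bg)
  names(bg) <- paste0("bg", seq_len(S - 1))
  c(dom = d, bg)
}

#' Index surfaces over a richness-by-dominance grid
#'
#' For every (S, d) grid cell, draws `replicates` gradient populations and
#' averages Shannon, Pielou and Simpson over the background draws; the tidy
#' result is ready for surface plotting. Cells where Pielou is undefined
#' (single clone) are reported as `NA` with `n_defined` showing how many
#' replicates contributed.
#'
#' @param S_grid richness values (all >= 2).
#' @param d_grid dominance values in \[0, 1).
#' @param replicates background draws per cell.
#' @param seed integer seed.
#' @return data.frame (S, d, index, mean, sd, n_defined) with index in
#'   shannon, pielou, simpson.
#' @export
diversity_surface <- function(S_grid = c(2L, 10L, 50L, 100L, 250L, 500L, 1000L),
                              d_grid = seq(0, 0.95, by = 0.05),
                              replicates = 20L,
                              seed = 1L) {
  stopifnot(length(S_grid) > 0, length(d_grid) > 0, all(S_grid >= 2),
            all(d_grid >= 0), all(d_grid < 1), replicates >= 1)
  set.seed(seed)
  idx <- c("shannon", "pielou", "simpson")
  grid <- expand.grid(S = S_grid, d = d_grid, KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    vals <- matrix(NA_real_, nrow = replicates, ncol = 3L,
                   dimnames = list(NULL, idx))
    for (r in seq_len(replicates)) {
      ab <- gradient_population(grid$S[i], grid$d[i])
      vals[r, ] <- c(shannon_index(ab), pielou_index(ab), simpson_index(ab))
    }
    out[[i]] <- data.frame(
      S = grid$S[i], d = grid$d[i], index = idx,
      mean = apply(vals, 2L, mean, na.rm = TRUE),
      sd = apply(vals, 2L, stats::sd, na.rm = TRUE),
      n_defined = apply(vals, 2L, function(v) sum(!is.na(v))),
      row.names = NULL)
  }
  do.call(rbind, out)
}
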