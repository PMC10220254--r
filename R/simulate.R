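#' Default per-step baseline proliferation rate
#'
#' Calibrated so that, with 1,000 clones and a 4x advantaged clone, the
#' dominant clone exceeds 95% relative abundance by pseudotime step 20.
#' Closed-form guide: dominant fraction ~ exp(3*r*t) / (exp(3*r*t) + N - 1);
#' the default also absorbs the small boost that stochastic rate drift gives
#' aggregate background growth (about exp(sigma^2 * t^3 / 6) over t steps),
#' which the closed form ignores.
#' @export
DEFAULT_BASELINE_RATE <- 0.18

#' Configuration of the clonal-dominance simulation
#'
#' The experiment: N clones start equi-abundant; each carries a per-step
#' proliferation rate, similar across clones except one "dominant" clone
#' whose rate is `dominant_multiplier` times the baseline. At each
#' pseudotime step abundances grow multiplicatively by exp(rate) and are
#' renormalised, and each non-dominant rate receives an additive Gaussian
#' perturbation. At every step the population is subsampled with replacement
#' (multinomial) at several sampling efforts, with replicates, and the full
#' index panel is computed per sample.
#'
#' @param n_clones number of clones N (>= 2).
#' @param n_steps pseudotime steps to simulate.
#' @param dominant_multiplier ratio of the dominant clone's rate to the
#'   baseline rate.
#' @param baseline_rate mean per-step log growth rate of non-dominant clones.
#' @param rate_volatility SD of the additive N(0, 1)-shaped per-step rate
#'   perturbation; default baseline_rate / 10, small enough that the
#'   selective advantage, not rate drift, drives the dominance trajectory.
#' @param init_rate_sd SD of the initial spread of non-dominant rates around
#'   the baseline ("a similar proliferation rate").
#' @param sample_sizes sampling efforts (cells drawn per sample).
#' @param n_replicates samples per (step, size) condition.
#' @param seed integer seed for the whole experiment.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_clones = 1000L,
                       n_steps = 20L,
                       dominant_multiplier = 4,
                       baseline_rate = DEFAULT_BASELINE_RATE,
                       rate_volatility = baseline_rate / 10,
                       init_rate_sd = baseline_rate / 10,
                       sample_sizes = c(10L, 100L, 1000L, 10000L),
                       n_replicates = 50L,
                       seed = 1L) {
  stopifnot(n_clones >= 2, n_steps >= 0, all(sample_sizes >= 1),
            n_replicates >= 1, baseline_rate > 0, rate_volatility >= 0,
            dominant_multiplier > 0)
  structure(list(n_clones = as.integer(n_clones),
                 n_steps = as.integer(n_steps),
                 dominant_multiplier = dominant_multiplier,
                 baseline_rate = baseline_rate,
                 rate_volatility = rate_volatility,
                 init_rate_sd = init_rate_sd,
                 sample_sizes = as.integer(sample_sizes),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Initialise the clone population
#'
#' All N clones start at relative abundance 1/N. Non-dominant rates are drawn
#' N(baseline_rate, init_rate_sd^2); the dominant clone (index 1) gets
#' exactly `dominant_multiplier * baseline_rate`. Uses the current RNG
#' state — seed at the experiment level (see [run_dominance_experiment()]).
#'
#' @param config a [sim_config()].
#' @return list of class `"clone_population"` with `abundances`, `rates`,
#'   `dominant_index`, `step`.
#' @export
init_population <- function(config) {
  N <- config$n_clones
  rates <- stats::rnorm(N, mean = config$baseline_rate,
                        sd = config$init_rate_sd)
  dominant <- 1L
  rates[dominant] <- config$dominant_multiplier * config$baseline_rate
  structure(list(abundances = rep(1 / N, N),
                 rates = rates,
                 dominant_index = dominant,
                 step = 0L),
            class = "clone_population")
}

#' Advance the population one pseudotime step
#'
#' Abundances grow multiplicatively, x_i <- x_i * exp(r_i), and are
#' renormalised to sum 1 (exponential growth of relative abundances; for two
#' clones with fixed rates r and 4r this gives the logistic dominance curve
#' exp(3rt) / (exp(3rt) + 1)). Each non-dominant rate is then perturbed by
#' rate_volatility * N(0, 1); the dominant clone's rate stays fixed so its
#' selective advantage persists. Abundances are floored at the smallest
#' positive double: clones never go extinct in the true population.
#'
#' @param pop a `"clone_population"`.
#' @param config the [sim_config()] it was created under.
#' @return the population advanced by one step.
#' @export
step_population <- function(pop, config) {
  x <- pop$abundances * exp(pop$rates)
  x <- pmax(x, .Machine$double.xmin)
  pop$abundances <- x / sum(x)
  nd <- seq_along(pop$rates)[-pop$dominant_index]
  if (config$rate_volatility > 0)
    pop$rates[nd] <- pop$rates[nd] +
      config$rate_volatility * stats::rnorm(length(nd))
  pop$step <- pop$step + 1L
  pop
}

#' Multinomial subsample of a population
#'
#' Sampling with replacement of `size` cells with probabilities equal to the
#' clone relative abundances. Clones not drawn are absent from the result,
#' so observed richness is at most min(size, N).
#'
#' @param abundances a `"clone_population"` or a bare vector of (relative)
#'   abundances; normalised internally.
#' @param size number of cells to draw.
#' @return integer vector of positive counts, named by clone index, summing
#'   to `size`.
#' @export
sample_counts <- function(abundances, size) {
  if (inherits(abundances, "clone_population"))
    abundances <- abundances$abundances
  stopifnot(size >= 1)
  prob <- abundances / sum(abundances)
  draw <- stats::rmultinom(1L, size = size, prob = prob)[, 1L]
  names(draw) <- as.character(seq_along(draw))
  draw[draw > 0L]
}

.panel_indices <- c("richness", "shannon", "pielou", "simpson", "gini",
                    "chao1", "uc50", "shannon_corrected",
                    "dominant_fraction")

.panel_as_row <- function(panel) {
  c(richness = panel$S, shannon = panel$shannon, pielou = panel$pielou,
    simpson = panel$simpson, gini = panel$gini, chao1 = panel$chao1,
    uc50 = panel$uc50, shannon_corrected = panel$shannon_corrected,
    dominant_fraction = panel$dominant_fraction)
}

#' Run the clonal-dominance sampling experiment
#'
#' For every pseudotime step 0..n_steps, every sampling effort and every
#' replicate, draws a multinomial sample of the current population and
#' computes the full index panel; summarises each index as mean and SD over
#' replicates (undefined sentinels excluded, with the number of defined
#' replicates reported) alongside the true-population value of the index at
#' that step. For samples, `dominant_fraction` is the sampled relative
#' abundance of the designated dominant clone (0 when it is not drawn).
#' Population values of Chao1 and the corrected Shannon are `NA`: both need
#' integer counts and estimate what the population value already is.
#'
#' @param config a [sim_config()].
#' @return list of class `"dominance_experiment"`:
#'   \describe{
#'     \item{summary}{data.frame (time, sample_size, index, mean, sd,
#'       n_defined, population_value), one row per condition and index.}
#'     \item{population}{data.frame (time, index, value) of true-population
#'       index trajectories.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
run_dominance_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pop <- init_population(config)
  times <- 0:config$n_steps
  idx <- .panel_indices
  res <- vector("list", length(times) * length(config$sample_sizes))
  popres <- vector("list", length(times))
  k <- 0L
  for (ti in seq_along(times)) {
    pp <- diversity_panel(pop$abundances)
    pop_row <- .panel_as_row(pp)
    # for the true population the dominant clone is known by index, not max
    pop_row["dominant_fraction"] <- pop$abundances[pop$dominant_index]
    popres[[ti]] <- data.frame(time = times[ti], index = idx,
                               value = unname(pop_row[idx]))
    for (sz in config$sample_sizes) {
      mat <- matrix(NA_real_, nrow = config$n_replicates, ncol = length(idx),
                    dimnames = list(NULL, idx))
      for (r in seq_len(config$n_replicates)) {
        cts <- sample_counts(pop, sz)
        row <- .panel_as_row(diversity_panel(cts))
        dom_ct <- cts[as.character(pop$dominant_index)]
        row["dominant_fraction"] <-
          if (is.na(dom_ct)) 0 else unname(dom_ct) / sz
        mat[r, ] <- row
      }
      k <- k + 1L
      res[[k]] <- data.frame(
        time = times[ti], sample_size = sz, index = idx,
        mean = apply(mat, 2L, mean, na.rm = TRUE),
        sd = apply(mat, 2L, stats::sd, na.rm = TRUE),
        n_defined = apply(mat, 2L, function(v) sum(!is.na(v))),
        population_value = unname(pop_row[idx]),
        row.names = NULL)
    }
    if (ti <= config$n_steps) pop <- step_population(pop, config)
  }
  structure(list(summary = do.call(rbind, res),
                 population = do.call(rbind, popres),
                 config = config),
            class = "dominance_experiment")
}
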