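#' Symmetric Dirichlet draw
#'
#' @param S number of components.
#' @param alpha concentration (> 0); large alpha gives near-even weights.
#' @return vector of S positive weights summing to 1.
#' @keywords internal
rdirichlet_sym <- function(S, alpha) {
  g <- stats::rgamma(S, shape = alpha, rate = 1)
  # guard against all-zero underflow at tiny alpha
  if (sum(g) == 0) g <- rep(1, S)
  g / sum(g)
}

#' Dirichlet concentration matching a target expected evenness
#'
#' For a symmetric Dirichlet(alpha) abundance vector of richness S, the
#' expected Shannon entropy is digamma(S*alpha + 1) - digamma(alpha + 1)
#' (natural log), so the expected Pielou evenness is that divided by log(S).
#' Solves for the alpha whose expected evenness equals `j_target`, used by
#' the trial generator to realise a prescribed baseline evenness.
#'
#' @param S richness (>= 2).
#' @param j_target expected Pielou evenness in (0, 1).
#' @return concentration parameter alpha.
#' @export
evenness_alpha <- function(S, j_target) {
  stopifnot(S >= 2, j_target > 0, j_target < 1)
  f <- function(log_a) {
    a <- exp(log_a)
    (digamma(S * a + 1) - digamma(a + 1)) / log(S) - j_target
  }
  exp(stats::uniroot(f, lower = log(1e-4), upper = log(1e6),
                     tol = 1e-10)$root)
}

#' Specification for the synthetic longitudinal trial generator
#'
#' Describes a cohort of gene-therapy patients monitored by insertion-site
#' sampling over time. Per-patient true richness is drawn log-uniformly over
#' `richness_range` (spanning orders of magnitude, as pyrosequencing- and
#' Illumina-era studies differ in how many unique ISs they recover);
#' baseline evenness is drawn from `evenness_band` and realised through a
#' symmetric Dirichlet background. Event patients develop a dominant clone:
#' the dominant fraction jumps to `event_onset_fraction` at the diagnosis
#' time and rises along a logistic-shaped trajectory to `event_peak` at the
#' last time point; with `recovery = TRUE` it collapses back to near zero
#' after the post-onset midpoint, emulating diversity restored by
#' chemotherapy.
#'
#' @param n_patients number of patients.
#' @param times sampling times in months since treatment.
#' @param richness_range range (min, max) of true per-patient clone richness.
#' @param evenness_band range (min, max) of baseline expected Pielou
#'   evenness for the polyclonal background.
#' @param event_patients integer indices of patients with a dominance event.
#' @param event_onset months at which the event is diagnosed (flagged).
#' @param event_onset_fraction dominant-clone fraction at onset.
#' @param event_peak dominant-clone fraction reached at the final time
#'   point, in \[0.2, 0.98\].
#' @param recovery logical; evenness rebound after treatment.
#' @param sampling_factor cells sampled per record = sampling_factor * true
#'   richness.
#' @param log_base base in which the generated Shannon values are reported.
#' @param study study label written into the records.
#' @param seed integer seed.
#' @return list of class `"trial_generator_spec"`.
#' @export
trial_generator_spec <- function(n_patients = 8L,
                                 times = c(3, 6, 12, 24, 36, 48),
                                 richness_range = c(100, 10000),
                                 evenness_band = c(0.85, 0.98),
                                 event_patients = integer(0),
                                 event_onset = 24,
                                 event_onset_fraction = 0.75,
                                 event_peak = 0.9,
                                 recovery = FALSE,
                                 sampling_factor = 10,
                                 log_base = exp(1),
                                 study = "synthetic",
                                 seed = 1L) {
  stopifnot(n_patients >= 1, length(times) >= 1,
            richness_range[1] >= 2, richness_range[2] >= richness_range[1],
            evenness_band[1] > 0, evenness_band[2] < 1,
            evenness_band[1] <= evenness_band[2],
            all(event_patients %in% seq_len(n_patients)),
            event_onset_fraction > 0, event_onset_fraction < 1,
            event_peak >= 0.2, event_peak <= 0.98,
            event_peak >= event_onset_fraction,
            sampling_factor > 0, log_base > 1)
  structure(list(n_patients = as.integer(n_patients), times = sort(times),
                 richness_range = richness_range,
                 evenness_band = evenness_band,
                 event_patients = as.integer(event_patients),
                 event_onset = event_onset,
                 event_onset_fraction = event_onset_fraction,
                 event_peak = event_peak, recovery = recovery,
                 sampling_factor = sampling_factor, log_base = log_base,
                 study = study, seed = as.integer(seed)),
            class = "trial_generator_spec")
}

# logistic-shaped rise from `from` to `to` over m+1 post-onset points
.event_trajectory <- function(m, from, to) {
  if (m == 0) return(from)
  s <- stats::plogis(seq(-1, 4, length.out = m + 1))
  s <- (s - s[1]) / (s[m + 1] - s[1])
  from + (to - from) * s
}

#' Generate a synthetic longitudinal trial summary table
#'
#' For each patient and time point, draws the true clone abundance vector
#' (Dirichlet background, plus the scheduled dominant clone for event
#' patients), subsamples it multinomially and emits the observed richness
#' and Shannon value — the two summaries published trials report — together
#' with the event flag. Because the summaries are computed rather than
#' transcribed, every record satisfies H <= log(S) exactly.
#'
#' @param spec a [trial_generator_spec()].
#' @return data.frame with columns
#'   `study, patient, time_months, cell_type, unique_is, shannon, log_base,
#'   event_flag`.
#' @export
generate_trial_table <- function(spec) {
  stopifnot(inherits(spec, "trial_generator_spec"))
  set.seed(spec$seed)
  rows <- vector("list", spec$n_patients * length(spec$times))
  k <- 0L
  for (i in seq_len(spec$n_patients)) {
    S_true <- round(exp(stats::runif(1, log(spec$richness_range[1]),
                                     log(spec$richness_range[2]))))
    j_base <- stats::runif(1, spec$evenness_band[1], spec$evenness_band[2])
    alpha <- evenness_alpha(S_true, j_base)
    bg <- rdirichlet_sym(S_true, alpha)
    is_event <- i %in% spec$event_patients
    post <- spec$times >= spec$event_onset
    dom_sched <- rep(0, length(spec$times))
    if (is_event && any(post)) {
      m <- sum(post) - 1L
      traj <- .event_trajectory(m, spec$event_onset_fraction,
                                spec$event_peak)
      if (spec$recovery && m >= 2) {
        # post-midpoint collapse back toward a polyclonal state
        half <- ceiling((m + 1) / 2)
        traj[(half + 1):(m + 1)] <- traj[half] *
          rev(.event_trajectory(m - half, 0.02, 1))
      }
      dom_sched[post] <- traj
    }
    for (t in seq_along(spec$times)) {
      d <- dom_sched[t]
      p <- if (d > 0) c(d, (1 - d) * bg) else bg
      n_cells <- max(round(spec$sampling_factor * S_true), 10)
      cts <- sample_counts(p, n_cells)
      k <- k + 1L
      rows[[k]] <- data.frame(
        study = spec$study,
        patient = sprintf("P%02d", i),
        time_months = spec$times[t],
        cell_type = "PBMC",
        unique_is = length(cts),
        shannon = shannon_index(cts, base = spec$log_base),
        log_base = spec$log_base,
        event_flag = is_event && post[t])
    }
  }
  do.call(rbind, rows)
}

#' Specification for the synthetic spiked-clone abundance series
#'
#' Emulates a spiking experiment in which DNA from a polyclonal
#' lentiviral-transduced population (around 900 distinct ISs for ~2,500
#' sampled cells) is mixed with increasing quantities of DNA from standard
#' cell clones, so that a small set of known ISs jointly carries a stated
#' expected share of the sample. Background clone identities and their
#' (near-even) relative weights are fixed across conditions, as they come
#' from the same source DNA.
#'
#' @param background_richness number of background clones (default 900).
#' @param cells multinomial sample size per condition (default 2500).
#' @param conditions data.frame with columns `n_spiked` (number of spiked
#'   ISs) and `expected_share` (their expected cumulated abundance, < 1).
#' @param copy_numbers relative weights splitting the spiked share among
#'   spiked ISs (recycled; default equal).
#' @param background_concentration Dirichlet concentration of the background
#'   weights; large = near-even.
#' @param seed integer seed.
#' @return list of class `"spiked_spec"`.
#' @export
spiked_spec <- function(background_richness = 900L,
                        cells = 2500L,
                        conditions = data.frame(
                          n_spiked = c(0L, 1L, 2L, 3L),
                          expected_share = c(0, 0.25, 0.5, 0.75)),
                        copy_numbers = 1,
                        background_concentration = 50,
                        seed = 1L) {
  stopifnot(background_richness >= 2, cells >= 1,
            is.data.frame(conditions),
            all(c("n_spiked", "expected_share") %in% names(conditions)),
            all(conditions$expected_share < 1),
            all(conditions$expected_share >= 0),
            all((conditions$n_spiked == 0) == (conditions$expected_share == 0)),
            all(copy_numbers > 0), background_concentration > 0)
  structure(list(background_richness = as.integer(background_richness),
                 cells = as.integer(cells), conditions = conditions,
                 copy_numbers = copy_numbers,
                 background_concentration = background_concentration,
                 seed = as.integer(seed)),
            class = "spiked_spec")
}

#' Generate spiked-clone abundance tables, one per condition
#'
#' Draws one multinomial sample of `cells` cells per condition. In each
#' condition the spiked clones jointly hold the condition's expected share
#' (split in proportion to their copy numbers) and the background clones
#' share the remainder according to fixed near-even weights. Clone
#' identifiers are stable across conditions.
#'
#' @param spec a [spiked_spec()].
#' @return named list of abundance count vectors (names
#'   `"spiked<k>_<share>"`), each named by clone id (`bg0001`, ...,
#'   `spike1`, ...); attribute `expected_share` carries the per-condition
#'   expected spiked shares, and attribute `true_abundances` the per-
#'   condition true relative-abundance vectors.
#' @export
generate_spiked_tables <- function(spec) {
  stopifnot(inherits(spec, "spiked_spec"))
  set.seed(spec$seed)
  nb <- spec$background_richness
  bg_ids <- sprintf("bg%04d", seq_len(nb))
  bg_w <- rdirichlet_sym(nb, spec$background_concentration)
  max_sp <- max(spec$conditions$n_spiked)
  sp_ids <- if (max_sp > 0) paste0("spike", seq_len(max_sp)) else character(0)
  out <- vector("list", nrow(spec$conditions))
  truth <- vector("list", nrow(spec$conditions))
  nms <- character(nrow(spec$conditions))
  for (i in seq_len(nrow(spec$conditions))) {
    k <- spec$conditions$n_spiked[i]
    share <- spec$conditions$expected_share[i]
    if (k > 0) {
      w <- rep_len(spec$copy_numbers, k)
      p <- c(share * w / sum(w), (1 - share) * bg_w)
      names(p) <- c(sp_ids[seq_len(k)], bg_ids)
    } else {
      p <- bg_w
      names(p) <- bg_ids
    }
    cts <- sample_counts(p, spec$cells)
    # sample_counts names by index; restore clone ids
    names(cts) <- names(p)[as.integer(names(cts))]
    nms[i] <- sprintf("spiked%d_%02d", k, round(100 * share))
    out[[i]] <- cts
    truth[[i]] <- p
  }
  names(out) <- nms
  names(truth) <- nms
  attr(out, "expected_share") <- spec$conditions$expected_share
  attr(out, "true_abundances") <- truth
  out
}
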