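test_that("log-base conversion of Shannon values", {
  expect_equal(convert_log_base(1, 2, exp(1)), log(2))
  expect_equal(convert_log_base(0, 2, 10), 0)
  expect_equal(convert_log_base(8.8, exp(1), 2), 8.8 / log(2))
  expect_error(convert_log_base(-1, 2, exp(1)), "non-negative")
})

test_that("Pielou from (Shannon, richness) summaries", {
  expect_equal(pielou_from_summary(log(100), 100), 1)
  expect_identical(pielou_from_summary(0, 1), NA_real_)
  expect_equal(pielou_from_summary(4.0, 1000), 4 / log(1000))
  # published rounding can push J marginally over 1: clamped with a warning
  expect_warning(j <- pielou_from_summary(4.7, 100), "clamped")
  expect_equal(j, 1)
  expect_error(pielou_from_summary(2, 0), ">= 1")
})

test_that("Pielou is invariant to the (H, base) representation", {
  set.seed(21)
  for (rep in 1:20) {
    S <- sample(2:5000, 1)
    h_e <- runif(1, 0, log(S))
    h_2 <- convert_log_base(h_e, exp(1), 2)
    expect_lt(abs(pielou_from_summary(h_e, S, exp(1)) -
                  pielou_from_summary(h_2, S, 2)), 1e-12)
  }
})

test_that("evenness labels use a strict threshold and keep sentinels", {
  rec <- data.frame(
    study = "s", patient = c("P1", "P1", "P2", "P3"),
    time_months = c(6, 3, 3, 3), cell_type = "PBMC",
    unique_is = c(100, 100, 100, 1),
    shannon = c(0.49 * log(100), 0.5 * log(100), 0.8 * log(100), 0),
    log_base = exp(1), event_flag = FALSE)
  out <- classify_evenness(rec)
  expect_identical(out$label[out$patient == "P3"], "undefined")
  expect_identical(out$label[out$patient == "P2"], "high")
  # 0.49 -> low; exactly 0.5 -> high (strictly below the threshold is low)
  p1 <- out[out$patient == "P1", ]
  expect_identical(p1$label[p1$pielou < 0.5 - 1e-9], "low")
  expect_identical(p1$label[abs(p1$pielou - 0.5) < 1e-9], "high")
  # longitudinal ordering by patient then time
  expect_identical(p1$time_months, c(3, 6))
})

test_that("a synthetic dominance event flips the label at onset", {
  spec <- trial_generator_spec(n_patients = 4, event_patients = 3,
                               event_onset = 24, event_peak = 0.98,
                               seed = 17)
  out <- classify_evenness(generate_trial_table(spec))
  ev <- out[out$patient == "P03", ]
  expect_true(all(ev$label[ev$time_months < 24] == "high"))
  expect_true(all(ev$label[ev$time_months >= 24] == "low"))
  expect_true(all(out$label[out$patient != "P03"] == "high"))
})

test_that("spiked-condition report orders conditions and tracks major clones", {
  even_bg <- rep(2, 999)
  names(even_bg) <- paste0("bg", 1:999)
  spiked <- c(one = 1998, even_bg)  # one clone at half the total
  rep_out <- spiked_condition_report(
    list(spiked = spiked, unspiked = even_bg),
    expected_share = c(0.5, 0))
  idx <- rep_out$indices
  # ordered by expected spiked share
  expect_identical(idx$condition, c("unspiked", "spiked"))
  expect_identical(idx$uc50[idx$condition == "spiked"], 1L)
  expect_lt(idx$pielou[idx$condition == "spiked"],
            idx$pielou[idx$condition == "unspiked"])
  expect_equal(idx$pielou[idx$condition == "unspiked"], 1)
  expect_equal(idx$minor_share[idx$condition == "unspiked"], 1)
  # the spiked clone is the only major one (cutoff 1%)
  maj <- rep_out$major_clones
  expect_identical(maj$clone_id, "one")
  expect_equal(maj$share, 0.5)
})

test_that("Pielou reacts more strongly than Simpson once spiking passes 20%", {
  spec <- spiked_spec(conditions = data.frame(
    n_spiked = c(0L, 1L, 2L, 3L, 3L),
    expected_share = c(0, 0.1, 0.3, 0.5, 0.7)), seed = 23)
  tabs <- generate_spiked_tables(spec)
  rep_out <- spiked_condition_report(tabs,
    expected_share = attr(tabs, "expected_share"))
  idx <- rep_out$indices
  d_p <- -diff(idx$pielou)
  d_s <- -diff(idx$simpson)
  high <- idx$expected_share[-1] > 0.2
  expect_true(all(d_p[high] >= d_s[high]))
})
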