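test_that("behavior generation is deterministic under the scenario seed", {
  sc <- tiny_scenario()
  a <- simulate_behavior(sc)
  b <- simulate_behavior(sc)
  expect_identical(a, b)
  # order-independence of substreams
  d2 <- simulate_behavior(sc, mice = 2, days = 2)[[1]][[1]]
  expect_identical(as.data.frame(a$mouse02$day2), as.data.frame(d2))
})

test_that("detection cohorts learn: mean d-prime rises from day 1 to last day", {
  sc <- cohort_scenario(n_mice = 14, n_days = 8, trials_per_session = 120,
                        seed = 3)
  beh <- simulate_behavior(sc)
  dp <- function(day) vapply(beh, function(m)
    session_performance(m[[paste0("day", day)]], day)$dprime, numeric(1))
  expect_gt(mean(dp(8)), mean(dp(1)))
  expect_gt(mean(dp(8)), 1.5)   # trained performance near d' = 2
  expect_lt(mean(dp(1)), 0.5)
})

test_that("neutral-exposure licking is independent of the stimulus", {
  sc <- cohort_scenario(paradigm = "neutral_exposure", n_mice = 6, n_days = 1,
                        trials_per_session = 300, seed = 5,
                        areas = area_defaults()[c(1, 6), ])
  tts <- do.call(rbind, lapply(simulate_behavior(sc, days = 1), function(m)
    as.data.frame(m[[1]])[c("kind", "outcome")]))
  tts <- tts[tts$outcome != "aborted", ]
  lick <- tts$outcome %in% c("hit", "false_alarm")
  p_stim <- mean(lick[tts$kind == "stimulus"])
  p_all <- mean(lick)
  se <- sqrt(p_all * (1 - p_all) / sum(tts$kind == "stimulus"))
  expect_lt(abs(p_stim - p_all), 3 * se)
})

test_that("noiseless LFP reproduces the programmed kernel sample-for-sample", {
  sc <- tiny_scenario(noise = list(sd_uv = 0), artifact_uv = 0,
                      trials_per_session = 30)
  sc$areas$hit_gain <- 1   # single amplitude for every stimulus trial
  trials <- simulate_behavior(sc, 1, 2)[[1]][[1]]
  dp <- 1.25
  lfp <- simulate_lfp(trials, sc, dp, seed = 1)
  ep <- extract_epochs(lfp, trials, "wS1")
  mask <- trial_mask(ep, trials, c("hit", "miss"), exclude_premature = FALSE)
  sep <- average_sep(ep, mask)
  cfg <- sc$areas[sc$areas$area == "wS1", ]
  expected <- cfg$polarity * cfg$base_uv *
    sep_kernel(pmax(sep$time_s, 0), cfg$latency_ms, cfg$tau_rise_ms,
               cfg$tau_decay_ms)
  expected[sep$time_s < 0] <- 0
  expect_equal(sep$waveform, expected, tolerance = 1e-9)
})

test_that("coupled-area amplitude scales linearly with d-prime by construction", {
  sc <- tiny_scenario(noise = list(sd_uv = 0), artifact_uv = 0,
                      trials_per_session = 30)
  sc$areas$hit_gain <- 1
  trials <- simulate_behavior(sc, 1, 1)[[1]][[1]]
  peak_at <- function(dp) {
    ep <- extract_epochs(simulate_lfp(trials, sc, dp, seed = 1), trials, "mPFC")
    sep <- average_sep(ep, trial_mask(ep, trials, c("hit", "miss"),
                                      exclude_premature = FALSE))
    find_first_peak(sep, polarity = 1)$peak_amp_uv
  }
  gain <- sc$areas$gain_uv_per_dprime[sc$areas$area == "mPFC"]
  # grid quantization puts the sampled peak within 0.1% of the kernel max
  expect_equal(peak_at(2) - peak_at(0), 2 * gain, tolerance = 1e-3)
})

test_that("programmed kernel latencies order sensory before higher areas", {
  cfg <- area_defaults()
  expect_lt(cfg$latency_ms[cfg$area == "wS1"], cfg$latency_ms[cfg$area == "dCA1"])
  expect_lt(cfg$latency_ms[cfg$area == "wS1"], cfg$latency_ms[cfg$area == "mPFC"])
  expect_true(all(cfg$peak_ms < 50))  # fast recruitment, before licking
})

test_that("AR(1) noise matches the programmed coefficient and variance", {
  set.seed(42)
  x <- whiskerlfp:::.ar1_noise(2e5, 0.95, 60)
  expect_equal(sd(x), 60, tolerance = 0.05)
  r1 <- cor(x[-1], x[-length(x)])
  expect_equal(r1, 0.95, tolerance = 0.01)
})

test_that("spike generator produces the programmed modulation structure", {
  sc <- tiny_scenario(trials_per_session = 120,
                      spikes = list(n_units = 30, frac_positive = 0.5,
                                    frac_negative = 0.5, mod_depth = 0.5))
  trials <- simulate_behavior(sc, 1, 2)[[1]][[1]]
  units <- simulate_spikes(trials, sc, seed = 9)
  stim_on <- trials$onset_s[trials$kind == "stimulus" &
                              trials$outcome != "aborted"]
  for (u in units[1:8]) {
    post <- mean(whiskerlfp:::.counts_in_window(u$spike_times_s, stim_on, 0, 1))
    pre <- mean(whiskerlfp:::.counts_in_window(u$spike_times_s, stim_on, -1, 0))
    kl <- attr(u, "programmed_class")
    if (kl == "positive") expect_gt(post, pre)
    if (kl == "negative") expect_lt(post, pre)
  }
})

test_that("zero modulation depth leaves pre/post rates equal in expectation", {
  sc <- tiny_scenario(trials_per_session = 150,
                      spikes = list(n_units = 20, mod_depth = 0))
  trials <- simulate_behavior(sc, 1, 2)[[1]][[1]]
  units <- simulate_spikes(trials, sc, seed = 4)
  stim_on <- trials$onset_s[trials$kind == "stimulus" &
                              trials$outcome != "aborted"]
  deltas <- vapply(units, function(u)
    mean(whiskerlfp:::.counts_in_window(u$spike_times_s, stim_on, 0, 1)) -
      mean(whiskerlfp:::.counts_in_window(u$spike_times_s, stim_on, -1, 0)),
    numeric(1))
  se <- sqrt(2 * sc$spikes$baseline_hz / length(stim_on) / length(units))
  expect_lt(abs(mean(deltas)), 4 * se)
})

test_that("waveform durations form the programmed RSU/FSU mixture", {
  sc <- tiny_scenario(trials_per_session = 40,
                      spikes = list(n_units = 300, frac_fsu = 0.5))
  trials <- simulate_behavior(sc, 1, 1)[[1]][[1]]
  units <- simulate_spikes(trials, sc, seed = 2)
  dur <- vapply(units, `[[`, numeric(1), "trough_to_peak_ms")
  cls <- classify_unit(dur)
  expect_equal(mean(dur[cls == "RSU"]), sc$spikes$rsu_ms, tolerance = 0.05)
  expect_equal(mean(dur[cls == "FSU"]), sc$spikes$fsu_ms, tolerance = 0.05)
  expect_equal(mean(cls == "FSU"), 0.5, tolerance = 0.12)
})

test_that("make_cohort writes one file per session plus a manifest", {
  sc <- tiny_scenario(n_mice = 2, n_days = 3, trials_per_session = 15)
  dir <- tempfile()
  paths <- make_cohort(sc, dir)
  expect_length(paths, 6)
  expect_true(all(file.exists(paths)))
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 6)
  # same seed => byte-identical trial CSVs
  dir2 <- tempfile()
  make_cohort(sc, dir2)
  f <- "mouse01_day02_trials.csv"
  expect_identical(readLines(file.path(dir, f)),
                   readLines(file.path(dir2, f)))
  unlink(c(dir, dir2), recursive = TRUE)
})

test_that("degenerate scenarios are rejected", {
  expect_error(cohort_scenario(n_days = 0), "n_days")
  expect_error(cohort_scenario(learning = list(asymptote = 0.1,
                                               fa_rate = 0.2)), "asymptote")
  expect_error(cohort_scenario(spikes = list(frac_positive = 0.7,
                                             frac_negative = 0.7)),
               "fractions")
})
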