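test_that("band-pass preprocessing attenuates out-of-band power and DC", {
  fs <- 2000
  t <- seq(0, 10, by = 1 / fs)
  sine200 <- sin(2 * pi * 200 * t)
  rec <- continuous_recording(cbind(sine200), fs, "wS1")
  out <- preprocess_lfp(rec, stim_times_s = numeric(0))
  mid <- seq(2 * fs, 8 * fs)  # avoid filter edges
  atten_db <- 20 * log10(sd(sine200[mid]) / sd(out$samples[mid, 1]))
  expect_gt(atten_db, 20)
  # a pure DC offset is removed by the high-pass edge
  dc <- continuous_recording(cbind(rep(50, 40 * fs)), fs, "wS1")
  out_dc <- preprocess_lfp(dc, numeric(0))
  inner <- seq(10 * fs, 30 * fs)  # beyond the high-pass settling time
  expect_lt(abs(mean(out_dc$samples[inner, 1])), 0.5)
  expect_lt(max(abs(out_dc$samples[inner, 1])), 1)
})

test_that("the compiled zero-phase filter matches signal::filtfilt", {
  set.seed(8)
  x <- cumsum(rnorm(4000))
  bf <- signal::butter(2, c(0.1, 100) / 1000, type = "pass")
  a <- whiskerlfp:::.iir_filtfilt(bf$b, bf$a, x)
  b <- signal::filtfilt(bf, x)
  mid <- 200:3800  # implementations differ only in edge handling
  expect_lt(max(abs(a[mid] - b[mid])) / sd(x), 0.02)
})

test_that("the stimulus artifact is removed by blanking", {
  fs <- 2000
  n <- 20 * fs
  x <- rep(0, n)
  stim <- c(5, 9.4, 14.2)
  idx <- round(stim * fs) + 1
  x[idx] <- 3000
  x[idx + 1] <- 2000
  rec <- continuous_recording(cbind(x), fs, "mPFC")
  out <- preprocess_lfp(rec, stim)
  expect_lt(max(abs(out$samples[, 1])), 5)
  expect_error(preprocess_lfp(rec, 100), "outside")
})

test_that("epoch extraction baseline-corrects each trial and counts trials", {
  fs <- 2000
  sc <- tiny_scenario(trials_per_session = 25)
  ses <- simulate_session(sc, 1, 2)
  rec <- preprocess_lfp(ses$lfp, whiskerlfp:::.stim_times(ses$trials))
  ep <- extract_epochs(rec, ses$trials, "wS1")
  expect_equal(nrow(ep$data), sum(ses$trials$outcome != "aborted"))
  bl <- ep$time_s >= -0.05 & ep$time_s < 0
  expect_lt(max(abs(rowMeans(ep$data[, bl]))), 1e-9)
  # constant signal => all-zero epochs
  const <- continuous_recording(cbind(rep(7, 400 * fs)), fs, "wS1")
  tt <- classify_trials(make_trials(rep("stimulus", 3), list(0.5, 0.5, 0.5),
                                    onsets = c(100, 107, 115)))
  ep2 <- extract_epochs(const, tt, "wS1")
  expect_equal(max(abs(ep2$data)), 0)
  # out-of-bounds trials are dropped with a warning
  tt3 <- classify_trials(make_trials(rep("stimulus", 2), list(0.5, 0.5),
                                     onsets = c(100, 399.99)))
  expect_warning(ep3 <- extract_epochs(const, tt3, "wS1"), "dropped")
  expect_equal(nrow(ep3$data), 1)
})

test_that("averaging returns the epoch itself for identical trials and scales SEM as 1/sqrt(n)", {
  row <- sin(seq(0, 3, length.out = 700))
  ep <- make_epochs(matrix(rep(row, 10), 10, byrow = TRUE))
  sep <- average_sep(ep)
  expect_equal(sep$waveform, row)
  expect_error(average_sep(ep, rep(FALSE, 10)), "no trials")
  set.seed(2)
  sems <- vapply(c(25, 400), function(n)
    mean(average_sep(make_epochs(matrix(rnorm(n * 100), n)))$sem), numeric(1))
  expect_equal(sems[1] / sems[2], 4, tolerance = 0.35)
})

test_that("hit masks exclude premature trials", {
  tt <- classify_trials(make_trials(rep("stimulus", 4),
                                    list(0.5, 0.05, 0.4, numeric(0))))
  ep <- make_epochs(matrix(0, 4, 100))
  expect_equal(trial_mask(ep, tt, "hit"), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(trial_mask(ep, tt, "hit", exclude_premature = FALSE),
               c(TRUE, TRUE, TRUE, FALSE))
})

test_that("first-peak detection finds the earliest qualifying extremum", {
  fs <- 2000
  t <- seq(-0.05, 0.3, by = 1 / fs)
  bump <- function(t0, amp, width = 0.008) amp * exp(-((t - t0) / width)^2)
  sep <- make_sep(bump(0.030, -200), fs)
  pk <- find_first_peak(sep, polarity = -1)
  expect_equal(pk$peak_time_s, 0.030)
  expect_equal(pk$peak_amp_uv, -200)
  # two bumps: the first wins even if smaller
  sep2 <- make_sep(bump(0.020, -120) + bump(0.060, -250), fs)
  expect_equal(find_first_peak(sep2, polarity = -1)$peak_time_s, 0.020,
               tolerance = 5e-4)
  # flat waveform: explicit no-peak result
  expect_true(is.na(find_first_peak(make_sep(rep(0, length(t)), fs),
                                    polarity = -1)$peak_time_s))
  # polarity gate: a negative bump is invisible to a positive search
  expect_true(is.na(find_first_peak(sep, polarity = 1)$peak_time_s))
})

test_that("measure_at uses the nearest sample", {
  fs <- 2000
  w <- seq_len(700)  # strictly increasing ramp, one unit per sample
  sep <- make_sep(w, fs)
  expect_equal(measure_at(sep, sep$time_s[300]), 300)
  expect_equal(measure_at(sep, sep$time_s[300] + 0.4 / fs), 300)
  expect_equal(measure_at(sep, sep$time_s[300] + 0.6 / fs), 301)
  expect_error(measure_at(sep, 1), "outside")
})

test_that("onset latency is the first sustained threshold crossing", {
  fs <- 2000
  t <- seq(-0.05, 0.3, by = 1 / fs)
  set.seed(3)
  base_noise <- rnorm(length(t), 0, 1)
  w <- base_noise
  w[t >= 0.008] <- w[t >= 0.008] + 10
  expect_equal(onset_latency(make_sep(w, fs)), 0.008, tolerance = 1e-3)
  # pure noise rarely crosses for 5 ms
  nohit <- vapply(1:40, function(i)
    is.na(onset_latency(make_sep(rnorm(length(t)), fs))), logical(1))
  expect_gte(mean(nohit), 0.95)
  # latency precedes the peak when both are defined
  sc <- tiny_scenario(trials_per_session = 60)
  ses <- simulate_session(sc, 1, 2)
  rec <- preprocess_lfp(ses$lfp, whiskerlfp:::.stim_times(ses$trials))
  ep <- extract_epochs(rec, ses$trials, "wS1")
  sep <- average_sep(ep, trial_mask(ep, ses$trials, c("hit", "miss"),
                                    exclude_premature = FALSE))
  lat <- onset_latency(sep)
  pk <- find_first_peak(sep, polarity = -1)
  expect_lte(lat, pk$peak_time_s)
})

test_that("windowed paired Wilcoxon flags only windows with a real shift", {
  fs <- 2000
  t <- seq(-0.05, 0.3, by = 1 / fs)
  shift <- ifelse(t >= 0.020 & t < 0.040, 5, 0)
  set.seed(7)
  pairs <- lapply(1:10, function(m)
    list(a = rnorm(length(t)), b = rnorm(length(t)) + shift))
  res <- windowed_paired_test(pairs, t)
  inside <- res$t_s > 0.020 & res$t_s < 0.040
  expect_true(all(res$p[inside] < 0.05))
  expect_lt(mean(res$p[!inside] < 0.05), 0.2)
  # identical conditions give p = 1 everywhere
  same <- lapply(1:6, function(m) { x <- rnorm(length(t)); list(a = x, b = x) })
  expect_true(all(windowed_paired_test(same, t)$p == 1))
  expect_error(windowed_paired_test(pairs[1], t), "two mice")
  expect_warning(windowed_paired_test(pairs[1:3], t), "5 mice")
})

test_that("peak-amplitude correlation matches hand-computed Pearson r", {
  expect_equal(peak_vs_dprime_correlation(
    data.frame(peak_amp = 1:6, dprime = 2 * (1:6)))$r, 1, tolerance = 1e-12)
  res <- peak_vs_dprime_correlation(
    data.frame(peak_amp = c(1, 2, 3), dprime = c(1, 3, 2)))
  expect_equal(res$r, 0.5, tolerance = 1e-12)
  expect_error(peak_vs_dprime_correlation(
    data.frame(peak_amp = c(1, 1, 1), dprime = 1:3)), "variance")
  # null: r small and p roughly uniform
  set.seed(11)
  ps <- replicate(200, peak_vs_dprime_correlation(
    data.frame(peak_amp = rnorm(40), dprime = rnorm(40)))$p)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.05)
})

test_that("the SEP pipeline is linear in the input scale", {
  sc <- tiny_scenario(trials_per_session = 40)
  ses <- simulate_session(sc, 1, 2)
  run <- function(scale) {
    lfp <- continuous_recording(ses$lfp$samples * scale, ses$lfp$fs_hz,
                                ses$lfp$channel_area)
    rec <- preprocess_lfp(lfp, whiskerlfp:::.stim_times(ses$trials))
    ep <- extract_epochs(rec, ses$trials, "wS1")
    sep <- average_sep(ep, trial_mask(ep, ses$trials, c("hit", "miss"),
                                      exclude_premature = FALSE))
    find_first_peak(sep, polarity = -1)
  }
  p1 <- run(1)
  p3 <- run(3)
  expect_equal(p3$peak_amp_uv, 3 * p1$peak_amp_uv, tolerance = 1e-9)
  expect_equal(p3$peak_time_s, p1$peak_time_s)
})

test_that("latency ordering across areas delegates to the joint-rank test", {
  set.seed(12)
  lat <- list(wS1 = rnorm(12, 6, 0.5), dCA1 = rnorm(12, 16, 0.5),
              mPFC = rnorm(12, 19, 0.5))
  res <- latency_ordering_test(lat)
  expect_s3_class(res, "pairwise_result")
  expect_true(res$significant["wS1", "mPFC"])
  expect_true(res$significant["wS1", "dCA1"])
})
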