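test_that("waveform duration classifies RSU vs FSU with >= tie-break", {
  expect_equal(classify_unit(0.6), "RSU")
  expect_equal(classify_unit(0.2), "FSU")
  expect_equal(classify_unit(0.35), "RSU")
  expect_equal(classify_unit(c(0.3, 0.5)), c("FSU", "RSU"))
  expect_error(classify_unit(0), "trough_to_peak")
})

test_that("psth recovers a homogeneous Poisson rate and normalizes by trials", {
  set.seed(31)
  u <- make_poisson_unit(10, 2000)
  onsets <- seq(50, 1950, by = 10)
  p <- psth(u, onsets)
  expect_equal(mean(p$rate_hz), 10, tolerance = 0.05)
  # per-bin SE: sqrt(rate / (n_trials * bin)) ~ 2.3 Hz at these sizes
  expect_lt(sd(p$rate_hz), 3.5)
  # duplicating onsets leaves the rate unchanged
  p2 <- psth(u, c(onsets, onsets))
  expect_equal(p2$rate_hz, p$rate_hz)
  # empty spike train: all-zero curve, not an error
  empty <- unit_data("u0", numeric(0), trough_to_peak_ms = 0.5)
  expect_true(all(psth(empty, onsets)$rate_hz == 0))
  expect_error(psth(u, numeric(0)), "onset")
})

test_that("z-scored PSTH has zero-mean unit-SD baseline and is linear", {
  set.seed(32)
  u <- make_poisson_unit(8, 1500)
  onsets <- seq(30, 1450, by = 9.5)
  p <- psth(u, onsets)
  z <- zscore_psth(p)
  bl <- p$t_s >= -1 & p$t_s < 0
  expect_lt(abs(mean(z[bl])), 1e-9)
  expect_equal(sd(z[bl]), 1, tolerance = 1e-9)
  # adding c baseline-SDs to one bin shifts its z by c
  sdv <- sd(p$rate_hz[bl])
  p2 <- p
  p2$rate_hz[200] <- p2$rate_hz[200] + 3 * sdv
  expect_equal(zscore_psth(p2)[200] - z[200], 3, tolerance = 1e-9)
  flat <- p
  flat$rate_hz[] <- 5
  expect_error(zscore_psth(flat), "baseline")
})

test_that("bootstrap modulation test detects strong effects with the right sign", {
  set.seed(33)
  onsets <- seq(20, 1010, by = 10)[1:100]
  up <- make_modulated_unit(5, 2, onsets, 1100)
  res_up <- modulation_test(up, onsets, seed = 1)
  expect_equal(res_up$klass, "positive")
  expect_gt(res_up$delta_hz, 0)
  down <- make_modulated_unit(5, 0, onsets, 1100)  # silenced post window
  res_down <- modulation_test(down, onsets, seed = 1)
  expect_equal(res_down$klass, "negative")
  expect_lt(res_down$delta_hz, 0)
  expect_error(modulation_test(up, onsets[1:5], seed = 1), "10 trials")
  # determinism
  expect_identical(modulation_test(up, onsets, seed = 7),
                   modulation_test(up, onsets, seed = 7))
})

test_that("bootstrap modulation test keeps its false-positive rate near alpha", {
  set.seed(34)
  onsets <- seq(20, 1010, by = 10)[1:100]
  flags <- vapply(1:200, function(i) {
    u <- make_poisson_unit(5, 1100, sprintf("u%03d", i))
    modulation_test(u, onsets, seed = i)$klass != "none"
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / 200)
  expect_lte(mean(flags), 0.05 + 2 * se)
})

test_that("modulated units are detected with >= 80% power at half-baseline depth", {
  set.seed(35)
  onsets <- seq(20, 1010, by = 10)[1:100]
  hit_pos <- vapply(1:30, function(i) {
    u <- make_modulated_unit(5, 1.5, onsets, 1100)   # +50% of baseline
    modulation_test(u, onsets, seed = i)$klass == "positive"
  }, logical(1))
  hit_neg <- vapply(1:30, function(i) {
    u <- make_modulated_unit(5, 0.5, onsets, 1100)   # -50% of baseline
    modulation_test(u, onsets, seed = i)$klass == "negative"
  }, logical(1))
  expect_gte(mean(hit_pos), 0.8)
  expect_gte(mean(hit_neg), 0.8)
})

test_that("hit-miss contrast flags real rate differences and holds its level", {
  set.seed(36)
  hit_on <- seq(20, 520, by = 10)[1:50]
  miss_on <- seq(530, 1030, by = 10)[1:50]
  u <- make_modulated_unit(5, 2, hit_on, 1100)  # modulated only on hits
  res <- hit_miss_unit_test(u, hit_on, miss_on, seed = 2)
  expect_true(res$significant)
  expect_gt(res$delta_hz, 0)
  # null level
  sig <- vapply(1:60, function(i) {
    u0 <- make_poisson_unit(5, 1100)
    hit_miss_unit_test(u0, hit_on, miss_on, seed = i)$significant
  }, logical(1))
  expect_lte(mean(sig), 0.05 + 2 * sqrt(0.05 * 0.95 / 60))
  expect_error(hit_miss_unit_test(u, hit_on, numeric(0)), "5 trials")
})

test_that("population summary reports modulated fractions", {
  mk <- function(k) structure(list(unit_id = "x", klass = k),
                              class = "modulation_result")
  res <- population_summary(c(replicate(6, mk("positive"), simplify = FALSE),
                              replicate(3, mk("negative"), simplify = FALSE),
                              replicate(9, mk("none"), simplify = FALSE)))
  expect_equal(res$fraction[res$klass == "positive"], 1 / 3)
  expect_equal(res$n[res$klass == "negative"], 3)
  expect_error(population_summary(list()), "no units")
  all_pos <- population_summary(replicate(4, mk("positive"), simplify = FALSE))
  expect_equal(all_pos$fraction, c(1, 0, 0))
})

test_that("programmed 1/3-1/3 modulated fractions are recovered on a synthetic session", {
  sc <- tiny_scenario(trials_per_session = 260,
                      spikes = list(n_units = 120))
  trials <- simulate_behavior(sc, 1, 5)[[1]][[1]]
  units <- simulate_spikes(trials, sc, seed = 37)
  hits <- trials$onset_s[trials$outcome == "hit" & !trials$premature]
  res <- lapply(units, modulation_test, hit_onsets_s = hits, seed = 38)
  fr <- population_summary(res)
  se <- sqrt((1 / 3) * (2 / 3) / 120)
  expect_lt(abs(fr$fraction[fr$klass == "positive"] - 1 / 3), 3.5 * se)
  expect_lt(abs(fr$fraction[fr$klass == "negative"] - 1 / 3), 3.5 * se)
})
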