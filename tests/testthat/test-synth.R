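zero_sd_params <- function() {
  bs <- reference_band_stats()
  bs$sd_pct <- 0
  generator_params(band_stats = bs, seed = 1)
}

test_that("band-fraction sampling hits the group means exactly when SD is zero", {
  p <- zero_sd_params()
  fr <- sample_band_fractions(p, "normal", n = 3)
  # normal means + exact residual complement already sum to 100, so the
  # renormalized fractions equal the means/100
  expect_equal(unname(fr[1, ]), c(0.3139, 0.1971, 0.3060, 0.1496, 0.0334),
               tolerance = 1e-12)
  expect_equal(fr[1, ], fr[3, ])
  expect_equal(rowSums(fr), rep(1, 3))
})

test_that("degenerate one-band stats give a one-band fraction vector", {
  bs <- data.frame(group = "normal",
                   band = c("delta", "theta", "alpha", "beta", "residual"),
                   mean_pct = c(100, 0, 0, 0, 0), sd_pct = 0)
  p <- generator_params(band_stats = bs, n_epochs = c(normal = 1L), seed = 1)
  expect_equal(unname(sample_band_fractions(p, "normal")[1, ]),
               c(1, 0, 0, 0, 0))
  expect_error(sample_band_fractions(p, "martian"),
               class = "eegsubband_config_error")
})

test_that("pre-renormalization draws follow the truncated normal (MC vs closed form)", {
  p <- generator_params(seed = 1)
  set.seed(1234)
  draws <- sample_band_fractions(p, "encephalopathy", n = 10000,
                                 renormalize = FALSE)
  target <- truncnorm0_mean(67.73, 19.34) / 100
  se <- sd(draws[, "delta"]) / sqrt(nrow(draws))
  expect_lt(abs(mean(draws[, "delta"]) - target), 3 * se)
  # truncation bias itself is tiny for this band (|alpha| ~ 3.5 SDs)
  expect_lt(abs(target - 0.6773), 3 * se)
  expect_true(all(draws >= 0))
})

test_that("synthesized epochs realize the requested band energy shares", {
  set.seed(7)
  fr <- c(0.31, 0.20, 0.31, 0.15, 0.03)
  ep <- synthesize_epoch(fr, fs = 500, duration_s = 12, total_power = 2500)
  expect_s3_class(ep, "eeg_epoch")
  expect_length(ep$samples, 6000)
  # total energy contract is exact for the FFT synthesis route
  expect_equal(sum(ep$samples^2), 2500 * 6000, tolerance = 1e-9)
  # periodogram oracle: each share exact to well under the 1% contract
  edges <- list(c(0.5, 4), c(4, 8), c(8, 13), c(13, 30), c(31.25, 250))
  meas <- vapply(edges, function(e) fft_band_fraction(ep$samples, 500, e[1], e[2]),
                 numeric(1))
  expect_equal(meas, fr, tolerance = 1e-6)
})

test_that("a pure-delta epoch has almost no energy above 4 Hz", {
  set.seed(8)
  ep <- synthesize_epoch(c(1, 0, 0, 0, 0), fs = 500, duration_s = 12)
  expect_lt(1 - fft_band_fraction(ep$samples, 500, 0, 4), 0.05)
})

test_that("zero total power gives an all-zero epoch and bad fractions error", {
  ep <- synthesize_epoch(c(1, 0, 0, 0, 0), total_power = 0)
  expect_true(all(ep$samples == 0))
  expect_error(synthesize_epoch(c(0.5, 0.2, 0.1, 0.1, 0.05)),
               class = "eegsubband_input_error")
  expect_error(synthesize_epoch(c(0.5, 0.2, 0.2, 0.1)),
               class = "eegsubband_input_error")
})

test_that("cohort generation is sized, labelled and bit-reproducible", {
  p <- generator_params(n_epochs = c(encephalopathy = 5L, normal = 4L), seed = 99)
  co <- generate_cohort(p)
  expect_length(co$epochs, 9)
  expect_equal(as.vector(table(co$manifest$group)[c("encephalopathy", "normal")]),
               c(5L, 4L))
  expect_true(all(co$manifest$n_samples == 6000))
  expect_false(anyDuplicated(co$manifest$epoch_id) > 0)
  co2 <- generate_cohort(p)
  expect_identical(co$epochs[[1]]$samples, co2$epochs[[1]]$samples)
  expect_identical(co$manifest, co2$manifest)
  # manifest fractions are the ground truth actually synthesized
  expect_equal(
    fft_band_fraction(co$epochs[[1]]$samples, 500, 0.5, 4),
    co$manifest$frac_delta[1], tolerance = 1e-6)
})

test_that("an empty cohort is valid and configuration errors are caught", {
  p <- generator_params(n_epochs = c(encephalopathy = 0L, normal = 0L))
  co <- generate_cohort(p)
  expect_length(co$epochs, 0)
  expect_equal(nrow(co$manifest), 0)
  expect_error(generator_params(fs = 500, duration_s = 1 / 3),
               class = "eegsubband_config_error")
  bs <- reference_band_stats(); bs$mean_pct[1] <- 120
  expect_error(generator_params(band_stats = bs),
               class = "eegsubband_config_error")
})

test_that("generator RNG is private: the session RNG stream is untouched", {
  set.seed(555)
  a <- rnorm(3)
  set.seed(555)
  invisible(generate_cohort(generator_params(
    n_epochs = c(encephalopathy = 1L, normal = 0L), duration_s = 1, seed = 7)))
  expect_identical(rnorm(3), a)
})
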