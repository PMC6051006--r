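test_that("db4 filter pair satisfies the orthonormality invariants", {
  f <- db4_filters()
  expect_length(f$g, 8)
  expect_equal(sum(f$g^2), 1, tolerance = 1e-14)
  expect_equal(sum(f$h^2), 1, tolerance = 1e-14)
  expect_equal(sum(f$g), sqrt(2), tolerance = 1e-12)
  # vanishing even-lag autocorrelation and quadrature-mirror orthogonality
  for (m in 1:3) {
    expect_equal(sum(f$g * c(f$g[-(1:(2 * m))], rep(0, 2 * m))), 0,
                 tolerance = 1e-14)
  }
  for (m in 0:3) {
    expect_equal(sum(f$g * c(f$h[-seq_len(2 * m)], rep(0, 2 * m))), 0,
                 tolerance = 1e-14)
  }
  expect_error(db4_filters("haar"), class = "eegsubband_config_error")
})

test_that("one analysis level matches the direct-convolution oracle", {
  f <- db4_filters()
  # unit impulse, length 8 (the filter wraps fully)
  imp <- c(1, rep(0, 7))
  lev <- dwt_level(imp, f)
  oracle <- direct_dwt_level(imp, f)
  expect_equal(lev$approx, oracle$approx, tolerance = 1e-15)
  expect_equal(lev$detail, oracle$detail, tolerance = 1e-15)
  # random signals, several even lengths
  set.seed(5)
  for (n in c(12, 64, 250)) {
    s <- rnorm(n)
    lev <- dwt_level(s, f)
    oracle <- direct_dwt_level(s, f)
    expect_equal(lev$approx, oracle$approx, tolerance = 1e-12)
    expect_equal(lev$detail, oracle$detail, tolerance = 1e-12)
    # Parseval at a single level
    expect_equal(sum(lev$approx^2) + sum(lev$detail^2), sum(s^2),
                 tolerance = 1e-12)
  }
  expect_equal(dwt_level(rep(0, 16), f),
               list(approx = rep(0, 8), detail = rep(0, 8)))
  expect_error(dwt_level(numeric(0), f), class = "eegsubband_input_error")
})

test_that("the 6-level cascade equals the explicit orthonormal matrix (n = 64)", {
  f <- db4_filters()
  n <- 64L
  W <- diag(n)
  rows_done <- 0L
  blocks <- list()
  approx_rows <- W
  len <- n
  for (k in 1:6) {
    mats <- dwt_level_matrix(len, f$g, f$h)
    blocks[[paste0("D", k)]] <- mats$H %*% approx_rows
    approx_rows <- mats$G %*% approx_rows
    len <- len %/% 2L
  }
  blocks[["A6"]] <- approx_rows
  Wfull <- do.call(rbind, blocks[c("A6", paste0("D", 6:1))])
  # the stacked matrix is orthogonal
  expect_lt(max(abs(Wfull %*% t(Wfull) - diag(n))), 1e-10)
  set.seed(6)
  s <- rnorm(n)
  sb <- wavedec6(s, f, fs = 500)
  expect_equal(unlist(sb$coeffs, use.names = FALSE),
               as.numeric(Wfull %*% s), tolerance = 1e-12)
})

test_that("wavedec6 coefficient counts follow the ceil(n/2) recursion", {
  set.seed(7)
  sb <- wavedec6(rnorm(6000), fs = 500)
  expect_equal(vapply(sb$coeffs, length, integer(1)),
               c(A6 = 94L, D6 = 94L, D5 = 188L, D4 = 375L, D3 = 750L,
                 D2 = 1500L, D1 = 3000L))
  expect_error(wavedec6(rnorm(32), fs = 500), class = "eegsubband_input_error")
})

test_that("energy is conserved and reconstruction is exact (periodized)", {
  set.seed(8)
  for (i in 1:5) {
    s <- rnorm(6000)
    sb <- wavedec6(s, fs = 500)
    e <- sum(vapply(sb$coeffs, function(z) sum(z^2), numeric(1)))
    expect_lt(abs(e - sum(s^2)) / sum(s^2), 1e-10)
    expect_lt(max(abs(waverec6(sb) - s)) / max(abs(s)), 1e-10)
  }
  # realistic generated epoch
  ep <- tiny_cohort(1L, seed = 31, duration_s = 12)$epochs[[1]]
  sb <- wavedec6(ep)
  expect_lt(max(abs(waverec6(sb) - ep$samples)) / max(abs(ep$samples)), 1e-10)
})

test_that("constants are annihilated into A6 at fully dyadic lengths", {
  # 6400 = 2^7 * 50: every level stays even, so the db4 vanishing moment
  # leaves all detail sets at zero. (At 6000 samples the level-5 oddness
  # forces a pad whose boundary puts ~0.2% of energy into D5/D6; see the
  # methods vignette.)
  sb <- wavedec6(rep(3, 6400), fs = 500)
  nrm <- sqrt(sum(rep(3, 6400)^2))
  for (k in 1:6)
    expect_lt(sqrt(sum(sb$coeffs[[paste0("D", k)]]^2)) / nrm, 1e-10)
  expect_equal(sum(sb$coeffs$A6^2), sum(rep(3, 6400)^2), tolerance = 1e-12)
})

test_that("pure tones land in the clinically mapped subbands", {
  t <- (0:5999) / 500
  expected <- c("2" = "A6", "6" = "D6", "10" = "D5", "20" = "D4")
  for (fhz in c(2, 6, 10, 20)) {
    sb <- wavedec6(sin(2 * pi * fhz * t), fs = 500)
    e <- vapply(sb$coeffs, function(z) sum(z^2), numeric(1))
    expect_identical(names(which.max(e)), unname(expected[as.character(fhz)]))
  }
  bm <- wavedec6(sin(2 * pi * 2 * t), fs = 500)$band_map
  expect_equal(bm$f_hi[bm$subband == "A6"], 500 / 128)
  expect_equal(bm$band[match(c("A6", "D6", "D5", "D4"), bm$subband)],
               c("delta", "theta", "alpha", "beta"))
})

test_that("waverec6 input validation and degenerate cases", {
  sb <- wavedec6(rnorm(128), fs = 500)
  for (nm in names(sb$coeffs)) sb$coeffs[[nm]] <- sb$coeffs[[nm]] * 0
  expect_equal(waverec6(sb), rep(0, 128))
  sb$coeffs$D6 <- c(sb$coeffs$D6, 0)
  expect_error(waverec6(sb), class = "eegsubband_input_error")
  sym <- wavedec6(rnorm(128), boundary = "symmetric", fs = 500)
  expect_error(waverec6(sym), class = "eegsubband_config_error")
})
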