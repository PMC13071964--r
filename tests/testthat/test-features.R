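test_that("ERB bandwidth follows the auditory fit and grows with frequency", {
  expect_equal(erb_bandwidth(1000), 24.7 * 5.37, tolerance = 1e-12)
  expect_equal(erb_bandwidth(0), 24.7)
  expect_gt(erb_bandwidth(2000), erb_bandwidth(50))
  expect_error(erb_bandwidth(-1), "non-negative")
  # scale transforms are inverses
  f <- c(50, 316, 2000)
  expect_equal(erbrate_to_hz(hz_to_erbrate(f)), f, tolerance = 1e-9)
})

test_that("gammatone impulse response vanishes at t=0 and peaks where predicted", {
  fc <- 440
  n <- 4; b <- 1.019
  t <- seq(0, 0.05, by = 1e-5)
  g <- gammatone_impulse_response(t, fc, n = n, b = b)
  expect_equal(g[1], 0)
  env <- t^(n - 1) * exp(-2 * pi * b * erb_bandwidth(fc) * t)
  expect_true(all(abs(g) <= env + 1e-12))
  t_star <- (n - 1) / (2 * pi * b * erb_bandwidth(fc))
  expect_equal(t[which.max(env)], t_star, tolerance = 1e-3 / t_star * 1e-2 + 1e-3)
})

test_that("filterbank centres span the band uniformly on the ERB-rate scale", {
  bank <- make_filterbank(n_filters = 64, f_low = 50, f_high = 2000, rate = 8000)
  cfs <- bank$center_freqs
  expect_equal(cfs[1], 50)
  expect_equal(cfs[64], 2000)
  expect_true(all(diff(cfs) > 0))
  er <- hz_to_erbrate(cfs)
  expect_lt(max(abs(diff(er) - (er[2] - er[1]))), 1e-6)
  tiny <- make_filterbank(n_filters = 2, f_low = 50, f_high = 2000, rate = 8000)
  expect_equal(tiny$center_freqs, c(50, 2000))
})

test_that("gammatonegram frame counts, silence floor and scaling monotonicity", {
  bank <- make_filterbank(n_filters = 16, rate = 8000)
  # frame-count arithmetic at the default 25 ms / 10 ms timing
  n10 <- (10 * 8000 - 200) %/% 80 + 1
  expect_identical(n10, 998)
  x <- sin(2 * pi * 300 * (0:15999) / 8000)
  gtg <- compute_gammatonegram(x, bank, rate = 8000)
  expect_identical(ncol(gtg$values), (16000L - 200L) %/% 80L + 1L)
  expect_identical(nrow(gtg$values), 16L)
  silent <- compute_gammatonegram(numeric(4000), bank, rate = 8000)
  expect_true(all(silent$values == log10(1e-10)))
  louder <- compute_gammatonegram(2 * x, bank, rate = 8000)
  expect_true(all(louder$values >= gtg$values))
  expect_error(compute_gammatonegram(numeric(100), bank, rate = 8000), "shorter")
})

test_that("tones excite the matched filter row (FFT path equals direct convolution)", {
  bank <- make_filterbank(n_filters = 24, rate = 8000)
  set.seed(21)
  picks <- sample(24, 20, replace = TRUE)
  for (k in picks) {
    tone <- sin(2 * pi * bank$center_freqs[k] * (0:7999) / 8000)
    gtg <- compute_gammatonegram(tone, bank, rate = 8000)
    expect_identical(which.max(rowMeans(gtg$values)), as.integer(k))
  }
  # FFT convolution agrees with the brute-force time-domain oracle
  set.seed(22)
  x <- rnorm(2000)
  nfft <- 2^ceiling(log2(2000 + nrow(bank$irs) - 1))
  xf <- stats::fft(c(x, numeric(nfft - 2000)))
  hf <- stats::fft(c(bank$irs[, 7], numeric(nfft - nrow(bank$irs))))
  y_fft <- Re(stats::fft(xf * hf, inverse = TRUE))[1:2000] / nfft
  y_direct <- oracle_fir_convolve(x, bank$irs[, 7])
  expect_equal(y_fft, y_direct, tolerance = 1e-9)
})

test_that("frequency axis is oriented low-to-high along rows", {
  bank <- make_filterbank(n_filters = 32, rate = 8000)
  low_tone <- sin(2 * pi * 100 * (0:7999) / 8000)
  high_tone <- sin(2 * pi * 1500 * (0:7999) / 8000)
  row_low <- which.max(rowMeans(compute_gammatonegram(low_tone, bank, rate = 8000)$values))
  row_high <- which.max(rowMeans(compute_gammatonegram(high_tone, bank, rate = 8000)$values))
  expect_lt(row_low, row_high)
})

test_that("model input is a standardized three-channel square", {
  bank <- make_filterbank(n_filters = 16, rate = 8000)
  set.seed(4)
  gtg <- compute_gammatonegram(rnorm(16000), bank, rate = 8000)
  gtg$label <- 2L
  mi <- to_model_input(gtg, side = 64)
  expect_identical(dim(mi), c(64L, 64L, 3L))
  expect_equal(mean(mi[, , 1]), 0, tolerance = 1e-8)
  expect_equal(stats::sd(as.vector(mi[, , 1])), 1, tolerance = 1e-6)
  expect_identical(mi[, , 1], mi[, , 2])
  expect_identical(mi[, , 2], mi[, , 3])
  expect_identical(attr(mi, "label"), 2L)
  # constant map standardizes to all zeros
  flat <- gtg
  flat$values[] <- 3.14
  expect_true(all(to_model_input(flat, side = 32) == 0))
})
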