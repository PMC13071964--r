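test_that("bandpass magnitude has half-power cutoffs, dead DC and flat centre", {
  filt <- design_bandpass(order = 4, low_hz = 50, high_hz = 2000, rate = 8000)
  edges <- filter_response(filt, c(50, 2000))
  expect_equal(edges, c(-3.01, -3.01), tolerance = 0.2 / 3.01)
  expect_equal(filter_response(filt, 0, db = FALSE), 0, tolerance = 1e-10)
  centre <- filter_response(filt, sqrt(50 * 2000))
  expect_lt(abs(centre), 0.2)
  expect_error(design_bandpass(high_hz = 4000, rate = 8000), "Nyquist")
})

test_that("zero-phase filtering attenuates stopband tones and passes the passband", {
  filt <- design_bandpass()
  t <- (0:79999) / 8000
  stop_tone <- sin(2 * pi * 10 * t)
  pass_tone <- sin(2 * pi * 500 * t)
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(apply_bandpass(stop_tone, filt, rate = 8000)) / rms(stop_tone), 0.01)
  expect_equal(rms(apply_bandpass(pass_tone, filt, rate = 8000)) / rms(pass_tone),
               1, tolerance = 0.05)
  expect_identical(apply_bandpass(numeric(1000), filt, rate = 8000), numeric(1000))
  # segments keep length, label and rate
  seg <- segment_recording(audio_recording(pass_tone, 8000, "s", label = 3), 10, 0.5)[[1]]
  out <- apply_bandpass(seg, filt)
  expect_identical(length(out$samples), length(seg$samples))
  expect_identical(out$label, 3L)
  expect_error(apply_bandpass(seg, design_bandpass(high_hz = 900, rate = 4000)),
               "rate mismatch")
})

test_that("passband filtering is near-idempotent", {
  filt <- design_bandpass()
  t <- (0:39999) / 8000
  tone <- sin(2 * pi * 300 * t)
  rms <- function(x) sqrt(mean(x^2))
  once <- apply_bandpass(tone, filt, rate = 8000)
  twice <- apply_bandpass(once, filt, rate = 8000)
  expect_lt(abs(rms(twice) - rms(once)) / rms(once), 0.10)
})

test_that("SMOTE balances to the majority count preserving originals", {
  set.seed(5)
  tab <- list("0" = matrix(rnorm(40 * 6), 40),
              "1" = matrix(rnorm(25 * 6, 3), 25),
              "2" = matrix(rnorm(12 * 6, -3), 12),
              "3" = matrix(rnorm(18 * 6, 6), 18))
  bal <- smote_balance(tab, k_neighbors = 5, seed = 42)
  expect_true(all(vapply(bal, nrow, integer(1)) == 40))
  for (cl in names(tab))
    expect_identical(bal[[cl]][seq_len(nrow(tab[[cl]])), ], tab[[cl]])
  # already balanced input comes back unchanged
  even <- list("0" = tab$`0`, "1" = tab$`0` + 1)
  expect_identical(smote_balance(even, seed = 1), even)
  # too-small class fails loudly
  expect_error(smote_balance(list("0" = matrix(1:40, 10), "1" = matrix(1:12, 3)),
                             k_neighbors = 5, seed = 1), "k_neighbors")
})

test_that("synthetic vectors interpolate verified same-class nearest neighbours", {
  set.seed(8)
  tab <- list("0" = matrix(rnorm(60 * 4), 60),
              "1" = matrix(rnorm(30 * 4, 5), 30))
  k <- 5
  bal <- smote_balance(tab, k_neighbors = k, seed = 7)
  x <- tab$`1`
  nn <- oracle_knn(x, k)
  synth <- bal$`1`[(nrow(x) + 1):60, , drop = FALSE]
  for (si in seq_len(nrow(synth))) {
    s <- synth[si, ]
    ok <- FALSE
    for (i in seq_len(nrow(x))) {
      diffs <- s - x[i, ]
      for (j in nn[i, ]) {
        dir <- x[j, ] - x[i, ]
        u <- sum(diffs * dir) / sum(dir * dir)
        if (u >= -1e-9 && u <= 1 + 1e-9 &&
            sqrt(sum((diffs - u * dir)^2)) < 1e-8) ok <- TRUE
      }
    }
    expect_true(ok, label = sprintf("synthetic row %d lies on a parent-neighbour segment", si))
  }
  # no class leakage: class-1 synthetics stay in the class-1 halfspace
  expect_true(all(rowMeans(synth) > 1))
})
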