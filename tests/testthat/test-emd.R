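# Empirical mode decomposition: extrema, envelopes, IMF conditions, sifting,
# IMF statistics and the 43-slot EMD block.

test_that("interior extrema are found, plateaus at their floor midpoint", {
  ex <- find_extrema(c(0, 1, 0, 1, 0))
  expect_identical(ex$maxima, c(2L, 4L))
  expect_identical(ex$minima, 3L)
  ex <- find_extrema(c(1, 2, 3, 4))
  expect_length(ex$maxima, 0L)
  expect_length(ex$minima, 0L)
  # plateau maximum [0,2,2,0]: run spans indices 2-3, midpoint floors to 2
  ex <- find_extrema(c(0, 2, 2, 0))
  expect_identical(ex$maxima, 2L)
  # longer plateau, brute-check the midpoint rule
  ex <- find_extrema(c(0, 5, 5, 5, 0, -1, -1, 0))
  expect_identical(ex$maxima, 3L)   # floor((2+4)/2)
  expect_identical(ex$minima, 6L)   # floor((6+7)/2)
  # too-short signals degenerate to empty extrema sets
  expect_identical(find_extrema(c(1, 2)), list(maxima = integer(0),
                                               minima = integer(0)))
})

test_that("envelope mean respects symmetry and recovers offsets", {
  t <- seq_len(64)
  sym <- sin(2 * pi * t / 8)
  m <- envelope_mean(sym)
  expect_lt(max(abs(m)), 0.05)
  const <- 3.7 + sin(2 * pi * t / 8)
  m2 <- envelope_mean(const)
  expect_equal(m2, rep(3.7, 64), tolerance = 0.05)
  # exactly 2 maxima / 2 minima still yields a defined envelope
  short <- sin(2 * pi * seq_len(17) / 8)
  ex <- find_extrema(short)
  expect_length(ex$maxima, 2L)
  expect_length(ex$minima, 2L)
  expect_length(envelope_mean(short), 17L)
  # no minima at all -> not-enough-extrema condition
  expect_error(envelope_mean(c(0, 1, 0, 1, 0, 1, 0)[1:3]),
               class = "pdhotspot_not_enough_extrema")
})

test_that("IMF test accepts oscillations and rejects trends and offsets", {
  t <- seq_len(32)
  expect_true(is_imf(sin(2 * pi * t / 32)))
  expect_false(is_imf(t / 32))                # monotone ramp
  expect_false(is_imf(sin(2 * pi * t / 8) + 10))  # envelope mean far from 0
})

test_that("sifting separates a fast oscillation from a slow trend", {
  t <- seq_len(64)
  fast <- sin(2 * pi * t / 8)
  trend <- 0.05 * t
  s <- sift(fast + trend)
  expect_gt(length(s$imfs), 0L)
  expect_gt(cor(s$imfs[[1]], fast), 0.9)
  # monotone signal: no IMFs, residual is the input
  s0 <- sift(as.numeric(1:16))
  expect_length(s0$imfs, 0L)
  expect_identical(s0$residual, as.numeric(1:16))
  # too-short signal
  s1 <- sift(c(1, 5, 2))
  expect_length(s1$imfs, 0L)
})

test_that("decomposition is complete, valid and deterministic", {
  set.seed(208)
  for (i in 1:40) {
    n <- sample(6:64, 1)
    x <- as.numeric(arima.sim(list(ar = 0.5), n)) +
      sin(2 * pi * seq_len(n) / max(4, n / 4))
    s <- sift(x)
    recon <- Reduce(`+`, s$imfs, numeric(n)) + s$residual
    expect_lt(max(abs(recon - x)), 1e-9 * diff(range(x)))
    for (imf in s$imfs) {
      ex <- find_extrema(imf)
      n_ext <- length(ex$maxima) + length(ex$minima)
      zc <- sum(with(rle(sign(imf)[sign(imf) != 0]), length(values)) - 1)
      expect_lte(abs(n_ext - zc), 1L)
    }
    s2 <- sift(x)
    expect_identical(s, s2)
  }
})

test_that("IMF statistics match direct formula evaluation", {
  st <- imf_stats(c(1, 2, 3))
  expect_identical(st$mean, 2)
  expect_identical(st$variance, 1)
  expect_identical(st$energy, 14)
  expect_identical(st$autocorr, 1 * 2 + 2 * 3)
  z <- imf_stats(rep(0, 5))
  expect_identical(unlist(unclass(z)), c(mean = 0, variance = 0, energy = 0,
                                         autocorr = 0))
  cst <- imf_stats(rep(1.5, 8))
  expect_identical(cst$variance, 0)
  expect_identical(cst$energy, 8 * 1.5^2)
  # brute-force oracle on random sequences, several lags
  set.seed(11)
  for (i in 1:25) {
    n <- sample(2:40, 1)
    x <- rnorm(n)
    m <- sample(0:(n - 1), 1)
    st <- imf_stats(x, m = m)
    expect_equal(st$mean, sum(x) / n, tolerance = 1e-12)
    expect_equal(st$variance, sum((x - sum(x) / n)^2) / (n - 1),
                 tolerance = 1e-12)
    expect_equal(st$energy, sum(x * x), tolerance = 1e-12)
    ac <- 0
    for (j in seq_len(n - m)) ac <- ac + x[j] * x[j + m]
    expect_equal(st$autocorr, ac, tolerance = 1e-12)
  }
  expect_error(imf_stats(1), "length")
  expect_error(imf_stats(c(1, 2), m = 2), "lag")
})

test_that("EMD block has 43 slots with zero-fill for absent IMFs", {
  rec <- make_record(7)
  block <- extract_emd_block(rec)
  expect_length(block, 43L)
  expect_identical(names(block), emd_feature_names())
  # constant signals produce no IMFs anywhere -> all zeros
  expect_identical(unname(extract_emd_block(make_record(1, constant = TRUE))),
                   rep(0, 43))
  # monotone dASA signal -> all dASA slots zero, others untouched
  mono <- extract_emd_block(make_record(7, monotone_dasa = TRUE))
  dasa_slots <- grepl("_dASA_", names(mono))
  expect_identical(unname(mono[dasa_slots]), rep(0, sum(dasa_slots)))
  expect_false(all(mono[!dasa_slots] == 0))
})

test_that("decomposition agrees with an independent reference", {
  set.seed(42)
  sigs <- lapply(1:20, function(i)
    as.numeric(arima.sim(list(ar = 0.6), 64)) + sin(2 * pi * (1:64) / 8))
  ref <- run_py_oracle("emd_reference.py", list(signals = sigs, max_imfs = 3))
  mine <- lapply(sigs, sift)
  n_mine <- vapply(mine, function(s) length(s$imfs), integer(1))
  n_ref <- unlist(ref$n_imfs)
  expect_true(all(abs(n_mine - n_ref) <= 1))
  cors <- mapply(function(m, r) {
    if (length(m$imfs) == 0 || length(r) == 0) return(NA_real_)
    cor(m$imfs[[1]], unlist(r))
  }, mine, ref$first_imf)
  expect_true(all(cors[!is.na(cors)] >= 0.9))
})
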