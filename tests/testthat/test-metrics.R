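test_that("metrics hit their closed-form values on degenerate slices", {
  const <- matrix(0.7, 16, 16)
  expect_equal(intensity_variance(const), 0)
  expect_equal(gradient_magnitude_variance(const), 0)
  expect_equal(laplacian_variance(const), 0)
  expect_equal(histogram_threshold(const), 0)   # strict > T excludes T itself
  expect_equal(histogram_entropy(const), 0)     # single bin, f/Hmax = 1
  expect_equal(frequency_threshold(const, 1), 0)  # all energy at DC
  expect_true(is.na(periodogram_kurtosis(const)))  # delta periodogram

  zeros <- matrix(0, 8, 8)
  expect_equal(histogram_threshold(zeros), 0)

  # half 0 / half 1: variance 1/4
  half <- matrix(c(rep(0, 32), rep(1, 32)), 8)
  expect_equal(intensity_variance(half), 0.25)

  # linear ramp: constant gradient, zero Laplacian in the interior
  ramp <- matrix(rep(seq(0, 1, length.out = 20), each = 20), 20)
  interior <- matrix(FALSE, 20, 20)
  interior[3:18, 3:18] <- TRUE
  expect_equal(gradient_magnitude_variance(ramp, interior), 0, tolerance = 1e-28)
  expect_equal(laplacian_variance(ramp, interior), 0, tolerance = 1e-28)

  # empty mask propagates NA
  none <- matrix(FALSE, 8, 8)
  expect_true(is.na(intensity_variance(half, none)))
  expect_true(is.na(histogram_entropy(half, none)))
})

test_that("histogram metrics match hand evaluations", {
  # pixels {0, 0.2, 0.8, 1.0}: T = 0.5, so 0.8 + 1.0 survive
  sl <- matrix(c(0, 0.2, 0.8, 1.0), 2)
  expect_equal(histogram_threshold(sl), 1.8, tolerance = 5e-3)

  # two occupied bins with counts (Hmax, Hmax/2): entropy = 0.5
  sl3 <- matrix(c(rep(0.125, 8), rep(0.875, 4)), 3)
  expect_equal(histogram_entropy(sl3, bins = 4L), 0.5)

  # frequency threshold with r = 0 sums everything including DC
  set.seed(5)
  sl <- rand_slice(8)
  expect_equal(frequency_threshold(sl, 0), sum(Mod(stats::fft(sl))))
})

test_that("every metric matches its naive-loop oracle on random slices", {
  set.seed(31)
  for (i in 1:6) {
    M <- sample(c(9, 12, 16), 1)
    sl <- rand_slice(M)
    mask <- internal_circle_mask(c(M, M), c((M - 1) / 2, (M - 1) / 2), r = M / 2.5)
    expect_equal(intensity_variance(sl, mask), naive_pop_var(sl[mask]),
                 tolerance = 1e-12)
    expect_equal(gradient_magnitude_variance(sl, mask),
                 naive_pop_var(naive_gradient_mag(sl)[mask]), tolerance = 1e-10)
    expect_equal(laplacian_variance(sl, mask),
                 naive_pop_var(naive_laplacian(sl)[mask]), tolerance = 1e-10)
    expect_equal(histogram_threshold(sl, mask),
                 naive_histogram_threshold(sl[mask]), tolerance = 1e-12)
    expect_equal(histogram_entropy(sl, mask),
                 naive_histogram_entropy(sl[mask]), tolerance = 1e-12)
    r <- M / 4
    expect_equal(frequency_threshold(sl, r), naive_frequency_threshold(sl, r),
                 tolerance = 1e-8)
    expect_equal(periodogram_kurtosis(sl), naive_periodogram_kurtosis(sl),
                 tolerance = 1e-8)
  }
})

test_that("periodogram satisfies Parseval under the unnormalized DFT", {
  set.seed(32)
  for (i in 1:5) {
    sl <- rand_slice(sample(8:24, 1), sample(8:24, 1))
    A <- Mod(stats::fft(sl))^2
    expect_equal(sum(A), length(sl) * sum(sl^2), tolerance = 1e-6)
  }
})

test_that("kurtosis reduces to the separable form when rho12 = 0 and flags blur", {
  # symmetric separable slice: rho12 = 0 by symmetry
  g <- outer(dnorm(seq(-3, 3, length.out = 17)), dnorm(seq(-3, 3, length.out = 17)))
  k <- periodogram_kurtosis(g)
  ref <- naive_periodogram_kurtosis(g)
  expect_equal(k, ref, tolerance = 1e-8)

  # defocus concentrates the periodogram: heavy blur scores far above light
  ph <- small_phantom(q = 0.9, seed = 3)
  sl <- normalize_stack(ph$stack)$slices[[8]]
  expect_gt(periodogram_kurtosis(blur_gaussian(sl, 3)),
            periodogram_kurtosis(blur_gaussian(sl, 1)))
})

test_that("masked derivative metrics use full-slice derivatives", {
  set.seed(33)
  sl <- rand_slice(16)
  mask <- matrix(FALSE, 16, 16)
  mask[5:12, 5:12] <- TRUE
  g_full <- gradient_field(sl)$magnitude
  expect_equal(gradient_magnitude_variance(sl, mask), naive_pop_var(g_full[mask]),
               tolerance = 1e-12)
  # cropping first would give a different (edge-contaminated) answer
  cropped <- gradient_field(sl[5:12, 5:12])$magnitude
  expect_false(isTRUE(all.equal(naive_pop_var(cropped),
                                naive_pop_var(g_full[mask]))))
})

test_that("metric over the internal circle equals whole-image metric when the
           circle covers the whole foreground", {
  sl <- matrix(0.05, 64, 64)
  i <- row(sl) - 1; j <- col(sl) - 1
  blob <- (j - 30)^2 + (i - 33)^2 < 10^2
  sl[blob] <- 0.9
  fg <- otsu_mask(sl)
  circ <- internal_circle_mask(dim(sl), centroid(sl, fg), r = 25)
  expect_true(all(fg[!circ] == FALSE))          # circle covers the foreground
  expect_equal(intensity_variance(sl, fg & circ), intensity_variance(sl, fg))
})

test_that("evaluate_stack respects masking modes and is deterministic", {
  st <- zstack(replicate(10, matrix(0.5, 16, 16), simplify = FALSE))
  pl <- evaluate_stack(st, "intensity_variance", masking = "none",
                       normalize = FALSE)
  expect_equal(pl$value, rep(0, 10))
  expect_equal(nrow(pl), 10)

  ph <- small_phantom(q = 0.7, seed = 9)
  a <- evaluate_stack(ph$stack, "gradient_variance", masking = "otsu")
  b <- evaluate_stack(ph$stack, "gradient_variance", masking = "otsu")
  expect_identical(a, b)
  expect_equal(nrow(a), length(ph$stack))
  expect_true(all(is.finite(a$value[2:(nrow(a) - 1)])))

  expect_warning(evaluate_stack(ph$stack, "kurtosis", masking = "otsu"),
                 "whole slice")
  expect_error(evaluate_stack(ph$stack, "no_such_metric"), "arg")

  # masking-mode aliases from run configurations
  al <- evaluate_stack(st, "intensity_variance", masking = "unmasked",
                       normalize = FALSE)
  expect_equal(al$masking, rep("none", 10))
})

test_that("blur strictly degrades sharpness metrics in the expected direction", {
  ph <- small_phantom(q = 0.8, seed = 14)
  sl <- normalize_stack(ph$stack)$slices[[6]]
  sigmas <- c(0, 1, 2, 4)
  vals <- sapply(sigmas, function(s) {
    b <- blur_gaussian(sl, s)
    c(iv = intensity_variance(b),
      gv = gradient_magnitude_variance(b),
      lv = laplacian_variance(b),
      ft = frequency_threshold(b),
      ku = periodogram_kurtosis(b))
  })
  for (m in c("iv", "gv", "lv", "ft")) {
    expect_true(all(diff(vals[m, ]) < 0), info = m)
  }
  # kurtosis separates heavy from light defocus; near the sharp end the
  # flat read-noise spectrum adds a heavy tail that breaks strict ordering
  expect_gt(vals["ku", 4], vals["ku", 2])

  # on a pure-noise image (flat spectrum) the rise is monotone from zero
  set.seed(15)
  nz <- matrix(runif(64 * 64), 64)
  kn <- sapply(c(0, 1, 2, 4), function(s) periodogram_kurtosis(blur_gaussian(nz, s)))
  expect_true(all(diff(kn) > 0))
})
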