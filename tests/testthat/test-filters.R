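# Digital filter design and zero-phase application.

test_that("Butterworth band-pass design matches the reference coefficients", {
  # frozen from scipy.signal.butter(5, c(2, 60), btype = "band", fs = 160)
  ref_b <- c(0.23339124338688366, 0, -1.1669562169344183, 0,
             2.3339124338688366, 0, -2.3339124338688366, 0,
             1.1669562169344183, 0, -0.23339124338688366)
  ref_a <- c(1, -2.2942853351604473, 0.15964600609286955, 2.030856902298469,
             0.6708164849222398, -1.9244256989960542, -0.46342018048554734,
             0.7315400869924459, 0.2690533017946407, -0.1253094224925312,
             -0.05444785477588919)
  bp <- butter_bandpass(5, 2, 60, 160)
  expect_equal(bp$b, ref_b, tolerance = 1e-12)
  expect_equal(bp$a, ref_a, tolerance = 1e-12)

  # frozen from scipy.signal.iirnotch(60, 30, fs = 160)
  nt <- iir_notch(60, 30, 160)
  expect_equal(nt$b, c(0.9621952458291035, 1.3607495663024323,
                       0.9621952458291035), tolerance = 1e-12)
  expect_equal(nt$a, c(1, 1.3607495663024323, 0.9243904916582071),
               tolerance = 1e-12)
})

test_that("analytic frequency responses have the designed shape", {
  nt <- iir_notch(60, 30, 160)
  bp <- butter_bandpass(5, 2, 60, 160)
  expect_lt(abs(filter_response(nt$b, nt$a, 60, 160)), 1e-12)   # exact null
  expect_equal(abs(filter_response(nt$b, nt$a, 30, 160)), 1,
               tolerance = 1e-2)                                 # unit passband
  expect_equal(abs(filter_response(bp$b, bp$a, 30, 160)), 1,
               tolerance = 1e-6)
  expect_lt(abs(filter_response(bp$b, bp$a, 0, 160)), 1e-10)     # DC blocked
})

test_that("a 60 Hz tone is suppressed and a 30 Hz tone preserved", {
  fs <- 160
  t <- seq_len(4 * fs) / fs
  core <- seq(fs + 1, length(t) - fs)  # steady state, away from edge transients
  spec <- filter_spec()                # notch 60 + band-pass 2-60 order 5

  x60 <- matrix(sin(2 * pi * 60 * t), 1)
  y60 <- apply_filters(x60, spec, fs = fs)
  expect_lt(sqrt(mean(y60[core]^2)) / sqrt(mean(x60[core]^2)), 0.05)

  x30 <- matrix(sin(2 * pi * 30 * t), 1)
  y30 <- apply_filters(x30, spec, fs = fs)
  expect_equal(sqrt(mean(y30[core]^2)) / sqrt(mean(x30[core]^2)), 1,
               tolerance = 0.05)

  xdc <- matrix(1, 1, length(t))
  ydc <- apply_filters(xdc, spec, fs = fs)
  expect_lt(max(abs(ydc)), 1e-10)
})

test_that("filtering is linear and shape-preserving", {
  withr::with_seed(4, {
    x <- matrix(rnorm(2 * 800), 2)
    y <- matrix(rnorm(2 * 800), 2)
  })
  spec <- filter_spec()
  fx <- apply_filters(x, spec, fs = 160)
  fy <- apply_filters(y, spec, fs = 160)
  fboth <- apply_filters(3 * x - 0.5 * y, spec, fs = 160)
  expect_equal(fboth, 3 * fx - 0.5 * fy, tolerance = 1e-8)
  expect_identical(dim(fx), dim(x))
})

test_that("Nyquist violations are rejected", {
  expect_error(apply_filters(matrix(0, 1, 500), filter_spec(), fs = 100),
               "Nyquist")
  expect_error(filter_spec(bandpass_low_hz = 10, bandpass_high_hz = 5))
  expect_error(butter_bandpass(5, 2, 90, 160), "Nyquist")
})
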