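test_that("FIR band-pass attenuates 60 Hz by 40 dB and passes 10 Hz", {
  fs <- 2048
  t <- seq_len(12 * fs) / fs
  mk <- function(f) {
    rec <- list(data = matrix(sin(2 * pi * f * t), nrow = 1),
                sampling_rate = fs)
    out <- preprocess_raw(rec, target_rate_hz = 512, reference = "none")
    # evaluate away from the edges (edge effects span one filter length)
    n <- ncol(out$data)
    keep <- floor(n * 0.35):ceiling(n * 0.65)
    sqrt(mean(out$data[1, keep]^2))
  }
  rms_in <- sqrt(0.5)
  expect_lt(20 * log10(mk(60) / rms_in), -40)
  expect_lt(abs(mk(10) / rms_in - 1), 0.05)
})

test_that("downsampling preserves duration: 12 s at 2048 Hz -> 6144 samples", {
  fs <- 2048
  rec <- list(data = matrix(rnorm(2 * 12 * fs), nrow = 2),
              sampling_rate = fs)
  out <- preprocess_raw(rec, target_rate_hz = 512, reference = "none")
  expect_equal(ncol(out$data), 12L * 512L)
  expect_equal(out$sampling_rate, 512)
})

test_that("filter cutoffs at or above Nyquist are rejected", {
  rec <- list(data = matrix(rnorm(512), nrow = 1), sampling_rate = 64)
  expect_error(preprocess_raw(rec, lowpass_hz = 45, target_rate_hz = 64,
                              reference = "none"), "Nyquist")
  rec2 <- list(data = matrix(rnorm(4096), nrow = 1), sampling_rate = 1024)
  expect_error(preprocess_raw(rec2, target_rate_hz = 100,
                              reference = "none"), "divide|divides")
})

test_that("filtering and downsampling commute with epoch extraction", {
  fs <- 1024
  set.seed(5)
  x <- matrix(rnorm(2 * 8 * fs), nrow = 2)
  rec <- list(data = x, sampling_rate = fs)
  out <- preprocess_raw(rec, target_rate_hz = 256, reference = "none")
  # extracting an interior window after processing equals processing the
  # whole record and cutting the same window (same pipeline, so this
  # checks the epoch indexing arithmetic, up to nothing at all inside)
  ep <- extract_epochs(out$data, onsets = c(257, 513), n_samples = 256)
  expect_equal(ep[1, , ], out$data[, 257:512], tolerance = 1e-12)
  expect_equal(ep[2, , ], out$data[, 513:768], tolerance = 1e-12)
  expect_error(extract_epochs(out$data, onsets = 10^6, n_samples = 256),
               "beyond")
})

test_that("a planted bad channel is flagged and interpolated, others untouched", {
  rec <- make_tiny_recording(seed = 2, noise_sd = 1)
  bad <- 5L
  set.seed(20)
  # noise at 100x the typical channel amplitude
  amp <- 100 * mean(apply(rec$epochs[, -bad, ], 2, sd))
  rec$epochs[, bad, ] <- amp * rnorm(length(rec$epochs[, bad, ]))
  orig <- rec$epochs
  out <- clean_epochs(rec)
  rep <- out$cleaning_report
  expect_equal(rep$channels_interpolated, bad)
  expect_equal(rep$n_channels_interpolated, 1L)
  expect_equal(rep$n_epochs_removed, 0L)
  # the interpolated channel changed; every other channel is bit-identical
  expect_false(isTRUE(all.equal(out$epochs[, bad, ], orig[, bad, ])))
  expect_identical(out$epochs[, -bad, ], orig[, -bad, ])
  # interpolation pulled the channel back to the scale of its neighbours
  expect_lt(sd(out$epochs[, bad, ]), 3 * max(apply(orig[, -bad, ], 2, sd)))
})

test_that("clean synthetic data passes the default thresholds untouched", {
  rec <- make_tiny_recording(seed = 3)
  out <- clean_epochs(rec)
  expect_equal(out$cleaning_report$n_channels_interpolated, 0L)
  expect_equal(out$cleaning_report$n_epochs_removed, 0L)
  expect_equal(out$cleaning_report$fraction_epochs_removed, 0)
  expect_identical(out$epochs, rec$epochs)
})

test_that("artifact epochs are removed and total rejection aborts", {
  rec <- make_tiny_recording(seed = 4)
  set.seed(21)
  rec$epochs[3, , ] <- rec$epochs[3, , ] +
    100 * matrix(rnorm(length(rec$epochs[3, , ])), dim(rec$epochs)[2])
  out <- clean_epochs(rec)
  expect_true(3L %in% out$cleaning_report$epochs_removed)
  expect_equal(dim(out$epochs)[1], 11L)
  expect_equal(out$epoch_stimulus, setdiff(1:12, out$cleaning_report$epochs_removed))

  rec2 <- make_tiny_recording(seed = 5)
  rec2$epochs <- rec2$epochs * 1e6  # everything over the ptp limit
  expect_error(clean_epochs(rec2), "all .* epochs rejected")
})

test_that("interpolation reproduces a clean channel on smooth fields", {
  # spatially smooth multi-dipole field: leave one channel out, rebuild it
  hm <- make_head_model(32)
  set.seed(6)
  topos <- sapply(1:3, function(i) lead_field(hm, runif(3, -40, 40),
                                              rnorm(3)))
  x <- topos %*% matrix(rnorm(3 * 400), 3)
  for (ch in c(1L, 7L, 25L)) {
    w <- icaffect:::interp_weights(hm$positions, ch)
    rebuilt <- as.numeric(w %*% x[-ch, ])
    expect_gt(cor(rebuilt, x[ch, ]), 0.9)
  }
})

test_that("ICA preparation reduces to rank and centers the reference", {
  rec <- make_tiny_recording(n_channels = 16, seed = 7)
  rec$interpolated <- rep(FALSE, 16)
  prep <- prepare_for_ica(rec)
  expect_equal(prep$rank, 15L)
  # rank oracle: singular values of the referenced data
  sv <- svd(prep$data)$d
  expect_equal(sum(sv > 1e-8 * sv[1]), 15L)
  # average-reference identity
  rms <- sqrt(mean(prep$data^2))
  expect_lt(max(abs(colMeans(prep$data))), 1e-10 * rms)

  rec$interpolated[c(2, 9)] <- TRUE
  prep2 <- prepare_for_ica(rec)
  expect_equal(prep2$rank, 13L)
  sv2 <- svd(prep2$data)$d
  expect_equal(sum(sv2 > 1e-8 * sv2[1]), 13L)
})

test_that("ICA preparation aborts when fewer than 4 dimensions remain", {
  rec <- make_tiny_recording(n_channels = 6, n_epochs = 4, seed = 8)
  rec$interpolated <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  expect_error(prepare_for_ica(rec), "rank")
})
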