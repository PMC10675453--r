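test_that("band-pass filter removes DC and validates its inputs", {
  # DC lies outside the 0.5-10 Hz pass band: after the forward-backward
  # edge transients settle, the output is zero to numerical precision
  x <- rep(5, 30000)
  y <- bandpass_filter(x, 500)
  expect_lt(abs(mean(y[10000:20000])), 1e-6 * 5)
  expect_error(bandpass_filter(c(1, NA, 3, rep(1, 100)), 500), "missing")
  expect_error(bandpass_filter(rnorm(100), 500,
                               filter_config(high_cut = 300)),
               "Nyquist")
  expect_error(filter_config(low_cut = 20, high_cut = 10), "low_cut")
})

test_that("filter is linear and zero-phase on a pass-band tone", {
  t <- seq(0, 10, by = 1 / 500)
  x <- sin(2 * pi * 2 * t)
  y <- bandpass_filter(x, 500)
  y3 <- bandpass_filter(3 * x, 500)
  expect_equal(y3, 3 * y, tolerance = 1e-9)
  # zero-phase: cross-correlation with the input peaks at lag 0
  core <- 1000:4000
  cc <- stats::ccf(y[core], x[core], lag.max = 20, plot = FALSE)
  expect_equal(as.numeric(cc$lag)[which.max(cc$acf)], 0)
})

test_that("middle-window extraction re-bases CO readings", {
  rec <- generate_case(sim_config(duration_s = 120, seed = 6))
  w <- extract_middle_window(rec, 60)
  expect_length(w$ppg, 30000)
  # samples [30 s, 90 s): the sub-record starts 15000 samples in
  expect_identical(w$ppg, rec$ppg[15001:45000])
  expect_true(all(w$co_sample_indices >= 1 &
                    w$co_sample_indices <= 30000))
  expect_identical(w$co_sample_indices,
                   as.integer(rec$co_sample_indices[
                     rec$co_sample_indices > 15000 &
                       rec$co_sample_indices <= 45000] - 15000L))
  # 60 s record: identity
  rec60 <- make_case(seed = 6)
  w60 <- extract_middle_window(rec60, 60)
  expect_identical(w60$ppg, rec60$ppg)
  expect_identical(w60$co_sample_indices, rec60$co_sample_indices)
})

test_that("short records are skipped with a classed warning", {
  rec <- generate_case(sim_config(duration_s = 30, seed = 2))
  expect_warning(out <- extract_middle_window(rec, 60),
                 class = "counet_short_record")
  expect_null(out)
})

test_that("records with missing samples in the window are flagged", {
  rec <- make_case(seed = 3)
  rec$ppg[15000] <- NA
  w <- extract_middle_window(rec, 60)
  expect_true(attr(w, "has_missing"))
})

test_that("segmentation keeps exactly the readings with full context", {
  rec <- make_case(seed = 1)
  segs <- segment_record(rec)
  # centers at samples 1000k; k = 1 lacks 1024 preceding samples and
  # k = 29, 30 lack trailing context, leaving 27 of 30
  expect_length(segs, 27)
  expect_identical(attr(segs, "boundary_dropped"), 3L)
  expect_identical(attr(segs, "n_candidates"), 30L)
  expect_identical(vapply(segs, function(s) s$center_index, integer(1)),
                   as.integer(seq(2000, 28000, by = 1000)))
  for (s in segs[c(1, 27)]) {
    expect_length(s$ppg_raw, 2048)
    expect_length(s$art_in, 2048)
  }
  # raw window content is the unfiltered waveform around the anchor
  expect_identical(segs[[1]]$ppg_raw, rec$ppg[976:3023])
})

test_that("boundary candidates are dropped and kept per the window rule", {
  rec <- make_case(seed = 5)
  rec$co_sample_indices <- c(1000L, 1025L)   # 1-based anchors
  rec$co_values <- c(5, 5)
  rec$true_co <- c(5, 5)
  segs <- segment_record(rec)
  expect_length(segs, 1)                     # anchor 1000 lacks context
  expect_identical(segs[[1]]$center_index, 1025L)
  expect_identical(segs[[1]]$ppg_raw, rec$ppg[1:2048])
  expect_identical(attr(segs, "boundary_dropped"), 1L)
})

test_that("per-segment normalization maps channels onto [0, 1]", {
  seg <- segment_record(make_case(seed = 2))[[4]]
  ns <- normalize_segment(seg)
  for (ch in c("ppg_in", "art_in")) {
    expect_equal(min(ns[[ch]]), 0)
    expect_equal(max(ns[[ch]]), 1)
  }
  # affine check: a channel spanning [30, 130] maps 80 to 0.5
  seg$ppg_in <- c(30, 80, 130, rep(30, 2045))
  expect_equal(normalize_segment(seg)$ppg_in[2], 0.5)
  # degenerate channel is an error naming the channel
  seg$art_in <- rep(1, 2048)
  expect_error(normalize_segment(seg), "art_in")
})

test_that("label scaling is the fixed affine map on [2, 10] L/min", {
  expect_equal(scale_co_label(6), 0.5)
  expect_equal(scale_co_label(2), 0)
  expect_equal(scale_co_label(10), 1)
  expect_equal(unscale_co_label(0.5), 6)
  expect_equal(unscale_co_label(0), 2)
  expect_equal(unscale_co_label(0.37625), 5.01)
  co <- seq(2, 10, length.out = 101)
  expect_equal(unscale_co_label(scale_co_label(co)), co, tolerance = 1e-9)
})
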