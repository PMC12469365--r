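test_that("background subtraction removes offsets and ramps, keeps peaks", {
  # constant profile -> all zero
  flat <- lane_profile(1:200, rep(10, 200))
  expect_true(all(subtract_background(flat, window = 51)$intensity == 0))

  # single Gaussian on a constant offset: offset removed, area kept (<1%)
  prof <- gauss_profile(centers = 400, areas = 5000, sigma = 6, offset = 80)
  sub <- subtract_background(prof)
  truth <- 5000
  got <- trapezoid_area(sub$position, sub$intensity)
  expect_lt(abs(got - truth) / truth, 0.01)

  # ramp + two Gaussians: residual baseline below 2% of peak height
  prof <- gauss_profile(centers = c(400, 700), areas = c(6000, 3000),
                        sigma = 6, offset = 50, slope = 0.2)
  sub <- subtract_background(prof)
  peak_height <- max(sub$intensity)
  band_free <- sub$position < 300 | (sub$position > 500 & sub$position < 600) |
    sub$position > 800
  expect_lt(max(sub$intensity[band_free]), 0.02 * peak_height)

  expect_error(subtract_background(flat, window = 2), "window")
  expect_error(subtract_background(flat, window = 500), "window")
})

test_that("band detection and integration recover known mixtures", {
  # clean 61:39 pair (the constitutive-skipping scenario)
  prof <- gauss_profile(centers = c(400, 500), areas = c(61, 39) * 100,
                        sigma = 6)
  bands <- detect_bands(subtract_background(prof))
  expect_equal(nrow(bands), 2L)
  expect_equal(bands$fraction, c(61, 39), tolerance = 2 / 61)
  expect_equal(sum(bands$fraction), 100, tolerance = 0.005)

  # single band -> 100%
  one <- detect_bands(subtract_background(
    gauss_profile(400, 4000, sigma = 6)))
  expect_equal(nrow(one), 1L)
  expect_equal(one$fraction, 100)

  # three bands 50/30/20
  prof3 <- gauss_profile(centers = c(350, 500, 650),
                         areas = c(50, 30, 20) * 100, sigma = 6)
  b3 <- detect_bands(subtract_background(prof3))
  expect_equal(b3$fraction, c(50, 30, 20), tolerance = 2 / 50)

  # no band at all is an empty table, not an error
  expect_equal(nrow(detect_bands(subtract_background(
    lane_profile(1:200, rep(3, 200)), window = 51))), 0L)
})

test_that("quantification is invariant to global intensity scaling", {
  prof <- gauss_profile(centers = c(400, 520), areas = c(7000, 3000),
                        sigma = 6, offset = 40, noise_sd = 10, seed = 5)
  f1 <- detect_bands(subtract_background(prof))$fraction
  scaled <- lane_profile(prof$position, prof$intensity * 7.3)
  f2 <- detect_bands(subtract_background(scaled))$fraction
  expect_equal(f1, f2, tolerance = 0.1 / max(f1))
})

test_that("integrated areas agree with brute-force trapezoids over true supports", {
  centers <- c(380, 520, 700)
  areas <- c(5000, 2600, 1700)
  prof <- gauss_profile(centers = centers, areas = areas, sigma = 6)
  sub <- subtract_background(prof)
  bands <- detect_bands(sub)
  expect_equal(nrow(bands), 3L)
  for (i in seq_along(centers)) {
    idx <- which(sub$position >= centers[i] - 30 &
                   sub$position <= centers[i] + 30)
    brute <- trapezoid_area(sub$position[idx], sub$intensity[idx])
    expect_lt(abs(bands$area[i] - brute) / brute, 0.01)
  }
})

test_that("ladder calibration interpolates sizes on the semi-log fit", {
  ladder <- sim_ladder(1200)
  # a band exactly on a rung recovers that rung's size within 1%
  bands <- tibble::tibble(center = ladder$position[4], left = 0, right = 0,
                          area = 1, fraction = 100)
  cal <- calibrate_sizes(bands, ladder)
  expect_equal(cal$size_bp, ladder$size_bp[4], tolerance = 0.01)
  expect_gt(attr(cal, "calibration")$r_squared, 0.99)

  # synthetic lane from known sizes: recovered within 5%
  sizes <- c(913, 831, 698)
  prof <- gauss_profile(centers = sapply(sizes, function(s)
    stats::approx(log10(ladder$size_bp), ladder$position, log10(s))$y),
    areas = c(5000, 3000, 2000), sigma = 6)
  bands <- detect_bands(subtract_background(prof))
  cal <- calibrate_sizes(bands, ladder)
  expect_equal(sort(cal$size_bp, decreasing = TRUE), sizes, tolerance = 0.05)

  expect_error(calibrate_sizes(bands, ladder[1:2, ]), "3 rungs")
  bad <- ladder
  bad$size_bp[2] <- 3000
  expect_error(calibrate_sizes(bands, bad), "decrease")
})

test_that("fragment sizes follow flanks plus retained exonic content", {
  m <- rpe65_model(with_sequences = FALSE)
  wt3 <- m$constructs[["WT-3"]]
  wt_size <- predict_fragment_size(wt3, splice_events(), m)
  expect_equal(wt_size, 150L + 130L + (1128L - 496L + 1L))
  expect_equal(predict_fragment_size(wt3, exon_skip(7), m), wt_size - 82L)
  wt4 <- m$constructs[["WT-4"]]
  wt4_size <- predict_fragment_size(wt4, splice_events(), m)
  expect_equal(
    predict_fragment_size(wt4, pseudoexon("1129-293", "1129-218"), m),
    wt4_size + 76L)
  expect_error(predict_fragment_size(wt4, exon_skip(7), m), "outside")
})

test_that("bands match to the nearest candidate within tolerance", {
  m <- rpe65_model(with_sequences = FALSE)
  wt3 <- m$constructs[["WT-3"]]
  cand <- candidate_transcripts(wt3, m)
  wt_size <- cand$size_bp[cand$label == "WT"]
  bands <- tibble::tibble(center = c(1, 2, 3), left = 0, right = 0,
                          area = c(5, 3, 1), fraction = c(50, 40, 10),
                          size_bp = c(wt_size, wt_size - 82, wt_size - 500))
  got <- match_transcripts(bands, cand, tolerance_bp = 30)
  expect_equal(got$identity, c("WT", "skip_7", "unidentified"))
})
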