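test_that("ellipse orientation is recovered within a degree", {
  for (a in c(0, 30, 60)) {
    f <- gen_eye_frames(c(a, if (a == 0) 45 else -a))
    o <- eye_orientation(f)
    expect_lt(abs(o["left", "angle_deg"] - a), 1)
    expect_false(o["left", "undefined"])
  }
})

test_that("orientation is rotation-equivariant modulo 180 degrees", {
  base <- 10
  for (phi in c(15, 40, 75)) {
    o1 <- eye_orientation(gen_eye_frames(c(base, 0)))["left", "angle_deg"]
    o2 <- eye_orientation(gen_eye_frames(c(base + phi, 0)))["left", "angle_deg"]
    d <- (o2 - o1 - phi) %% 180
    expect_lt(min(d, 180 - d), 1)
  }
})

test_that("small specks do not disturb the two-largest-component selection", {
  clean <- eye_orientation(gen_eye_frames(c(20, -35)))
  noisy <- eye_orientation(gen_eye_frames(c(20, -35), noise_frac = 0.003,
                                          seed = 4))
  expect_equal(noisy$angle_deg, clean$angle_deg)
  expect_equal(noisy$cx, clean$cx)
})

test_that("degenerate frames are flagged", {
  expect_error(eye_orientation(matrix(0, 50, 50)), "tracking failure")
  one <- matrix(0, 50, 50); one[20:30, 20:30] <- 1
  expect_error(eye_orientation(one), "tracking failure")
  circles <- gen_eye_frames(c(0, 0), axes = c(15, 15))
  expect_true(all(eye_orientation(circles)$undefined))
})

test_that("slow phases avoid saccades and stimulus reversals", {
  tr <- gen_eye_trace(noise_sd = 0, saccade_rate = 0.3, seed = 21)
  sp <- segment_slow_phases(tr, "left")
  sac <- attr(tr, "saccade_idx")
  in_phase <- unlist(mapply(seq, sp$start, sp$end, SIMPLIFY = FALSE))
  expect_length(intersect(sac, in_phase), 0)
  # never spans a reversal
  rate <- attr(tr, "sample_rate")
  rev_idx <- round(attr(tr, "reversal_times") * rate) + 1
  expect_length(intersect(rev_idx, in_phase), 0)
})

test_that("clean traces are covered by slow phases up to guard windows", {
  tr <- gen_eye_trace(noise_sd = 0, saccade_rate = 0, seed = 2)
  sp <- segment_slow_phases(tr, "left")
  covered <- sum(sp$end - sp$start + 1)
  expect_gt(covered / nrow(tr), 0.9)
  # one slow phase per inter-reversal interval
  expect_equal(nrow(sp), length(attr(tr, "reversal_times")) + 1)
})

test_that("an all-fast threshold yields an empty set with a warning", {
  tr <- gen_eye_trace(noise_sd = 0, saccade_rate = 0, seed = 2)
  expect_warning(sp <- segment_slow_phases(tr, "left",
                                           velocity_threshold = 0),
                 "no slow phases")
  expect_equal(nrow(sp), 0)
  expect_warning(g <- compute_gain(tr, "left", "nasal", slow_phases = sp),
                 "NA")
  expect_true(is.na(g))
})

test_that("perfect tracking yields gain 1 to numerical precision", {
  tr <- gen_eye_trace(gain_nasal = 1, gain_temporal = 1, noise_sd = 0,
                      saccade_rate = 0, seed = 1)
  for (eye in c("left", "right")) {
    for (dir in c("nasal", "temporal")) {
      expect_equal(compute_gain(tr, eye, dir), 1, tolerance = 1e-6)
    }
  }
})

test_that("a stationary eye has gain 0", {
  tr <- gen_eye_trace(gain_nasal = 0, gain_temporal = 0, noise_sd = 0,
                      saccade_rate = 0, seed = 1)
  expect_equal(compute_gain(tr, "left", "nasal"), 0)
  expect_equal(compute_gain(tr, "left", "temporal"), 0)
})

test_that("gains are invariant to a constant angle offset", {
  tr <- gen_eye_trace(noise_sd = 0.3, saccade_rate = 0.2, seed = 31)
  g0 <- compute_gain(tr, "left", "nasal")
  tr$angle_left <- tr$angle_left + 12.5
  expect_equal(compute_gain(tr, "left", "nasal"), g0, tolerance = 1e-9)
})

test_that("reversing the stimulus sign swaps nasal and temporal exactly", {
  tr <- gen_eye_trace(gain_nasal = 0.9, gain_temporal = 0.4, noise_sd = 0,
                      saccade_rate = 0.2, seed = 41)
  flipped <- tr
  flipped$angle_left <- -tr$angle_left
  flipped$angle_right <- -tr$angle_right
  flipped$stim_velocity <- -tr$stim_velocity
  for (attr_name in c("sample_rate", "reversal_times")) {
    attr(flipped, attr_name) <- attr(tr, attr_name)
  }
  expect_equal(compute_gain(flipped, "left", "temporal"),
               compute_gain(tr, "left", "nasal"), tolerance = 1e-9)
  expect_equal(compute_gain(flipped, "left", "nasal"),
               compute_gain(tr, "left", "temporal"), tolerance = 1e-9)
})

test_that("generator gains are recovered from noisy traces", {
  r <- okr_analyze(gen_eye_trace(gain_nasal = 0.8, gain_temporal = 0.5,
                                 noise_sd = 0.5, saccade_rate = 0.2,
                                 seed = 7))
  expect_lt(abs(r$gain_nasal - 0.8), 0.05)
  expect_lt(abs(r$gain_temporal - 0.5), 0.05)
})

test_that("gain recovery is essentially unbiased across replicates", {
  est <- sapply(1:20, function(s) {
    tr <- gen_eye_trace(gain_nasal = 0.8, gain_temporal = 0.5,
                        noise_sd = 0.5, saccade_rate = 0.2, seed = 100 + s)
    r <- okr_analyze(tr)
    c(r$gain_nasal, r$gain_temporal)
  })
  expect_lt(abs(mean(est[1, ]) - 0.8), 0.02)
  expect_lt(abs(mean(est[2, ]) - 0.5), 0.02)
})

test_that("eye range and dominance follow the session extremes", {
  t <- seq(0, 10, by = 0.01)
  tr <- data.frame(t = t, angle_left = 15 * sin(t),
                   angle_right = 10 * sin(t), stim_velocity = 10)
  attr(tr, "sample_rate") <- 100
  r <- eye_range_and_dominance(tr)
  expect_equal(unname(r$eye_range["left"]), 30, tolerance = 1e-3)
  expect_equal(unname(r$eye_range["right"]), 20, tolerance = 1e-3)
  expect_equal(r$strong_eye, "left")
  expect_equal(r$weak_eye, "right")
})

test_that("the strong eye tracks the larger excursion in full analyses", {
  tr <- gen_eye_trace(noise_sd = 0.2, saccade_rate = 0.2, seed = 51)
  tr$angle_right <- tr$angle_right * 0.5 # weaken one eye
  r <- okr_analyze(tr)
  expect_equal(r$strong_eye, "left")
})

test_that("traces round-trip through delimited text", {
  tr <- gen_eye_trace(noise_sd = 0.1, seed = 61)
  path <- tempfile(fileext = ".tsv")
  write_eye_trace(tr, path)
  back <- read_eye_trace(path)
  expect_equal(back$angle_left, tr$angle_left, tolerance = 1e-6)
  expect_equal(attr(back, "sample_rate"), attr(tr, "sample_rate"),
               tolerance = 1e-6)
})
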