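test_that("generators are pure functions of their seed", {
  t1 <- synthetic_truth(seed = 42)
  expect_identical(gen_occupancy_dataset(t1), gen_occupancy_dataset(t1))
  expect_identical(gen_clustered_nucleus(30, seed = 9),
                   gen_clustered_nucleus(30, seed = 9))
  expect_identical(gen_eye_trace(seed = 5, noise_sd = 0.3),
                   gen_eye_trace(seed = 5, noise_sd = 0.3))
  expect_identical(gen_eye_frames(c(10, 40), noise_frac = 0.01, seed = 3),
                   gen_eye_frames(c(10, 40), noise_frac = 0.01, seed = 3))
  s1 <- gen_intensity_stack(seed = 7)
  s2 <- gen_intensity_stack(seed = 7)
  expect_identical(s1$stack, s2$stack)
  # different seeds differ
  expect_false(identical(gen_clustered_nucleus(30, seed = 9),
                         gen_clustered_nucleus(30, seed = 10)))
})

test_that("sub-seeds differ across labels but are reproducible", {
  expect_identical(split_seed(1, "a"), split_seed(1, "a"))
  expect_false(split_seed(1, "a") == split_seed(1, "b"))
  expect_true(split_seed(.Machine$integer.max, "long label") >= 0)
})

test_that("synthetic truth validates its invariants", {
  g <- default_io_grid()
  expect_equal(sum(g), 1, tolerance = 1e-14)
  expect_true(all(g >= 0))
  expect_error(synthetic_truth(occupancy_probs = g * 2), "sum to 1")
  expect_error(synthetic_truth(scatter_factor = 0.5), "scatter_factor")
  bad <- g; bad[1, 1] <- -bad[2, 2]; bad[2, 2] <- 2 * bad[2, 2]
  expect_error(synthetic_truth(occupancy_probs = bad), "non-negative")
})

test_that("a degenerate single-bin grid places every cell in that bin", {
  probs <- matrix(0, 15, 4)
  probs[1, 1] <- 1
  tr <- synthetic_truth(occupancy_probs = probs, n_larvae = 5,
                        cells_per_larva = c(10, 10), seed = 3)
  cells <- gen_occupancy_dataset(tr)
  b <- assign_bins(cells)
  expect_equal(nrow(b), 50)
  expect_true(all(b$z_bin == 0))
  expect_true(all(b$x_bin == 0))
})

test_that("sampled bins are recovered exactly on re-binning", {
  tr <- synthetic_truth(n_larvae = 8, seed = 11)
  cells <- gen_occupancy_dataset(tr, genotype = "wt")
  bt <- attr(cells, "bins_true")
  b <- assign_bins(cells)
  # align on coordinates (binning regroups rows by larva)
  key <- function(df) paste(df$larva_id, df$x_um, df$z_um)
  targ <- cells[cells$marker == "negative", ]
  m <- match(key(targ), key(b))
  expect_false(any(is.na(m)))
  expect_equal(b$z_bin[m], unname(bt[, "z_bin"]))
  expect_equal(b$x_bin[m], unname(bt[, "x_bin"]))
})

test_that("empirical occupancy of a uniform grid matches multinomial sampling", {
  probs <- matrix(1 / 60, 15, 4)
  tr <- synthetic_truth(occupancy_probs = probs, n_larvae = 19,
                        cells_per_larva = c(15, 15), seed = 1)
  grid <- pool_counts(assign_bins(gen_occupancy_dataset(tr)))
  n <- sum(grid)
  freq <- empirical_distribution(grid)
  se <- sqrt((1 / 60) * (1 - 1 / 60) / n)
  expect_true(all(abs(freq - 1 / 60) <= 3.5 * se))
})

test_that("empirical occupancy converges to the generating truth", {
  probs <- default_io_grid()
  kl_emp <- sapply(c(20, 200, 2000), function(cpl) {
    tr <- synthetic_truth(occupancy_probs = probs, n_larvae = 10,
                          cells_per_larva = c(cpl, cpl), seed = 2)
    emp <- empirical_distribution(pool_counts(assign_bins(
      gen_occupancy_dataset(tr))))
    sum(ifelse(emp > 0, emp * log(emp / probs), 0))
  })
  expect_true(all(diff(kl_emp) < 0))
  expect_lt(kl_emp[3], 0.05)
})

test_that("scatter factor dilates clouds monotonically", {
  ctr <- rbind(c(0, 0, 0), c(10, 5, 0))
  p1 <- gen_clustered_nucleus(40, ctr, sd = 3, scatter_factor = 1, seed = 5)
  p3 <- gen_clustered_nucleus(40, ctr, sd = 3, scatter_factor = 3, seed = 5)
  expect_gt(convex_hull_volume(p3), convex_hull_volume(p1))
  d1 <- delaunay_local_density(p1)$density
  d3 <- delaunay_local_density(p3)$density
  expect_lt(median(d3), median(d1))
})

test_that("clustered generator degenerates to its center as sd -> 0", {
  p <- gen_clustered_nucleus(10, rbind(c(3, -2, 7)), sd = 1e-12, seed = 1)
  expect_true(all(abs(sweep(p, 2, c(3, -2, 7))) < 1e-9))
  expect_error(gen_clustered_nucleus(3), "n_cells")
})

test_that("noise-free eye traces track the stimulus at the stated gain", {
  tr <- gen_eye_trace(gain_nasal = 1, gain_temporal = 1, noise_sd = 0,
                      saccade_rate = 0, stim_speed = 10, seed = 1)
  sp <- attr(tr, "slow_phases_true")
  dt <- 1 / attr(tr, "sample_rate")
  for (i in seq_len(nrow(sp))) {
    idx <- (sp[i, "start"] + 1):sp[i, "end"]
    v <- diff(tr$angle_left[c(idx[1] - 1, idx)]) / dt
    expect_equal(v, tr$stim_velocity[idx - 1], tolerance = 1e-9)
  }
  flat <- gen_eye_trace(gain_nasal = 0, gain_temporal = 0, noise_sd = 0,
                        saccade_rate = 0, seed = 1)
  expect_true(all(flat$angle_left == 0) && all(flat$angle_right == 0))
  expect_error(gen_eye_trace(duration = 5, reversal_period = 6),
               "2 stimulus reversals")
})

test_that("rendered frames validate geometry and carry orientation", {
  expect_error(gen_eye_frames(c(0, 0), centers = rbind(c(100, 80), c(120, 80))),
               "overlap")
  expect_error(gen_eye_frames(c(0, 0), centers = rbind(c(10, 80), c(180, 80))),
               "fit inside")
  clean <- gen_eye_frames(c(0, 30), seed = 2)
  noisy <- gen_eye_frames(c(0, 30), noise_frac = 0.002, seed = 2)
  expect_identical(eye_orientation(clean)[, c("eye", "angle_deg")],
                   eye_orientation(noisy)[, c("eye", "angle_deg")])
})

test_that("intensity stacks honour their stated means", {
  syn <- gen_intensity_stack(roi_mean = 2000, bg_mean = 500, noise_sd = 0,
                             seed = 1)
  m <- corrected_mean_intensity(syn$stack, syn$roi_masks, syn$bg_masks)
  expect_equal(m$corrected_mean, 1500)
  syn0 <- gen_intensity_stack(roi_mean = 800, bg_mean = 800, noise_sd = 0)
  m0 <- corrected_mean_intensity(syn0$stack, syn0$roi_masks, syn0$bg_masks)
  expect_equal(m0$corrected_mean, 0)
  syn3 <- gen_intensity_stack(roi_mean = 2000, bg_mean = 500, noise_sd = 50,
                              seed = 3)
  m3 <- corrected_mean_intensity(syn3$stack, syn3$roi_masks, syn3$bg_masks)
  n_roi <- sum(sapply(syn3$roi_masks, function(r) sum(r$mask)))
  se <- 50 / sqrt(n_roi) # dominated by ROI pixels; background adds less
  expect_lt(abs(m3$corrected_mean - 1500), 3 * (se + 50 / sqrt(75)))
})
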