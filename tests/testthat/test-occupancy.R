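ref_cells <- function(larva = "L1") {
  # reference cells spanning z in [0, 30] and |x| up to 12
  data.frame(larva_id = larva, genotype = "wt", side = "right",
             x_um = c(0, 0, 12), y_um = 0, z_um = c(0, 30, 15),
             marker = "positive", label = NA_character_,
             stringsAsFactors = FALSE)
}

with_targets <- function(x, z, larva = "L1") {
  tab <- rbind(ref_cells(larva),
               data.frame(larva_id = larva, genotype = "wt", side = "right",
                          x_um = x, y_um = 0, z_um = z,
                          marker = "negative", label = NA_character_,
                          stringsAsFactors = FALSE))
  validate_cell_table(tab)
}

test_that("bin assignment anchors extremes and uses half-open bins", {
  b <- assign_bins(with_targets(x = c(0.01, 0.01, 0.01, 11.99, 0.01),
                                z = c(0, 30, 15, 10, 29.9)))
  expect_equal(b$z_bin, c(0L, 14L, 7L, 5L, 14L)) # floor(0.5*15) = 7
  expect_equal(b$x_bin, c(0L, 0L, 0L, 3L, 0L))
  # midline cell -> x_bin 0; lateral-most reference -> bin 3
  b2 <- assign_bins(with_targets(x = c(0, 12), z = c(1, 2)))
  expect_equal(b2$x_bin, c(0L, 3L))
  # left-side coordinates fold onto the same mediolateral bins
  tab <- with_targets(x = c(-11.99, -0.01), z = c(1, 2))
  tab$side[tab$marker == "negative"] <- "left"
  expect_equal(assign_bins(tab)$x_bin, c(3L, 0L))
})

test_that("degenerate reference extents are rejected", {
  flat <- data.frame(larva_id = "L", genotype = "g", side = "right",
                     x_um = c(1, 2, 3), y_um = 0, z_um = 5,
                     marker = "positive", label = NA, stringsAsFactors = FALSE)
  expect_error(assign_bins(validate_cell_table(flat)), "zero dorsoventral")
})

test_that("pooled counts are additive over larvae", {
  b1 <- assign_bins(with_targets(x = rep(0.5, 3), z = c(1, 2, 3), "L1"))
  b2 <- assign_bins(with_targets(x = rep(0.5, 2), z = c(20, 25), "L2"))
  g1 <- pool_counts(b1)
  g2 <- pool_counts(b2)
  g12 <- pool_counts(rbind(b1, b2))
  expect_equal(unclass(g12), unclass(g1) + unclass(g2),
               ignore_attr = TRUE)
  expect_equal(sum(g12), 5)
  single <- pool_counts(assign_bins(with_targets(rep(0.01, 50), rep(0, 50))))
  expect_equal(single[1, 1], 50L)
  expect_equal(sum(single), 50)
})

test_that("empirical distributions normalise exactly", {
  counts <- matrix(0L, 15, 4); counts[3, 2] <- 30L; counts[9, 1] <- 10L
  g <- occupancy_grid(counts)
  p <- empirical_distribution(g)
  expect_equal(p[3, 2], 0.75)
  expect_equal(p[9, 1], 0.25)
  expect_equal(sum(p), 1, tolerance = 1e-14)
  expect_error(empirical_distribution(occupancy_grid(matrix(0L, 15, 4))),
               "empty")
})

test_that("the conjugate posterior has the closed-form mean", {
  # flat prior, no data
  g0 <- occupancy_grid(matrix(0L, 15, 4))
  p0 <- posterior_sample(g0, alpha_prior = 1, n_samples = 4000, seed = 2)
  se <- apply(p0$samples, 2, sd) / sqrt(4000)
  expect_true(all(abs(colMeans(p0$samples) - 1 / 60) <= 4 * se))
  # concentrated data
  cts <- matrix(0L, 15, 4); cts[8, 2] <- 1000L
  p1 <- posterior_sample(occupancy_grid(cts), alpha_prior = 1,
                         n_samples = 4000, seed = 3)
  k <- which(as.vector(cts) == 1000)
  expect_equal(mean(p1$samples[, k]), 1001 / 1060, tolerance = 3e-3)
  # every sample is a probability vector
  expect_true(all(p1$samples >= 0))
  expect_true(max(abs(rowSums(p1$samples) - 1)) < 1e-9)
  expect_error(posterior_sample(g0, alpha_prior = -1), "alpha_prior")
})

test_that("MCMC sampling agrees with the conjugate closed form", {
  skip_if_not_installed("rjags")
  set.seed(91)
  cts <- matrix(rpois(60, 4), 15, 4)
  g <- occupancy_grid(cts)
  pd <- posterior_sample(g, n_samples = 4000, seed = 4)
  pm <- posterior_sample(g, n_samples = 4000, method = "mcmc", seed = 5)
  closed <- (as.vector(cts) + pd$alpha_prior) /
    (sum(cts) + 60 * pd$alpha_prior)
  # MC-SE from the effective sample size (MCMC draws are autocorrelated)
  ess <- pmin(coda::effectiveSize(coda::mcmc(pm$samples)), nrow(pm$samples))
  se <- apply(pm$samples, 2, sd) / sqrt(ess)
  expect_true(all(abs(colMeans(pm$samples) - closed) <= 4 * se))
  # variances agree too (conjugacy makes the MCMC redundant, not different)
  vd <- unname(apply(pd$samples, 2, var))
  vm <- unname(apply(pm$samples, 2, var))
  expect_equal(vm, vd, tolerance = 0.2)
})

test_that("differential maps subtract elementwise and conserve mass", {
  cts <- matrix(0L, 15, 4); cts[2, 1] <- 10L
  cts2 <- matrix(0L, 15, 4); cts2[12, 3] <- 10L
  d <- differential_map(occupancy_grid(cts), occupancy_grid(cts2))
  expect_equal(d[2, 1], -1)
  expect_equal(d[12, 3], 1)
  expect_equal(sum(d), 0, tolerance = 1e-14)
  expect_true(all(d >= -1 & d <= 1))
  same <- differential_map(occupancy_grid(cts), occupancy_grid(cts))
  expect_true(all(same == 0))
  expect_error(differential_map(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("KL of a sample set against itself is exactly zero", {
  g <- pool_counts(assign_bins(gen_occupancy_dataset(
    synthetic_truth(seed = 8))))
  p <- posterior_sample(g, n_samples = 2000, seed = 9)
  kl <- kl_posterior(p, p)
  expect_identical(kl$kl_mean, 0)
  expect_identical(kl$kl_ci_low, 0)
})

test_that("KL matches the direct formula on fixed two-bin vectors", {
  p <- c(0.9, 0.1); q <- c(0.4, 0.6)
  post_p <- as_posterior(list(p), dim = c(2, 1))
  post_q <- as_posterior(list(q), dim = c(2, 1))
  kl <- kl_posterior(post_p, post_q)
  expect_equal(kl$kl_mean, kl_formula(p, q), tolerance = 1e-14)
  expect_equal(kl$kl_reverse_mean, kl_formula(q, p), tolerance = 1e-14)
  expect_equal(kl$jeffreys_mean,
               (kl_formula(p, q) + kl_formula(q, p)) / 2, tolerance = 1e-14)
})

test_that("KL is non-negative across random posterior pairs", {
  set.seed(17)
  g1 <- occupancy_grid(matrix(rpois(60, 5), 15, 4))
  g2 <- occupancy_grid(matrix(rpois(60, 5), 15, 4))
  pa <- posterior_sample(g1, n_samples = 1000, seed = 1)
  pb <- posterior_sample(g2, n_samples = 1000, seed = 2)
  kl <- kl_posterior(pa, pb)
  expect_true(all(kl$kl_samples >= 0))
  expect_true(kl$kl_ci_low <= kl$kl_mean && kl$kl_mean <= kl$kl_ci_high)
})

test_that("axis shifts recover hand-computable extremes", {
  top <- matrix(0, 15, 4); top[15, 1] <- 1
  bottom <- matrix(0, 15, 4); bottom[1, 1] <- 1
  pa <- as_posterior(list(as.vector(top)), dim = c(15, 4))
  pb <- as_posterior(list(as.vector(bottom)), dim = c(15, 4))
  zs <- axis_shift(pa, pb, "dv")
  expect_equal(zs$shift_mean, 14)
  lat <- matrix(0, 15, 4); lat[1, 4] <- 1
  xshift <- axis_shift(as_posterior(list(as.vector(lat)), dim = c(15, 4)),
                       pb, "ml")
  expect_equal(xshift$shift_mean, 3)
  # identical posteriors: zero shift, CI straddles 0
  g <- occupancy_grid(matrix(rpois(60, 3), 15, 4))
  p1 <- posterior_sample(g, n_samples = 2000, seed = 3)
  p2 <- posterior_sample(g, n_samples = 2000, seed = 4)
  zs0 <- axis_shift(p1, p2, "dv")
  expect_lt(abs(zs0$shift_mean), 0.2)
  expect_true(zs0$ci_low < 0 && zs0$ci_high > 0)
  # bounds
  expect_true(abs(zs$shift_mean) <= 14)
  expect_error(axis_shift(p1, p2, "ap"), "arg")
})

test_that("posterior summaries are seed-stable at the terminal sample size", {
  g1 <- pool_counts(assign_bins(gen_occupancy_dataset(
    synthetic_truth(seed = 5), "wt")), "wt")
  g2 <- pool_counts(assign_bins(gen_occupancy_dataset(
    synthetic_truth(occupancy_probs = shift_grid(default_io_grid(), dz = -1),
                    seed = 6), "mut")), "mut")
  kl_run <- function(s1, s2) {
    kl_posterior(posterior_sample(g1, n_samples = 20000, seed = s1),
                 posterior_sample(g2, n_samples = 20000, seed = s2))
  }
  r1 <- kl_run(1, 2)
  r2 <- kl_run(3, 4)
  ciw <- r1$kl_ci_high - r1$kl_ci_low
  expect_lt(abs(r1$kl_mean - r2$kl_mean), ciw / 10)
})

test_that("the KL ladder flags identical grids as converged immediately", {
  g <- occupancy_grid(matrix(1000L, 15, 4))
  cc <- convergence_check(g, g, sample_sizes = c(500, 1000, 2000), seed = 2)
  expect_equal(cc$converged_at, 500)
  expect_true(all(cc$table$kl_mean < 0.05))
})
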