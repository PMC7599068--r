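#' Ground truth for synthetic datasets
#'
#' Bundles every parameter a synthetic dataset is generated from, so that
#' parameter-recovery tests can compare estimates against known truth. The
#' truth object travels with each generated dataset (as an attribute and,
#' when written to disk, as a JSON sidecar).
#'
#' @param occupancy_probs A `n_z x n_x` matrix of bin occupancy
#'   probabilities (non-negative, summing to 1). Defaults to
#'   [default_io_grid()].
#' @param n_larvae Number of larvae to simulate.
#' @param cells_per_larva Length-2 integer range; per-larva cell counts are
#'   drawn uniformly from it. The default emulates the order of 15 cells per
#'   larva seen in pooled datasets of ~280 cells over 19 larvae.
#' @param scatter_factor Dimensionless dispersion multiplier (>= 1) for
#'   clustered point clouds; 1 = wild-type-like compactness.
#' @param gain_true Named numeric, true optokinetic gains
#'   (`nasal`, `temporal`).
#' @param seed Master seed for the dataset.
#' @return A list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(occupancy_probs = default_io_grid(),
                            n_larvae = 19,
                            cells_per_larva = c(10, 20),
                            scatter_factor = 1,
                            gain_true = c(nasal = 0.8, temporal = 0.5),
                            seed = 1L) {
  occupancy_probs <- as.matrix(occupancy_probs)
  if (any(occupancy_probs < 0)) {
    stop("occupancy_probs must be non-negative", call. = FALSE)
  }
  if (abs(sum(occupancy_probs) - 1) > 1e-12) {
    stop("occupancy_probs must sum to 1 (within 1e-12)", call. = FALSE)
  }
  if (scatter_factor < 1) stop("scatter_factor must be >= 1", call. = FALSE)
  stopifnot(length(cells_per_larva) == 2, cells_per_larva[1] >= 1,
            cells_per_larva[2] >= cells_per_larva[1], n_larvae >= 1)
  structure(
    list(occupancy_probs = occupancy_probs,
         n_larvae = as.integer(n_larvae),
         cells_per_larva = as.integer(cells_per_larva),
         scatter_factor = scatter_factor,
         gain_true = gain_true,
         seed = as.integer(seed)),
    class = "synthetic_truth"
  )
}

#' Default occupancy probability grid
#'
#' A smooth, unimodal 15 x 4 occupancy grid emulating the wild-type-like
#' spatial pattern of an inferior-oblique-type subnucleus: probability mass
#' biased towards medial columns and mildly towards dorsal rows. The top and
#' bottom dorsoventral rows carry no mass so that the grid can be shifted by
#' one row in either direction ([shift_grid()]) without losing mass, which
#' keeps the true axis shift of shifted variants exactly at the nominal
#' value.
#'
#' @param n_z,n_x Grid dimensions (dorsoventral rows, mediolateral columns).
#' @return A probability matrix summing to 1.
#' @export
default_io_grid <- function(n_z = 15, n_x = 4) {
  z <- rep(0, n_z)
  rows <- 2:(n_z - 1)
  z[rows] <- exp(-0.5 * ((rows - (0.55 * (n_z - 1) + 1)) / (0.22 * n_z))^2)
  x <- exp(-0.9 * (seq_len(n_x) - 1))
  g <- outer(z, x)
  g / sum(g)
}

#' Shift an occupancy grid by whole bins
#'
#' Moves all probability mass by `dz` rows (dorsoventral, positive =
#' dorsal) and `dx` columns (mediolateral, positive = lateral). Mass is
#' never wrapped or clipped: if any non-zero mass would leave the grid the
#' call fails, so the mean-position shift of the result is exactly
#' `(dz, dx)`.
#'
#' @param probs A probability grid.
#' @param dz,dx Integer shifts in bin units.
#' @return The shifted grid.
#' @export
shift_grid <- function(probs, dz = 0, dx = 0) {
  probs <- as.matrix(probs)
  nz <- nrow(probs); nx <- ncol(probs)
  out <- matrix(0, nz, nx)
  for (i in seq_len(nz)) {
    for (j in seq_len(nx)) {
      if (probs[i, j] == 0) next
      ii <- i + dz; jj <- j + dx
      if (ii < 1 || ii > nz || jj < 1 || jj > nx) {
        stop("shift would move probability mass off the grid", call. = FALSE)
      }
      out[ii, jj] <- out[ii, jj] + probs[i, j]
    }
  }
  out
}

# physical extents used by the occupancy generator (micrometres); typical
# larval subnucleus scale
.DV_EXTENT_UM <- 30
.ML_EXTENT_UM <- 12

#' Generate a synthetic occupancy dataset
#'
#' Simulates per-larva cell tables whose spatial bin occupancy follows a
#' known probability grid: for each larva a cell count is drawn from the
#' truth's `cells_per_larva` range, bins are drawn multinomially from
#' `occupancy_probs`, and continuous coordinates are placed uniformly within
#' the interior of each bin's spatial extent. Each larva additionally
#' carries three `marker = "positive"` reference cells anchoring the
#' dorsoventral extremes and the lateral-most position, so that
#' [assign_bins()] recovers the sampled bin of every target cell exactly
#' (round-trip exactness).
#'
#' @param truth A [synthetic_truth()].
#' @param genotype Genotype label attached to all cells.
#' @return A [cell_table()] with attributes `truth` and `bins_true`
#'   (the sampled 0-based `(z_bin, x_bin)` per target cell).
#' @export
gen_occupancy_dataset <- function(truth, genotype = "wt") {
  stopifnot(inherits(truth, "synthetic_truth"))
  p <- truth$occupancy_probs
  nz <- nrow(p); nx <- ncol(p)
  with_subseed(truth$seed, paste0("occupancy/", genotype), {
    rows <- list()
    bins <- list()
    for (l in seq_len(truth$n_larvae)) {
      id <- sprintf("%s_larva%02d", genotype, l)
      counts_range <- truth$cells_per_larva[1]:truth$cells_per_larva[2]
      n <- counts_range[sample.int(length(counts_range), 1)]
      k <- sample.int(nz * nx, n, replace = TRUE, prob = as.vector(p))
      z_bin <- (k - 1) %% nz          # 0-based row (ventral -> dorsal)
      x_bin <- (k - 1) %/% nz         # 0-based column (medial -> lateral)
      u <- runif(n, 0.01, 0.99)
      z <- (z_bin + u) * .DV_EXTENT_UM / nz
      ux <- runif(n, 0.01, 0.99)
      xmag <- (x_bin + ux) * .ML_EXTENT_UM / nx
      side <- sample(c("left", "right"), n, replace = TRUE)
      x <- ifelse(side == "left", -xmag, xmag)
      y <- runif(n, 0, 20)
      rows[[length(rows) + 1]] <- data.frame(
        larva_id = id, genotype = genotype, side = side,
        x_um = x, y_um = y, z_um = z,
        marker = "negative", label = NA_character_,
        stringsAsFactors = FALSE
      )
      # reference cells anchoring the per-larva extents
      rows[[length(rows) + 1]] <- data.frame(
        larva_id = id, genotype = genotype,
        side = c("right", "right", "right"),
        x_um = c(0, 0, .ML_EXTENT_UM),
        y_um = c(10, 10, 10),
        z_um = c(0, .DV_EXTENT_UM, .DV_EXTENT_UM / 2),
        marker = "positive", label = NA_character_,
        stringsAsFactors = FALSE
      )
      bins[[l]] <- cbind(z_bin = z_bin, x_bin = x_bin)
    }
    out <- validate_cell_table(do.call(rbind, rows))
    attr(out, "truth") <- truth
    attr(out, "bins_true") <- do.call(rbind, bins)
    out
  })
}

#' Generate a clustered (or scattered) 3D point cloud
#'
#' Samples cell coordinates from a Gaussian mixture around the given
#' centres, with the per-axis standard deviation multiplied by a scatter
#' factor. Scatter factor 1 emulates a compact wild-type-like nucleus;
#' larger factors emulate the sparser distributions seen after adhesion
#' perturbation.
#'
#' @param n_cells Number of points (>= 4; convex hulls and tessellations
#'   need non-degenerate input).
#' @param centers Matrix of mixture centres (rows = 3D points, um).
#' @param sd Baseline per-axis standard deviation (um).
#' @param scatter_factor Dimensionless dispersion multiplier (>= 1).
#' @param seed Seed.
#' @return An `n_cells x 3` coordinate matrix (um).
#' @export
gen_clustered_nucleus <- function(n_cells, centers = matrix(0, 1, 3), sd = 5,
                                  scatter_factor = 1, seed = 1L) {
  if (n_cells < 4) {
    stop("n_cells must be >= 4 for non-degenerate geometry", call. = FALSE)
  }
  centers <- matrix(as.numeric(centers), ncol = 3)
  with_subseed(seed, "clustered_nucleus", {
    idx <- sample.int(nrow(centers), n_cells, replace = TRUE)
    pts <- centers[idx, , drop = FALSE] +
      matrix(rnorm(n_cells * 3, 0, sd * scatter_factor), ncol = 3)
    colnames(pts) <- c("x_um", "y_um", "z_um")
    pts
  })
}

#' Generate a synthetic optokinetic eye-position trace
#'
#' The stimulus is a constant-speed grating whose direction reverses every
#' `reversal_period` seconds (a triangular-wave position profile). During
#' slow phases each eye integrates gain x stimulus velocity; fast resetting
#' saccades occur at Poisson-random times and instantaneously return the eye
#' to its rest angle. Gaussian sample noise is added on top. Angles are
#' stored rightward-positive for both eyes, so the nasal direction is
#' positive velocity for the left eye and negative for the right eye.
#'
#' @param gain_nasal,gain_temporal True gains for nasally / temporally
#'   directed slow phases (applied to both eyes).
#' @param stim_speed Grating speed (deg/s), positive.
#' @param reversal_period Time between direction reversals (s).
#' @param duration Trace duration (s); must cover at least 2 reversals.
#' @param saccade_rate Expected resetting saccades per second.
#' @param noise_sd Gaussian angle noise (deg) per sample.
#' @param sample_rate Sampling rate (Hz).
#' @param seed Seed.
#' @return A `data.frame` of class `eye_trace` with columns `t`,
#'   `angle_left`, `angle_right`, `stim_velocity`, and attributes
#'   `reversal_times`, `saccade_idx`, `slow_phases_true` (index ranges),
#'   `sample_rate` and `gain_true`.
#' @export
gen_eye_trace <- function(gain_nasal = 0.8, gain_temporal = 0.5,
                          stim_speed = 10, reversal_period = 6,
                          duration = 60, saccade_rate = 0.2,
                          noise_sd = 0, sample_rate = 100, seed = 1L) {
  stopifnot(sample_rate > 0, stim_speed > 0, reversal_period > 0)
  if (duration < 2 * reversal_period) {
    stop("duration must cover at least 2 stimulus reversals", call. = FALSE)
  }
  with_subseed(seed, "eye_trace", {
    dt <- 1 / sample_rate
    t <- seq(0, duration - dt, by = dt)
    n <- length(t)
    phase <- floor(t / reversal_period)
    v <- stim_speed * ifelse(phase %% 2 == 0, 1, -1)
    reversal_times <- seq(reversal_period, duration - dt, by = reversal_period)
    saccade <- which(runif(n) < saccade_rate * dt)
    saccade <- saccade[saccade > 1]
    is_sac <- logical(n)
    is_sac[saccade] <- TRUE

    gl <- ifelse(v > 0, gain_nasal, gain_temporal)  # left eye
    gr <- ifelse(v > 0, gain_temporal, gain_nasal)  # right eye
    al <- numeric(n); ar <- numeric(n)
    for (i in 2:n) {
      if (is_sac[i]) {
        al[i] <- 0; ar[i] <- 0  # instantaneous reset to rest
      } else {
        al[i] <- al[i - 1] + gl[i - 1] * v[i - 1] * dt
        ar[i] <- ar[i - 1] + gr[i - 1] * v[i - 1] * dt
      }
    }
    # true slow phases: maximal runs free of saccades and reversals
    breaks <- sort(unique(c(1, saccade, which(diff(phase) != 0) + 1, n + 1)))
    sp <- list()
    for (b in seq_len(length(breaks) - 1)) {
      s <- breaks[b]; e <- breaks[b + 1] - 1
      if (is_sac[s]) s <- s + 1
      if (e > s) sp[[length(sp) + 1]] <- c(start = s, end = e)
    }
    slow_true <- do.call(rbind, sp)

    if (noise_sd > 0) {
      al <- al + rnorm(n, 0, noise_sd)
      ar <- ar + rnorm(n, 0, noise_sd)
    }
    out <- data.frame(t = t, angle_left = al, angle_right = ar,
                      stim_velocity = v)
    class(out) <- c("eye_trace", class(out))
    attr(out, "reversal_times") <- reversal_times
    attr(out, "saccade_idx") <- saccade
    attr(out, "slow_phases_true") <- slow_true
    attr(out, "sample_rate") <- sample_rate
    attr(out, "gain_true") <- c(nasal = gain_nasal, temporal = gain_temporal)
    out
  })
}

#' Render a synthetic binary video frame of two eyes
#'
#' Draws two filled ellipses (left and right eye) at the stated orientations
#' into a binary image, optionally adding salt noise of single-pixel specks
#' well away from the eyes. Angles are measured counter-clockwise from the
#' image x-axis with y pointing up, the convention [eye_orientation()]
#' reports in.
#'
#' @param angles Length-2 numeric, orientations (deg) of the left and right
#'   eye ellipses.
#' @param axes Length-2 numeric, semi-major and semi-minor axes in pixels.
#' @param image_size Length-2 integer `(rows, cols)`.
#' @param centers Optional 2 x 2 matrix of ellipse centres `(x, y)` in pixel
#'   coordinates; defaults to symmetric placement.
#' @param noise_frac Fraction of background pixels set to 1 as specks.
#' @param seed Seed for the speck noise.
#' @return A binary integer matrix.
#' @export
gen_eye_frames <- function(angles, axes = c(30, 12), image_size = c(160, 240),
                           centers = NULL, noise_frac = 0, seed = 1L) {
  stopifnot(length(angles) == 2, length(axes) == 2, axes[1] >= axes[2])
  h <- image_size[1]; w <- image_size[2]
  if (is.null(centers)) {
    centers <- rbind(c(0.28 * w, 0.5 * h), c(0.72 * w, 0.5 * h))
  }
  if (any(centers[, 1] - axes[1] < 1) || any(centers[, 1] + axes[1] > w) ||
      any(centers[, 2] - axes[1] < 1) || any(centers[, 2] + axes[1] > h)) {
    stop("ellipses do not fit inside the frame", call. = FALSE)
  }
  cc <- matrix(rep(seq_len(w), each = h), h, w)
  rr <- matrix(rep(seq_len(h), times = w), h, w)
  masks <- vector("list", 2)
  for (e in 1:2) {
    th <- angles[e] * pi / 180
    u <- cc - centers[e, 1]
    v <- -(rr - centers[e, 2])  # y up
    uu <- u * cos(th) + v * sin(th)
    vv <- -u * sin(th) + v * cos(th)
    masks[[e]] <- (uu / axes[1])^2 + (vv / axes[2])^2 <= 1
  }
  if (any(masks[[1]] & masks[[2]])) {
    stop("ellipses overlap", call. = FALSE)
  }
  img <- masks[[1]] | masks[[2]]
  if (noise_frac > 0) {
    with_subseed(seed, "eye_frames", {
      # keep specks clear of the eyes so components never merge with them
      d1 <- sqrt((cc - centers[1, 1])^2 + (rr - centers[1, 2])^2)
      d2 <- sqrt((cc - centers[2, 1])^2 + (rr - centers[2, 2])^2)
      free <- which(!img & d1 > axes[1] + 4 & d2 > axes[1] + 4)
      k <- min(length(free), ceiling(noise_frac * h * w))
      img[sample(free, k)] <- TRUE
    })
  }
  mode(img) <- "integer"
  img
}

#' Generate a synthetic fluorescence intensity stack with ROI masks
#'
#' Produces a 3D intensity array with Gaussian noise around a stated region
#' mean inside ROI masks and around a background mean elsewhere, together
#' with the ROI and background mask specifications that
#' [corrected_mean_intensity()] consumes. By default, left/right ROI
#' rectangles are placed on the five interior measurement slices (see
#' [slice_selection()]) and three background ROIs on three distinct slices.
#'
#' @param roi_mean,bg_mean True mean grey values (a.u.) inside the ROI and
#'   in the background.
#' @param noise_sd Gaussian noise standard deviation (a.u.).
#' @param n_slices Stack depth (>= 7 for the default mask layout).
#' @param dim Length-2 integer, in-plane image size.
#' @param roi_masks,bg_masks Optional mask specifications (lists of
#'   `list(slice =, side =, mask =)` / `list(slice =, mask =)`); defaults
#'   are auto-generated.
#' @param seed Seed.
#' @return A list with `stack` (array), `roi_masks`, `bg_masks`, and
#'   `truth` (the generating parameters, including the true corrected
#'   intensity `roi_mean - bg_mean`).
#' @export
gen_intensity_stack <- function(roi_mean = 2000, bg_mean = 500, noise_sd = 50,
                                n_slices = 9, dim = c(48, 48),
                                roi_masks = NULL, bg_masks = NULL, seed = 1L) {
  h <- dim[1]; w <- dim[2]
  if (is.null(roi_masks)) {
    slices <- slice_selection(n_slices)
    rect <- function(r1, r2, c1, c2) {
      m <- matrix(FALSE, h, w); m[r1:r2, c1:c2] <- TRUE; m
    }
    roi_masks <- list()
    for (s in slices) {
      roi_masks[[length(roi_masks) + 1]] <-
        list(slice = s, side = "left",
             mask = rect(round(h * 0.35), round(h * 0.65),
                         round(w * 0.10), round(w * 0.40)))
      roi_masks[[length(roi_masks) + 1]] <-
        list(slice = s, side = "right",
             mask = rect(round(h * 0.35), round(h * 0.65),
                         round(w * 0.60), round(w * 0.90)))
    }
    if (is.null(bg_masks)) {
      bg_masks <- lapply(slices[1:3], function(s) {
        list(slice = s, mask = rect(2, 6, 2, 6))
      })
    }
  }
  if (is.null(bg_masks)) stop("bg_masks must be supplied with roi_masks")
  # ROI and background masks must not overlap on any shared slice
  for (r in roi_masks) {
    for (b in bg_masks) {
      if (r$slice == b$slice && any(r$mask & b$mask)) {
        stop("ROI and background masks overlap", call. = FALSE)
      }
    }
  }
  with_subseed(seed, "intensity_stack", {
    stack <- array(bg_mean, dim = c(h, w, n_slices))
    if (noise_sd > 0) {
      stack <- stack + array(rnorm(h * w * n_slices, 0, noise_sd),
                             dim = c(h, w, n_slices))
    }
    for (r in roi_masks) {
      plane <- stack[, , r$slice]
      plane[r$mask] <- roi_mean +
        if (noise_sd > 0) rnorm(sum(r$mask), 0, noise_sd) else 0
      stack[, , r$slice] <- plane
    }
    list(stack = stack, roi_masks = roi_masks, bg_masks = bg_masks,
         truth = list(roi_mean = roi_mean, bg_mean = bg_mean,
                      noise_sd = noise_sd, corrected = roi_mean - bg_mean,
                      seed = seed))
  })
}
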