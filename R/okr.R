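#' Eye orientation from image central moments
#'
#' Segments a thresholded (binary) frame into connected components, keeps
#' the two largest (which in this preparation invariably correspond to the
#' eyes), and computes each component's orientation from its central second
#' moments, \eqn{\theta = \tfrac12 \mathrm{atan2}(2\mu_{11},
#' \mu_{20}-\mu_{02})}, reported in degrees in `(-90, 90]` measured
#' counter-clockwise from the image x-axis (y up). Components are assigned
#' left/right by centroid x. Components with no dominant axis
#' (\eqn{\mu_{20} \approx \mu_{02}} and \eqn{\mu_{11} \approx 0}, e.g.
#' circles) are flagged as orientation-undefined.
#'
#' @param frame A binary matrix (nonzero = foreground).
#' @return A `data.frame` with rows `left`, `right` and columns `eye`,
#'   `angle_deg`, `cx`, `cy`, `area`, `undefined`.
#' @export
eye_orientation <- function(frame) {
  frame <- (as.matrix(frame) != 0) * 1
  lab <- EBImage::bwlabel(frame)
  n_obj <- max(lab)
  if (n_obj < 2) {
    stop("tracking failure: fewer than 2 connected components in frame",
         call. = FALSE)
  }
  areas <- tabulate(lab[lab > 0], nbins = n_obj)
  keep <- order(areas, decreasing = TRUE)[1:2]
  res <- lapply(keep, function(id) {
    idx <- which(lab == id, arr.ind = TRUE)
    x <- idx[, 2]
    y <- -idx[, 1]  # y up
    cx <- mean(x); cy <- mean(y)
    mu20 <- mean((x - cx)^2)
    mu02 <- mean((y - cy)^2)
    mu11 <- mean((x - cx) * (y - cy))
    undef <- abs(mu20 - mu02) < 2e-2 * (mu20 + mu02) &&
      abs(mu11) < 2e-2 * (mu20 + mu02)
    th <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
    if (th <= -90) th <- th + 180
    if (th > 90) th <- th - 180
    data.frame(angle_deg = th, cx = cx, cy = -cy, area = length(x),
               undefined = undef)
  })
  res <- do.call(rbind, res)
  res$eye <- ifelse(rank(res$cx, ties.method = "first") == 1, "left", "right")
  res <- res[order(res$cx), c("eye", "angle_deg", "cx", "cy", "area",
                              "undefined")]
  rownames(res) <- res$eye
  res
}

# smoothed central-difference eye velocity (deg/s)
eye_velocity <- function(angle, sample_rate, smooth = 5) {
  sm <- as.numeric(stats::filter(angle, rep(1 / smooth, smooth), sides = 2))
  sm[is.na(sm)] <- angle[is.na(sm)]
  n <- length(sm)
  v <- c(NA, (sm[3:n] - sm[1:(n - 2)]) * sample_rate / 2, NA)
  v[1] <- v[2]; v[n] <- v[n - 1]
  v
}

#' Segment slow phases of an optokinetic trace
#'
#' Marks samples whose smoothed eye velocity exceeds a threshold as fast
#' phase (saccadic), expands the exclusion by a symmetric guard window to
#' remove smoothing-contaminated samples, and additionally breaks runs at
#' stimulus reversals (a slow phase never spans a reversal). Remaining runs
#' of at least `min_duration` are the slow phases.
#'
#' @param trace An eye trace ([gen_eye_trace()] or a data frame with `t`,
#'   `angle_left`, `angle_right`, `stim_velocity` and a `sample_rate`
#'   attribute).
#' @param eye `"left"` or `"right"`.
#' @param velocity_threshold Fast-phase threshold (deg/s); default 3x the
#'   maximum stimulus speed (fast phases are an order of magnitude faster
#'   than slow tracking).
#' @param guard_ms Guard window around fast-phase samples (ms).
#' @param min_duration Minimum slow-phase duration (s).
#' @return A `data.frame` of intervals (`start`, `end` sample indices,
#'   `direction` sign of the stimulus velocity within the interval). Empty
#'   (with a warning) if no slow phase survives.
#' @export
segment_slow_phases <- function(trace, eye = c("left", "right"),
                                velocity_threshold = NULL,
                                guard_ms = 50, min_duration = 0.5) {
  eye <- match.arg(eye)
  rate <- attr(trace, "sample_rate") %||%
    (1 / median(diff(trace$t)))
  angle <- trace[[paste0("angle_", eye)]]
  n <- length(angle)
  if (is.null(velocity_threshold)) {
    velocity_threshold <- 3 * max(abs(trace$stim_velocity))
  }
  v <- eye_velocity(angle, rate)
  fast <- abs(v) > velocity_threshold
  guard <- max(1L, round(guard_ms / 1000 * rate))
  bad <- which(fast)
  if (length(bad) > 0) {
    bad <- unique(unlist(lapply(bad, function(i) {
      max(1, i - guard):min(n, i + guard)
    })))
  }
  ok <- rep(TRUE, n)
  ok[bad] <- FALSE
  # never span a stimulus reversal; also trim a guard window around it so
  # smoothed velocities inside an interval reflect a single direction
  rev_idx <- which(diff(sign(trace$stim_velocity)) != 0) + 1
  for (i in rev_idx) {
    ok[max(1, i - guard):min(n, i + guard)] <- FALSE
  }
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & (r$lengths >= min_duration * rate)
  if (!any(keep)) {
    warning("no slow phases detected", call. = FALSE)
    return(data.frame(start = integer(0), end = integer(0),
                      direction = numeric(0)))
  }
  out <- data.frame(start = starts[keep], end = ends[keep])
  out$direction <- vapply(seq_len(nrow(out)), function(i) {
    sign(median(trace$stim_velocity[out$start[i]:out$end[i]]))
  }, numeric(1))
  out
}

# nasal direction sign in rightward-positive angle coordinates
nasal_sign <- function(eye) if (eye == "left") 1 else -1

#' Slow-phase gain of the optokinetic reflex
#'
#' Gain is the ratio of slow-phase eye velocity to grating velocity,
#' quantified separately per eye and per direction (nasal: towards the
#' nose; temporal: towards the temple). Eye velocity within each slow
#' phase is the least-squares slope of angle against time over the phase
#' (robust to sample noise); a phase counts as nasal or temporal by the
#' sign of that slope relative to the eye's nasal direction (left eye
#' nasal = rightward-positive, right eye nasal = leftward). The reported
#' gain averages `|slope| / |grating speed|` over qualifying phases.
#'
#' @param trace An eye trace.
#' @param eye `"left"` or `"right"`.
#' @param direction `"nasal"` or `"temporal"`.
#' @param slow_phases Optional precomputed [segment_slow_phases()] result.
#' @param ... Passed to [segment_slow_phases()].
#' @return The gain (dimensionless), or `NA` with a warning if no
#'   qualifying slow phase exists.
#' @export
compute_gain <- function(trace, eye = c("left", "right"),
                         direction = c("nasal", "temporal"),
                         slow_phases = NULL, ...) {
  eye <- match.arg(eye)
  direction <- match.arg(direction)
  if (is.null(slow_phases)) {
    slow_phases <- segment_slow_phases(trace, eye = eye, ...)
  }
  if (nrow(slow_phases) == 0) {
    warning("no slow phases; gain is NA", call. = FALSE)
    return(NA_real_)
  }
  angle <- trace[[paste0("angle_", eye)]]
  gains <- c()
  for (i in seq_len(nrow(slow_phases))) {
    s <- slow_phases$start[i]; e <- slow_phases$end[i]
    tt <- trace$t[s:e]
    slope <- unname(coef(lm(angle[s:e] ~ tt))[2])
    speed <- abs(median(trace$stim_velocity[s:e]))
    if (speed == 0) next
    # a zero slope has no direction; it contributes its (zero) gain to both
    dir_i <- if (slope == 0) direction
             else if (sign(slope) == nasal_sign(eye)) "nasal" else "temporal"
    if (dir_i == direction) gains <- c(gains, abs(slope) / speed)
  }
  if (length(gains) == 0) {
    warning("no ", direction, " slow phase for the ", eye, " eye",
            call. = FALSE)
    return(NA_real_)
  }
  mean(gains)
}

#' Eye movement range and eye dominance
#'
#' The range of movement of each eye is the difference between its maximum
#' and minimum angle over the session; the strong eye is the one with the
#' larger range (ties go to the left eye, with a note). Resting-referenced
#' excursions (max above and below the median rest angle) are reported as
#' well.
#'
#' @param trace An eye trace.
#' @return A list with `eye_range` (named, deg), `strong_eye`,
#'   `weak_eye`, and `excursion` (rostral/caudal excursions per eye).
#' @export
eye_range_and_dominance <- function(trace) {
  rng <- c(left = max(trace$angle_left) - min(trace$angle_left),
           right = max(trace$angle_right) - min(trace$angle_right))
  if (rng["left"] == rng["right"]) {
    message("eye ranges tie; assigning 'left' as the strong eye")
    strong <- "left"
  } else {
    strong <- names(rng)[which.max(rng)]
  }
  exc <- lapply(c(left = "angle_left", right = "angle_right"), function(col) {
    rest <- median(trace[[col]])
    c(positive = max(trace[[col]]) - rest, negative = rest - min(trace[[col]]))
  })
  list(eye_range = rng, strong_eye = strong,
       weak_eye = setdiff(c("left", "right"), strong), excursion = exc)
}

#' Full optokinetic-reflex analysis of one trace
#'
#' Runs slow-phase segmentation, per-eye and per-direction gain
#' estimation, and eye-range / dominance assignment.
#'
#' @param trace An eye trace.
#' @param ... Passed to [segment_slow_phases()].
#' @return An `okr_result` list: `gain` (matrix eyes x directions),
#'   `gain_nasal`, `gain_temporal` (averaged over eyes), `eye_range`,
#'   `strong_eye`, `weak_eye`.
#' @export
okr_analyze <- function(trace, ...) {
  gain <- matrix(NA_real_, 2, 2,
                 dimnames = list(c("left", "right"),
                                 c("nasal", "temporal")))
  for (eye in c("left", "right")) {
    sp <- segment_slow_phases(trace, eye = eye, ...)
    for (dir in c("nasal", "temporal")) {
      gain[eye, dir] <- compute_gain(trace, eye = eye, direction = dir,
                                     slow_phases = sp)
    }
  }
  rng <- eye_range_and_dominance(trace)
  structure(
    list(gain = gain,
         gain_nasal = mean(gain[, "nasal"], na.rm = TRUE),
         gain_temporal = mean(gain[, "temporal"], na.rm = TRUE),
         eye_range = rng$eye_range,
         strong_eye = rng$strong_eye, weak_eye = rng$weak_eye),
    class = "okr_result"
  )
}

#' Read / write eye traces as tab-delimited text
#'
#' @param path File path.
#' @param sample_rate Sampling rate (Hz) attached on read when the file
#'   has no uniform time column to infer it from.
#' @return `read_eye_trace` returns an `eye_trace` data frame.
#' @export
read_eye_trace <- function(path, sample_rate = NULL) {
  df <- read.delim(path)
  need <- c("t", "angle_left", "angle_right", "stim_velocity")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("eye trace is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  class(df) <- c("eye_trace", class(df))
  attr(df, "sample_rate") <- sample_rate %||% 1 / median(diff(df$t))
  df
}

#' @rdname read_eye_trace
#' @param trace An eye trace.
#' @export
write_eye_trace <- function(trace, path) {
  write.table(as.data.frame(trace)[, c("t", "angle_left", "angle_right",
                                       "stim_velocity")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
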