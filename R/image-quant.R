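#' Select equally spaced interior slices of a substack
#'
#' Picks `n` equally spaced slices spanning the interior of a substack,
#' excluding the first and last slice (which typically clip the structure).
#' Indices are 1-based; for a depth-7 substack the selection is slices
#' 2 to 6, for depth 11 it is 2, 4, 6, 8, 10.
#'
#' @param depth Substack depth (>= `n + 2`).
#' @param n Number of slices (default 5).
#' @return Integer vector of `n` slice indices.
#' @export
slice_selection <- function(depth, n = 5) {
  if (depth < n + 2) {
    stop("substack depth ", depth, " leaves fewer than ", n,
         " interior slices", call. = FALSE)
  }
  unique(round(seq(2, depth - 1, length.out = n)))
}

#' Background-corrected mean ROI intensity
#'
#' Measures the mean grey value of every ROI (per slice, per side), the
#' average of the three background ROI means, and the background-corrected
#' value of each measurement; the specimen-level value is the mean of the
#' corrected measurements. Negative corrected values are allowed and
#' reported (signal below background). The specimen value is categorised
#' with [expression_category()].
#'
#' @param stack A 3D intensity array `(rows, cols, slices)`.
#' @param roi_masks List of `list(slice =, side =, mask =)` measurement
#'   ROIs (logical in-plane masks).
#' @param bg_masks List of exactly 3 `list(slice =, mask =)` background
#'   ROIs.
#' @param specimen_id Identifier attached to the result.
#' @return An `intensity_measurement` list: `specimen_id`, `measurements`
#'   (per-ROI table with raw and corrected means), `background_mean`,
#'   `corrected_mean`, `category`.
#' @export
corrected_mean_intensity <- function(stack, roi_masks, bg_masks,
                                     specimen_id = "specimen") {
  stopifnot(length(dim(stack)) == 3)
  if (length(bg_masks) != 3) {
    stop("exactly 3 background ROIs are required", call. = FALSE)
  }
  roi_mean <- function(roi) {
    if (roi$slice < 1 || roi$slice > dim(stack)[3]) {
      stop("mask slice index out of range", call. = FALSE)
    }
    m <- roi$mask
    if (!any(m)) stop("empty ROI mask", call. = FALSE)
    mean(stack[, , roi$slice][m])
  }
  bg <- vapply(bg_masks, roi_mean, numeric(1))
  background_mean <- mean(bg)
  meas <- do.call(rbind, lapply(roi_masks, function(r) {
    raw <- roi_mean(r)
    data.frame(slice = r$slice, side = r$side %||% NA_character_,
               roi_mean = raw, corrected = raw - background_mean,
               stringsAsFactors = FALSE)
  }))
  corrected_mean <- mean(meas$corrected)
  structure(
    list(specimen_id = specimen_id, measurements = meas,
         background_mean = background_mean,
         background_roi_means = bg,
         corrected_mean = corrected_mean,
         category = expression_category(corrected_mean)),
    class = "intensity_measurement"
  )
}

#' Categorise an expression intensity
#'
#' Maps a background-corrected mean intensity (a.u.) onto the discrete
#' expression bands used for display: below 500 the probe is omitted;
#' 500-1500 small; 1500-2500 regular; 2500-3500 large; 3500 and above
#' large_bold. Bands are left-closed/right-open, so a value exactly on a
#' printed boundary belongs to the higher band (1500 is `regular`, 3500 is
#' `large_bold`).
#'
#' @param intensity Numeric vector of corrected intensities (a.u.).
#' @return Character vector of categories (`omitted`, `small`, `regular`,
#'   `large`, `large_bold`).
#' @export
expression_category <- function(intensity) {
  stopifnot(all(is.finite(intensity)))
  cut(intensity,
      breaks = c(-Inf, 500, 1500, 2500, 3500, Inf),
      labels = c("omitted", "small", "regular", "large", "large_bold"),
      right = FALSE) |> as.character()
}

#' Fluorescence area in the midline sagittal section
#'
#' Reslices a stack to the sagittal plane at the midline and measures the
#' area of supra-threshold fluorescence there, the measure used to
#' quantify midline convergence of a bilateral cell population. A
#' connected-component report is included (converged signal typically
#' appears as one large area).
#'
#' @param stack A 3D intensity array `(rows, cols, slices)` whose column
#'   axis is mediolateral.
#' @param midline_index Column index of the midline plane.
#' @param threshold Intensity threshold (a.u.); pixels `>= threshold`
#'   count.
#' @param pixel_size Pixel edge length (um).
#' @return A list with `area_um2`, `n_pixels`, `n_components`,
#'   `largest_component_um2`.
#' @export
midline_area <- function(stack, midline_index, threshold, pixel_size = 1) {
  stopifnot(length(dim(stack)) == 3, threshold >= 0)
  if (midline_index < 1 || midline_index > dim(stack)[2]) {
    stop("midline plane index out of range", call. = FALSE)
  }
  plane <- stack[, midline_index, ]  # rows x slices sagittal section
  bw <- (plane >= threshold) * 1
  n_pix <- sum(bw)
  if (n_pix == 0) {
    warning("no supra-threshold pixels in the midline plane", call. = FALSE)
    return(list(area_um2 = 0, n_pixels = 0L, n_components = 0L,
                largest_component_um2 = 0))
  }
  lab <- EBImage::bwlabel(bw)
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  list(area_um2 = n_pix * pixel_size^2,
       n_pixels = as.integer(n_pix),
       n_components = as.integer(length(sizes)),
       largest_component_um2 = max(sizes) * pixel_size^2)
}
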