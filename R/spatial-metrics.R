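#' 3D Delaunay tessellation of cell coordinates
#'
#' Computes the Delaunay tessellation of a 3D point cloud via the paraboloid
#' lift (the lower convex hull of points lifted to
#' \eqn{(x, y, z, x^2+y^2+z^2)} in 4D is the Delaunay tessellation).
#' Exactly degenerate configurations (cospherical or coplanar point
#' subsets) are broken by a deterministic jitter of `jitter` micrometres
#' keyed to `seed`; the jitter decides combinatorics only — all lengths and
#' volumes derived from the tessellation use the original coordinates.
#'
#' @param points An `n x 3` numeric matrix of coordinates (um), `n >= 5`.
#' @param jitter Degeneracy-breaking jitter magnitude (um).
#' @param seed Seed for the jitter.
#' @return An `m x 4` integer matrix of tetrahedron vertex indices.
#' @export
delaunay_tetrahedra <- function(points, jitter = 1e-6, seed = 1L) {
  points <- as_coord_matrix(points)
  if (nrow(points) < 5) {
    stop("at least 5 points are required for a Delaunay tessellation",
         call. = FALSE)
  }
  jit <- with_subseed(seed, "delaunay_jitter", {
    matrix(runif(length(points), -jitter, jitter), nrow = nrow(points))
  })
  .delaunay3d_cpp(points + jit)
}

as_coord_matrix <- function(points) {
  if (is.data.frame(points)) {
    points <- as.matrix(points[, c("x_um", "y_um", "z_um")])
  }
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3 || !all(is.finite(points))) {
    stop("points must be a finite n x 3 coordinate matrix", call. = FALSE)
  }
  points
}

tet_volume <- function(points, tets) {
  # sum of |det|/6 over tetrahedra; the division happens once at the end so
  # integer-valued determinants (e.g. lattice fixtures) sum exactly
  s <- 0
  for (i in seq_len(nrow(tets))) {
    v <- tets[i, ]
    a <- points[v[2], ] - points[v[1], ]
    b <- points[v[3], ] - points[v[1], ]
    cc <- points[v[4], ] - points[v[1], ]
    s <- s + abs(a[1] * (b[2] * cc[3] - b[3] * cc[2]) -
                 a[2] * (b[1] * cc[3] - b[3] * cc[1]) +
                 a[3] * (b[1] * cc[2] - b[2] * cc[1]))
  }
  unname(s) / 6
}

#' Convex-hull volume of a 3D point cloud
#'
#' Volume of the smallest convex set containing all coordinates, the
#' standard measure of the spatial extent of a cell group. The volume is
#' obtained by triangulating the cloud ([delaunay_tetrahedra()]) and
#' summing tetrahedron volumes computed from the original (unjittered)
#' coordinates, so lattice fixtures (e.g. a unit cube) come out exact.
#'
#' @param points An `n x 3` coordinate matrix or a [cell_table()],
#'   `n >= 4`, not all coplanar.
#' @param seed Seed for the degeneracy-breaking jitter.
#' @return Hull volume in cubic micrometres.
#' @export
convex_hull_volume <- function(points, seed = 1L) {
  points <- as_coord_matrix(points)
  n <- nrow(points)
  if (n < 4) {
    stop("convex hull volume needs at least 4 points; got ", n, call. = FALSE)
  }
  ctr <- sweep(points, 2, colMeans(points))
  sv <- svd(ctr)$d
  if (sv[3] <= 1e-9 * max(sv[1], 1)) {
    stop("degenerate geometry: points are coplanar (or collinear); ",
         "the convex hull has zero volume", call. = FALSE)
  }
  if (n == 4) {
    return(tet_volume(points, matrix(1:4, 1)))
  }
  tets <- delaunay_tetrahedra(points, seed = seed)
  tet_volume(points, tets)
}

#' Delaunay local cell density
#'
#' Per-cell local density derived from the Delaunay tessellation: the
#' density at a point is the reciprocal of the mean length of the Delaunay
#' edges incident to it (units 1/um, reported as arbitrary units). Densely
#' packed cells have short edges to their natural neighbours and hence high
#' density; the measure is scale-covariant (dilating the cloud by `s`
#' multiplies all densities by `1/s`).
#'
#' @param points An `n x 3` coordinate matrix or a [cell_table()],
#'   `n >= 5`.
#' @param seed Seed for the degeneracy-breaking jitter.
#' @return A list with `density` (per-point vector, 1/um), `mean_density`
#'   (summary over the cloud), and `edges` (2-column index matrix of unique
#'   Delaunay edges).
#' @export
delaunay_local_density <- function(points, seed = 1L) {
  points <- as_coord_matrix(points)
  n <- nrow(points)
  if (n < 5) {
    stop("local density needs at least 5 points; got ", n, call. = FALSE)
  }
  tets <- delaunay_tetrahedra(points, seed = seed)
  pairs <- rbind(tets[, c(1, 2)], tets[, c(1, 3)], tets[, c(1, 4)],
                 tets[, c(2, 3)], tets[, c(2, 4)], tets[, c(3, 4)])
  pairs <- t(apply(pairs, 1, sort))
  pairs <- unique(pairs)
  len <- sqrt(rowSums((points[pairs[, 1], , drop = FALSE] -
                       points[pairs[, 2], , drop = FALSE])^2))
  dens <- vapply(seq_len(n), function(i) {
    inc <- pairs[, 1] == i | pairs[, 2] == i
    1 / mean(len[inc])
  }, numeric(1))
  list(density = dens, mean_density = mean(dens), edges = pairs)
}

#' Per-larva clustering metrics
#'
#' Computes a clustering metric per side of each larva and averages the two
#' sides to give one value per larva, the aggregation level at which group
#' comparisons are made. Sides with too few cells for the requested
#' geometry (fewer than 4 for hulls, 5 for densities) are excluded from the
#' side average with a warning; a larva with no usable side yields `NA`.
#'
#' @param cells A [cell_table()].
#' @param metric One of `"hull"` (convex-hull volume, um^3), `"density"`
#'   (mean Delaunay local density, 1/um) or `"count"` (cells per side).
#' @param dorsal_only If `TRUE`, restrict to the dorsal half of each larva
#'   first (see [dorsal_half()]).
#' @param seed Seed passed to the geometric routines.
#' @return A `data.frame` with columns `larva_id`, `genotype`, `value`,
#'   `n_sides_used`, `n_cells_per_side`.
#' @export
per_larva_summary <- function(cells, metric = c("hull", "density", "count"),
                              dorsal_only = FALSE, seed = 1L) {
  metric <- match.arg(metric)
  cells <- validate_cell_table(cells)
  if (dorsal_only) cells <- dorsal_half(cells)
  min_n <- switch(metric, hull = 4L, density = 5L, count = 1L)
  res <- lapply(split(cells, cells$larva_id), function(lv) {
    vals <- c(); ns <- c()
    for (s in c("left", "right")) {
      side <- lv[lv$side == s, , drop = FALSE]
      ns <- c(ns, nrow(side))
      if (nrow(side) < min_n) {
        if (nrow(side) > 0) {
          warning(sprintf(
            "larva %s, %s side: %d cell(s) < %d required for %s; side excluded",
            lv$larva_id[1], s, nrow(side), min_n, metric), call. = FALSE)
        }
        next
      }
      v <- switch(metric,
        hull = convex_hull_volume(side, seed = seed),
        density = delaunay_local_density(side, seed = seed)$mean_density,
        count = nrow(side))
      vals <- c(vals, v)
    }
    data.frame(larva_id = lv$larva_id[1], genotype = lv$genotype[1],
               value = if (length(vals) > 0) mean(vals) else NA_real_,
               n_sides_used = length(vals),
               n_cells_per_side = mean(ns),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Two-sample rank comparison (Mann-Whitney U)
#'
#' Compares two groups of per-larva values with the two-tailed
#' Mann-Whitney U test: exact enumeration when the combined sample size is
#' at most 20 and there are no ties, the tie-corrected normal approximation
#' otherwise. Group medians and ranges are reported alongside, matching how
#' such comparisons are usually summarised.
#'
#' @param group_a,group_b Numeric vectors of per-specimen values
#'   (each of length >= 3).
#' @param exact_max Combined sample size up to which the exact null
#'   distribution is used.
#' @return A list with `U` (statistic for `group_a`), `p` (two-tailed),
#'   `method`, and per-group `median` and `range`.
#' @export
rank_compare <- function(group_a, group_b, exact_max = 20) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 3 || length(group_b) < 3) {
    stop("each group needs at least 3 non-missing values", call. = FALSE)
  }
  ties <- any(duplicated(c(group_a, group_b)))
  exact <- (length(group_a) + length(group_b)) <= exact_max && !ties
  wt <- suppressWarnings(
    wilcox.test(group_a, group_b, exact = exact, correct = FALSE)
  )
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal approximation (tie-corrected)",
       median_a = median(group_a), median_b = median(group_b),
       range_a = range(group_a), range_b = range(group_b),
       n_a = length(group_a), n_b = length(group_b))
}

#' Compare clustering metrics between two genotype groups
#'
#' Convenience wrapper: computes a per-larva metric for each genotype in a
#' combined cell table and runs [rank_compare()] between the two groups.
#'
#' @param cells A [cell_table()] containing exactly two genotypes.
#' @inheritParams per_larva_summary
#' @return A list with the two per-larva tables and the comparison report.
#' @export
compare_groups <- function(cells, metric = c("hull", "density", "count"),
                           dorsal_only = FALSE, seed = 1L) {
  metric <- match.arg(metric)
  cells <- validate_cell_table(cells)
  gs <- unique(cells$genotype)
  if (length(gs) != 2) {
    stop("cell table must contain exactly 2 genotypes; found ",
         length(gs), call. = FALSE)
  }
  pl <- per_larva_summary(cells, metric = metric,
                          dorsal_only = dorsal_only, seed = seed)
  a <- pl$value[pl$genotype == gs[1]]
  b <- pl$value[pl$genotype == gs[2]]
  cmp <- rank_compare(a, b)
  cmp$direction <- stats::setNames(gs, c("a", "b"))
  list(per_larva = pl, comparison = cmp, metric = metric)
}
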