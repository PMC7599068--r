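# Independent oracles used across the suite. These are deliberately naive
# (brute-force / closed-form) implementations kept separate from the package
# code paths they check.

# brute-force empty-circumsphere check: every returned tetrahedron's
# circumsphere must contain no other point in its interior (up to `tol`,
# which absorbs the degeneracy-breaking jitter)
circumsphere_ok <- function(points, tets, tol = 1e-4) {
  for (i in seq_len(nrow(tets))) {
    v <- tets[i, ]
    p <- points[v, , drop = FALSE]
    # circumcenter: solve 2 (p_k - p_1) . c = |p_k|^2 - |p_1|^2
    A <- 2 * sweep(p[2:4, , drop = FALSE], 2, p[1, ])
    b <- rowSums(p[2:4, , drop = FALSE]^2) - sum(p[1, ]^2)
    cc <- tryCatch(solve(A, b), error = function(e) return(NULL))
    if (is.null(cc)) next # degenerate sliver, no interior to violate
    r <- sqrt(sum((p[1, ] - cc)^2))
    d <- sqrt(rowSums(sweep(points, 2, cc)^2))
    inside <- which(d < r - tol)
    if (length(setdiff(inside, v)) > 0) return(FALSE)
  }
  TRUE
}

# naive R implementation of the quadrant-based 2D two-sample KS statistic
mks_stat_oracle <- function(a, b) {
  quad_frac <- function(pts, x0, y0) {
    # strict quadrants; boundary points count for neither quadrant
    c(sum(pts[, 1] < x0 & pts[, 2] < y0),
      sum(pts[, 1] < x0 & pts[, 2] > y0),
      sum(pts[, 1] > x0 & pts[, 2] < y0),
      sum(pts[, 1] > x0 & pts[, 2] > y0)) / nrow(pts)
  }
  cond_max <- function(cond) {
    mx <- 0
    for (i in seq_len(nrow(cond))) {
      d <- abs(quad_frac(a, cond[i, 1], cond[i, 2]) -
               quad_frac(b, cond[i, 1], cond[i, 2]))
      mx <- max(mx, d)
    }
    mx
  }
  (cond_max(a) + cond_max(b)) / 2
}

# direct KL formula on two probability vectors
kl_formula <- function(p, q) sum(p * log(p / q))

# wrap fixed probability vectors as a degenerate posterior sample set
as_posterior <- function(vectors, dim = c(length(vectors[[1]]), 1),
                         genotype = "manual") {
  structure(
    list(samples = do.call(rbind, vectors), dim = as.integer(dim),
         alpha_prior = 1, n_samples = length(vectors), method = "direct",
         seed = 0L, genotype = genotype),
    class = "posterior_sample_set"
  )
}

# a unit-edge regular tetrahedron (closed-form volume 1/(6*sqrt(2)))
unit_tetrahedron <- function() {
  rbind(c(0, 0, 0),
        c(1, 0, 0),
        c(0.5, sqrt(3) / 2, 0),
        c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
}

random_cloud <- function(n, seed) {
  set.seed(seed)
  matrix(rnorm(3 * n, sd = 10), ncol = 3)
}
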