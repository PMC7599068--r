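#' Two-sample multivariate (2D) Kolmogorov-Smirnov permutation test
#'
#' A two-dimensional two-sample KS statistic in the Fasano-Franceschini
#' sense: at every data point of a conditioning sample, the probability
#' content of the four axis-aligned quadrants anchored there is compared
#' between the two samples; the statistic `k` is the maximum absolute
#' difference, conditioned on each sample in turn and averaged over the
#' two. `k` lies in `[0, 1]`: 0 for identical samples, 1 when the samples
#' occupy disjoint quadrants. Because bin coordinates are heavily tied, the
#' p-value comes from label permutations (exact under exchangeability)
#' rather than any asymptotic null.
#'
#' @param sample_a,sample_b Two-column matrices or data frames of
#'   coordinates; binned cell tables (with `z_bin`, `x_bin` columns) are
#'   accepted directly. Each sample needs at least 5 points.
#' @param n_perm Number of label permutations (>= 99; default 999).
#' @param seed Seed for the permutation shuffles.
#' @return A list with `k`, `p` (permutation p-value,
#'   `(1 + #{perm >= k}) / (n_perm + 1)`), `n_perm`, `n_a`, `n_b`.
#' @export
mks_test <- function(sample_a, sample_b, n_perm = 999, seed = 1L) {
  a <- as_pair_matrix(sample_a)
  b <- as_pair_matrix(sample_b)
  if (nrow(a) < 5 || nrow(b) < 5) {
    stop("each sample needs at least 5 points", call. = FALSE)
  }
  if (n_perm < 99) stop("n_perm must be at least 99", call. = FALSE)
  res <- .mks_cpp(a[, 1], a[, 2], b[, 1], b[, 2],
                  as.integer(n_perm), split_seed(seed, "mks"))
  k <- res$k
  p <- (1 + sum(res$perm >= k - 1e-12)) / (n_perm + 1)
  list(k = k, p = p, n_perm = as.integer(n_perm),
       n_a = nrow(a), n_b = nrow(b))
}

as_pair_matrix <- function(x) {
  if (is.data.frame(x) && all(c("z_bin", "x_bin") %in% names(x))) {
    x <- cbind(x$z_bin, x$x_bin)
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 2 || !all(is.finite(x))) {
    stop("samples must be finite two-column coordinate matrices",
         call. = FALSE)
  }
  x
}
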