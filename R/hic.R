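# Hi-C matrix balancing, normalization, observed/expected, coarsening,
# virtual 4C extraction and BRICK signal comparison. Matrices are plain
# symmetric numeric matrices; missing data are NA (never zero — zeros are
# real contact counts).

check_hic <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) abort("Hi-C matrix must be square.")
  if (any(abs(m - t(m)) > tol * (1 + abs(m)), na.rm = TRUE)) {
    abort("Hi-C matrix must be symmetric.")
  }
  invisible(m)
}

#' Knight-Ruiz style matrix balancing
#'
#' Finds a positive per-bin scale vector `x` such that
#' `diag(x) %*% m %*% diag(x)` has unit row sums over unmasked bins (doubly
#' stochastic), by symmetric iterative proportional scaling
#' (`x <- x / sqrt(rowsums)`). Bins whose row is all zero (or all missing) are
#' masked first and receive `NA`.
#'
#' @param m Symmetric non-negative matrix; `NA` marks missing entries.
#' @param tolerance Maximum allowed deviation of unmasked row sums from 1.
#' @param max_iterations Iteration cap; non-convergence is an error carrying
#'   the last residual.
#' @return A list: `x` (scale vector, `NA` on masked bins), `balanced`
#'   (matrix), `iterations`, `residual`.
#' @export
#' @examples
#' kr_balance(matrix(c(2, 1, 1, 2), 2))$x * sqrt(3)  # c(1, 1)
kr_balance <- function(m, tolerance = 1e-10, max_iterations = 10000L) {
  check_hic(m)
  if (any(m < 0, na.rm = TRUE)) abort("Hi-C matrix must be non-negative.")
  n <- nrow(m)
  active <- vapply(seq_len(n), function(i) any(m[i, ] > 0, na.rm = TRUE), TRUE)
  if (!any(active)) abort("All bins are masked.")
  a <- m[active, active, drop = FALSE]
  a[is.na(a)] <- 0

  x <- rep(1, nrow(a))
  res <- Inf
  for (it in seq_len(max_iterations)) {
    r <- x * as.vector(a %*% x)  # row sums of diag(x) a diag(x)
    res <- max(abs(r - 1))
    if (res <= tolerance) break
    x <- x / sqrt(r)
  }
  if (res > tolerance) {
    abort(sprintf("KR balancing did not converge in %d iterations (residual %.3g).",
                  max_iterations, res))
  }

  xf <- rep(NA_real_, n); xf[active] <- x
  bal <- m * outer(xf, xf)
  list(x = xf, balanced = bal, iterations = it, residual = res)
}

#' Apply a per-bin normalization vector
#'
#' `out[i, j] = m[i, j] / (k_i * k_j)`; bins with missing or zero `k` are
#' masked (row and column set to `NA`).
#'
#' @param m Symmetric matrix.
#' @param k Per-bin normalization vector of length `nrow(m)`.
#' @return The normalized matrix.
#' @export
apply_normalization <- function(m, k) {
  check_hic(m)
  if (length(k) != nrow(m)) abort("`k` must have one entry per bin.")
  k[!is.na(k) & k == 0] <- NA
  if (all(is.na(k))) abort("All bins are masked by the normalization vector.")
  m / outer(k, k)
}

#' Observed/expected transformation with a clamped expected vector
#'
#' Divides each entry by the expected contact value at its distance,
#' `max(e[|i - j| + 1], clamp_floor)`: expected values below the clamp floor
#' (1 by convention) are raised to it, avoiding inflation of long-range
#' values where the expected signal is tiny.
#'
#' @param m Symmetric matrix.
#' @param e Expected value per distance (index 1 = distance 0); must cover
#'   every occurring distance.
#' @param clamp_floor Lower clamp applied to `e` (default 1).
#' @return The O/E matrix.
#' @export
observed_expected <- function(m, e, clamp_floor = 1) {
  check_hic(m)
  n <- nrow(m)
  if (length(e) < n) abort("Expected vector does not cover all distances.")
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  m / pmax(matrix(e[d + 1], n, n), clamp_floor)
}

#' Empirical expected vector (mean contact per distance)
#'
#' @param m Symmetric matrix.
#' @return Numeric vector: mean of non-missing entries at each distance
#'   `0..n-1`.
#' @export
expected_vector <- function(m) {
  check_hic(m)
  n <- nrow(m)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  vapply(0:(n - 1), function(dd) mean(m[d == dd], na.rm = TRUE), numeric(1))
}

#' Coarsen a matrix by block summation
#'
#' Sums `factor x factor` sub-matrices (e.g. 40 kb bins to 400 kb with
#' `factor = 10`); trailing partial blocks are summed as-is. Missing entries
#' are absent from the sum; a fully missing block stays missing.
#'
#' @param m Symmetric matrix.
#' @param factor Coarsening factor (>= 2).
#' @return The coarsened matrix.
#' @export
coarsen <- function(m, factor = 10L) {
  if (factor < 2) abort("`factor` must be >= 2.")
  check_hic(m)
  n <- nrow(m)
  grp <- (seq_len(n) - 1L) %/% factor
  nb <- max(grp) + 1L
  out <- matrix(NA_real_, nb, nb)
  for (i in seq_len(nb)) {
    ri <- which(grp == i - 1L)
    for (j in i:nb) {
      block <- m[ri, which(grp == j - 1L), drop = FALSE]
      if (!all(is.na(block))) out[i, j] <- out[j, i] <- sum(block, na.rm = TRUE)
    }
  }
  out
}

#' Virtual 4C track: one viewpoint row of a Hi-C matrix
#'
#' Extracts the matrix row of the viewpoint bin as a per-bin contact track;
#' the viewpoint bin itself is masked and missing bins propagate as missing.
#'
#' @param m Symmetric matrix.
#' @param viewpoint_bin 1-based bin index of the viewpoint.
#' @return Numeric per-bin track.
#' @export
virtual_4c <- function(m, viewpoint_bin) {
  check_hic(m)
  if (viewpoint_bin < 1 || viewpoint_bin > nrow(m)) abort("Viewpoint bin out of range.")
  track <- m[viewpoint_bin, ]
  track[viewpoint_bin] <- NA
  track
}

#' Compare Hi-C signal in selected vs non-selected BRICKs
#'
#' Each BRICK is quantified by the mean virtual-4C signal over the bins whose
#' midpoint falls inside it (non-missing bins only); the two groups of
#' per-BRICK means are compared by a Welch two-sided t-test. Identical groups
#' (zero pooled variance) give t = 0, p = 1. With `per_bin = TRUE`, bin
#' values are compared directly instead of per-BRICK means.
#'
#' @param track Virtual-4C per-bin track (see [virtual_4c()]).
#' @param bricks_selected,bricks_nonselected Tibbles with `start`, `end`
#'   (bp) on the track's chromosome.
#' @param bin_size Bin size of the track (bp); bin `i` covers
#'   `[(i-1) * bin_size, i * bin_size)`.
#' @param per_bin Compare per-bin values rather than per-BRICK means.
#' @return A one-row tibble: `mean_selected`, `mean_nonselected`,
#'   `t_statistic`, `p`, `n_selected`, `n_nonselected`, `n_bins`,
#'   `frac_bins_used` (fraction of covered bins that are non-missing).
#' @export
compare_brick_signal <- function(track, bricks_selected, bricks_nonselected,
                                 bin_size, per_bin = FALSE) {
  mids <- (seq_along(track) - 0.5) * bin_size
  brick_values <- function(bricks) {
    lapply(seq_len(nrow(bricks)), function(i) {
      v <- track[mids >= bricks$start[i] & mids < bricks$end[i]]
      v
    })
  }
  sel <- brick_values(bricks_selected)
  non <- brick_values(bricks_nonselected)
  n_bins <- sum(lengths(sel)) + sum(lengths(non))
  n_used <- sum(!is.na(unlist(c(sel, non))))

  summarize_group <- function(vals) {
    if (per_bin) {
      v <- unlist(vals); v[!is.na(v)]
    } else {
      v <- vapply(vals, function(x) mean(x, na.rm = TRUE), numeric(1))
      v[!is.nan(v) & !is.na(v)]
    }
  }
  a <- summarize_group(sel)
  b <- summarize_group(non)
  if (length(a) < 2L || length(b) < 2L) {
    abort("Each group needs at least 2 BRICKs with usable Hi-C bins.")
  }
  if (var(a) == 0 && var(b) == 0 && mean(a) == mean(b)) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- t.test(a, b)
  }
  tibble(mean_selected = mean(a), mean_nonselected = mean(b),
         t_statistic = unname(tt$statistic), p = tt$p.value,
         n_selected = length(a), n_nonselected = length(b),
         n_bins = n_bins,
         frac_bins_used = if (n_bins > 0) n_used / n_bins else NA_real_)
}
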