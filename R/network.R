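# Network hit-set connectivity: K-function over shortest-path distances with
# a weight-permutation null.

edges_to_graph <- function(edges, weights = NULL) {
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE,
                                     vertices = if (!is.null(weights)) weights$vertex)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (igraph::vcount(g) == 0L) abort("The network is empty.")
  g
}

#' Pairwise shortest-path distances of an undirected network
#'
#' Unweighted breadth-first shortest paths; unreachable pairs are `Inf` and
#' never satisfy any distance threshold.
#'
#' @param edges A two-column tibble (or data frame) of undirected edges.
#' @param vertices Optional character vector fixing the vertex set (isolated
#'   vertices included).
#' @return A symmetric numeric matrix of path lengths.
#' @export
shortest_path_distances <- function(edges, vertices = NULL) {
  g <- edges_to_graph(edges,
                      weights = if (!is.null(vertices)) tibble(vertex = vertices))
  igraph::distances(g, algorithm = "unweighted")
}

#' Network K-function of a weighted hit set
#'
#' For vertex weights `p_i` (hit indicators or confidences) with mean `pbar`,
#' `K(s) = (2 / (n * pbar)) * sum_i p_i * sum_{j != i} (p_j - pbar) *
#' 1[d(i, j) <= s]` for `s = 1..D`, `D` the largest finite shortest-path
#' distance. Positive values mean hits cluster closer than the network
#' average; constant weights give `K` identically 0. The area under the curve
#' `AUK = sum_s K(s)` is the scalar connectivity summary.
#'
#' @param edges Two-column edge tibble.
#' @param weights Tibble `vertex`, `weight` covering every vertex (isolated
#'   vertices allowed); weights in `[0, 1]`.
#' @return A `knet_result`: `k` (tibble `s`, `k`), `auk`, `n_vertices`,
#'   `mean_weight`; `p_value` is `NA` until [knet_pvalue()].
#' @export
knet_curve <- function(edges, weights) {
  weights <- as_tibble(weights)
  g <- edges_to_graph(edges, weights)
  w <- weights$weight[match(igraph::V(g)$name, weights$vertex)]
  if (any(is.na(w))) abort("Every vertex needs a weight.")
  if (all(w == 0)) abort("At least one positive weight is required.")
  n <- length(w)
  pbar <- mean(w)
  degenerate <- stats::var(w) == 0
  if (degenerate) warn("All weights equal: K is identically 0 and the permutation null is degenerate.")

  d <- igraph::distances(g, algorithm = "unweighted")
  finite <- is.finite(d) & d > 0
  D <- if (any(finite)) max(d[finite]) else 0L
  ks <- vapply(seq_len(max(D, 1L)), function(s) {
    ind <- finite & d <= s
    (2 / (n * pbar)) * sum(w * (ind %*% (w - pbar)))
  }, numeric(1))
  if (D == 0L) ks <- numeric(0)

  structure(list(k = tibble(s = seq_along(ks), k = ks), auk = sum(ks),
                 n_vertices = n, mean_weight = pbar, p_value = NA_real_,
                 n_perm = NA_integer_, seed = NA_integer_,
                 degenerate = degenerate),
            class = "knet_result")
}

# AUK as a quadratic form: auk = (2/(n pbar)) * w' W (w - pbar), where
# W_ij = D - d_ij + 1 for finite positive d_ij. Used for fast permutation.
auk_kernel <- function(d) {
  finite <- is.finite(d) & d > 0
  D <- if (any(finite)) max(d[finite]) else 0
  W <- matrix(0, nrow(d), ncol(d))
  W[finite] <- D - d[finite] + 1
  W
}

#' Permutation significance of the Knet connectivity
#'
#' Null model: the vertex weights are permuted over the fixed graph. For
#' `mode = "monte_carlo"`, `p = (1 + #[perm AUK >= observed]) / (1 + n_perm)`.
#' For `mode = "exhaustive"` (binary hit weights only) the exact fraction of
#' all distinct hit-set placements with AUK at least the observed one,
#' including the observed placement.
#'
#' @param edges Two-column edge tibble.
#' @param weights Tibble `vertex`, `weight`.
#' @param n_perm Number of permutations (default 1e4).
#' @param seed Integer seed.
#' @param mode `"monte_carlo"` (default) or `"exhaustive"`.
#' @return A `knet_result` with `p_value`, `n_perm`, `seed` filled.
#' @export
knet_pvalue <- function(edges, weights, n_perm = 10000L, seed = 1L,
                        mode = c("monte_carlo", "exhaustive")) {
  mode <- match.arg(mode)
  res <- knet_curve(edges, weights)
  weights <- as_tibble(weights)
  g <- edges_to_graph(edges, weights)
  w <- weights$weight[match(igraph::V(g)$name, weights$vertex)]
  n <- length(w); pbar <- mean(w)
  d <- igraph::distances(g, algorithm = "unweighted")
  W <- auk_kernel(d)
  auk_of <- function(wv) (2 / (n * pbar)) * sum(wv * (W %*% (wv - pbar)))

  if (res$degenerate) {
    res$p_value <- 1
    res$n_perm <- if (mode == "monte_carlo") as.integer(n_perm) else NA_integer_
    res$seed <- as.integer(seed)
    return(res)
  }

  if (mode == "exhaustive") {
    if (!all(w %in% c(0, 1))) abort("Exhaustive mode requires binary hit weights.")
    m <- sum(w)
    if (choose(n, m) > 1e6) {
      abort("More than 1e6 placements; use mode = 'monte_carlo'.")
    }
    combos <- utils::combn(n, m)
    auks <- apply(combos, 2, function(idx) {
      wv <- numeric(n); wv[idx] <- 1
      auk_of(wv)
    })
    res$p_value <- mean(auks >= res$auk - 1e-12)
    res$n_perm <- NA_integer_
  } else {
    if (n_perm < 1) abort("`n_perm` must be >= 1.")
    set.seed(seed)
    P <- vapply(seq_len(n_perm), function(i) sample(w), numeric(n))
    perm_auks <- (2 / (n * pbar)) * colSums(P * (W %*% (P - pbar)))
    res$p_value <- (1 + sum(perm_auks >= res$auk - 1e-12)) / (1 + n_perm)
    res$n_perm <- as.integer(n_perm)
  }
  res$seed <- as.integer(seed)
  res
}

#' @export
print.knet_result <- function(x, ...) {
  cat(sprintf("<knet_result> %d vertices, mean weight %.3f, AUK %.4f",
              x$n_vertices, x$mean_weight, x$auk))
  if (!is.na(x$p_value)) cat(sprintf(", p = %.4g", x$p_value))
  cat("\n")
  invisible(x)
}
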