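# Domainogram BRICK calling: rank transform, window tail probabilities under
# the sum-of-uniforms null, greedy maximal-segment selection, permutation FDR.

# Cumulant generating function of Uniform(0,1) and derivatives, stable near 0
# and for large arguments.
unif_cgf <- function(th) log(expm1(abs(th))) - log(abs(th)) + pmin(th, 0)
unif_cgf_d1 <- function(th) {
  small <- abs(th) < 1e-4
  out <- 0.5 + th / 12 - th^3 / 720
  out[!small] <- 1 / (1 - exp(-th[!small])) - 1 / th[!small]
  out
}
unif_cgf_d2 <- function(th) {
  small <- abs(th) < 1e-4
  out <- rep(1 / 12, length(th)) - th^2 / 240
  e <- exp(-abs(th[!small]))
  out[!small] <- 1 / th[!small]^2 - e / (1 - e)^2
  out
}

# Lugannani-Rice saddlepoint upper tail for the mean m = s/w in [0.5, 1);
# w may be a vector aligned with m (the saddlepoint itself depends on m only).
saddlepoint_upper <- function(m, w) {
  lo <- rep(0, length(m))
  hi <- 1.2 / (1 - m) + 25
  for (i in seq_len(52L)) {
    mid <- (lo + hi) / 2
    high <- unif_cgf_d1(mid) > m
    hi[high] <- mid[high]
    lo[!high] <- mid[!high]
  }
  th <- (lo + hi) / 2
  p <- rep(0.5, length(m))
  pos <- th > 1e-7
  if (any(pos)) {
    tp <- th[pos]; mp <- m[pos]
    wp <- if (length(w) == 1L) w else w[pos]
    zw <- sqrt(pmax(2 * wp * (tp * mp - unif_cgf(tp)), 0))
    u <- tp * sqrt(wp * unif_cgf_d2(tp))
    p[pos] <- pnorm(zw, lower.tail = FALSE) + dnorm(zw) * (1 / u - 1 / zw)
  }
  pmin(pmax(p, 0), 1)
}

# Upper tail for sums with per-element widths; batches the saddlepoint solve
# across widths (one bisection for all windows of a scan).
tail_by_width <- function(s, w) {
  p <- numeric(length(s))
  small <- w <= 12L
  for (ws in unique(w[small])) {
    idx <- which(w == ws)
    p[idx] <- uniform_sum_tail(s[idx], ws)
  }
  big <- which(!small)
  if (length(big)) {
    m <- s[big] / w[big]
    pb <- numeric(length(big))
    pb[m <= 0] <- 1
    up <- m >= 0.5 & m < 1
    dn <- m > 0 & m < 0.5
    if (any(up)) pb[up] <- saddlepoint_upper(m[up], w[big][up])
    if (any(dn)) pb[dn] <- 1 - saddlepoint_upper(1 - m[dn], w[big][dn])
    p[big] <- pb
  }
  p
}

#' Upper tail of a sum of w standard uniform ranks
#'
#' Null distribution of a domainogram window sum: `w` independent
#' Uniform(0,1] variables. Exact Irwin-Hall closed form for `w <= 12` (the
#' alternating-sum formula, numerically safe at these widths); for larger
#' windows the Lugannani-Rice saddlepoint approximation to the Irwin-Hall
#' tail, which is strictly positive, monotone and accurate to well under 1%
#' relative error from the bulk into the far tail (a plain Gaussian with mean
#' `w/2`, variance `w/12` errs by >30% already at p ~ 1e-4 for w = 30).
#'
#' @param s Observed window sum(s) (vectorized).
#' @param w Window width (single integer >= 1).
#' @return `P(S_w >= s)` for each element of `s`.
#' @export
#' @examples
#' uniform_sum_tail(1.8, 2)  # (2 - 1.8)^2 / 2 = 0.02
uniform_sum_tail <- function(s, w) {
  if (w < 1) abort("Window width must be >= 1.")
  if (w <= 12L) {
    t <- w - s
    p <- numeric(length(s))
    p[t >= w] <- 1
    mid <- t > 0 & t < w
    if (any(mid)) {
      tm <- t[mid]
      acc <- numeric(length(tm))
      for (k in 0:floor(max(tm))) {
        use <- tm >= k
        acc[use] <- acc[use] + (-1)^k * choose(w, k) * (tm[use] - k)^w
      }
      p[mid] <- acc / factorial(w)
    }
    return(pmin(pmax(p, 0), 1))
  }
  m <- s / w
  p <- numeric(length(s))
  p[m <= 0] <- 1
  p[m >= 1] <- 0
  upper <- m >= 0.5 & m < 1
  lower <- m > 0 & m < 0.5
  if (any(upper)) p[upper] <- saddlepoint_upper(m[upper], w)
  # symmetry of the Irwin-Hall density about w/2
  if (any(lower)) p[lower] <- 1 - saddlepoint_upper(1 - m[lower], w)
  p
}

#' Upper-tail p-value of one domainogram window
#'
#' @param ranks Vector of scaled ranks in (0, 1].
#' @param start 1-based start index of the window.
#' @param width Window width in fragments.
#' @return The Irwin-Hall upper-tail probability of the window's rank sum.
#' @export
window_pvalue <- function(ranks, start, width) {
  if (width < 1) abort("Window width must be >= 1.")
  if (start < 1 || start + width - 1 > length(ranks)) abort("Window outside the rank vector.")
  uniform_sum_tail(sum(ranks[start:(start + width - 1)]), width)
}

#' Rank-transform a profile genome-wide
#'
#' Scaled average ranks of the unmasked signal densities, pooled across all
#' chromosomes (cis and trans share one pool, matching a single calling
#' threshold for both): `rank / n` in (0, 1]. Masked fragments carry no rank.
#'
#' With `midrank = TRUE` the continuity-corrected scaling `(rank - 0.5) / n`
#' is used instead. The domainogram scan uses this form: with `rank / n` the
#' maximum fragment has rank exactly 1 and its width-1 window gets p = 0 — a
#' guaranteed "infinitely significant" call in every dataset and every
#' permutation, which distorts FDR count ratios when true BRICKs are few. The
#' midrank gives the top fragment its honest discrete tail probability
#' `~ 0.5/n`.
#'
#' @param profile A `fourc_profile`.
#' @param midrank Use the continuity-corrected `(rank - 0.5) / n` scaling.
#' @return The profile with a `rank` column (`NA` where masked).
#' @export
rank_transform <- function(profile, midrank = FALSE) {
  ok <- !profile$masked
  if (sum(ok) < 2L) abort("Need at least 2 unmasked fragments.")
  v <- profile$density[ok]
  if (max(v) == min(v)) abort("degenerate signal: all unmasked values identical")
  profile$rank <- NA_real_
  shift <- if (midrank) 0.5 else 0
  profile$rank[ok] <- (rank(v, ties.method = "average") - shift) / length(v)
  profile
}

# Per-chromosome runs of unmasked fragments, in genomic order.
profile_runs <- function(profile) {
  ok <- !profile$masked
  lapply(split(which(ok), profile$chrom[ok]), function(i) {
    list(start = profile$start[i], end = profile$end[i], idx = i)
  })
}

# Scan all (start, width) windows of rank runs; keep windows with p below
# p_cut, prefiltered by critical sums when supplied. Candidate sums are
# collected first and their tail probabilities computed in one batched call:
# this sits inside the permutation loop.
scan_windows <- function(rank_runs, w_max, p_cut = Inf, crit = NULL) {
  a_ch <- character(0); a_pos <- integer(0); a_w <- integer(0)
  a_start <- numeric(0); a_end <- numeric(0); a_sum <- numeric(0)
  for (chrom in names(rank_runs)) {
    run <- rank_runs[[chrom]]
    r <- run$rank; n <- length(r)
    if (n == 0L) next
    cs <- cumsum(c(0, r))
    for (w in seq_len(min(w_max, n))) {
      s <- cs[(w + 1L):(n + 1L)] - cs[1L:(n - w + 1L)]
      keep <- if (!is.null(crit)) which(s >= crit[w]) else seq_along(s)
      if (!length(keep)) next
      a_ch <- c(a_ch, rep(chrom, length(keep)))
      a_pos <- c(a_pos, keep); a_w <- c(a_w, rep(w, length(keep)))
      a_start <- c(a_start, run$start[keep]); a_end <- c(a_end, run$end[keep + w - 1L])
      a_sum <- c(a_sum, s[keep])
    }
  }
  a_p <- tail_by_width(a_sum, a_w)
  sel <- which(a_p < p_cut)
  tibble(chrom = a_ch[sel], pos = a_pos[sel], width = a_w[sel],
         start = a_start[sel], end = a_end[sel], sum = a_sum[sel], p = a_p[sel])
}

# Critical window sums: smallest s with P(S_w >= s) <= p_cut, per width.
# Memoized per p_cut: the inversion is by far the most expensive part of a
# scan and identical across permutations and seeds.
crit_cache <- new.env(parent = emptyenv())
critical_sums <- function(w_max, p_cut) {
  key <- sprintf("p%.17g", p_cut)
  cached <- crit_cache[[key]]
  if (!is.null(cached) && length(cached) >= w_max) return(cached[seq_len(w_max)])
  from <- length(cached) + 1L
  more <- vapply(from:w_max, function(w) {
    if (uniform_sum_tail(w, w) >= p_cut) return(w + 1)  # unreachable width
    stats::uniroot(function(s) uniform_sum_tail(s, w) - p_cut,
                   lower = 0, upper = w, tol = 1e-10)$root
  }, numeric(1))
  crit_cache[[key]] <- c(cached, more)
  crit_cache[[key]]
}

#' Build a multi-scale domainogram
#'
#' Evaluates the upper-tail p-value of every window of width `1..w_max` over
#' the unmasked fragments of each chromosome, using sliding sums of the
#' genome-wide scaled ranks. The width-1 row equals the per-fragment rank
#' tail probabilities.
#'
#' @param profile A rank-transformed `fourc_profile` (see [rank_transform()];
#'   applied automatically, with the midrank scaling, if the `rank` column is
#'   absent).
#' @param w_max Maximum window width in fragments (default 301); clipped with
#'   a warning where it exceeds a chromosome's unmasked fragment count.
#' @return A `domainogram` tibble: `chrom`, `pos` (index within the
#'   chromosome's unmasked run), `width`, `start`/`end` (bp), `sum`, `p`.
#' @export
build_domainogram <- function(profile, w_max = 301L) {
  if (w_max < 1) abort("`w_max` must be >= 1.")
  if (!("rank" %in% names(profile))) profile <- rank_transform(profile, midrank = TRUE)
  runs <- profile_runs(profile)
  for (chrom in names(runs)) {
    i <- runs[[chrom]]$idx
    runs[[chrom]]$rank <- profile$rank[i]
    if (w_max > length(i)) {
      warn(sprintf("w_max clipped to %d on %s.", length(i), chrom))
    }
  }
  dom <- scan_windows(runs, w_max, p_cut = Inf)
  structure(dom, class = c("domainogram", class(dom)), w_max = w_max)
}

#' Call BRICKs from a domainogram
#'
#' Candidate windows with `p < p_threshold` are accepted greedily by ascending
#' p-value (ties: wider window first, then leftmost); each accepted window
#' removes all overlapping candidates. Accepted windows become BRICKs —
#' non-overlapping significantly interacting intervals.
#'
#' @param domainogram A `domainogram` from [build_domainogram()] (or any
#'   tibble with `chrom`, `pos`, `width`, `start`, `end`, `p`).
#' @param p_threshold Calling threshold in (0, 1), default 0.01.
#' @return A `bricks` tibble: `chrom`, `start`, `end` (bp half-open), `p`,
#'   `width` (fragments).
#' @export
call_bricks <- function(domainogram, p_threshold = 0.01) {
  if (p_threshold <= 0 || p_threshold >= 1) abort("`p_threshold` must be in (0, 1).")
  cand <- domainogram[domainogram$p < p_threshold, , drop = FALSE]
  empty <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  p = numeric(), width = integer())
  if (nrow(cand) == 0L) return(structure(empty, class = c("bricks", class(empty))))

  cand <- cand[order(cand$p, -cand$width, cand$chrom, cand$pos), ]
  v_ch <- cand$chrom; v_lo <- cand$pos; v_hi <- cand$pos + cand$width - 1L
  acc_lo <- list(); acc_hi <- list()
  keep <- logical(nrow(cand))
  for (i in seq_along(v_ch)) {
    ch <- v_ch[i]
    if (!any(acc_lo[[ch]] <= v_hi[i] & acc_hi[[ch]] >= v_lo[i])) {
      keep[i] <- TRUE
      acc_lo[[ch]] <- c(acc_lo[[ch]], v_lo[i])
      acc_hi[[ch]] <- c(acc_hi[[ch]], v_hi[i])
    }
  }
  out <- cand[keep, c("chrom", "start", "end", "p", "width")]
  out <- out[order(out$chrom, out$start), ]
  structure(as_tibble(out), class = c("bricks", c("tbl_df", "tbl", "data.frame")))
}

#' Permutation false discovery rate for BRICK calling
#'
#' Estimates, for each calling threshold, the expected fraction of false
#' BRICKs by genome-wide permutation of the unmasked profile values: each
#' permutation shuffles the (pre-smoothing) values, re-applies the smoothing
#' window if one is used, and re-runs rank transform, domainogram and greedy
#' BRICK selection. Re-smoothing inside the permutation preserves the
#' autocorrelation the smoothing induces, which a post-hoc value shuffle would
#' destroy — without it the null is anti-conservative.
#'
#' The estimate uses the add-one permutation convention,
#' `FDR(theta) = ((1 + total permuted BRICK count) / (n_perm + 1)) /
#' observed count` (0 observed -> 0 or 1 by whether permutations also found
#' nothing; capped at 1; monotonized so the estimate never increases as the
#' threshold tightens). The add-one term keeps a lone extreme observed window
#' from certifying itself against a finite permutation sample; it also sets
#' the estimator's resolution — certifying FDR <= f requires at least
#' `1 / (f * (n_perm + 1))` observed BRICKs, e.g. >= 50 permutations to place
#' two BRICKs in a 1% tier. The tier threshold for e.g. FDR <= 1% is the
#' largest theta in the grid meeting the tier; BRICKs are reported with the
#' smallest tier they satisfy.
#'
#' @param profile A corrected, unsmoothed `fourc_profile`.
#' @param thresholds Decreasing grid of calling thresholds.
#' @param n_perm Number of permutations (>= 10; default 20).
#' @param seed Integer seed for the permutations.
#' @param w_max Maximum domainogram window width (default 301).
#' @param smooth_window Odd smoothing window applied before ranking, to the
#'   observed and to every permuted profile alike (`NULL` = no smoothing).
#' @param tiers FDR tiers to calibrate (default 1% and 10%).
#' @return A `brick_fdr` object: `fdr` (tibble `threshold`, `observed`,
#'   `perm_mean`, `fdr`), `tiers` (tibble `fdr_tier`, `threshold`,
#'   `n_bricks`), `bricks` (tier-labelled `bricks` tibble), plus `n_perm`,
#'   `seed`.
#' @export
estimate_fdr <- function(profile,
                         thresholds = c(1e-2, 3e-3, 1e-3, 3e-4, 1e-4, 3e-5, 1e-5, 1e-6),
                         n_perm = 20L, seed = 1L, w_max = 301L,
                         smooth_window = NULL, tiers = c(0.01, 0.10)) {
  if (n_perm < 10L) abort("`n_perm` must be >= 10.")
  thresholds <- sort(thresholds, decreasing = TRUE)
  p_cut <- max(thresholds)

  runs <- profile_runs(profile)
  vals0 <- lapply(runs, function(r) profile$density[r$idx])
  n_unmasked <- sum(lengths(vals0))
  crit <- critical_sums(min(w_max, n_unmasked), p_cut)

  prepare <- function(vals_by_chrom) {
    if (!is.null(smooth_window)) {
      vals_by_chrom <- lapply(vals_by_chrom, running_mean, window = smooth_window)
    }
    all_ranks <- (rank(unlist(vals_by_chrom, use.names = FALSE),
                       ties.method = "average") - 0.5) / n_unmasked
    split_ranks <- split(all_ranks, rep(names(vals_by_chrom), lengths(vals_by_chrom)))
    for (chrom in names(runs)) runs[[chrom]]$rank <- split_ranks[[chrom]]
    runs
  }
  count_at <- function(windows) {
    vapply(thresholds,
           function(th) nrow(call_bricks(windows, th)), numeric(1))
  }

  obs_windows <- scan_windows(prepare(vals0), w_max, p_cut, crit)
  observed <- count_at(obs_windows)

  set.seed(seed)
  flat <- unlist(vals0, use.names = FALSE)
  grp <- rep(names(vals0), lengths(vals0))
  perm_counts <- matrix(0, n_perm, length(thresholds))
  for (b in seq_len(n_perm)) {
    shuffled <- split(sample(flat), grp)[names(vals0)]
    perm_counts[b, ] <- count_at(scan_windows(prepare(shuffled), w_max, p_cut, crit))
  }
  perm_mean <- colMeans(perm_counts)
  perm_total <- colSums(perm_counts)

  fdr <- ifelse(observed == 0, ifelse(perm_total == 0, 0, 1),
                pmin(((1 + perm_total) / (n_perm + 1)) / observed, 1))
  fdr <- cummin(fdr)  # monotone: never increases as the threshold tightens

  tier_rows <- purrr::map_dfr(tiers, function(tier) {
    ok <- which(fdr <= tier)
    th <- if (length(ok)) thresholds[min(ok)] else NA_real_
    n_b <- if (is.na(th)) 0L else observed[min(ok)]
    tibble(fdr_tier = tier, threshold = th, n_bricks = as.integer(n_b))
  })

  bricks <- NULL
  tiers_sorted <- sort(tiers)
  for (tier in rev(tiers_sorted)) {  # loosest first
    th <- tier_rows$threshold[tier_rows$fdr_tier == tier]
    if (is.na(th)) next
    b <- call_bricks(obs_windows, th)
    if (is.null(bricks)) {
      bricks <- b
      bricks$fdr_tier <- rep(tier, nrow(b))
    } else {
      in_tighter <- paste(bricks$chrom, bricks$start) %in% paste(b$chrom, b$start)
      bricks$fdr_tier[in_tighter] <- tier
    }
  }
  if (is.null(bricks)) {
    bricks <- call_bricks(obs_windows[0, ], 0.5)
    bricks$fdr_tier <- numeric(0)
  }

  structure(list(
    fdr = tibble(threshold = thresholds, observed = observed,
                 perm_mean = perm_mean, fdr = fdr),
    tiers = tier_rows, bricks = bricks,
    n_perm = n_perm, seed = seed, smooth_window = smooth_window, w_max = w_max
  ), class = "brick_fdr")
}

#' @export
print.brick_fdr <- function(x, ...) {
  cat(sprintf("<brick_fdr> %d permutations, seed %d\n", x$n_perm, x$seed))
  print(x$tiers)
  invisible(x)
}
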