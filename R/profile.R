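# Profile construction: normalization, replicate combination, smoothing,
# distance-decay fit and correction.

new_profile <- function(df, stage, viewpoint, exclusion_radius, scale = NA_real_) {
  structure(df, class = c("fourc_profile", "tbl_df", "tbl", "data.frame"),
            stage = stage, viewpoint = viewpoint,
            exclusion_radius = exclusion_radius, scale = scale)
}

#' Normalize fragment counts to signal densities
#'
#' Converts per-fragment read counts to reads-per-`scale` densities:
#' `density_i = scale * count_i / total`, where the total is taken over
#' unmasked fragments, so unmasked densities sum exactly to `scale`. The mask
#' combines the viewpoint exclusion zone with blind fragments (no
#' secondary-enzyme site), which carry no signal into any downstream
#' statistic.
#'
#' @param counts A `fragment_counts` tibble from [assign_reads()].
#' @param scale Normalization total (default 1e6, i.e. reads per million).
#' @param mask_blind Mask fragments flagged invalid by [flag_validity()]
#'   (default `TRUE`; ignored when validity was never flagged).
#' @return A `fourc_profile` tibble: library columns plus `density` and
#'   `masked`.
#' @export
normalize_profile <- function(counts, scale = 1e6, mask_blind = TRUE) {
  stopifnot(inherits(counts, "fragment_counts"))
  vp <- attr(counts, "viewpoint")
  radius <- attr(counts, "exclusion_radius") %||% 1L

  masked <- counts$chrom == vp$chrom & abs(counts$frag - vp$frag) <= radius
  if (mask_blind && !all(is.na(counts$valid))) {
    masked <- masked | (!is.na(counts$valid) & !counts$valid)
  }
  total <- sum(counts$count[!masked])
  if (total == 0) abort("empty library: all unmasked counts are zero")

  df <- counts
  df$density <- scale * df$count / total
  df$masked <- masked
  df$count <- NULL
  class(df) <- c("tbl_df", "tbl", "data.frame")
  new_profile(df, "normalized", vp, radius, scale)
}

#' Combine replicate profiles by averaging
#'
#' Per-fragment arithmetic mean of signal densities across replicates built on
#' the identical fragment library.
#'
#' @param profiles A list of `fourc_profile` objects.
#' @return A combined `fourc_profile`.
#' @export
combine_replicates <- function(profiles) {
  stopifnot(length(profiles) >= 1L, all(vapply(profiles, inherits, TRUE, "fourc_profile")))
  ref <- profiles[[1]]
  for (p in profiles[-1]) {
    if (nrow(p) != nrow(ref) ||
        !all(p$chrom == ref$chrom & p$start == ref$start & p$end == ref$end)) {
      abort("Replicates were built on different fragment libraries.")
    }
  }
  out <- ref
  out$density <- rowMeans(vapply(profiles, function(p) p$density, numeric(nrow(ref))))
  new_profile(out, "combined", attr(ref, "viewpoint"),
              attr(ref, "exclusion_radius"), attr(ref, "scale"))
}

#' Local and global Spearman concordance between two profiles
#'
#' Rank correlation (average ranks for ties) between two replicate profiles,
#' computed globally over all jointly unmasked fragments and locally in
#' non-overlapping windows of `window` unmasked fragments per chromosome.
#' Windows with a constant vector have undefined correlation and are reported
#' as `NA`.
#'
#' @param profile_a,profile_b Two `fourc_profile` objects on the same library.
#' @param window Window size in fragments (default 29, the smoothing window).
#' @return A list: `global` (Spearman rho) and `windows`, a tibble with
#'   columns `chrom`, `start`, `end`, `n`, `rho`.
#' @export
local_spearman <- function(profile_a, profile_b, window = 29L) {
  if (nrow(profile_a) != nrow(profile_b) ||
      !all(profile_a$start == profile_b$start & profile_a$chrom == profile_b$chrom)) {
    abort("Profiles were built on different fragment libraries.")
  }
  ok <- !profile_a$masked & !profile_b$masked
  a <- profile_a$density[ok]; b <- profile_b$density[ok]
  spear <- function(x, y) {
    if (length(x) < 3L || sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y, method = "spearman")
  }
  global <- spear(a, b)

  sub <- profile_a[ok, ]
  sub$b_density <- b
  windows <- sub |>
    group_by(.data$chrom) |>
    mutate(win = (row_number() - 1L) %/% window) |>
    group_by(.data$chrom, .data$win) |>
    summarise(start = min(.data$start), end = max(.data$end), n = n(),
              rho = spear(.data$density, .data$b_density), .groups = "drop") |>
    select(-"win")
  list(global = global, windows = windows)
}

# Centered running mean with truncated (shrinking) windows at the edges.
running_mean <- function(x, window) {
  n <- length(x)
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Smooth a profile with a centered running mean
#'
#' Running mean over the sequence of unmasked fragments of each chromosome
#' (masked fragments are skipped, not averaged in). At chromosome edges the
#' window truncates to the available fragments. A constant profile is
#' preserved exactly; window 1 is the identity.
#'
#' @param profile A `fourc_profile`.
#' @param window Odd window size in fragments (default 29).
#' @return The smoothed `fourc_profile`.
#' @export
smooth_profile <- function(profile, window = 29L) {
  if (window < 1L || window %% 2L == 0L) abort("`window` must be odd and >= 1.")
  out <- profile
  for (chrom in unique(profile$chrom)) {
    i <- which(profile$chrom == chrom & !profile$masked)
    if (length(i)) out$density[i] <- running_mean(profile$density[i], window)
  }
  new_profile(out, "smoothed", attr(profile, "viewpoint"),
              attr(profile, "exclusion_radius"), attr(profile, "scale"))
}

#' Fit the cis distance-decay model with fixed slope -1
#'
#' Models the expected cis contact density as `exp(a) / d`, with `d` the
#' fragment rank distance to the viewpoint. With the slope pinned at -1 the
#' least-squares intercept on the log-log scale has the closed form
#' `a = mean(ln density + ln d)` over the fitted fragments (cis, unmasked,
#' nonzero signal). The trans background `b` is the mean density over unmasked
#' trans fragments. A free-slope diagnostic fit is reported but unused by the
#' correction.
#'
#' @param profile A `fourc_profile`.
#' @return A `decay_fit` object with fields `intercept`, `slope` (-1),
#'   `trans_background`, `n_fit`, `free_slope` and `viewpoint`.
#' @export
fit_decay <- function(profile) {
  vp <- attr(profile, "viewpoint")
  cis <- profile$chrom == vp$chrom
  d <- abs(profile$frag - vp$frag)
  fit_set <- cis & !profile$masked & profile$density > 0 & d >= 1
  if (sum(fit_set) < 2L) abort("No eligible cis fragments to fit the decay.")

  ld <- log(profile$density[fit_set])
  lr <- log(d[fit_set])
  a <- mean(ld + lr)
  free <- stats::coef(stats::lm(ld ~ lr))

  trans <- !cis & !profile$masked
  b <- if (any(trans)) mean(profile$density[trans]) else NA_real_

  structure(list(intercept = a, slope = -1, trans_background = b,
                 n_fit = sum(fit_set),
                 free_slope = unname(free[2]), viewpoint = vp),
            class = "decay_fit")
}

#' Expected density under a decay fit
#'
#' @param fit A `decay_fit`.
#' @param d Rank distance(s) >= 1.
#' @return Expected densities `exp(a) / d`.
#' @export
expected_decay <- function(fit, d) {
  stopifnot(inherits(fit, "decay_fit"))
  exp(fit$intercept) / pmax(d, 1)
}

#' Correct a profile for distance decay and trans background
#'
#' Cis fragments are divided by the fitted expectation `exp(a)/d`; trans
#' fragments by the mean trans background. Zeros map to zeros; a profile
#' generated exactly from the fitted model becomes identically 1. If the trans
#' background is zero the trans side is left unscaled and flagged in the
#' `trans_unscaled` attribute.
#'
#' @param profile A `fourc_profile`.
#' @param fit The `decay_fit` from the same profile's library.
#' @return The corrected (dimensionless) `fourc_profile`.
#' @export
correct_profile <- function(profile, fit) {
  stopifnot(inherits(fit, "decay_fit"))
  vp <- fit$viewpoint
  out <- profile
  cis <- profile$chrom == vp$chrom
  d <- pmax(abs(profile$frag - vp$frag), 1)
  out$density[cis] <- profile$density[cis] / expected_decay(fit, d[cis])
  trans_unscaled <- FALSE
  if (any(!cis)) {
    if (is.na(fit$trans_background) || fit$trans_background == 0) {
      trans_unscaled <- TRUE
    } else {
      out$density[!cis] <- profile$density[!cis] / fit$trans_background
    }
  }
  out <- new_profile(out, "corrected", vp, attr(profile, "exclusion_radius"))
  attr(out, "trans_unscaled") <- trans_unscaled
  out
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_fit> expected(d) = exp(%.4f)/d over %d fragments; trans background %.4g (free slope %.3f)\n",
    x$intercept, x$n_fit, x$trans_background, x$free_slope))
  invisible(x)
}
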