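make_counts <- function(counts, masked_valid = NULL, viewpoint_idx = 1L,
                        radius = 0L) {
  n <- length(counts)
  df <- tibble::tibble(chrom = "chrA", frag = seq_len(n) - 1L,
                       start = (seq_len(n) - 1L) * 10L, end = seq_len(n) * 10L,
                       valid = masked_valid %||% rep(NA, n), count = counts)
  structure(df, class = c("fragment_counts", "fragment_library",
                          "tbl_df", "tbl", "data.frame"),
            excluded = tibble::tibble(reason = c("self_ligated", "undigested"),
                                      n = c(0L, 0L)),
            viewpoint = df[viewpoint_idx, ], exclusion_radius = radius)
}

test_that("normalization scales to reads-per-million over unmasked fragments", {
  # viewpoint on fragment 4 with radius 0 masks only that fragment
  fc <- make_counts(c(2L, 0L, 8L, 0L), viewpoint_idx = 4L)
  prof <- normalize_profile(fc)
  expect_equal(prof$density[1:3], c(200000, 0, 800000))
  expect_equal(sum(prof$density[!prof$masked]), 1e6)

  set.seed(21)
  counts <- rpois(50, 5); counts[1] <- counts[1] + 1L
  fc2 <- make_counts(as.integer(counts), viewpoint_idx = 50L)
  prof2 <- normalize_profile(fc2)
  keep <- !prof2$masked
  expect_equal(prof2$density[keep] / 1e6, counts[keep] / sum(counts[keep]))

  expect_error(normalize_profile(make_counts(c(0L, 0L, 5L), viewpoint_idx = 3L)),
               "empty library")
})

test_that("blind fragments are masked out of the normalization total", {
  fc <- make_counts(c(5L, 5L, 10L), masked_valid = c(TRUE, FALSE, TRUE),
                    viewpoint_idx = 3L)
  prof <- normalize_profile(fc)
  expect_true(prof$masked[2])
  expect_equal(prof$density[1], 1e6)  # only fragment 1 is unmasked: 5/5
})

test_that("replicate combination averages densities and validates libraries", {
  fc <- make_counts(c(2L, 0L, 8L, 1L), viewpoint_idx = 4L)
  p1 <- normalize_profile(make_counts(c(0L, 2L, 0L, 1L), viewpoint_idx = 4L))
  p2 <- normalize_profile(make_counts(c(2L, 0L, 0L, 1L), viewpoint_idx = 4L))
  comb <- combine_replicates(list(p1, p2))
  expect_equal(comb$density[1:2], c(5e5, 5e5))
  expect_equal(combine_replicates(list(p1))$density, p1$density)
  expect_equal(combine_replicates(list(p1, p1))$density, p1$density)

  p3 <- normalize_profile(make_counts(c(1L, 1L), viewpoint_idx = 2L))
  expect_error(combine_replicates(list(p1, p3)), "different fragment libraries")
})

test_that("spearman concordance matches rank-then-pearson and handles ties", {
  a <- make_profile(c(1, 5, 3, 9, 2, 7, 4, 6))
  expect_equal(local_spearman(a, a, window = 4)$global, 1)
  b <- make_profile(10 - c(1, 5, 3, 9, 2, 7, 4, 6))  # strictly reversed order
  expect_equal(local_spearman(a, b, window = 4)$global, -1)

  set.seed(31)
  for (i in 1:5) {
    x <- sample(1:5, 30, replace = TRUE)  # ties
    y <- sample(1:5, 30, replace = TRUE)
    pa <- make_profile(as.numeric(x)); pb <- make_profile(as.numeric(y))
    oracle <- stats::cor(rank(x, ties.method = "average"),
                         rank(y, ties.method = "average"))
    expect_equal(local_spearman(pa, pb)$global, oracle)
  }

  # constant window reported as missing
  pc <- make_profile(c(rep(1, 5), 2, 3, 4, 5, 6))
  pd <- make_profile(c(1:5, 2, 3, 4, 5, 6))
  win <- local_spearman(pc, pd, window = 5)$windows
  expect_true(is.na(win$rho[1]))
})

test_that("smoothing is a truncated centered running mean", {
  prof <- make_profile(c(0, 3, 0, 3, 0))
  expect_equal(smooth_profile(prof, 3)$density, c(1.5, 1, 2, 1, 1.5))
  expect_equal(smooth_profile(prof, 1)$density, prof$density)
  const <- make_profile(rep(4, 9))
  expect_equal(smooth_profile(const, 5)$density, rep(4, 9))
  expect_error(smooth_profile(prof, 4), "odd")
  # masked fragments are skipped, not averaged in
  pm <- make_profile(c(0, 3, 100, 0, 3, 0), masked = c(rep(FALSE, 2), TRUE, rep(FALSE, 3)))
  expect_equal(smooth_profile(pm, 3)$density[-3], c(1.5, 1, 2, 1, 1.5))
})

test_that("decay fit recovers the closed-form intercept and exact power laws", {
  # exact 10/d profile: intercept ln 10, corrected identically 1
  d <- 1:50
  prof <- make_profile(c(5, 10 / d), masked = c(TRUE, rep(FALSE, 50)),
                       viewpoint_frag = 0L)
  fit <- fit_decay(prof)
  expect_equal(exp(fit$intercept), 10, tolerance = 1e-12)
  corr <- correct_profile(prof, fit)
  expect_equal(corr$density[-1], rep(1, 50), tolerance = 1e-12)

  # densities [8, 2] at distances [1, 2]
  prof2 <- make_profile(c(1, 8, 2), masked = c(TRUE, FALSE, FALSE))
  fit2 <- fit_decay(prof2)
  expect_equal(fit2$intercept, (log(8) + log(4)) / 2, tolerance = 1e-12)
  expect_equal(expected_decay(fit2, 1:2), c(exp(fit2$intercept), exp(fit2$intercept) / 2))
  expect_equal(correct_profile(prof2, fit2)$density[2:3],
               c(sqrt(2), 1 / sqrt(2)), tolerance = 1e-10)

  # zero-signal fragments do not move the fit
  prof3 <- make_profile(c(1, 8, 2, 0, 0), masked = c(TRUE, rep(FALSE, 4)))
  expect_equal(fit_decay(prof3)$intercept, fit2$intercept)

  expect_error(fit_decay(make_profile(c(1, 0, 0), masked = c(TRUE, FALSE, FALSE))),
               "eligible")
})

test_that("correction divides trans fragments by the trans background", {
  prof <- make_profile(c(1, 4, 2, 3, 3, 3), masked = c(TRUE, rep(FALSE, 5)),
                       chrom = c(rep("chrA", 3), rep("chrB", 3)))
  fit <- fit_decay(prof)
  expect_equal(fit$trans_background, 3)
  corr <- correct_profile(prof, fit)
  expect_equal(corr$density[4:6], c(1, 1, 1))
  # zeros map to zeros, in cis and trans alike
  prof0 <- make_profile(c(1, 4, 2, 0, 3, 0, 3), masked = c(TRUE, rep(FALSE, 6)),
                        chrom = c(rep("chrA", 4), rep("chrB", 3)))
  corr0 <- correct_profile(prof0, fit_decay(prof0))
  expect_equal(corr0$density[c(4, 6)], c(0, 0))
})
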