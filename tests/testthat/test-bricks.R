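test_that("uniform sum tail matches closed forms and Monte-Carlo", {
  expect_equal(uniform_sum_tail(0.99, 1), 0.01)
  expect_equal(uniform_sum_tail(1.8, 2), 0.02)
  expect_error(uniform_sum_tail(1, 0), ">= 1")

  # exact widths against the independent lower-CDF formula
  set.seed(51)
  for (w in c(2, 5, 12)) {
    s <- runif(20, 0, w)
    expect_equal(uniform_sum_tail(s, w),
                 vapply(s, ih_upper_oracle, numeric(1), w = w),
                 tolerance = 1e-9)
  }

  # w = 2 against simulation
  set.seed(52)
  draws <- runif(1e5) + runif(1e5)
  for (s in c(1.5, 1.8, 1.9)) {
    mc <- mean(draws >= s)
    expect_lt(abs(uniform_sum_tail(s, 2) - mc), 3 * sqrt(mc * (1 - mc) / 1e5))
  }

  # saddlepoint widths against the oracle formula (stable at these widths)
  for (w in c(13, 20, 40)) {
    for (z in c(1, 2, 3, 4)) {
      s <- w / 2 + z * sqrt(w / 12)
      expect_equal(uniform_sum_tail(s, w), ih_upper_oracle(s, w), tolerance = 0.02)
    }
  }

  # continuity at the exact/approximate switch
  for (z in c(0.5, 1.5, 2.5)) {
    p12 <- uniform_sum_tail(6 + z * sqrt(1), 12)
    p13 <- uniform_sum_tail(6.5 + z * sqrt(13 / 12), 13)
    expect_equal(p12, p13, tolerance = 0.05)
  }

  # monotone non-increasing in s
  s <- seq(0, 30, by = 0.25)
  expect_true(all(diff(uniform_sum_tail(s, 30)) <= 1e-15))
})

test_that("rank transform scales average ranks into (0, 1]", {
  prof <- make_profile(c(3, 1, 4, 2))
  expect_equal(sort(rank_transform(prof)$rank), c(0.25, 0.5, 0.75, 1))
  tied <- make_profile(c(1, 5, 5, 2))
  expect_equal(rank_transform(tied)$rank[2:3], c(0.875, 0.875))
  masked <- make_profile(c(1, 9, 2, 3), masked = c(FALSE, TRUE, FALSE, FALSE))
  r <- rank_transform(masked)$rank
  expect_true(is.na(r[2]))
  expect_equal(sort(r[-2]), c(1, 2, 3) / 3)
  expect_error(rank_transform(make_profile(rep(2, 5))), "degenerate")
})

test_that("window p-values validate their window", {
  ranks <- c(0.2, 0.4, 0.9, 0.99)
  expect_equal(window_pvalue(ranks, 4, 1), 0.01)
  expect_equal(window_pvalue(ranks, 3, 2), uniform_sum_tail(1.89, 2))
  expect_error(window_pvalue(ranks, 4, 2), "outside")
  expect_error(window_pvalue(ranks, 1, 0), ">= 1")
})

test_that("domainogram width-1 row equals per-fragment tail probabilities", {
  prof <- make_profile(c(5, 1, 3, 2, 4))
  dom <- suppressWarnings(build_domainogram(prof, w_max = 1))
  ranked <- rank_transform(prof, midrank = TRUE)
  expect_equal(dom$p[order(dom$pos)], 1 - ranked$rank)
})

test_that("domainogram null width-1 p-values are uniform and planted runs are found", {
  set.seed(53)
  prof <- make_profile(runif(500))
  dom1 <- build_domainogram(prof, w_max = 1)
  ks <- suppressWarnings(stats::ks.test(dom1$p, "punif"))
  expect_gt(ks$p.value, 0.01)

  # planted run of 10 top values: the global minimum-p window overlaps it
  vals <- runif(500)
  vals[201:210] <- 2 + runif(10)
  domp <- build_domainogram(make_profile(vals), w_max = 30)
  best <- domp[which.min(domp$p), ]
  expect_lt(best$pos, 211)
  expect_gt(best$pos + best$width - 1, 200)

  expect_warning(build_domainogram(make_profile(runif(20)), w_max = 50), "clipped")
})

test_that("greedy BRICK selection matches a brute-force oracle", {
  dom0 <- build_domainogram(make_profile(runif(50)), w_max = 5)
  expect_equal(nrow(call_bricks(dom0, 1e-12)), 0L)

  # two overlapping candidates: only the smaller p survives
  cand <- tibble::tibble(chrom = "chrA", pos = c(1L, 3L), width = c(5L, 5L),
                         start = c(0, 20), end = c(50, 70), sum = c(5, 4.5),
                         p = c(1e-5, 1e-3))
  got <- call_bricks(cand, 0.01)
  expect_equal(nrow(got), 1L)
  expect_equal(got$p, 1e-5)

  # randomized candidate sets vs a quadratic brute-force greedy
  set.seed(54)
  for (i in 1:10) {
    n <- 20
    cand <- tibble::tibble(chrom = sample(c("c1", "c2"), n, replace = TRUE),
                           pos = sample.int(30, n, replace = TRUE),
                           width = sample.int(8, n, replace = TRUE),
                           p = round(runif(n, 0, 0.02), 4))
    cand$start <- cand$pos * 10; cand$end <- (cand$pos + cand$width) * 10
    cand$sum <- 0
    got <- call_bricks(cand, 0.01)

    keep <- cand[cand$p < 0.01, ]
    keep <- keep[order(keep$p, -keep$width, keep$chrom, keep$pos), ]
    acc <- keep[0, ]
    for (j in seq_len(nrow(keep))) {
      row <- keep[j, ]
      clash <- any(acc$chrom == row$chrom &
                   acc$pos <= row$pos + row$width - 1 &
                   acc$pos + acc$width - 1 >= row$pos)
      if (!clash) acc <- rbind(acc, row)
    }
    acc <- acc[order(acc$chrom, acc$start), ]
    expect_equal(got$start, acc$start)
    expect_equal(got$p, acc$p)
  }
})

test_that("BRICKs within a call are non-overlapping and below threshold", {
  set.seed(55)
  vals <- runif(400); vals[51:70] <- 3 + runif(20); vals[201:215] <- 3 + runif(15)
  dom <- build_domainogram(make_profile(vals), w_max = 40)
  bricks <- call_bricks(dom, 0.01)
  expect_true(all(bricks$p < 0.01))
  b <- bricks[order(bricks$start), ]
  if (nrow(b) > 1) expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
})

test_that("permutation FDR is reproducible, monotone, and tier sets nest", {
  set.seed(56)
  vals <- rexp(600); vals[101:130] <- vals[101:130] * 30
  prof <- make_profile(vals)
  f1 <- estimate_fdr(prof, thresholds = 10^-(2:8), n_perm = 10, seed = 9, w_max = 40)
  f2 <- estimate_fdr(prof, thresholds = 10^-(2:8), n_perm = 10, seed = 9, w_max = 40)
  expect_identical(f1$fdr, f2$fdr)
  expect_identical(f1$bricks, f2$bricks)

  # monotone after capping as the threshold tightens
  expect_true(all(diff(f1$fdr$fdr) <= 1e-12))

  # FDR-1% BRICK set is a subset of the FDR-10% set
  b01 <- f1$bricks[f1$bricks$fdr_tier == 0.01, ]
  b10 <- f1$bricks  # all reported bricks satisfy the 10% tier
  expect_true(all(paste(b01$chrom, b01$start) %in% paste(b10$chrom, b10$start)))

  expect_error(estimate_fdr(prof, n_perm = 5), ">= 10")
})

test_that("doubling permutations moves FDR estimates within sampling error", {
  set.seed(57)
  vals <- rexp(500); vals[51:75] <- vals[51:75] * 25
  prof <- make_profile(vals)
  f10 <- estimate_fdr(prof, thresholds = c(1e-2, 1e-4), n_perm = 10, seed = 1, w_max = 30)
  f20 <- estimate_fdr(prof, thresholds = c(1e-2, 1e-4), n_perm = 20, seed = 2, w_max = 30)
  # permuted mean counts at the loose threshold agree within binomial-ish error
  expect_lt(abs(f10$fdr$perm_mean[1] - f20$fdr$perm_mean[1]),
            3 * sqrt(max(f10$fdr$perm_mean[1], 1)))
})
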