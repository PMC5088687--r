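test_that("genome simulation is deterministic with uniform base composition", {
  cfg <- sim_config(seed = 3, chrom_lengths = c(chrA = 256000),
                    viewpoint = "chrA:1000")
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(as.character(g1), as.character(g2))

  # GATC occurrences ~ Binomial(L, 4^-4)
  n_gatc <- Biostrings::countPattern("GATC", g1[[1]])
  expected <- 256000 * 4^-4
  sd3 <- 3 * sqrt(256000 * 4^-4 * (1 - 4^-4))
  expect_lt(abs(n_gatc - expected), sd3)

  expect_error(sim_config(seed = 1, chrom_lengths = numeric(0)), "at least one")
  expect_error(sim_config(seed = 1, chrom_lengths = c(chrA = 0)), "positive")
})

test_that("4C read simulation conserves totals and follows the decay slope", {
  fx <- small_genome(seed = 19, lengths = c(chrA = 500000, chrB = 100000))
  cfg <- sim_config(seed = 7, chrom_lengths = c(chrA = 500000, chrB = 100000),
                    viewpoint = "chrA:250000", trans_background = 1,
                    n_reads = 10000L)
  reads <- simulate_4c_reads(fx$library, cfg)
  expect_equal(nrow(reads), 10000L)
  expect_identical(reads, simulate_4c_reads(fx$library, cfg))

  # slope regression on binned mean counts vs rank distance
  cfg2 <- sim_config(seed = 8, chrom_lengths = c(chrA = 500000, chrB = 100000),
                     viewpoint = "chrA:250000", trans_background = 0.5,
                     n_reads = 200000L)
  reads2 <- simulate_4c_reads(fx$library, cfg2)
  counts <- assign_reads(reads2, fx$library, "chrA:250000", 0L)
  vp <- attr(counts, "viewpoint")
  cis <- counts[counts$chrom == "chrA", ]
  d <- abs(cis$frag - vp$frag)
  keep <- d >= 1
  bins <- cut(log(d[keep]), breaks = 12)
  mean_count <- tapply(cis$count[keep], bins, mean)
  mid <- tapply(log(d[keep]), bins, mean)
  fit <- stats::lm(log(mean_count) ~ mid)
  expect_lt(abs(unname(stats::coef(fit)[2]) + 1), 0.1)
})

test_that("planted blocks are enriched by their fold factor", {
  lengths <- c(chrA = 500000)
  fx <- small_genome(seed = 23, lengths = lengths)
  block <- data.frame(chrom = "chrA", start = 400000, end = 420000, fold = 20)
  base <- list(chrom_lengths = lengths, viewpoint = "chrA:250000",
               trans_background = 0, n_reads = 100000L)
  r_blk <- simulate_4c_reads(fx$library, do.call(sim_config, c(base, list(
    seed = 9, planted_blocks = block))))
  r_ref <- simulate_4c_reads(fx$library, do.call(sim_config, c(base, list(seed = 9))))
  in_block <- function(r) sum(r$pos >= 400000 & r$pos < 420000)
  # mirrored control window at matched distance on the other side
  ctrl <- function(r) sum(r$pos >= 80000 & r$pos < 100000)
  ratio <- in_block(r_blk) / ctrl(r_blk)
  expect_gt(ratio, 20 - 2 * 20 / sqrt(ctrl(r_blk)))
  expect_lt(ratio, 20 + 2 * 20 / sqrt(ctrl(r_blk)))

  expect_error(sim_config(seed = 1, chrom_lengths = lengths,
                          viewpoint = "chrA:250000",
                          planted_blocks = data.frame(chrom = "chrA", start = 1,
                                                      end = 10, fold = 0.5)),
               "> 1")
  expect_error(sim_config(seed = 1, chrom_lengths = lengths,
                          viewpoint = "chrA:250000",
                          planted_blocks = data.frame(chrom = "chrA",
                                                      start = 499000,
                                                      end = 600000, fold = 2)),
               "bounds")
})

test_that("expression simulation calibrates type-I error and recovers effects", {
  cfg <- sim_config(seed = 13, expression = list(n_probes = 2000, n_per_group = 3,
                                                 baseline_sd = 0.25))
  sim <- simulate_expression(cfg)
  expect_identical(sim$matrix, simulate_expression(cfg)$matrix)
  expect_equal(dim(sim$matrix), c(2000L, 6L))

  # all effects zero: t-test rejection rate ~ alpha
  p <- apply(sim$matrix, 1, function(x) stats::t.test(x[4:6], x[1:3])$p.value)
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))

  # planted +1 effects at low noise: fold change within [0.8, 1.2] for >= 95%
  eff <- setNames(rep(1, 200), paste0("probe_", 1:200))
  cfg2 <- sim_config(seed = 14, expression = list(n_probes = 2000, n_per_group = 3,
                                                  baseline_sd = 0.1, effects = eff))
  sim2 <- simulate_expression(cfg2)
  fc <- fold_changes(sim2$matrix, sim2$groups, method = "log_means")
  expect_gte(mean(fc$log2_fc[1:200] >= 0.8 & fc$log2_fc[1:200] <= 1.2), 0.95)

  expect_error(simulate_expression(sim_config(seed = 1, expression = list(
    n_probes = 10, effects = c(nope = 1)))), "unknown probe")
  expect_error(sim_config(seed = 1, expression = list(n_per_group = 1)), ">= 2")
})

test_that("network simulation plants connected modules with unit weights", {
  cfg <- sim_config(seed = 15, network = list(n_vertices = 60, module_size = 8,
                                              mean_degree = 4))
  net <- simulate_network(cfg)
  expect_equal(sum(net$weights$weight), 8)
  expect_identical(net, simulate_network(cfg))

  # the planted module is a connected induced subgraph
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$weights$vertex)
  hits <- net$weights$vertex[net$weights$weight == 1]
  expect_true(igraph::is_connected(igraph::induced_subgraph(g, hits)))

  expect_error(sim_config(seed = 1, network = list(n_vertices = 5, module_size = 9)),
               "cannot exceed")
})

test_that("Hi-C simulation is symmetric with distance-only structure when unbiased", {
  cfg <- sim_config(seed = 16, hic = list(n_bins = 20, bias_range = c(1, 1)))
  sim <- simulate_hic(cfg)
  m <- sim$matrix
  expect_equal(m, t(m))
  d <- abs(outer(1:20, 1:20, "-"))
  for (dd in 0:5) expect_equal(var(m[d == dd]), 0)

  cfgp <- sim_config(seed = 16, hic = list(n_bins = 20, bias_range = c(1, 1),
                                           peaks = data.frame(i = 3, j = 9, factor = 7)))
  mp <- simulate_hic(cfgp)$matrix
  expect_equal(mp[3, 9] / m[3, 9], 7)
  expect_equal(mp[9, 3], mp[3, 9])

  expect_error(simulate_hic(sim_config(seed = 1, hic = list(
    n_bins = 20, peaks = data.frame(i = 25, j = 1, factor = 2)))), "outside")
  expect_error(sim_config(seed = 1, hic = list(n_bins = 5)), ">= 10")
})
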