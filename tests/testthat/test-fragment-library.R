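test_that("digestion places cuts at motif starts with no empty leading fragment", {
  lib <- digest(Biostrings::DNAStringSet(c(chrA = "AAAA")))
  expect_equal(nrow(lib), 1L)
  expect_equal(c(lib$start, lib$end), c(0L, 4L))

  lib <- digest(Biostrings::DNAStringSet(c(chrA = "AAGATCCC")))
  expect_equal(lib$start, c(0L, 2L))
  expect_equal(lib$end, c(2L, 8L))

  lib <- digest(Biostrings::DNAStringSet(c(chrA = "GATCGATC")))
  expect_equal(lib$start, c(0L, 4L))
  expect_equal(lib$end, c(4L, 8L))
})

test_that("digestion matches a brute-force scan and tiles randomized genomes", {
  set.seed(401)
  for (rep in 1:5) {
    seq <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE), collapse = "")
    lib <- digest(Biostrings::DNAStringSet(c(chr = seq)))

    # brute-force left-to-right scan for GATC starts
    starts <- integer(0)
    for (i in seq_len(nchar(seq) - 3)) {
      if (substr(seq, i, i + 3) == "GATC") starts <- c(starts, i - 1L)
    }
    expect_equal(lib$start, c(0L, setdiff(starts, 0L)))

    # tiling: no gaps, no overlaps, full coverage, consecutive indices
    expect_equal(lib$start[1], 0L)
    expect_equal(lib$end[nrow(lib)], nchar(seq))
    expect_true(all(lib$start[-1] == lib$end[-nrow(lib)]))
    expect_equal(lib$frag, seq_len(nrow(lib)) - 1L)
  }
})

test_that("digesting the concatenated fragment sequences is idempotent", {
  fx <- small_genome()
  lib <- fx$library
  chrom <- names(fx$genome)[1]
  seqs <- vapply(which(lib$chrom == chrom), function(i) {
    as.character(Biostrings::subseq(fx$genome[[chrom]], lib$start[i] + 1, lib$end[i]))
  }, character(1))
  relib <- digest(Biostrings::DNAStringSet(setNames(paste(seqs, collapse = ""), chrom)))
  expect_equal(relib$start, lib$start[lib$chrom == chrom])
  expect_equal(relib$end, lib$end[lib$chrom == chrom])
})

test_that("digest rejects invalid motifs and N never matches", {
  g <- Biostrings::DNAStringSet(c(chrA = "GANCGATC"))
  expect_error(digest(g, ""), "non-empty")
  expect_error(digest(g, "GAXC"), "A/C/G/T")
  lib <- digest(g)  # GANC must not cut
  expect_equal(lib$start, c(0L, 4L))
})

test_that("validity flagging detects secondary sites inside fragments", {
  g <- Biostrings::DNAStringSet(c(chrA = "GATCAAACATGAAGATCAAAAA"))
  lib <- flag_validity(digest(g), g)
  expect_equal(lib$valid, c(TRUE, FALSE))  # CATG only in first fragment
  expect_error(flag_validity(lib, g, ""), "non-empty")
})

test_that("locate agrees with a linear scan on random loci", {
  fx <- small_genome()
  lib <- fx$library
  expect_equal(locate(lib, lib$chrom[1], 0)$frag, 0L)
  # half-open convention: a fragment start belongs to that fragment
  f5 <- lib[lib$chrom == lib$chrom[1], ][5, ]
  expect_equal(locate(lib, f5$chrom, f5$start)$frag, f5$frag)

  set.seed(402)
  for (chrom in unique(lib$chrom)) {
    sub <- lib[lib$chrom == chrom, ]
    L <- max(sub$end)
    pos <- sample.int(L, 2000) - 1L
    got <- vapply(pos, function(p) locate(lib, chrom, p)$frag, integer(1))
    oracle <- vapply(pos, function(p) {
      sub$frag[which(sub$start <= p & p < sub$end)]
    }, integer(1))
    expect_equal(got, oracle)
  }
  expect_error(locate(lib, "nope", 1), "Unknown chromosome")
  expect_error(locate(lib, lib$chrom[1], -1), "outside")
  expect_error(locate(lib, lib$chrom[1], 1e9), "outside")
})

test_that("read assignment counts, excludes the viewpoint zone, and conserves totals", {
  fx <- small_genome()
  lib <- fx$library
  target <- lib[lib$chrom == "chrA", ][20, ]
  vp <- lib[lib$chrom == "chrA", ][10, ]
  vp_locus <- sprintf("chrA:%d", vp$start)

  reads <- tibble::tibble(chrom = "chrA", pos = rep(target$start, 3), strand = "+")
  fc <- assign_reads(reads, lib, vp_locus, exclusion_radius = 1L)
  expect_equal(fc$count[fc$chrom == "chrA" & fc$frag == target$frag], 3L)
  expect_equal(sum(fc$count), 3L)

  # read on the viewpoint fragment: counts unchanged, self-ligated tally +1
  fc2 <- assign_reads(tibble::tibble(chrom = "chrA", pos = vp$start, strand = "+"),
                      lib, vp_locus)
  expect_equal(sum(fc2$count), 0L)
  excl <- attr(fc2, "excluded")
  expect_equal(excl$n[excl$reason == "self_ligated"], 1L)

  # neighbor fragment: undigested
  nb <- lib[lib$chrom == "chrA", ][11, ]
  fc3 <- assign_reads(tibble::tibble(chrom = "chrA", pos = nb$start, strand = "+"),
                      lib, vp_locus)
  excl3 <- attr(fc3, "excluded")
  expect_equal(excl3$n[excl3$reason == "undigested"], 1L)

  # conservation on 1000 simulated reads
  cfg <- sim_config(seed = 5, chrom_lengths = c(chrA = 60000, chrB = 20000),
                    viewpoint = vp_locus, n_reads = 1000L)
  sim_reads <- simulate_4c_reads(lib, cfg)
  fc4 <- assign_reads(sim_reads, lib, vp_locus)
  expect_equal(sum(fc4$count) + sum(attr(fc4, "excluded")$n), 1000L)

  expect_error(assign_reads(tibble::tibble(chrom = "chrZ", pos = 1), lib, vp_locus),
               "absent")
})
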