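# Shared fixtures: hand-built profiles and small simulated genomes.

# Build a fourc_profile tibble directly, bypassing the read pipeline.
make_profile <- function(density, masked = rep(FALSE, length(density)),
                         chrom = rep("chrA", length(density)),
                         starts = NULL, width = 10,
                         viewpoint_frag = 0L, viewpoint_chrom = chrom[1],
                         exclusion_radius = 0L) {
  n <- length(density)
  frag <- integer(n)
  for (ch in unique(chrom)) frag[chrom == ch] <- seq_len(sum(chrom == ch)) - 1L
  if (is.null(starts)) starts <- frag * width
  df <- tibble::tibble(chrom = chrom, frag = frag, start = starts,
                       end = starts + width, valid = NA,
                       density = density, masked = masked)
  structure(df, class = c("fourc_profile", "tbl_df", "tbl", "data.frame"),
            stage = "test",
            viewpoint = list(chrom = viewpoint_chrom, frag = viewpoint_frag,
                             start = viewpoint_frag * width,
                             end = viewpoint_frag * width + width),
            exclusion_radius = exclusion_radius, scale = 1e6)
}

# A small digested genome shared across tests (built once per test run).
test_genome_env <- new.env()
small_genome <- function(seed = 11, lengths = c(chrA = 60000, chrB = 20000)) {
  key <- paste(seed, paste(names(lengths), lengths, collapse = "_"))
  if (is.null(test_genome_env[[key]])) {
    cfg <- sim_config(seed = seed, chrom_lengths = lengths,
                      viewpoint = paste0(names(lengths)[1], ":", lengths[1] %/% 2))
    g <- simulate_genome(cfg)
    test_genome_env[[key]] <- list(genome = g,
                                   library = flag_validity(digest(g), g),
                                   config = cfg)
  }
  test_genome_env[[key]]
}

# Independent Irwin-Hall upper tail via the lower-CDF alternating formula
# (textbook form, written separately from the package implementation).
ih_upper_oracle <- function(s, w) {
  if (s <= 0) return(1)
  if (s >= w) return(0)
  k <- 0:floor(s)
  cdf <- sum((-1)^k * choose(w, k) * (s - k)^w) / factorial(w)
  1 - cdf
}
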