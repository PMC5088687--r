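#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generators: a genome, a
#' 4C viewpoint with a power-law contact decay and planted enriched blocks, a
#' two-group expression experiment with planted fold changes, a network with a
#' planted connected hit module, and a biased Hi-C contact matrix. The
#' defaults describe the study conditions the downstream statistics assume:
#' cis contact density falling as distance^-1 from the viewpoint, a low
#' uniform trans background, 3-vs-3 log-normal expression, and multiplicative
#' per-bin Hi-C biases.
#'
#' @param seed Integer seed; every generator is a pure function of the config
#'   including this seed.
#' @param chrom_lengths Named numeric vector, chromosome name -> length (bp).
#' @param viewpoint `"chrom:pos"` string or `list(chrom =, pos =)`; must fall
#'   on a fragment of the digested genome.
#' @param decay_slope Log-log slope of the cis contact decay (default -1).
#' @param planted_blocks `NULL` or a data frame with columns `chrom`, `start`,
#'   `end` (bp, half-open) and `fold` (> 1): contact enrichment blocks.
#' @param trans_background Expected reads per trans fragment (>= 0).
#' @param n_reads Total number of reads to emit (> 0).
#' @param distance_unit `"rank"` (fragment index difference, default) or
#'   `"bp"` for the decay distance.
#' @param expression List: `n_probes`, `n_per_group` (>= 2), `baseline_sd`
#'   (log2 scale), `effects` (named numeric, probe id -> log2 effect in the
#'   mutant group), `chrom_props` (named proportions summing to 1).
#' @param network List: `n_vertices`, `edge_model`
#'   (`"erdos_renyi"` or `"preferential_attachment"`), `mean_degree`,
#'   `module_size`, `mode` (`"planted"` connected module or `"random"` hit
#'   set).
#' @param hic List: `n_bins` (>= 10), `bin_size` (bp), `bias_range`
#'   (length-2, multiplicative per-bin biases drawn log-uniformly), `peaks`
#'   (`NULL` or data frame `i`, `j`, `factor`, 1-based bins).
#' @return A `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, chrom_lengths = c(chrA = 50000, chrB = 20000),
#'                   viewpoint = "chrA:25000", n_reads = 1000)
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 1024000, chr2 = 256000),
                       viewpoint = "chr1:512000",
                       decay_slope = -1,
                       planted_blocks = NULL,
                       trans_background = 2,
                       n_reads = 100000L,
                       distance_unit = c("rank", "bp"),
                       expression = list(),
                       network = list(),
                       hic = list()) {
  check_chrom_lengths(chrom_lengths)
  if (n_reads <= 0) abort("`n_reads` must be positive.")
  if (trans_background < 0) abort("`trans_background` must be >= 0.")
  distance_unit <- match.arg(distance_unit)

  if (!is.null(planted_blocks)) {
    planted_blocks <- as_tibble(planted_blocks)
    stopifnot(all(c("chrom", "start", "end", "fold") %in% names(planted_blocks)))
    if (any(planted_blocks$fold <= 1)) abort("Planted block fold-enrichment must be > 1.")
    if (any(planted_blocks$start >= planted_blocks$end)) abort("Planted blocks must have start < end.")
    for (i in seq_len(nrow(planted_blocks))) {
      b <- planted_blocks[i, ]
      if (!b$chrom %in% names(chrom_lengths)) abort("Planted block on unknown chromosome.")
      if (b$start < 0 || b$end > chrom_lengths[[b$chrom]]) abort("Planted block outside chromosome bounds.")
    }
    same <- split(planted_blocks, planted_blocks$chrom)
    for (g in same) {
      g <- g[order(g$start), ]
      if (nrow(g) > 1 && any(g$start[-1] < g$end[-nrow(g)])) abort("Planted blocks must not overlap.")
    }
  }

  expression <- utils::modifyList(list(
    n_probes = 2000L, n_per_group = 3L, baseline_sd = 0.25,
    effects = numeric(0),
    chrom_props = c(chr11 = 0.1, other = 0.9)
  ), expression)
  if (expression$n_per_group < 2) abort("`n_per_group` must be >= 2.")

  network <- utils::modifyList(list(
    n_vertices = 100L, edge_model = "erdos_renyi", mean_degree = 4,
    module_size = 10L, mode = "planted"
  ), network)
  if (network$module_size > network$n_vertices) {
    abort("`module_size` cannot exceed `n_vertices`.")
  }

  hic <- utils::modifyList(list(
    n_bins = 100L, bin_size = 40000L, bias_range = c(0.5, 2), peaks = NULL
  ), hic)
  if (hic$n_bins < 10) abort("`hic$n_bins` must be >= 10.")

  structure(list(
    seed = as.integer(seed), chrom_lengths = chrom_lengths,
    viewpoint = parse_locus(viewpoint), decay_slope = decay_slope,
    planted_blocks = planted_blocks, trans_background = trans_background,
    n_reads = as.integer(n_reads), distance_unit = distance_unit,
    expression = expression, network = network, hic = hic
  ), class = "sim_config")
}

#' Simulate a genome sequence set
#'
#' Draws uniform independent A/C/G/T at every position of every configured
#' chromosome. Deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  check_chrom_lengths(config$chrom_lengths)
  set.seed(derive_seed(config$seed, "genome"))
  seqs <- vapply(config$chrom_lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(seqs)
}

#' Simulate 4C-seq aligned reads
#'
#' Samples `n_reads` read positions over the fragments of a virtual library.
#' Cis fragments are weighted proportionally to distance^`decay_slope` from
#' the viewpoint fragment (distance in fragment ranks by default), multiplied
#' by the fold-enrichment of any planted block covering the fragment midpoint;
#' trans fragments receive a uniform weight calibrated so their expected count
#' equals `trans_background` reads per fragment. Counts are multinomial over
#' fragments (total fixed at `n_reads`); the read position within a fragment
#' and the strand are uniform.
#'
#' @param library A fragment library from [digest()].
#' @param config A [sim_config()]; the viewpoint must lie inside a library
#'   fragment.
#' @return A tibble with columns `chrom`, `pos` (0-based) and `strand`.
#' @export
simulate_4c_reads <- function(library, config) {
  stopifnot(inherits(config, "sim_config"))
  vp <- config$viewpoint
  vp_frag <- locate(library, vp$chrom, vp$pos)

  frags <- library
  is_cis <- frags$chrom == vp$chrom
  w <- numeric(nrow(frags))

  d <- abs(frags$frag[is_cis] - vp_frag$frag)
  if (config$distance_unit == "bp") {
    mid <- (frags$start[is_cis] + frags$end[is_cis]) / 2
    vp_mid <- (vp_frag$start + vp_frag$end) / 2
    d <- abs(mid - vp_mid) / mean(frags$end[is_cis] - frags$start[is_cis])
  }
  d[d < 1] <- 1  # the viewpoint fragment itself; excluded downstream anyway
  w[is_cis] <- d^config$decay_slope

  if (!is.null(config$planted_blocks)) {
    mid <- (frags$start + frags$end) / 2
    for (i in seq_len(nrow(config$planted_blocks))) {
      b <- config$planted_blocks[i, ]
      hit <- frags$chrom == b$chrom & mid >= b$start & mid < b$end
      w[hit] <- w[hit] * b$fold
    }
  }

  n_trans <- sum(!is_cis)
  trans_total <- n_trans * config$trans_background
  if (trans_total >= config$n_reads) {
    abort("Trans background leaves no reads for the cis profile; lower `trans_background`.")
  }
  if (sum(w[is_cis]) > 0) {
    w[is_cis] <- w[is_cis] / sum(w[is_cis]) * (config$n_reads - trans_total)
  }
  w[!is_cis] <- config$trans_background
  if (all(w == 0)) abort("All fragment weights are zero.")

  set.seed(derive_seed(config$seed, "reads"))
  counts <- as.vector(rmultinom(1, config$n_reads, prob = w / sum(w)))
  idx <- rep.int(seq_len(nrow(frags)), counts)
  offset <- floor(runif(length(idx)) * (frags$end[idx] - frags$start[idx]))
  tibble(
    chrom = frags$chrom[idx],
    pos = frags$start[idx] + offset,
    strand = sample(c("+", "-"), length(idx), replace = TRUE)
  )
}

#' Simulate a two-group log2 expression matrix
#'
#' Baseline probe means are uniform on log2 4..12; values are
#' Normal(mean, `baseline_sd`); probes named in `effects` are shifted by their
#' log2 effect in the mutant group only. Probes are assigned to chromosomes by
#' the configured proportions.
#'
#' @param config A [sim_config()].
#' @return A list: `matrix` (probes x samples, log2), `probe_info` tibble
#'   (`probe`, `gene`, `chrom`), `groups` (character vector of
#'   `"control"`/`"mutant"` per sample column).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ex <- config$expression
  probes <- paste0("probe_", seq_len(ex$n_probes))
  effects <- ex$effects
  if (length(effects) && !all(names(effects) %in% probes)) {
    abort("Effect table references unknown probe(s).")
  }
  set.seed(derive_seed(config$seed, "expression"))
  mu <- runif(ex$n_probes, 4, 12)
  n <- ex$n_per_group
  mat <- matrix(rnorm(ex$n_probes * 2 * n, mean = mu, sd = ex$baseline_sd),
                nrow = ex$n_probes, ncol = 2 * n)
  rownames(mat) <- probes
  colnames(mat) <- c(paste0("control_", seq_len(n)), paste0("mutant_", seq_len(n)))
  if (length(effects)) {
    i <- match(names(effects), probes)
    mat[i, n + seq_len(n)] <- mat[i, n + seq_len(n)] + effects
  }
  chrom <- sample(names(ex$chrom_props), ex$n_probes, replace = TRUE,
                  prob = ex$chrom_props)
  list(
    matrix = mat,
    probe_info = tibble(probe = probes, gene = sub("probe", "gene", probes),
                        chrom = chrom),
    groups = rep(c("control", "mutant"), each = n)
  )
}

#' Simulate a weighted network with a planted hit module
#'
#' Draws a graph from the configured edge model and assigns weight 1 either to
#' a connected induced subgraph of `module_size` vertices (`mode = "planted"`,
#' grown by seeded breadth-first search) or to a uniform random vertex subset
#' (`mode = "random"`); all other weights are 0.
#'
#' @param config A [sim_config()].
#' @return A list: `edges` tibble (`from`, `to`), `weights` tibble (`vertex`,
#'   `weight`).
#' @export
simulate_network <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  nw <- config$network
  if (nw$module_size > nw$n_vertices) abort("`module_size` cannot exceed `n_vertices`.")
  set.seed(derive_seed(config$seed, "network"))
  g <- switch(nw$edge_model,
    erdos_renyi = igraph::sample_gnp(nw$n_vertices,
                                     min(1, nw$mean_degree / (nw$n_vertices - 1))),
    preferential_attachment = igraph::sample_pa(nw$n_vertices,
                                                m = max(1, round(nw$mean_degree / 2)),
                                                directed = FALSE),
    abort("Unknown `edge_model`.")
  )
  igraph::V(g)$name <- paste0("v", seq_len(nw$n_vertices))

  hit <- switch(nw$mode,
    random = sample(igraph::V(g)$name, nw$module_size),
    planted = {
      found <- NULL
      for (attempt in seq_len(100L)) {
        start <- sample(seq_len(nw$n_vertices), 1)
        ord <- igraph::bfs(g, root = start, order = TRUE, unreachable = FALSE)
        reach <- ord$order[!is.na(ord$order)]
        reach <- reach[seq_len(min(length(reach), nw$module_size))]
        if (length(reach) == nw$module_size) { found <- reach$name; break }
      }
      if (is.null(found)) {
        abort("No connected subgraph of the requested size found after bounded attempts.")
      }
      found
    },
    abort("Unknown network `mode`.")
  )
  el <- igraph::as_edgelist(g)
  list(
    edges = tibble(from = el[, 1], to = el[, 2]),
    weights = tibble(vertex = igraph::V(g)$name,
                     weight = as.numeric(igraph::V(g)$name %in% hit))
  )
}

#' Simulate a binned Hi-C contact matrix
#'
#' Builds a symmetric matrix `bias_i * bias_j * f(|i - j|)` with a power-law
#' distance decay `f(d) = (1 + d)^-1`, per-bin biases drawn log-uniformly from
#' `bias_range`, and planted peaks multiplying the specified cells
#' symmetrically.
#'
#' @param config A [sim_config()].
#' @return A list: `matrix` (square symmetric), `bias` (true per-bin factors),
#'   `bin_size`.
#' @export
simulate_hic <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  hc <- config$hic
  n <- hc$n_bins
  set.seed(derive_seed(config$seed, "hic"))
  bias <- exp(runif(n, log(hc$bias_range[1]), log(hc$bias_range[2])))
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  m <- outer(bias, bias) * (1 + d)^-1
  if (!is.null(hc$peaks)) {
    pk <- as_tibble(hc$peaks)
    if (any(pk$i < 1 | pk$i > n | pk$j < 1 | pk$j > n)) {
      abort("Planted peak outside the matrix.")
    }
    for (r in seq_len(nrow(pk))) {
      m[pk$i[r], pk$j[r]] <- m[pk$i[r], pk$j[r]] * pk$factor[r]
      if (pk$i[r] != pk$j[r]) m[pk$j[r], pk$i[r]] <- m[pk$j[r], pk$i[r]] * pk$factor[r]
    }
  }
  list(matrix = m, bias = bias, bin_size = hc$bin_size)
}
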