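# End-to-end orchestration: synthetic inputs (or user files) through fragment
# library, profile, BRICK calling, annotation, network, expression and Hi-C
# comparison, with per-stage derived seeds and a machine-readable summary.

#' Default pipeline configuration
#'
#' Nested list of every tunable of the pipeline, overridable field-by-field
#' via `run_pipeline(config = list(...))` or a YAML file. A small demo genome
#' keeps the full run in seconds.
#'
#' @return A nested configuration list.
#' @export
pipeline_defaults <- function() {
  list(
    seed = 1L,
    genome = list(fasta = NULL, chrom_lengths = c(chr1 = 400000, chr2 = 120000)),
    viewpoint = "chr1:200000",
    enzymes = list(primary = "GATC", secondary = "CATG"),
    exclusion_radius = 1L,
    reads = list(n_reads = 50000L, n_replicates = 2L, decay_slope = -1,
                 trans_background = 2,
                 planted_blocks = data.frame(
                   chrom = "chr1", start = c(60000, 120000, 300000),
                   end = c(75000, 135000, 315000), fold = 20)),
    profile = list(scale = 1e6, smooth_window = 29L),
    bricks = list(w_max = 101L, n_perm = 50L, fdr_tiers = c(0.01, 0.10),
                  thresholds = 10^-(2:12), smooth_window = NULL),
    genes = list(bed = NULL, spacing = 25000, length = 5000),
    annotation = list(flank = 500000, window_size = 50000),
    network = list(n_vertices = 60L, mean_degree = 4, module_size = 8L,
                   edge_model = "erdos_renyi", mode = "planted",
                   n_perm = 1000L),
    expression = list(n_probes = 1000L, n_per_group = 3L, baseline_sd = 0.25,
                      n_de = 30L, effect = 1, de_cis_bias = 4,
                      lfc_threshold = 0.5, alpha = 0.05),
    hic = list(n_bins = 80L, bias_range = c(0.5, 2), clamp_floor = 1,
               coarsen_factor = 10L)
  )
}

merge_config <- function(defaults, override) {
  for (k in names(override)) {
    if (is.list(defaults[[k]]) && is.list(override[[k]]) &&
        !is.data.frame(override[[k]]) && !is.data.frame(defaults[[k]])) {
      defaults[[k]] <- merge_config(defaults[[k]], override[[k]])
    } else {
      defaults[[k]] <- override[[k]]
    }
  }
  defaults
}

synthetic_genes <- function(chrom_lengths, spacing, gene_length) {
  purrr::map_dfr(names(chrom_lengths), function(ch) {
    starts <- seq(spacing / 2, chrom_lengths[[ch]] - gene_length, by = spacing)
    tibble(name = sprintf("gene_%s_%03d", ch, seq_along(starts)),
           chrom = ch, start = starts, end = starts + gene_length,
           strand = rep(c("+", "-"), length.out = length(starts)))
  })
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate (unless files are supplied) -> digest -> assign ->
#' profile -> BRICK calling with FDR tiers -> annotation and window
#' enrichment -> network connectivity -> differential expression and
#' chromosome bias -> Hi-C balancing, observed/expected and BRICK signal
#' comparison. Every intermediate is written in its standard plain-text
#' format under `out_dir`; a single JSON summary collects the headline
#' numbers with the seeds and permutation counts behind each randomized
#' statistic. One global seed deterministically derives per-stage seeds, so
#' the same config yields byte-identical summaries.
#'
#' @param config A nested list overriding [pipeline_defaults()], or the path
#'   of a YAML file of such overrides.
#' @param out_dir Output directory (created if absent).
#' @param quiet Suppress progress messages.
#' @return The summary list, invisibly; written to `out_dir/summary.json`.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("loop4c_run_"),
                         quiet = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("Config file '%s' does not exist.", config))
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(pipeline_defaults(), config)
  if (!is.null(cfg$genome$fasta) && !file.exists(cfg$genome$fasta)) {
    abort(sprintf("Genome FASTA '%s' does not exist.", cfg$genome$fasta))
  }
  if (!is.null(cfg$genes$bed) && !file.exists(cfg$genes$bed)) {
    abort(sprintf("Gene BED '%s' does not exist.", cfg$genes$bed))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- as.integer(cfg$seed)
  cfg$genome$chrom_lengths <- unlist(cfg$genome$chrom_lengths)

  # --- genome & fragment library -------------------------------------------
  genome <- run_stage("genome", {
    if (!is.null(cfg$genome$fasta)) read_genome_fasta(cfg$genome$fasta)
    else {
      g <- simulate_genome(sim_config(seed = seed,
                                      chrom_lengths = cfg$genome$chrom_lengths,
                                      viewpoint = cfg$viewpoint))
      write_genome_fasta(g, file.path(out_dir, "genome.fa"))
      g
    }
  })
  say("digesting %d chromosome(s)", length(genome))
  lib <- run_stage("digest", {
    lib <- digest(genome, cfg$enzymes$primary)
    lib <- flag_validity(lib, genome, cfg$enzymes$secondary)
    write_library_bed(lib, file.path(out_dir, "library.bed"))
    lib
  })

  # --- reads, profiles, replicates -----------------------------------------
  chrom_lengths <- setNames(Biostrings::width(genome), names(genome))
  blocks <- cfg$reads$planted_blocks
  if (!is.null(blocks)) blocks <- as_tibble(blocks)
  profiles <- run_stage("profile", {
    lapply(seq_len(cfg$reads$n_replicates), function(r) {
      rc <- sim_config(seed = derive_seed(seed, paste0("rep", r)),
                       chrom_lengths = chrom_lengths,
                       viewpoint = cfg$viewpoint,
                       decay_slope = cfg$reads$decay_slope,
                       planted_blocks = blocks,
                       trans_background = cfg$reads$trans_background,
                       n_reads = cfg$reads$n_reads)
      reads <- simulate_4c_reads(lib, rc)
      write_reads_tsv(reads, file.path(out_dir, sprintf("reads_rep%d.tsv", r)))
      counts <- assign_reads(reads, lib, cfg$viewpoint, cfg$exclusion_radius)
      normalize_profile(counts, scale = cfg$profile$scale)
    })
  })
  concord <- if (length(profiles) >= 2) {
    local_spearman(smooth_profile(profiles[[1]], cfg$profile$smooth_window),
                   smooth_profile(profiles[[2]], cfg$profile$smooth_window),
                   cfg$profile$smooth_window)$global
  } else NA_real_
  combined <- combine_replicates(profiles)
  fit <- fit_decay(combined)
  corrected <- correct_profile(combined, fit)
  write_profile_bedgraph(corrected, file.path(out_dir, "profile.bedgraph"))

  # --- BRICK calling ---------------------------------------------------------
  say("calling BRICKs (%d permutations)", cfg$bricks$n_perm)
  fdr <- run_stage("call-bricks", {
    estimate_fdr(corrected, thresholds = cfg$bricks$thresholds,
                 n_perm = cfg$bricks$n_perm,
                 seed = derive_seed(seed, "fdr"),
                 w_max = cfg$bricks$w_max,
                 smooth_window = cfg$bricks$smooth_window,
                 tiers = cfg$bricks$fdr_tiers)
  })
  bricks <- classify_cis_trans(fdr$bricks, cfg$viewpoint)
  write_bricks_bed(bricks, file.path(out_dir, "bricks.bed"))

  # --- annotation & enrichment ----------------------------------------------
  genes <- run_stage("annotate", {
    if (!is.null(cfg$genes$bed)) {
      readr::read_tsv(cfg$genes$bed,
                      col_names = c("chrom", "start", "end", "name", "score",
                                    "strand"), show_col_types = FALSE) |>
        select("name", "chrom", "start", "end", "strand")
    } else {
      synthetic_genes(chrom_lengths, cfg$genes$spacing, cfg$genes$length)
    }
  })
  annotation <- annotate_bricks(bricks, genes, cfg$annotation$flank)
  readr::write_tsv(annotation, file.path(out_dir, "annotation.tsv"))
  gene_sets <- brick_gene_sets(annotation)
  windows <- count_in_windows(bricks, chrom_lengths,
                              window_size = cfg$annotation$window_size)
  readr::write_tsv(windows, file.path(out_dir, "window_enrichment.tsv"))

  # --- network connectivity --------------------------------------------------
  say("network connectivity (%d permutations)", cfg$network$n_perm)
  knet <- run_stage("knet", {
    net <- simulate_network(sim_config(seed = derive_seed(seed, "network"),
                                       chrom_lengths = cfg$genome$chrom_lengths,
                                       viewpoint = cfg$viewpoint,
                                       network = cfg$network))
    write_network_tsv(net, file.path(out_dir, "network.tsv"))
    knet_pvalue(net$edges, net$weights, n_perm = cfg$network$n_perm,
                seed = derive_seed(seed, "knet"))
  })

  # --- expression ------------------------------------------------------------
  de <- run_stage("expression", {
    ex <- cfg$expression
    gene_chroms <- table(genes$chrom)
    props <- as.numeric(gene_chroms) / sum(gene_chroms)
    names(props) <- names(gene_chroms)
    sc <- sim_config(seed = derive_seed(seed, "expression"),
                     chrom_lengths = cfg$genome$chrom_lengths,
                     viewpoint = cfg$viewpoint,
                     expression = list(n_probes = ex$n_probes,
                                       n_per_group = ex$n_per_group,
                                       baseline_sd = ex$baseline_sd,
                                       chrom_props = props))
    # Plant DE probes with a bias toward the viewpoint chromosome, the
    # chromosome-of-residence effect the bias test is meant to detect.
    vp_chrom <- parse_locus(cfg$viewpoint)$chrom
    sim0 <- simulate_expression(sc)
    set.seed(derive_seed(seed, "de-placement"))
    wgt <- ifelse(sim0$probe_info$chrom == vp_chrom, ex$de_cis_bias, 1)
    de_probes <- sample(sim0$probe_info$probe, ex$n_de, prob = wgt)
    effects <- setNames(rep(ex$effect, ex$n_de), de_probes)
    sc$expression$effects <- effects
    sim <- simulate_expression(sc)
    sim$probe_info <- sim0$probe_info
    # map probes onto annotated genes of the same chromosome
    set.seed(derive_seed(seed, "probe-genes"))
    sim$probe_info$gene <- vapply(sim$probe_info$chrom, function(ch) {
      sample(genes$name[genes$chrom == ch], 1)
    }, character(1))
    write_expression_tsv(sim, file.path(out_dir, "expression.tsv"))
    res <- de_call(sim$matrix, sim$groups, lfc_threshold = ex$lfc_threshold,
                   alpha = ex$alpha)
    bias <- chromosome_bias(res$probe[res$pass], sim$probe_info)
    list(result = res, bias = bias, sim = sim, vp_chrom = vp_chrom)
  })
  de_genes <- unique(de$sim$probe_info$gene[match(de$result$probe[de$result$pass],
                                                  de$sim$probe_info$probe)])
  overlap <- fisher_overlap(gene_sets$overlapping, de_genes, genes$name)

  # --- Hi-C -------------------------------------------------------------------
  say("Hi-C comparison")
  hic <- run_stage("hic", {
    vp <- parse_locus(cfg$viewpoint)
    bin_size <- ceiling(chrom_lengths[[vp$chrom]] / cfg$hic$n_bins)
    peaks <- NULL
    if (!is.null(blocks)) {
      cis_blocks <- blocks[blocks$chrom == vp$chrom, ]
      if (nrow(cis_blocks)) {
        peaks <- tibble(i = floor(vp$pos / bin_size) + 1L,
                        j = floor((cis_blocks$start + cis_blocks$end) / 2 / bin_size) + 1L,
                        factor = cis_blocks$fold)
      }
    }
    sh <- simulate_hic(sim_config(seed = derive_seed(seed, "hic"),
                                  chrom_lengths = cfg$genome$chrom_lengths,
                                  viewpoint = cfg$viewpoint,
                                  hic = list(n_bins = cfg$hic$n_bins,
                                             bin_size = bin_size,
                                             bias_range = cfg$hic$bias_range,
                                             peaks = peaks)))
    bal <- kr_balance(sh$matrix)
    oe <- observed_expected(bal$balanced, expected_vector(bal$balanced),
                            cfg$hic$clamp_floor)
    write_hic_tsv(oe, file.path(out_dir, "hic_oe.tsv"), bin_size)
    track <- virtual_4c(oe, floor(vp$pos / bin_size) + 1L)
    sel <- bricks[bricks$cis & bricks$fdr_tier == min(cfg$bricks$fdr_tiers), ]
    non <- bricks[bricks$cis & bricks$fdr_tier > min(cfg$bricks$fdr_tiers), ]
    type <- "selected_vs_nonselected"
    if (nrow(non) < 2 && nrow(sel) >= 2) {
      # too few tier-10%-only BRICKs at demo scale: fall back to matched
      # background intervals (selected BRICKs shifted half a chromosome)
      L <- chrom_lengths[[vp$chrom]]
      width <- sel$end - sel$start
      ctrl_start <- (sel$start + L / 2) %% (L - width)
      non <- tibble(start = ctrl_start, end = ctrl_start + width)
      type <- "selected_vs_background"
    }
    cmp <- tryCatch(compare_brick_signal(track, sel, non, bin_size),
                    error = function(e) NULL)
    list(comparison = cmp, comparison_type = if (is.null(cmp)) NULL else type,
         bin_size = bin_size, n_bins = cfg$hic$n_bins,
         kr_iterations = bal$iterations)
  })

  # --- summary ----------------------------------------------------------------
  tier_counts <- setNames(as.list(fdr$tiers$n_bricks),
                          sprintf("fdr_%g", fdr$tiers$fdr_tier))
  summary <- list(
    package = "loop4c",
    version = as.character(utils::packageVersion("loop4c")),
    seed = seed,
    replicate_spearman = concord,
    bricks = c(tier_counts, list(
      cis = attr(bricks, "n_cis"),
      cis_percentage = attr(bricks, "cis_fraction"),
      total = nrow(bricks))),
    fdr = list(thresholds = fdr$fdr$threshold, estimates = fdr$fdr$fdr,
               n_perm = fdr$n_perm, seed = fdr$seed),
    genes = list(n_brick_genes = length(gene_sets$overlapping),
                 n_flanking_genes = length(gene_sets$flanking)),
    window_enrichment = list(n_windows = nrow(windows),
                             min_p_adj = suppressWarnings(min(windows$p_adj))),
    knet = list(auk = knet$auk, p = knet$p_value, n_perm = knet$n_perm,
                seed = knet$seed),
    expression = list(
      n_up = unname(attr(de$result, "counts")["up"]),
      n_down = unname(attr(de$result, "counts")["down"]),
      chi_square = de$bias$statistic, chi_square_df = de$bias$df,
      chi_square_p = de$bias$p,
      viewpoint_chrom_fraction =
        de$bias$table$fraction[de$bias$table$chrom == de$vp_chrom]),
    overlap_test = list(p = overlap$p, odds_ratio = overlap$odds_ratio,
                        overlap = overlap$overlap),
    hic = list(bin_size = hic$bin_size, n_bins = hic$n_bins,
               kr_iterations = hic$kr_iterations,
               comparison_type = hic$comparison_type,
               comparison = if (is.null(hic$comparison)) NULL
                            else as.list(hic$comparison))
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  say("summary written to %s", file.path(out_dir, "summary.json"))
  invisible(summary)
}
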