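# BRICK classification, gene annotation, window/cytoband enrichment and
# gene-set overlap testing.

#' Classify BRICKs as cis or trans and report the cis fraction
#'
#' A BRICK is cis when it lies on the viewpoint chromosome. The cis fraction
#' is reported as a percentage rounded half away from zero.
#'
#' @param bricks A `bricks` tibble.
#' @param viewpoint `"chrom:pos"` or `list(chrom =, pos =)`.
#' @param decimals Decimal places for the printed percentage (default 0).
#' @return The bricks with a `cis` logical column; attributes `cis_fraction`
#'   (percentage, `NA` when the set is empty) and `n_cis`.
#' @export
#' @examples
#' b <- tibble::tibble(chrom = c(rep("chr17", 66), rep("chr2", 87)),
#'                     start = 0, end = 1)
#' attr(classify_cis_trans(b, "chr17:17700000"), "cis_fraction")  # 43
classify_cis_trans <- function(bricks, viewpoint, decimals = 0) {
  vp <- parse_locus(viewpoint)
  bricks$cis <- bricks$chrom == vp$chrom
  frac <- if (nrow(bricks) == 0) NA_real_ else {
    round_half_up(100 * sum(bricks$cis) / nrow(bricks), decimals)
  }
  structure(bricks, cis_fraction = frac, n_cis = sum(bricks$cis))
}

#' Annotate BRICKs with overlapping and flanking genes
#'
#' For every BRICK: all genes with nonzero interval intersection, plus the
#' closest non-overlapping gene on each side (upstream = lower coordinates,
#' downstream = higher coordinates, irrespective of gene strand) by
#' edge-to-edge distance, reported only when the distance is within the flank
#' window.
#'
#' @param bricks A `bricks` tibble (`chrom`, `start`, `end`).
#' @param genes A tibble of gene models: `name`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param flank Maximum flank distance in bp (default 500 kb).
#' @return A tibble with one row per BRICK: `chrom`, `start`, `end`,
#'   `overlapping` (`;`-joined gene names), `upstream_gene`,
#'   `upstream_distance`, `downstream_gene`, `downstream_distance`.
#' @export
annotate_bricks <- function(bricks, genes, flank = 500000) {
  genes <- as_tibble(genes)
  purrr::map_dfr(seq_len(nrow(bricks)), function(i) {
    b <- bricks[i, ]
    g <- genes[genes$chrom == b$chrom, ]
    ov <- g$start < b$end & g$end > b$start
    up <- g[!ov & g$end <= b$start, ]
    dn <- g[!ov & g$start >= b$end, ]
    up_d <- b$start - up$end
    dn_d <- dn$start - b$end
    pick <- function(gg, dd) {
      keep <- dd <= flank
      if (!any(keep)) return(list(name = NA_character_, dist = NA_real_))
      j <- which(keep)[which.min(dd[keep])]
      list(name = gg$name[j], dist = dd[j])
    }
    u <- pick(up, up_d); d <- pick(dn, dn_d)
    tibble(chrom = b$chrom, start = b$start, end = b$end,
           overlapping = paste(sort(g$name[ov]), collapse = ";"),
           upstream_gene = u$name, upstream_distance = u$dist,
           downstream_gene = d$name, downstream_distance = d$dist)
  })
}

#' Gene sets attached to annotated BRICKs
#'
#' Convenience accessors for the two gene universes the downstream comparisons
#' use: genes overlapped by BRICKs, and flanking genes (closest upstream and
#' downstream within the flank window).
#'
#' @param annotation Output of [annotate_bricks()].
#' @return A list with character vectors `overlapping` and `flanking`.
#' @export
brick_gene_sets <- function(annotation) {
  ov <- unlist(strsplit(annotation$overlapping[nzchar(annotation$overlapping)], ";"))
  fl <- c(annotation$upstream_gene, annotation$downstream_gene)
  list(overlapping = sort(unique(ov)), flanking = sort(unique(fl[!is.na(fl)])))
}

#' Count BRICKs in genomic windows with binomial enrichment tests
#'
#' Partitions each chromosome into fixed-size windows (or uses supplied
#' cytoband intervals), assigns every BRICK to the window containing its
#' midpoint, and tests each window's count against a binomial null in which a
#' BRICK falls into a window with probability proportional to the window's
#' share of the genome. P-values are upper tails, Benjamini-Hochberg adjusted
#' across windows.
#'
#' @param bricks A `bricks` tibble.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param window_size Window size in bp (e.g. 5e6, 1e6, 5e5); ignored when
#'   `cytobands` is given.
#' @param cytobands Optional tibble `chrom`, `start`, `end`, `name` of bands
#'   to use as windows.
#' @return A tibble: `chrom`, `start`, `end`, `name`, `n_bricks`, `p`,
#'   `p_adj`.
#' @export
count_in_windows <- function(bricks, chrom_lengths, window_size = 5e6,
                             cytobands = NULL) {
  check_chrom_lengths(chrom_lengths)
  if (is.null(cytobands)) {
    if (window_size <= 0) abort("`window_size` must be positive.")
    wins <- purrr::map_dfr(names(chrom_lengths), function(ch) {
      L <- chrom_lengths[[ch]]
      s <- seq(0, L - 1, by = window_size)
      tibble(chrom = ch, start = s, end = pmin(s + window_size, L))
    })
    wins$name <- paste0(wins$chrom, ":", wins$start, "-", wins$end)
  } else {
    wins <- as_tibble(cytobands)
    if (any(wins$end <= wins$start)) abort("Zero-length windows are not allowed.")
  }

  mid <- (bricks$start + bricks$end) / 2
  counts <- vapply(seq_len(nrow(wins)), function(i) {
    sum(bricks$chrom == wins$chrom[i] & mid >= wins$start[i] & mid < wins$end[i])
  }, numeric(1))

  n_total <- nrow(bricks)
  genome <- sum(chrom_lengths)
  p_win <- (wins$end - wins$start) / genome
  p <- pbinom(counts - 1, n_total, p_win, lower.tail = FALSE)
  wins$n_bricks <- as.integer(counts)
  wins$p <- p
  wins$p_adj <- p.adjust(p, method = "BH")
  wins
}

#' One-sided gene-set overlap test (hypergeometric / Fisher)
#'
#' Builds the 2x2 membership table of two gene sets within a universe and
#' tests over-representation of their overlap: p is the hypergeometric upper
#' tail; the odds ratio is `(ad)/(bc)`, with the Haldane-Anscombe +0.5
#' correction applied (and flagged) only when a zero cell occurs. Gene names
#' are case-normalized before matching.
#'
#' @param set_a,set_b Character vectors of gene names, subsets of `universe`.
#' @param universe Character vector of all eligible gene names.
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`.
#' @return A one-row tibble: `overlap`, `n_a`, `n_b`, `n_universe`,
#'   `odds_ratio`, `p`, `corrected` (zero-cell flag).
#' @export
fisher_overlap <- function(set_a, set_b, universe,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  norm <- function(x) unique(toupper(x))
  universe <- norm(universe)
  if (length(universe) == 0L) abort("`universe` must be non-empty.")
  set_a <- intersect(norm(set_a), universe)
  set_b <- intersect(norm(set_b), universe)

  a <- length(intersect(set_a, set_b))
  b <- length(setdiff(set_a, set_b))
  c_ <- length(setdiff(set_b, set_a))
  d <- length(universe) - a - b - c_
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE)

  p <- if (alternative == "greater") {
    phyper(a - 1, length(set_b), length(universe) - length(set_b),
           length(set_a), lower.tail = FALSE)
  } else {
    stats::fisher.test(tab, alternative = "two.sided")$p.value
  }
  corrected <- any(tab == 0)
  if (corrected) tab <- tab + 0.5
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  tibble(overlap = a, n_a = length(set_a), n_b = length(set_b),
         n_universe = length(universe), odds_ratio = or, p = p,
         corrected = corrected)
}
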