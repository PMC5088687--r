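#' In-silico restriction digestion into a virtual fragment library
#'
#' Cuts every chromosome at the 5' start of each occurrence of the primary
#' restriction motif (DpnII's GATC by default). Every occurrence opens a new
#' fragment that begins with the motif; an occurrence at position 0 produces
#' no empty leading fragment. The fragments of a chromosome tile it exactly.
#' Ambiguity characters (N) never match the motif.
#'
#' @param genome A [Biostrings::DNAStringSet] (or named character vector)
#'   named by chromosome.
#' @param primary_motif Recognition sequence of the primary enzyme
#'   (default `"GATC"`).
#' @return A tibble of class `fragment_library` with columns `chrom`, `frag`
#'   (0-based rank along the chromosome), `start`, `end` (bp, 0-based
#'   half-open) and `valid` (`NA` until [flag_validity()] is applied). The
#'   primary motif is stored as an attribute.
#' @export
#' @examples
#' genome <- Biostrings::DNAStringSet(c(chrA = "AAGATCCC"))
#' digest(genome)  # fragments [0,2) and [2,8)
digest <- function(genome, primary_motif = "GATC") {
  check_motif(primary_motif, "primary_motif")
  if (!methods::is(genome, "DNAStringSet")) genome <- Biostrings::DNAStringSet(genome)
  if (is.null(names(genome))) abort("Genome sequences must be named by chromosome.")

  lib <- purrr::map_dfr(names(genome), function(chrom) {
    L <- Biostrings::width(genome[chrom])
    hits <- Biostrings::start(Biostrings::matchPattern(primary_motif, genome[[chrom]])) - 1L
    cuts <- sort(unique(hits[hits > 0L]))
    starts <- c(0L, cuts)
    tibble(chrom = chrom, frag = seq_along(starts) - 1L,
           start = starts, end = c(cuts, L))
  })
  lib$valid <- NA
  structure(lib, class = c("fragment_library", class(lib)),
            primary_motif = primary_motif)
}

#' Flag fragments by secondary-enzyme site presence
#'
#' A 4C template requires a secondary digestion site (NlaIII's CATG by
#' default) inside the fragment for circularization; fragments lacking one are
#' "blind": retained but flagged, and excluded from rank statistics
#' downstream. A site counts if its full motif lies within the fragment.
#'
#' @param library A `fragment_library` from [digest()].
#' @param genome The same genome the library was built from.
#' @param secondary_motif Recognition sequence of the secondary enzyme.
#' @return The library with the `valid` column filled.
#' @export
flag_validity <- function(library, genome, secondary_motif = "CATG") {
  check_motif(secondary_motif, "secondary_motif")
  if (!methods::is(genome, "DNAStringSet")) genome <- Biostrings::DNAStringSet(genome)
  k <- nchar(secondary_motif)
  valid <- logical(nrow(library))
  for (chrom in unique(library$chrom)) {
    rows <- which(library$chrom == chrom)
    s <- Biostrings::start(Biostrings::matchPattern(secondary_motif, genome[[chrom]])) - 1L
    fr <- findInterval(s, library$start[rows])
    inside <- fr >= 1L & (s + k) <= library$end[rows][pmax(fr, 1L)]
    valid[rows] <- tabulate(fr[inside], nbins = length(rows)) > 0L
  }
  library$valid <- valid
  attr(library, "secondary_motif") <- secondary_motif
  library
}

#' Locate the fragment covering a genomic position
#'
#' Binary-search lookup of the unique fragment with `start <= pos < end`.
#'
#' @param library A `fragment_library`.
#' @param chrom Chromosome name.
#' @param pos 0-based position (bp).
#' @return The one-row tibble for the covering fragment.
#' @export
locate <- function(library, chrom, pos) {
  rows <- which(library$chrom == chrom)
  if (length(rows) == 0L) abort(sprintf("Unknown chromosome '%s'.", chrom))
  L <- max(library$end[rows])
  if (pos < 0 || pos >= L) abort("Position outside the chromosome.")
  i <- findInterval(pos, library$start[rows])
  library[rows[i], ]
}

#' Assign aligned reads to library fragments
#'
#' Each read's 5' position is assigned to its covering fragment. Reads on the
#' viewpoint fragment are counted as self-ligated and reads on fragments
#' within `exclusion_radius` fragment ranks of it as undigested; both are
#' excluded from the counts and tallied by reason, so that
#' `sum(counts) + sum(excluded)` equals the number of input reads.
#'
#' @param reads Tibble with columns `chrom` and `pos` (0-based).
#' @param library A `fragment_library`.
#' @param viewpoint `"chrom:pos"` or `list(chrom =, pos =)`; must fall inside
#'   a library fragment.
#' @param exclusion_radius Number of neighboring fragments on each side of the
#'   viewpoint treated as undigested carry-over (default 1).
#' @return A tibble of class `fragment_counts`: the library columns plus
#'   `count`, with attributes `excluded` (tibble `reason`, `n`) and
#'   `viewpoint` (the viewpoint fragment row).
#' @export
assign_reads <- function(reads, library, viewpoint, exclusion_radius = 1L) {
  vp <- parse_locus(viewpoint)
  vp_frag <- locate(library, vp$chrom, vp$pos)
  if (!all(reads$chrom %in% unique(library$chrom))) {
    abort("Reads reference chromosomes absent from the library.")
  }

  counts <- integer(nrow(library))
  self_ligated <- 0L; undigested <- 0L
  for (chrom in unique(reads$chrom)) {
    rows <- which(library$chrom == chrom)
    pos <- reads$pos[reads$chrom == chrom]
    if (any(pos < 0 | pos >= max(library$end[rows]))) {
      abort("Read position outside the chromosome.")
    }
    i <- findInterval(pos, library$start[rows])
    tab <- tabulate(i, nbins = length(rows))
    if (chrom == vp$chrom) {
      vp_i <- vp_frag$frag + 1L
      zone <- setdiff(intersect(seq_along(rows),
                                (vp_i - exclusion_radius):(vp_i + exclusion_radius)),
                      vp_i)
      self_ligated <- self_ligated + tab[vp_i]
      undigested <- undigested + sum(tab[zone])
      tab[c(vp_i, zone)] <- 0L
    }
    counts[rows] <- counts[rows] + tab
  }

  out <- library
  out$count <- counts
  structure(out, class = c("fragment_counts", class(library)),
            excluded = tibble(reason = c("self_ligated", "undigested"),
                              n = c(self_ligated, undigested)),
            viewpoint = vp_frag,
            exclusion_radius = as.integer(exclusion_radius))
}
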