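# Readers and writers for the plain-text interchange formats: FASTA, BED,
# bedGraph, TSV tables, Hi-C coordinate triplets with a JSON header.

#' @rdname loop4c-io
#' @param genome A [Biostrings::DNAStringSet].
#' @param path Output file path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' @rdname loop4c-io
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Plain-text input/output
#'
#' Interchange formats used between pipeline stages: reads as TSV
#' (`chrom`, `pos`, `strand`), fragment libraries as BED with a validity
#' sidecar TSV, profiles as bedGraph with a mask sidecar BED, BRICKs as BED6+
#' (score = -log10 p), networks as edge-list and weight TSVs, Hi-C matrices
#' as 0-based upper-triangle `i j value` triplets with a JSON header carrying
#' the bin size. Every writer's output is re-loadable by the matching reader.
#'
#' @name loop4c-io
#' @param reads,library,profile,bricks,m Objects to serialize.
#' @return Readers return the reconstructed object; writers return the path
#'   invisibly.
NULL

#' @rdname loop4c-io
#' @export
write_reads_tsv <- function(reads, path) {
  readr::write_tsv(reads, path)
  invisible(path)
}

#' @rdname loop4c-io
#' @export
read_reads_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname loop4c-io
#' @export
write_library_bed <- function(library, path) {
  bed <- tibble(chrom = library$chrom, start = library$start, end = library$end,
                name = paste0(library$chrom, "_", library$frag), score = 0L,
                strand = ".")
  readr::write_tsv(bed, path, col_names = FALSE)
  readr::write_tsv(tibble(name = bed$name, valid = library$valid),
                   paste0(path, ".valid.tsv"))
  invisible(path)
}

#' @rdname loop4c-io
#' @export
read_library_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                             "score", "strand"),
                         show_col_types = FALSE)
  valid <- readr::read_tsv(paste0(path, ".valid.tsv"), show_col_types = FALSE)
  lib <- tibble(chrom = bed$chrom,
                frag = as.integer(sub(".*_", "", bed$name)),
                start = bed$start, end = bed$end,
                valid = valid$valid[match(bed$name, valid$name)])
  structure(lib, class = c("fragment_library", class(lib)))
}

#' @rdname loop4c-io
#' @export
write_profile_bedgraph <- function(profile, path) {
  readr::write_tsv(tibble(chrom = profile$chrom, start = profile$start,
                          end = profile$end, value = profile$density),
                   path, col_names = FALSE)
  mask <- profile[profile$masked, c("chrom", "start", "end")]
  readr::write_tsv(mask, paste0(path, ".mask.bed"), col_names = FALSE)
  invisible(path)
}

#' @rdname loop4c-io
#' @export
read_profile_bedgraph <- function(path) {
  bg <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                        show_col_types = FALSE)
  mask <- tryCatch(
    readr::read_tsv(paste0(path, ".mask.bed"),
                    col_names = c("chrom", "start", "end"),
                    show_col_types = FALSE),
    error = function(e) tibble(chrom = character(), start = numeric(), end = numeric()))
  df <- bg |>
    group_by(.data$chrom) |>
    mutate(frag = row_number() - 1L) |>
    ungroup() |>
    mutate(density = .data$value,
           masked = paste(.data$chrom, .data$start) %in%
             paste(mask$chrom, mask$start)) |>
    select("chrom", "frag", "start", "end", "density", "masked")
  structure(df, class = c("fourc_profile", class(df)))
}

#' @rdname loop4c-io
#' @export
write_bricks_bed <- function(bricks, path) {
  score <- pmin(-log10(pmax(bricks$p, 1e-300)), 300)
  extra <- bricks[, setdiff(names(bricks), c("chrom", "start", "end", "p")),
                  drop = FALSE]
  bed <- tibble(chrom = bricks$chrom, start = bricks$start, end = bricks$end,
                name = paste0("brick_", seq_len(nrow(bricks))),
                score = round(score, 4), strand = ".")
  readr::write_tsv(dplyr::bind_cols(bed, extra), path, col_names = TRUE)
  invisible(path)
}

#' @rdname loop4c-io
#' @export
read_bricks_bed <- function(path) {
  bed <- readr::read_tsv(path, show_col_types = FALSE)
  bed$p <- 10^(-bed$score)
  out <- bed[, c("chrom", "start", "end", "p",
                 setdiff(names(bed), c("chrom", "start", "end", "p", "name",
                                       "score", "strand")))]
  structure(out, class = c("bricks", class(out)))
}

#' @rdname loop4c-io
#' @param bin_size Bin size (bp) stored in the JSON header sidecar.
#' @export
write_hic_tsv <- function(m, path, bin_size = NA) {
  check_hic(m)
  idx <- which(upper.tri(m, diag = TRUE) & !is.na(m), arr.ind = TRUE)
  readr::write_tsv(tibble(i = idx[, 1] - 1L, j = idx[, 2] - 1L,
                          value = m[idx]), path)
  jsonlite::write_json(list(n_bins = nrow(m), bin_size = bin_size),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname loop4c-io
#' @export
read_hic_tsv <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"))
  tri <- readr::read_tsv(path, show_col_types = FALSE)
  n <- hdr$n_bins
  m <- matrix(NA_real_, n, n)
  m[cbind(tri$i + 1L, tri$j + 1L)] <- tri$value
  m[cbind(tri$j + 1L, tri$i + 1L)] <- tri$value
  attr(m, "bin_size") <- hdr$bin_size
  m
}

#' @rdname loop4c-io
#' @param network A list with `edges` and `weights` tibbles.
#' @export
write_network_tsv <- function(network, path) {
  readr::write_tsv(network$edges, path)
  readr::write_tsv(network$weights, paste0(path, ".weights.tsv"))
  invisible(path)
}

#' @rdname loop4c-io
#' @export
read_network_tsv <- function(path) {
  list(edges = readr::read_tsv(path, show_col_types = FALSE),
       weights = readr::read_tsv(paste0(path, ".weights.tsv"),
                                 show_col_types = FALSE))
}

#' @rdname loop4c-io
#' @param expression A list with `matrix`, `probe_info`, `groups` (see
#'   [simulate_expression()]).
#' @export
write_expression_tsv <- function(expression, path) {
  mat <- as.data.frame(expression$matrix)
  mat <- cbind(probe = rownames(expression$matrix), mat)
  readr::write_tsv(as_tibble(mat), path)
  readr::write_tsv(expression$probe_info, paste0(path, ".probes.tsv"))
  readr::write_tsv(tibble(sample = colnames(expression$matrix),
                          group = expression$groups),
                   paste0(path, ".groups.tsv"))
  invisible(path)
}

#' @rdname loop4c-io
#' @export
read_expression_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  mat <- as.matrix(tab[, -1])
  rownames(mat) <- tab$probe
  groups <- readr::read_tsv(paste0(path, ".groups.tsv"), show_col_types = FALSE)
  list(matrix = mat,
       probe_info = readr::read_tsv(paste0(path, ".probes.tsv"),
                                    show_col_types = FALSE),
       groups = groups$group[match(colnames(mat), groups$sample)])
}
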