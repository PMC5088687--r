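# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves moving away from zero, the
#' convention used when quoting cohort percentages (base `round()` rounds
#' halves to even).
#'
#' @param x Numeric vector.
#' @param digits Integer number of decimal places.
#' @return Numeric vector of the same length as `x`.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Derive a reproducible stage seed from a global seed
#'
#' Mixes a global integer seed with a stage name so that every pipeline stage
#' gets its own deterministic stream, reproducible in isolation. The result is
#' kept below 2^31.
#'
#' @param seed Global integer seed.
#' @param stage Character stage name.
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(1L, "reads")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000003L
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% .Machine$integer.max)
}

# Validate a chromosome-name -> length map.
check_chrom_lengths <- function(chrom_lengths) {
  if (length(chrom_lengths) == 0L) {
    abort("`chrom_lengths` must name at least one chromosome.")
  }
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    abort("`chrom_lengths` must be a named vector of lengths.")
  }
  if (any(chrom_lengths <= 0)) {
    abort("Chromosome lengths must be positive.")
  }
  chrom_lengths
}

# Parse "chrom:pos" or list(chrom=, pos=) into a list(chrom, pos).
parse_locus <- function(x) {
  if (is.list(x)) {
    stopifnot(!is.null(x$chrom), !is.null(x$pos))
    return(list(chrom = as.character(x$chrom), pos = as.numeric(x$pos)))
  }
  parts <- strsplit(as.character(x), ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L) abort("Locus must be 'chrom:pos' or list(chrom=, pos=).")
  list(chrom = parts[1], pos = as.numeric(parts[2]))
}

# Motif sanity shared by digestion operations.
check_motif <- function(motif, arg = "motif") {
  if (!is.character(motif) || length(motif) != 1L || nchar(motif) < 1L) {
    abort(sprintf("`%s` must be a non-empty DNA string.", arg))
  }
  if (grepl("[^ACGT]", motif)) {
    abort(sprintf("`%s` must contain only A/C/G/T.", arg))
  }
  motif
}
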