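# Differential-expression criteria, chromosome-distribution bias, and cohort
# percentage arithmetic.

check_groups <- function(mat, groups) {
  if (length(groups) != ncol(mat)) abort("`groups` must label every sample column.")
  lev <- unique(groups)
  if (length(lev) != 2L) abort("`groups` must partition samples into two groups.")
  if (any(table(groups) < 1L)) abort("Empty group.")
  lev
}

#' Per-probe fold changes between two groups
#'
#' The fold change is the ratio of group mean expression values computed on
#' the intensity scale (anti-logged), reported as a log2 ratio; set
#' `method = "log_means"` for the difference of log2 group means instead.
#'
#' @param mat Probes x samples matrix of log2 expression values.
#' @param groups Character vector of group labels per column, two levels; the
#'   first level encountered is treated as the reference (control).
#' @param method `"mean_intensity"` (default) or `"log_means"`.
#' @return A tibble `probe`, `log2_fc`.
#' @export
fold_changes <- function(mat, groups, method = c("mean_intensity", "log_means")) {
  method <- match.arg(method)
  lev <- check_groups(mat, groups)
  ctrl <- mat[, groups == lev[1], drop = FALSE]
  mut <- mat[, groups == lev[2], drop = FALSE]
  lfc <- if (method == "mean_intensity") {
    log2(rowMeans(2^mut) / rowMeans(2^ctrl))
  } else {
    rowMeans(mut) - rowMeans(ctrl)
  }
  tibble(probe = rownames(mat) %||% as.character(seq_len(nrow(mat))),
         log2_fc = unname(lfc))
}

#' Differential-expression call with fold-change and p-value criteria
#'
#' A probe passes when its absolute log2 fold change exceeds `lfc_threshold`,
#' its two-sided t-test p-value (on log2 values) is below `alpha`, and
#' it is not low-expression (overall mean below `min_mean_expression`;
#' low-expression probes never pass regardless of fold change). The default
#' test pools variances (Student), which is exactly calibrated at the 3-vs-3
#' design under equal group variances; `welch = TRUE` switches to the
#' unequal-variance test, which is noticeably conservative at n = 3. Probes
#' with zero variance in both groups get p = 1. No multiple-testing
#' correction is applied to the pass criterion; a Benjamini-Hochberg column
#' is emitted for information.
#'
#' @param mat Probes x samples matrix of log2 expression values.
#' @param groups Two-level group labels per column (first level = control).
#' @param lfc_threshold Absolute log2 fold-change threshold (default 0.5).
#' @param alpha P-value threshold (default 0.05).
#' @param min_mean_expression Low-expression cutoff on the overall probe mean
#'   (default: the 20th percentile of probe means).
#' @param fc_method Passed to [fold_changes()].
#' @param welch Use the Welch unequal-variance t-test instead of the pooled
#'   test.
#' @return A `de_result` tibble: `probe`, `log2_fc`, `p`, `p_bh`,
#'   `low_expression`, `pass`, `direction`; attribute `counts` holds the
#'   up/down totals.
#' @export
de_call <- function(mat, groups, lfc_threshold = 0.5, alpha = 0.05,
                    min_mean_expression = NULL,
                    fc_method = c("mean_intensity", "log_means"),
                    welch = FALSE) {
  lev <- check_groups(mat, groups)
  if (any(table(groups) < 2L)) abort("Each group needs at least 2 samples.")
  if (lfc_threshold <= 0 || alpha <= 0) abort("Thresholds must be positive.")
  if (is.null(min_mean_expression)) {
    min_mean_expression <- unname(quantile(rowMeans(mat), 0.2))
  }

  ctrl <- mat[, groups == lev[1], drop = FALSE]
  mut <- mat[, groups == lev[2], drop = FALSE]
  p <- vapply(seq_len(nrow(mat)), function(i) {
    x <- mut[i, ]; y <- ctrl[i, ]
    if (var(x) == 0 && var(y) == 0) return(1)
    t.test(x, y, var.equal = !welch)$p.value
  }, numeric(1))

  fc <- fold_changes(mat, groups, method = match.arg(fc_method))
  low <- rowMeans(mat) < min_mean_expression
  pass <- abs(fc$log2_fc) > lfc_threshold & p < alpha & !low
  out <- tibble(
    probe = fc$probe, log2_fc = fc$log2_fc, p = p,
    p_bh = p.adjust(p, method = "BH"),
    low_expression = unname(low), pass = pass,
    direction = dplyr::case_when(!pass ~ NA_character_,
                                 fc$log2_fc > 0 ~ "up", TRUE ~ "down")
  )
  structure(out, class = c("de_result", class(out)),
            counts = c(up = sum(out$direction == "up", na.rm = TRUE),
                       down = sum(out$direction == "down", na.rm = TRUE)),
            lfc_threshold = lfc_threshold, alpha = alpha,
            min_mean_expression = min_mean_expression)
}

#' Chromosome-distribution bias of a regulated gene set
#'
#' Pearson chi-square goodness-of-fit of the observed per-chromosome counts
#' of a probe set against expectations proportional to the universe's
#' chromosome composition. Chromosomes with expected count below 1 are pooled
#' into one category; df = categories - 1.
#'
#' @param de_probes Character vector of regulated probe ids.
#' @param universe Tibble `probe`, `chrom` covering all probes (and all DE
#'   probes).
#' @return A list: `table` (tibble `chrom`, `observed`, `expected`,
#'   `fraction`), `statistic`, `df`, `p`.
#' @export
chromosome_bias <- function(de_probes, universe) {
  if (length(de_probes) == 0L) abort("Empty regulated set.")
  universe <- as_tibble(universe)
  if (!all(de_probes %in% universe$probe)) {
    abort("`universe` must cover all regulated probes.")
  }
  n <- length(de_probes)
  comp <- table(universe$chrom)
  expected <- n * as.numeric(comp) / sum(comp)
  observed <- as.numeric(table(factor(
    universe$chrom[match(de_probes, universe$probe)], levels = names(comp))))

  tab <- tibble(chrom = names(comp), observed = observed, expected = expected,
                fraction = observed / n)
  pool <- expected < 1
  if (any(pool) && sum(!pool) >= 1) {
    obs2 <- c(observed[!pool], sum(observed[pool]))
    exp2 <- c(expected[!pool], sum(expected[pool]))
  } else {
    obs2 <- observed; exp2 <- expected
  }
  x2 <- sum((obs2 - exp2)^2 / exp2)
  df <- length(obs2) - 1L
  list(table = tab, statistic = x2, df = df,
       p = pchisq(x2, df, lower.tail = FALSE))
}

#' Percentage of a count within a total
#'
#' `100 * count / total`, rounded half away from zero to `decimals` places —
#' the convention of quoted cohort proportions.
#'
#' @param count Numerator (0 <= count <= total).
#' @param total Denominator (> 0).
#' @param decimals Decimal places (default 0).
#' @return The percentage.
#' @export
#' @examples
#' percentage_summary(96, 134)     # 72
#' percentage_summary(10, 134, 1)  # 7.5
percentage_summary <- function(count, total, decimals = 0) {
  if (total <= 0) abort("`total` must be positive.")
  if (count < 0 || count > total) abort("`count` must lie in [0, total].")
  round_half_up(100 * count / total, decimals)
}
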