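# broom-style tidy()/glance() methods for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a decay fit
#'
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @return One row per model term (`intercept`, fixed `slope`).
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         fixed = c(FALSE, TRUE))
}

#' @rdname tidy.decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble(intercept = x$intercept, slope = x$slope,
         trans_background = x$trans_background, n_fit = x$n_fit,
         free_slope = x$free_slope)
}

#' Tidy a Knet result
#'
#' @param x A `knet_result`.
#' @param ... Unused.
#' @return `tidy()`: the K(s) curve; `glance()`: one row with AUK,
#'   permutation p-value, permutation count and seed.
#' @export
tidy.knet_result <- function(x, ...) x$k

#' @rdname tidy.knet_result
#' @export
glance.knet_result <- function(x, ...) {
  tibble(auk = x$auk, p_value = x$p_value, n_perm = x$n_perm,
         seed = x$seed, n_vertices = x$n_vertices,
         mean_weight = x$mean_weight)
}

#' Tidy a BRICK FDR estimate
#'
#' @param x A `brick_fdr`.
#' @param ... Unused.
#' @return `tidy()`: the FDR estimate per calling threshold; `glance()`: one
#'   row per calibrated tier.
#' @export
tidy.brick_fdr <- function(x, ...) x$fdr

#' @rdname tidy.brick_fdr
#' @export
glance.brick_fdr <- function(x, ...) x$tiers
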