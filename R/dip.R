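#' Hartigan's dip statistic
#'
#' The dip is the largest vertical distance between the empirical CDF of a
#' sample and the closest unimodal CDF, located by the greatest-convex-
#' minorant / least-concave-majorant algorithm over candidate modal
#' intervals. It is bounded by `1/(2n)` (attained by perfectly unimodal
#' configurations such as an equally spaced grid) and `0.25` (two separated
#' point masses), and is invariant under monotone affine transformations of
#' the sample.
#'
#' @param x numeric vector of at least two finite values.
#' @return the dip statistic, a single number in `[1/(2n), 0.25]`.
#' @seealso [dip_pvalue()], [dip_test()]
#' @examples
#' dip_statistic(c(0, 1))              # 0.25, the maximal dip
#' dip_statistic(seq(0, 1, length = 100))  # 1/200, the minimal dip
#' @export
dip_statistic <- function(x) {
  if (!is.numeric(x)) stop("`x` must be numeric")
  if (length(x) < 2) stop("dip statistic needs at least 2 observations")
  if (!all(is.finite(x))) stop("`x` must contain only finite values")
  .dip_c(as.numeric(x))
}

#' Monte-Carlo p-value for the dip test
#'
#' The null reference distribution is the dip of uniform(0,1) samples of the
#' same size, the standard calibration for the dip test. The p-value uses
#' the add-one estimator `(1 + #\{null dips >= observed\}) / (reps + 1)`,
#' which never returns exactly zero.
#'
#' @param dip observed dip statistic.
#' @param n sample size the dip was computed from.
#' @param reps number of null replicates (default 10000).
#' @param seed optional integer seed applied locally (the caller's RNG state
#'   is restored on exit); if `NULL` the current RNG stream is consumed.
#' @return p-value in `(0, 1]`.
#' @export
dip_pvalue <- function(dip, n, reps = 10000L, seed = NULL) {
  stopifnot(is.numeric(dip), length(dip) == 1L, n >= 2, reps >= 1)
  null_dips <- dip_null(n, reps, seed = seed)
  (1 + sum(null_dips >= dip)) / (reps + 1)
}

#' Null distribution of the dip statistic
#'
#' Draws `reps` uniform(0,1) samples of size `n` and returns their dip
#' statistics. Exposed so that simulation studies can reuse one null table
#' across many observed samples of equal size.
#'
#' @inheritParams dip_pvalue
#' @return numeric vector of `reps` dip statistics.
#' @export
dip_null <- function(n, reps, seed = NULL) {
  stopifnot(n >= 2, reps >= 1)
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  .dip_null_c(as.integer(n), as.integer(reps))
}

#' Dip test of unimodality
#'
#' Convenience wrapper combining [dip_statistic()] and [dip_pvalue()]. A
#' small p-value indicates departure from unimodality; in the vein-
#' arrangement context it flags an opposite-like (bimodal) spacing-ratio
#' distribution.
#'
#' @inheritParams dip_statistic
#' @inheritParams dip_pvalue
#' @return a list of class `"vein_dip"` with fields `n`, `dip`, `p_value`,
#'   `reps` and `seed`.
#' @export
dip_test <- function(x, reps = 10000L, seed = NULL) {
  d <- dip_statistic(x)
  structure(
    list(n = length(x), dip = d,
         p_value = dip_pvalue(d, length(x), reps = reps, seed = seed),
         reps = as.integer(reps), seed = seed),
    class = "vein_dip")
}

#' @export
print.vein_dip <- function(x, ...) {
  cat("Hartigan dip test (Monte-Carlo)\n")
  cat(sprintf("  n = %d, dip = %.6g, p = %.4g (%d null replicates)\n",
              x$n, x$dip, x$p_value, x$reps))
  invisible(x)
}
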