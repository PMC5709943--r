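#' Demonstration: t-test applied directly to ratio-scale values
#'
#' A deliberately improper analysis, kept only to show why it must not be
#' used. Per-pair expression ratios \eqn{b^{-\Delta\Delta C_{q;r}^{(w)}}}
#' are tested against a hypothesized mean of 1 with a one-sample t-test,
#' once in each direction (A vs. B and B vs. A, i.e. with the ratios
#' reciprocated). Because ratios are not normally distributed (their logs
#' are), the two directions can disagree about significance: the same data
#' would both reject and fail to reject the same hypothesis. The log-scale
#' test ([pairedTest()]) is immune: swapping the groups only negates the
#' estimate, statistic and interval, leaving the p-value unchanged.
#'
#' @param a,b per-pair delta-Cq values for the two sample types (numeric
#'   vectors or data.frames with \code{replicate} and \code{dcq} columns;
#'   pairing as in [pairedTest()]).
#' @param base logarithm base, default 10.
#' @param alpha significance level for the consistency flag, default 0.05.
#' @param quiet suppress the warning that this analysis is improper.
#' @return a [MisuseReport-class].
#' @examples
#' a <- c(1.1387, 0.845, 0.499, 0.699)
#' b <- c(1.4077, 1.291, 1.496, 1.172)
#' improperRatioTest(a, b, quiet = TRUE)
#' @export
improperRatioTest <- function(a, b, base = 10, alpha = 0.05, quiet = FALSE) {
  checkBase(base)
  ab <- alignGroups(a, b, paired = TRUE)
  dd <- ab$a - ab$b
  if (length(dd) < 2L) stop("need >= 2 pairs", call. = FALSE)
  if (!quiet)
    warning("improperRatioTest() is a demonstration of an invalid analysis ",
            "(direction-dependent); use pairedTest() on log-scale values",
            call. = FALSE)
  ratios_ab <- base^(-dd)
  ratios_ba <- base^(dd)
  dir_ab <- directionRecord(ratios_ab)
  dir_ba <- directionRecord(ratios_ba)
  new("MisuseReport", direction.ab = dir_ab, direction.ba = dir_ba,
      ratios.ab = ratios_ab, ratios.ba = ratios_ba, alpha = alpha,
      consistent = (dir_ab[["p"]] < alpha) == (dir_ba[["p"]] < alpha))
}

directionRecord <- function(r) {
  if (sd(r) == 0) {
    # constant ratios: zero spread around the hypothesized mean of 1
    t0 <- if (mean(r) == 1) 0 else sign(mean(r) - 1) * Inf
    return(c(mean_ratio = mean(r), sd = 0, t = t0,
             p = if (t0 == 0) 1 else 0))
  }
  tt <- t.test(r, mu = 1)
  c(mean_ratio = mean(r), sd = sd(r), t = unname(tt$statistic),
    p = tt$p.value)
}

#' Check reciprocity of a two-group analysis
#'
#' A direction-symmetric analysis must give mirrored answers when the two
#' group labels are exchanged: the p-values must be equal, the test
#' statistics must negate, and the expression ratios (and their interval
#' bounds, order-reversed) must be multiplicative inverses. The log-scale
#' tests satisfy this by construction; the ratio-scale misuse test
#' generically does not.
#'
#' @param ab,ba results of the same analysis run in the two directions
#'   ([CommonBaseTest-class] objects), or a single [MisuseReport-class]
#'   (whose two internal directions are then compared).
#' @param tol tolerance: absolute for p-values and statistics, relative for
#'   ratios. Default \code{1e-8}.
#' @return logical(1).
#' @rdname reciprocityCheck
#' @export
setMethod("reciprocityCheck", signature("CommonBaseTest", "CommonBaseTest"),
          function(ab, ba, tol = 1e-8) {
  if (!identical(ab@n, ba@n) && !identical(ab@n, rev(ba@n)))
    stop("results come from different sample sizes; they cannot be the two ",
         "directions of one analysis", call. = FALSE)
  p_ok <- abs(ab@p.value - ba@p.value) <= tol
  t_ok <- abs(ab@statistic + ba@statistic) <= tol
  r_ok <- abs(ba@ratio * ab@ratio - 1) <= tol
  ci_ok <- all(abs(ba@ratio.conf.int * rev(ab@ratio.conf.int) - 1) <= tol)
  isTRUE(p_ok && t_ok && r_ok && ci_ok)
})

#' @rdname reciprocityCheck
#' @export
setMethod("reciprocityCheck", signature("MisuseReport", "missing"),
          function(ab, ba, tol = 1e-8) {
  x <- ab@direction.ab; y <- ab@direction.ba
  p_ok <- abs(x[["p"]] - y[["p"]]) <= tol
  t_ok <- abs(x[["t"]] + y[["t"]]) <= tol
  r_ok <- abs(x[["mean_ratio"]] * y[["mean_ratio"]] - 1) <= tol
  isTRUE(p_ok && t_ok && r_ok)
})
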