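#' @importFrom stats anova lm pt qt sd shapiro.test t.test var
NULL

#' Unpaired (two-sample) test of delta-Cq values
#'
#' Compares the mean normalized log-scale expression
#' (\eqn{\Delta C_q^{(w)}}) of two sample types whose biological replicates
#' are unrelated. By default variances are not assumed equal (Welch test
#' with Satterthwaite degrees of freedom, kept non-integer); the confidence
#' interval uses Student-t quantiles on those degrees of freedom. The
#' estimate, interval and ratio are reported both in log scale and
#' back-transformed to the expression-ratio scale.
#'
#' @param a,b numeric vectors of delta-Cq values (or data.frames with a
#'   \code{dcq} column, e.g. subsets of [deltaCq()] output); group A is the
#'   numerator of the reported ratio.
#' @param conf.level nominal confidence level, default 0.95.
#' @param var.equal use the classical pooled-variance test instead of Welch.
#' @param base logarithm base the delta-Cq values were computed in.
#' @param check.assumptions if TRUE, run an advisory Shapiro-Wilk normality
#'   screen on each group and warn (never fail) when it rejects at 0.05.
#' @return a [CommonBaseTest-class].
#' @examples
#' a <- c(1.1387, 0.845, 0.499, 0.699)
#' b <- c(1.4077, 1.291, 1.496, 1.172)
#' unpairedTest(a, b)
#' @export
unpairedTest <- function(a, b, conf.level = 0.95, var.equal = FALSE,
                         base = 10, check.assumptions = FALSE) {
  checkBase(base)
  ab <- alignGroups(a, b, paired = FALSE)
  a <- ab$a; b <- ab$b
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs >= 2 values for inference; for a point estimate ",
         "only, use deltaDeltaCq()", call. = FALSE)
  if (var(a) == 0 && var(b) == 0)
    stop("both groups have zero variance: inference is degenerate",
         call. = FALSE)
  if (check.assumptions) adviseNormality(list(`group A` = a, `group B` = b))
  tt <- t.test(a, b, var.equal = var.equal, conf.level = conf.level)
  buildTestResult(estimate = mean(a) - mean(b), se = tt$stderr,
                  df = unname(tt$parameter), statistic = unname(tt$statistic),
                  p.value = tt$p.value, conf.int = as.numeric(tt$conf.int),
                  conf.level = conf.level, base = base,
                  n = c(length(a), length(b)),
                  method = if (var.equal)
                    "Unpaired pooled-variance t-test on delta-Cq(w)"
                  else "Unpaired Welch t-test on delta-Cq(w)")
}

#' Paired test of delta-Cq values
#'
#' For designs in which every biological replicate of sample type A is
#' paired with one of sample type B (same individual, same location, same
#' plate pairing), the per-pair differences of \eqn{\Delta C_q^{(w)}} are
#' tested against zero with a one-sample t-test on \eqn{n - 1} degrees of
#' freedom. Pairing is by position for numeric input and by replicate label
#' for data.frame input.
#'
#' @inheritParams unpairedTest
#' @return a [CommonBaseTest-class].
#' @examples
#' a <- c(1.1387, 0.845, 0.499, 0.699)
#' b <- c(1.4077, 1.291, 1.496, 1.172)
#' pairedTest(a, b)
#' @export
pairedTest <- function(a, b, conf.level = 0.95, base = 10,
                       check.assumptions = FALSE) {
  checkBase(base)
  ab <- alignGroups(a, b, paired = TRUE)
  d <- ab$a - ab$b
  if (length(d) < 2L)
    stop("paired inference needs >= 2 pairs", call. = FALSE)
  if (var(d) == 0)
    stop("all per-pair differences are identical: zero variance, inference ",
         "is degenerate", call. = FALSE)
  if (check.assumptions) adviseNormality(list(`pair differences` = d))
  tt <- t.test(d, mu = 0, conf.level = conf.level)
  buildTestResult(estimate = mean(d), se = tt$stderr,
                  df = unname(tt$parameter), statistic = unname(tt$statistic),
                  p.value = tt$p.value, conf.int = as.numeric(tt$conf.int),
                  conf.level = conf.level, base = base, n = length(d),
                  method = "Paired t-test on delta-Cq(w) differences")
}

buildTestResult <- function(estimate, se, df, statistic, p.value, conf.int,
                            conf.level, base, n, method) {
  new("CommonBaseTest", estimate = estimate, se = se, df = df,
      statistic = statistic, p.value = p.value, conf.int = conf.int,
      ratio = ratioFromDeltaDelta(estimate, base = base),
      ratio.conf.int = backtransformInterval(conf.int, base = base),
      conf.level = conf.level, base = base, n = as.integer(n),
      method = method)
}

adviseNormality <- function(groups) {
  for (nm in names(groups)) {
    x <- groups[[nm]]
    if (length(x) >= 3L && length(x) <= 5000L && var(x) > 0) {
      p <- shapiro.test(x)$p.value
      if (p < 0.05)
        warning("advisory: Shapiro-Wilk normality screen rejects for ", nm,
                " (p = ", signif(p, 3), "); log-scale normality is an ",
                "assumption of these tests", call. = FALSE)
    }
  }
  invisible(NULL)
}

#' One-factor ANOVA of delta-Cq values with additive blocking
#'
#' Decomposes normalized log-scale expression into a sample-type effect,
#' additive block effects (plates, individuals), and residual error.
#' Blocking partitions nuisance variation out of the error term; block F
#' statistics are reported but are not of inferential interest. With an
#' empty block list this is a one-way ANOVA. Interactions with blocks are
#' never fitted.
#'
#' Balanced complete designs use the classical sequential decomposition
#' (orthogonal here, so order is irrelevant). Unbalanced-but-complete
#' designs fall back to the marginal (each-term-after-all-others)
#' decomposition with a warning; a factor level entirely absent from a
#' block is an error.
#'
#' @param data data.frame holding one row per (replicate, sample type)
#'   delta-Cq value.
#' @param value name of the response column (default \code{"dcq"}).
#' @param factor name of the sample-type column (default
#'   \code{"sample_type"}).
#' @param blocks character vector of blocking-column names (possibly
#'   empty), e.g. \code{"plate"} or \code{"replicate"}.
#' @param conf.level confidence level for post-hoc intervals.
#' @param base logarithm base of the delta-Cq values.
#' @param adjust \code{"bonferroni"} (default) or \code{"none"} for the
#'   post-hoc p-values. Post-hoc confidence intervals are always
#'   unadjusted.
#' @return a [CommonBaseAnova-class]; pairwise comparisons via
#'   [posthocPairwise()].
#' @examples
#' d <- data.frame(dcq = c(0.855, 0.711, 0.582, 0.699,
#'                         1.203, 1.056, 0.890, 0.775,
#'                         0.866, 0.799, 0.522, 0.669),
#'                 sample_type = rep(c("A", "B", "C"), each = 4),
#'                 plate = rep(rep(c("p1", "p2"), each = 2), 3))
#' blockedAnova(d, blocks = "plate")
#' @export
blockedAnova <- function(data, value = "dcq", factor = "sample_type",
                         blocks = NULL, conf.level = 0.95, base = 10,
                         adjust = c("bonferroni", "none")) {
  checkBase(base)
  adjust <- match.arg(adjust)
  blocks <- as.character(blocks %||% character())
  need <- c(value, factor, blocks)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("data is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  y <- as.numeric(data[[value]])
  if (any(!is.finite(y))) stop("response values must be finite", call. = FALSE)
  f <- base::factor(data[[factor]])
  if (nlevels(f) < 2L)
    stop("need >= 2 sample-type levels", call. = FALSE)
  blk <- lapply(blocks, function(b) base::factor(data[[b]]))
  names(blk) <- blocks

  balanced <- TRUE
  for (b in blocks) {
    tab <- table(f, blk[[b]])
    if (any(tab == 0L)) {
      empty <- which(tab == 0L, arr.ind = TRUE)[1, ]
      stop(sprintf(
        "design error: sample type '%s' has no observation in %s '%s'",
        levels(f)[empty[1]], b, levels(blk[[b]])[empty[2]]), call. = FALSE)
    }
    if (length(unique(as.vector(tab))) > 1L) balanced <- FALSE
  }
  if (length(unique(table(f))) > 1L) balanced <- FALSE

  n <- length(y)
  model_df <- data.frame(.y = y, .f = f)
  for (b in blocks) model_df[[b]] <- blk[[b]]
  rhs <- paste(c(".f", blocks), collapse = " + ")

  if (var(y) == 0) {
    # constant response: every SS is 0, F ratios are undefined, not errors
    dfs <- c(nlevels(f) - 1L, vapply(blk, function(x) nlevels(x) - 1L,
                                     integer(1)))
    err_df <- n - 1L - sum(dfs)
    sources <- data.frame(
      source = c(factor, blocks, "Error", "Total"),
      df = c(dfs, err_df, n - 1L),
      ss = 0, ms = c(rep(0, length(dfs) + 1L), NA_real_),
      f = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
    sources$ms[nrow(sources)] <- NA_real_
    fit <- NULL
  } else {
    fit <- lm(stats::as.formula(paste(".y ~", rhs)), data = model_df)
    if (fit$df.residual == 0L)
      stop("zero residual degrees of freedom: the additive model saturates ",
           "the data", call. = FALSE)
    if (balanced) {
      at <- anova(fit)
      terms_idx <- seq_len(nrow(at) - 1L)
      ss <- at[["Sum Sq"]]; dfv <- at[["Df"]]
      mse <- ss[nrow(at)] / dfv[nrow(at)]
      sources <- data.frame(
        source = c(factor, blocks, "Error", "Total"),
        df = c(dfv, sum(dfv)),
        ss = c(ss, sum(ss)),
        ms = c(ss / dfv, NA_real_),
        f = c((ss[terms_idx] / dfv[terms_idx]) / mse, NA_real_, NA_real_),
        p = c(at[["Pr(>F)"]][terms_idx], NA_real_, NA_real_),
        stringsAsFactors = FALSE)
    } else {
      warning("unbalanced design: using the marginal ",
              "(each-term-after-all-others) decomposition; component sums ",
              "of squares need not add to the total", call. = FALSE)
      dr <- stats::drop1(fit, test = "F")
      rss_full <- sum(stats::residuals(fit)^2)
      err_df <- fit$df.residual
      mse <- rss_full / err_df
      term_names <- rownames(dr)[-1L]
      ss <- dr[["Sum of Sq"]][-1L]
      dfv <- dr[["Df"]][-1L]
      label <- ifelse(term_names == ".f", factor, term_names)
      sources <- data.frame(
        source = c(label, "Error", "Total"),
        df = c(dfv, err_df, n - 1L),
        ss = c(ss, rss_full, sum((y - mean(y))^2)),
        ms = c(ss / dfv, mse, NA_real_),
        f = c((ss / dfv) / mse, NA_real_, NA_real_),
        p = c(dr[["Pr(>F)"]][-1L], NA_real_, NA_real_),
        stringsAsFactors = FALSE)
    }
  }

  means <- tapply(y, f, mean)
  n_per <- table(f)
  result <- new("CommonBaseAnova", sources = sources,
                posthoc = data.frame(), means = as.numeric(means),
                n.per.level = as.numeric(n_per),
                conf.level = conf.level, base = base, balanced = balanced)
  names(result@means) <- levels(f)
  names(result@n.per.level) <- levels(f)
  result@posthoc <- if (is.null(fit)) emptyPosthoc() else
    computePosthoc(result, adjust = adjust)
  validObject(result)
  result
}

`%||%` <- function(x, y) if (is.null(x)) y else x

emptyPosthoc <- function() {
  data.frame(level_a = character(), level_b = character(), diff = numeric(),
             se = numeric(), df = numeric(), t = numeric(),
             p_adjusted = numeric(), ci_lower = numeric(),
             ci_upper = numeric(), ratio = numeric(),
             ratio_ci_lower = numeric(), ratio_ci_upper = numeric(),
             n_eff = numeric(), stringsAsFactors = FALSE)
}

computePosthoc <- function(object, adjust = "bonferroni") {
  src <- object@sources
  mse <- src$ms[src$source == "Error"]
  dfe <- src$df[src$source == "Error"]
  lv <- names(object@means)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  m <- length(pairs)
  unequal <- length(unique(object@n.per.level)) > 1L
  if (unequal)
    warning("unequal level sizes: post-hoc standard errors use the ",
            "harmonic-mean sample size (flagged in n_eff)", call. = FALSE)
  rows <- lapply(pairs, function(pr) {
    na <- object@n.per.level[pr[1]]; nb <- object@n.per.level[pr[2]]
    n_eff <- 2 / (1 / na + 1 / nb)          # harmonic mean; = n when equal
    se <- sqrt(2 * mse / n_eff)
    diff <- object@means[pr[1]] - object@means[pr[2]]
    tstat <- diff / se
    p_raw <- 2 * pt(-abs(tstat), dfe)
    p_adj <- if (adjust == "bonferroni") min(1, p_raw * m) else p_raw
    half <- qt((1 + object@conf.level) / 2, dfe) * se   # unadjusted quantile
    ci <- c(diff - half, diff + half)
    rci <- backtransformInterval(ci, base = object@base)
    data.frame(level_a = pr[1], level_b = pr[2], diff = unname(diff),
               se = se, df = dfe, t = unname(tstat), p_adjusted = p_adj,
               ci_lower = ci[1], ci_upper = ci[2],
               ratio = ratioFromDeltaDelta(unname(diff), object@base),
               ratio_ci_lower = rci[1], ratio_ci_upper = rci[2],
               n_eff = unname(n_eff), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Post-hoc pairwise comparisons of an ANOVA fit
#'
#' For each pair of sample-type levels: the difference of level means, a
#' t-test using the pooled error mean square on the error degrees of
#' freedom, Bonferroni-multiplied p-values (capped at 1), an unadjusted
#' confidence interval, and their ratio-scale back-transforms. This mixed
#' convention (adjusted p, unadjusted CI) mirrors standard reporting of
#' blocked qPCR designs.
#'
#' @param object a [CommonBaseAnova-class].
#' @return data.frame with one row per level pair: \code{level_a},
#'   \code{level_b}, \code{diff}, \code{se}, \code{df}, \code{t},
#'   \code{p_adjusted}, \code{ci_lower}, \code{ci_upper}, \code{ratio},
#'   \code{ratio_ci_lower}, \code{ratio_ci_upper}, \code{n_eff} (the
#'   per-level sample size; harmonic mean when levels are unequal).
#' @rdname posthocPairwise
#' @export
setMethod("posthocPairwise", "CommonBaseAnova", function(object)
  object@posthoc)

#' Result accessors
#'
#' @param object a [CommonBaseTest-class].
#' @return \code{logEstimate()} the delta-delta-Cq estimate;
#'   \code{logConfInt()} its log-scale interval; \code{expressionRatio()}
#'   the back-transformed ratio; \code{ratioConfInt()} the ratio-scale
#'   interval; \code{pValue()} the two-tailed p-value.
#' @name result-accessors
NULL

#' @rdname result-accessors
#' @export
logEstimate <- function(object) object@estimate

#' @rdname result-accessors
#' @export
logConfInt <- function(object) object@conf.int

#' @rdname result-accessors
#' @export
expressionRatio <- function(object) object@ratio

#' @rdname result-accessors
#' @export
ratioConfInt <- function(object) object@ratio.conf.int

#' @rdname result-accessors
#' @export
pValue <- function(object) object@p.value
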