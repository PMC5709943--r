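#' Efficiency-weighted quantification cycle
#'
#' Multiplies each quantification cycle by the base-\code{base} logarithm of
#' its well's amplification efficiency, putting wells with differing
#' efficiencies on a common log-quantity scale:
#' \eqn{C_q^{(w)} = \log_b(E)\, C_q}. Since
#' \eqn{b^{\log_b(E) C_q} = E^{C_q}}, the weighted value is the log (base
#' \eqn{b}) of the amount of amplification the well underwent.
#'
#' @param efficiency numeric, fold-amplification per cycle; must be > 1
#'   (an efficiency of exactly 1 has log-weight 0 and carries no quantity
#'   information).
#' @param cq numeric, quantification cycles; finite, recycled against
#'   \code{efficiency}.
#' @param base logarithm base, default 10. Must exceed 1.
#' @return numeric vector of weighted Cq values, full precision.
#' @examples
#' weightedCq(1.836, 32.316)        # ~8.527
#' weightedCq(10, 5)                # exactly 5
#' @export
weightedCq <- function(efficiency, cq, base = 10) {
  checkBase(base)
  if (any(!is.finite(efficiency)) || any(efficiency <= 1))
    stop("efficiency must be finite and > 1 (fold-amplification per cycle, ",
         "not percent or E-1)", call. = FALSE)
  if (any(!is.finite(cq)))
    stop("cq must be finite", call. = FALSE)
  log(efficiency, base = base) * cq
}

checkBase <- function(base) {
  if (!is.numeric(base) || length(base) != 1L || !is.finite(base) || base <= 1)
    stop("base must be a single finite number > 1", call. = FALSE)
  invisible(base)
}

#' Aggregate technical replicates of efficiency-weighted Cq values
#'
#' Averages weighted Cq values over the technical-replicate wells of each
#' (replicate, sample type, gene) group:
#' \eqn{C^{(w)}_{q;r,t,g} = \frac1n \sum_i \log_b(E_i) C_{q;i}}.
#' Averaging happens in the weighted (log) space, never on raw Cq, so wells
#' with different efficiencies contribute on a common scale. Groups may have
#' unequal numbers of wells.
#'
#' @param object a [QPCRExperiment-class], or a data.frame with columns
#'   \code{replicate}, \code{sample_type}, \code{gene} and either \code{wcq}
#'   (pre-weighted values) or \code{efficiency} + \code{cq}.
#' @param base logarithm base, default 10.
#' @return data.frame with columns \code{replicate}, \code{sample_type},
#'   \code{gene}, \code{wcq} (the group mean weighted Cq) and \code{n_wells}.
#' @rdname aggregateTechnical
#' @export
setMethod("aggregateTechnical", "QPCRExperiment", function(object, base = 10) {
  w <- object@wells
  w$wcq <- weightedCq(w$efficiency, w$cq, base = base)
  aggregateWeighted(w)
})

#' @rdname aggregateTechnical
#' @export
setMethod("aggregateTechnical", "data.frame", function(object, base = 10) {
  need <- c("replicate", "sample_type", "gene")
  if (!all(need %in% names(object)))
    stop("need columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (!"wcq" %in% names(object)) {
    if (!all(c("efficiency", "cq") %in% names(object)))
      stop("need either a 'wcq' column or 'efficiency' and 'cq' columns",
           call. = FALSE)
    object$wcq <- weightedCq(object$efficiency, object$cq, base = base)
  }
  if (any(!is.finite(object$wcq)))
    stop("weighted Cq values must be finite", call. = FALSE)
  aggregateWeighted(object)
})

aggregateWeighted <- function(w) {
  if (nrow(w) == 0L) stop("no wells to aggregate", call. = FALSE)
  key <- interaction(w$replicate, w$sample_type, w$gene, drop = TRUE,
                     lex.order = TRUE)
  first <- !duplicated(key)
  out <- data.frame(replicate = w$replicate[first],
                    sample_type = w$sample_type[first],
                    gene = w$gene[first],
                    wcq = as.numeric(tapply(w$wcq, key, mean)[
                      as.character(key[first])]),
                    n_wells = as.integer(table(key)[
                      as.character(key[first])]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Normalized (delta) efficiency-weighted Cq values
#'
#' For each (replicate, sample type), subtracts the arithmetic mean of the
#' reference genes' aggregated weighted Cq values from the gene of
#' interest's: \eqn{\Delta C^{(w)}_{q;r,t} = C^{(w)}_{q;GOI} -
#' \frac1n\sum_i C^{(w)}_{q;REF_i}}. Because the values live in log scale,
#' the arithmetic mean of the reference values is equivalent to normalizing
#' by the geometric mean of the reference quantities.
#'
#' @param object a [QPCRExperiment-class] (the GOI and reference genes are
#'   taken from the object), or an aggregated weighted-Cq data.frame as
#'   returned by [aggregateTechnical()].
#' @param goi,refs gene labels; required for the data.frame method.
#' @param base logarithm base, default 10.
#' @return data.frame with columns \code{replicate}, \code{sample_type},
#'   \code{dcq}, one row per (replicate, sample type). The
#'   \code{QPCRExperiment} method adds a \code{plate} column when all wells
#'   of a group sit on one plate (\code{NA} otherwise), so plate-blocked
#'   analyses can be run directly on the result.
#' @examples
#' plate <- examplePlate()
#' deltaCq(plate)
#' @rdname deltaCq
#' @export
setMethod("deltaCq", "QPCRExperiment", function(object, base = 10) {
  agg <- aggregateTechnical(object, base = base)
  out <- deltaCqFromAggregated(agg, object@goi, object@refs)
  w <- object@wells
  out$plate <- vapply(seq_len(nrow(out)), function(k) {
    p <- unique(w$plate[w$replicate == out$replicate[k] &
                        w$sample_type == out$sample_type[k]])
    if (length(p) == 1L) p else NA_character_
  }, character(1))
  out
})

#' @rdname deltaCq
#' @export
setMethod("deltaCq", "data.frame", function(object, goi, refs, base = 10) {
  if (!"wcq" %in% names(object) || !"gene" %in% names(object))
    stop("expected an aggregated weighted-Cq data.frame ",
         "(columns replicate, sample_type, gene, wcq)", call. = FALSE)
  deltaCqFromAggregated(object, goi, refs)
})

deltaCqFromAggregated <- function(agg, goi, refs) {
  if (length(refs) < 1L) stop("at least one reference gene is required",
                              call. = FALSE)
  grp <- unique(agg[, c("replicate", "sample_type")])
  dcq <- numeric(nrow(grp))
  for (k in seq_len(nrow(grp))) {
    sel <- agg$replicate == grp$replicate[k] &
           agg$sample_type == grp$sample_type[k]
    g <- agg$wcq[sel & agg$gene == goi]
    if (length(g) != 1L)
      stop(sprintf("replicate %s / sample type %s: expected one aggregated ",
                   grp$replicate[k], grp$sample_type[k]),
           "GOI value, found ", length(g), call. = FALSE)
    r <- vapply(refs, function(rf) {
      v <- agg$wcq[sel & agg$gene == rf]
      if (length(v) != 1L)
        stop(sprintf("replicate %s / sample type %s: missing reference %s",
                     grp$replicate[k], grp$sample_type[k], rf), call. = FALSE)
      v
    }, numeric(1))
    dcq[k] <- g - mean(r)
  }
  out <- data.frame(replicate = grp$replicate,
                    sample_type = grp$sample_type,
                    dcq = dcq, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Delta-delta Cq between two sample types
#'
#' \eqn{\Delta\Delta C^{(w)}_q = \Delta C^{(w)}_{q;A} - \Delta
#' C^{(w)}_{q;B}}: the difference of group means (unpaired) or the mean of
#' per-pair differences (paired). The two coincide on balanced complete
#' data; they differ in the inference attached to them, not the point
#' estimate.
#'
#' @param a,b numeric vectors of delta-Cq values, or data.frames with
#'   columns \code{replicate} and \code{dcq} (paired mode matches on the
#'   replicate label).
#' @param paired logical; paired mode requires matched replicates.
#' @return numeric(1), the delta-delta Cq estimate.
#' @export
deltaDeltaCq <- function(a, b, paired = FALSE) {
  ab <- alignGroups(a, b, paired = paired)
  if (paired) mean(ab$a - ab$b) else mean(ab$a) - mean(ab$b)
}

alignGroups <- function(a, b, paired = FALSE) {
  if (is.data.frame(a) != is.data.frame(b))
    stop("a and b must both be vectors or both be data.frames",
         call. = FALSE)
  if (is.data.frame(a)) {
    if (!all(c("replicate", "dcq") %in% names(a)) ||
        !all(c("replicate", "dcq") %in% names(b)))
      stop("data.frames need columns 'replicate' and 'dcq'", call. = FALSE)
    if (paired) {
      if (!setequal(a$replicate, b$replicate) ||
          anyDuplicated(a$replicate) || anyDuplicated(b$replicate))
        stop("paired mode requires matching, unique replicate labels ",
             "across the two sample types", call. = FALSE)
      b <- b[match(a$replicate, b$replicate), ]
    }
    return(list(a = a$dcq, b = b$dcq))
  }
  if (paired && length(a) != length(b))
    stop("paired mode requires equal-length groups", call. = FALSE)
  list(a = as.numeric(a), b = as.numeric(b))
}

#' Back-transform a delta-delta Cq to an expression ratio
#'
#' \eqn{R = b^{-\Delta\Delta C^{(w)}_q}}. The value of \eqn{R} does not
#' depend on the base used, provided the same base was used for the
#' weighting.
#'
#' @param ddcq numeric, delta-delta Cq value(s).
#' @param base logarithm base, default 10.
#' @return positive numeric, the relative expression ratio(s).
#' @examples
#' ratioFromDeltaDelta(-0.546)   # ~3.52
#' @export
ratioFromDeltaDelta <- function(ddcq, base = 10) {
  checkBase(base)
  if (any(!is.finite(ddcq))) stop("ddcq must be finite", call. = FALSE)
  base^(-ddcq)
}

#' Back-transform a log-scale confidence interval to the ratio scale
#'
#' Maps a log-scale interval \eqn{(l, u)} for \eqn{\Delta\Delta C^{(w)}_q}
#' to \eqn{(b^{-u}, b^{-l})} for the expression ratio. The negation flips
#' the order, so the output is again (low, high); the resulting interval is
#' asymmetric about the point ratio.
#'
#' @param ci numeric(2), log-scale interval with \code{ci[1] <= ci[2]}.
#' @param base logarithm base, default 10.
#' @return numeric(2), ratio-scale interval ordered low to high.
#' @examples
#' backtransformInterval(c(-1.046, -0.047))   # ~(1.11, 11.1)
#' @export
backtransformInterval <- function(ci, base = 10) {
  checkBase(base)
  if (length(ci) != 2L || any(!is.finite(ci)) || ci[1] > ci[2])
    stop("ci must be an ordered finite (lower, upper) pair", call. = FALSE)
  base^(-c(ci[2], ci[1]))
}

#' Reference-implementation ratios (equivalence oracles)
#'
#' Direct transcriptions of the two classical single-reference relative
#' quantification formulas, kept as independent cross-checks for the common
#' base pipeline: \code{livakRatio()} computes
#' \eqn{2^{-\Delta\Delta C_q}} from raw Cq means (assumes every reaction
#' doubles per cycle), and \code{pfafflRatio()} computes
#' \eqn{E_{GOI}^{-\Delta C_{q,GOI}} / E_{REF}^{-\Delta C_{q,REF}}} with
#' gene-wise constant efficiencies. Both support exactly one reference
#' gene; they are oracles, not the analysis path.
#'
#' @param cq_goi_a,cq_goi_b,cq_ref_a,cq_ref_b numeric vectors of raw Cq
#'   values (technical replicates are averaged arithmetically on the raw
#'   scale, as the classical methods prescribe).
#' @param e_goi,e_ref gene-wise constant amplification efficiencies.
#' @return numeric(1), the relative expression ratio A vs. B.
#' @export
livakRatio <- function(cq_goi_a, cq_ref_a, cq_goi_b, cq_ref_b) {
  ddcq <- (mean(cq_goi_a) - mean(cq_ref_a)) -
          (mean(cq_goi_b) - mean(cq_ref_b))
  2^(-ddcq)
}

#' @rdname livakRatio
#' @export
pfafflRatio <- function(cq_goi_a, cq_ref_a, cq_goi_b, cq_ref_b,
                        e_goi, e_ref) {
  if (length(e_goi) != 1L || length(e_ref) != 1L)
    stop("pfafflRatio supports a single gene-wise constant efficiency per ",
         "gene (oracle scope)", call. = FALSE)
  dcq_goi <- mean(cq_goi_a) - mean(cq_goi_b)
  dcq_ref <- mean(cq_ref_a) - mean(cq_ref_b)
  e_goi^(-dcq_goi) / e_ref^(-dcq_ref)
}
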