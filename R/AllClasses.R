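#' @import methods
NULL

WELL_COLUMNS <- c("replicate", "sample_type", "gene", "role",
                  "plate", "well", "efficiency", "cq")

#' QPCRExperiment: per-well qPCR measurements for one experiment
#'
#' Holds a long-format table of wells (one row per well) together with the
#' identity of the gene of interest (GOI) and the reference genes used for
#' normalization. Each well carries its amplification efficiency \eqn{E}
#' (fold-amplification per cycle, \eqn{1 < E \le 2} nominally) and its
#' quantification cycle \eqn{C_q}.
#'
#' @slot wells data.frame with columns \code{replicate}, \code{sample_type},
#'   \code{gene}, \code{role} (\code{"target"} or \code{"reference"}),
#'   \code{plate}, \code{well}, \code{efficiency}, \code{cq}.
#' @slot goi character(1), label of the gene of interest.
#' @slot refs character, labels of the reference genes (at least one).
#'
#' @seealso [QPCRExperiment()], [readPlateCsv()], [deltaCq()]
#' @export
setClass("QPCRExperiment",
         representation(wells = "data.frame",
                        goi = "character",
                        refs = "character"))

setValidity("QPCRExperiment", function(object) {
  w <- object@wells
  msgs <- character()
  missing_cols <- setdiff(WELL_COLUMNS, names(w))
  if (length(missing_cols))
    return(paste("wells is missing columns:",
                 paste(missing_cols, collapse = ", ")))
  if (length(object@goi) != 1L || is.na(object@goi) || !nzchar(object@goi))
    msgs <- c(msgs, "goi must be a single non-empty gene label")
  if (length(object@refs) < 1L || anyNA(object@refs))
    msgs <- c(msgs, "refs must name at least one reference gene")
  if (object@goi %in% object@refs)
    msgs <- c(msgs, "goi cannot also be a reference gene")
  bad_e <- !is.finite(w$efficiency) | w$efficiency <= 1
  if (any(bad_e))
    msgs <- c(msgs, sprintf(
      "efficiency must be finite and > 1 (rows: %s)",
      paste(which(bad_e), collapse = ", ")))
  bad_cq <- !is.finite(w$cq) | w$cq <= 0
  if (any(bad_cq))
    msgs <- c(msgs, sprintf("cq must be finite and > 0 (rows: %s)",
                            paste(which(bad_cq), collapse = ", ")))
  stray <- setdiff(unique(w$gene), c(object@goi, object@refs))
  if (length(stray))
    msgs <- c(msgs, sprintf("gene(s) %s are neither the GOI nor a reference",
                            paste(stray, collapse = ", ")))
  has_well <- !is.na(w$well) & nzchar(as.character(w$well))
  if (any(has_well)) {
    key <- paste(w$replicate, w$sample_type, w$gene, w$well)[has_well]
    if (anyDuplicated(key))
      msgs <- c(msgs, "duplicated (replicate, sample_type, gene, well) keys")
  }
  # every (replicate, sample_type) needs the GOI and every reference gene
  grp <- unique(w[, c("replicate", "sample_type")])
  need <- c(object@goi, object@refs)
  for (k in seq_len(nrow(grp))) {
    present <- unique(w$gene[w$replicate == grp$replicate[k] &
                             w$sample_type == grp$sample_type[k]])
    lack <- setdiff(need, present)
    if (length(lack))
      msgs <- c(msgs, sprintf(
        "replicate %s / sample type %s has no well for gene(s): %s",
        grp$replicate[k], grp$sample_type[k], paste(lack, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a QPCRExperiment
#'
#' @param wells data.frame of per-well records; missing \code{plate} defaults
#'   to a single plate label \code{"plate1"}, missing \code{well} to \code{NA}.
#'   Missing \code{role} is inferred from \code{goi}/\code{refs}.
#' @param goi label of the gene of interest.
#' @param refs character vector of reference-gene labels.
#' @return A validated [QPCRExperiment-class] object. Row order is preserved.
#' @examples
#' w <- data.frame(replicate = "r1", sample_type = rep(c("A", "B"), each = 2),
#'                 gene = rep(c("g", "ref1"), 2),
#'                 efficiency = 1.9, cq = c(31, 26, 32, 26))
#' QPCRExperiment(w, goi = "g", refs = "ref1")
#' @export
QPCRExperiment <- function(wells, goi, refs) {
  wells <- as.data.frame(wells)
  for (col in c("replicate", "sample_type", "gene")) {
    if (!col %in% names(wells))
      stop("wells must contain a '", col, "' column", call. = FALSE)
    wells[[col]] <- trimws(as.character(wells[[col]]))
  }
  if (!"plate" %in% names(wells)) wells$plate <- "plate1"
  wells$plate <- trimws(as.character(wells$plate))
  wells$plate[is.na(wells$plate) | !nzchar(wells$plate)] <- "plate1"
  if (!"well" %in% names(wells)) wells$well <- NA_character_
  wells$well <- as.character(wells$well)
  goi <- trimws(goi); refs <- trimws(refs)
  if (!"role" %in% names(wells)) wells$role <- NA_character_
  wells$role <- trimws(as.character(wells$role))
  blank <- is.na(wells$role) | !nzchar(wells$role)
  wells$role[blank] <- ifelse(wells$gene[blank] %in% refs,
                              "reference", "target")
  wells <- wells[, WELL_COLUMNS]
  rownames(wells) <- NULL
  new("QPCRExperiment", wells = wells, goi = goi, refs = refs)
}

#' CommonBaseTest: result of a log-scale two-group comparison
#'
#' The log-scale estimate is the efficiency-weighted
#' \eqn{\Delta\Delta C_q^{(w)}}; the expression ratio and its confidence
#' interval are its back-transform \eqn{R = b^{-\Delta\Delta C_q^{(w)}}}.
#'
#' @slot estimate numeric(1), \eqn{\Delta\Delta C_q^{(w)}} in log units.
#' @slot se numeric(1), standard error of the estimate.
#' @slot df numeric(1), degrees of freedom (non-integer under Welch).
#' @slot statistic numeric(1), t statistic for the null
#'   \eqn{\Delta\Delta C_q^{(w)} = 0}.
#' @slot p.value numeric(1), two-tailed p-value.
#' @slot conf.int numeric(2), log-scale confidence interval.
#' @slot ratio numeric(1), back-transformed expression ratio.
#' @slot ratio.conf.int numeric(2), back-transformed interval (low, high).
#' @slot conf.level numeric(1), nominal confidence level.
#' @slot base numeric(1), logarithm base used throughout.
#' @slot n integer, group sizes (unpaired) or number of pairs (paired).
#' @slot method character(1), description of the test performed.
#' @export
setClass("CommonBaseTest",
         representation(estimate = "numeric", se = "numeric", df = "numeric",
                        statistic = "numeric", p.value = "numeric",
                        conf.int = "numeric", ratio = "numeric",
                        ratio.conf.int = "numeric", conf.level = "numeric",
                        base = "numeric", n = "integer", method = "character"))

setValidity("CommonBaseTest", function(object) {
  msgs <- character()
  if (length(object@conf.int) != 2L || object@conf.int[1] > object@conf.int[2])
    msgs <- c(msgs, "conf.int must be an ordered (lower, upper) pair")
  if (object@p.value < 0 || object@p.value > 1)
    msgs <- c(msgs, "p.value must lie in [0, 1]")
  if (object@ratio <= 0)
    msgs <- c(msgs, "ratio must be positive")
  if (length(object@ratio.conf.int) == 2L &&
      object@ratio.conf.int[1] > object@ratio.conf.int[2])
    msgs <- c(msgs, "ratio.conf.int must be ordered low to high")
  if (length(msgs)) msgs else TRUE
})

#' CommonBaseAnova: blocked analysis-of-variance of delta-Cq values
#'
#' @slot sources data.frame with columns \code{source}, \code{df}, \code{ss},
#'   \code{ms}, \code{f}, \code{p}; one row per model term plus
#'   \code{"Error"} (and a trailing \code{"Total"} row).
#' @slot posthoc data.frame of pairwise comparisons (see [posthocPairwise()]).
#' @slot means named numeric, level means of the factor.
#' @slot n.per.level named numeric, observations per factor level.
#' @slot conf.level numeric(1).
#' @slot base numeric(1).
#' @slot balanced logical(1), whether the design was balanced and complete.
#' @export
setClass("CommonBaseAnova",
         representation(sources = "data.frame", posthoc = "data.frame",
                        means = "numeric", n.per.level = "numeric",
                        conf.level = "numeric", base = "numeric",
                        balanced = "logical"))

setValidity("CommonBaseAnova", function(object) {
  src <- object@sources
  need <- c("source", "df", "ss", "ms", "f", "p")
  if (!all(need %in% names(src)))
    return("sources must have columns source, df, ss, ms, f, p")
  if (!"Error" %in% src$source)
    return("sources must include an Error row")
  TRUE
})

#' MisuseReport: a t-test run (improperly) on ratio-scale values, both ways
#'
#' Demonstration object only: testing per-pair expression ratios against a
#' mean of 1 gives direction-dependent answers, unlike the log-scale test.
#'
#' @slot direction.ab named numeric: mean ratio, sd, t, p for A vs. B.
#' @slot direction.ba named numeric: the same for B vs. A.
#' @slot ratios.ab numeric, per-pair ratios A vs. B.
#' @slot ratios.ba numeric, per-pair ratios B vs. A.
#' @slot alpha numeric(1), significance level used for the consistency flag.
#' @slot consistent logical(1), TRUE iff both directions agree on
#'   significance at \code{alpha}.
#' @export
setClass("MisuseReport",
         representation(direction.ab = "numeric", direction.ba = "numeric",
                        ratios.ab = "numeric", ratios.ba = "numeric",
                        alpha = "numeric", consistent = "logical"))
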