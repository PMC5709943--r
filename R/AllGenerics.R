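#' Accessors for QPCRExperiment
#'
#' @param object a [QPCRExperiment-class].
#' @return \code{wells()} the per-well data.frame; \code{goi()} the gene of
#'   interest label; \code{refGenes()} the reference-gene labels.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wells", function(object) standardGeneric("wells"))

#' @rdname accessors
#' @export
setGeneric("goi", function(object) standardGeneric("goi"))

#' @rdname accessors
#' @export
setGeneric("refGenes", function(object) standardGeneric("refGenes"))

#' @rdname accessors
#' @export
setMethod("wells", "QPCRExperiment", function(object) object@wells)

#' @rdname accessors
#' @export
setMethod("goi", "QPCRExperiment", function(object) object@goi)

#' @rdname accessors
#' @export
setMethod("refGenes", "QPCRExperiment", function(object) object@refs)

#' @rdname aggregateTechnical
#' @export
setGeneric("aggregateTechnical",
           function(object, ...) standardGeneric("aggregateTechnical"))

#' @rdname deltaCq
#' @export
setGeneric("deltaCq", function(object, ...) standardGeneric("deltaCq"))

#' @rdname writeResults
#' @export
setGeneric("writeResults",
           function(object, path, ...) standardGeneric("writeResults"))

#' @rdname posthocPairwise
#' @export
setGeneric("posthocPairwise",
           function(object, ...) standardGeneric("posthocPairwise"))

#' @rdname reciprocityCheck
#' @export
setGeneric("reciprocityCheck",
           function(ab, ba, ...) standardGeneric("reciprocityCheck"))

setMethod("show", "QPCRExperiment", function(object) {
  w <- object@wells
  cat("QPCRExperiment:", nrow(w), "wells\n")
  cat("  gene of interest:", object@goi, "\n")
  cat("  reference genes: ", paste(object@refs, collapse = ", "), "\n")
  cat("  sample types:    ", paste(unique(w$sample_type), collapse = ", "),
      "\n")
  cat("  replicates:      ", length(unique(w$replicate)),
      " | plates: ", length(unique(w$plate)), "\n", sep = "")
})

setMethod("show", "CommonBaseTest", function(object) {
  cat(object@method, "\n")
  cat(sprintf("  ddCq(w) = %.4f  (se %.4f, df %.3f, base %g)\n",
              object@estimate, object@se, object@df, object@base))
  cat(sprintf("  t = %.3f, two-tailed p = %.4g\n",
              object@statistic, object@p.value))
  cat(sprintf("  %g%% CI (log scale): (%.4f, %.4f)\n", 100 * object@conf.level,
              object@conf.int[1], object@conf.int[2]))
  cat(sprintf("  expression ratio = %.3g, %g%% CI (%.3g, %.3g)\n",
              object@ratio, 100 * object@conf.level,
              object@ratio.conf.int[1], object@ratio.conf.int[2]))
})

setMethod("show", "CommonBaseAnova", function(object) {
  cat("Common Base blocked ANOVA (base", object@base, ")\n")
  src <- object@sources
  src$ss <- signif(src$ss, 5); src$ms <- signif(src$ms, 5)
  src$f <- signif(src$f, 5); src$p <- signif(src$p, 4)
  print(src, row.names = FALSE)
  if (nrow(object@posthoc)) {
    cat("Post-hoc pairwise comparisons (Bonferroni-adjusted p, unadjusted CI):\n")
    ph <- object@posthoc
    num <- vapply(ph, is.numeric, logical(1))
    ph[num] <- lapply(ph[num], signif, 4)
    print(ph, row.names = FALSE)
  }
})

setMethod("show", "MisuseReport", function(object) {
  cat("Improper ratio-scale t-test demonstration (do not use for analysis)\n")
  m <- rbind(`A vs. B` = object@direction.ab, `B vs. A` = object@direction.ba)
  print(signif(m, 4))
  cat(sprintf("  directions agree on significance at alpha = %g: %s\n",
              object@alpha, object@consistent))
})
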