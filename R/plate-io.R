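CANONICAL_COLUMNS <- c("replicate", "sample_type", "gene", "role",
                       "plate", "well", "efficiency", "cq")
REQUIRED_COLUMNS <- c("replicate", "sample_type", "gene", "efficiency", "cq")

#' Read a long-format per-well qPCR table
#'
#' Reads a CSV with one well per row and validates it into a
#' [QPCRExperiment-class]. Canonical headers are \code{replicate},
#' \code{sample_type}, \code{gene}, \code{role}, \code{plate}, \code{well},
#' \code{efficiency}, \code{cq}; instrument-specific headers (e.g.
#' \code{Ct}) are handled through a schema mapping. Efficiencies are the
#' fold-amplification per cycle, nominally in (1, 2]: percent efficiencies
#' (e.g. 92) or E-1 values (e.g. 0.92) are rejected rather than silently
#' converted, and values above \code{warn.efficiency} trigger a unit-mistake
#' warning.
#'
#' @param path CSV file (RFC 4180, header row, UTF-8, decimal point).
#' @param schema optional header mapping: a named character vector/list
#'   (\code{canonical = "file header"}) or the path to a YAML/JSON file with
#'   those entries.
#' @param goi,refs gene labels; if omitted, derived from the \code{role}
#'   column (\code{role == "reference"} marks reference genes, everything
#'   else is the target, which must then be a single gene).
#' @param warn.efficiency efficiency above which a warning flags a likely
#'   unit mistake (default 2.2).
#' @return a validated [QPCRExperiment-class]; row order preserved, labels
#'   stripped of surrounding whitespace.
#' @examples
#' path <- system.file("extdata", "example_plate.csv", package = "commonbase")
#' readPlateCsv(path)
#' @export
readPlateCsv <- function(path, schema = NULL, goi = NULL, refs = NULL,
                         warn.efficiency = 2.2) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         fileEncoding = "UTF-8")
  map <- resolveSchema(schema)
  for (canonical in names(map)) {
    hit <- which(names(raw) == map[[canonical]])
    if (length(hit)) names(raw)[hit[1]] <- canonical
  }
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         " (use a schema mapping for nonstandard headers)", call. = FALSE)

  w <- data.frame(replicate = trimws(raw$replicate),
                  sample_type = trimws(raw$sample_type),
                  gene = trimws(raw$gene),
                  stringsAsFactors = FALSE)
  w$role <- if ("role" %in% names(raw)) trimws(raw$role) else NA_character_
  w$plate <- if ("plate" %in% names(raw)) trimws(raw$plate) else "plate1"
  w$well <- if ("well" %in% names(raw)) trimws(raw$well) else NA_character_

  w$efficiency <- parseNumericColumn(raw$efficiency, "efficiency")
  w$cq <- parseNumericColumn(raw$cq, "cq")
  bad_e <- !is.finite(w$efficiency) | w$efficiency <= 1
  if (any(bad_e))
    stop("efficiency must be > 1 (fold-amplification per cycle) in row(s): ",
         paste(which(bad_e), collapse = ", "), call. = FALSE)
  bad_cq <- !is.finite(w$cq) | w$cq <= 0
  if (any(bad_cq))
    stop("cq must be a positive finite cycle number in row(s): ",
         paste(which(bad_cq), collapse = ", "), call. = FALSE)
  high <- w$efficiency > warn.efficiency
  if (any(high))
    warning("efficiency > ", warn.efficiency, " in row(s) ",
            paste(which(high), collapse = ", "),
            "; check units (expected fold-amplification per cycle, ",
            "nominally <= 2)", call. = FALSE)

  if (is.null(goi) || is.null(refs)) {
    if (all(is.na(w$role)))
      stop("no 'role' column: pass goi= and refs= explicitly", call. = FALSE)
    role <- tolower(w$role)
    ref_genes <- unique(w$gene[role %in% c("reference", "ref")])
    tgt_genes <- unique(w$gene[!role %in% c("reference", "ref")])
    if (is.null(refs)) refs <- ref_genes
    if (is.null(goi)) {
      if (length(tgt_genes) != 1L)
        stop("role column marks ", length(tgt_genes), " target genes; pass ",
             "goi= to disambiguate", call. = FALSE)
      goi <- tgt_genes
    }
  }
  QPCRExperiment(w, goi = goi, refs = refs)
}

parseNumericColumn <- function(x, name) {
  out <- suppressWarnings(as.numeric(trimws(x)))
  bad <- is.na(out) & !is.na(x)
  if (any(bad))
    stop("non-numeric ", name, " value in row(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  out
}

resolveSchema <- function(schema) {
  if (is.null(schema)) return(list())
  if (is.character(schema) && length(schema) == 1L && file.exists(schema)) {
    schema <- if (grepl("\\.(ya?ml)$", schema, ignore.case = TRUE))
      yaml::read_yaml(schema)
    else jsonlite::read_json(schema, simplifyVector = TRUE)
  }
  schema <- as.list(schema)
  unknown <- setdiff(names(schema), CANONICAL_COLUMNS)
  if (length(unknown))
    stop("schema maps unknown canonical column(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  schema
}

#' The worked single-plate example experiment
#'
#' A hypothetical 18-well plate (2 sample types x 3 genes x 3 technical
#' replicates; one gene of interest \code{g}, references \code{ref1} and
#' \code{ref2}) shipped with the package and used throughout the
#' documentation.
#'
#' @return a [QPCRExperiment-class].
#' @export
examplePlate <- function() {
  readPlateCsv(system.file("extdata", "example_plate.csv",
                           package = "commonbase"))
}

#' The worked four-replicate example experiment
#'
#' A constructed (synthetic) experiment of four biological replicates x two
#' sample types, one plate per replicate pair, whose normalized delta-Cq
#' values equal the worked two-sample example (A: 1.1387, 0.845, 0.499,
#' 0.699; B: 1.4077, 1.291, 1.496, 1.172). All efficiencies are 1.9; the
#' per-well Cq values were back-calculated from those targets, so the full
#' pipeline reproduces the published unpaired and paired analyses.
#'
#' @return a [QPCRExperiment-class].
#' @export
exampleExperiment <- function() {
  readPlateCsv(system.file("extdata", "example_experiment.csv",
                           package = "commonbase"))
}

#' Write analysis results to a flat CSV
#'
#' One row per estimate or comparison; log-scale and ratio-scale values are
#' kept in separate columns and written at full precision (no display
#' rounding). ANOVA results additionally carry their source-table rows,
#' distinguished by the \code{row_type} column.
#'
#' @param object a [CommonBaseTest-class] or [CommonBaseAnova-class].
#' @param path output CSV path.
#' @return invisibly, the data.frame that was written.
#' @seealso [readResults()] for the lossless inverse.
#' @rdname writeResults
#' @export
setMethod("writeResults", "CommonBaseTest", function(object, path) {
  df <- data.frame(row_type = "estimate",
                   comparison = object@method,
                   estimate_log = object@estimate,
                   se_log = object@se,
                   df = object@df,
                   statistic = object@statistic,
                   p_value = object@p.value,
                   ci_log_lower = object@conf.int[1],
                   ci_log_upper = object@conf.int[2],
                   ratio = object@ratio,
                   ratio_ci_lower = object@ratio.conf.int[1],
                   ratio_ci_upper = object@ratio.conf.int[2],
                   conf_level = object@conf.level,
                   base = object@base,
                   stringsAsFactors = FALSE)
  writeFullPrecision(df, path)
})

#' @rdname writeResults
#' @export
setMethod("writeResults", "CommonBaseAnova", function(object, path) {
  src <- object@sources
  src_rows <- data.frame(row_type = "source",
                         comparison = src$source,
                         estimate_log = NA_real_, se_log = NA_real_,
                         df = src$df, statistic = src$f, p_value = src$p,
                         ci_log_lower = NA_real_, ci_log_upper = NA_real_,
                         ratio = NA_real_, ratio_ci_lower = NA_real_,
                         ratio_ci_upper = NA_real_,
                         conf_level = object@conf.level, base = object@base,
                         ss = src$ss, ms = src$ms,
                         stringsAsFactors = FALSE)
  ph <- object@posthoc
  ph_rows <- data.frame(row_type = "comparison",
                        comparison = paste(ph$level_a, "vs.", ph$level_b),
                        estimate_log = ph$diff, se_log = ph$se,
                        df = ph$df, statistic = ph$t,
                        p_value = ph$p_adjusted,
                        ci_log_lower = ph$ci_lower,
                        ci_log_upper = ph$ci_upper,
                        ratio = ph$ratio,
                        ratio_ci_lower = ph$ratio_ci_lower,
                        ratio_ci_upper = ph$ratio_ci_upper,
                        conf_level = object@conf.level, base = object@base,
                        ss = NA_real_, ms = NA_real_,
                        stringsAsFactors = FALSE)
  writeFullPrecision(rbind(src_rows, ph_rows), path)
})

writeFullPrecision <- function(df, path) {
  out <- df
  num <- vapply(out, is.numeric, logical(1))
  # 17 significant digits round-trips doubles exactly
  out[num] <- lapply(out[num], function(x) {
    s <- formatC(x, digits = 17, format = "g")
    s[is.na(x)] <- NA_character_
    s
  })
  tryCatch(utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                            na = ""),
           error = function(e) stop("cannot write results to ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
  invisible(df)
}

#' Write a QPCRExperiment back to a long-format per-well CSV
#'
#' Canonical headers, full numeric precision; [readPlateCsv()] is the
#' inverse.
#'
#' @param experiment a [QPCRExperiment-class].
#' @param path output CSV path.
#' @return invisibly, the wells data.frame.
#' @export
writePlateCsv <- function(experiment, path) {
  stopifnot(is(experiment, "QPCRExperiment"))
  writeFullPrecision(wells(experiment), path)
}

#' Read back a results CSV written by writeResults
#'
#' @param path CSV path.
#' @return data.frame with numeric columns restored at full precision.
#' @export
readResults <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  char_cols <- c("row_type", "comparison")
  for (nm in setdiff(names(df), char_cols)) df[[nm]] <- as.numeric(df[[nm]])
  df
}
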