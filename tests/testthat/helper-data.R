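# Fixtures built in code: the worked single-plate example and the small
# grouped data sets used across the tests.

# Per-well weighted Cq values of the worked plate example (the published
# per-well log(E)*Cq column; the first B/goi well's printed weighted value
# is kept as printed even though it is slightly inconsistent with its own
# raw (E, Cq) pair - downstream values follow this column).
table1Weighted <- function() {
  data.frame(
    replicate = "r1",
    sample_type = rep(rep(c("A", "B"), each = 3), 3),
    gene = rep(c("g", "ref1", "ref2"), each = 6),
    wcq = c(8.303, 8.360, 8.527, 8.647, 8.631, 8.555,
            7.458, 7.335, 7.215, 7.382, 7.309, 7.368,
            7.298, 7.129, 7.113, 6.998, 6.940, 7.223),
    stringsAsFactors = FALSE)
}

# Four-replicate delta-Cq values for the two-sample worked examples
unpairedGroups <- function() {
  list(a = c(1.1387, 0.845, 0.499, 0.699),
       b = c(1.4077, 1.291, 1.496, 1.172))
}

# Three sample types on two plates (replicates 1-2 on plate 1, 3-4 on 2)
plateBlockedData <- function() {
  data.frame(
    dcq = c(0.855, 0.711, 0.582, 0.699,
            1.203, 1.056, 0.890, 0.775,
            0.866, 0.799, 0.522, 0.669),
    sample_type = rep(c("A", "B", "C"), each = 4),
    plate = rep(rep(c("p1", "p2"), each = 2), 3),
    stringsAsFactors = FALSE)
}

# Three sample types paired within four individuals
individualBlockedData <- function() {
  data.frame(
    dcq = c(0.855, 0.845, 0.499, 0.699,
            1.408, 1.056, 1.291, 1.172,
            0.866, 0.799, 0.532, 0.707),
    sample_type = rep(c("A", "B", "C"), each = 4),
    replicate = rep(paste0("r", 1:4), 3),
    stringsAsFactors = FALSE)
}

# A small valid well table built in code (2 types x 2 genes x 2 wells)
tinyWells <- function() {
  expand.grid(tech = 1:2, sample_type = c("A", "B"),
              gene = c("g", "ref1"), KEEP.OUT.ATTRS = FALSE,
              stringsAsFactors = FALSE) |>
    transform(replicate = "r1",
              efficiency = 1.9,
              cq = ifelse(gene == "g", 31, 26) + tech / 10,
              well = paste0("w", seq_len(8)))
}

# Absolute-tolerance comparison against printed (rounded) values: a value
# printed to k decimals is matched within half an ulp of that printing.
expect_close <- function(actual, printed, tol) {
  act <- testthat::quasi_label(rlang::enquo(actual))
  ok <- length(act$val) == length(printed) && all(is.finite(act$val)) &&
    all(abs(act$val - printed) <= tol)
  testthat::expect(ok, sprintf(
    "%s = (%s) not within %g of printed (%s)", act$lab,
    paste(signif(act$val, 8), collapse = ", "), tol,
    paste(printed, collapse = ", ")))
  invisible(act$val)
}

writeTempCsv <- function(df, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = env)
  utils::write.csv(df, path, row.names = FALSE)
  path
}
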