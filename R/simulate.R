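#' @importFrom stats rnorm pnorm
NULL

#' Configuration for the synthetic plate generator
#'
#' Describes a ground-truth qPCR experiment: relative expression is
#' lognormal (Gaussian on the log10 scale) with biological, plate and
#' technical variance components, and per-well amplification efficiencies
#' are drawn from a truncated Gaussian near 2. Reference genes are
#' unaffected by sample type unless \code{ref_response} is nonzero.
#'
#' @param offsets named numeric: sample-type labels with their true log10
#'   relative-expression offsets. The true expression ratio of type
#'   \eqn{t_1} vs. \eqn{t_2} is \eqn{10^{o_1 - o_2}}.
#' @param n_replicates biological replicates per sample type.
#' @param design \code{"unpaired"} (independent organisms per sample type)
#'   or \code{"paired"} (each replicate index yields one sample of every
#'   type, sharing a plate).
#' @param n_plates number of qPCR plates; replicates are split evenly
#'   across plates with every sample type present on every plate (a
#'   complete randomized block).
#' @param sd_biological SD of per-sample biological noise, log10 scale.
#' @param sd_plate SD of the additive per-plate shift, log10 scale.
#' @param sd_technical per-well SD in the weighted (log10) scale.
#' @param n_technical technical replicate wells per (sample, gene).
#' @param efficiency_mean,efficiency_sd per-well efficiency distribution,
#'   truncated to \code{(1, efficiency_max]}.
#' @param efficiency_max upper truncation bound, default 2.2.
#' @param n_ref_genes number of reference genes.
#' @param ref_response log10 shift of reference genes per unit of
#'   sample-type offset; 0 (default) = stable references, nonzero values
#'   deliberately violate the normalization assumption for robustness
#'   experiments.
#' @return a validated \code{SimulationConfig} list.
#' @export
simulationConfig <- function(offsets = c(A = 0, B = -0.546),
                             n_replicates = 4L,
                             design = c("unpaired", "paired"),
                             n_plates = 1L,
                             sd_biological = 0.25,
                             sd_plate = 0.15,
                             sd_technical = 0.05,
                             n_technical = 3L,
                             efficiency_mean = 1.87,
                             efficiency_sd = 0.025,
                             efficiency_max = 2.2,
                             n_ref_genes = 2L,
                             ref_response = 0) {
  design <- match.arg(design)
  if (is.null(names(offsets)) || any(!nzchar(names(offsets))))
    names(offsets) <- LETTERS[seq_along(offsets)]
  stopifnot(length(offsets) >= 2L, all(is.finite(offsets)),
            n_replicates >= 1L, n_plates >= 1L, n_technical >= 1L,
            n_ref_genes >= 1L,
            sd_biological >= 0, sd_plate >= 0, sd_technical >= 0,
            efficiency_sd >= 0, efficiency_mean > 1,
            efficiency_mean <= efficiency_max)
  if (n_plates > n_replicates)
    stop("n_plates cannot exceed n_replicates: every plate must hold at ",
         "least one complete replicate block", call. = FALSE)
  structure(list(offsets = offsets, n_replicates = as.integer(n_replicates),
                 design = design, n_plates = as.integer(n_plates),
                 sd_biological = sd_biological, sd_plate = sd_plate,
                 sd_technical = sd_technical,
                 n_technical = as.integer(n_technical),
                 efficiency_mean = efficiency_mean,
                 efficiency_sd = efficiency_sd,
                 efficiency_max = efficiency_max,
                 n_ref_genes = as.integer(n_ref_genes),
                 ref_response = ref_response),
            class = "SimulationConfig")
}

#' Simulate a qPCR experiment with known ground truth
#'
#' Generates per-well (efficiency, Cq) records whose analysis estimand
#' equals the configured truth: each sample's normalized log10 expression
#' is its type offset plus biological noise plus its plate's shift; the
#' gene of interest's weighted-Cq target decreases one-for-one with
#' expression while reference genes stay at fixed baselines; per-well Cq is
#' the weighted target plus technical noise, divided by log10 of that
#' well's drawn efficiency (inverting the weighting). Plate and biological
#' shifts act on the normalized expression — variation that reference
#' normalization cannot remove, which is exactly what blocking is for.
#'
#' @param config a [simulationConfig()].
#' @param seed integer seed; every call is deterministic given
#'   (config, seed) and leaves the global RNG state untouched.
#' @return list with \code{experiment} (a [QPCRExperiment-class]) and
#'   \code{truth}: the per-sample assignments (replicate, sample type,
#'   plate, true log10 expression, true delta-Cq), plate shifts, and the
#'   true pairwise delta-delta-Cq / expression ratio for every ordered
#'   type pair.
#' @examples
#' sim <- simulateExperiment(simulationConfig(), seed = 1)
#' unpairedTest(deltaCq(sim$experiment)$dcq[1:4],
#'              deltaCq(sim$experiment)$dcq[5:8])
#' @export
simulateExperiment <- function(config, seed) {
  if (!inherits(config, "SimulationConfig"))
    stop("config must come from simulationConfig()", call. = FALSE)
  if (missing(seed) || !is.finite(seed))
    stop("an explicit integer seed is required", call. = FALSE)
  withSeed(seed, {
    types <- names(config$offsets)
    nr <- config$n_replicates
    goi_base <- 8.4
    ref_bases <- 7.3 - 0.2 * (seq_len(config$n_ref_genes) - 1)
    ref_names <- paste0("ref", seq_len(config$n_ref_genes))

    # replicate index -> plate (even split; all types of an index share it)
    plate_of <- ((seq_len(nr) - 1L) * config$n_plates) %/% nr + 1L
    plate_shift <- rnorm(config$n_plates, 0, config$sd_plate)

    grid <- expand.grid(idx = seq_len(nr), sample_type = types,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$replicate <- if (config$design == "paired")
      paste0("r", grid$idx)
    else paste0(grid$sample_type, "_r", grid$idx)
    grid$plate <- paste0("plate", plate_of[grid$idx])
    bio <- rnorm(nrow(grid), 0, config$sd_biological)
    grid$true_L <- config$offsets[grid$sample_type] + bio +
      plate_shift[plate_of[grid$idx]]
    grid$true_dcq <- (goi_base - grid$true_L) - mean(ref_bases)

    genes <- c("goi", ref_names)
    gene_base <- c(goi = goi_base, structure(ref_bases, names = ref_names))
    wellrows <- grid[rep(seq_len(nrow(grid)),
                         each = length(genes) * config$n_technical), ]
    wellrows$gene <- rep(rep(genes, each = config$n_technical),
                         times = nrow(grid))
    target <- ifelse(wellrows$gene == "goi",
                     goi_base - wellrows$true_L,
                     gene_base[wellrows$gene] -
                       config$ref_response *
                       config$offsets[wellrows$sample_type])
    eff <- rtruncnorm(nrow(wellrows), config$efficiency_mean,
                      config$efficiency_sd, 1, config$efficiency_max)
    wcq <- target + rnorm(nrow(wellrows), 0, config$sd_technical)
    wells <- data.frame(replicate = wellrows$replicate,
                        sample_type = wellrows$sample_type,
                        gene = wellrows$gene,
                        role = ifelse(wellrows$gene == "goi", "target",
                                      "reference"),
                        plate = wellrows$plate,
                        well = sprintf("w%03d", seq_len(nrow(wellrows))),
                        efficiency = eff,
                        cq = wcq / log10(eff),
                        stringsAsFactors = FALSE)
    experiment <- QPCRExperiment(wells, goi = "goi", refs = ref_names)

    prs <- expand.grid(type_a = types, type_b = types,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    prs <- prs[prs$type_a != prs$type_b, ]
    prs$true_ddcq <- -(config$offsets[prs$type_a] -
                         config$offsets[prs$type_b])
    prs$true_ratio <- 10^(-prs$true_ddcq)
    rownames(prs) <- NULL

    assignments <- grid[, c("replicate", "sample_type", "plate",
                            "true_L", "true_dcq")]
    rownames(assignments) <- NULL
    list(experiment = experiment,
         truth = list(offsets = config$offsets, pairs = prs,
                      assignments = assignments,
                      plate_shifts = plate_shift, seed = seed))
  })
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  if (pnorm(hi, mean, sd) - pnorm(lo, mean, sd) < 1e-6)
    stop("efficiency truncation bounds leave almost no probability mass",
         call. = FALSE)
  x <- rnorm(n, mean, sd)
  bad <- x <= lo | x > hi
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
    bad <- x <= lo | x > hi
  }
  x
}

withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  code
}
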