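---
title: "Log-scale relative quantification of qPCR data with commonbase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Log-scale relative quantification of qPCR data with commonbase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commonbase)
```

## The model

A qPCR well yields two numbers: the quantification cycle $C_q$ (the cycle
at which fluorescence crosses the detection threshold) and the
amplification efficiency $E$ (fold-amplification per cycle, at most 2 for
perfect doubling). The amount of amplification the well underwent is
$E^{C_q}$, which is awkward to analyze because each well has its own base
$E$. Since $E^{C_q} = b^{\log_b(E)\,C_q}$ for any base $b > 1$, the package
works instead with the *efficiency-weighted* quantification cycle

$$C_q^{(w)} = \log_b(E)\, C_q,$$

which places every well on one common log scale (base 10 by default). From
there the analysis stays in log scale as long as possible:

1. **Technical replicates** of one (biological replicate, sample type,
   gene) are averaged arithmetically in weighted space:
   $C^{(w)}_{q;r,t,g} = \tfrac1n \sum_i \log_b(E_i)\,C_{q;i}$.
2. **Normalization** subtracts the arithmetic mean of the reference genes'
   aggregated values from the gene of interest's:
   $\Delta C^{(w)}_{q;r,t} = C^{(w)}_{q;GOI} - \tfrac1n\sum_i
   C^{(w)}_{q;REF_i}$. Because this mean is taken in log scale it is
   exactly the geometric-mean normalization used elsewhere, without
   needing geometric means.
3. **Comparison** of two sample types uses
   $\Delta\Delta C^{(w)}_q = \Delta C^{(w)}_{q;A} - \Delta C^{(w)}_{q;B}$ —
   a difference of group means for unpaired designs, a mean of per-pair
   differences for paired ones. Both give the same point estimate on
   balanced data; they differ in the inference.
4. **Back-transformation**, the very last step, reports the relative
   expression ratio $R = b^{-\Delta\Delta C^{(w)}_q}$ and maps the
   log-scale confidence interval $(l, u)$ to $(b^{-u}, b^{-l})$. The ratio
   does not depend on the choice of $b$; log-scale estimates do, so
   results always record their base.

With gene-wise constant efficiencies this pipeline reproduces the
classical single-reference efficiency-corrected ratio exactly, and with
$E = 2$ it reproduces the $2^{-\Delta\Delta C_q}$ ratio; both identities
are kept as test oracles (`pfafflRatio()`, `livakRatio()`).

The central assumption, supported by experimental evidence in the
literature, is that relative expression is **lognormal**: $\Delta\Delta
C^{(w)}_q$ is then approximately Gaussian, and ordinary parametric
statistics apply *in log scale*. Applying them directly to ratios is
invalid, and the package includes a demonstrator of what goes wrong (see
below).

## Inference

`unpairedTest()` compares unrelated groups of $\Delta C^{(w)}_q$ values.
Unequal variances are the conservative default (Welch, with the
Satterthwaite degrees of freedom kept non-integer); `var.equal = TRUE`
gives the classical pooled test. `pairedTest()` handles designs where each
replicate of type A is paired with one of type B, testing the per-pair
differences against zero on $n - 1$ degrees of freedom.

All confidence intervals use **Student-t quantiles** on the test's degrees
of freedom, never the large-sample 1.96: at the group sizes typical of
qPCR ($n = 3$–$6$) the normal quantile would understate the interval
substantially (at $n = 4$ pairs the correct multiplier is 3.182).

`blockedAnova()` extends the comparison to several sample types with
additive blocks. qPCR experiments often span several plates, and
plate-to-plate variation (reagent age, machine, run conditions) can
swamp the effect of interest; declaring each plate a complete randomized
block partitions that variation out of the error term. The same machinery
handles individuals as blocks in paired multi-organ designs (a two-level
blocked ANOVA *is* the paired t-test: $F = t^2$, identical p). Blocks are
fitted as fixed additive effects; their F ratios are reported for
completeness but are not of inferential interest, and block-by-treatment
interactions are never fitted. `posthocPairwise()` compares every pair of
levels with the pooled error mean square on the error degrees of freedom,
multiplying p-values by the number of comparisons (Bonferroni, capped at
1) while leaving the confidence intervals unadjusted — the mixed
convention standard in this literature, and the one the worked examples
embody.

Numerical conventions worth stating:

* Everything is computed at full floating precision; printed tables in the
  field round intermediates (e.g. $\log E$ to 3 decimals), so agreement
  with published worked examples is at printed precision, not bit-exact.
* A constant response yields all-zero sums of squares and an *undefined*
  F (reported as `NA`, not an error, and not 0).
* Unbalanced-but-complete designs fall back to the marginal
  (each-term-after-all-others) decomposition with a warning, and post-hoc
  standard errors use harmonic-mean level sizes, flagged in the output. A
  treatment level entirely absent from a block is an error naming the
  cell.
* Normality screening (Shapiro-Wilk) is available behind
  `check.assumptions = TRUE` and only ever warns; at qPCR sample sizes a
  hard normality gate would be noise. It is off by default so that large
  simulation studies are not flooded with advisory messages.

## Why not test ratios directly

`improperRatioTest()` deliberately performs the analysis the package
exists to replace: back-transform each pair's $\Delta\Delta C^{(w)}_{q;r}$
to a ratio first, then t-test the ratios against 1. Because per-pair
ratios are right-skewed, the outcome depends on which group is called the
numerator — the same data can reject in one direction and fail to reject
in the other. The log-scale test is immune: swapping groups negates the
estimate, statistic and interval bounds and leaves the p-value unchanged
(`reciprocityCheck()` verifies this mechanically, and the test suite
checks it property-style across random draws). The misuse path always
warns when called and is exposed on the command line only as a clearly
named `demo-misuse` subcommand.

## The synthetic plate generator

`simulateExperiment()` exists so that every pipeline stage can be
validated against known truth without external data. Its model follows
the lognormality assumption: each sample's normalized log10 expression is

$$L_{r,t} = o_t + \varepsilon_{r,t} + \pi_{p(r)},$$

a sample-type offset plus Gaussian biological noise plus its plate's
shift. The gene of interest's weighted-Cq target decreases one-for-one
with $L$; reference genes sit at fixed baselines (they are normalizers —
a `ref_response` switch deliberately violates this for robustness
experiments). Per-well efficiencies are drawn from a Gaussian truncated
to $(1, 2.2]$, technical noise is added in weighted space, and the well's
Cq is recovered by inverting the weighting, $C_q = C_q^{(w)} / \log_{10}
E$. By construction the analysis estimand equals the configured truth:
with all noise at zero the pipeline returns the configured ratio to
floating-point accuracy.

Plate and biological shifts act on the *normalized* expression. Variation
that hit the gene of interest and the reference genes identically would
cancel in normalization and be invisible to every downstream analysis;
what blocking removes is precisely the component that survives
normalization, so that is what the generator produces. In paired designs
each replicate's samples share a plate, which is also what makes the
pairs correlated.

Default parameter choices (all configurable) reflect the magnitudes
visible in the worked data sets of this literature and are illustrative,
not estimates: biological SD 0.25 and technical SD 0.05 on the log10
scale, plate-shift SD 0.15, efficiencies $\mathcal{N}(1.87, 0.025)$
truncated to $(1, 2.2]$, four biological replicates, three technical
replicates, two reference genes, and sample-type offsets $(0, -0.546)$ —
a true expression ratio of $10^{0.546} \approx 3.52$, the effect size of
the worked examples.

What the generator does *not* emulate: amplification-curve shape and the
estimation error of $E$ (efficiencies are inputs here, not estimated),
heteroskedasticity between sample types, non-Gaussian log-scale noise,
and missing wells. Passing simulation-based tests therefore shows the
statistics are correct under the stated model, not that real instruments
satisfy the model.

The test suite uses the generator for calibration checks at the study's
own scale: 2,000 null simulations for the Welch test's type-I error,
1,000 simulations per design for 95% interval coverage (checked against
99% binomial bounds), 400 for estimator bias, and 300 three-type
two-plate simulations for the blocking comparison, where the
plate-blocked ANOVA shows a smaller mean error MS and a higher rejection
rate than the unblocked fit. These sizes keep the whole suite under a
minute while leaving the Monte-Carlo error well inside the asserted
bounds.

## Scope and known limitations

* Efficiencies are inputs. Estimating $E$ from fluorescence curves, and
  parsing instrument-native formats (RDML, proprietary exports), are out
  of scope; the long-format CSV with a header-mapping schema covers
  instrument export variation.
* Percent efficiencies (92) and $E - 1$ values (0.92) are rejected, not
  silently converted — silent unit conversion is how such mistakes
  propagate. Values above 2.2 draw a warning as likely unit errors.
* Blocking is additive only, and at most the simple structures shown
  (plate blocks or individual blocks). Crossed plate-by-individual
  designs, ANCOVA/regression formulations, and random-effects estimation
  are not implemented.
* The two-group designs assume two-tailed tests against a null ratio of
  1; one-tailed variants are intentionally absent.
* With a single reference gene and strongly regulated "reference"
  expression, normalization is biased like any reference-gene method;
  the simulator's `ref_response` switch exists to quantify that
  sensitivity.

## A worked session

```{r example}
plate <- examplePlate()          # one plate: 2 sample types x 3 genes x 3 wells
deltaCq(plate)

experiment <- exampleExperiment()   # four replicate pairs, one plate each
d <- deltaCq(experiment)
a <- d[d$sample_type == "A", c("replicate", "dcq")]
b <- d[d$sample_type == "B", c("replicate", "dcq")]
pairedTest(a, b)
```

```{r anova}
sim <- simulateExperiment(
  simulationConfig(offsets = c(A = 0, B = -0.3, C = 0.2),
                   n_replicates = 4, n_plates = 2, sd_plate = 0.25),
  seed = 1)
fit <- blockedAnova(deltaCq(sim$experiment), blocks = "plate")
fit
plotRatios(fit)
```
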