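# commonbase

Relative quantification of gene expression from qPCR data, done entirely
in log scale. The package is for experimentalists analyzing quantification
cycles (Cq) and per-well amplification efficiencies (E) from qPCR plates —
the data behind treatment-vs-control, genotype, tissue or time-point
comparisons of a gene of interest normalized to reference genes — and for
anyone who needs those comparisons with defensible statistics: t-tests,
blocked ANOVA, and confidence intervals that transform correctly to the
ratio scale.

## The method

Each well's amplification amount is E^Cq. Because
E^Cq = b^(log_b(E)·Cq) for any base b > 1, every well can be placed
on one common log scale via the efficiency-weighted quantification cycle

    Cq(w) = log_b(E) · Cq           (base 10 by default)

The analysis then stays in log scale as long as possible:

* technical replicates are averaged arithmetically in weighted space:
  Cq(w)_{r,t,g} = (1/n) Σ_i log_b(E_i)·Cq_i
* normalization subtracts the arithmetic mean of the reference genes
  (equivalent to geometric-mean normalization of quantities):
  ΔCq(w)_{r,t} = Cq(w)_{GOI} − (1/n) Σ_i Cq(w)_{REF_i}
* two sample types are compared through
  ΔΔCq(w) = ΔCq(w)_A − ΔCq(w)_B (difference of means, unpaired; mean of
  per-pair differences, paired), tested against 0 with Welch/paired
  t-tests or a blocked ANOVA with Bonferroni post-hoc comparisons
* only at the end is anything back-transformed: the expression ratio is
  R = b^(−ΔΔCq(w)), and a log-scale confidence interval (l, u) becomes
  the asymmetric ratio-scale interval (b^(−u), b^(−l))

With gene-wise constant efficiencies this reproduces the classical
efficiency-corrected (Pfaffl) ratio exactly, and with E = 2 the
2^(−ΔΔCq) (Livak) ratio; both are kept as oracles in the test suite.
Working in log scale is what makes parametric statistics valid here —
t-tests applied directly to ratios give direction-dependent answers, and
the package ships a demonstrator of exactly that failure
(`improperRatioTest()`, CLI subcommand `demo-misuse`).

Plate-to-plate variation is handled by declaring each plate a complete
randomized block (`blockedAnova(..., blocks = "plate")`), which partitions
nuisance variation out of the error term and can turn an undetectable
effect into a clear one.

## Worked example

The package ships a constructed four-replicate experiment
(`exampleExperiment()`; per-well data for the first replicate pair are
also available as `examplePlate()`). Each replicate pair sits on its own
plate, so the comparison is paired:

```r
library(commonbase)

experiment <- exampleExperiment()
d <- deltaCq(experiment)        # weighting + aggregation + normalization
head(d, 4)
#>   replicate sample_type       dcq  plate
#> 1        r1           A 1.1386945 plate1
#> 2        r1           B 1.4076917 plate1
#> 3        r2           A 0.8449997 plate2
#> 4        r2           B 1.2910055 plate2

a <- d[d$sample_type == "A", c("replicate", "dcq")]
b <- d[d$sample_type == "B", c("replicate", "dcq")]
pairedTest(a, b)
#> Paired t-test on delta-Cq(w) differences
#>   ddCq(w) = -0.5462  (se 0.1569, df 3.000, base 10)
#>   t = -3.481, two-tailed p = 0.04002
#>   95% CI (log scale): (-1.0456, -0.0469)
#>   expression ratio = 3.52, 95% CI (1.11, 11.1)
```

Reading: the gene of interest is expressed about 3.5-fold higher in
sample type A than in B after normalization to the two reference genes;
the 95% interval (1.11, 11.1) excludes a ratio of 1, matching the
p-value of 0.040. The interval is asymmetric about 3.52 — that is the
correct consequence of back-transforming from log scale, and the reason
the package reports confidence intervals instead of transformed standard
errors. `plotRatios()` draws these ratios with their CI bars;
`writeResults()` exports full-precision CSV tables.

A command-line front end over the same functions lives at
`inst/scripts/cbm.R` (after installation:
`system.file("scripts", "cbm.R", package = "commonbase")`):

    Rscript cbm.R analyze --input wells.csv --design paired --out run
    Rscript cbm.R analyze --input wells.csv --design anova --block plate --out run
    Rscript cbm.R simulate --config sim.yaml --seed 1 --out sim
    Rscript cbm.R demo-misuse --input wells.csv --out misuse

`simulate` generates synthetic plates with known ground truth
(lognormal expression with biological, plate and technical variance
components; see `?simulateExperiment`), which is also how the test suite
checks estimator bias, interval coverage, type-I error and the power gain
from plate blocking.

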