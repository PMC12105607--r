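# focalsna

Post-conflict proximity networks from focal-sampling behavioral data.

Zoo-housed bonobo groups reorganize their affiliative behavior around
conflict, and not only among the individuals who fought. This package turns
focal-sampling event logs of group-housed animals into directed,
observation-time-normalized proximity networks — one per (group, conflict
context) — and runs the statistical battery needed to ask whether dominant
females sit at the center of those networks, whether their position is
maintained by initiations from others, how proximity rates shift in the
hour after conflicts and single-individual outbursts, and whether
sociosexual behavior is elevated post-conflict. Because raw records for
this kind of zoo study are rarely depositable, a fully parameterized
generator of focal schedules, disruption events, and dyadic bouts stands in
for the data and supports power and type-I-error experiments.

## The core quantities

Every directed dyad in a (group, context) cell gets the weight

```
w(A -> B) = seconds of proximity initiated by A toward B
            -------------------------------------------------
            (minutes observing A) + (minutes observing B)
```

so effort-rich and effort-poor cells are comparable. On each network the
package computes eigenvector centrality (principal eigenvector of the
symmetrized weight matrix by power iteration, rescaled to max = 1) and
in-/out-/total strength. The battery comprises Lilliefors normality screens
with Monte Carlo p-values, one-way rank ANOVA across contexts with three a
priori orthogonal contrasts (non-conflict vs conflict, intragroup vs
intergroup, neutral vs outburst), two-way rank ANOVA (dominance x context,
Type III), Spearman validation of the behavior pooling, and a replicated
goodness-of-fit G-test of sociosexual counts with observation time as the
expectation, partitioned into pooled and heterogeneity components.

## Worked example

The directed weight for a dyad whose initiator was observed 33 focal
minutes, recipient 26 minutes, with 171 s of initiated proximity:

```r
library(focalsna)
dyadic_rate(171, 33, 26)
#> [1] 2.898305
```

A complete synthetic study and its analysis:

```r
sim <- make_fixture(seed = 20230701)   # 5 groups, 271 focals, 2,710 min
res <- run_pipeline(sim$log, sim$roster)
res$stats$sociosexual_g
#> Replicated goodness-of-fit G-test
#>   Total G         =   52.211, df = 4, p = 1.2463e-10
#>   Pooled G        =   51.894, df = 1, p = 5.8568e-13
#>   Heterogeneity G =    0.316, df = 3, p = 0.9569
```

Sociosexual events cluster in post-conflict observation time far beyond
the exposure expectation (the pooled component), and the five groups agree
(no heterogeneity) — the qualitative signature the generator's study
conditions encode. The numbered drivers under `analysis/` run the same
sequence as standalone steps (simulate, networks, metrics, statistics,
recovery experiments) and write their tables under `results/`; step 3, for
instance, reports that dominant females average eigenvector centrality
0.819 against 0.647 for other individuals in this dataset.

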