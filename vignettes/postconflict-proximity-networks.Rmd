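---
title: "Methods: post-conflict proximity networks from focal-sampling data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-conflict proximity networks from focal-sampling data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(focalsna)
```

## The problem

Group-living primates adjust their social behavior around conflict, and
those adjustments are not confined to the individuals who fought. To see
group-level change, one needs a representation of the whole group's
affiliative structure under different conditions. `focalsna` converts
focal-sampling event logs of group-housed bonobos into directed,
observation-time-normalized proximity networks, stratified by *conflict
context* — neutral, the hour after a single-individual outburst, the hour
after an intragroup conflict, and the hour after an intergroup conflict —
and then asks, with a battery of nonparametric tests, how centrality,
initiation rates, and sociosexual behavior differ between dominant females
and other individuals and across those contexts.

Because the source data for this kind of study are typically not
depositable, the package ships a generative model of the whole observation
process. The generator is first-class code: every distributional claim the
tests make about the pipeline is checked against data the generator
produced under known parameters.

## From event log to networks

**Records.** The event-log CSV carries four record types: focal samples
(who was watched, when, for how long), social state bouts (behavior,
actor, partner, initiator, duration in seconds), point events (sociosexual,
aggression, submission counts), and disruption events (outburst,
intragroup, intergroup). A roster gives group membership, one
dominant-female flag per group, and whether the group can interact with
another group (which is what makes intergroup conflict possible).

**Pooling.** The six affiliative state behaviors that imply proximity
within 2 m — grooming, play, co-feeding, contact, close proximity, partial
proximity — are pooled into a single *proximity* category; single-behavior
networks would be too sparse at realistic focal effort. The pooling is
validated by a Spearman correlation between per-dyad totals of the
affiliative subclass (groom/play/cofeed) and the proximity subclass
(contact/close/partial).

**Context windows.** A focal sample's context is decided by its start
time: post-X if a disruption of kind X occurred in the half-open window
$(t - 60\ \mathrm{min},\, t]$, neutral otherwise. Three decisions close
gaps the windowing rule leaves open:

* *Precedence.* When windows overlap, conflicts outrank outbursts and
  intergroup outranks intragroup; within a kind, the most recent event
  wins. Conflicts are the analytic focus; outbursts are the weakest
  signal.
* *Whole-focal assignment.* The entire sample inherits the context of its
  start time; a conflict mid-focal changes only subsequent samples. The
  observation-time ledger then reports whole minutes per individual per
  context, and minutes are conserved by construction.
* *Window boundary.* An event exactly 60 minutes old is outside the
  window; an event at the focal's start instant is inside.
* *Session boundary.* Post-event windows do not carry across calendar
  sessions; with single-observer daily sessions there is no way to know
  what happened between sessions.

**Dyadic weights.** For each ordered pair in each (group, context), the
edge weight is

$$w_{A \to B} \;=\;
  \frac{\text{seconds of proximity initiated by } A \text{ toward } B}
       {\text{minutes observing } A + \text{minutes observing } B},$$

in units of seconds per combined observation minute. Normalizing by the
dyad's combined focal time makes weights comparable across individuals and
cells with unequal effort: doubling all observation with the same behavior
halves every weight, and weights reconstruct raw seconds exactly when
multiplied back by combined minutes (both are tested properties). A bout
whose initiator was not observed becomes an undirected edge: it
contributes to total strength but to neither in- nor out-strength.

**Exclusions.** Two rules guard small cells. If two or more members of a
cell have zero focal minutes, interactions between them were unobservable,
so the whole network's eigenvector centrality is marked invalid and those
individuals' strengths are excluded. If fewer than two distinct dyads were
observed (configurable), centrality is likewise invalid but strengths are
kept. Individuals with zero minutes can still appear in networks — they
are visible as partners during others' focals — so a single unobserved
member does not invalidate anything.

## Node metrics

*Strengths.* In-strength of $i$ is $\sum_j w_{j \to i}$ (rate of receiving
initiations), out-strength $\sum_j w_{i \to j}$, total their sum. The
handshake identity $\sum_i s^{in}_i = \sum_i s^{out}_i = \sum_e w_e$ is
asserted on every generated network.

*Eigenvector centrality* is the principal eigenvector of the network's
non-negative weight matrix, computed by power iteration (tolerance
$10^{-10}$, max 10,000 iterations) and rescaled so the most central
individual scores exactly 1, which makes scores comparable across group
sizes. Numerical choices:

* **Symmetrization (default).** Proximity is physically mutual, and a
  directed spectrum is ill-defined for nodes that never receive
  initiations — common at this sparsity — so the default matrix is
  $W + W^\top$. Directed variants are exposed as modes for sensitivity
  analysis.
* **Diagonal shift.** A symmetrized star graph has paired $\pm\lambda$
  eigenvalues on which plain power iteration oscillates; iterating on
  $W + cI$ with $c$ the maximum absolute row sum makes the dominant
  eigenvalue unique without changing eigenvectors.
* **Disconnected support.** If positive edges span several components,
  the principal vector is computed per component (processed in order of
  smallest node ID), each component's scores are scaled by its dominant
  eigenvalue relative to the global maximum, and a warning is raised.
  Isolated nodes score 0. This keeps the scores deterministic when the
  principal eigenvalue would otherwise be degenerate.

The power-iteration implementation is verified against a dense
eigendecomposition oracle to $10^{-8}$ on hundreds of random weighted
networks of 3–8 nodes, and against igraph on simulated networks.

## The statistical battery

*Normality screening* uses the Lilliefors variant of the
Kolmogorov–Smirnov test (mean and SD estimated from the sample) with a
seeded Monte Carlo p-value (10,000 normal samples by default), reported in
the classical bound style: `> 0.15` above the table cap, `< 0.01` below
it, the estimate itself in between. Strength distributions are generally
non-normal at this scale, which motivates the rank transforms below.

*Rank ANOVAs.* Responses are converted to midranks (ties get average
ranks; ranks sum to $n(n+1)/2$), making every result invariant under
strictly monotone transforms of the raw response. The one-way analysis of
total strength across the four contexts carries three a priori orthogonal
contrasts in the order (neutral, post-outburst, post-intragroup,
post-intergroup):

| contrast | coefficients | question |
|---|---|---|
| non-conflict vs conflict | $(+1, +1, -1, -1)$ | does proximity differ after real conflicts? |
| intragroup vs intergroup | $(0, 0, +1, -1)$ | do the two conflict kinds differ? |
| neutral vs outburst | $(+1, -1, 0, 0)$ | is an outburst a social event at all? |

Each contrast is a 1-df F ratio
$SS_c = (\sum_k c_k \bar y_k)^2 / \sum_k (c_k^2/n_k)$ against the omnibus
within-cell mean square; under balance the three $SS_c$ partition the
between-context sum of squares exactly (tested to $10^{-9}$). The two-way
analyses (dominance × context, for in- and out-strength) use Type III sums
of squares with sum-to-zero contrasts, the appropriate choice for this
unbalanced 2 × 4 design; Type II is a configuration switch. A context
observed for only one dominance class would alias the interaction and is
dropped with a warning, like an empty factor level.

*Ranking scope.* For the two-way models, ranks are taken over the full
analysis sample (the default); for the per-class context comparisons a
`within_category` switch ranks inside each dominance class instead. Both
are defensible readings of standard practice; the global default keeps the
two-way response on one scale, and the switch is echoed into every report
header.

*Sociosexual counts* are tested with a replicated goodness-of-fit G-test
using observation time as expectation: for each group,
$G = 2\sum O \ln(O/E)$ with $E$ = group total × exposure share, categories
being conflict (post-intragroup + post-intergroup) vs non-conflict
(neutral + post-outburst) minutes. Summing per-group G gives the total
(df = number of informative groups); the pooled G (df = 1) uses summed
counts against summed exposures; heterogeneity is their difference. With
five groups the partition has df 5 = 1 + 4. The two-category,
groups-as-replicates partition is a reconstruction of standard practice
for this design, not something the windowing rule forces. Williams'
small-sample correction is available but off by default. Zero-count cells
contribute zero; a group with no events carries no information and is
dropped from the partition with a warning.

## The generator

`sim_config()` collects every generative parameter; `simulate_observations()`
draws a complete study: one session per calendar day (a single observer
cannot overlap focals), each session one 10-minute focal of every group
member in random order; disruption events Poisson in session time, with
intergroup conflict only in access-enabled groups; per-directed-dyad
proximity bouts Poisson at rate

$$\lambda \cdot m_{\text{context}} \cdot \alpha^{[\text{target is DF}]}
  \quad \text{bouts per observation hour},$$

with log-normal durations (median 60 s, $\sigma_{\log} = 0.75$ — positive
and right-skewed, as behavioral bouts are) truncated to the focal window;
and sociosexual point events at context-dependent per-individual rates.
The seed fully determines the output, and the output parses through the
ingestion layer unchanged.

Defaults are the study conditions, chosen once:

* **Group structure**: the five observed compositions (sizes 6, 7, 4, 4,
  3), one dominant female each, two mesh-adjacent groups with intergroup
  access; session counts give ~2,700 focal minutes, the observed
  magnitude.
* **$\alpha = 2.5$** (dominance attraction): members initiate proximity
  toward the dominant female at 2.5× the base rate, entering through the
  in-strength pathway — the study system's dominant females are more
  central and receive, rather than make, more initiations.
* **$m = (1, 1.6, 0.6, 0.6)$** (neutral, outburst, intragroup,
  intergroup): proximity is elevated after outbursts and suppressed after
  conflicts. The ordering is the observed one; the magnitudes are
  order-of-magnitude choices, not estimates, and are labeled as such.
* **Sociosexual rates** 0.2/h per individual in non-conflict contexts vs
  4/h post-conflict, giving a few dozen events per schedule with the
  strong post-conflict elevation the printed G statistic implies.
* **$\lambda = 0.7$ bouts/h** per directed dyad, giving bout totals of a
  few hundred per schedule at this effort.

What the generator does *not* emulate: dyad-level behavioral consistency
(each bout's behavior label is drawn independently, so the
affiliative-vs-proximity pooling correlation is much weaker than in real
dyads, where relationships express themselves across behaviors),
individual personalities and histories, kinship, within-session rate
autocorrelation, and observer error. Passing tests therefore show that the
pipeline measures what the generative model encodes — not that real
bonobo groups behave like the model.

## Calibration and recovery experiments

`recovery_experiment()` simulates datasets over a grid of $\alpha$ values
and reports how often dominant females top the mean centrality ranking and
how often the dominance main effect (two-way rank ANOVA on in-strength)
rejects at 0.05; `contrast_recovery_experiment()` elevates only the
post-outburst rate modifier and reports per-contrast rejection rates.

These experiments run on five equal-sized groups of five
(`calibration_groups()`), not the observed sizes. The reason is a
confound: strength scales with the number of incoming dyads, and each
group contributes exactly one dominant female, so with unequal group sizes
the dominance factor is partially a group-size factor even under the null
and the nominal level is not the right yardstick. With equal sizes the
dominant female is exchangeable with her groupmates at $\alpha = 1$, and
the type-I error of the dominance test is a meaningful quantity. At 1,000
replicates the dominance main effect rejects at the nominal rate; power
rises steeply with $\alpha$ and is essentially 1 at $\alpha = 5$; and with
only the outburst modifier raised, the neutral-vs-outburst contrast is the
most frequently rejecting of the three, with non-conflict-vs-conflict
(which receives half the effect) second. The test suite computes all of
these; replicate counts there (1,000 for the null calibration, 200 per
grid point for power, 120 for the contrast experiment) were sized to keep
Monte Carlo error well inside the asserted margins at a few minutes of
runtime.

A caveat the diagnostics surfaced: with a real context effect present, the
rank-transform two-way F test for the *other* main effect is known to be
mildly anticonservative, and 200-replicate pilots showed rejection rates
up to ~0.08–0.095 at some seed sets. Users calibrating against their own
designs should prefer large replicate counts and treat p-values near the
threshold with correspondingly mild confidence.

## Known limitations

* Eigenvector centrality in groups of 3–4 is dominated by the max-1
  rescaling; interpret small-group centralities cautiously (the exclusion
  rules remove only the worst cases).
* The per-component eigenvalue scaling for disconnected networks is a
  documented convention, not a canonical definition; fully principled
  comparisons should restrict to connected networks.
* The G-test expectation assumes detection probability is constant across
  contexts; if post-conflict sociosexual behavior is easier to notice,
  the test conflates rate and detectability.
* Whole-focal context assignment misclassifies the tail of a focal that
  spans a window boundary; at 10-minute focals against 60-minute windows
  the distortion is small, but it is systematic.
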