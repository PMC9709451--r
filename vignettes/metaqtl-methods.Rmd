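---
title: "Methods: consensus clustering of rice grain-yield QTLs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus clustering of rice grain-yield QTLs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaqtl)
```

## The problem

Individual QTL mapping studies for rice grain-yield components
(spikelet fertility, panicles per plant, grains per panicle,
thousand-grain weight) disagree: each uses its own biparental cross,
marker panel and genetic map, and each reports loci with wide, design-
dependent confidence intervals. Meta-QTL analysis asks which of these
reports describe the same underlying locus. The answer is obtained by
placing every reported QTL on one consensus map and clustering
co-locating peaks, weighting each report by how precisely its design
could localise the locus.

## Confidence intervals from mapping design

A reported QTL rarely ships a usable interval, but its 95% CI can be
approximated from the population type, the population size $N$ and the
proportion of phenotypic variance explained $R^2$:

$$\mathrm{CI}_{95} = \frac{c}{N R^2}, \qquad
  c = \begin{cases} 530 & \text{BC, F}_2\\ 287 & \text{DH}\\
  163 & \text{RIL}\end{cases}$$

$R^2$ enters as a proportion. Treating it as a percent would make a
RIL study of $N = 200$, $R^2 = 10$ claim a 0.08 cM interval — far
tighter than any linkage study resolves — while the proportion reading
gives 8.15 cM, in line with the 0.6–112 cM spread of projected-QTL
intervals this kind of compendium shows. External tables store PVE as
percent (as journals print it); the package divides by 100 at the
module boundary.

Reports lacking a LOD score receive the conventional detection
threshold LOD = 3.0; reports lacking $R^2$ receive 10%. Both defaults
are flagged per record (`imputed_lod`, `imputed_pve`) so sensitivity
analyses can exclude them. Under the Gaussian position model a 95%
interval spans $3.92\sigma$, so each QTL's standard deviation is
$\sigma_i = \mathrm{CI}_{95,i}/3.92$.

## Consensus map and projection

The consensus map is built from a high-density scaffold by anchor
interpolation: scaffold markers keep their positions exactly, and each
component-map marker is placed by linear interpolation of its component
position between the two nearest markers shared with the scaffold.
This replaces linear-programming map merging deliberately: the merged
map serves only as a coordinate frame for projection, and
interpolation preserves that role while being deterministic and
directly testable. Markers beyond a component's terminal anchors are
extrapolated with the chromosome-level mean scaling ratio and dropped
(with reason) if that places them outside the scaffold chromosome;
component chromosomes whose anchors are order-inconsistent with the
scaffold contribute nothing and are reported rather than silently
reconciled — how published maps' order conflicts should be arbitrated
is genuinely open, and drop-and-report is the auditable choice.
Position ties are broken by a smallest-workable offset in input order,
because downstream interpolation requires strict ordering and
determinism beats arbitrariness.

Each QTL's peak and both CI endpoints (peak ± CI/2 on the source map,
clipped at the chromosome bounds) are then projected independently,
each through its own nearest flanking shared anchors. Projecting
endpoints separately handles intervals spanning several anchor
intervals and reduces to a simple homothety when all three points share
one interval. Failures are never silent: every unprojectable QTL gets
one of five reason codes (`NO_SHARED_ANCHOR_LEFT/RIGHT`,
`ANCHOR_ORDER_CONFLICT`, `ZERO_INTERVAL`, `MISSING_PEAK`), and the
report conserves counts (projected + rejected = input). A QTL with
flanking markers but no peak is salvaged as the flank midpoint and
flagged `PEAK_FROM_FLANKS`.

## The mixture model

On each chromosome the projected peaks $x_i$ are modelled as

$$x_i \sim \sum_{k=1}^{K} \pi_k\, N(\mu_k, \sigma_i^2),$$

with the per-QTL $\sigma_i$ **known** from the projected CI. Only the
cluster positions $\mu_k$ and mixing proportions $\pi_k$ are free, so
$\nu = 2K - 1$. EM is standard: responsibilities
$r_{ik} \propto \pi_k \phi(x_i;\mu_k,\sigma_i^2)$ in the E-step;
precision-weighted means
$\mu_k = \sum_i r_{ik} x_i/\sigma_i^2 \big/ \sum_i r_{ik}/\sigma_i^2$
and $\pi_k = \bar r_{\cdot k}$ in the M-step. No general mixture
package fits this known-heteroscedastic-variance case (mclust, for
example, estimates its variances), so the EM core is implemented here
and cross-checked in the tests against closed forms ($K=1$ is exactly
the precision-weighted mean) and a brute-force enumeration of all hard
partitions at small $n$.

Numerical choices:

* responsibilities via log-sum-exp, never raw densities;
* $\sigma$ floor of 0.1 cM — an implausibly tight report (CI < 0.4 cM)
  would otherwise dominate its chromosome and spike the likelihood;
* 10 restarts per $K$ (one quantile-spread start plus nine seeded
  draws of $K$ data points), relative log-likelihood tolerance 1e-6,
  at most 500 iterations; every restart seed derives from one master
  seed that is echoed in the output;
* the log-likelihood is asserted non-decreasing each iteration
  (tolerance 1e-9); a violation aborts with a diagnostic rather than
  returning a silently wrong fit;
* a component left empty under hard assignment triggers a refit at
  $K-1$, flagged in the result.

## Choosing K

Model scores are
AIC $= -2\ln L + 2\nu$,
AIC3 $= -2\ln L + 3\nu$,
AICc $=$ AIC $+ 2\nu(\nu+1)/(n-\nu-1)$ (infinite once $n \le \nu + 1$),
BIC $= -2\ln L + \nu \ln n$, and
AWE $= -2\ln L_c + 2\nu(3/2 + \ln n)$ with $L_c$ the classified
(hard-assignment) likelihood.

Selection is two-branch: chromosomes with at most 10 QTLs use the
minimum-AIC model; larger chromosomes let all five criteria vote for
their minimising $K$, majority wins. "Lowest value across five
criteria" is ill-defined when the criteria disagree, so the vote with
a smaller-$K$ tie-break operationalises it conservatively. Both
branches share one likelihood core — the historical small-$n$ method's
modified criterion is not restated anywhere accessible, and plain AIC
within the same framework keeps the branches comparable. $K$ ranges
over $1..\min(n, 10)$ per chromosome; published per-chromosome MQTL
counts stay below ten, and the cap bounds cost.

An MQTL takes $\mu_k$ as its position and, by precision addition over
its hard-assigned members,
$$\mathrm{CI}_{95}^{\mathrm{MQTL}} = 3.92\sqrt{1 \Big/ \sum_{i \in k}
  1/\sigma_i^2},$$
which is strictly tighter than its tightest member whenever two or
more QTLs co-locate — the formal content of the "CI fold reduction"
a meta-analysis reports. Responsibilities are retained as percent
membership. Names run `MQTL{chr}.{k}` by ascending position; flanking
markers are the nearest consensus markers outside the CI. Fold
reduction is reported three ways — overall mean ratio, per chromosome,
and per-chromosome maximum — because a single "up to" figure conflates
the latter two.

MQTLs with at least six member QTLs are called stable; the threshold
is a parameter (`stable_filter(mqtls, threshold)`).

## Candidate genes

Stable MQTLs are resolved to physical intervals by looking up their
flanking markers in a marker→bp table (1-based inclusive; BED export
converts to 0-based half-open). The table replaces sequence BLAST of
marker sequences deliberately: it keeps the artifact deterministic and
self-contained, and any alignment route can produce it externally.
Genes are the `gene` features of a GFF3 overlapping the interval by at
least 1 bp — partial overlap, not containment, because a gene
straddling an interval end is still a candidate. GO enrichment is the
one-sided hypergeometric upper tail per term with Benjamini–Hochberg
correction at FDR 0.05. Expression ranking scores each gene by
$(\bar e_{\mathrm{target}} + c)/(\bar e_{\mathrm{other}} + c)$ with
pseudocount $c = 0.1$ against a configurable yield-tissue set (anther,
pistil, seed at 5 and 10 DAP, embryo, endosperm, pre/post-emergence
inflorescence); the default 2-fold shortlist threshold quantifies the
otherwise vague notion of "high fold change" and is exposed as a
parameter.

## The synthetic generator

`simulate_compendium()` emulates the compendium a literature search
produces, with the truth recorded. Defaults mirror the panel the
published tables describe: 47 studies, RIL/BC/F2/DH drawn 26/11/9/1,
population sizes uniform on [24, 472], $R^2$ log-normal with median
0.08 clipped to [0.01, 0.52] (the printed PVE range reaches 0.03%, but
a 0.0003 proportion yields absurd kilocentimorgan CIs, so the lower
clip is raised to 1%), detection probability 0.16 per study × locus
(sized so 47 studies over 62 true loci yield roughly 460 reports), and
a 12-chromosome architecture of 62 loci on 2,945.67 cM. Component maps
are scaffold subsamples with per-interval multiplicative length jitter
Uniform(0.8, 1.25) — order-preserving by construction, so projection
error remains attributable to the projection model rather than
confounded with order conflicts. Observed peaks are drawn
$N(\mu_{\mathrm{true}}, \sigma_i^2)$ truncated to the chromosome, with
$\sigma_i$ computed from the same CI formula the pipeline will apply,
via inverse-CDF truncation so the RNG stream length never depends on
rejection counts and reruns are byte-identical.

What the generator does **not** emulate: genotype/phenotype-level QTL
scans (noise enters at the reported-QTL level only), marker-name
curation problems, genuinely conflicting published marker orders
(jitter never permutes), trait-correlated pleiotropy, or
publication-bias selection of large effects. Passing recovery tests
therefore demonstrates correctness of the statistical machinery under
its own assumptions, not robustness to every pathology of real
literature data.

## Problem sizes and calibration checks

The test suite works at two scales, chosen to keep the default run
fast while still exercising the model where its behaviour is
non-trivial: two-chromosome architectures with two well-separated loci
each (cluster separation at least five times the largest $\sigma$,
eight or more QTLs per cluster) for selection-accuracy and calibration
loops of 100 seeds, and the full 12-chromosome panel scale in the
`analysis/` drivers. On the well-specified setting (no map jitter,
$R^2$ clipped to [0.05, 0.4], $N \in [150, 400]$) the MQTL 95% CI
covers the true position at the nominal rate (observed ≈ 0.95 over
100 seeds), which is the calibration statement behind the precision-
addition interval.

## Known limitations

* QTLs are weighted only through $\sigma_i$; no extra weighting by
  study quality or replication.
* One trait per QTL record; multi-trait joint modelling is out of
  scope.
* The consensus map inherits whatever bias the scaffold has; component
  evidence never moves a scaffold marker.
* Greedy truth-matching in `recovery_metrics()` is not an optimal
  assignment, which can understate recovery when clusters split.
* The two-branch rule's small-$n$ branch uses plain AIC; if the
  historical modified criterion differed materially, small chromosomes
  could select differently.
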