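---
title: "Methods: consensus maps, QTL projection and meta-QTL delineation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus maps, QTL projection and meta-QTL delineation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model, the algorithmic and
numerical choices, and the known limitations of the package. It is the
place where design decisions that were genuinely open are recorded.

# The compendium and its completion rules

A QTL compendium row carries what a published mapping study reports: the
chromosome, the two flanking markers, optionally a peak position and a 95%
confidence interval (cM), a LOD score, the phenotypic variance explained
(PVE, stored as the percent the papers print), and the mapping-population
type and size. Published tables are incomplete in predictable ways, and
the completion rules mirror standard curation practice:

* missing peak → midpoint of the flanking-marker positions, looked up on
  the study's own linkage map;
* missing LOD → 3.0, the conventional declaration threshold, since a
  reported QTL must have reached at least that support;
* missing CI → the population-specific approximation
  CI(95%) = c/(N·R²) with c = 530 (F2/backcross), 287 (doubled haploid)
  and 163 (recombinant inbred lines), centred on the peak.

Three choices here were open and are resolved as follows. PVE is stored as
percent but the CI formula consumes a proportion; the division by 100
happens inside the catalog so the formula itself stays in its textbook
form. Near-isogenic lines have no published constant; they descend from
inbred-line crosses, so the RIL constant 163 is used. The formulas return
only a width, so the estimated CI is centred symmetrically on the peak.
Records with neither a peak nor resolvable flanking positions cannot be
placed at all; they are excluded and logged, mirroring the non-projectable
QTLs every meta-analysis reports.

# Consensus-map construction

Per chromosome, the merge estimates consensus positions $y$ by minimizing

$$\sum_j \frac{1}{n_j} \sum_{(a,b)\ \text{adjacent in map } j}
  \bigl| (y_b - y_a) - d_j(a,b) \bigr|$$

subject to $y_b - y_a \ge \delta$ for every retained ordered adjacent pair
of every component map, where $d_j(a,b)$ is the distance map $j$ reports,
$n_j$ its number of adjacent pairs on the chromosome, and
$\delta = 10^{-6}$ cM makes "strictly ordered" representable as a linear
constraint. This is a linear program; it is solved as a constrained median
(L1) regression via the Frisch–Newton interior-point method
(`quantreg::rq.fit.fnc`), with the design matrix holding one ±1 difference
row per component-map adjacency.

**Order conflicts.** When component maps disagree on marker order the
constraint set contains directed cycles. Finding the minimum set of
constraints to delete is NP-hard (minimum feedback arc set), so a greedy,
fully reproducible approximation is used: while a cycle exists, delete
from it the constraint supported by the fewest component maps, breaking
ties toward the edge whose supporting maps carry fewer markers, then
lexicographically. Deleted constraints are reported, and their distances
are also dropped from the objective.

**Tie-breaking on flat optima.** An L1 objective can be minimized on a
whole interval (two maps reporting distances 10 and 20 make any consensus
distance in [10, 20] optimal). The package prefers, among equally optimal
configurations, positions closest in L1 to the per-pair *mean* component
distance, implemented as secondary pseudo-observations with weight
$10^{-3} \min_j (1/n_j)$. This resolves the example above to 15 — the
behaviour a scientist expects of a *consensus* — and keeps the solution
deterministic. An alternative (lexicographically smallest positions) was
considered and rejected because it systematically compresses maps toward
the proximal end.

**Degenerate inputs.** Markers constrained by no retained pair are placed
by linear interpolation between their nearest placed neighbours on each
source map (averaged across maps); chromosomes with fewer than two markers
pass through with a warning; each chromosome is finally shifted so its
first marker sits at 0 cM.

# QTL projection

A QTL moves from its source map to the consensus map by the affine map
defined by an anchor pair: the closest two markers shared by both maps
that bracket the peak (if the peak lies outside all shared markers, the
two nearest shared markers are used and the record is flagged as
extrapolated). The scale ratio is the consensus span divided by the source
span of the anchors; peak and both CI endpoints are transformed with the
same ratio, which keeps the projection affine (the CI midpoint maps to the
midpoint exactly). Projection is refused, with a reason code, when the
chromosome is absent from the consensus, no shared pair exists, the
anchors are inverted on the consensus, the source span is zero, or the
ratio leaves the guard interval (0.1, 10) — a configurable stand-in for
the marker-interval consistency checks interactive projection tools apply.
The projected CI width $w$ becomes the observation standard deviation
$\sigma = w/3.92$, i.e. a 95% interval read as ±1.96σ.

# The mixture model and model selection

Within a chromosome the projected peaks $x_i$ are modelled as

$$x_i \mid \text{component } k \sim \mathcal N(\mu_k, \sigma_i^2),$$

with $\sigma_i^2$ **known** from each QTL's projected CI and *not*
re-estimated — each study's reported interval is taken as an honest
statement of its positional precision. EM alternates the standard E-step
with precision-weighted M-step updates
$\mu_k = \sum_i r_{ik} x_i/\sigma_i^2 \big/ \sum_i r_{ik}/\sigma_i^2$,
$\pi_k = \bar r_{\cdot k}$, stopping when the log-likelihood improves by
less than $10^{-8}$ or after 500 iterations. Initialization is quantile
seeding with deterministic jittered restarts (default 5); densities are
evaluated in log space with log-sum-exp normalization. Components are
reported sorted by mean, which makes fits invariant to input order.

The number of components is chosen by five information criteria with
$p = 2K - 1$ free parameters:

* AIC $= -2L + 2p$
* AICc $= \mathrm{AIC} + 2p(p+1)/(n-p-1)$ (infinite when $n \le p+1$)
* AIC3 $= -2L + 3p$
* BIC $= -2L + p\ln n$
* AWE $= -2L_c + 2p(3/2 + \ln n)$, with $L_c$ the classification
  log-likelihood under hard max-posterior assignment.

The K winning at least three criteria is selected; failing that, the K
with the most wins, ties resolved toward the smaller K. The AICc, AIC3 and
AWE forms above are pinned here because the clustering literature offers
several variants and reproducibility requires one fixed set.

# From components to regions

Each QTL joins its max-posterior component. A component's consensus
position is the precision-weighted mean of member peaks, its variance
$1/\sum_i 1/\sigma_i^2$, and its 95% CI position ± 1.96·√variance — the
variance of the *estimated position*, which is what drives the
characteristic CI shrinkage of meta-analysis.

**Supporting intervals.** A member whose peak is inconsistent with its
component is set aside ("non-supporting") in a single refinement pass,
after which the component is recomputed once. Consistency is judged
against the member's own 95% *predictive* interval,
$|x_i - \hat\mu| \le 1.96\sqrt{\widehat{\mathrm{var}}(\hat\mu) + \sigma_i^2}$.
Judging against the component CI alone was considered and rejected: that
interval shrinks as $1/\sqrt{n}$ while member scatter does not, so for
well-populated components it would reject typical members wholesale
(roughly half, in simulation) rather than the small outlier fraction the
procedure is meant to catch.

Components left with a single member are singletons, counted separately.
Remaining regions are MQTLs when their members come from at least two
studies and QTL hotspots when a single study supplied them all; they are
numbered by position within the chromosome (`MQTL3A.2`,
`QTLhotspot_5D.1`). The flanking markers attached to a region are the
nearest consensus markers outside its CI.

# Physical anchoring and downstream layers

Base-pair coordinates are 1-based inclusive everywhere except BED output
(0-based half-open, file only). A region is anchored by its two flanking
markers through the marker physical-position table; when a flank has no
physical position the nearest anchorable marker inside the CI is used,
then outside within 5 cM, with the substitution recorded — published
compendia mix SSR and SNP markers and not all of them BLAST cleanly. The
peak's physical position is linear cM→bp interpolation between the two
anchors (the originating workflow cites an unprinted formula; linear
interpolation is the natural choice and is exact at both anchors).
Candidate-gene windows follow the 2 Mb rule: intervals under 2 Mb are
scanned whole, wider intervals contribute the 2 Mb around the peak,
clipped — not shifted — to the interval. Genes overlap a window by ≥ 1 bp
(inclusive); expression filtering requires TPM strictly greater than 2 in
at least one sample of at least one relevant tissue (defaults: grain,
spike, senescing flag leaf); GWAS verification uses the full anchored
interval, inclusive bounds and de-duplicated SNPs. Interval overlap is
delegated to GenomicRanges.

# The synthetic generator

The generator emulates the situation the pipeline is built for: a handful
of true loci per chromosome; a master marker grid whose cM→bp mapping is
piecewise linear with a centromeric plateau (a thin cM slice covering a
large bp slice), which reproduces the huge physical footprints real
mid-chromosome MQTLs show; per-study maps that are subsets of the grid
rescaled by $e^{\mathcal N(0, 0.05^2)}$; per-study detection of each locus
with probability 0.8; peaks perturbed by $\mathcal N(0, 3^2)$ cM; PVE
drawn uniformly on 3–15%; population types RIL/DH/NIL in proportions
0.7/0.25/0.05 with sizes drawn from the printed compendium ranges
(93–302, 95–414, 120); CI widths from the population formula; LOD =
3 + Exp(mean 3). Defaults are desk-scale — 3 chromosomes of 300 cM /
600 Mb, 30 markers each, 10 studies, seconds per run — so the whole suite
runs quickly; the acceptance script uses 50 seeded replicates of this
scenario.

The PVE range deserves a note: the CI formula ties a QTL's stated
precision to N·R², and the mixture model trusts those stated precisions.
Ranges dominated by high PVE would produce stated precisions far tighter
than the 3 cM peak noise, i.e. studies whose reported intervals are
overconfident; 3–15% keeps the two broadly consistent and matches the
compendium picture (most QTLs explaining under 10%).

Two scenario variants appear in the tests. The default exercises the
completion rules by blanking 20% of peaks, 30% of LODs and 50% of CIs.
The *recovery* scenario used for parameter-recovery checks sets the
missingness to zero and the locus separation to 20 cM: midpoint-completed
peaks are quantized onto marker midpoints, which is exactly the distortion
the completion tests cover, and leaving it in would conflate two separate
questions.

What the generator does **not** emulate: linkage disequilibrium and shared
parents between studies, systematic map-function differences, selective
reporting of significant QTLs, multi-QTL interference within a study, and
reference-genome assembly error. Passing tests therefore demonstrate the
pipeline's correctness under honest, independently-erring studies, not
robustness to every pathology of literature-curated data.

# Numerical choices and limitations

* `min_gap` $10^{-6}$ cM; LP tie-break weight $10^{-3}$ of the smallest
  primary weight; interior-point solutions are exact only to solver
  tolerance (~$10^{-7}$), which the tests treat as such.
* EM: tolerance $10^{-8}$, 500 iterations, 5 restarts (seeded
  deterministically from the user seed); mixing proportions floored at
  $10^{-12}$ for log-space stability.
* Kmax defaults to min(n, 10) per chromosome.
* The greedy feedback-edge removal is an approximation; it can remove
  more constraints than the true minimum, but it is deterministic and
  every removal is reported.
* Model selection errs toward oversplitting on crowded chromosomes: three
  of the five criteria are AIC-family and liberal, so the vote can favour
  K one above the truth; downstream this partly self-corrects because
  split-off single-member components become singletons, not regions. On
  the recovery scenario the per-chromosome chosen-K accuracy sits around
  the high 70s to high 80s percent depending on the seed stream, as the
  acceptance script reports.
* With one chromosome per LP and desk-scale maps, merging is fast; very
  dense maps (tens of thousands of markers per chromosome) would need a
  sparse LP formulation that is out of scope here.
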