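---
title: "Methods: models, estimators and design choices in deepseep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in deepseep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deepseep)
```

deepseep packages the quantitative layer of a comparative study of deep
continental subsurface microbial communities: how fast organisms *are*
replicating in situ, how fast their genomes say they *could* replicate, what
chemolithoautotrophic metabolism a community encodes, and how genomic
similarity between populations decays with geographic distance. Every
estimator ships with a seeded synthetic generator that knows the ground
truth, so the whole pipeline can be exercised and validated without any
sequencing data.

## The replication-fork coverage model

A bacterial population in which some cells carry active replication forks
over-represents DNA near the replication origin in shotgun sequencing:
a cell that has replicated half its chromosome contributes two copies of
origin-proximal sequence but one of terminus-proximal sequence. For a
circular chromosome of length $L$ with the origin at position 0 and the
terminus opposite, the expected depth at circular distance $d$ from the
origin ($d \in [0, L/2]$, measured along either arm) is modelled
piecewise-exponentially:

$$ \mathbb{E}[\mathrm{depth}(d)] \;=\; c_0 \,\cdot\, \mathrm{PTR}^{\,1 - 2d/L}, $$

where PTR (peak-to-trough ratio) is the origin/terminus depth ratio. The
log-linear form is what a constant per-cell fork-initiation rate implies,
and it makes the estimator below provably consistent. `simulate_coverage()`
draws from exactly this model, rescaled so the genome-wide mean equals the
requested depth exactly; Poisson per-position noise models reads as counts.
The noise model of real coverage data is an assumption — real libraries are
overdispersed by GC bias, mappability and strain variation, none of which
are simulated — so passing recovery tests here demonstrates correctness of
the estimator under its own model, not robustness to every artefact of real
data.

### The index estimator

`estimate_irep()` follows the sorted-trend strategy: window means (default
5 kb non-overlapping windows, pooled across the scaffolds of a genome bin)
are sorted ascending, and $\log_2$ of the window mean is regressed on the
window's rank fraction. Under the model above the distance-from-origin of a
random position is uniform, so sorted log-depths are linear in rank fraction
with slope $\log_2 \mathrm{PTR}$; the index is $2^{\hat\beta}$. Sorting
means neither the origin nor terminus position needs to be known — the
realistic case for metagenome-assembled genomes, which arrive as unordered
scaffold fragments.

Numerical choices worth stating:

* **Trimming keeps original ranks.** The extreme 5% of windows at each tail
  are discarded as outlier shields, but the remaining windows keep the rank
  fraction $(r - \tfrac12)/n$ they had in the *full* sorted set. Re-ranking
  the surviving windows over $[0,1]$ would shrink the slope by a factor
  $1 - 2\,\mathrm{trim}$ and make the estimator inconsistent.
* **Zero-coverage windows** are excluded before the log and counted against
  the retention fraction; a genome with no coverage at all returns an
  explicit `no-coverage` status rather than a misleading index of 1.
* **Exactly flat profiles** have an undefined regression $r^2$ (zero total
  sum of squares); it is reported as 1.0 by convention, since the fit is
  perfect and the index (1.0) is exact.
* **QC gates** default to $r^2 \ge 0.90$ and retention $\ge 0.75$; both are
  exposed. With 5 kb windows a genome must span at least ~115 kb to leave
  the required 20 windows after trimming.
* **Archaeal genomes are refused** unless forced: archaea can replicate
  from multiple origins, so a single ori→ter trend is not comparable.
* The 2% read-mismatch filter applied upstream of coverage profiles is
  recorded as provenance metadata (`mismatch_tolerance`) — filtering reads
  is outside this package.

The index interpretation (`fraction_replicating()`) is linear: an index of
1.4 means 40% of the population carries an active pair of forks.
Cross-sample averaging (`average_irep()`) uses QC-passing estimates only.

## Codon-usage bias and minimal generation times

Translationally optimized genomes concentrate the codon usage of highly
expressed genes (ribosomal proteins, used here as that set) on preferred
codons. `codon_usage()` pools in-frame codon counts over the 59 informative
codons — the 61 sense codons minus single-codon Met and Trp — and
normalizes within each synonymous family. The bias statistic
(`codon_bias()`) is the mean over shared families of half the L1 distance
between the family frequency vectors: 0 for identical usage, 1 when every
family's synonym choice is disjoint.

The generation-time map is a deliberate, package-owned calibration:
$\ln(\text{hours}) = a - b\,\cdot\,\text{bias}$ with $a = \ln 40$,
$b = \ln 100$, anchoring bias 0 at 40 h and bias 1 at 0.4 h — a
hundred-fold dynamic range covering unoptimized subsurface organisms down
to fast heterotrophs. These constants are *not* a published tool's fitted
values; validation therefore rests on order recovery (injected bias
strength must order predicted times perfectly), not absolute hours. The
reported SD is the calibration's residual scale on the log scale (0.25),
delta-method transformed. Growth temperature is accepted and recorded but
numerically inert, because a temperature correction would need coefficients
this package has no basis to fit.

The generator injects bias by interpolating ribosomal-gene codon sampling
between the uniform background and a fixed preferred-codon table (the
alphabetically first codon of each family — a modelling device, documented
in `preferred_codons()`). For a family with $k$ synonyms the expected
half-L1 distance is $b\,(1 - 1/k)$, giving a closed-form expectation the
tests compare against.

## Scaffold taxonomy by strict majority

`vote_lineage()` walks the seven canonical ranks from superkingdom down,
assigning at each rank the label carried by strictly more than half of the
scaffold's proteins and stopping at the first rank without such a winner.
Exactly 50% never wins. Unannotated proteins count toward the denominator
by default — the conservative reading of "more than half of the proteins
agree" — with a switch (`count_unannotated = FALSE`) for the
annotated-only denominator, since either behaviour is defensible. Output
order is sorted by scaffold id, making classification invariant to input
row order.

## Pathway abundance matrices

Scaffold coverages are normalized to coverage per Gbp sequenced
(`normalize_abundance()`); the unit constant is arbitrary and cancels in
the Z-scaled view. When several key enzymes diagnose one pathway, the
enzyme with the highest frequency of hits represents it
(`select_key_enzyme()`); "frequency" is the count of distinct hit-bearing
scaffolds by default (a plain reading of hit frequency), with a
summed-coverage alternative, and ties break lexicographically so selection
is deterministic. The per-sample pathway abundance is the sum of the
selected enzyme's normalized scaffold abundances; an `all_enzymes` mode
sums every key enzyme instead, since the selection-versus-summation
interplay admits both readings. Rows of the resulting pathways × samples
matrix are Z-scaled (n−1 SD) for heatmap-style comparison; zero-variance
rows become zeros and are flagged rather than producing NaNs. Community
diversity from marker (rpS3) scaffold abundances is the Shannon–Wiener
index in nats.

## Gene-sharing networks

Pairwise protein hits in BLAST outfmt-6 dialect are scored with
`similarity() = alignment_length × identity / query_length`, capped at 1.
The "density" term of that score is read as the alignment's fractional
identity — the only interpretation that makes the formula a
coverage-times-identity score on $[0,1]$ — and this reading is flagged
here deliberately. Edges join genes whose better directed score (max rule;
a stricter min rule is available) reaches the threshold, after an E-value
cutoff of $10^{-5}$; connected components are gene families. Families
spanning at most two genomes are exported as gene-loss / horizontal-transfer
candidates (`rare_genes()`); downstream phylogenetic screening of those
candidates is out of scope.

## Biogeography

Distances are geodesics on the WGS84 ellipsoid (Karney-style solver via
geosphere), not spherical approximations. `fragment_ani()` chops one genome
into 1 kb fragments, finds candidate loci in the other genome by exact
15-mer seeds (start, middle, end of the fragment), aligns each fragment
gap-tolerantly against the candidate window, keeps matches with ≥70%
identity over ≥70% of the fragment, and averages kept identities
reciprocally. Unrelated sequences essentially never share an exact 15-mer
at these genome sizes, so they return a `no-alignment` status rather than a
spurious identity. The 70/70 floors follow common whole-genome ANI
convention.

The biogeography generator derives genomes from one ancestor by *nested*
substitution along a transect: site $i$'s genome substitutes the first
$\lfloor L q_i \rceil$ positions of one shared random permutation, with
$q_i$ proportional to the site's distance from the anchor. Nesting makes
pairwise divergence exactly $|q_i - q_j|$ — deterministic, not merely in
expectation. Exact linearity of identity in *pairwise* distance
additionally requires distances to be additive along the layout, which is
why the default sites lie on a meridian transect through the Geyser
Andernach reference point (meridians are geodesics). For arbitrary
coordinates the generator still reports its achieved expected-identity
matrix as ground truth, but that matrix coincides with the linear
decay law only for collinear layouts. Distance decay is tested by Pearson
correlation of pairwise distance against pairwise identity over unordered
pairs.

## Carbon mass balance

The geyser budget is unit bookkeeping made explicit: cylinder volume from
the surveyed tubing geometry (7.5 cm radius × 351.5 m), eruptions per year
as season days × eruptions per day (defaults 210 × 12, an eruption roughly
every two hours over an April–October season), erupted inorganic carbon
from dissolved CO₂ and HCO₃⁻ concentrations via exact molar carbon
fractions (12.011/44.009 and 12.011/61.016), cell-bound carbon from cell
density at 14 fg C per cell, and the headline fixed fraction as their
ratio. The eruption count and concentration totals behind any particular
published figure are accepted as *inputs* rather than hard-coded: the
package computes the chain from whatever measurements are supplied.

## Statistical layer

Depth trends are Pearson correlations either across all genome values or
across per-ecosystem medians, with an optional exclusion mask (the natural
use: removing degassing-impacted sites, whose elevated replication sits off
the depth trend — on synthetic panels built with such an offset, exclusion
demonstrably strengthens the negative correlation). Group tests are
two-sided throughout; Welch's t is the t default because group variances
are never assumed equal. No multiple-testing correction is applied by
default; `p.adjust` composes trivially where wanted.

Equivalence testing uses two one-sided pooled-variance t-tests against
symmetric bounds derived from power: the bound is the standardized effect
(Cohen's d, pooled SD — the conventional parametrization) that the design
would detect with 33% power, found by root-finding on the noncentral-t
power curve. One structural consequence deserves emphasis: when bound and
test share the same design, the TOST statistic at zero observed difference
equals the bound's noncentrality, which at 33% power (≈1.5) is below the
one-sided 5% critical value — so with these bounds the procedure cannot
declare equivalence at equal n no matter how similar the groups, a
deliberate conservatism of narrow power-derived bounds. The verdict
becomes attainable for `power_for_bound` above roughly 0.38.

The genome quality gate retains bins with completeness ≥ 70% and
contamination ≤ 10%, both inclusive.

## Synthetic panels: what they emulate, and what they do not

`generate_site_panel()` emulates a multi-ecosystem survey: sites at evenly
spaced depths (default 12 sites over 0–3000 m), each carrying a few genomes
whose true replication index follows
$\mathrm{base} + \mathrm{slope}\cdot\mathrm{depth}$ with a positive offset
at flagged high-CO₂ sites and genome-level Gaussian scatter, floored at 1.
Defaults — base 1.6, slope $-1.3\times10^{-4}$ per m, scatter SD 0.1,
offset +0.25 — are chosen so near-surface communities sit in the actively
replicating range (index ≈ 1.4–1.7), 3 km deep communities approach
quiescence, and the degassing offset is large enough to be biologically
meaningful yet small enough not to dominate the depth signal. The panels do
*not* simulate read sampling, assembly artefacts, chimeric bins, or strain
mixtures; conclusions about those failure modes cannot be drawn from these
tests.

Determinism is a contract: every generator takes a seed and reproduces
byte-identical output, and `run_demo()` writes its configuration hash into
every output file.

## Problem sizes used by the test-suite

The suite validates on deliberately modest sizes: 150 kb genomes (30
windows) for coverage recovery, cohorts of 50 genomes for error medians,
100 seeded panels of 10 sites × 3 genomes for depth-trend power and 100
slope-zero panels for null calibration, 100 randomized fixtures per oracle
equivalence check, 5000 null replicates for Welch type-I calibration, and
12–30 kb genomes for ANI. These sizes put Monte-Carlo tolerances well below
the asserted bounds while keeping a full run in the order of a minute or
two.

## Known limitations

* The coverage model is single-origin, bidirectional, and GC-unbiased;
  the estimator's accuracy on real libraries depends on upstream filtering
  it does not perform.
* The generation-time calibration is an internal scale; absolute hours are
  not comparable to any external tool's output.
* Fragment ANI uses exact-seed candidate discovery; highly diverged pairs
  (below ~85% identity) lose fragments to seed misses before the identity
  floor applies, biasing the aligned fraction (not the identity of aligned
  fragments) downward.
* The biogeography generator's linear decay law is exact only for
  transect layouts, as discussed above.
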