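---
title: "Methods and design of ypopgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of ypopgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ypopgen)
```

`ypopgen` analyses paternal population structure from three kinds of
input: haploid sequence alignments, haplogroup calls with nested
nomenclature, and dated rooted trees, each with per-sample population and
geographic metadata. This vignette explains the statistical models, the
parameters that matter, the synthetic-data generator the test suite is
built on, and the design decisions taken where conventions genuinely
diverge.

## Diversity and neutrality statistics

For a population sample of $n$ haploid sequences we report $S$
(segregating sites), $\pi$ (mean pairwise differences),
$\theta_W = S/a_1$ with $a_1=\sum_{i=1}^{n-1}1/i$, Tajima's
$D=(\pi-\theta_W)/\sqrt{e_1 S+e_2 S(S-1)}$ with the 1989 constants
derived from $n$, Fu's $F_S$, and the unbiased Nei gene diversity
$\frac{n}{n-1}(1-\sum_i p_i^2)$ applied to haplotype labels (HD) and to
haplogroup labels (HGD).

$F_S=\ln\frac{S'}{1-S'}$ with $S'=P(K\ge k_{obs})$ under the Ewens
sampling formula at $\theta=\pi$, where
$P(K=k)=|s(n,k)|\,\theta^k/\theta^{(n)}$ and $|s(n,k)|$ are unsigned
Stirling numbers of the first kind. These are computed by the recurrence
$|s(n,k)|=|s(n-1,k-1)|+(n-1)|s(n-1,k)|$ entirely in log space
(log-sum-exp), which stays finite for $n$ in the thousands where the raw
integers overflow long before $n=200$.

Two statistics can be undefined: $D$ when $S=0$ or its variance term
vanishes (any $n=2$ sample), $F_S$ when $\pi=0$. Both are *represented*
(`NA` plus a flag) rather than raised, so per-population batch profiles
always complete. Populations under the minimum size (default 20, the
usual cut-off for frequency-based comparisons) are flagged excluded but
still reported.

**Missing data.** Sites with `N` are handled by pairwise deletion: each
pair is compared over its mutually observed sites and scaled by
$L/L_{compared}$; a site is segregating only among non-missing states.
This matches common practice; no imputation is attempted.

**Significance of $F_S$.** There is no closed-form null. The p-value is
the fraction of $B$ coalescent simulations (constant size,
$\theta=\pi_{obs}$) with a simulated $F_S$ at or below the observed one,
reported as $(b+1)/(B+1)$ with $B=1000$ by default. The conventional
reporting threshold $p<0.02$ corresponds to roughly the 5% level for
this statistic, and the test suite verifies that the false-positive rate
at that convention stays at or below 0.05 under the neutral null. The
null simulation runs in C++ (one small routine simulating the pair
$(\pi, K)$ per replicate); simulated replicates with $\pi=0$ map to
$F_S=+\infty$, consistent with $S'\to 1$ as $\theta\to 0$.

## AMOVA, Phi-statistics and their permutation tests

The AMOVA decomposition operates on squared molecular distances between
individuals: the number of pairwise sequence differences in sequence
mode, or the 0/1 label mismatch in haplogroup-frequency mode (the two
modes mirror how Fst is computed from sequences at fine scale and from
haplogroup frequencies at continental scale). Sums of squared deviations
are partitioned into among-group, among-population-within-group, and
within-population components with the standard n-coefficients for
unequal sample sizes. Negative variance components are retained as
computed — clipping them would silently break the identity that the three
percentages sum to 100 and would hide exchangeable-data behaviour.

Permutation schemes follow the standard three-scheme convention: whole
populations among groups ($\Phi_{CT}$), individuals among populations
within their group ($\Phi_{SC}$), individuals among all populations
($\Phi_{ST}$); p-values are $(b+1)/(B+1)$ with $B=1000$ by default.
A design in which every group contains exactly one population leaves the
middle stratum with zero degrees of freedom and is rejected with advice
to drop the group level; single-group designs report the among-group
fields as absent. Pairwise $\Phi_{st}$ is the two-population restriction
of the same decomposition, permuting individuals between the two
populations only.

## Frequency tables, haplogroup levels and HDHs

The "level" of a haplogroup is its depth in a supplied parent–child
nomenclature hierarchy (root = level 1). When no hierarchy is available
the segment fallback counts alternating letter/digit runs of the name
(`O`=1, `O2`=2, `O2a`=3, `O2a2`=4). Both conventions are exposed because
published analyses rarely state which grouping was used; unresolvable
names are bucketed into an explicit `unresolved` column rather than
dropped.

Highly differentiated haplogroups (HDHs) between two groups follow a
two-stage rule: candidacy at $|\Delta f| \ge 0.05$, then confirmation
only when *both* a 2×2 chi-square (no Yates correction by default; the
correction is a flag) and a two-sided Fisher exact test are significant
at $\alpha=0.05$. No multiple-testing correction is applied by default,
matching how the procedure is usually run; a Benjamini–Hochberg option
exists and is logged in the output when used.

## PCA and UPGMA

PCA is a column-centred (unscaled) SVD of the population × haplogroup
frequency matrix, the standard treatment for frequency matrices where
columns share a scale; explained variances are percentages of total
variance, and each component's sign is fixed by making its
largest-magnitude loading positive so outputs are reproducible. UPGMA is
written out explicitly rather than delegated, because reproducible
Newick output requires a defined tie-break: ties between candidate
merges are resolved lexicographically by the smallest original member of
each cluster. Its correctness is cross-checked in the tests against
average-linkage heights and cophenetic distances from an independent
clustering routine.

## Chronology

Node ages are computed from branch lengths as (maximum root-to-tip path)
minus (distance from root), so ultrametric trees put all tips at age 0.
Branching-events-through-time histograms assign each internal node to the
half-open bin $[kw,(k+1)w)$ by age — a node exactly on a boundary goes to
the *younger* bin — with $w = 500$ years by default and cumulative counts
accumulated from the oldest bin toward the present.

The shared-lineage rule between two regions requires strictly more than
`min_descendants` (default 30) downstream tips and at least `min_freq`
of each region's tips inside the clade. The defining frequency is not
fixed by convention, so `min_freq` defaults to 0.01 and is echoed in
every output. Because any ancestor of a qualifying clade also qualifies,
maximal-only reporting collapses nested hits to the topmost clade;
`report_nested = TRUE` reports all qualifying clades, and both views are
provided because collapsing conventions differ between studies.

Placement of a low-coverage query walks from the root: each child branch
is scored over its annotated SNPs observed in the query as derived
matches minus ancestral conflicts, and the walk descends only when
exactly one child reaches `min_support`. Ties and no-support stop the
walk where it stands. This is deliberately conservative: ambiguous
queries end up on an ancestor of their true branch (upstream bias)
rather than in a guessed subclade, which is the documented behaviour of
SNP-path placement on sparse data.

## Spatial statistics

Gi\* uses binary distance-band weights including self (the "star"
convention), haversine distances on a 6371-km sphere, and the global
(population) standard deviation in the denominator. When no band is
given it defaults to the median distance to the 8th nearest neighbour —
a data-driven band choice that is logged with the result; no claim is
made of replicating any proprietary "optimized" routine. Two-sided
normal p-values are BH-adjusted across locations and classified at
adjusted p < 0.01/0.05/0.10, signed hot/cold by z.

Subsistence-strategy profiles assign each sample to the category of its
deepest matching mapped lineage (by hierarchy ancestry, or nomenclature
prefix without one). The default map carries only the millet-farming and
rice-farming associated lineage lists; foraging and pastoralism lists
must be user-supplied, so no speculative assignments ship as defaults. A
haplogroup matching two categories at equal depth is a configuration
error rather than an arbitrary pick.

## Median-joining networks

The minimum spanning network at tolerance $\varepsilon$ contains an edge
$(i,j)$ iff $i$ and $j$ are disconnected using all edges shorter than
$d_{ij}-\varepsilon$; at $\varepsilon=0$ this is exactly the union of
all minimum spanning trees, so every tie is retained. Median joining
iterates: enumerate connected triplets $(u,v,w)$, form majority-state
median vectors (at a three-way disagreement — possible only on
non-binary alphabets — the central node's state is kept), add those whose
connection cost is within $\varepsilon$ of the round minimum, and
finally prune inferred nodes of degree < 3. Haplotypes are ordered
lexicographically throughout, so output is invariant to input order.
Multiplicities annotate node sizes and never affect topology.

The reported `total_cost` is the cost of the cheapest tree *contained in*
the network that connects all observed haplotypes. The distinction
matters: an MJ network is a union of optimal trees and may legitimately
retain alternative medians that no single cheapest tree uses, so an MST
over all retained nodes can exceed the true tree length. Cost is found
by exact enumeration over median subsets up to 12 medians and greedy
median elimination beyond; on tiny instances the tests verify equality
with an exhaustive Steiner search.

## The synthetic-data generator

The generator produces every input the pipeline consumes, emulating the
statistical structure such studies rest on; its defaults are the study
conditions of the test suite.

* **Genealogies.** Kingman coalescent with rate $\binom{k}{2}/(2N(t))$
  per generation, so $E[T_2]=2N_0$ generations and
  $E[T_{MRCA}]=4N_0(1-1/n)$ generations; per-locus
  $\theta = 4N_0\mu_{locus}$. Growth is modelled backward as
  $N(t)=N_0e^{-gt}$ until `growth_onset`, constant earlier, with waiting
  times drawn by exact time rescaling (closed-form inversion of the
  intensity integral in each phase) rather than discrete-generation
  simulation. Generation time defaults to 29 years; the mutation rate to
  $7.6\times10^{-10}$ per site per year — both the constants
  conventionally used for Y-chromosome dating.
* **Mutations.** Poisson per branch at $\mu \times$ length $\times$
  sites, each mutation assigned to a distinct site of a finite grid.
  Exceeding the grid is an error ("increase `n_sites`"), never a silent
  reuse, keeping site→branch maps unambiguous for placement tests.
* **Haplogroup tables.** Per-population frequency vectors drawn from a
  Dirichlet with user concentrations; planted lineages overwrite their
  entries with a deterministic cline
  $f = \text{baseline} + \text{slope}\,(\text{lat}-\overline{\text{lat}})$
  clamped to $[0,1]$; vectors renormalised; counts multinomial.
* **Hotspots.** Binomial counts with success probability
  $bg + (peak-bg)\exp(-d^2/2r^2)$ around a planted centre. Recovery
  experiments plant the centre on a grid point of a 10×10, 3°-spaced
  grid with peak 0.6, background 0.05, $r=200$ km and $n=500$ per point.
* **Queries.** True genotype = derived exactly on the root→branch path;
  calls dropped at `missing_rate` and flipped at `error_rate`
  (experiments use 0.8 / 0.01, emulating low-coverage samples with few
  informative positions).

All randomness flows through one seed per call (restored afterwards, no
global state); the pipeline derives per-stage seeds deterministically
from the run seed so stages can be rerun independently.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: sequencing error and alignment artefacts,
recurrent or back mutation (infinite sites only), recombination (none on
the analysed Y region, so this is mild), selection, population
substructure within a "population", non-multinomial sampling designs,
and spatial autocorrelation beyond a single Gaussian hotspot. Calibration
results transfer to real data only to the extent these assumptions hold.

## Experimental designs frozen into the tests

The acceptance suite fixes these conditions (chosen once as realistic
for the field, at sizes a desk machine handles in minutes):

* Neutral calibration: $n=20$, per-locus $\theta=5$
  ($N_0=1000$, 2000-site grid, $\mu$ set by
  $\theta=4N_0\mu_{locus}$), 2000 replicates.
* Type-I error: $\Phi_{st}$ on two populations of 50 drawn from one
  6-category pool with 199 permutations; Gi\* on a permuted 30-location
  field (per-location z-test at $\alpha=0.05$; the BH-adjusted rate is
  checked separately); HDH on paired multinomials of 200 over five
  categories with the candidacy threshold at 0 so the joint test itself
  is measured.
* Recovery: cline slope $-0.02$/degree across 20 populations of 200;
  placement of 500 noisy queries on a 50-tip tree with 20 SNPs per
  branch; growth-onset histogram at $N_0=2\times10^6$, $g=0.2$ per
  generation, onset 5 kya — parameters giving a sharp expected event
  peak, whose location a deterministic lineage-count ODE (the
  rate-integral oracle) predicts independently.

## Numerical choices and limitations

Tie-breaks are documented wherever output must be byte-reproducible
(UPGMA merges, MJ orderings, bin boundaries). Percentages and
frequencies are validated to machine tolerance (rows sum to 1, AMOVA
percentages to 100). Exact enumeration backstops every approximate path
in the tests: Ewens probabilities by integer Stirling rows ($n\le 8$),
Mann–Whitney by full U-distribution enumeration, MSN by all-MST
enumeration, MJ cost by exhaustive Steiner search on tiny instances.

Known limitations: AMOVA permutations recompute components from the full
distance matrix and scale quadratically in sample size; Gi\* p-values
rely on the normal approximation (fields with very few neighbours per
band are flagged); the Fu's $F_S$ null assumes constant population size
as is conventional; BEAST-style annotated Newick is stripped of
comments, not parsed, so node HPD intervals must be supplied separately
if needed; and the placement walk does not model recurrent mutation on
branch SNPs beyond the symmetric error rate.
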