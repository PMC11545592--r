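---
title: "Methods: diet analysis from faecal DNA metabarcoding read counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diet analysis from faecal DNA metabarcoding read counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fecaldiet)
```

`fecaldiet` turns a sample × OTU read-count table, a per-OTU best-hit
taxonomy table and a field-survey abundance table into dietary metrics,
a feeding-strategy classification, prey-selectivity indices and group
comparisons. This vignette documents the model behind each stage, the
tunable parameters and their defaults, the numerical conventions, and what
the synthetic-data generator does and does not emulate.

## The filtering model

Read counts from faecal metabarcoding are contaminated in predictable ways:
the predator's own DNA usually dominates (blocking primers are often
inefficient and omitted), database searches return spurious or unidentifiable
hits, and a low-level background of secondary predation (prey of the prey),
lab contamination and sequencing error spreads across many small OTUs. The
filter cascade addresses each in turn, in a fixed order:

1. **Relative read-count threshold** (`min_relative_reads`, default `1e-4`,
   i.e. 0.01 %). An OTU is kept when its dataset-wide read sum is at least
   `min_relative_reads` × the table's total reads. The cutoff is computed
   *once from the raw input total* — including host and contaminant reads —
   because the threshold models sequencing artefacts, whose rate scales with
   total sequencing effort, not with the post-hoc prey fraction. The
   comparison is `>=`: an OTU exactly at the cutoff survives. A test
   verifies that re-ordering the cascade (host removal before the
   threshold) changes results, so the order is load-bearing and guarded.
   The dataset-wide interpretation is a deliberate choice: the
   alternative, a per-sample threshold, is available via
   `per_sample_threshold = TRUE` (it zeroes sub-threshold cells within each
   sample), but per-sample totals in faecal data are dominated by variable
   host content, which would make the effective prey threshold erratic.
2. **Identity threshold** (`min_identity`, default 97): a best hit below
   97 % identity is not trusted at any rank. The value is compared without
   rounding (96.99 fails, 97.0 passes). Query coverage is read but not
   thresholded by default; `min_coverage` enables a check for data sets
   where low-coverage chimeric hits are a concern.
3. **Host, no-match and non-prey exclusion**: OTUs hitting the host taxon
   (`host_taxon`), the literal `"no match"`, or a configurable non-prey
   list (`nonprey_exclusions`: fungi, Chromista, livestock, matched against
   the full name and the genus token) are dropped with distinct audit
   reasons. OTUs present in the count table but absent from the taxonomy
   file are synthesised as "no match" rather than erroring: an
   unidentifiable OTU is a normal outcome of a database search, not a file
   defect.
4. **Survey harmonisation**: a kept species absent from the local
   field-survey species list is most plausibly a database artefact — the
   true local congener lacks a reference sequence, so reads land on its
   closest sequenced relative. Such assignments are demoted to
   "*Genus* sp.". When the genus is absent from the survey too, the item is
   kept (at genus rank) but flagged: metabarcoding can legitimately detect
   taxa a bounded field survey missed, and discarding them would bias the
   diet toward the survey.
5. **Collapse** (`collapse_rank`, default `"genus"`): reads of all kept
   OTUs mapping to the same final item are summed per sample. Genus is the
   default reporting rank because it is the finest rank at which faecal
   detections and field surveys are mutually comparable. Samples left with
   zero prey reads are dropped with a warning (they carry no dietary
   information), and `S` is the retained sample count.

Every input OTU appears exactly once in the audit table with exactly one
reason — a property the tests enforce — so the filter is fully
reconstructible from its output.

## Dietary metrics

For item $i$ and sample $k$ with read counts $n_{i,k}$, $S$ samples and $T$
items:

$$\%FOO_i = \frac{100}{S} \sum_k I(n_{i,k} > 0), \qquad
\%RRA_i = \frac{100}{S} \sum_k \frac{n_{i,k}}{\sum_j n_{j,k}}, \qquad
\%P_i = 100 \frac{\sum_k n_{i,k}}{\sum_{k:\, n_{i,k}>0} \sum_j n_{j,k}}.$$

%RRA averages *within-sample proportions*, so it is invariant to per-sample
sequencing depth and sums to 100 over items; %FOO is invariant to any
positive rescaling of a sample's counts. %P (prey-specific abundance)
restricts the denominator to the samples where the item occurs, which can
only increase it relative to the pooled read share — that inequality is a
tested invariant. %P is undefined for an item occurring nowhere and is
reported as missing, never as 0; `metrics_report()` excludes zero-occurrence
items entirely.

The Costello diagram plots %P against %FOO. The package classifies items
into its four quadrants with both cutlines at 50 % (`cutline` argument) and
ties (`>=`) assigned to the upper/right region. The 50 % value and the tie
rule are conventions: the graphical method defines the axes but no numeric
boundary, and published applications read the diagram qualitatively. The
diagonal interpretations (dominant vs rare; between- vs within-phenotype
niche component) are reported as the region labels `dominant`, `rare`,
`specialist_bpc`, `generalist_wpc` rather than as separate axes. A caveat
inherent to applying this classical method to metabarcoding: with many
detectable items, per-sample read shares disperse and %P values compress
toward the bottom of the diagram, so between-study comparisons of absolute
%P are not meaningful.

## Selectivity

Jacobs's index for diet share $r$ and availability share $p$:

$$D = \frac{r - p}{r + p - 2rp} \in [-1, 1].$$

Within each prey group (fish; benthic invertebrates) the package sets $r_i$
to the item's %RRA renormalised over the group's items, and $p_i$ to the
item's share of the group's surveyed individuals. Renormalisation makes $r$
and $p$ live on the same simplex — without it, $\sum r < 1$ whenever the
other group contributes reads and $D$ would be biased negative for every
item; with it, items detected only in faeces get exactly $D = 1$ and items
recorded only in the field exactly $D = -1$, matching the one-sided reading
of the index. `renormalise = FALSE` provides the raw %RRA/100 alternative
for sensitivity analyses. Numerical conventions: $r = p$ returns 0
(including $r = p = 1$, where the raw expression is 0/0) and $r = p = 0$ is
undefined (NaN). Chironomidae genera are merged to the family on both sides
before shares are computed (`chironomidae_genera`), reflecting the family-
level identification limit of typical benthic surveys; the merge happens
*before* renormalisation so the family's $r$ is the sum of its genera's
shares. Availability uses raw individual counts, not biomass — the only
quantity field surveys consistently report.

## Group statistics

`compare_prey_groups()` compares fish vs benthic invertebrates across
samples, using each sample as one observation: the group's share of the
sample's prey reads, and the group's item richness in that sample. The
per-sample unit is the only choice that yields enough observations for a
rank test from a single study (two values per sample, $n = S$ per group).

The Mann–Whitney U statistic is computed from midrank sums, so
$U(x,y) + U(y,x) = n_1 n_2$ holds with ties. For tie-free data with
$\min(n_1, n_2) \le 8$ the two-sided p-value is exact, from the full null
distribution of U computed by the classic count recurrence
$c(u; m, n) = c(u - n; m - 1, n) + c(u; m, n - 1)$; the cutoff at 8 keeps
enumeration cheap while covering every sample size where the normal
approximation is questionable. Beyond it (or under ties) a normal
approximation with tie correction and a 0.5 continuity correction is used.
Exact mode under ties is refused rather than approximated silently: the
rank-permutation null is no longer distribution-free there. The test suite
checks the exact path against an independent full enumeration of rank
subsets, against `wilcox.test`, and calibrates the approximation's type-I
error at $n = 20/20$.

Rarefaction uses the exact hypergeometric forms
$E[S_m] = \sum_i \left(1 - \binom{N - N_i}{m}\big/\binom{N}{m}\right)$
(individual-based, $N_i$ = item read totals) and the analogous sample-based
form with occurrence counts $F_i$ out of $S$ samples. Binomial coefficients
are evaluated in log space (`lchoose`), so curves remain stable at
sequencing-scale $N$. Both curves are non-decreasing and concave and end at
the observed richness — tested properties.

## The synthetic-data generator

`generate_dataset()` emulates the structure of a faecal COI metabarcoding
study with known truth. Per sample: depth is drawn (negative binomial,
default mean 311,858 and size 5, matching the scale and heavy variation of
a MiSeq run pooled over ~24 faecal samples; a lognormal alternative is
available); prey incidence is Bernoulli per item with probability $\psi_i$;
the prey composition is Dirichlet with concentration $\alpha$ (default 20)
around the present items' renormalised mean shares; and reads are allocated
in one multinomial draw across the host OTU (default `host_fraction`
0.55 — host DNA dominates when blocking primers are not used), the noise
OTUs (default 200 OTUs sharing `noise_share` 0.5 % of reads, each far below
the 0.01 % threshold), and the prey OTUs (each item's reads split across
its `n_otus` sequence variants). Samples in which no item occurred are
re-drawn so $S$ stays as configured; the count is logged in the truth
object. Noise OTUs are assigned in fixed proportions to the four exclusion
paths (no-match hits, absent from the hit file, non-prey contaminants at
high identity, prey-like hits below 97 % identity), so every filter branch
is exercised by construction.

The default profile set has 13 genus-level items in two groups, with one
dominant item, a tail of occasional items, two items split over two OTUs
each and two faecal-only taxa per group; occupancy and share magnitudes
were chosen once to resemble a small stream predator's diet and are not
fitted to anything.

What the generator deliberately does not emulate: sequence-level error
(no reads, chimeras or clustering artefacts — it starts at the OTU table),
primer or amplification bias (reads are proportional to the latent
composition), biomass–read-count decoupling, PCR-replicate structure, and
taxonomic mis-assignment beyond the modelled identity values. Passing
recovery tests therefore shows the *pipeline arithmetic* is faithful to the
generating model, not that read counts faithfully represent diet in real
data.

Two statistical caveats the tests respect. First, expected %RRA equals the
profile mean shares only under full co-occurrence ($\psi \equiv 1$);
partial occupancy renormalises per-sample compositions over present items,
shifting shares upward. The concentration-recovery test (within 1
percentage point at $\alpha = 10^4$) therefore forces $\psi = 1$. Second,
%FOO equals $100\psi$ only when detection given presence is near-certain;
at low depth a present item with a tiny Dirichlet share can draw zero
reads, and with few items the empty-sample re-draw conditions incidence
upward. The occupancy tests use depths, concentrations and item counts
where both effects are negligible (e.g. $\ge 6$ items, so the all-empty
probability is < 1 %).

## Problem sizes and tolerances

The test suite runs metric-oracle comparisons on 5 × 6 tables (100
replicates against a naive double-loop reference, equal up to floating
summation order, 1e-12 relative), exact-vs-enumeration Mann–Whitney checks
over *all* rank configurations with $n_1, n_2 \le 5$, a 5,000-replicate
type-I-error calibration at 20/20, 100k-draw resampling checks of the
rarefaction closed form, and full simulate→filter→metrics recovery at
$S = 200$ with a 3-standard-error band on %FOO. Percentages in report
files are rounded half-up to one decimal; all returned objects keep full
precision.

## Known limitations

- One best hit per OTU is assumed; no lowest-common-ancestor logic over
  multiple hits.
- Secondary-predation removal rests entirely on the read-count threshold;
  a heavily consumed secondary prey above 0.01 % of reads would pass.
- The Costello cutline and tie rule are conventions; items near 50 % on
  either axis should be read qualitatively.
- Selectivity compares read shares with survey counts; both are imperfect
  proxies for consumed and available biomass.
- Ordination of diet against environmental covariates (e.g. canonical
  correspondence analysis) is out of scope; standard tools (`vegan::cca`)
  apply directly to the `prey_table` counts.
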