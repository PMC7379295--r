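---
title: "Methods: introgression mapping and mQTL scanning in backcross inbred lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: introgression mapping and mQTL scanning in backcross inbred lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(bilqtl)
library(dplyr)
```

## The population model

bilqtl analyses backcross inbred line (BIL) populations: an
interspecific F1 between a wild donor and a cultivated recurrent
parent is backcrossed to the recurrent parent (three times in the
design the defaults emulate), then selfed to near-homozygosity by
single-seed descent (ten generations by default).  Each finished line
carries a handful of wild-species chromosome segments — sparse
introgressions — in an otherwise uniform cultivated background.
Genotyping with a genome-anchored SNP panel gives, per line and
marker, one of four categorical calls:

* `A` — homozygous for the recurrent (cultivated) allele,
* `B` — homozygous for the donor (wild) allele,
* `H` — heterozygous,
* `U` — missing.

All physical coordinates are 1-based inclusive base pairs and segment
intervals are closed `[start, end]`.

## Segment calling

`call_segments()` turns one line's calls on one chromosome into donor
segments.  The rules, in order:

1. A segment is a maximal run of donor-informative calls (`B` or
   `H`).  A heterozygous call carries a wild allele, so it is
   donor-informative for segmentation; zygosity (`homozygous`,
   `heterozygous`, `mixed`) is recorded separately.  This choice makes
   a BIL-hybrid (every introgression heterozygous) yield the same
   segment coordinates as its homozygous parent line, which is what a
   hybrid cross preserves.
2. Missing calls are transparent: a `U` neither breaks nor extends a
   run.  Borders are computed only from informative calls.  Nothing
   in the data constrains what a missing call was, so transparency is
   the least-assumption rule.
3. An interior border is placed half-way between the outermost
   donor-informative marker of the run and the nearest flanking
   recurrent (`A`) marker, with integer floor.  The floor is
   scientifically irrelevant at Mbp scale but makes the border
   deterministic.
4. If a run reaches the first or last informative marker of the
   chromosome, the border extends to the chromosome tip (position 1,
   or the chromosome length).

`summarize_population()` reports how many lines carry at least one
segment, segments per line, and per-line summed lengths.  Lines with
no segment are counted but excluded from the per-line means and
medians — the statistics describe the introgression-bearing subset —
and genome coverage is the union of all segments across lines divided
by the summed chromosome lengths, so a segment shared by many lines
counts once.

## Mapping bins

`build_bins()` partitions each chromosome into bins: maximal runs of
adjacent markers whose genotype columns are identical across the
whole population, i.e. no line recombines between them.  Two
numerical choices matter:

* **Missing calls are wildcards.**  A `U` is compatible with any
  call.  Without this, sporadic missing data would shatter bins far
  beyond the population's true recombinational resolution.
* **Greedy left-to-right merging anchored on the running
  consensus.**  Under wildcards, compatibility is not transitive
  (`B,U` is compatible with `U,A`, but the pair `B`/`A` is not), so
  some deterministic tie-break is needed; the greedy scan merges a
  marker into the open bin iff its column is compatible with the
  consensus accumulated so far, then fills the consensus's missing
  entries from the new column.  Without missing data this reduces to
  splitting exactly where adjacent columns differ.

Bin physical intervals tile each chromosome completely (floor-midpoint
boundaries between bins, tips at the ends, consistent with the segment
border rule), so every QTL interval can be reported in physical
coordinates.

## The genetic map

`estimate_rf()` computes, for two bins, the fraction of lines —
among those scored in both — whose donor states differ, capped at
0.5.  This is a *line-level discordance* fraction, not a per-meiosis
recombination rate: each line's genome has passed through roughly a
dozen meioses, which multiplies the chance of a breakpoint between
two loci, while repeated backcrossing removes donor material, which
hides breakpoints.  The net scale is design- and coverage-dependent,
so the resulting centiMorgans are an internally consistent relative
scale along each chromosome rather than single-meiosis distances, and
the package deliberately applies no map-expansion correction by
default.  Map positions are therefore validated by rank agreement
(Spearman correlation of estimated versus true cumulative positions
within linkage groups, in simulation), not by absolute length.

`build_map()` chains adjacent-bin distances (Haldane by default,
`d = -50 ln(1 - 2r)`; Kosambi selectable) into cumulative positions
and starts a new linkage group wherever linkage information is
absent: the rf is undefined, it reaches 0.5, or — the common case in
a BIL population — no line's donor segment bridges the interval.
Adjacent bins always differ in at least one line (that is what makes
them separate bins), so an uncovered stretch of genome shows up not
as rf = 0 but as an interval with no bridging donor line; splitting
there reproduces the expected behaviour that incomplete donor
coverage yields more linkage groups than chromosomes, including
single-bin groups that exist only on the physical scale.

## QTL scanning

Replicates are collapsed to line means before scanning: the
biological replicates of a line are block replicates, not independent
segregants.  Genotype classes collapse to donor state — recurrent
(`A`) versus donor-carrying (`B`/`H`) — which scans a homozygous
population as `A` vs `B` (residual heterozygous calls grouped with the
donor class) and a hybrid population as `A` vs `H` with the same code
path.

**ANOVA scan.** `anova_scan()` fits, per trait and bin, the one-way
comparison of line means between classes and reports

\[ \mathrm{LOD} = \frac{n}{2}\log_{10}\frac{RSS_0}{RSS_1}, \]

with \(RSS_0\) the residual sum of squares of the grand-mean model.
Bins with fewer than two lines in either class are skipped (no
within-class variance estimate).

**Haley–Knott scan.** `hk_scan()` scans each linkage group on a cM
grid (bin positions plus a 1-cM default step).  At each position the
expected donor dosage of a line is the conditional expectation of a
two-state Markov chain given the nearest informative flanking bin
calls, with transition probabilities from the inverse map function
(no interference):

\[ P(g = 1 \mid g_L, g_R) =
   \frac{t(g_L, 1; r_1)\, t(1, g_R; r_2)}{t(g_L, g_R; r_{12})},
   \qquad t(a, b; r) = \begin{cases} 1-r & a = b \\ r & a \ne b.\end{cases} \]

Lines missing both flanks are excluded; a single available flank uses
the one-sided transition.  Line means are regressed on the dosage and
the LOD uses the same RSS ratio, so at a fully observed bin position
(dosage = the 0/1 call) the two scans coincide exactly.  A single-bin
linkage group has no flanking information and collapses to the ANOVA
on that bin.

**Significance.**  The default is a trait-wise permutation threshold:
line means are shuffled across lines, the maximum LOD over the scan is
recorded per permutation (1000 by default, at least 100), and the
\(1-\alpha\) quantile is the threshold (\(\alpha = 0.05\)).  Bonferroni
on the per-bin p-values is available as a cheaper conservative
fallback; its test count is the number of bins, not HK grid points,
because interior grid positions interpolate the same bin data.
Permutations are seeded and reproducible.

**Reporting.**  One QTL per trait and chromosome (linkage group for
HK) at the peak-LOD position, with the allelic effect reported as the
donor-class minus recurrent-class mean and its direction relative to
the wild allele, and a LOD support interval: the maximal contiguous
region around the peak within `lod_drop` (default 1.0) of the peak
LOD, mapped to physical coordinates.  `conserved_qtls()` clusters
same-trait QTLs on the same chromosome by transitive interval overlap
and flags clusters spanning two or more experiments — the package's
operational definition of a QTL conserved across harvests or
zygosity sets, chosen because interval overlap is the weakest claim
the support intervals license.

## Metabolite normalisation

`normalize_to_control()` divides each line's per-trait mean response
by the control (recurrent parent) line's mean, giving dimensionless
fold changes whose control value is exactly 1.  Zero raw responses
are treated as GC-MS non-detects (missing), not literal zeros, so the
log2 heat-map transform stays defined; traits whose control mean is
zero are dropped with a message.  `fold_range()` reports the global
min and max fold change over all cells excluding the control itself,
on line means — the population-wide variation span.

## The simulator

`simulate_population()` forward-simulates the breeding scheme.
Meiosis follows the Haldane model: crossovers per chromosome are
Poisson with mean equal to the length in Morgans, breakpoint
positions uniform on the cM axis, no interference, and a fair coin
for phase.  Selfing advances one offspring per generation
(single-seed descent).  There is no selection and no selfing
failure — nothing in the target design motivates either.  The
cM-to-bp conversion of emitted coordinates is linear per chromosome,
the simplest model that keeps physical and genetic truth consistent.

Defaults emulate the target study: 141 lines, 12 chromosomes of
100 cM / 65 Mbp, ~260 markers per chromosome, BC3 + 10 selfings,
three replicates, unit noise.  Under these defaults the expected
donor allele fraction is \((1/2)^4 = 6.25\%\) after the third
backcross and residual heterozygosity decays by half per selfing
generation; the realised mean segments-per-line falls in the 2–8
band characteristic of this design.  `simulate_phenotypes()` adds
per-replicate trait values, `baseline + effect x dosage + N(0,
noise_sd)`, with dosage the line's true donor-allele dosage at the
planted marker (0, 0.5, 1), plus an optional dominance deviation for
heterozygotes.  Effects are in trait units; at the default unit noise
they equal phenotypic SDs.

What the simulator does *not* emulate: marker ascertainment,
genotyping error beyond a uniform missing-call rate, crossover
interference, segregation distortion, non-additive (epistatic) trait
architecture, and non-Gaussian metabolite noise.  Tests passing on
simulated data therefore validate the estimators under the stated
breeding and meiosis model, not the full error structure of a real
GC-MS × SNP-chip experiment.

## Validation problem sizes

The package's tests validate each stage at sizes chosen to make the
statistical checks sharp while staying quick to run:

* segment calling against an independent brute-force oracle on all
  \(4^5\) five-marker vectors and \(10^4\) random 12-marker vectors;
* type-I error of the ANOVA scan on 1000 simulated null traits over a
  107-line population genotyped at 8 markers per chromosome — sparse
  markers spread the tests across many near-independent bins so the
  binomial reference for the rejection rate is meaningful;
* power and interval coverage for a planted 1-SD QTL at 107 lines and
  3 replicates over 100 simulation seeds, with detection defined as
  the trait's genome-wide peak landing within one bin of the true
  bin — the localisation criterion the bin resolution supports;
* Mendelian expectations (donor fraction \(1/16\) after BC3,
  heterozygosity halving per selfing) against 3-standard-error
  Monte-Carlo bands;
* Haley–Knott dosages against exhaustive gamete-path enumeration.

## A small worked example

```{r example}
cfg <- sim_config(
  n_lines = 60, n_chrom = 4, markers_per_chrom = 40, seed = 42,
  planted_qtls = tibble::tibble(trait_id = "phenylalanine",
                                marker_id = "chr03_m0020", effect = 1.5),
  noise_sd = 1)
sim <- simulate_bil_study(cfg, null_traits = "glucose")

segments <- call_introgressions(sim$genotypes, sim$marker_map, sim$chrom_lengths)
summarize_population(segments, nrow(sim$genotypes), sim$chrom_lengths)

bins <- build_bins(sim$genotypes, sim$marker_map, sim$chrom_lengths)
bin_summary(bins)

gmap <- build_map(bins)
glance(gmap)

scan <- hk_scan(sim$phenotypes, bins, gmap,
                scan_config(threshold_mode = "bonferroni"))
tidy(scan)
```

```{r plots, fig.width = 7, fig.height = 4}
plot_introgressions(segments, sim$chrom_lengths)
autoplot(scan, traits = "phenylalanine")
```

## Known limitations

* The rf estimator's cM scale is relative (see above); absolute map
  lengths depend on the breeding depth and donor coverage and should
  not be compared across designs.
* One QTL is reported per trait and chromosome (per linkage group for
  HK); two linked QTLs on one chromosome are merged into the stronger
  peak's interval.  Composite interval mapping and multi-QTL models
  are out of scope.
* No genotype error correction: a miscalled marker that creates a
  spurious singleton recombination will split a bin.  Quality control
  belongs upstream.
* Permutation thresholds are per-trait; no multiplicity adjustment is
  applied across traits.
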