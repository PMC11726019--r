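---
title: "Detecting chromothripsis from copy-number segments and SV junctions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting chromothripsis from copy-number segments and SV junctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromoshatter)
```

## The problem

Chromothripsis is a one-off catastrophe in which a chromosome (often after
mis-segregation into a micronucleus) is shattered into many fragments that
are re-ligated in essentially random order and orientation. Fragments lost
during re-ligation leave copy-number (CN) valleys, so the surviving genome
shows two hallmark signals:

* **oscillating copy number** — consecutive segments alternating between
  two integer CN states (retained vs lost material), and
* **clustered rearrangements** — many structural-variant (SV) junctions
  whose spans interleave and whose orientations look random.

When part of the shattered material circularizes, the resulting
extrachromosomal DNA (ecDNA, cytogenetically "double minutes") is amplified
to tens or hundreds of copies and appears as extreme CN spikes sitting
*inside* the oscillating region. In the tumor type that motivated this
package — *RB1*/*TP53*-proficient small cell lung carcinoma arising in
never-smokers — this mechanism recurrently amplifies cyclin-pathway
oncogenes (*CCND1*, *CCND2*/*CDK4*/*MDM2*) to >100 copies.

`chromoshatter` fixes the two detection procedures used in that setting as
deterministic, auditable rules: a targeted-panel (tNGS) caller that sees
only CN segments, and a WGS caller that combines SV clusters, oscillating
CN and three statistical tests. A seeded generative simulator provides
ground truth so both callers can be benchmarked without patient data.

## The oscillation primitive

Both callers are built on *maximal two-state alternating runs*. Within one
chromosome's sorted segment list, a run is a stretch whose total CN
strictly alternates between two values $\{s_1, s_2\}$. "Predominantly two
states" is formalized as an allowed number $d$ of interior *deviations*
(default $d = 0$): a deviant segment has CN outside the two states, is
bridged without terminating the run, and is excluded from the run-length
count. Two further choices make the decomposition deterministic:

* when maximal runs overlap, disjoint runs are selected longest-first,
  ties toward the leftmost run;
* segments whose CN exceeds `amp_baseline_factor` (default 5) times the
  length-weighted modal CN of the chromosome are *always* bridgeable —
  ecDNA spikes sit inside chromothriptic regions and must not break the
  alternation they interrupt.

Each run is annotated with its size ratio (longest/shortest segment,
1-based inclusive lengths), the minimum segment cellular fraction, and
*track concordance*: at every internal boundary the sign of the log-ratio
change must match the sign of the integer-CN change, and, where allelic
log-odds and minor CN are present, the change in $|\mathrm{logOR}|$ must
match the sign of the change in $\mathrm{tCN} - 2\,\mathrm{minorCN}$. The
log-odds *magnitude* is compared because its sign is phase-arbitrary in
allele-specific CN output. Boundaries where the integer track does not
change carry no sign constraint and are skipped.

## The targeted-panel rule

A chromosome is `suggestive_positive` when it contains **at least five
consecutive oscillating, uniformly sized segments, each with cellular
fraction ≥ 50%, with concordant tracks**. Two readings of "uniformly
sized" are possible: applied to the whole maximal run, or applied to the
five-plus consecutive segments actually being called. The rule is stated
for the consecutive segments, and the package implements it that way: a
window search inside each run accepts the longest stretch of
≥ `min_panel_run` consecutive segments whose internal size ratio is at
most `uniformity_max_ratio` (default 10). A long oscillation containing
one disproportionate segment therefore still calls on its uniform
stretch, which also preserves the monotonicity property that relaxing any
threshold can only add positives.

The run-length threshold of five exists to avoid over-calling when two
independent gene-level amplifications or deletions happen to sit close
together; the size-ratio bound of 10 quantifies the otherwise qualitative
"uniformly sized" in a scale-free, configurable way.

## The WGS criteria

Per chromosome, candidate regions are maximal clusters of
intrachromosomal breakends with gaps ≤ 10 Mb (extended to cover member
junctions), plus always the whole chromosome — whole-chromosome
involvement is frequent in this disease setting. For each region the
caller computes:

* the **interleaved SV count**: junctions $a, b$ interleave when
  $a_1 < b_1 < a_2 < b_2$ (overlap without nesting); the count is the
  largest connected component of the interleave graph, so isolated
  junctions never count;
* the longest two-state oscillation run;
* three tests, whose exact forms the source procedure names but does not
  print; the package uses the standard published readings:
  * *fragment joins*: equal-proportion multinomial goodness of fit over
    the four orientation classes (χ² on 3 df for ≥ 20 junctions, exact
    enumeration below); **passes when not rejected** ($p \ge 0.05$) —
    random ligation is the chromothriptic signature;
  * *breakpoint exponentiality*: one-sample Kolmogorov–Smirnov against
    uniformity of breakend positions on the region (equivalently,
    exponential spacings); **passes when not rejected**;
  * *chromosomal enrichment*: one-sided binomial tail
    $P[X \ge n_\mathrm{chrom}]$,
    $X \sim \mathrm{Bin}(n_\mathrm{genome}, L_\mathrm{chrom}/L_\mathrm{genome})$;
    **passes when rejected** toward excess ($p \le 0.05$).

A region is chromothriptic when any of these hold (intra = interleaved
intrachromosomal count, inter = interchromosomal count, osc = oscillation
run length):

| criterion | rule |
|---|---|
| i | intra ≥ 6, osc ≥ 7, joins, and (enrichment or exponentiality) |
| ii | intra ≥ 3 and inter ≥ 4, osc ≥ 7, and joins |
| iii | intra ≥ 40 and joins |
| iv | total SVs ≥ 100 and osc ≥ 5 |
| v | intra ≥ 6, osc in 4–6, joins, and (enrichment or exponentiality) |

Any of i–iv gives verdict `positive`; v alone gives `low_density`;
otherwise `negative`. A missing p-value (e.g. fewer than five distinct
breakends for the KS test) counts as a failed test — conservative by
construction. The per-chromosome verdict is the best region verdict.

One consequence of the enrichment test deserves emphasis: a lone
chromosome analyzed in isolation is its own genome, making enrichment
undetectable. `call_wgs()` therefore takes a `genome_length` (default the
GRCh37 autosomal total), so a single rearranged chromosome is assessed
against a whole-genome background in which it is the only rearranged one.

## Cancer cell fraction

The expected variant allele frequency of a mutation present in a fraction
CCF of tumor cells is

$$\mathrm{VAF} = \frac{p \cdot \mathrm{CCF}}
  {\mathrm{CN}_\mathrm{diploid}\,(1-p) + \mathrm{CN}_\mathrm{mut}\,p}$$

with purity $p$. The estimator evaluates the binomial likelihood of the
observed alt/total read counts on a CCF grid over $[0, 1]$ (step 0.01),
normalizes with a uniform prior (none being stated by the source
procedure), and reports the grid argmax with a central 95% credible
interval. CCF ≥ 0.8 is classed `clonal_or_near_clonal`. Two deliberate
choices: the formula is implemented verbatim — mutant-copy multiplicity is
not modeled in the numerator, and callers who know it should fold it into
`cn_mut`; and estimates whose raw VAF inversion exceeds 1 are clamped at
1 and flagged rather than extrapolated, since CCF is a fraction.

## The simulator

`simulate_chromothripsis()` draws $K$ breakpoints uniformly on the region,
shatters **one homolog** of a diploid chromosome (giving the canonical
\{1, 2\} oscillation), retains each fragment with probability $r$,
permutes and randomly flips the retained fragments, and emits a ligation
junction per adjacent pair, with strand pairs determined by the chosen
orientations — under random ligation the four orientation classes are
uniform by construction. An optional subset of retained fragments is
removed from the derivative, circularized (circular junction count equals
fragment count) and amplified to a fixed $A$ copies, so ecDNA fragments sit
at total CN $2 - 1 + A$ and a duplicated oncogene fragment at
$2 - 1 + 2A$; $A$ is a config constant, not a birth–death process,
because the detectors only need the plateau. `simulate_control()` scatters
a few isolated deletions/tandem duplications and verifies by construction
that no four-segment alternation arises.

Default conditions were chosen once as the realistic regime for this
disease setting and are not tuned: a chr11-sized chromosome (135 Mb,
the most recurrently shattered chromosome here), $K = 30$, $r = 0.5$,
purity 0.8, log-ratio noise sd 0.1, ecDNA $A = 60$ (a duplicated fragment
then reaches 121 copies, the >100-copy regime reported for ecDNA-amplified
*CCND1*), three control events, and a 505-target panel matching the
largest clinical panel version.

Renderers convert truth to caller input. `render_wgs()` maps CN to
log-ratio via $\log_2\!\big((p\,\mathrm{cn} + 2(1-p))/2\big)$ plus noise
and jitters junction breakends by ≤ 100 bp (detectors use midpoints, so
calls are jitter-invariant). `render_panel()` observes CN only where
panel targets intersect the profile, merges consecutive equal-CN targets
into one segment spanning first to last target, and drops junctions.

What the simulator does **not** emulate: FFPE artifacts and wavy
log-ratio bias, segmentation errors (integer CN is rendered exactly),
subclonal chromothripsis (all somatic segments have cellular fraction 1),
whole-genome-doubled baselines (configurable but not default),
breakage–fusion–bridge cycles, chromoplexy, and multi-chromosome
co-shattering. Passing benchmarks therefore demonstrate correctness of
the rules under the generative model, not clinical performance.

A consequence worth knowing: at 505 gene-footprint targets the simulated
panel carries ~20–25 markers on a 135-Mb chromosome, far fewer effective
CN probes than the real assay (which also tiles genome-wide SNPs), and
single-target segments are 10–100 kb against multi-megabase neighbors. The
size-uniformity filter therefore removes most panel-rendered oscillations,
and the simulated panel caller's sensitivity sits well below the WGS
caller's — the qualitative panel ≤ WGS ordering with panel specificity
≈ 1, not a quantitative reproduction of the published concordance
percentages, which were computed on patient data.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive internally; BEDPE (0-based half-open)
  is converted at the boundary, breakends collapsing to interval
  midpoints rounded down. `"chr"` prefixes are stripped.
* Segment tables must be proper segmentations: overlap on a chromosome is
  an error, not silently resolved.
* Missing `cell_fraction` becomes 1.0 with a disclosure flag carried into
  the call object — older segment tables omit it, and the CCF filter then
  never rejects.
* The exact multinomial p-value sums the probability of all outcomes at
  most as probable as the observed counts (with a $10^{-9}$ tolerance on
  the comparison, so ties at equal probability are included).
* The length-weighted CN baseline breaks ties toward the lower state.
* `estimate_ccf` interval endpoints are the grid's central 95% mass; the
  argmax is clamped into the interval in the rare boundary case.
* All simulator randomness flows through seeds recorded in configs and
  manifests; benchmarks derive per-replicate seeds from one master seed.

## Benchmark sizes

The shipped tests and the acceptance script use 200 paired
positive/control genomes for operating characteristics, 1000 Monte-Carlo
replicates per test-calibration check, 10⁴ random tuples against the
criteria truth-table oracle, and 1000 random junction sets against the
interleave oracle — sizes at which the binomial uncertainty on the
reported rates is a few percent, chosen as the package's own benchmark
design.

## A worked example

```{r example, eval = FALSE}
cfg <- shatter_config(seed = 42)
truth <- simulate_chromothripsis(cfg)
wgs <- render_wgs(truth, cfg)
calls <- call_wgs(wgs$segments, wgs$junctions,
                  chrom_lengths = c("11" = cfg$chrom_length))
print(calls)
concordance_vs_truth(calls, c("11" = TRUE))
```

## Known limitations

The callers consume segmentations and junction calls; they do not
re-segment noisy data, reconcile discordant CN fits of the same sample, or
parse SV VCFs beyond BEDPE. Verdicts are per chromosome (region
coordinates are reported, sub-chromosomal verdicts are not separate
calls). The three statistical tests are declared substitutes with matching
pass semantics for an upstream procedure whose exact functional forms are
not printed; their null calibration is verified by Monte-Carlo in the test
suite.
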