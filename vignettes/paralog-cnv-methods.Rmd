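---
title: "Resolving copy-number variation of a two-unit segmental duplication"
author: "paralogCNV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving copy-number variation of a two-unit segmental duplication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paralogCNV)
```

## The problem

Tandem segmental duplications such as the low-affinity Fc-gamma receptor
cluster consist of two long, highly similar repeat units (here called
paralogs A and B, ~98.5% identical). Nonallelic homologous recombination
(NAHR) between the units produces reciprocal products: a deletion allele
with a single chimeric unit (A-derived sequence up to the crossover,
B-derived beyond it) and a duplication allele with three units whose
middle unit is the reciprocal chimera. Which gene is lost depends on
where the crossover falls: a crossover in the proximal hotspot removes
the A-side gene, one in the distal hotspot removes the B-side gene.
Gene conversion additionally copies tracts of one paralog onto the
other without changing copy number.

The only sequence-level handle on any of this is the catalog of paralog
sequence variants (PSVs): the fixed positions at which the two units
differ. A clone contig walking across a chimeric unit changes from
matching the A base at every PSV to matching the B base; the crossover
lies between the last A-like and the first B-like PSV. Array-CGH probes
hybridize to both units, more strongly to the one they were designed
against, so probe intensities respond to both total copy number and the
paralog identity of the retained units.

`paralogCNV` implements this entire chain as testable code on synthetic
data with known truth: locus and cohort simulation, contig-to-paralog
assignment, PSV switch detection, copy-number calling, deletion-type
classification, and exact case/control association.

## What the simulator emulates

`simulate_paralog_pair()` draws a random unit sequence and plants
`round(divergence * unit_length)` PSVs uniformly without replacement; the
defaults (16 kb, 1.5% divergence, 240 PSVs) mirror the distal analysis
window of the real locus at its published identity. Real PSVs cluster —
there are PSV deserts in which breakpoints cannot be refined — which the
generator reproduces only if an optional reduced-density interval is
requested (`psv_desert`); it is off by default, so synthetic breakpoint
intervals are uniformly narrow in a way real ones are not.

`build_allele()` composes a haplotype from at most one NAHR event plus
non-overlapping conversion tracts. The deletion chimera is A-source on
`[1, b]` and B-source beyond; the duplication's middle unit is the
reciprocal (B then A). Both conventions are fixed by construction and
exercised by the reciprocality tests.

`simulate_acgh()` uses a deliberately small response model. For probe
`p` at position `x` designed against paralog `T`, with `m` units whose
source at `x` is `T` and `u` units sourced from the other paralog:

    value = log2(max(m + gamma * u, floor) / (2 + 2 * gamma))
            + cohort_offset + Normal(0, noise_sd)

`gamma` is the cross-hybridization weight: at `gamma = 1` a probe cannot
tell the paralogs apart and A-type and B-type deletions become
indistinguishable (an invariant asserted in the tests); at `gamma = 0`
probes are perfectly paralog-specific. The defaults `gamma = 0.3`,
`noise_sd = 0.15` define the study conditions used across the test
suite and the acceptance script: they give cluster separations
comparable to good-quality real aCGH histograms — distinct loss /
normal / gain modes with visible overlap — rather than idealized
point clouds. The `floor` (0.05 effective copies) only guards the
logarithm for homozygous deletions under full probe specificity.

The default probe panel has 33 probes, 20 of which lie strictly between
the two breakpoint hotspots. That region is the deletion-determining
region: on a B-type deletion chromosome the retained chimera is
A-source there, on an A-type deletion chromosome it is B-source, so
only those probes carry type information. The 13 flanking probes see
identical paralog content for both deletion types.

What the simulator does **not** emulate: gapped or structural
sequencing errors (contig errors are i.i.d. substitutions), probe GC
or wave artifacts, batch structure beyond an additive per-cohort shift,
technical duplicates, and PSV clustering as noted above. Passing tests
therefore demonstrate correctness of the analysis logic under the
stated statistical model, not robustness to every failure mode of real
arrays.

## Breakpoint and conversion mapping

`psv_profile()` reduces a placed contig to ordered PSV states (A, B, or
`other` for bases matching neither paralog — sequencing errors land
here and are thereby ignored). `detect_switches()` masks discordant
runs shorter than `min_run` (default 2, the analog of blacking out
single ambiguous PSVs in breakpoint figures) and reports each boundary
between surviving runs as an open interval from the last informative
PSV of one state to the first of the other: the true crossover lies
strictly inside. Masking is an exact dynamic program that keeps the
maximum number of PSVs subject to the run-length constraint; a greedy
"drop short runs and iterate" rule was found by the enumeration oracle
in the tests to over-mask configurations such as `A B A A B B`, where
dropping only the lone `B` suffices.

`classify_events()` reads the switch sequence: an interior tract that
returns to its flanking state is a gene conversion (reported inclusive
of its inner PSVs, with donor and acceptor); an unpaired switch is an
NAHR breakpoint. Interior tracts are *always* called conversions here;
a long tract could equally be a double crossover, and that alternative
reading is deliberately not a separate call class. `compare_alleles()`
declares two mapped deletions consistent with identity-by-descent only
when both the breakpoint interval and every shared informative flanking
PSV state agree — the logic behind distinguishing recurrent NAHR from a
shared ancestral event. `divergence_separation()` provides the
pairwise-difference stand-in for a phylogenetic median network: the
ratio of mean between-label to mean within-label Hamming distance,
with values above 1 indicating that A- and B-derived sequences form
separable clusters.

## Copy-number calling and deletion typing

`pc_scores()` computes PC1 of the column-centred intensity matrix with
equal probe weighting. The sign is fixed so PC1 correlates negatively
with the per-sample mean log2 ratio: deletions sit at high PC1, which
is the orientation under which a high cutoff isolates homozygous
deletions. `fit_gaussian_mixture()` is an EM fit of a univariate
mixture whose component means share an additive per-cohort offset
(reference cohort fixed at zero), absorbing between-cohort assay bias
without letting each cohort move the class boundaries independently.
Numerical choices: k-means initialization with 10 restarts, convergence
at a log-likelihood gain below 1e-8, at most 500 iterations, a standard
deviation floor of 1e-4 against component collapse, unequal variances
by default with an `equal_var` switch. The log-likelihood trace is
retained and its monotonicity asserted on every fit in the test suite.

`call_copy_number()` requires three components — loss, normal, gain by
decreasing mean on the oriented PC1 scale — because that is the model
the reanalysis it reproduces chose for cohorts of varying data quality.
A known limitation follows: if the array noise is made unrealistically
small, homozygous deletions form their own sharply separated cluster
and the three-component maximum-likelihood fit prefers to spend a
component on it, scrambling the rank-based class mapping. At the
default noise level the mapping is exact (the truth-versus-call
confusion table in the pipeline report is diagonal).

Deletion typing then proceeds in the published order: homozygous
deletions are excluded *before* the second PCA, since with no retained
chimeric unit they carry no type signal. The published cutoff (PC1 >
3.8, strictly) is data-scale-specific, so it is a config value; the
`"auto"` mode fits a two-component mixture to the deletion carriers'
scores and places the cutoff at the equal-posterior valley — but only
accepts the split when the component separation is at least 0.75 of
the loss-to-normal spacing from the genome-wide fit. The guard matters:
the A-versus-B contrast also projects onto full-panel PC1, and without
it the auto mode can mistake the two heterozygote types for a
het/hom split when homozygotes are rare or absent.

`classify_deletion_type()` recomputes PC1 on the deletion heterozygotes
restricted to the 20 discriminating probes (all such samples share one
total copy number, so the leading variation is paralog identity) and
splits them with a two-component mixture using case/control status as
the additive factor. The component holding more samples is labelled the
B-type deletion — the common type at this locus — with the minority
component the A type; an optional anchor panel of known-type samples
overrides the majority rule, which is how an orthogonal-assay
validation would be wired in. If the components sit closer than one
pooled standard deviation (as at `gamma = 1`), every call is flagged
low-confidence and a warning is raised.

## Association

Carrier counts go into a 2-by-2 table and out come the sample
(cross-product) odds ratio, the conditional maximum-likelihood odds
ratio, the two-sided exact p-value under the point-probability rule,
and the exact conditional confidence interval — the conventions of the
standard R implementation, against which the tests run a full
hypergeometric enumeration and a noncentral-hypergeometric grid
inversion on small tables. Two wrinkles surfaced by those oracles are
worth recording: the two-sided point-probability p-value is not
strictly monotone in the carrier count (discreteness can produce
sub-percent upticks), and the reference root finder carries about 1%
relative error on extreme interval bounds. A single primary hypothesis
(B-deletion carriage) is tested, so no multiplicity correction is
applied; the secondary A-deletion table is supported as a second,
explicitly secondary run.

## Study conditions and problem sizes

The generator defaults are the package's study conditions and are not
tuned per test: 16-kb units at 1.5% divergence; 33/20 probes;
`gamma = 0.3`, `noise_sd = 0.15`; control B-deletion allele frequency
0.0126 (carrier frequency ~2.5%, the scale of the published control
carriage), A-deletions at 0.005 and duplications at 0.01; case/control
arms of 2,000 with carrier enrichment at odds ratio 1.6. The
validation cohort is 400 samples with 24 B-type and 10 A-type
heterozygous carriers (15 of them, 2:1 B:A, forming the held-out
known-type panel), 4 homozygous deletions and 8 duplications. The
end-to-end odds-ratio recovery check uses 50 pipeline replicates at
full cohort size; property suites use 100 simulated alleles for
breakpoint containment and margins up to 12 for exact-test
enumeration.

## Coordinates and serialization

All in-memory coordinates are 1-based inclusive, the R/Bioconductor
convention (`interval_length(a, b) = b - a + 1`, so the published tract
coordinates reproduce the published kb figures directly). BED output is
0-based half-open as the format requires; the conversion lives in one
audited function pair (`write_bed()` / `read_bed()`) backed by
rtracklayer. Intensity matrices round-trip through TSV at 17
significant digits, i.e. exactly.

## Known limitations

* The three-component calling model is mis-specified when homozygous
  deletions form a well-separated fifth cluster (see above); this is a
  property of the published model choice, faithfully reproduced.
* The majority-component labelling rule assumes B-type deletions
  outnumber A-type among carriers (true at this locus); cohorts
  violating it need the anchor panel.
* Contig placement uses the simulator's truth coordinates by default
  (a PSV-anchored exact-match placement would be needed for label-free
  use with real contigs); gapped alignment is out of scope.
* The quantile normalization of real array data is taken as given; the
  simulator produces centred log-ratios directly.
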