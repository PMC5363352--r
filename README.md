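# paralogCNV

Copy-number variation at long tandem segmental duplications — the
low-affinity Fc-gamma receptor cluster being the motivating example — is
hard to genotype because the two repeat units (paralogs A and B,
~98.5% identical) confuse both sequencing reads and array probes.
Nonallelic homologous recombination (NAHR) between the units creates
reciprocal deletion and duplication alleles whose chimeric units switch
from A-derived to B-derived sequence at the crossover, and the position
of that crossover decides *which* gene is lost. Generic copy-number
callers that ignore paralog identity cannot distinguish an A-gene
deletion from a B-gene deletion — and only one of them may carry a
disease association.

`paralogCNV` implements the full resolution strategy as tested R code
on synthetic data with known truth, for statistical geneticists and
method developers working on segmental-duplication CNV:

* **Locus and cohort simulation** — paralog pairs with a paralog
  sequence variant (PSV) catalog, NAHR deletion/duplication and
  gene-conversion alleles, fosmid-like contigs, and aCGH log2-ratio
  matrices in which probe response depends on copy number *and* paralog
  identity through a cross-hybridization weight γ:
  `value = log2(max(m + γu, floor) / (2 + 2γ)) + cohort offset + noise`,
  with `m` matched and `u` mismatched unit counts at the probe.
* **Contig assignment and breakpoint mapping** — assignment to the
  paralog of highest sequence identity (400-bp span filter, maximal
  non-overlapping alignment selection by weighted interval scheduling),
  PSV-state profiles, switch detection with short-run masking,
  gene-conversion versus breakpoint classification, hotspot labelling,
  and identity-by-descent comparison of mapped alleles.
* **Copy-number calling** — oriented PC1 of the probe matrix fed to a
  three-component Gaussian mixture (loss/normal/gain) with an additive
  per-cohort offset, fitted by EM with restarts; posterior-based calls.
* **Deletion typing** — exclusion of homozygous deletions by PC1
  cutoff, then PC1 on the 20 probes of the deletion-determining region
  and a two-component status-adjusted mixture separating A-type from
  B-type heterozygous deletions.
* **Association** — exact 2×2 statistics: sample and conditional-MLE
  odds ratios, two-sided Fisher p, exact conditional confidence
  interval.

## Worked example

```r
library(paralogCNV)

## exact association statistics from a carrier table
associate(contingency_table(79, 82, 1903, 3189))
#> association: OR 1.61 (CMLE 1.61), 95% CI 1.16-2.24, p = 0.00292

## tract lengths from 1-based inclusive coordinates
round(interval_length(159806619, 159815757) / 1000, 1)  # 9.1 (kb)
round(interval_length(159888397, 159890836) / 1000, 1)  # 2.4 (kb)

## simulate a 400-sample validation cohort and type its deletions
vr <- validation_concordance(seed = 1, gamma = 0.3, noise_sd = 0.15)
vr$concordance_pct  # 100
head(vr$calls, 4)
#>   sample_id true_label       call
#> 1     v0238 B_deletion B_deletion
#> 2     v0249 B_deletion B_deletion
#> 3     v0101 B_deletion B_deletion
#> 4     v0328 B_deletion B_deletion
```

The association line reads: carriers of the B-type deletion are 1.61
times more likely (on the odds scale) among cases than controls, with
an exact 95% interval excluding 1 and a two-sided exact p of 0.0029.
The validation run simulates an aCGH cohort containing heterozygous
deletion carriers of known type, runs copy-number calling, homozygote
exclusion and the two-component type classifier, and reports percent
agreement on the 15 held-out known-type carriers.

An end-to-end run (simulation → calling → typing → association, with
FASTA/BED/TSV/JSON outputs) is:

```r
report <- run_pipeline(pipeline_config(seed = 1), outdir = "run1")
report$association$or_sample
```

A thin command-line wrapper is installed at
`inst/scripts/run_pipeline.R`.

## Vignette

`vignettes/paralog-cnv-methods.Rmd` documents the response model and
its assumptions, the EM and PCA conventions, the masking dynamic
program for PSV switch detection, the guard on the automatic
homozygote threshold, numerical tolerances, and known limitations.
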