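# atcgeomap

Geomapping of amplification-associated transcription coupling (ATC) regions
and dense ERα binding hubs in breast-tumor genomes, with
rearrangement-enrichment and survival analysis.

## What it does, and for whom

In luminal breast cancer, amplified chromosome segments often carry genes
whose expression tracks their copy number across tumors ("transcription
coupling"), and those segments are hotspots of clustered rearrangements
whose partner breakpoints concentrate near dense estrogen-receptor-α
binding regions. This package is for computational biologists who want to
run that analysis end to end on cohort-style inputs (expression matrix,
100-kb segment copy number, sample metadata, BreakDancer/BEDPE
rearrangement calls, ChIP-seq peak BEDs):

* **ATC screen** — per gene, Pearson *r* between log2(x+1) expression and
  the copy number of the 100-kb segment containing the gene midpoint;
  genes with *r* ≥ 0.6 are ATC loci.
* **Region aggregation** — exact optimal univariate k-means (dynamic
  programming, global WCSS minimum) over gene positions, k selected by a
  Gaussian-mixture BIC; candidate regions are kept when they hold ≥ 15
  genes, span < 20 Mb, and exceed a per-bp kernel density of 1e-8.
* **ERα hubs** — base-pair three-way intersection of three peak sets, then
  the same 1-D clustering over common-site midpoints.
* **Rearrangement links** — confidence filter (score > 80), inter/intra
  classification, and link counts from bait regions to 1-Mb partner bins
  and to hubs; Mann–Whitney U comparisons between sample groups.
* **Concordance & survival** — cumulative z-score signatures, gene–gene
  correlation profiles in genomic order, median-split log-rank test.

Because the cohorts this analysis targets are controlled-access, the
package includes a synthetic-cohort generator (`sim_config()`,
`simulate_cohort()`) that plants dosage-coupled regions, hub-targeted
breakpoints, and score-linked survival, giving every stage a ground truth.
See the methods vignette (`vignettes/atc-geomapping.Rmd`) for the model and
every default.

## Worked example

The analysis is organised as numbered drivers that write under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R 1   # seed 1
Rscript analysis/02_map_atc_regions.R
Rscript analysis/03_call_er_hubs.R
Rscript analysis/04_rearrangement_enrichment.R
Rscript analysis/05_concordance_survival.R
```

With seed 1 this prints (abridged):

```
Simulated cohort (seed 1):
  samples:           200
  genes:            1000 (90 dosage-coupled)
  ER-positive:       141
  rearrangements:    3421

ATC screen: 74 genes at r >= 0.6
ATC regions called:
  region_id chrom    start      end gene_count  span_mb
1       R01  chr1 20522460 27919026         25 7.396566
2       R02  chr1 60065100 67879854         27 7.814754
3       R03  chr2 40593207 47902802         22 7.309595
  planted chr1:20000000-28000000 -> best boundary Jaccard 0.925
  planted chr1:60000000-68000000 -> best boundary Jaccard 0.977
  planted chr2:40000000-48000000 -> best boundary Jaccard 0.914

common sites: 64
hubs called: 4 (mean hub length: 1.80 Mb)

events: 3421 read, 2778 pass score > 80 (81.2%)
ER+ vs ER- filtered events/sample: U = 206.5, p = 2.96e-26
ATC-prone vs ATC-less events/sample: U = 52.0, p = 0.0119

correlation profiles over 74 ATC genes (top-10 samples)
  expression r: within-region 0.30, cross-region -0.08
  copy-number r: within-region 1.00, cross-region -0.20
log-rank high vs low cumulative score: chisq = 14.77, p = 0.0001
```

Reading: the three planted dosage-coupled regions are recovered (and only
those three) with boundary Jaccard ≥ 0.91; 74 of the 90 planted genes pass
the r ≥ 0.6 screen at this noise level, which is the expected retention
when the true per-gene correlation (~0.63) sits near the threshold. The
three-way peak intersection recovers exactly the 4 × 16 planted common
sites and the four ~2-Mb hubs. ER-positive samples carry roughly three
times more filtered rearrangements than ER-negative ones, ATC-prone
samples more than ATC-less ones, and samples with high cumulative ATC
scores have significantly shorter overall survival — each reflecting the
planted effect sizes.

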