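# pgxkit

Offline pharmacogenomics annotation for individual genomes and cohorts.

Genetic variation changes how people respond to drugs: the warfarin
maintenance dose depends on `VKORC1` and `CYP2C9` genotypes, clopidogrel is
less effective in `CYP2C19` poor metabolizers, and common SNPs modulate
cisplatin toxicity. `pgxkit` matches observed diploid genotypes against a
curated knowledge base of variant–drug associations and reports, per person
and per population, which drug responses (efficacy, dosage, toxicity) are
expected to **increase** or **decrease**, at which PharmGKB-style evidence
tier (`1A` strongest … `4` weakest), and whether the drug carries an FDA
pharmacogenomic biomarker label.

It is aimed at bioinformaticians who have genotypes in hand — a multi-sample
VCF v4.2 or a consumer-array export (23andMe, Affymetrix, deCODEme, Family
Tree DNA) — and want desk-scale, reproducible annotation with no server, no
database and no network access.

## The method in brief

A knowledge base `K` is a set of rows `(rsid, genotype, drug, aspect,
direction, evidence, fda)`, with `genotype` a canonical diploid string
(uppercase, alleles sorted, e.g. `AG`). An observed call `(s, rsid, g)` for
sample `s` matches row `k` iff `rsid` and the canonical genotype are exactly
equal — a KB row for `AG` never matches an observed `GG`, because phenotypes
are annotated per genotype, not per allele. All matching is phase-blind:
VCF `0|1`, `1/0` and an array `GA` all canonicalize to `AG`.

On top of the per-sample match sets, the package computes:

* sample × gene and sample × drug count tables (distinct matched rsids);
* per-population genotype and allele frequency distributions, with missing
  calls tracked separately and excluded from the denominators;
* population burden summaries — mean ± SD (n−1) of matched SNPs per
  individual, for all matches and for the FDA-labeled subset;
* an individual-vs-population divergence report (loci where the person's
  genotype is carried by < 50 % of their population);
* a tri-partite directed network **gene → drug → drug category**, exportable
  to GraphML/JSON/DOT;
* navigable individual reports (HTML or Markdown) with FDA highlighting.

A built-in simulator draws cohorts under Hardy–Weinberg proportions
(p², 2pq, q²) at the KB loci with per-population allele frequencies and
carries the exact expected results alongside, so every claim the package
makes is testable offline.

## Worked example

```r
library(pgxkit)

calls <- tibble::tibble(
  sample_id = "subject01",
  rsid     = c("rs1042522", "rs11615", "rs9923231"),
  chrom    = c("17", "19", "16"),
  pos      = c(7579472L, 45923653L, 31107689L),
  genotype = c("CC", "GG", "AA"),
  source   = "23andme"
)
m <- annotate_sample(calls, mini_kb())
m[, c("rsid", "gene", "genotype", "drug", "aspect", "direction",
      "evidence", "fda_labeled")]
#> # A tibble: 3 × 8
#>   rsid      gene      genotype drug      aspect   direction evidence fda_labeled
#>   <chr>     <chr>     <chr>    <chr>     <chr>    <chr>     <chr>    <lgl>
#> 1 rs1042522 GENE_CIS1 CC       cisplatin toxicity decrease  2A       FALSE
#> 2 rs11615   GENE_CIS3 GG       cisplatin toxicity decrease  2A       FALSE
#> 3 rs9923231 VKORC1    AA       warfarin  dosage   decrease  1A       TRUE
```

The two cisplatin rows say this person carries the homozygous genotypes
(`rs1042522` CC, `rs11615` GG) associated with *reduced* cisplatin toxicity,
at evidence tier 2A; the VKORC1 row says they need a *lower* warfarin dose,
at the strongest tier, for a drug whose FDA label references genotyping.

```r
glance(build_report(m, mini_kb()))
#> # A tibble: 1 × 4
#>   sample_id n_drugs n_matches n_fda_drugs
#> 1 subject01       2         3           1
```

Cohort analysis on a simulated five-population cohort (100 samples each):

```r
sim <- simulate_cohort(mini_kb(), default_population_specs(mini_kb(), n = 100),
                       seed = 7)
group_summary(annotate_cohort(sim$calls, mini_kb()), sim$groups)
#> # A tibble: 5 × 6
#>   population     n mean_all sd_all mean_fda sd_fda
#> 1 AFR          100     2.22  0.799     0.08  0.273
#> 2 AMR          100     2.61  1.17      0.46  0.658
#> 3 EAS          100     3.34  1.13      0.98  0.635
#> 4 EUR          100     2.51  1.16      0.49  0.628
#> 5 SAS          100     2.34  1.09      0.43  0.624
```

Each row is one population: the mean and SD of drug-response SNPs matched
per individual, overall (`mean_all`) and counting only FDA-biomarker-labeled
associations (`mean_fda`, always ≤ `mean_all`).

A command-line front end wraps the same functions
(`inst/scripts/pgxkit`): `kb-validate`, `parse`, `annotate`, `report`,
`network`, `group`, `simulate` and `run --config pipeline.yaml`.

## Limitations

The package annotates biallelic SNVs by rsID and exact genotype; star-allele
(diplotype) calling, indels/CNVs, imputation and genome-build liftover are
out of scope, as is any quantitative dosing algorithm. The built-in
`mini_kb()` is a small curated fixture for demonstration and testing — for
real analyses supply your own knowledge-base export in the two-file TSV
schema (see `?read_kb`).
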