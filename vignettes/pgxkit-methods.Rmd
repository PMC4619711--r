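---
title: "pgxkit: methods, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pgxkit: methods, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxkit)
```

## The annotation model

`pgxkit` treats pharmacogenomic annotation as an exact join between two
relations. The knowledge base is a set of rows

> (rsid, gene, genotype, drug, aspect, direction, evidence, fda_labeled)

at the finest joinable granularity: one row per variant–genotype–drug–aspect
association, so a SNP affecting three drugs occupies three rows and a SNP
whose heterozygote and homozygote have different consequences occupies two.
An observed call is `(sample, rsid, genotype)`. A call matches a row iff the
rsid and the *canonical* genotype are string-equal.

Canonicalization is the load-bearing convention: every genotype anywhere in
the package is uppercase with its two alleles sorted (`canonical_genotype("G",
"A")` is `"AG"`). This makes matching phase-blind (`0|1`, `1/0`, `GA`, `AG`
are one genotype) and commutative by construction, and it is idempotent, so
re-loading already-canonical data changes nothing.

Two modeling assumptions follow from the biology:

* **Per-genotype exactness.** A row annotated for `AG` does not match an
  observed `GG`. Drug-response phenotypes are curated per genotype
  (heterozygous and homozygous carriers can have different — even opposite —
  dose implications), so no dominance model is imposed.
* **rsID as the primary key.** Every supported input format carries rsIDs,
  and the knowledge base is curated against dbSNP, so matching is keyed on
  rsid. Chromosome/position matching is used only as a fallback for calls
  that lack an rsID, and it is announced with a warning, because positions
  are build-dependent while rsIDs are not.

All genotypes are assumed reported on the forward strand of the reference,
the dbSNP convention. The package does not attempt to detect or flip
strand-swapped array exports; A/T and C/G SNPs are inherently ambiguous
under strand flips and a knowledge base containing them should be curated
with that in mind.

## Input handling

**VCF v4.2.** Records are accepted when FILTER is `PASS` or `.` — upstream
callers emit filtered records precisely because they distrust them — and
when the record is a biallelic A/C/G/T SNV. Multi-allelic and indel records
are skipped and counted (the counts are attached to the returned call table
and summarized in a message) rather than erroring, because both are routine
in real VCFs and out of scope for a biallelic-SNV knowledge base. GT fields
are resolved index-by-index against REF/ALT; haploid calls (male chrX/Y) are
duplicated to a homozygous diploid representation, and `.`, `./.` or a
half-missing `0/.` all become missing. Phase separators are ignored.

**Array dialects.** The four vendor layouts differ only in delimiter,
header and column names; `array_dialects()` exposes the mapping as data so
a revised vendor export can be accommodated by overriding the config rather
than editing code. No-call tokens (`--`, `00`, `NN`, empty) become missing;
single-letter hemizygous calls are duplicated like haploid VCF calls;
genotype strings containing non-ACGT characters (indel codes such as `II`,
`DD`) are treated as missing rather than rejected, since consumer files
routinely contain them. Chromosome names are normalized (`chr` prefix
stripped, `M` unified to `MT`). Gzip-compressed inputs are accepted.

**Evidence levels.** The six-tier scale `1A < 1B < 2A < 2B < 3 < 4`
(strongest to weakest) is a total order; `min_evidence` filters are
inclusive ("at least this strong"). The default is no filter: reports show
every tier with the tier printed per row, leaving the strength judgment to
the reader.

## Cohort statistics

**Counting unit.** "Drug-related SNPs per individual" counts *distinct
matched rsids*, not annotation rows: one SNP annotated to three drugs is
still one SNP in a person's burden. The count tables use the same unit per
cell — entry (sample, drug) is the number of distinct rsids matched for
that drug — so a pleiotropic SNP contributes once to each of its drugs'
columns. Standard deviations use the n−1 sample estimator; a one-sample
population reports `NA` rather than a fabricated zero.

**Frequencies.** Genotype distributions are computed per (rsid,
population). Missing genotypes — a no-call, or no call at all at that locus
— are tracked as an explicit `MISSING` category and excluded from the
frequency denominator, so observed-genotype frequencies always sum to 1 and
a cohort with patchy coverage does not silently deflate its frequencies.
Imputation is deliberately not attempted. Between-population differences
are reported descriptively only; no significance test is attached, because
choosing one (and its multiple-testing policy) is an analysis decision that
belongs to the user.

**Individual-vs-group divergence.** `compare_to_group()` flags a matched
locus when the index sample's genotype is carried by less than a threshold
fraction (default 0.5) of the comparison population's genotyped samples —
"differs from the group majority". The threshold is a parameter, not a
constant, because "different from the group" has no canonical definition;
0.5 is the weakest value at which a flagged genotype cannot be the
majority.

## The network

The interaction graph is tri-partite and directed: gene → drug edges
(witnessed by at least one annotation row linking them; deduplicated) and
drug → category edges (from the drug table's functional classifications).
Arrows point *toward* the drug so that a drug whose response many genes
modulate is visually a sink with high in-degree — the in-degree of a drug
node equals its number of distinct annotated genes, which is the level at
which that observation is testable. Effect directions are attached as an
edge attribute but deliberately unused by any structural invariant, since
one gene–drug pair can carry both directions (different genotypes).
Isolated nodes are omitted. GraphML is the fidelity format (it round-trips
the typed attributes); JSON node-link and DOT are conveniences.

## Reports

Individual reports are emitted as HTML and Markdown rather than PDF: both
preserve the navigable index-to-section structure (each drug in the index
is an intra-document link), diff cleanly, and render everywhere. The
summary table uses a compact `aspect`/`direction` column pair by default;
`wide = TRUE` spreads the direction into sparse `efficacy`/`dosage`/
`toxicity` columns for readers used to that layout. Sections are ordered
alphabetically by drug and rows within a section by evidence rank then
rsid, so rendering is deterministic — identical inputs give byte-identical
files. The index can alternatively be grouped by drug category
(`index_by = "category"`), since a classification-first index is the other
reasonable reading of "a drug classification list as the index"; drug-name
indexing is the default.

## The simulator and what passing tests mean

`simulate_cohort()` draws, per sample and per KB locus, a diploid genotype
under Hardy–Weinberg proportions (p², 2pq, q²) from the sample's population
allele frequency, using a single seeded stream. Alongside the cohort it
returns the *exact* expected outputs: the truth match table, computed by an
exhaustive scan of every annotation row against every planted call
(deliberately not the annotation engine's join), and the closed-form
genotype probabilities.

The default study conditions (`default_population_specs()`) are five
populations named after the 1000 Genomes super-populations, 500 samples
each, with a fixed allele-frequency table at the mini-KB loci chosen once
to reproduce the qualitative between-population patterns of those variants
— e.g. rs1042522 CC-dominant in the American/European populations and
GG-dominant in the African population, rs11615 heterozygote-dominant in
Europeans and GG-dominant elsewhere, a nearly uniform rs3957357, a strong
East-Asian skew at the VKORC1 promoter variant, and a CYP2C9\*2 allele that
is rare outside Europeans. Loci without an entry default to 0.5. These
numbers are package constants, not fits.

The simulator emulates genotype sampling only. It does **not** model
linkage disequilibrium, relatedness, genotyping error, batch effects,
strand flips, or population substructure. Passing the simulation-based
tests therefore demonstrates that the bookkeeping — parsing,
canonicalization, joining, counting, normalizing — is exact under known
truth; it says nothing about the clinical validity of any knowledge base.

Test and acceptance problem sizes were chosen as the smallest at which the
statistical checks are meaningful: 20 independent 100-sample × 200-row
instances for engine-vs-oracle equivalence, a 5 × 500 cohort for frequency
recovery (binomial SE at n = 500 separates the planted frequencies
comfortably), and 200 small fuzzed instances for the conservation
invariants.

## The built-in mini knowledge base

`mini_kb()` is a self-contained fixture covering classic associations: four
cisplatin-toxicity SNPs (rs1042522, rs316019, rs11615, rs3957357), warfarin
dosage variants in VKORC1, CYP2C9 and CYP4F2 (the CYP4F2 variant shared
with phenprocoumon), a warfarin dosage-lowering genotype at rs2292566, and
a clopidogrel efficacy variant in CYP2C19, with FDA biomarker-label flags
on the warfarin and clopidogrel rows. Three entries are fixture
conventions, documented here because they are choices rather than curated
facts:

* the cisplatin SNPs carry placeholder gene symbols `GENE_CIS1`–`GENE_CIS4`
  rather than guessed real symbols;
* rs3957357 is assigned genotype TT → toxicity decrease; only the locus and
  its drug association are established, not a per-genotype direction;
* rs2292566 is filed under CYP2C9 so that warfarin's gene neighborhood in
  the network is exactly {VKORC1, CYP2C9, CYP4F2}; its true host gene is
  not part of the fixture's scope;
* heterozygous directions for rs1042522 and rs316019 are omitted entirely
  rather than invented.

For real work, export your own knowledge base into the two-file TSV schema
(`kb_annotations.tsv` + `kb_drugs.tsv`; see `?read_kb`). TSV was chosen
over a relational database because it is diff-able, versionable and
dependency-free at desk scale.

## Degenerate inputs and tie-breaking

* Empty knowledge bases, header-only VCFs and zero-match samples are valid
  everywhere and produce empty-but-well-formed outputs (a report explicitly
  states "no findings").
* Duplicate KB rows collapse on load; *conflicting* rows (same key,
  opposite direction) are not silently resolved — `validate_kb()` reports
  them and the CLI's `kb-validate` exits nonzero.
* Match output ordering is total: drug, then evidence rank, then rsid, then
  aspect; cohort outputs preserve input sample order. Two runs on the same
  inputs are byte-identical.
* Monomorphic sites are written to VCF with a placeholder ALT allele (never
  referenced by a GT) so the record stays a well-formed biallelic SNV.
* Frequencies compare within 1e-9 of 1 in the normalization invariants;
  no other numerical tolerance exists in the package — everything else is
  integer counting and string equality.

## Known limitations

Only biallelic SNVs with rsIDs are annotated. Star-allele haplotypes
(CYP2D6 diplotypes and friends), indels, CNVs, imputation, phasing and
genome-build liftover are out of scope. The qualitative
increase/decrease vocabulary follows the curation style of the upstream
sources; no quantitative dosing model is provided or implied. FASTQ
alignment and variant calling belong upstream of this package.
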