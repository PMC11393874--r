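---
title: "Prioritizing rare germline variants in DNA-repair genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing rare germline variants in DNA-repair genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repairsieve)
```

## The screening problem

Cohorts of early-onset breast cancer patients without pathogenic BRCA1/2
alleles are a natural place to look for additional inherited risk variants,
and DNA-repair genes are the natural gene universe to search: most known
breast cancer susceptibility genes act in double-strand-break repair,
mismatch repair or nucleotide-excision repair. After exome sequencing and
annotation, the analytic problem is triage: from tens of thousands of
panel-gene variants per cohort, keep a defensible short list of rare,
predicted-deleterious candidates per patient.

`repairsieve` implements one published form of that triage as a
deterministic, auditable cascade over a tidy variant table. The package
deliberately separates three concerns:

1. **I/O and normalization** — VEP-style `INFO/CSQ` parsing out of VCF,
   multi-allelic decomposition, transcript selection, parsimonious indel
   trimming, dual-caller consensus intersection, cohort merging, and a flat
   TSV dialect for curated tables.
2. **The cascade** — panel restriction, CADD, canonical-transcript rule,
   allele-frequency classing, the consequence-stratum split, REVEL, in two
   rounds.
3. **Cohort aggregation** — carriers per variant, variants per patient,
   novelty, age and clinical-flag summaries, and overlap against an
   external validation cohort.

## The cascade and its parameters

All thresholds live in `filter_config()`; `published_profile()` is the
default and mirrors the screen the bundled fixtures transcribe.

| parameter | default | meaning |
|---|---|---|
| `cadd_min` | 20 | CADD PHRED floor; a score of exactly 20 passes ("smaller than 20" is excluded). ≥20 means top 1% most deleterious genome-wide. |
| `af_strict` | 0.01 | strict-round allele-frequency ceiling (exclusive) |
| `af_relaxed` | 0.02 | relaxed-round ceiling (exclusive) |
| `revel_strict` | 0.75 | strict-round REVEL floor (exclusive), Group 2 only |
| `revel_relaxed` | 0.4 | relaxed-round floor; a REVEL operating point balancing sensitivity and specificity |
| `retain_missing_*` | `TRUE` | unscored variants / unreported frequencies are kept |

**Missing-value semantics.** Absence is representation-level: an empty CSQ
field or an `NA` table cell. A frequency of exactly 0 is *reported* —
population databases print 0 for known alleles unseen in a sub-population —
so a zero-frequency variant is rare, not ultra-rare, and is never counted as
novel. The frequency rule requires *every reported* frequency (exome and
genome cohorts, global and Finnish) to stay below the ceiling; a variant
with no reported frequency at all is ultra-rare and kept. Missing CADD and
REVEL scores are kept because missingness is structural, not informative:
CADD leaves many indels unscored and REVEL scores only missense changes.

**Consequence strata.** Group 1 holds the truncating / splice-site-altering
classes (`stop_gained`, `start_lost`, splice acceptor/donor, non-coding
transcript exon) and is prioritized on frequency alone; Group 2 holds the
non-synonymous classes and additionally faces the REVEL rule. Group 1 takes
precedence when a variant carries terms from both strata. Our default
Group 2 set goes beyond missense and frameshift: it includes in-frame
indels, protein-altering, downstream-gene and splice-region variants,
because the published screen demonstrably retained variants of all these
classes inside its subcategories. In particular, we count
`splice_region_variant` as a Group 2 term on its own: the screen retained a
splice-region/polypyrimidine-tract variant with no accompanying
non-synonymous term, which no narrower reading reproduces. Both term sets
are configuration, so a purist profile can drop the extensions.

**The relaxed round's gene universe.** The screen's second round re-filters
"all variants in the affected genes" at relaxed thresholds. Which genes are
"affected" is the one genuinely open design point. Restricting to genes of
*strict-round retainees* fails to reproduce the published output: several
published subcategory-2 variants (in RPA1, LIG3, RNF8, SPIDR) sit in genes
where no variant survives the strict round. The published table is only
reproduced when the relaxed round's universe is the genes surviving the
*general* filter — panel, CADD, canonical transcript — before the frequency
and REVEL rules. `classify_variants()` therefore defaults to
`affected_genes = "prefilter"`; the narrower `"strict"` mode is available,
and `run_strict()` still reports the strict-retainee gene set for callers
composing the rounds manually.

**Subcategories.** Strict-round Group 2 retainees are subcategory 1,
relaxed-round Group 2 retainees subcategory 2. Group 1 retainees carry no
subcategory in either round — the published table prints none for them, and
a Group 1 variant re-admitted by the relaxed frequency ceiling is still a
Group 1 call. Note one internal inconsistency of the source screen: one
printed subcategory-1 variant has a reported Finnish genome frequency of
0.01085, which violates the strict ceiling its own caption states; the
cascade classes it subcategory 2 (retention is unaffected). The bundled
fixture carries all printed labels verbatim as metadata
(`subcategory_printed`) rather than silently "correcting" either side.

**Novelty** is operational: no dbSNP identifier *and* no reported frequency
in any column. This reproduces exactly the variants the screen printed by
chromosomal position instead of rs-number.

## Keys, consensus and merging

Variant keys are (contig, 1-based position, ref, alt) under VCF
conventions, compared after stripping `chr` prefixes and parsimonious indel
trimming (shared suffix first, then shared prefix with the position
advancing). Trimming is representation-level; no reference genome is
consulted, which is sufficient to reconcile the indel spellings two callers
emit for the same event. `consensus_merge()` is a set intersection on those
keys — symmetric, idempotent, sorted — and refuses call sets whose headers
declare different reference builds. `merge_cohort()` unions carriers across
patients for equal (key, gene) records and keeps the first-seen annotation
on conflict, with a warning naming the variant.

The flat table dialect carries no genomic alleles (curated tables print
HGVS notation and positions, not ref/alt pairs), so table-derived keys are
position-plus-identifier; VCF-derived keys are always complete. Carrier
status is any non-reference genotype; homozygotes are recorded and
reported, not filtered.

## The synthetic generator

`simulate_cohort()` exists so the cascade's behavior can be verified against
a known answer. Each variant is assigned one of seven fates —
`STRICT_GROUP1`, `STRICT_SUB1`, `RELAXED_SUB2`, `FAIL_REVEL`, `COMMON_AF`,
`LOW_CADD`, `OFF_PANEL` — and its attributes are *constructed* so the fate
is guaranteed: values are placed strictly inside the relevant threshold
interval with a margin of 1e-6, never on a boundary. `RELAXED_SUB2`
variants are planted in genes already hosting a strict-round variant (and
reach the relaxed round either through a frequency between the two ceilings
or a REVEL score between the two floors); requesting them with no strict
stratum is a configuration error. Unscored variants are emitted as indels,
mirroring where CADD missingness arises in practice; a configurable
fraction of ultra-rare variants carries no rs-number, exercising novelty
detection.

Randomness comes from per-variant substreams keyed by (seed, index), so a
run is reproducible and growing the cohort's final stratum does not
reshuffle earlier variants. Default cohort dimensions mirror the emulated
screen: 63 patients, ages 23–40, ~19% bilateral, ~29% Lund-negative,
heterozygous carriers with a small Poisson-distributed count per variant.

What the generator does **not** emulate: linkage and haplotype structure,
realistic per-gene variant densities, correlated pathogenicity scores
(CADD, REVEL, SIFT and PolyPhen are drawn independently of each other), or
caller-specific error modes. Passing planted-fate recovery therefore
demonstrates that the cascade's decision logic is correct, not that the
thresholds are well-calibrated for any particular real cohort.

## Numerical and degenerate-input choices

* Comparisons are exactly as published: frequency strictly below the
  ceiling, REVEL strictly above the floor, CADD at-or-above the floor.
* The cohort median age uses the lower-middle element for even counts
  (ranking convention of the emulated screen's cohort description); ages
  are ages at *first* diagnosis.
* Duplicate (key, gene) records are evaluated once; records differing in
  gene are evaluated per gene after per-gene transcript selection
  (canonical first, non-transcript-only kept, non-canonical-only dropped).
* Empty inputs flow through every stage as empty tibbles, not errors;
  dangling patient-to-variant references and malformed CSQ entries are
  errors that name the offending id or record.
* Fixture loaders verify a frozen checksum before parsing.

## Problem sizes

The test suite runs the full bundled screen (72 variants × 63 patients),
oracle comparisons on cohorts of 150–1,000 random variants against a flat
single-expression reimplementation of the retention predicate, planted-fate
recovery on cohorts of 40–130 variants, and VCF round-trips on cohorts of
30–80 variants — sizes at which the whole suite completes in well under two
minutes while every code path is exercised.

## Limitations

* Scores are inputs: the package never computes CADD, REVEL, SIFT or
  PolyPhen, and performs no ClinVar/ACMG interpretation.
* The bundled panel is a frozen snapshot of a curated DNA-repair inventory;
  the live inventory evolves, so panel membership for new data should use a
  current list (the file format is one symbol per line plus an optional
  alias map).
* The published validation-cohort comparison (shared variants and carriers
  in an independent familial breast cancer series) cannot be reproduced
  because those genotypes are not public; `validation_overlap()` is instead
  verified on synthetic cohorts with planted hits.
* Statistical association testing is out of scope — the cascade produces
  candidates, not risk estimates.
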