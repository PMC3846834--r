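---
title: "Methods: cross-species analysis of miRNA regulation of CNV genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species analysis of miRNA regulation of CNV genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis

Copy number variable (CNV) regions harbour genes whose dosage changes
between individuals; microRNAs (miRNAs) repress mRNAs
post-transcriptionally through 3'UTR binding and are one candidate
mechanism for buffering that dosage variability. `mircnv` implements a
comparative pipeline that asks whether genes inside CNV regions are under
heavier miRNA regulation than genes outside them, and whether that
pressure differs between species:

1. **Homolog atlas.** Starting from a human CNV gene table and a
   cross-species homology table, each species retains exactly the genes
   with a human homolog. A gene is `CNV` iff its span overlaps a
   catalogued CNV region by at least one base (0-based half-open
   coordinates, strand-agnostic); each species is classified against its
   own CNV catalogue, because CNV calls are species-specific. An
   inherit-from-human fallback exists for species without CNV catalogues
   but is off by default.
2. **Dual-predictor target scan.** Two deterministic predictors scan every
   (miRNA, 3'UTR) combination: a canonical seed-match predictor (8mer,
   7mer-m8, 7mer-A1 site types, longest-type-wins at a locus) and a
   5'-complementarity "walk" predictor (longest run of consecutive G:C/A:U
   pairs of the miRNA 5' end, anchored at position 1 or 2, reported at
   length >= 7). Only (miRNA, gene) pairs found by **both** predictors are
   kept. The two published web resources this mirrors are external
   services whose internals are not reproducible; the predictors here are
   documented stand-ins with the canonical rules, and externally computed
   prediction tables can be injected (`read_predictions()`, the
   `predictions` path of `pipeline_config()`) to bypass them.
3. **Partition at the overall mean.** For each species, the overall mean
   is total intersected pairs divided by the number of catalogued miRNAs
   (or families; a family is the set of miRNAs sharing seed nucleotides
   2-8). Units above the mean define the "above" gene list (union of their
   targets), the rest the "below" list. The lists may overlap; that is
   deliberate, since enrichment is reported for both.
4. **Enrichment.** Each list is tested against every pathway with a
   one-sided Fisher's exact test (hypergeometric upper tail) and BH
   correction at 5%. Curated gene classes are tallied per CNV stratum.
5. **Binding-site overrepresentation (ORA).** Per-gene binding-site
   density (sites / UTR length) is compared between members and
   non-members of each set with a one-sided rank-sum test, BH across sets;
   a Fisher-on-median-dichotomised-density variant is available.
6. **Host-gene scan.** A miRNA is "hosted" by a gene iff its genomic
   interval is fully contained in the gene span (any-overlap mode
   available); per-species hosted counts in the two strata are normalised
   by the stratum gene counts and labelled `cnv-biased` / `similar` /
   `noncnv-biased` with `similar` meaning a density ratio within
   [1/1.2, 1.2].

## Design choices where the method was open

* **Overlap rule for CNV membership** is any-base overlap; public CNV gene
  annotations are strand-agnostic region memberships, and the boundary
  case (a gene abutting a region in half-open coordinates) is non-CNV.
* **Intersection granularity** is the (miRNA, gene) pair, not the binding
  site: the two predictors' site coordinate systems are not commensurable,
  and the analysis counts interactions.
* **G:U wobble** is disallowed in both predictors, matching canonical seed
  definitions and keeping the predictors exactly checkable against
  brute-force scanning.
* **Ties at the partition cut-off** go to "below" (`ties_below`); the
  inclusive rule is a flag. The cut-off is the overall mean itself.
* **Partition unit** is the miRNA (or family) — the quantity with the
  cut-off's units (targets per miRNA); partitioning genes by miRNA count
  is the alternative reading and is not implemented as the default.
* **Enrichment universe** is the species' CNV genes annotated to at least
  one pathway (`universe = "annotated"`); `"all"` uses every CNV gene.
  Sidedness is one-sided enrichment; alpha is 0.05 on adjusted values.
* **ORA mechanics** are not derivable from the published tables; the
  rank-sum density comparison is this package's documented choice, with
  the Fisher variant behind a flag. Degenerate groups (fewer than two
  genes, zero variance) return `NA` rather than a fabricated p.
* **Host-gene "within"** is full containment; a miRNA inside genes of both
  strata counts once in each; the 1.2x "similar" band is this package's
  operationalisation of a qualitative three-way call and is configurable.
  When one stratum has hosts and the other none, the ratio is infinite and
  the call is the hosting stratum's bias; with no hosts at all it is `NA`.

## The synthetic cohort generator

Real inputs (CNV catalogues, homology builds, UTR releases, miRNA
catalogues) are version-dependent downloads, so the package carries a
generator that emulates their structure with a complete truth record.

* Species (default 8, human first), homology groups (default 300, all
  present in human, elsewhere with probability 0.92), one synthetic
  chromosome per species with non-overlapping gene spans, and per-species
  CNV regions covering a configurable fraction (default 0.5) of genes.
* 3'UTRs are i.i.d. uniform A/C/G/U (default length 250 +/- 50 nt,
  truncated at 30). Uniform background keeps the chance-match rate
  analytically computable — the expected 7mer-m8 count per (miRNA, UTR) is
  (L-6)/4^7 — which the tests exploit. One UTR per gene; transcript-level
  ambiguity is deliberately collapsed.
* miRNAs (default 30) are random 21-25 nt sequences; planted binding
  sites are exact 8mer matches (the unambiguous truth set; weaker types
  arise only by chance), overwritten at uniformly drawn non-overlapping
  offsets, with per-gene counts Poisson at the configured
  per-(species, CNV status) rate — default 1.0 for human CNV genes and
  0.3 elsewhere, which makes the human-CNV per-gene density the highest
  by construction while background pairs (about 0.9 per gene at the
  default sizes) add equal noise everywhere.
* **Prolific miRNAs.** The miRNA used for each planted site is drawn
  non-uniformly: a small set (default 3 of 30) receives most of the
  planted mass (default share 0.7). Real catalogues are similarly
  heterogeneous — a few seeds account for a large share of conserved
  sites — and the skew is what gives the above/below-mean partition a
  planted signal: prolific miRNAs land far above the mean, so genes with
  at least one prolific planted site (about half of human CNV genes at
  the defaults) form the expected "above" pool recorded in the truth.
* **Planted pathways** (default 3 of 20) draw a configurable excess
  (default 0.9) of their members from that pool; the remaining pathways
  and the curated classes are uniform draws, so they are exact nulls for
  the enrichment test regardless of how the partition falls.
* **miRNA placement**: 60% of miRNAs are intragenic on the human
  chromosome, choosing a CNV host with probability 0.8; the rest sit in
  inter-gene gaps clear of the CNV-region margins. Host scanning in
  synthetic mode therefore exercises the human genome; files mode scans
  any species with miRNA coordinates.

Defaults were fixed once from this power reasoning (a pathway of 20-40
genes drawn at 90% from a pool covering half a 150-gene universe sits
4-5 SDs above its null expectation) and from the intended simulation
scale — about 100 full-pipeline replicates for the planted-recovery
suite and 200 for the null control, each cohort scanning roughly 1,200
CNV genes against 30 miRNAs. The generator does **not** emulate realistic
nucleotide composition, conservation, UTR secondary structure or
indels/SNPs; a green simulation suite shows the pipeline recovers the
effects it defines, not that the stand-in predictors match any particular
published predictor on real sequence.

## Numerical and degenerate-input behaviour

* Fisher's tail is computed as `phyper(a-1, a+c, b+d, a+b, lower = FALSE)`
  and is exact; the tests sweep every 2x2 table with total <= 40 against
  direct combinatorial enumeration.
* BH follows the step-up definition with the cumulative-minimum
  monotonicity enforcement; sets whose ORA p is `NA` (degenerate groups)
  do not count towards the number of tests.
* The UTR-length control normalises each species' CNV UTR lengths by that
  species' all-gene mean (scale-invariant per species) and applies a
  Kruskal-Wallis omnibus test; species with fewer than two CNV UTRs are
  excluded with a warning, and fewer than two usable species yields an
  `NA` p.
* All randomness flows from one seed (Mersenne-Twister with fixed normal
  and sample kinds), so a cohort, a pipeline run and the simulation
  suites are byte-reproducible; TSVs are written with fixed quoting,
  separators and line endings.
* Malformed intervals (start >= end) are rejected naming the offending
  record; T in input FASTA is transliterated to U with a logged message;
  duplicated gene ids keep the first occurrence with a warning.

## Known limitations

* The stand-in predictors implement canonical seed and 5'-complementarity
  rules only: no context scoring, conservation filtering, free-energy
  model or non-canonical site classes. Published interaction totals from
  the original web resources are version-dependent and are not
  reproduced; the package reproduces the analysis *shapes* and verifies
  the machinery on planted truth.
* Family collapse uses the seed (positions 2-8) as the family key, a
  simplification of curated family definitions.
* The per-species miRNA denominator is explicit (`n_units`); published
  per-species means that mix denominators cannot be recovered without
  knowing those denominators.
* Synthetic miRNA coordinates exist on the human chromosome only, so the
  host-gene scan's cross-species table is exercised in files mode, not by
  the generator.
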