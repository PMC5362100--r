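---
title: "Designing and evaluating a SNP genotyping array: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating a SNP genotyping array}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SNPArrayKit)
```

SNPArrayKit turns a population re-sequencing VCF into a genotyping-array
design and then grades the array's performance once genotype calls exist.
This vignette explains the model behind each stage, the tunable parameters
and their defaults, the decisions taken where the methodology is genuinely
open, and what the synthetic-data generator does and does not emulate.

## Data model

Four S4 classes carry the pipeline's state. `VariantCallSet` holds variant
sites as a `GRanges` (one alternate allele per row; multiallelic VCF records
are split on input) with sites × samples matrices of genotype code (0/1/2,
`NA` missing), read depth (DP) and genotype quality (GQ). `GeneModelSet`
holds gene spans, exons and phased CDS intervals, one transcript per gene
(when a GFF3 supplies several, the longest-CDS transcript is kept — the
pipeline reports per-gene, not per-transcript, statistics). `CallMatrix` is
a markers × samples grid over AA/AB/BB/NoCall, where "A" is always the
marker's design reference allele, with optional per-sample dish-QC values.
`ArrayDesign` is the ordered, deduplicated marker table plus probe
templates. All coordinates are 1-based closed, mirroring VCF/GFF3; any
half-open arithmetic stays inside individual functions.

When a multiallelic record is split, sample alleles equal to the current
alternate count as ALT and every other allele (reference or another
alternate) counts as REF, as `bcftools norm`-style splitting does. Phased
genotype separators are accepted and treated as unphased; phase is never
used.

## Site filtering

A call is invalidated when DP < `dpMin` (10), DP > `dpMax` (100) or
GQ < `gqMin` (20). The thresholds are strict removal inequalities, so
DP = 10, DP = 100 and GQ = 20 remain valid; the same convention keeps sites
with MAF exactly 0.05 or missing rate exactly 0.1. The depth and quality
conditions combine with OR semantics — any one failing condition
invalidates the call — matching universal GATK-style practice. The missing
rate is the fraction of individuals with an absent or invalidated call; MAF
is computed over valid calls only (a heterozygote contributes one alternate
allele, a homozygous-alternate call two). Indel proximity uses the indel's
VCF anchor position with an inclusive 20-bp radius; indel length is not
modeled because anchor-only proximity is the only information a single VCF
coordinate reliably gives. A site at which every call is invalid is failed
with missing rate 1 and undefined MAF.

## Effect classification and priority

Coding SNPs are classified by strand-aware codon translation: the spliced,
phase-trimmed CDS is assembled in transcription orientation, the affected
codon is substituted, and both codons are translated with the standard
genetic code. Identical amino acids give `synonymous` (`stop_retained` when
both are stops); a change gives `missense`, a gained stop `stop_gained`, a
lost stop `stop_lost`. Any substitution in the annotated first codon is
start-affecting: `initiator_codon` when the alternate codon still encodes
Met, otherwise `start_lost`. With the standard code a single substitution of
ATG never preserves Met, so `initiator_codon` in practice covers annotated
non-ATG starts; this mapping is a labeled assumption, as the distinction is
not defined in the class vocabulary itself.

Intronic SNPs within 2 bp of the exon junction are `splice_donor` (5′ side
of the intron) or `splice_acceptor` (3′ side); 3–8 bp into the intron is
`splice_region`; deeper is `intron`. These distances follow the standard
effect-predictor convention — the class vocabulary names the categories
without stating distances. Exonic positions outside the CDS (untranslated
regions) are grouped with the gene body as `intron` (priority 2); the
vocabulary has no UTR class. SNPs within 2,000 bp of a gene span are
`upstream2k`/`downstream2k` relative to the gene's strand, measured from the
full gene span including any UTR exons; everything else is `intergenic`.
When a SNP touches several genes, the highest-priority effect wins and ties
go to the lexicographically first gene id. A coding SNP whose codon cannot
be resolved (truncated model) falls back to `intron` with a warning rather
than failing the run.

Priorities are 4 for non-synonymous coding and splice-site-disrupting
classes, 3 for synonymous coding, 2 for intron/splice_region/2-kb flanks,
1 for intergenic. `splice_region` is deliberately not large-effect: only
donor/acceptor disruption, stop gain/loss and start loss qualify.

## Window selection

The "sliding" window scan is implemented as a non-overlapping tiling
anchored at scaffold position 1: an overlapping slide would re-select the
same best SNP in every window it covers, whereas the procedure picks exactly
one SNP per window. Within a window, ties on priority break by higher MAF
(more informative assays), then by smaller position (determinism). The
expected marker count per scaffold is `max(1, floor(length / 2800))`; floor
keeps the genome-wide sum at or below the nominal capacity, and the minimum
of one marker keeps short scaffolds represented.

The fill-in pass runs only for scaffolds below their expected count. It
re-tiles with 1-kb windows, takes the best remaining candidate in each
window that holds no selected marker, and processes windows in order of
their best candidate's rank rather than left to right — under a deficit this
maximizes design quality; left-to-right processing is available via
`selectionConfig(fillinOrder = "position")` for sensitivity checks.

Must-include markers (e.g. trait-associated SNPs) and large-effect SNPs are
seeded before the scans and may therefore share a window with a scanned
selection. Under capacity pressure, non-must-include markers are dropped in
ascending (priority, MAF) order; must-include markers are never dropped, and
the run fails if capacity cannot hold them all. Identical inputs produce
byte-identical designs. Probe templates are plus-strand flanks of 35 bp per
side with the variant written `[ref/alt]`, truncated without padding at
scaffold edges.

## Post-genotyping QC

Sample gating uses the platform-default cutoffs: call rate ≥ 0.970 and,
when dish-QC values are supplied, DQC ≥ 0.82. Marker categories follow the
Axiom cluster vocabulary but are assigned from calls, not from intensity
space: all three genotypes present is `PolyHighResolution`; one homozygote
class plus heterozygotes is `NoMinorHom`; a single homozygote class is
`MonoHighResolution`; a marker call rate below the threshold overrides the
rest as `CallRateBelowThreshold`; anything else — including the unnamed
pattern of two homozygote classes with no heterozygote — is `Other`.
`OTV` (off-target variant) clusters are detectable only in intensity space,
so the category exists in the vocabulary but is assignable solely through
externally supplied labels that override the call-based assignment.
Converted markers are `PolyHighResolution` plus `NoMinorHom`.

Summary tables round percentages half-up to the table's printed precision
(one decimal; conversion rates two decimals) via `roundHalfUp`, since
banker's rounding would disagree with printed values on exact ties. The
spacing distribution uses consecutive same-scaffold position differences; a
scaffold with *k* markers contributes *k* − 1 intervals, so the percentage
denominator is markers − scaffolds. The reported mean spacing is total
occupied span / intervals; note that published per-study "average interval"
figures do not always state their averaging rule, so this package reports
the span-based mean and leaves alternatives to the caller. Gene-level
counts treat every non-intergenic marker as belonging to its assigned gene.

## Concordance

Per marker, only samples non-missing on both platforms are compared; the
rate is matches / comparisons and is undefined when nothing is comparable.
The mean over converted markers excludes undefined rates. The mean over all
on-chip markers keeps each marker's observed rate when a record exists and
counts markers that never produced a comparable call as 0 — failed assays
should depress the all-chip mean rather than silently vanish. The
high-concordance share uses rate ≥ threshold (default 0.971) over converted
markers with defined rates.

## Family-based error accounting

Markers with either parent uncalled are excluded entirely. Same-homozygote
parent pairs fold into `AAxAA` (the accounting is label-symmetric) while
hom × het orientation is preserved (`AAxAB` vs `ABxAA`). The allowed
offspring sets are the Mendelian ones; het × het allows all three genotypes,
so its errors are structurally undetectable. The error call rate is
unexpected calls / non-missing offspring calls — a definition chosen
because, applied to the published family table, it reproduces the printed
totals and the printed per-individual unexpected-call range and accuracy.
Per-individual accuracy is 1 − unexpected/typed for that offspring.

Under a uniform miscall model (a wrong call replaces truth with either
other genotype with equal probability), the expected detectable fraction of
miscalls is 1 for `AAxAA` and `AAxBB` (both wrong genotypes are
inconsistent), 1/2 for hom × het, and 0 for `ABxAB`; the test suite verifies
recovery of e, e/2 and 0 within three binomial standard errors on simulated
families of 10,000 markers with e ∈ {0.01, 0.05}.

`fisherExact2x2` computes the two-sided exact probability as the sum of
hypergeometric point probabilities not exceeding the observed table's
(with a 1 + 1e-7 relative slack against floating-point ties, as
`stats::fisher.test` uses); tests cross-check it against exhaustive table
enumeration and against `stats::fisher.test`.

## The synthetic-data generator

`simConfig` defaults describe a desk-scale rendition of an array-design
study: 10 scaffolds of 500 kb (a 5-Mb genome), 20 genes per scaffold,
a 96-sample cohort at 30× mean depth (high-coverage short-read sequencing
territory, where fewer than 5% of calls fail the DP/GQ filters), SNPs at
1 per 200 bp, indels at 2 × 10⁻⁴ per bp, a 2% per-call missing rate, a 1%
array miscall rate, 0.5% array no-call rate, and a full-sib family of 24
offspring. True MAFs are drawn uniformly on (0.01, 0.5) so both sides of
the MAF filter boundary are exercised. These values are the generator's
fixed study conditions, not tuning knobs: genotypes are Hardy-Weinberg, GQ
is a deterministic ramp of DP plus Gaussian noise (a stand-in for caller
behavior, which published pipelines consume rather than describe), and
gene structures are multi-exon CDSs that start ATG, end at a stop, contain
no internal stop, and are written into the scaffold sequence so that codon
arithmetic against the genome is exact. Designated marker subsets are
forced monomorphic, heterozygote-free and low-call-rate so every assignable
cluster category occurs, and the generating label is exported for recovery
tests.

What the generator does **not** emulate: linkage disequilibrium, population
structure, intensity-space clustering (hence no OTV), probe thermodynamics
and cross-hybridization (p-convert scores are accepted as input, never
computed), read-level sequencing artifacts, and genotype-calling error
correlated across samples. Passing tests therefore demonstrate the
correctness of the accounting and selection logic under known truth, not
the field performance of any physical array.

## Numerical and degenerate-input conventions

Every generator draw is fixed by the configured seed; the CLI and the
acceptance script thread one seed through all stages. Empty inputs return
empty, well-typed results (an empty GFF3 gives an empty model set; a
scaffold with one marker contributes no spacing intervals; a filter over
zero variants yields zero rows). Ties anywhere in selection break
deterministically (priority, MAF, position, then lexicographic ids).
Percentages of zero denominators are avoided by construction (`max(1, n)`
guards) and undefined concordance rates are `NA`, excluded from means over
converted markers.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run the full pipeline on the
default 5-Mb genome with 96 samples, brute-force window-selection
equivalence on 50-kb scaffolds with up to 200 candidates, filter-oracle
equivalence on 1,000 random sites, exhaustive Fisher enumeration for
margins up to 12, and family-error recovery on 10,000-marker families —
sizes chosen so the whole suite completes in a few minutes on one CPU while
every combinatorial path is still exercised.

## Known limitations

Call-based cluster categories approximate intensity clustering: a marker a
clustering algorithm would flag as `OTV` or `Other` from cluster geometry
can look `PolyHighResolution` in call space. Concordance requires the
sequencing genotypes already mapped onto the design's ref/alt orientation;
the package does not re-call or re-orient them. The family module handles
one full-sib family (two parents); multi-generation pedigrees and linkage
mapping are out of scope, as are variant calling, alignment, p-convert
scoring and population-structure analysis.
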