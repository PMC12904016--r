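---
title: "Methods: non-canonical splicing variant analysis with ncsvtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-canonical splicing variant analysis with ncsvtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncsvtools)
```

## The problem

Exome pipelines classify variants by their direct coding effect. A
missense, synonymous or deep-intronic variant near a splice junction can
nonetheless destroy or create splice signals, producing exon skipping,
cryptic-site partial exon deletion, or intron retention — consequences far
more severe than the nominal annotation suggests. `ncsvtools` models this
analysis end to end: prioritizing candidate splice-altering variants from
score annotations, converting an observed splicing outcome into a
protein-level consequence with a quantitative severity (the
disrupted-protein fraction), assigning ACMG/ClinGen PVS1 strength, and
screening cohorts for recessive (biallelic) and X-linked candidates.

The package never predicts *which* aberrant event a variant causes; that is
the job of a wet-lab splicing assay (minigene or RT-PCR on patient tissue).
Events are inputs, as descriptors like "exon 14 skipping" or "intron 10,
79 bp retention".

## Transcript model and coordinates

A transcript is a set of 1-based, inclusive genomic exon intervals on a
named contig with a strand and the genomic positions of the translation
start and stop. `build_transcript()` derives the mRNA (exon concatenation,
reverse-complemented on the minus strand), the CDS and the protein, and
enforces the invariants: CDS divisible by 3, a leading methionine, no
internal stop, a terminal stop, no ambiguity codes inside the CDS. The CDS
span includes the stop codon; `protein_length` excludes it.

`map_g_to_c()` / `map_c_to_g()` convert between genomic and HGVS-c
coordinates. Intronic positions anchor to the nearest junction: the first
half of an intron is `c.N+k` off the last base of the upstream exon, the
second half `c.N−k` off the first base of the downstream exon; the exact
midpoint of an even-length intron anchors to the donor. This convention is
the standard HGVS one; it is stated here because published tables rarely
spell it out. UTR positions are flagged (`utr5`/`utr3`) but no `c.-N`/
`c.*N` notation is generated — single-isoform toy transcripts do not need
it, and isoform selection is out of scope.

## Junction context and the consensus windows

The signed distance to the nearest junction follows the convention
reverse-engineered from published distance columns: intronic bases after a
donor are positive, before an acceptor negative; the exonic base
immediately before a donor is −1 and the k-th exonic base after an
acceptor +k. Ties between equidistant junctions resolve toward the donor.
The splicing consensus windows are **donor −3..+8** and **acceptor
−12..+2**; both ends inclusive. These are exposed as `pipeline_config()`
parameters but are not tuning knobs — they are the windows the field uses.

## Prioritization

A variant is a potential splicing variant when `spcards ≥ 9` (nine or more
of the 18 integrated prediction methods) **or** `spliceai ≥ 0.5`. Both
thresholds are inclusive, the combination is a union, and a missing score
on one arm never vetoes the other — published prioritizations include
variants carried by a single arm. Prioritization is monotone in both
scores (property-tested). Canonical ±2 and stop-gain variants are excluded
from the NCSV validation track (`select_for_validation()`): they are
already loss-of-function under standard rules.

## The consequence engine

`apply_event()` edits the mature mRNA: exon skipping removes the exon's
nucleotides, partial exon deletion removes a sub-interval (anchored at a
cryptic site), intron retention inserts the retained intronic sequence at
its junction. Compound outcomes (one variant, several products) are lists
of events applied jointly. The alternate CDS runs from the original start
codon to the 3' end of the edited mRNA; if an edit removes the start codon
the consequence is `none` with a warning, mirroring how first-exon events
are reported without a protein prediction.

`protein_consequence()` compares the re-translated alternate protein with
the reference by trimming the maximal common prefix first, then the
maximal common suffix. Prefix-first trimming places deletions in repeated
context 3'-most, which is the HGVS rule (suffix-first would give the
5'-most placement). Frame disruption is decided at the nucleotide level —
the alternate tail length modulo 3 against the unedited tail — not from
the residue alignment, because a frameshifted tail can coincidentally
resemble an in-frame replacement. A premature stop exactly at the first
altered codon is a stop gain (`p.A394*`); frameshifts are
`p.<ref><pos><new>fs*N` with `N` counting from the first changed residue
(=1) to the new stop; a tail with no stop at all is flagged
`no_stop_found` and printed `fs*?`.

### Disrupted-count conventions

The fraction column of published consequence tables follows, on every
internally consistent row, these conventions (fixed by majority evidence;
e.g. a 46-residue exon-skip deletion printed as 46/940, a frameshift at
residue 69 of 134 printed as 65/134, a frameshift at 194 of 1464 printed
as 1270/1464):

| kind                | disrupted count                           |
|---------------------|-------------------------------------------|
| in-frame deletion   | `end − start + 1` (inclusive)             |
| in-frame delins     | `end − start + 1` (removed range)         |
| in-frame insertion  | number of inserted residues               |
| frameshift / stop   | `protein_length − first_altered_residue`  |

Rows that contradict the conventions are shipped in the fixture with
`count_ok`/`pct_ok = FALSE` and a note (an off-by-one inclusive count, a
truncated rather than half-up percentage, a reversed residue range). The
engine reports the convention value and the tests assert the
*discrepancy*, never the slip — e.g. the 34-residue deletion printed as
"33/1091 (3.02%)" is asserted to be 34/1091 (3.12%).

### PVS1

`PVS1_Strong` requires a LoF-type kind (frameshift or stop gain) **and**
a disrupted fraction strictly greater than 0.10 ("more than 10% of the
protein product"). Exactly 10.00% is `not_met`; in-frame consequences are
`not_met` regardless of size. The threshold lives once in
`pipeline_config()`.

### Six-class taxonomy

Validated NCSVs are classified by variant region × outcome: A/B exonic and
intronic exon skipping, C/D partial exon deletion, E/F intron retention.
Compound outcomes yield one label per event.

## Cohort screening

The frequency filter drops a variant when **any** configured population
frequency is strictly above 0.01; a missing frequency never drops. A
borderline 0.010 is kept. Compound-heterozygous *partners* are filtered at
a lenient configurable ceiling (default 0.05): published screens retain a
partner at gnomAD 0.043, so the strict filter evidently applied to the
NCSV arm only; the semantics are logged and configurable.

Missense deleteriousness is "three or more of the four" tools (SIFT `D`;
PolyPhen-2 `D` or `P`; MutationTaster `A` or `D`; CADD > 20). A literal
"more than three" would make the missing-data fallback incoherent and
contradicts retained three-call rows, so ≥ 3 is used. `P` (possibly
damaging) counts as damaging — a retained partner with calls D/P/N/23.7
requires it. Variants with all four predictions missing are retained as
deleterious-unknown, mirroring the stated practice.

The inheritance screen emits homozygous NCSVs, hemizygous NCSVs (X
chromosome, male patients only — the screened cohort design; autosomal
hemizygosity is rejected as a data error), and compound-het pairs of a
heterozygous NCSV with a same-gene heterozygous partner in the allowed
class set. Pairs with identical haplotype labels are rejected as cis;
pairs with distinct labels are `validated_trans`; unphased pairs are
emitted with `phase_status = "unknown"` rather than silently assumed
trans, matching the recall-and-Sanger confirmation workflow. Emission is
order-independent (canonical pair orientation by variant key).

## Summary statistics

Percentages are rounded half-up at 2 decimal places, matching the printed
style (`28.99%`, `86.75%`); base R's round-half-even would differ on exact
halves. `fisher_exact()` computes the two-sided p by hypergeometric
enumeration with the "as or less probable" criterion (and the conventional
1e−7 relative tolerance for floating-point ties); the odds ratio is the
conditional MLE with the exact conditional CI (delegated to
`stats::fisher.test`, which implements exactly these conventions and
doubles as the independent cross-check in the tests). The exonic/intronic
validation-rate contrast is exposed as a function, but the published
negative-cell split is not printed anywhere, so no test asserts those
cells. `tally_classes()` reports both the class-tally sum (2403) and the
stated non-redundant total (2404) without forcing agreement.

## Synthetic data: what it emulates and what it does not

The generator's defaults are the study conditions: a latent score
correlation of ρ = 0.83 between the method-count and SpliceAI-like scores,
70% of spiked variants placed inside consensus windows (echoing the
29/41 consensus share), and a 34-patient cohort carrying 7 homozygous, 9
compound-heterozygous and 1 hemizygous planted configuration with decoys
(lone heterozygotes, common-frequency variants, cis pairs) filling the
rest.

Scores come from a Gaussian copula: latent bivariate normal with
correlation ρ, `spliceai = Φ(z₁)` and `spcards = round(18·Φ(z₂))` clipped
to 0..18, with a mean shift (+1.8 probit units) for spiked variants and
−1.5 for decoys. For a homogeneous draw the Pearson correlation of the
transformed scores is ≈ (6/π)·asin(ρ/2) ≈ 0.817 at ρ = 0.83, within the
±0.05 recovery band; the parameter-recovery test therefore draws a
single-component sample, because a mixture of shifted components inflates
the pooled correlation well above ρ. The mixture view is the right one for
threshold-separation tests (sensitivity/specificity 1.0 under fully
separated means), the homogeneous view for correlation recovery.

Spiked events carry truth computed by a deliberately separate
string-surgery oracle (list surgery on the exon sequences, naive
residue-by-residue trimming) — the engine is tested against it on ≥ 1000
random events with 100% required agreement. Toy transcripts have 4–7
exons of ≥ 40 nt, GT..AG introns of 60–300 nt, 120–400-residue proteins,
and UTRs of 12–60 nt; one transcript sits on `chrX` for hemizygous
genotypes. What the toys do *not* emulate: real splice-site strength,
nonsense-mediated decay, isoform diversity, base-composition biases, or
genotype error — so green tests demonstrate the correctness of the
bookkeeping and arithmetic on defined events, not predictive accuracy on
real data.

`sim_transcript_event()` constructs transcripts realising a *prescribed*
consequence geometry (e.g. "codon-aligned exon covering residues 430–475",
"79-nt retention with first altered residue 480"). Because random sequence
can coincidentally extend the common prefix or insert a matching residue,
the constructor verifies the oracle consequence against the requested
geometry and redraws the sequence if needed; this is a postcondition of
the generated *input*, not a calibration of any output.

## Numerical and design choices

* Problem sizes in the routine test run: 10-transcript toy genomes,
  ~1000-event engine-vs-oracle sweeps, a full 2×2 enumeration up to table
  total 60, 10⁴ coordinate round-trips, 5000-draw score recovery. The
  whole suite runs in about two minutes on one CPU.
* Thresholds (9, 0.5, 0.01, 0.05, 20, 0.10) and windows appear exactly
  once, in `pipeline_config()`.
* All generator functions restore the caller's RNG state and derive their
  streams from a single config seed, so outputs are byte-identical across
  runs and independent of call order.
* Degenerate inputs: empty catalogs flow through as empty outputs;
  single-exon transcripts have no junction context; degenerate Fisher
  margins give p = 1 with an undefined odds ratio; an empty gene panel
  warns and passes candidates through.
* Known limitations: indel splice variants are classified only by length
  mod 3 (the score databases the pipeline consumes are SNV-centric);
  multi-isoform genes and UTR-aware HGVS are out of scope; compound
  outcomes report per-event classes and the worst (largest) fraction is
  the caller's choice to aggregate.
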