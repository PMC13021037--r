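---
title: "Methods: panel-restricted rare-variant triage and classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: panel-restricted rare-variant triage and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raretriage)
```

## Scope and model

`raretriage` turns a VEP-annotated exome call set into a short, auditable
list of candidate variants in curated disease-gene panels, each carrying a
clinical-precedence classification. The pipeline assumes that variant
calling, normalisation and VEP annotation have already happened upstream;
its inputs are annotations, never reads or alignments. Its outputs are an
interpreted label per candidate observation and cohort tallies of those
labels.

The unit of analysis is the **variant observation**: one (sample,
alternate allele) pair joined to the single canonical transcript
consequence of that allele. A recurrent variant therefore counts once per
carrier in observation-level tallies; distinct-variant tallies (keyed on
chrom:pos:ref:alt) are always reported alongside, because both readings of
recurrence are in common use.

## Ingest and canonical-consequence selection

`parse_vep_vcf()` reads VCF v4.2+ through `vcfR` and parses the
pipe-delimited per-transcript `CSQ` INFO annotations itself. The subfield
order is taken from the file's own `##INFO=<ID=CSQ...>` header
description; a YAML map can override the binding of subfield names to
model fields, since CSQ dialects differ across VEP configurations. A
missing CSQ header with no override is a fatal configuration error rather
than a guess.

Multi-allelic records are decomposed at ingest, each allele keeping only
its own annotation blocks. Indel left-alignment is *not* performed: inputs
are assumed VEP-normalised, and silently re-normalising coordinates would
make the audit trace diverge from the source file. Coordinates are VCF
coordinates (1-based, anchored reference) everywhere.

Per allele, `select_canonical()` keeps the consequence flagged canonical;
among several flagged, the most severe impact wins (HIGH > MODERATE >
LOW > MODIFIER), ties broken by the lexicographically smallest transcript
id so the choice is deterministic and permutation-invariant. If nothing is
flagged, the same severity-then-id rule is applied over all entries with a
warning. The canonical flag is used exactly as present in the input; the
package does not adjudicate between VEP-canonical and MANE, because the
flag's provenance is an upstream annotation decision.

Two deliberate conventions govern missingness:

* an unparseable allele-frequency token becomes *absent* with a warning —
  never silently zero;
* an absent frequency passes every rarity stage. Novel variants have no
  reference frequencies by definition, and treating absence as zero would
  be indistinguishable from evidence of rarity.

`parse_annotation_tsv()` accepts the same record contract from a flattened
one-row-per-observation TSV (the format `export_cohort()` writes, which
makes export/re-ingest a fixed point). Only `gene`, `consequence` and
`impact` are mandatory; every other field defaults to absent. The shipped
key-variant fixture uses this path; its genomic coordinates are synthetic
placeholders (transcript c. position on the gene's true chromosome)
because the source table reports variants at HGVS resolution only, and its
per-tool prediction columns are consensus-consistent reconstructions of
the published damaging/neutral verdicts so that the consensus engine
recomputes — rather than copies — each verdict.

## The filter cascade

Four predicates, each total, all evaluated for every observation so the
filter trace never hides a stage behind short-circuiting:

1. **Panel**: the gene symbol (case-insensitive) maps to FH, CA or PAH in
   the panel file. Assignment is exclusive — a gene under two panels is a
   configuration error — because downstream panel tallies must sum to the
   candidate count. The shipped 23-gene map covers the candidate genes of
   the default analysis; its PAH panel is completed with canonical
   PanelApp PAH genes (BMPR2, ACVRL1, EIF2AK4, KCNK3) where the studied
   set is not enumerated, and any full PanelApp export can be supplied
   instead (CA > PAH > FH precedence is the recommended collapse rule when
   building such a file).
2. **Region/impact**: impact HIGH or MODERATE *and* at least one
   consequence term in the shipped protein-coding/canonical-splice list
   (missense, frameshift, stop gained/lost, start lost, in-frame indels,
   splice donor/acceptor, protein-altering). The list ships as a
   plain-text config so the membership is inspectable and overridable.
3. **Global rarity**: each of the 1000 Genomes, gnomAD exome and gnomAD
   genome frequencies is absent or `<= 0.01`. "1% or less" is implemented
   inclusively, exactly as worded. The screen applies to the three global
   fields only.
4. **PopMax**: the maximum over *all* stored subpopulation frequencies is
   strictly `< 0.001`. No bottleneck populations (ASJ, FIN, OTH) are
   excluded — the threshold is read as applying across all gnomAD
   subpopulations — but the subpopulation set is config-driven, so
   gnomAD's own popmax convention is expressible by supplying fewer
   fields. An empty subpopulation map gives PopMax 0, so never-observed
   variants pass. A cutoff of 0 is accepted as a degenerate bound that
   nothing passes (useful as a command-line sanity check).

The cascade is monotone in both cutoffs, idempotent on its own candidate
output, and order-independent (the candidate set is the conjunction of
four independently evaluated predicates); all three properties are
asserted in the test suite.

## In-silico consensus

Each tool's native vocabulary is normalised to damaging/tolerated via a
shipped YAML table (PolyPhen `possibly_damaging` counts as damaging;
MutationTaster A/D damaging versus N/P tolerated; MutationAssessor H/M
versus L/N; unrecognised values become absent with a warning). The
tri-state verdict D/N/U is then computed by consequence route:

* **Missense / in-frame** (default): D iff CADD phred >= 20 *and* at
  least 3 of the six tools call damaging; N iff CADD is present below 20,
  fewer than 3 damaging calls, *and* at least 3 tools were callable;
  otherwise U. CADD gates but never votes, and the callable-tool floor
  prevents "neutral by missingness".
* **Indel** (frameshift, or in-frame indel with a SIFT-indel call): D iff
  SIFT-indel is damaging and CADD is absent or >= 20; N iff SIFT-indel is
  neutral; else U. Most missense tools cannot score indels, so the route
  is driven by the one tool built for them; a frameshift without a
  SIFT-indel call is U rather than being guessed from missense tools.
* **Truncating/splice** (stop gained/lost, start lost, canonical splice
  sites): CADD alone decides — D at or above 20, N below, U when absent.
  This route is required for stop-gained variants to receive a damaging
  verdict at all, since the missense tools are silent there.

Both thresholds (CADD 20, 3 tools) are arguments everywhere they appear;
the defaults are the analysis' stated criteria. The verdict is monotone —
flipping any single call from tolerated to damaging, or raising CADD,
never moves D towards N — and the missense route is verified
exhaustively against a direct evaluation of the stated predicate over all
2^6 x {CADD absent, low, high} combinations.

## Clinical-precedence classification

Assertion levels live on the lattice B < LB < US < LP < P, with
composites `P/LP` and `B_LB` between their endpoints and a `conflicting`
marker outside it. Resolution of the two sources (ClinVar, UniProtVar):

* both absent: no clinical evidence (`none`);
* one present: that level, with a lone composite split by the in-silico
  verdict (`P/LP` is P on a damaging verdict, else LP; `B/LB` is B on a
  neutral verdict, else LB);
* both present and equal after composite resolution: that level;
* US versus a pathogenic-leaning level (LP, P, `P/LP`): **LP**, without
  consulting the in-silico verdict. This is the one place the
  implementation deliberately narrows the stated "conflicts consult
  in-silico" rule: the published key-variant table assigns LP to a
  US-vs-`LP/P` conflict *despite* a neutral in-silico verdict, so the
  table is taken as ground truth and the in-silico consult is reserved
  for composite resolution;
* US versus benign-leaning: LB, symmetrically;
* benign-leaning versus pathogenic-leaning, or a `conflicting` record in
  either source: an explicit benign-vs-pathogenic conflict;
* two same-leaning but unequal levels (e.g. LP vs P, B vs LB): the more
  severe resolved level. The source analysis never states this cell; the
  choice keeps classification monotone on the lattice (raising a
  non-conflicting clinical level can never lower the final label) and is
  asserted as such.

The final label: a resolved P/LP/LB/B stands; US and benign-vs-pathogenic
conflicts are VUS (clinical uncertainty is presence, and is never
overridden by in-silico evidence — a US record with a damaging consensus
stays VUS); with no clinical record at all, a damaging consensus earns the
sixth tier **predicted deleterious (D)** and anything else is VUS. The
full 9 x 9 x 3 decision table (243 cells) is exported by
`decision_table()` and tested cell-by-cell against an independently
transcribed oracle.

## Synthetic cohorts

`generate_cohort()` exists so the pipeline is testable end-to-end without
any restricted data. Its defaults are the study conditions the package
emulates, chosen once:

* consequence mixture: intronic 0.37, synonymous 0.20, missense 0.12,
  3'UTR 0.145, 5'UTR 0.017, frameshift 0.0022, other 0.1458 — the
  remainder category is sub-divided so that high-impact non-frameshift
  terms stay rare (~0.3% of all variants) and in-frame/protein-altering
  terms a small minority, matching exome-wide consequence profiles;
* novelty rate 2%; novel variants carry no identifiers *and* no reference
  frequencies;
* frequency strata: common 0.60 (AF ~ U(0.01, 0.5)), rare 0.20
  (U(0.001, 0.01)), ultra-rare 0.15 (U(0, 0.001)), absent 0.05;
  subpopulation frequencies scatter log-normally (sd 0.3) around the
  global value over a configurable eight-population set;
* a latent deleteriousness state (5% of coding variants) drives the six
  tool calls, CADD side-of-cutoff and SIFT-indel, each agreeing with the
  latent state with probability `tool_reliability` (default 0.9; at 0.999
  the pipeline recovers >= 99% of intended labels, which is the
  noiseless-recovery test);
* sparse clinical injection (per-level probabilities, coding variants
  only), 28 carrier samples, one carrier per record (5% homozygous).

Positions are uniform over a fake contig per gene — no reference genome is
shipped or required — and ref/alt alleles are drawn from {A,C,G,T} with
ref-anchored indels (frameshift lengths not a multiple of three). All
draws come from one seeded Mersenne-Twister stream consumed in a fixed
vectorised order, so a fixed seed yields byte-identical VCF and truth
files. With `spike_table2 = TRUE` the eleven shipped key variants are
appended with their fixture annotations, the recurrent TRPM4 frameshift
going to two carriers.

What the generator does *not* emulate: linkage and haplotype structure,
per-site depth/quality, population stratification between carriers,
correlated tool errors, and the real joint distribution of clinical
assertions with frequency. Passing the recovery tests therefore
demonstrates that the pipeline's logic is faithful to its stated rules on
inputs with the right marginal structure — not that the rules themselves
would achieve any particular accuracy on real patients.

## Over-representation analysis

`ora()` is a plain upper-tail hypergeometric test per term
(`P(X >= k)` via `phyper`), against a background defaulting to the GMT's
own gene universe, with BH (default) or Bonferroni adjustment. The g:SCS
correction used by g:Profiler is intentionally not re-implemented — it
depends on g:Profiler's internal term universe — so published g:SCS
p-values are context, not targets. For panel-restricted candidate genes
the stage is descriptive annotation by construction; the shipped
`cardio_terms.gmt` transcribes published cardiac term-gene sets for use as
a worked example.

## Numerical and testing choices

* Frequencies are written with `%.6g` and re-parsed exactly; the only
  boundary at risk (a subpopulation AF within 5e-10 of the 0.001 cutoff)
  has negligible probability under the continuous strata.
* Exports are byte-stable for fixed input; JSON is written with full
  numeric precision (`digits = NA`), display percentages rounded to
  integers alongside the raw fractions.
* Test problem sizes: exhaustive enumeration wherever the space is small
  (243 classification cells, 192 missense-consensus cells, all term ×
  impact pairs, backgrounds of size <= 12 for the hypergeometric
  enumeration oracle); seeded simulation at n = 1,200–2,500 for cascade
  and recovery properties; n = 8,251 once for mixture calibration. These
  sizes give the property checks power while keeping the default suite
  fast.
* Degenerate inputs are first-class: empty VCFs and header-only TSVs
  yield empty streams, empty candidate sets summarise to zero counts, and
  an empty consequence list is an error (annotation corruption), not a
  silent skip.

## Known limitations

* Gene symbols are matched textually (case-insensitive); no HGNC alias
  resolution is attempted, so a panel file and an annotation source using
  different symbols for the same gene will silently miss.
* ClinVar star ratings and per-submitter records are assumed collapsed to
  one level per source upstream; the package's `conflicting` level is the
  hook for ingest pipelines that detect intra-source conflict.
* The indel consensus route reflects the one indel-capable tool available
  in the annotation set; with no SIFT-indel call a frameshift is U, which
  is conservative but means CADD-only evidence never rescues an indel.
* How a ClinVar B versus UniProt P variant should be labelled is
  unknowable from the source analysis; the package's
  benign-vs-pathogenic conflict cell maps to VUS as the most conservative
  reading, and the decision-table export makes the choice auditable.
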