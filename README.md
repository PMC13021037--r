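# raretriage

Panel-restricted rare-variant triage and clinical classification for
VEP-annotated exomes.

## The problem

Exome studies of cardiovascular disease routinely sequence patients whose
primary diagnosis (here, obstructive coronary artery disease) does not
explain their full risk profile. Screening the variants that fall in
curated disease-gene panels — familial hypercholesterolaemia (FH), cardiac
arrhythmias (CA), pulmonary arterial hypertension (PAH) — can surface
clinically actionable secondary findings, but only after aggressive
filtering: a panel-wide exome yields thousands of variants, of which only a
handful are rare and plausibly deleterious.

`raretriage` implements that triage as a reusable, auditable pipeline:

1. **Ingest** — VEP-annotated VCFs (pipe-delimited `CSQ` INFO field, order
   read from the file's own header or overridden by YAML) or flattened
   annotation TSVs. Multi-allelic records are decomposed; per allele, a
   single canonical transcript consequence is selected (canonical flag,
   then impact severity HIGH > MODERATE > LOW > MODIFIER, then smallest
   transcript id).
2. **Filter cascade** — four stages, all evaluated for every variant so the
   trace is complete: (i) gene on a panel (exclusive gene-to-panel map);
   (ii) protein-coding or canonical-splice consequence with HIGH/MODERATE
   impact; (iii) global allele frequency <= 1% in 1000 Genomes and gnomAD
   exomes/genomes (absent counts as rare, never as zero); (iv) PopMax
   AF — the maximum over all gnomAD subpopulation frequencies — strictly
   below 0.1%.
3. **In-silico consensus** — SIFT, PolyPhen-2, FATHMM, MutationTaster,
   MutationAssessor and PROVEAN calls are normalised to damaging/tolerated
   and combined with CADD (phred >= 20) into a tri-state verdict
   D/N/U, with separate routes for missense, indels (SIFT-indel) and
   truncating/splice variants (CADD alone).
4. **Clinical-precedence classification** — ClinVar and UniProtVar
   assertions are resolved on the lattice B < LB < US < LP < P (composites
   `P/LP`, `B/LB` split by the in-silico verdict; US-vs-pathogenic
   conflicts downgrade to LP) and mapped to the five interpreted tiers
   Benign, Likely benign, VUS, Likely pathogenic, Pathogenic, plus a
   sixth **predicted deleterious (D)** tier for variants with no clinical
   record but a damaging consensus.
5. **Report** — observation-level and distinct-variant tallies by class,
   panel, consequence category, impact and gene; novelty (no dbSNP/COSMIC
   identifier); TSV/JSON exports and a per-variant filter trace.

A generic hypergeometric over-representation analysis (`ora()` over GMT
term-gene maps, BH or Bonferroni correction) provides descriptive
functional annotation of candidate genes, and a seeded synthetic cohort
generator (`generate_cohort()`) emits VEP-style annotated VCFs with known
latent truth so the whole pipeline is testable without any data download.

## Worked example

The package ships an eleven-variant fixture of key pathogenic, likely
pathogenic and predicted deleterious findings (six *SCN10A*, and one each
of *ANK2*, *KCNQ1*, *LDLR*, *SCN5A*, *TRPM4*); `table2_observations()`
expands the recurrent *TRPM4* frameshift to its two carriers:

```r
library(raretriage)

obs  <- table2_observations()            # 12 observations, 11 distinct
casc <- run_cascade(obs)                 # panel / region / rarity cascade
cl   <- classify_cohort(casc$candidates) # consensus + classification
summarize_cohort(cl, nrow(obs))
#> Cohort summary: 12 candidate observation(s) ( 11 distinct ) across 6 gene(s) of 12 ingested
#>   by class: B=0, LB=0, VUS=0, D=9, LP=2, P=1
#>   by panel: FH=1, CA=11, PAH=0
#>   novel: 5 (42%)
```

One pathogenic call (the *LDLR* missense variant, whose composite `P/LP`
ClinVar assertion resolves to P on a damaging consensus), two likely
pathogenic (*KCNQ1* and *SCN5A*, both US-vs-`LP/P` conflicts, downgraded
to LP regardless of their opposite in-silico verdicts), and nine predicted
deleterious observations with no clinical record — five of them novel
*SCN10A* variants. Descriptive over-representation of the candidate genes
against the shipped cardiac term-gene map:

```r
gmt <- read_gmt(system.file("extdata", "cardio_terms.gmt", package = "raretriage"))
ora(unique(cl$gene_symbol), gmt)
#> # A tibble: 15 x 9  (top row)
#> term_id    term_name            k     K     N p_raw p_adj
#> GO:0030001 metal ion transport  5    12    17 0.395 0.703
```

(With only six candidate genes against a 17-gene map universe nothing is
significant — the ORA stage is descriptive annotation, as it must be for
pre-selected panel genes.)

A command-line wrapper is installed at `inst/scripts/raretriage`:

```sh
Rscript inst/scripts/raretriage triage --tsv table2.tsv --out out/
Rscript inst/scripts/raretriage simulate --n 8251 --seed 1 --spike-table2 --out sim/
Rscript inst/scripts/raretriage ora --genes KCNQ1,SCN5A --gmt terms.gmt --out ora.tsv
```

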