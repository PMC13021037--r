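# Filter cascade: panel-gene restriction, region/impact filter, two-stage
# allele-frequency rarity filter, novelty determination.

#' Load a gene-to-panel map
#'
#' Reads a two-column TSV (`gene`, `panel`) assigning each gene to exactly
#' one of the FH, CA or PAH panels. `#` lines are comments. A gene appearing
#' under two different panels is a configuration error: the candidate
#' tallies downstream assume exclusive assignment.
#'
#' @param path Path to the panel TSV; default is the shipped 23-gene map.
#' @return A tibble with columns `gene` and `panel`.
#' @export
load_panel_map <- function(path = NULL) {
  path <- path %||% sysfile("panel_genes.tsv")
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(c("gene", "panel") %in% names(df))) {
    stop("panel map needs columns gene and panel", call. = FALSE)
  }
  if (!all(df$panel %in% c("FH", "CA", "PAH"))) {
    stop("panel must be one of FH, CA, PAH", call. = FALSE)
  }
  key <- toupper(df$gene)
  dup <- unique(key[duplicated(key)])
  for (g in dup) {
    if (length(unique(df$panel[key == g])) > 1) {
      stop("gene ", g, " is assigned to more than one panel; ",
           "exclusive assignment is required", call. = FALSE)
    }
  }
  tibble::as_tibble(df[!duplicated(key), c("gene", "panel")])
}

#' Panel assignment for a gene symbol
#'
#' @param gene_symbol Character vector of gene symbols; matching is
#'   case-insensitive.
#' @param panel_map Tibble from [load_panel_map()].
#' @return Character vector of panels (`FH`, `CA`, `PAH`) with `NA` for
#'   genes on no panel (such variants are excluded by the cascade).
#' @export
assign_panel <- function(gene_symbol, panel_map = load_panel_map()) {
  panel_map$panel[match(toupper(gene_symbol), toupper(panel_map$gene))]
}

#' Region and impact filter
#'
#' TRUE iff the canonical consequence has HIGH or MODERATE VEP impact and at
#' least one consequence term is a protein-coding-region or canonical
#' splice-site term (see [coding_terms()]).
#'
#' @param consequence_terms List of character vectors (or a single character
#'   vector) of SO terms.
#' @param impact Character vector of VEP impact categories.
#' @param terms Membership list of qualifying SO terms.
#' @return Logical vector.
#' @export
region_impact_pass <- function(consequence_terms, impact,
                               terms = coding_terms()) {
  if (!is.list(consequence_terms)) {
    consequence_terms <- list(consequence_terms)
  }
  coding <- vapply(consequence_terms, function(tt) any(tt %in% terms),
                   logical(1))
  impact %in% c("HIGH", "MODERATE") & coding
}

#' PopMax allele frequency
#'
#' Maximum allele frequency over the stored subpopulation frequencies;
#' 0 when none are stored, so that variants absent from the reference
#' cohorts (novel variants in particular) pass the rarity filter.
#'
#' @param subpop_afs A named numeric vector of subpopulation allele
#'   frequencies, or a list of such vectors.
#' @return Numeric vector of PopMax values.
#' @export
popmax_af <- function(subpop_afs) {
  if (!is.list(subpop_afs)) subpop_afs <- list(subpop_afs)
  vapply(subpop_afs, function(a) {
    a <- a[!is.na(a)]
    if (length(a) == 0) 0 else max(a)
  }, numeric(1))
}

#' Two-stage allele-frequency rarity filter
#'
#' Stage one retains variants whose global frequencies (1000 Genomes,
#' gnomAD exomes, gnomAD genomes) are each absent or at most `common_cutoff`
#' (1% by default, inclusive). Stage two requires PopMax AF strictly below
#' `popmax_cutoff` (0.1% by default) across all stored gnomAD
#' subpopulations. A missing frequency is absent, not zero, and passes both
#' stages: variants never observed in the reference cohorts are retained.
#'
#' @param af_1000g,gnomad_exome_af,gnomad_genome_af Numeric vectors of
#'   global allele frequencies (`NA` = absent).
#' @param subpop_afs List of named numeric subpopulation AF vectors.
#' @param common_cutoff Inclusive global-frequency cutoff, in (0, 1].
#' @param popmax_cutoff Strict PopMax cutoff, in [0, 1]; 0 is a degenerate
#'   bound that no variant passes.
#' @return Logical vector (`stage1 & stage2`); the stages are also
#'   available separately via attributes `af1pct` and `popmax`.
#' @export
rarity_pass <- function(af_1000g, gnomad_exome_af, gnomad_genome_af,
                        subpop_afs, common_cutoff = 0.01,
                        popmax_cutoff = 0.001) {
  stopifnot(common_cutoff > 0, common_cutoff <= 1,
            popmax_cutoff >= 0, popmax_cutoff <= 1)
  le_or_absent <- function(x) is.na(x) | x <= common_cutoff
  s1 <- le_or_absent(af_1000g) & le_or_absent(gnomad_exome_af) &
    le_or_absent(gnomad_genome_af)
  s2 <- popmax_af(subpop_afs) < popmax_cutoff
  out <- s1 & s2
  attr(out, "af1pct") <- s1
  attr(out, "popmax") <- s2
  out
}

#' Novelty of a variant observation
#'
#' A variant is novel iff none of its external identifiers is a dbSNP
#' (`rs...`) or COSMIC (`COSV...`/`COSM...`) identifier.
#'
#' @param external_ids List of character vectors of identifiers.
#' @return Logical vector.
#' @export
is_novel <- function(external_ids) {
  if (!is.list(external_ids)) external_ids <- list(external_ids)
  !vapply(external_ids, function(ids) {
    any(grepl("^rs[0-9]+$", ids)) || any(grepl("^COS[VM][0-9]+$", ids))
  }, logical(1))
}

#' Run the four-stage triage cascade
#'
#' Evaluates panel restriction, region/impact, the 1% global-frequency
#' screen and the PopMax screen for every variant (all four stages are
#' evaluated for the audit trace; there is no short-circuiting) and returns
#' the candidates together with the complete per-variant filter trace.
#'
#' @param variants Annotated variant tibble ([parse_vep_vcf()] /
#'   [parse_annotation_tsv()]).
#' @param panel_map Tibble from [load_panel_map()].
#' @param common_cutoff,popmax_cutoff Rarity cutoffs, see [rarity_pass()].
#' @param terms Coding/splice term membership, see [region_impact_pass()].
#' @return A list with `candidates` (input rows passing all stages, plus a
#'   `panel` column) and `trace` (one row per input observation with the
#'   stage booleans and the first rejecting stage, `NA` if none).
#' @export
run_cascade <- function(variants, panel_map = load_panel_map(),
                        common_cutoff = 0.01, popmax_cutoff = 0.001,
                        terms = coding_terms()) {
  panel <- assign_panel(variants$gene_symbol, panel_map)
  panel_pass <- !is.na(panel)
  region_pass <- region_impact_pass(variants$consequence_terms,
                                    variants$impact, terms)
  rp <- rarity_pass(variants$af_1000g, variants$gnomad_exome_af,
                    variants$gnomad_genome_af, variants$subpop_afs,
                    common_cutoff, popmax_cutoff)
  af1pct_pass <- as.logical(attr(rp, "af1pct"))
  popmax_pass <- as.logical(attr(rp, "popmax"))
  candidate <- panel_pass & region_pass & af1pct_pass & popmax_pass

  stage_names <- c("panel", "region_impact", "af1pct", "popmax")
  stages <- cbind(panel_pass, region_pass, af1pct_pass, popmax_pass)
  rejected <- apply(!stages, 1, function(f) {
    if (any(f)) stage_names[which(f)[1]] else NA_character_
  })
  if (nrow(variants) == 0) rejected <- character(0)

  trace <- tibble::tibble(
    sample_id = variants$sample_id, chrom = variants$chrom,
    pos = variants$pos, ref = variants$ref, alt = variants$alt,
    gene_symbol = variants$gene_symbol,
    panel_pass = panel_pass, region_impact_pass = region_pass,
    af1pct_pass = af1pct_pass, popmax_pass = popmax_pass,
    candidate = candidate, rejected_stage = rejected
  )
  candidates <- variants[candidate, , drop = FALSE]
  candidates$panel <- panel[candidate]
  list(candidates = candidates, trace = trace)
}
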