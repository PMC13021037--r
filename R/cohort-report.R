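# Cohort-level summarisation and export, plus the command-line entry point.

CLASS_LABELS <- c("B", "LB", "VUS", "D", "LP", "P")

count_by <- function(x, levels) {
  t <- table(factor(x, levels = levels))
  stats::setNames(as.integer(t), levels)
}

variant_key <- function(x) {
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

category_of <- function(consequence_terms, cat_map = consequence_categories()) {
  vapply(consequence_terms, function(tt) {
    hit <- cat_map[tt]
    hit <- hit[!is.na(hit)]
    if (length(hit) == 0) "other" else hit[[1]]
  }, character(1))
}

#' Summarise a classified candidate cohort
#'
#' Tallies classified candidate observations by interpreted class, panel,
#' consequence category, impact and gene, plus novelty counts. Class
#' tallies are observation-level (a recurrent variant counts once per
#' carrier); companion distinct-variant tallies (keyed on
#' chrom:pos:ref:alt) are included so both readings of recurrence are
#' checkable.
#'
#' @param classified Tibble from [classify_cohort()] (needs `label`,
#'   `panel`, `novel` columns).
#' @param all_variants_count Total number of ingested variant observations
#'   before filtering (defaults to the candidate count).
#' @param cat_map Consequence term-to-category map
#'   ([consequence_categories()]).
#' @return A `cohort_summary` list with counts, fractions and
#'   display-rounded percentages.
#' @export
summarize_cohort <- function(classified,
                             all_variants_count = nrow(classified),
                             cat_map = consequence_categories()) {
  n <- nrow(classified)
  by_class <- count_by(classified$label, CLASS_LABELS)
  panel <- if ("panel" %in% names(classified)) classified$panel else
    rep(NA_character_, n)
  by_panel <- count_by(panel, c("FH", "CA", "PAH"))
  cats <- unique(c(unname(cat_map), "other"))
  by_consequence <- count_by(category_of(classified$consequence_terms,
                                         cat_map), cats)
  by_impact <- count_by(classified$impact, IMPACT_LEVELS)
  burden <- sort(table(classified$gene_symbol), decreasing = TRUE)
  n_novel <- sum(classified$novel)

  keys <- variant_key(classified)
  first <- !duplicated(keys)
  by_class_distinct <- count_by(classified$label[first], CLASS_LABELS)

  out <- list(
    n_total_variants = as.integer(all_variants_count),
    n_candidates = as.integer(n),
    n_genes_with_candidates =
      length(unique(classified$gene_symbol[!is.na(classified$gene_symbol)])),
    by_class = as.list(by_class),
    by_panel = as.list(by_panel),
    by_consequence = as.list(by_consequence),
    by_impact = as.list(by_impact),
    gene_burden = as.list(stats::setNames(as.integer(burden),
                                          names(burden))),
    n_novel = as.integer(n_novel),
    novel_fraction = if (n > 0) n_novel / n else 0,
    n_distinct_variants = as.integer(sum(first)),
    by_class_distinct = as.list(by_class_distinct),
    display = list(
      pct_by_class = as.list(round(100 * by_class / max(n, 1))),
      pct_novel = round(100 * (if (n > 0) n_novel / n else 0))
    )
  )
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary:", x$n_candidates, "candidate observation(s) (",
      x$n_distinct_variants, "distinct ) across",
      x$n_genes_with_candidates, "gene(s) of", x$n_total_variants,
      "ingested\n")
  cat("  by class:",
      paste(names(x$by_class), unlist(x$by_class), sep = "=",
            collapse = ", "), "\n")
  cat("  by panel:",
      paste(names(x$by_panel), unlist(x$by_panel), sep = "=",
            collapse = ", "), "\n")
  cat("  novel:", x$n_novel, sprintf("(%d%%)\n", x$display$pct_novel))
  invisible(x)
}

fmt_num <- function(x) ifelse(is.na(x), "", sprintf("%.10g", x))

#' Export classified candidates, summary and filter trace
#'
#' Writes `candidates.tsv` (one row per classified observation, re-readable
#' by [parse_annotation_tsv()]), `summary.json` and `filter_trace.tsv`
#' (stage booleans as 0/1) into `out_dir`. Output bytes are stable for a
#' fixed input.
#'
#' @param summary A [summarize_cohort()] result.
#' @param classified Tibble from [classify_cohort()].
#' @param trace Filter trace tibble from [run_cascade()] (optional).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
export_cohort <- function(summary, classified, trace = NULL, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    stop("cannot create output directory ", out_dir, call. = FALSE)
  }
  flat <- tibble::tibble(
    sample_id = classified$sample_id, chrom = classified$chrom,
    pos = classified$pos, ref = classified$ref, alt = classified$alt,
    variant_id = vapply(classified$external_ids, encode_ids, character(1)),
    zygosity = classified$zygosity,
    transcript_id = classified$transcript_id,
    gene = classified$gene_symbol,
    consequence = vapply(classified$consequence_terms, paste,
                         character(1), collapse = "&"),
    impact = classified$impact,
    canonical = as.integer(classified$canonical),
    hgvs_c = classified$hgvs_c, hgvs_p = classified$hgvs_p,
    af_1000g = fmt_num(classified$af_1000g),
    gnomad_exome_af = fmt_num(classified$gnomad_exome_af),
    gnomad_genome_af = fmt_num(classified$gnomad_genome_af),
    subpop_afs = vapply(classified$subpop_afs, encode_subpops,
                        character(1)),
    sift = classified$sift, polyphen = classified$polyphen,
    fathmm = classified$fathmm,
    mutation_taster = classified$mutation_taster,
    mutation_assessor = classified$mutation_assessor,
    provean = classified$provean,
    cadd_phred = fmt_num(classified$cadd_phred),
    sift_indel = classified$sift_indel,
    clinvar = classified$clinvar, uniprot = classified$uniprot
  )
  extra <- intersect(c("panel", "verdict", "n_damaging", "n_called",
                       "outcome", "label", "novel"), names(classified))
  for (e in extra) flat[[e]] <- classified[[e]]

  cand_path <- file.path(out_dir, "candidates.tsv")
  readr::write_tsv(flat, cand_path, na = "", progress = FALSE)

  json_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(unclass(summary), json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  paths <- c(candidates = cand_path, summary = json_path)
  if (!is.null(trace)) {
    tr <- trace
    for (b in c("panel_pass", "region_impact_pass", "af1pct_pass",
                "popmax_pass", "candidate")) {
      tr[[b]] <- as.integer(tr[[b]])
    }
    trace_path <- file.path(out_dir, "filter_trace.tsv")
    readr::write_tsv(tr, trace_path, na = "", progress = FALSE)
    paths <- c(paths, trace = trace_path)
  }
  invisible(paths)
}

# ---- command-line entry point ----

cli_usage <- function() {
  paste(
    "usage: raretriage <triage|simulate|ora> [options]",
    "",
    "triage   --vcf FILE | --tsv FILE   input annotations",
    "         [--panels FILE] [--csq-map FILE] [--sample-id ID]",
    "         [--common-af 0.01] [--popmax-af 0.001]",
    "         [--cadd 20] [--min-tools 3] --out DIR",
    "simulate --n N --seed S [--spike-table2] --out DIR",
    "ora      --genes G1,G2,... --gmt FILE [--background FILE]",
    "         [--correction BH|bonferroni] --out FILE",
    sep = "\n"
  )
}

cli_opt <- function(argv, flag, default = NULL) {
  i <- which(argv == flag)
  if (length(i) == 0) return(default)
  if (i[1] == length(argv)) stop("missing value for ", flag, call. = FALSE)
  argv[i[1] + 1]
}

cli_flag <- function(argv, flag) any(argv == flag)

#' Command-line entry point
#'
#' Implements the `triage`, `simulate` and `ora` subcommands used by the
#' installed `raretriage` script. Returns (rather than calls `quit()` with)
#' the exit code: 0 on success, 2 on a usage or configuration error.
#'
#' @param argv Character vector of command-line arguments (excluding the
#'   program name).
#' @return Integer exit code, invisibly.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  code <- tryCatch({
    if (length(argv) == 0) {
      message(cli_usage())
      return(invisible(2L))
    }
    sub <- argv[1]
    argv <- argv[-1]
    known <- c("--vcf", "--tsv", "--panels", "--csq-map", "--sample-id",
               "--common-af", "--popmax-af", "--cadd", "--min-tools",
               "--out", "--n", "--seed", "--spike-table2", "--genes",
               "--gmt", "--background", "--correction", "--log-level")
    flags <- argv[startsWith(argv, "--")]
    if (length(setdiff(flags, known)) > 0 || !sub %in%
        c("triage", "simulate", "ora")) {
      message(cli_usage())
      return(invisible(2L))
    }
    switch(sub,
      triage = cli_triage(argv),
      simulate = cli_simulate(argv),
      ora = cli_ora(argv)
    )
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(code)
}

cli_triage <- function(argv) {
  vcf <- cli_opt(argv, "--vcf")
  tsv <- cli_opt(argv, "--tsv")
  out <- cli_opt(argv, "--out")
  if ((is.null(vcf) && is.null(tsv)) || is.null(out)) {
    message(cli_usage())
    return(2L)
  }
  panel_map <- load_panel_map(cli_opt(argv, "--panels"))
  variants <- if (!is.null(vcf)) {
    parse_vep_vcf(vcf, sample_id = cli_opt(argv, "--sample-id"),
                  csq_map = cli_opt(argv, "--csq-map"))
  } else {
    parse_annotation_tsv(tsv)
  }
  casc <- run_cascade(
    variants, panel_map,
    common_cutoff = as.numeric(cli_opt(argv, "--common-af", "0.01")),
    popmax_cutoff = as.numeric(cli_opt(argv, "--popmax-af", "0.001"))
  )
  classified <- classify_cohort(
    casc$candidates,
    min_tools = as.integer(cli_opt(argv, "--min-tools", "3")),
    cadd_cutoff = as.numeric(cli_opt(argv, "--cadd", "20"))
  )
  summ <- summarize_cohort(classified, nrow(variants))
  export_cohort(summ, classified, casc$trace, out)
  message(nrow(classified), " candidate(s) written to ", out)
  0L
}

cli_simulate <- function(argv) {
  n <- cli_opt(argv, "--n")
  seed <- cli_opt(argv, "--seed")
  out <- cli_opt(argv, "--out")
  if (is.null(n) || is.null(seed) || is.null(out)) {
    message(cli_usage())
    return(2L)
  }
  cfg <- generator_config(as.integer(n), as.integer(seed),
                          spike_table2 = cli_flag(argv, "--spike-table2"))
  res <- generate_cohort(cfg, out)
  message("wrote ", res$vcf)
  0L
}

cli_ora <- function(argv) {
  genes <- cli_opt(argv, "--genes")
  gmt <- cli_opt(argv, "--gmt")
  out <- cli_opt(argv, "--out")
  if (is.null(genes) || is.null(gmt) || is.null(out)) {
    message(cli_usage())
    return(2L)
  }
  gene_set <- if (file.exists(genes)) readLines(genes) else
    strsplit(genes, ",", fixed = TRUE)[[1]]
  bg <- cli_opt(argv, "--background")
  background <- if (is.null(bg)) "map-universe" else readLines(bg)
  res <- ora(trimws(gene_set), read_gmt(gmt), background,
             correction = cli_opt(argv, "--correction", "BH"))
  res$hit_genes <- vapply(res$hit_genes, paste, character(1),
                          collapse = ",")
  readr::write_tsv(res, out, progress = FALSE)
  message(nrow(res), " term(s) written to ", out)
  0L
}
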