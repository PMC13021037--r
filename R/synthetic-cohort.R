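# Seeded generator of VEP-annotated synthetic cohorts with the statistical
# structure the triage pipeline assumes: consequence/impact mixtures,
# multi-source allele frequencies with subpopulation scatter, correlated
# in-silico tool calls driven by a latent deleteriousness state, clinical
# assertion injection, and optional spike-in of the shipped key-variant
# fixture. Every variant is emitted with its latent truth record so that
# recovery can be tested end-to-end.

# Terms drawn within the "other" mixture category, with relative weights
# chosen so that high-impact non-frameshift terms stay rare and the
# moderate-impact remainder (in-frame indels, protein-altering) is a small
# minority, as in exome-wide consequence profiles.
OTHER_TERMS <- c(
  stop_gained = 0.0014, splice_donor_variant = 0.0007,
  splice_acceptor_variant = 0.0007, inframe_deletion = 0.034,
  inframe_insertion = 0.027, protein_altering_variant = 0.032,
  splice_region_variant = 0.21, upstream_gene_variant = 0.34,
  downstream_gene_variant = 0.33,
  non_coding_transcript_exon_variant = 0.0242
)

TERM_BY_CATEGORY <- list(
  intronic = "intron_variant", synonymous = "synonymous_variant",
  missense = "missense_variant", UTR3 = "3_prime_UTR_variant",
  UTR5 = "5_prime_UTR_variant", frameshift = "frameshift_variant"
)

IMPACT_BY_TERM <- c(
  missense_variant = "MODERATE", inframe_deletion = "MODERATE",
  inframe_insertion = "MODERATE", protein_altering_variant = "MODERATE",
  frameshift_variant = "HIGH", stop_gained = "HIGH",
  splice_donor_variant = "HIGH", splice_acceptor_variant = "HIGH",
  synonymous_variant = "LOW", splice_region_variant = "LOW",
  intron_variant = "MODIFIER", `3_prime_UTR_variant` = "MODIFIER",
  `5_prime_UTR_variant` = "MODIFIER", upstream_gene_variant = "MODIFIER",
  downstream_gene_variant = "MODIFIER",
  non_coding_transcript_exon_variant = "MODIFIER"
)

#' Synthetic cohort generator configuration
#'
#' Defaults encode the study conditions the generator emulates: an
#' exome-wide consequence mixture dominated by intronic (37%) and
#' synonymous (20%) variants with a 12% missense share, a 2% novelty rate,
#' allele-frequency strata spanning common to never-observed, sparse
#' clinical assertion injection, and a latent deleteriousness state that
#' drives correlated tool calls and CADD scores.
#'
#' @param n_variants Number of variant records to generate.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param consequence_mixture Named category-to-probability vector over
#'   `intronic`, `synonymous`, `missense`, `UTR3`, `UTR5`, `frameshift`,
#'   `other`; must sum to 1.
#' @param novelty_rate Fraction of variants with no dbSNP/COSMIC identifier
#'   (novel variants also carry no reference allele frequencies).
#' @param af_strata Named weights over the frequency strata `common`
#'   (AF ~ U(0.01, 0.5)), `rare` (U(0.001, 0.01)), `ultra_rare`
#'   (U(0, 0.001)) and `absent`.
#' @param clinical_injection Named per-level probabilities that a clinical
#'   source asserts that level on a coding variant; the remainder is
#'   absent.
#' @param deleterious_latent Probability that a coding variant is latently
#'   damaging.
#' @param tool_reliability Probability that each tool call, the CADD side
#'   of the cutoff, and the SIFT-indel call agree with the latent state.
#' @param tool_call_rate Probability that each missense tool is callable.
#' @param n_samples Number of cohort samples carrying the variants.
#' @param subpops Subpopulation codes receiving scattered AFs.
#' @param spike_table2 Append the shipped key-variant fixture (the
#'   recurrent TRPM4 frameshift to two carriers)?
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(
    n_variants, seed,
    consequence_mixture = c(intronic = 0.37, synonymous = 0.20,
                            missense = 0.12, UTR3 = 0.145, UTR5 = 0.017,
                            frameshift = 0.0022, other = 0.1458),
    novelty_rate = 0.02,
    af_strata = c(common = 0.60, rare = 0.20, ultra_rare = 0.15,
                  absent = 0.05),
    clinical_injection = c(P = 0.001, P_LP = 0.001, LP = 0.002,
                           US = 0.010, LB = 0.003, B_LB = 0.001,
                           B = 0.002),
    deleterious_latent = 0.05,
    tool_reliability = 0.9,
    tool_call_rate = 0.95,
    n_samples = 28,
    subpops = c("AFR", "AMR", "EAS", "NFE", "SAS", "FIN", "ASJ", "OTH"),
    spike_table2 = FALSE) {
  cfg <- list(
    n_variants = as.integer(n_variants), seed = as.integer(seed),
    consequence_mixture = consequence_mixture,
    novelty_rate = novelty_rate, af_strata = af_strata,
    clinical_injection = clinical_injection,
    deleterious_latent = deleterious_latent,
    tool_reliability = tool_reliability,
    tool_call_rate = tool_call_rate,
    n_samples = as.integer(n_samples), subpops = subpops,
    spike_table2 = isTRUE(spike_table2)
  )
  if (cfg$n_variants < 0) stop("n_variants must be >= 0", call. = FALSE)
  need <- c("intronic", "synonymous", "missense", "UTR3", "UTR5",
            "frameshift", "other")
  if (!setequal(names(consequence_mixture), need)) {
    stop("consequence_mixture must cover exactly: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (abs(sum(consequence_mixture) - 1) > 1e-9) {
    stop("consequence_mixture probabilities must sum to 1", call. = FALSE)
  }
  rates <- c(novelty_rate, deleterious_latent, tool_reliability,
             tool_call_rate, clinical_injection, af_strata)
  if (any(rates < 0 | rates > 1)) {
    stop("all rates must lie in [0, 1]", call. = FALSE)
  }
  if (sum(clinical_injection) > 1) {
    stop("clinical_injection probabilities must sum to at most 1",
         call. = FALSE)
  }
  structure(cfg, class = "generator_config")
}

csq_fields_for <- function(subpops) {
  c("Allele", "Consequence", "IMPACT", "SYMBOL", "Feature", "CANONICAL",
    "HGVSc", "HGVSp", "Existing_variation", "AF", "gnomADe_AF",
    "gnomADg_AF", sprintf("gnomADe_%s_AF", subpops),
    "SIFT", "PolyPhen", "FATHMM", "MutationTaster", "MutationAssessor",
    "PROVEAN", "CADD_PHRED", "SIFT_indel", "ClinVar_CLNSIG", "UniProtVar")
}

fmt_af <- function(x) ifelse(is.na(x), "", sprintf("%.6g", x))

draw_cat <- function(n, weights) {
  if (n == 0) return(character(0))
  sample(names(weights), n, replace = TRUE, prob = unname(weights))
}

# Native-vocabulary damaging / tolerated call for each missense tool.
TOOL_NATIVE <- list(
  sift = c(damaging = "deleterious", tolerated = "tolerated"),
  polyphen = c(damaging = "probably_damaging", tolerated = "benign"),
  fathmm = c(damaging = "D", tolerated = "T"),
  mutation_taster = c(damaging = "D", tolerated = "N"),
  mutation_assessor = c(damaging = "M", tolerated = "L"),
  provean = c(damaging = "D", tolerated = "N")
)

#' Generate a synthetic annotated cohort
#'
#' Writes a VEP-style annotated VCF (v4.2, self-describing CSQ header,
#' per-sample genotype columns) and a tab-separated truth table carrying
#' each variant's latent state: intended candidacy, intended consensus
#' verdict and intended interpreted label. Output is deterministic for a
#' fixed seed: all draws come from one seeded stream consumed in a fixed
#' vectorised order, so insertion order cannot perturb downstream draws.
#'
#' @param config A [generator_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `vcf` and `truth` file paths and the
#'   in-memory `truth` tibble.
#' @export
generate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "generator_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")

  n <- config$n_variants
  panel_map <- load_panel_map()
  genes <- c(panel_map$gene, sprintf("DECOY%02d", 1:20))
  samples <- sprintf("S%02d", seq_len(config$n_samples))

  cat_draw <- draw_cat(n, config$consequence_mixture)
  term <- character(n)
  is_other <- cat_draw == "other"
  term[!is_other] <- unlist(TERM_BY_CATEGORY[cat_draw[!is_other]],
                            use.names = FALSE)
  term[is_other] <- draw_cat(sum(is_other), OTHER_TERMS)
  impact <- unname(IMPACT_BY_TERM[term])

  gene <- if (n > 0) sample(genes, n, replace = TRUE) else character(0)
  pos <- if (n > 0) sample.int(500000L, n, replace = TRUE) else integer(0)
  bases <- c("A", "C", "G", "T")
  ref <- if (n > 0) sample(bases, n, replace = TRUE) else character(0)
  alt <- vapply(seq_len(n), function(i) {
    sample(setdiff(bases, ref[i]), 1)
  }, character(1))
  # ref-anchored indel alleles; frameshift lengths not a multiple of 3
  fs <- term == "frameshift_variant"
  ins <- fs & (stats::runif(n) < 0.5)
  del <- fs & !ins
  tail1 <- if (n > 0) sample(bases, n, replace = TRUE) else character(0)
  alt[ins] <- paste0(ref[ins], tail1[ins])
  ref[del] <- paste0(alt[del], tail1[del])
  inf_ins <- term == "inframe_insertion"
  alt[inf_ins] <- paste0(ref[inf_ins], "AGT")
  inf_del <- term == "inframe_deletion"
  ref[inf_del] <- paste0(alt[inf_del], "AGT")
  alt[inf_del] <- substr(ref[inf_del], 1, 1)

  novel <- stats::runif(n) < config$novelty_rate
  ids <- ifelse(novel, ".", sprintf("rs%d", 100000000L + seq_len(n)))

  stratum <- draw_cat(n, config$af_strata)
  stratum[novel] <- "absent"
  u <- stats::runif(n)
  global_af <- rep(NA_real_, n)
  global_af[stratum == "common"] <- 0.01 + 0.49 * u[stratum == "common"]
  global_af[stratum == "rare"] <- 0.001 + 0.009 * u[stratum == "rare"]
  global_af[stratum == "ultra_rare"] <- 0.001 * u[stratum == "ultra_rare"]
  gnomad_e <- global_af
  gnomad_g <- global_af * stats::runif(n, 0.8, 1.2)
  af_1000g <- ifelse(stratum %in% c("common", "rare"),
                     pmin(1, global_af * stats::runif(n, 0.7, 1.3)),
                     NA_real_)
  n_sub <- length(config$subpops)
  sub_mat <- matrix(NA_real_, n, n_sub)
  has_af <- !is.na(global_af)
  scatter <- matrix(exp(stats::rnorm(n * n_sub, 0, 0.3)), n, n_sub)
  sub_mat[has_af, ] <- pmin(1, global_af[has_af] * scatter[has_af, ])

  coding <- term %in% c("missense_variant", "inframe_insertion",
                        "inframe_deletion", "protein_altering_variant",
                        "frameshift_variant", TRUNCATING_TERMS)
  latent <- coding & (stats::runif(n) < config$deleterious_latent)

  rel <- config$tool_reliability
  missense_like <- term %in% c("missense_variant", "inframe_insertion",
                               "inframe_deletion",
                               "protein_altering_variant")
  tool_calls <- lapply(MISSENSE_TOOLS, function(tl) {
    called <- missense_like & (stats::runif(n) < config$tool_call_rate)
    damaging <- ifelse(latent, stats::runif(n) < rel,
                       stats::runif(n) >= rel)
    out <- rep("", n)
    nat <- TOOL_NATIVE[[tl]]
    out[called] <- ifelse(damaging[called], nat[["damaging"]],
                          nat[["tolerated"]])
    out
  })
  names(tool_calls) <- MISSENSE_TOOLS

  cadd_hi <- ifelse(latent, stats::runif(n) < rel, stats::runif(n) >= rel)
  cadd <- rep(NA_real_, n)
  cadd[coding] <- ifelse(cadd_hi[coding],
                         20 + 25 * stats::runif(sum(coding)),
                         3 + 16.9 * stats::runif(sum(coding)))
  noncoding_scored <- !coding & (stats::runif(n) < 0.2)
  cadd[noncoding_scored] <- 15 * stats::runif(sum(noncoding_scored))

  indel_like <- term %in% c("frameshift_variant", INFRAME_TERMS)
  si_damaging <- ifelse(latent, stats::runif(n) < rel,
                        stats::runif(n) >= rel)
  sift_indel <- rep("", n)
  sift_indel[indel_like] <- ifelse(si_damaging[indel_like], "damaging",
                                   "neutral")

  inj <- config$clinical_injection
  draw_clin <- function() {
    w <- c(inj, absent = 1 - sum(inj))
    lv <- draw_cat(n, w)
    ifelse(lv == "absent" | !coding, "", lv)
  }
  clinvar <- draw_clin()
  uniprot <- draw_clin()

  carrier <- if (n > 0) sample.int(config$n_samples, n, replace = TRUE)
             else integer(0)
  hom <- stats::runif(n) < 0.05

  # intended (latent-truth) consensus verdict and label
  route <- ifelse(term %in% TRUNCATING_TERMS, "truncating",
                  ifelse(indel_like, "indel",
                         ifelse(missense_like, "missense", "none")))
  intended_verdict <- ifelse(route == "none", "U",
                             ifelse(latent, "D", "N"))
  resolved <- resolve_clinical(norm_clin_level(ifelse(clinvar == "",
                                                      NA, clinvar)),
                               norm_clin_level(ifelse(uniprot == "",
                                                      NA, uniprot)),
                               intended_verdict)
  intended_label <- classify_variant(resolved$outcome, intended_verdict)

  on_panel <- !is.na(assign_panel(gene, panel_map))
  subpop_list <- lapply(seq_len(n), function(i) {
    v <- sub_mat[i, ]
    stats::setNames(v, config$subpops)[!is.na(v)]
  })
  rare_ok <- as.logical(rarity_pass(af_1000g, gnomad_e, gnomad_g,
                                    subpop_list))
  region_ok <- impact %in% c("HIGH", "MODERATE") &
    term %in% coding_terms()
  intended_candidate <- on_panel & region_ok & rare_ok

  truth <- tibble::tibble(
    chrom = gene, pos = pos, ref = ref, alt = alt, gene = gene,
    sample_id = samples[carrier], variant_id = ids,
    consequence = term, impact = impact, category = cat_draw,
    novel = as.integer(novel), latent_deleterious = as.integer(latent),
    intended_candidate = as.integer(intended_candidate),
    intended_verdict = intended_verdict, intended_label = intended_label,
    spiked = 0L
  )

  csq_fields <- csq_fields_for(config$subpops)
  sub_txt <- apply(sub_mat, 1, function(v) {
    paste(fmt_af(v), collapse = "|")
  })
  if (n == 0) sub_txt <- character(0)
  csq <- paste(
    alt, term, impact, gene, sprintf("TX_%s.1", gene), "YES",
    sprintf("c.%d%s>%s", pos, substr(ref, 1, 1), substr(alt, 1, 1)), "",
    "", fmt_af(af_1000g), fmt_af(gnomad_e), fmt_af(gnomad_g), sub_txt,
    tool_calls$sift, tool_calls$polyphen, tool_calls$fathmm,
    tool_calls$mutation_taster, tool_calls$mutation_assessor,
    tool_calls$provean, fmt_af(cadd), sift_indel, clinvar, uniprot,
    sep = "|"
  )

  gt <- matrix("0/0", nrow = n, ncol = config$n_samples)
  if (n > 0) {
    gt[cbind(seq_len(n), carrier)] <- ifelse(hom, "1/1", "0/1")
  }

  body <- if (n > 0) {
    paste(gene, pos, ids, ref, alt, ".", "PASS",
          paste0("CSQ=", csq), "GT",
          do.call(paste, c(as.data.frame(gt, stringsAsFactors = FALSE),
                           sep = "\t")),
          sep = "\t")
  } else character(0)

  spike <- NULL
  if (config$spike_table2) {
    spike <- spike_records(samples, csq_fields)
    body <- c(body, spike$lines)
    truth <- dplyr::bind_rows(truth, spike$truth)
  }

  contigs <- unique(c(gene, if (!is.null(spike)) spike$chroms))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=raretriage-synthetic-cohort",
    sprintf("##contig=<ID=%s>", sort(contigs)),
    paste0("##INFO=<ID=CSQ,Number=.,Type=String,Description=\"",
           "Consequence annotations from Ensembl VEP. Format: ",
           paste(csq_fields, collapse = "|"), "\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t")
  )

  vcf_path <- file.path(out_dir, "cohort.vcf")
  truth_path <- file.path(out_dir, "truth.tsv")
  writeLines(c(header, body), vcf_path, sep = "\n")
  readr::write_tsv(truth, truth_path, progress = FALSE)
  invisible(list(vcf = vcf_path, truth_path = truth_path, truth = truth))
}

# VCF lines + truth rows for the shipped key-variant fixture; the recurrent
# TRPM4 frameshift is assigned to two carriers.
spike_records <- function(samples, csq_fields) {
  fx <- table2_fixture()
  expected <- c("D", "LP", "P", "D", "D", "D", "D", "D", "D", "LP", "D")
  n <- nrow(fx)
  ns <- length(samples)
  carrier_idx <- ((seq_len(n) - 1L) %% ns) + 1L
  lines <- character(n)
  chroms <- character(n)
  truth_rows <- vector("list", n)
  for (i in seq_len(n)) {
    r <- fx[i, ]
    sp <- r$subpop_afs[[1]]
    sub_txt <- vapply(sub("^gnomADe_([A-Z]{3})_AF$", "\\1",
                          grep("^gnomADe_[A-Z]{3}_AF$", csq_fields,
                               value = TRUE)),
                      function(code) {
                        if (code %in% names(sp)) sprintf("%.6g", sp[[code]])
                        else ""
                      }, character(1))
    fmt1 <- function(x) if (is.na(x)) "" else sprintf("%.6g", x)
    chr1 <- function(x) if (is.na(x)) "" else x
    csq <- paste(
      r$alt, paste(r$consequence_terms[[1]], collapse = "&"), r$impact,
      r$gene_symbol, r$transcript_id, "YES", chr1(r$hgvs_c),
      chr1(r$hgvs_p), encode_ids(r$external_ids[[1]]),
      fmt1(r$af_1000g), fmt1(r$gnomad_exome_af), fmt1(r$gnomad_genome_af),
      paste(sub_txt, collapse = "|"),
      chr1(r$sift), chr1(r$polyphen), chr1(r$fathmm),
      chr1(r$mutation_taster), chr1(r$mutation_assessor), chr1(r$provean),
      fmt1(r$cadd_phred), chr1(r$sift_indel),
      chr1(r$clinvar), chr1(r$uniprot),
      sep = "|"
    )
    gt <- rep("0/0", ns)
    is_trpm4 <- r$gene_symbol == "TRPM4"
    carriers <- if (is_trpm4) {
      c(carrier_idx[i], (carrier_idx[i] %% ns) + 1L)
    } else carrier_idx[i]
    gt[carriers] <- "0/1"
    id <- if (length(r$external_ids[[1]]) == 0) "." else
      encode_ids(r$external_ids[[1]])
    lines[i] <- paste(c(r$chrom, r$pos, id, r$ref, r$alt, ".", "PASS",
                        paste0("CSQ=", csq), "GT", gt), collapse = "\t")
    chroms[i] <- r$chrom
    truth_rows[[i]] <- tibble::tibble(
      chrom = r$chrom, pos = r$pos, ref = r$ref, alt = r$alt,
      gene = r$gene_symbol, sample_id = samples[carriers[1]],
      variant_id = id, consequence = r$consequence_terms[[1]][1],
      impact = r$impact, category = NA_character_,
      novel = as.integer(length(r$external_ids[[1]]) == 0),
      latent_deleterious = 1L, intended_candidate = 1L,
      intended_verdict = if (expected[i] == "LP" &&
                             r$gene_symbol == "SCN5A") "N" else "D",
      intended_label = expected[i], spiked = 1L
    )
  }
  list(lines = lines, truth = dplyr::bind_rows(truth_rows),
       chroms = unique(chroms))
}
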