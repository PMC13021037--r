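# In-code fixtures: minimal VEP-annotated VCF text and independent oracles.

`%||%` <- function(x, y) if (is.null(x)) y else x

MINI_CSQ_FIELDS <- c(
  "Allele", "Consequence", "IMPACT", "SYMBOL", "Feature", "CANONICAL",
  "HGVSc", "HGVSp", "Existing_variation", "AF", "gnomADe_AF",
  "gnomADg_AF", "gnomADe_NFE_AF", "gnomADe_AFR_AF",
  "SIFT", "PolyPhen", "FATHMM", "MutationTaster", "MutationAssessor",
  "PROVEAN", "CADD_PHRED", "SIFT_indel", "ClinVar_CLNSIG", "UniProtVar"
)

mini_vcf_header <- function(samples = NULL) {
  h <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr19>", "##contig=<ID=chr3>",
    paste0("##INFO=<ID=CSQ,Number=.,Type=String,Description=\"",
           "Consequence annotations from Ensembl VEP. Format: ",
           paste(MINI_CSQ_FIELDS, collapse = "|"), "\">")
  )
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (!is.null(samples)) {
    h <- c(h, "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">")
    cols <- c(cols, "FORMAT", samples)
  }
  c(h, paste(cols, collapse = "\t"))
}

# Build a CSQ block from a named list over MINI_CSQ_FIELDS.
mini_csq <- function(...) {
  vals <- list(...)
  paste(vapply(MINI_CSQ_FIELDS, function(f) {
    v <- vals[[f]]
    if (is.null(v)) "" else as.character(v)
  }, character(1)), collapse = "|")
}

write_mini_vcf <- function(body, samples = NULL,
                           path = tempfile(fileext = ".vcf")) {
  writeLines(c(mini_vcf_header(samples), body), path)
  path
}

# ---- independent oracles ----

# Brute-force canonical-consequence selection: filter to flagged entries
# (all entries when none flagged), then scan every entry keeping the best
# by severity then transcript id.
oracle_select_canonical <- function(df) {
  sev <- c(HIGH = 1, MODERATE = 2, LOW = 3, MODIFIER = 4)
  pool <- df[df$canonical %in% TRUE, , drop = FALSE]
  if (nrow(pool) == 0) pool <- df
  best <- 1
  for (i in seq_len(nrow(pool))) {
    si <- sev[[pool$impact[i]]]
    sb <- sev[[pool$impact[best]]]
    if (si < sb || (si == sb && pool$transcript_id[i] <
                    pool$transcript_id[best])) {
      best <- i
    }
  }
  pool[best, , drop = FALSE]
}

# Literal transcription of the classification decision rules, case by case.
oracle_label <- function(cv, up, v) {
  lean <- function(l) {
    if (is.na(l)) return("absent")
    if (l %in% c("P", "LP", "P_LP")) return("path")
    if (l %in% c("B", "LB", "B_LB")) return("benign")
    if (l == "US") return("us")
    "conflicting"
  }
  comp <- function(l) {
    if (identical(l, "P_LP")) return(if (v == "D") "P" else "LP")
    if (identical(l, "B_LB")) return(if (v == "N") "B" else "LB")
    l
  }
  rank <- c(B = 1, LB = 2, US = 3, LP = 4, P = 5)
  out <- if (lean(cv) == "conflicting" || lean(up) == "conflicting") {
    "conflict"
  } else if (is.na(cv) && is.na(up)) {
    "none"
  } else if (is.na(up)) {
    comp(cv)
  } else if (is.na(cv)) {
    comp(up)
  } else {
    a <- comp(cv); b <- comp(up)
    if (a == b) a
    else {
      la <- lean(cv); lb <- lean(up)
      if ((la == "us" && lb == "path") || (lb == "us" && la == "path")) {
        "LP"
      } else if ((la == "us" && lb == "benign") ||
                 (lb == "us" && la == "benign")) {
        "LB"
      } else if (la != lb) {
        "conflict"
      } else if (rank[[a]] >= rank[[b]]) a else b
    }
  }
  if (out %in% c("P", "LP", "LB", "B")) out
  else if (out %in% c("US", "conflict")) "VUS"
  else if (v == "D") "D"
  else "VUS"
}

# Stated missense consensus predicate, evaluated directly.
oracle_missense_verdict <- function(calls, cadd, min_tools = 3,
                                    cutoff = 20) {
  nd <- sum(calls == "damaging")
  nc <- sum(calls != "absent")
  if (!is.na(cadd) && cadd >= cutoff && nd >= min_tools) return("D")
  if (!is.na(cadd) && cadd < cutoff && nd < min_tools && nc >= min_tools) {
    return("N")
  }
  "U"
}

# One-row annotated tibble for consensus tests.
consensus_row <- function(terms, impact, sift = NA, polyphen = NA,
                          fathmm = NA, mutation_taster = NA,
                          mutation_assessor = NA, provean = NA,
                          cadd = NA_real_, sift_indel = NA) {
  tibble::tibble(
    consequence_terms = list(terms), impact = impact,
    sift = as.character(sift), polyphen = as.character(polyphen),
    fathmm = as.character(fathmm),
    mutation_taster = as.character(mutation_taster),
    mutation_assessor = as.character(mutation_assessor),
    provean = as.character(provean), cadd_phred = cadd,
    sift_indel = as.character(sift_indel)
  )
}

# Exhaustive hypergeometric upper-tail probability by enumerating every
# candidate draw of size n from a background of size N.
oracle_enum_pval <- function(N, K, n, k) {
  if (n == 0) return(if (k == 0) 1 else 0)
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(d) sum(d <= K)) >= k)
}

expected_table2_labels <- function() {
  c(ANK2 = "D", KCNQ1 = "LP", LDLR = "P", SCN10A = "D", SCN5A = "LP",
    TRPM4 = "D")
}
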