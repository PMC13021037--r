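# Domain model: one row per variant observation joined to its selected
# canonical transcript consequence, allele frequencies, in-silico
# predictions and clinical assertions.

ANNOTATED_COLS <- c(
  "sample_id", "chrom", "pos", "ref", "alt", "external_ids", "zygosity",
  "transcript_id", "gene_symbol", "consequence_terms", "impact", "canonical",
  "hgvs_c", "hgvs_p",
  "af_1000g", "gnomad_exome_af", "gnomad_genome_af", "subpop_afs",
  "sift", "polyphen", "fathmm", "mutation_taster", "mutation_assessor",
  "provean", "cadd_phred", "sift_indel",
  "clinvar", "uniprot"
)

# Default binding of VEP CSQ subfield names to model roles. `subpop_pattern`
# is a regex with one capture group extracting the subpopulation code.
default_csq_map <- function() {
  list(
    allele = "Allele", consequence = "Consequence", impact = "IMPACT",
    symbol = "SYMBOL", feature = "Feature", canonical = "CANONICAL",
    hgvs_c = "HGVSc", hgvs_p = "HGVSp", existing = "Existing_variation",
    af_1000g = "AF", gnomad_exome_af = "gnomADe_AF",
    gnomad_genome_af = "gnomADg_AF",
    subpop_pattern = "^gnomADe_([A-Z]{3})_AF$",
    sift = "SIFT", polyphen = "PolyPhen", fathmm = "FATHMM",
    mutation_taster = "MutationTaster",
    mutation_assessor = "MutationAssessor", provean = "PROVEAN",
    cadd_phred = "CADD_PHRED", sift_indel = "SIFT_indel",
    clinvar = "ClinVar_CLNSIG", uniprot = "UniProtVar"
  )
}

#' Select the canonical transcript consequence
#'
#' Reduces the per-transcript consequences of one variant allele to the
#' single consequence used downstream: the one flagged canonical; among
#' several canonical flags the most severe impact (HIGH > MODERATE > LOW >
#' MODIFIER) wins, ties broken by lexicographically smallest transcript id.
#' When no consequence is flagged canonical the same severity-then-id rule
#' is applied over all entries, with a warning.
#'
#' @param consequences Data frame with one row per transcript consequence;
#'   needs columns `transcript_id`, `impact` and logical `canonical`.
#' @return The selected one-row data frame.
#' @export
select_canonical <- function(consequences) {
  if (!is.data.frame(consequences) || nrow(consequences) == 0) {
    stop("empty consequence list: annotation is corrupt", call. = FALSE)
  }
  flagged <- consequences[consequences$canonical %in% TRUE, , drop = FALSE]
  if (nrow(flagged) == 0) {
    warning("no consequence flagged canonical; falling back to ",
            "severity-then-transcript-id selection", call. = FALSE)
    flagged <- consequences
  }
  ord <- order(impact_rank(flagged$impact), flagged$transcript_id)
  flagged[ord[1L], , drop = FALSE]
}

# ---- small codecs shared by the TSV ingest/export round trip ----

encode_subpops <- function(afs) {
  if (length(afs) == 0) return("")
  afs <- afs[order(names(afs))]
  paste(sprintf("%s:%.10g", names(afs), unname(afs)), collapse = ",")
}

decode_subpops <- function(s) {
  if (is.na(s) || !nzchar(s) || s %in% c("-", ".")) {
    return(stats::setNames(numeric(0), character(0)))
  }
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
  stats::setNames(vapply(parts, function(p) as.numeric(p[2]), numeric(1)),
                  vapply(parts, `[`, character(1), 1))
}

encode_ids <- function(ids) paste(ids, collapse = ";")

decode_ids <- function(s) {
  if (is.na(s)) return(character(0))
  ids <- strsplit(s, "[;&]")[[1]]
  ids <- trimws(ids)
  ids[nzchar(ids) & !(ids %in% c("-", ".")) & tolower(ids) != "novel"]
}

# Normalise a printed clinical assertion level to the internal vocabulary;
# absent markers map to NA, unrecognised tokens map to NA with a warning.
norm_clin_level <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    u <- toupper(trimws(s))
    if (u %in% c("", "-", ".", "NA")) return(NA_character_)
    u <- gsub("/", "_", u)
    out <- switch(u,
      B = "B", LB = "LB", US = "US", VUS = "US", LP = "LP", P = "P",
      B_LB = "B_LB", LB_B = "B_LB", P_LP = "P_LP", LP_P = "P_LP",
      BENIGN = "B", LIKELY_BENIGN = "LB", PATHOGENIC = "P",
      LIKELY_PATHOGENIC = "LP", UNCERTAIN_SIGNIFICANCE = "US",
      CONFLICTING = "conflicting",
      NA_character_)
    if (is.na(out)) {
      warning("unrecognised clinical assertion level: ", s, call. = FALSE)
    }
    out
  }, character(1), USE.NAMES = FALSE)
}

# AF token -> numeric fraction; non-empty unparseable tokens become absent
# with a warning (never silently zero).
parse_af <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  has <- !is.na(x) & nzchar(x) & !(x %in% c("-", "."))
  val <- suppressWarnings(as.numeric(x[has]))
  bad <- is.na(val)
  if (any(bad)) {
    warning("unparseable allele-frequency token(s) treated as absent: ",
            paste(unique(x[has][bad]), collapse = ", "), call. = FALSE)
  }
  out[has] <- val
  out
}

chr_or_na <- function(x) {
  x <- trimws(as.character(x))
  ifelse(is.na(x) | !nzchar(x) | x %in% c("-", "."), NA_character_, x)
}

# Assemble the canonical annotated-variant tibble from parallel lists and
# enforce the model invariants.
build_annotated <- function(rows) {
  f <- function(field, how) {
    switch(how,
      chr = vapply(rows, function(r) r[[field]] %||% NA_character_,
                   character(1)),
      num = vapply(rows, function(r) r[[field]] %||% NA_real_, numeric(1)),
      int = vapply(rows, function(r) r[[field]] %||% NA_integer_,
                   integer(1)),
      lgl = vapply(rows, function(r) r[[field]] %||% NA, logical(1)),
      lst = lapply(rows, function(r) r[[field]])
    )
  }
  out <- tibble::tibble(
    sample_id = f("sample_id", "chr"), chrom = f("chrom", "chr"),
    pos = f("pos", "int"), ref = f("ref", "chr"), alt = f("alt", "chr"),
    external_ids = f("external_ids", "lst"),
    zygosity = f("zygosity", "chr"),
    transcript_id = f("transcript_id", "chr"),
    gene_symbol = f("gene_symbol", "chr"),
    consequence_terms = f("consequence_terms", "lst"),
    impact = f("impact", "chr"), canonical = f("canonical", "lgl"),
    hgvs_c = f("hgvs_c", "chr"), hgvs_p = f("hgvs_p", "chr"),
    af_1000g = f("af_1000g", "num"),
    gnomad_exome_af = f("gnomad_exome_af", "num"),
    gnomad_genome_af = f("gnomad_genome_af", "num"),
    subpop_afs = f("subpop_afs", "lst"),
    sift = f("sift", "chr"), polyphen = f("polyphen", "chr"),
    fathmm = f("fathmm", "chr"),
    mutation_taster = f("mutation_taster", "chr"),
    mutation_assessor = f("mutation_assessor", "chr"),
    provean = f("provean", "chr"), cadd_phred = f("cadd_phred", "num"),
    sift_indel = f("sift_indel", "chr"),
    clinvar = f("clinvar", "chr"), uniprot = f("uniprot", "chr")
  )
  validate_annotated(out)
  out
}

empty_annotated <- function() build_annotated(list())

# Invariant checks on the annotated-variant table.
validate_annotated <- function(x) {
  stopifnot(identical(names(x), ANNOTATED_COLS))
  if (nrow(x) == 0) return(invisible(x))
  if (any(x$pos < 1L, na.rm = TRUE)) stop("pos must be >= 1", call. = FALSE)
  if (any(!nzchar(x$ref) | !nzchar(x$alt) | x$ref == x$alt)) {
    stop("ref and alt must be non-empty and differ", call. = FALSE)
  }
  if (!all(x$impact %in% IMPACT_LEVELS)) {
    stop("impact outside {HIGH, MODERATE, LOW, MODIFIER}", call. = FALSE)
  }
  if (any(lengths(x$consequence_terms) == 0)) {
    stop("consequence_terms must be non-empty", call. = FALSE)
  }
  afs <- c(x$af_1000g, x$gnomad_exome_af, x$gnomad_genome_af,
           unlist(x$subpop_afs, use.names = FALSE))
  if (any(afs < 0 | afs > 1, na.rm = TRUE)) {
    stop("allele frequencies must lie in [0, 1]", call. = FALSE)
  }
  if (any(x$cadd_phred < 0, na.rm = TRUE)) {
    stop("cadd_phred must be non-negative", call. = FALSE)
  }
  if (!all(x$zygosity %in% ZYGOSITY_LEVELS)) {
    stop("zygosity outside {het, hom, unknown}", call. = FALSE)
  }
  invisible(x)
}

#' Parse a VEP-annotated VCF into annotated variant observations
#'
#' Reads a VCF whose INFO field carries pipe-delimited per-transcript VEP
#' annotations (the `CSQ` field), decomposes multi-allelic records, selects
#' the canonical transcript consequence per allele, and emits one row per
#' (carrier sample, alternate allele). When the file has genotype columns,
#' observations are derived from the carriers (`0/1` het, `1/1` hom);
#' otherwise a single observation per allele is emitted under `sample_id`.
#'
#' Records whose allele has no consequence block are skipped with a warning;
#' the number skipped is available as `attr(result, "n_skipped")`.
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @param csq_spec Ordered character vector of CSQ subfield names. Default:
#'   read from the file's own `##INFO=<ID=CSQ...>` header description;
#'   missing both is a configuration error.
#' @param sample_id Observation label used when the VCF has no genotype
#'   columns.
#' @param csq_map Named list (or path to a YAML file) overriding the default
#'   binding of CSQ subfield names to model fields; see
#'   `raretriage:::default_csq_map()` for the recognised roles.
#' @return A tibble of annotated variant observations.
#' @export
parse_vep_vcf <- function(path, csq_spec = NULL, sample_id = NULL,
                          csq_map = NULL) {
  if (is.character(csq_map) && length(csq_map) == 1) {
    csq_map <- yaml::read_yaml(csq_map)
  }
  map <- utils::modifyList(default_csq_map(), csq_map %||% list())
  v <- vcfR::read.vcfR(path, verbose = FALSE)

  if (is.null(csq_spec)) {
    meta <- v@meta
    line <- grep("^##INFO=<ID=CSQ[,>]", meta, value = TRUE)
    if (length(line) == 0) {
      stop("no CSQ INFO header in ", path,
           " and no csq_spec override supplied", call. = FALSE)
    }
    fmt <- sub('.*Format: ?([^">]*).*', "\\1", line[1])
    csq_spec <- strsplit(fmt, "|", fixed = TRUE)[[1]]
  }

  n_rec <- nrow(v@fix)
  if (is.null(n_rec) || n_rec == 0) {
    out <- empty_annotated()
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  fix <- v@fix
  info <- fix[, "INFO"]
  m <- regexpr("(^|;)CSQ=[^;]*", info)
  csq_str <- rep(NA_character_, n_rec)
  hit <- m > 0
  csq_str[hit] <- sub("^;?CSQ=", "",
                      regmatches(info, m))
  blocks <- strsplit(csq_str, ",", fixed = TRUE)
  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)

  gt <- v@gt
  has_gt <- !is.null(gt) && ncol(gt) > 1
  if (has_gt) {
    samples <- colnames(gt)[-1]
    cells <- strsplit(sub(":.*", "", as.vector(gt[, -1, drop = FALSE])),
                      "[/|]")
    gt_alleles <- lapply(cells, function(g) suppressWarnings(as.integer(g)))
    # column-major: cell (record r, sample s) = [[ (s - 1) * n_rec + r ]]
  }

  subpop_idx <- grep(map$subpop_pattern, csq_spec)
  subpop_codes <- sub(map$subpop_pattern, "\\1", csq_spec[subpop_idx])
  roles <- setdiff(names(map), "subpop_pattern")
  role_idx <- vapply(roles, function(role) match(map[[role]], csq_spec),
                     integer(1))
  fld <- function(block_fields, role) {
    i <- role_idx[[role]]
    if (is.na(i) || i > length(block_fields)) return(NA_character_)
    chr_or_na(block_fields[i])
  }

  rows <- vector("list", 0)
  n_skipped <- 0L
  for (r in seq_len(n_rec)) {
    rec_blocks <- if (is.na(csq_str[r])) list() else
      lapply(blocks[[r]], function(b) strsplit(b, "|", fixed = TRUE)[[1]])
    for (k in seq_along(alts[[r]])) {
      alt_k <- alts[[r]][k]
      use <- rec_blocks
      if (length(rec_blocks) > 0 && length(alts[[r]]) > 1) {
        al <- vapply(rec_blocks, fld, character(1), role = "allele")
        use <- rec_blocks[!is.na(al) & al == alt_k]
      }
      if (length(use) == 0) {
        n_skipped <- n_skipped + 1L
        next
      }
      cons <- tibble::tibble(
        transcript_id = vapply(use, fld, character(1), role = "feature"),
        impact = vapply(use, fld, character(1), role = "impact"),
        canonical = vapply(use, function(b) {
          isTRUE(fld(b, "canonical") %in% c("YES", "1", "TRUE"))
        }, logical(1)),
        idx = seq_along(use)
      )
      sel <- use[[suppressWarnings(select_canonical(cons))$idx]]

      terms <- strsplit(fld(sel, "consequence") %||% NA_character_,
                        "&", fixed = TRUE)[[1]]
      terms <- terms[!is.na(terms) & nzchar(terms)]
      sp <- vapply(subpop_idx, function(i) {
        if (i > length(sel)) NA_real_ else parse_af(sel[i])
      }, numeric(1))
      names(sp) <- subpop_codes
      sp <- sp[!is.na(sp)]

      ids <- decode_ids(chr_or_na(fix[r, "ID"]))
      ids <- union(ids, decode_ids(fld(sel, "existing")))

      base <- list(
        chrom = fix[r, "CHROM"], pos = as.integer(fix[r, "POS"]),
        ref = fix[r, "REF"], alt = alt_k, external_ids = ids,
        transcript_id = fld(sel, "feature"),
        gene_symbol = fld(sel, "symbol"),
        consequence_terms = terms,
        impact = fld(sel, "impact"),
        canonical = TRUE,
        hgvs_c = fld(sel, "hgvs_c"), hgvs_p = fld(sel, "hgvs_p"),
        af_1000g = parse_af(fld(sel, "af_1000g")),
        gnomad_exome_af = parse_af(fld(sel, "gnomad_exome_af")),
        gnomad_genome_af = parse_af(fld(sel, "gnomad_genome_af")),
        subpop_afs = sp,
        sift = fld(sel, "sift"), polyphen = fld(sel, "polyphen"),
        fathmm = fld(sel, "fathmm"),
        mutation_taster = fld(sel, "mutation_taster"),
        mutation_assessor = fld(sel, "mutation_assessor"),
        provean = fld(sel, "provean"),
        cadd_phred = parse_af(fld(sel, "cadd_phred")),
        sift_indel = fld(sel, "sift_indel"),
        clinvar = norm_clin_level(fld(sel, "clinvar")),
        uniprot = norm_clin_level(fld(sel, "uniprot"))
      )
      if (has_gt) {
        for (s in seq_along(samples)) {
          a <- gt_alleles[[(s - 1L) * n_rec + r]]
          if (!any(a %in% k)) next
          row <- base
          row$sample_id <- samples[s]
          row$zygosity <- if (length(a) >= 2 && all(a == k)) "hom" else "het"
          rows[[length(rows) + 1L]] <- row
        }
      } else {
        base$sample_id <- sample_id %||% "sample"
        base$zygosity <- "unknown"
        rows[[length(rows) + 1L]] <- base
      }
    }
  }
  if (n_skipped > 0) {
    warning(n_skipped, " allele record(s) without a consequence block ",
            "were skipped", call. = FALSE)
  }
  out <- build_annotated(rows)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Parse a flattened annotation TSV into annotated variant observations
#'
#' Alternate, flattened input: one row per variant observation with the
#' annotations already joined (the format written by [export_cohort()], and
#' of the shipped key-variant fixture). Columns `gene`, `consequence` and
#' `impact` are mandatory; every other model field defaults to absent when
#' its column is missing.
#'
#' @param path Path to a UTF-8, tab-delimited file with a header row;
#'   `#` lines are comments.
#' @param column_map Named character vector mapping model fields to file
#'   column names, overriding the defaults (which expect the exported
#'   column names).
#' @return A tibble of annotated variant observations.
#' @export
parse_annotation_tsv <- function(path, column_map = NULL) {
  df <- utils::read.delim(path, comment.char = "#", sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", na.strings = NULL)
  cmap <- c(
    sample_id = "sample_id", chrom = "chrom", pos = "pos", ref = "ref",
    alt = "alt", external_ids = "variant_id", zygosity = "zygosity",
    transcript_id = "transcript_id", gene_symbol = "gene",
    consequence_terms = "consequence", impact = "impact",
    canonical = "canonical", hgvs_c = "hgvs_c", hgvs_p = "hgvs_p",
    af_1000g = "af_1000g", gnomad_exome_af = "gnomad_exome_af",
    gnomad_genome_af = "gnomad_genome_af", subpop_afs = "subpop_afs",
    sift = "sift", polyphen = "polyphen", fathmm = "fathmm",
    mutation_taster = "mutation_taster",
    mutation_assessor = "mutation_assessor", provean = "provean",
    cadd_phred = "cadd_phred", sift_indel = "sift_indel",
    clinvar = "clinvar", uniprot = "uniprot"
  )
  if (!is.null(column_map)) cmap[names(column_map)] <- unlist(column_map)
  mandatory <- c("gene_symbol", "consequence_terms", "impact")
  missing_cols <- setdiff(cmap[mandatory], names(df))
  if (length(missing_cols) > 0) {
    stop("mandatory column(s) missing from ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  col <- function(field) {
    nm <- cmap[[field]]
    if (!is.null(nm) && nm %in% names(df)) df[[nm]] else
      rep(NA_character_, nrow(df))
  }
  n <- nrow(df)
  if (n == 0) {
    out <- empty_annotated()
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  pos <- suppressWarnings(as.integer(col("pos")))
  rows <- lapply(seq_len(n), function(i) {
    zyg <- chr_or_na(col("zygosity")[i])
    list(
      sample_id = chr_or_na(col("sample_id")[i]) %||% sprintf("S%03d", i),
      chrom = chr_or_na(col("chrom")[i]) %||% "chrUn",
      pos = if (is.na(pos[i])) i else pos[i],
      ref = chr_or_na(col("ref")[i]) %||% "N",
      alt = chr_or_na(col("alt")[i]) %||% "A",
      external_ids = decode_ids(col("external_ids")[i]),
      zygosity = if (is.na(zyg) || !(zyg %in% ZYGOSITY_LEVELS)) "unknown"
                 else zyg,
      transcript_id = chr_or_na(col("transcript_id")[i]),
      gene_symbol = chr_or_na(col("gene_symbol")[i]),
      consequence_terms = {
        t <- strsplit(col("consequence_terms")[i], "[&,]")[[1]]
        trimws(t[nzchar(trimws(t))])
      },
      impact = chr_or_na(col("impact")[i]),
      canonical = chr_or_na(col("canonical")[i]) %in% c("1", "TRUE", "YES"),
      hgvs_c = chr_or_na(col("hgvs_c")[i]),
      hgvs_p = chr_or_na(col("hgvs_p")[i]),
      af_1000g = parse_af(col("af_1000g")[i]),
      gnomad_exome_af = parse_af(col("gnomad_exome_af")[i]),
      gnomad_genome_af = parse_af(col("gnomad_genome_af")[i]),
      subpop_afs = decode_subpops(col("subpop_afs")[i]),
      sift = chr_or_na(col("sift")[i]),
      polyphen = chr_or_na(col("polyphen")[i]),
      fathmm = chr_or_na(col("fathmm")[i]),
      mutation_taster = chr_or_na(col("mutation_taster")[i]),
      mutation_assessor = chr_or_na(col("mutation_assessor")[i]),
      provean = chr_or_na(col("provean")[i]),
      cadd_phred = suppressWarnings(
        as.numeric(chr_or_na(col("cadd_phred")[i]) %||% NA_character_)),
      sift_indel = chr_or_na(col("sift_indel")[i]),
      clinvar = norm_clin_level(chr_or_na(col("clinvar")[i])),
      uniprot = norm_clin_level(chr_or_na(col("uniprot")[i]))
    )
  })
  out <- build_annotated(rows)
  attr(out, "n_skipped") <- 0L
  out
}

#' Shipped key-variant fixture
#'
#' Loads the package's fixture of eleven key pathogenic, likely pathogenic
#' and predicted deleterious variants (one row per distinct variant).
#'
#' @return A tibble of 11 annotated variant observations.
#' @export
table2_fixture <- function() {
  parse_annotation_tsv(sysfile("table2_variants.tsv"))
}

#' Key-variant fixture at observation level
#'
#' As [table2_fixture()], but with the recurrent TRPM4 frameshift duplicated
#' to its two carriers, giving the 12 observation-level records used for
#' cohort tallies.
#'
#' @return A tibble of 12 annotated variant observations.
#' @export
table2_observations <- function() {
  x <- table2_fixture()
  trpm4 <- x[x$gene_symbol == "TRPM4", , drop = FALSE]
  trpm4$sample_id <- "P10"
  dplyr::bind_rows(x, trpm4)
}
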