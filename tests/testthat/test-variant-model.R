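test_that("select_canonical honours the canonical flag and severity order", {
  cons <- tibble::tibble(
    transcript_id = c("ENST2", "ENST1"),
    impact = c("MODIFIER", "MODERATE"),
    canonical = c(FALSE, TRUE)
  )
  expect_equal(select_canonical(cons)$transcript_id, "ENST1")

  two <- tibble::tibble(
    transcript_id = c("ENSTA", "ENSTB"),
    impact = c("LOW", "HIGH"),
    canonical = c(TRUE, TRUE)
  )
  expect_equal(select_canonical(two)$impact, "HIGH")

  expect_error(select_canonical(tibble::tibble()), "empty")
  none <- tibble::tibble(transcript_id = c("T2", "T1"),
                         impact = c("LOW", "LOW"),
                         canonical = c(FALSE, FALSE))
  expect_warning(sel <- select_canonical(none), "canonical")
  expect_equal(sel$transcript_id, "T1")
})

test_that("select_canonical matches a brute-force scan on random lists", {
  set.seed(41)
  for (i in 1:1000) {
    n <- sample(1:6, 1)
    df <- tibble::tibble(
      transcript_id = sample(sprintf("ENST%03d", 1:20), n),
      impact = sample(c("HIGH", "MODERATE", "LOW", "MODIFIER"), n,
                      replace = TRUE),
      canonical = sample(c(TRUE, FALSE), n, replace = TRUE)
    )
    got <- suppressWarnings(select_canonical(df))
    want <- oracle_select_canonical(df)
    expect_identical(got$transcript_id, want$transcript_id)
    # permutation invariance
    perm <- df[sample(nrow(df)), ]
    expect_identical(suppressWarnings(select_canonical(perm))$transcript_id,
                     want$transcript_id)
  }
})

test_that("parse_vep_vcf ingests a missense record with its identifiers", {
  csq <- mini_csq(Allele = "G", Consequence = "missense_variant",
                  IMPACT = "MODERATE", SYMBOL = "LDLR",
                  Feature = "ENST00000558518.6", CANONICAL = "YES",
                  HGVSc = "c.1255T>G", HGVSp = "p.Tyr419Asp",
                  gnomADe_AF = "4e-06", gnomADe_NFE_AF = "8.9e-06",
                  SIFT = "deleterious", PolyPhen = "probably_damaging",
                  CADD_PHRED = "27.5", ClinVar_CLNSIG = "P/LP")
  path <- write_mini_vcf(paste("chr19", 11089432, "rs879254847", "T", "G",
                               ".", "PASS", paste0("CSQ=", csq),
                               sep = "\t"))
  v <- parse_vep_vcf(path, sample_id = "PT1")
  expect_equal(nrow(v), 1)
  expect_equal(v$external_ids[[1]], "rs879254847")
  expect_equal(v$gene_symbol, "LDLR")
  expect_equal(v$consequence_terms[[1]], "missense_variant")
  expect_equal(v$gnomad_exome_af, 4e-06)
  expect_equal(v$subpop_afs[[1]], c(NFE = 8.9e-06))
  expect_equal(v$clinvar, "P_LP")
  expect_true(is.na(v$af_1000g))  # absent, not zero
})

test_that("multi-allelic records decompose into per-allele observations", {
  csq_a <- mini_csq(Allele = "A", Consequence = "missense_variant",
                    IMPACT = "MODERATE", SYMBOL = "SCN5A",
                    Feature = "ENST1", CANONICAL = "YES",
                    CADD_PHRED = "25")
  csq_g <- mini_csq(Allele = "G", Consequence = "synonymous_variant",
                    IMPACT = "LOW", SYMBOL = "SCN5A", Feature = "ENST1",
                    CANONICAL = "YES")
  path <- write_mini_vcf(paste("chr3", 100, ".", "C", "A,G", ".", "PASS",
                               paste0("CSQ=", csq_a, ",", csq_g),
                               sep = "\t"))
  v <- parse_vep_vcf(path)
  expect_equal(nrow(v), 2)
  expect_equal(v$alt, c("A", "G"))
  expect_equal(vapply(v$consequence_terms, `[`, character(1), 1),
               c("missense_variant", "synonymous_variant"))
  expect_equal(v$cadd_phred, c(25, NA))
})

test_that("ingest is loss-aware: emitted + skipped = decomposed records", {
  csq_a <- mini_csq(Allele = "A", Consequence = "missense_variant",
                    IMPACT = "MODERATE", SYMBOL = "KCNQ1",
                    Feature = "ENST1", CANONICAL = "YES")
  body <- c(
    paste("chr3", 100, ".", "C", "A,G", ".", "PASS",
          paste0("CSQ=", csq_a), sep = "\t"),  # G allele unannotated
    paste("chr3", 200, ".", "T", "C", ".", "PASS", ".", sep = "\t")
  )
  path <- write_mini_vcf(body)
  expect_warning(v <- parse_vep_vcf(path), "skipped")
  expect_equal(nrow(v) + attr(v, "n_skipped"), 3)
  expect_equal(attr(v, "n_skipped"), 2)
})

test_that("genotype columns drive observations and zygosity", {
  csq <- mini_csq(Allele = "T", Consequence = "missense_variant",
                  IMPACT = "MODERATE", SYMBOL = "RYR2", Feature = "ENST1",
                  CANONICAL = "YES")
  body <- paste("chr3", 300, ".", "C", "T", ".", "PASS",
                paste0("CSQ=", csq), "GT", "0/1", "1/1", "0/0",
                sep = "\t")
  path <- write_mini_vcf(body, samples = c("S1", "S2", "S3"))
  v <- parse_vep_vcf(path)
  expect_equal(v$sample_id, c("S1", "S2"))
  expect_equal(v$zygosity, c("het", "hom"))
})

test_that("missing CSQ header without an override is a config error", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", "##contig=<ID=chr1>",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO"), collapse = "\t"),
               paste("chr1", 1, ".", "A", "G", ".", ".", "X=1",
                     sep = "\t")), path)
  expect_error(parse_vep_vcf(path), "CSQ")
})

test_that("the shipped fixture loads into the expected 11 records", {
  fx <- table2_fixture()
  expect_equal(nrow(fx), 11)
  expect_setequal(unique(fx$gene_symbol),
                  c("ANK2", "KCNQ1", "LDLR", "SCN10A", "SCN5A", "TRPM4"))
  expect_equal(sum(fx$gene_symbol == "SCN10A"), 6)
  # novel rows have no identifiers and no frequencies
  novel <- lengths(fx$external_ids) == 0
  expect_equal(sum(novel), 5)
  expect_true(all(is.na(fx$gnomad_exome_af[novel])))
  expect_equal(nrow(table2_observations()), 12)
})

test_that("an annotation TSV with only a header yields an empty stream", {
  path <- tempfile(fileext = ".tsv")
  writeLines("gene\tconsequence\timpact", path)
  v <- parse_annotation_tsv(path)
  expect_equal(nrow(v), 0)
  expect_error(
    parse_annotation_tsv({
      p2 <- tempfile(); writeLines("gene\tfoo", p2); p2
    }),
    "mandatory"
  )
})

test_that("exported candidates round-trip through parse_annotation_tsv", {
  cl <- classify_cohort(run_cascade(table2_observations())$candidates)
  out <- tempfile()
  export_cohort(summarize_cohort(cl), cl, out_dir = out)
  back <- parse_annotation_tsv(file.path(out, "candidates.tsv"))
  expect_equal(nrow(back), nrow(cl))
  for (col in c("sample_id", "gene_symbol", "impact", "clinvar", "uniprot",
                "cadd_phred", "sift", "sift_indel", "gnomad_exome_af")) {
    expect_equal(back[[col]], cl[[col]], info = col)
  }
  expect_equal(back$subpop_afs, cl$subpop_afs)
  expect_equal(back$external_ids, cl$external_ids)
  # absent stays absent through the round trip
  expect_true(all(is.na(back$af_1000g) == is.na(cl$af_1000g)))
})

test_that("a generated VCF round-trips against the generator's truth", {
  cfg <- generator_config(100, seed = 7)
  res <- generate_cohort(cfg, tempfile())
  v <- parse_vep_vcf(res$vcf)
  expect_equal(nrow(v), 100)
  tr <- res$truth
  key_v <- paste(v$chrom, v$pos, v$ref, v$alt)
  key_t <- paste(tr$chrom, tr$pos, tr$ref, tr$alt)
  m <- match(key_v, key_t)
  expect_false(anyNA(m))
  expect_equal(vapply(v$consequence_terms, `[`, character(1), 1),
               tr$consequence[m])
  expect_equal(v$impact, tr$impact[m])
  expect_equal(v$gene_symbol, tr$gene[m])
  expect_equal(v$sample_id, tr$sample_id[m])
  expect_equal(unname(is_novel(v$external_ids)),
               as.logical(tr$novel[m]))
})
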