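classified_fixture <- function() {
  casc <- run_cascade(table2_observations())
  list(cl = classify_cohort(casc$candidates), trace = casc$trace)
}

test_that("summaries tally the key-variant observations correctly", {
  cl <- classified_fixture()$cl
  s <- summarize_cohort(cl, all_variants_count = 12)
  expect_equal(s$n_candidates, 12)
  expect_equal(s$by_class$P, 1)
  expect_equal(s$by_class$LP, 2)
  expect_equal(s$by_class$D, 9)
  expect_equal(s$n_distinct_variants, 11)
  expect_equal(s$by_class_distinct$D, 8)
  # invariant: class and panel tallies sum to the candidate count
  expect_equal(sum(unlist(s$by_class)), s$n_candidates)
  expect_equal(sum(unlist(s$by_panel)), s$n_candidates)
  expect_lte(s$n_novel, s$n_candidates)
  expect_equal(s$gene_burden[[1]], 6)  # SCN10A carries the most

  s0 <- summarize_cohort(cl[0, ], all_variants_count = 0)
  expect_equal(s0$n_candidates, 0)
  expect_true(all(unlist(s0$by_class) == 0))
})

test_that("summary tallies agree with an independent one-pass recount", {
  cfg <- generator_config(1200, seed = 17)
  res <- generate_cohort(cfg, tempfile())
  v <- parse_vep_vcf(res$vcf)
  casc <- run_cascade(v)
  cl <- classify_cohort(casc$candidates)
  s <- summarize_cohort(cl, nrow(v))

  counts <- list()
  novel <- 0
  for (i in seq_len(nrow(cl))) {
    lab <- cl$label[i]
    counts[[lab]] <- (counts[[lab]] %||% 0) + 1
    if (isTRUE(cl$novel[i])) novel <- novel + 1
  }
  for (lab in names(counts)) {
    expect_equal(s$by_class[[lab]], counts[[lab]], info = lab)
  }
  expect_equal(s$n_novel, novel)
  pct <- unlist(s$display$pct_by_class)
  recomputed <- round(100 * unlist(s$by_class) / max(s$n_candidates, 1))
  expect_equal(pct, recomputed)
})

test_that("exports are byte-stable and conserve every observation", {
  fx <- classified_fixture()
  s <- summarize_cohort(fx$cl, 12)
  d1 <- tempfile(); d2 <- tempfile()
  export_cohort(s, fx$cl, fx$trace, d1)
  export_cohort(s, fx$cl, fx$trace, d2)
  for (f in c("candidates.tsv", "summary.json", "filter_trace.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  tr <- readr::read_tsv(file.path(d1, "filter_trace.tsv"),
                        show_col_types = FALSE)
  expect_equal(nrow(tr), 12)  # conservation: one row per observation
  key <- paste(tr$sample_id, tr$chrom, tr$pos, tr$ref, tr$alt)
  obs <- table2_observations()
  expect_setequal(key, paste(obs$sample_id, obs$chrom, obs$pos, obs$ref,
                             obs$alt))
})

test_that("re-ingesting exported candidates is a classification fixed point", {
  fx <- classified_fixture()
  out <- tempfile()
  export_cohort(summarize_cohort(fx$cl, 12), fx$cl, fx$trace, out)
  back <- parse_annotation_tsv(file.path(out, "candidates.tsv"))
  cl2 <- classify_cohort(run_cascade(back)$candidates)
  expect_equal(nrow(cl2), nrow(fx$cl))
  expect_equal(sort(cl2$label), sort(fx$cl$label))
})

test_that("the triage subcommand runs end to end from the shell surface", {
  out <- tempfile()
  fixture <- system.file("extdata", "table2_variants.tsv",
                         package = "raretriage")
  code <- suppressMessages(cli_main(c("triage", "--tsv", fixture,
                                      "--out", out)))
  expect_equal(code, 0L)
  cand <- readr::read_tsv(file.path(out, "candidates.tsv"),
                          show_col_types = FALSE)
  expect_equal(nrow(cand), 11)

  expect_equal(suppressMessages(cli_main(c("triage"))), 2L)
  expect_equal(suppressMessages(cli_main(c("triage", "--bogus", "x"))), 2L)
  expect_equal(suppressMessages(cli_main(character(0))), 2L)

  # degenerate strict popmax bound: nothing passes
  out0 <- tempfile()
  code0 <- suppressMessages(cli_main(c("triage", "--tsv", fixture,
                                       "--popmax-af", "0",
                                       "--out", out0)))
  expect_equal(code0, 0L)
  cand0 <- readr::read_tsv(file.path(out0, "candidates.tsv"),
                           show_col_types = FALSE)
  expect_equal(nrow(cand0), 0)
})

test_that("the simulate and ora subcommands work from the shell surface", {
  out <- tempfile()
  expect_equal(suppressMessages(
    cli_main(c("simulate", "--n", "50", "--seed", "3", "--out", out))), 0L)
  expect_true(file.exists(file.path(out, "cohort.vcf")))

  gmt <- system.file("extdata", "cardio_terms.gmt", package = "raretriage")
  res_path <- tempfile(fileext = ".tsv")
  expect_equal(suppressMessages(
    cli_main(c("ora", "--genes", "KCNQ1,SCN5A,KCNH2,LDLR", "--gmt", gmt,
               "--out", res_path))), 0L)
  res <- readr::read_tsv(res_path, show_col_types = FALSE)
  expect_equal(nrow(res), 15)
  expect_true(all(res$p_raw > 0 & res$p_raw <= 1))
})
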