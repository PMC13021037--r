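test_that("tool vocabularies normalise via the shipped table", {
  expect_equal(normalize_call("PolyPhen", "possibly_damaging"), "damaging")
  expect_equal(normalize_call("MutationAssessor", "L"), "tolerated")
  expect_equal(normalize_call("SIFT", NA), "absent")
  expect_warning(out <- normalize_call("SIFT", "weird"), "unrecognised")
  expect_equal(out, "absent")
  expect_error(normalize_call("NotATool", "D"), "unknown prediction tool")

  # every (tool, vocabulary item) pair matches the table read independently
  tab <- yaml::read_yaml(system.file("extdata", "prediction_vocab.yaml",
                                     package = "raretriage"))
  for (tool in names(tab)) {
    for (raw in names(tab[[tool]])) {
      expect_equal(normalize_call(tool, raw), tab[[tool]][[raw]],
                   info = paste(tool, raw))
    }
  }
})

test_that("consensus verdicts follow the three consequence routes", {
  # missense with 4/6 damaging and CADD 25
  r <- consensus_row("missense_variant", "MODERATE", sift = "deleterious",
                     polyphen = "probably_damaging", fathmm = "D",
                     mutation_taster = "D", mutation_assessor = "L",
                     provean = "N", cadd = 25)
  v <- consensus_verdict(r)
  expect_equal(v$verdict, "D")
  expect_equal(v$n_damaging, 4)
  expect_equal(v$n_called, 6)

  # frameshift with damaging SIFT-indel and CADD absent
  fs <- consensus_row("frameshift_variant", "HIGH",
                      sift_indel = "damaging")
  expect_equal(consensus_verdict(fs)$verdict, "D")
  fs_n <- consensus_row("frameshift_variant", "HIGH",
                        sift_indel = "neutral")
  expect_equal(consensus_verdict(fs_n)$verdict, "N")
  fs_u <- consensus_row("frameshift_variant", "HIGH")
  expect_equal(consensus_verdict(fs_u)$verdict, "U")

  # truncating route: CADD alone decides
  expect_equal(consensus_verdict(
    consensus_row("stop_gained", "HIGH", cadd = 38))$verdict, "D")
  expect_equal(consensus_verdict(
    consensus_row("stop_gained", "HIGH", cadd = 12))$verdict, "N")
  expect_equal(consensus_verdict(
    consensus_row("splice_donor_variant", "HIGH"))$verdict, "U")

  # in-frame indel with a SIFT-indel call takes the indel route
  inf <- consensus_row("inframe_deletion", "MODERATE", cadd = 30,
                       sift_indel = "neutral")
  expect_equal(consensus_verdict(inf)$verdict, "N")
})

test_that("missense verdicts match the stated predicate exhaustively", {
  natives <- list(sift = c("deleterious", "tolerated"),
                  polyphen = c("probably_damaging", "benign"),
                  fathmm = c("D", "T"),
                  mutation_taster = c("D", "N"),
                  mutation_assessor = c("M", "L"),
                  provean = c("D", "N"))
  for (mask in 0:63) {
    damaging <- as.logical(bitwAnd(bitwShiftR(mask, 0:5), 1L))
    args <- lapply(seq_along(natives), function(j) {
      natives[[j]][if (damaging[j]) 1 else 2]
    })
    names(args) <- names(natives)
    for (cadd in list(NA_real_, 15, 25)) {
      row <- do.call(consensus_row,
                     c(list(terms = "missense_variant",
                            impact = "MODERATE", cadd = cadd), args))
      calls <- ifelse(damaging, "damaging", "tolerated")
      expect_equal(consensus_verdict(row)$verdict,
                   oracle_missense_verdict(calls, cadd),
                   info = paste(mask, cadd))
    }
  }
})

test_that("the verdict is monotone in tool calls and CADD", {
  set.seed(3)
  natives <- list(sift = c("deleterious", "tolerated"),
                  polyphen = c("probably_damaging", "benign"),
                  fathmm = c("D", "T"),
                  mutation_taster = c("D", "N"),
                  mutation_assessor = c("M", "L"),
                  provean = c("D", "N"))
  rank <- c(N = 1, U = 2, D = 3)
  for (i in 1:100) {
    damaging <- runif(6) < 0.5
    cadd <- sample(c(NA, 10, 19.9, 20, 30), 1)
    mk <- function(dmg, cd) {
      args <- lapply(seq_along(natives), function(j) {
        natives[[j]][if (dmg[j]) 1 else 2]
      })
      names(args) <- names(natives)
      do.call(consensus_row, c(list(terms = "missense_variant",
                                    impact = "MODERATE", cadd = cd), args))
    }
    base <- consensus_verdict(mk(damaging, cadd))$verdict
    # flipping one tolerated call to damaging never demotes D towards N
    j <- which(!damaging)[1]
    if (!is.na(j)) {
      up <- damaging; up[j] <- TRUE
      flipped <- consensus_verdict(mk(up, cadd))$verdict
      if (base == "D") expect_equal(flipped, "D")
      if (flipped == "N") expect_true(base %in% c("N", "U"))
    }
    # raising CADD never demotes D
    if (!is.na(cadd) && base == "D") {
      expect_equal(consensus_verdict(mk(damaging, cadd + 10))$verdict, "D")
    }
  }
})
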