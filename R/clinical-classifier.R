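# Clinical-precedence classification: ClinVar/UniProtVar assertions are
# resolved on the B < LB < US < LP < P lattice (composites P_LP and B_LB
# sit between their endpoints) and mapped, together with the in-silico
# verdict, onto the five interpreted tiers plus the predicted-deleterious
# tier. Clinical data takes precedence over in-silico predictions: the
# consensus verdict is consulted only to resolve composite assertions and,
# failing any clinical evidence, to award the predicted-deleterious label.

clin_leaning <- function(level) {
  if (is.na(level)) return("absent")
  if (level %in% c("LP", "P", "P_LP")) return("path")
  if (level %in% c("B", "LB", "B_LB")) return("benign")
  if (level == "US") return("us")
  "conflicting"
}

resolve_composite <- function(level, verdict) {
  if (is.na(level)) return(level)
  if (level == "P_LP") return(if (verdict == "D") "P" else "LP")
  if (level == "B_LB") return(if (verdict == "N") "B" else "LB")
  level
}

resolve_one <- function(cv, up, verdict) {
  if (clin_leaning(cv) == "conflicting" ||
      clin_leaning(up) == "conflicting") {
    prov <- if (clin_leaning(cv) == "conflicting") "ClinVar" else
      "UniProtVar"
    return(list(outcome = "conflict_benign_vs_path", provenance = prov))
  }
  if (is.na(cv) && is.na(up)) {
    return(list(outcome = "none", provenance = "none"))
  }
  if (is.na(up)) {
    return(list(outcome = resolve_composite(cv, verdict),
                provenance = "ClinVar"))
  }
  if (is.na(cv)) {
    return(list(outcome = resolve_composite(up, verdict),
                provenance = "UniProtVar"))
  }
  rcv <- resolve_composite(cv, verdict)
  rup <- resolve_composite(up, verdict)
  if (rcv == rup) {
    return(list(outcome = rcv, provenance = "both"))
  }
  lcv <- clin_leaning(cv)
  lup <- clin_leaning(up)
  if ((lcv == "us" && lup == "path") || (lup == "us" && lcv == "path")) {
    # uncertainty-vs-pathogenic conflict downgrades to LP; the in-silico
    # verdict is deliberately not consulted here
    return(list(outcome = "LP", provenance = "both"))
  }
  if ((lcv == "us" && lup == "benign") ||
      (lup == "us" && lcv == "benign")) {
    return(list(outcome = "LB", provenance = "both"))
  }
  if (lcv != lup) {
    return(list(outcome = "conflict_benign_vs_path", provenance = "both"))
  }
  # same leaning but unequal after composite resolution: the more severe
  # resolved level wins (keeps the classification monotone on the lattice)
  sev <- if (CLIN_RANK[[rcv]] >= CLIN_RANK[[rup]]) rcv else rup
  list(outcome = sev, provenance = "both")
}

#' Resolve ClinVar and UniProt assertions with clinical precedence
#'
#' Collapses the two clinical sources into one outcome on the lattice
#' B < LB < US < LP < P. Composite assertions are split by the in-silico
#' verdict (`P_LP` is `P` when the verdict is `D`, else `LP`; `B_LB` is `B`
#' when the verdict is `N`, else `LB`). A US assertion against a
#' pathogenic-leaning one resolves to `LP`; against a benign-leaning one to
#' `LB`. A benign-leaning against a pathogenic-leaning assertion, or a
#' `conflicting` record in either source, yields
#' `conflict_benign_vs_path`. Two same-leaning but unequal levels resolve
#' to the more severe.
#'
#' @param clinvar,uniprot Character vectors of assertion levels (`B`,
#'   `B_LB`, `LB`, `US`, `LP`, `P_LP`, `P`, `conflicting`; `NA` = absent).
#' @param verdict Character vector of consensus verdicts (`D`/`N`/`U`).
#' @return A tibble with columns `outcome` (a resolved level, `none`, or
#'   `conflict_benign_vs_path`) and `provenance` (`ClinVar`, `UniProtVar`,
#'   `both`, `none`).
#' @export
resolve_clinical <- function(clinvar, uniprot, verdict) {
  res <- Map(resolve_one, clinvar, uniprot, verdict)
  tibble::tibble(
    outcome = vapply(res, `[[`, character(1), "outcome",
                     USE.NAMES = FALSE),
    provenance = vapply(res, `[[`, character(1), "provenance",
                        USE.NAMES = FALSE)
  )
}

#' Final interpreted classification
#'
#' Maps the clinical resolution and in-silico verdict to the interpreted
#' label: a resolved `P`, `LP`, `LB` or `B` stands as-is; uncertainty
#' (`US`) and cross-source benign-vs-pathogenic conflicts are `VUS`
#' (clinical uncertainty is never overridden by in-silico evidence); with
#' no clinical record at all, a damaging consensus earns the
#' predicted-deleterious label `D` and anything else is `VUS`.
#'
#' @param outcome Character vector of resolution outcomes
#'   ([resolve_clinical()]).
#' @param verdict Character vector of consensus verdicts (`D`/`N`/`U`).
#' @return Character vector over `B`, `LB`, `VUS`, `D`, `LP`, `P`.
#' @export
classify_variant <- function(outcome, verdict) {
  mapply(function(o, v) {
    if (o %in% c("P", "LP", "LB", "B")) return(o)
    if (o == "US" || o == "conflict_benign_vs_path") return("VUS")
    if (v == "D") "D" else "VUS"
  }, outcome, verdict, USE.NAMES = FALSE)
}

#' Classify a stream of triaged candidates
#'
#' Vectorised application of the consensus engine and the clinical
#' classifier: appends the consensus columns, the clinical resolution, the
#' interpreted label and the novelty flag to every candidate row.
#'
#' @param candidates Annotated candidate tibble (e.g. the `candidates`
#'   element of [run_cascade()]).
#' @param min_tools,cadd_cutoff,vocab Consensus parameters, see
#'   [consensus_verdict()].
#' @return The input tibble with columns `verdict`, `n_damaging`,
#'   `n_called`, `cadd_ok`, `outcome`, `provenance`, `label`, `novel`
#'   appended; row order and cardinality are preserved.
#' @export
classify_cohort <- function(candidates, min_tools = 3, cadd_cutoff = 20,
                            vocab = prediction_vocab()) {
  cons <- consensus_verdict(candidates, min_tools, cadd_cutoff, vocab)
  res <- resolve_clinical(candidates$clinvar, candidates$uniprot,
                          cons$verdict)
  out <- dplyr::bind_cols(
    candidates,
    cons[, c("verdict", "n_damaging", "n_called", "cadd_ok")]
  )
  out$outcome <- res$outcome
  out$provenance <- res$provenance
  out$label <- classify_variant(res$outcome, cons$verdict)
  out$novel <- is_novel(candidates$external_ids)
  out
}

#' Full classification decision table
#'
#' Enumerates every (ClinVar level, UniProt level, consensus verdict)
#' combination — nine levels per source including absent, three verdicts —
#' with its resolution and interpreted label, for audit or export.
#'
#' @return A 243-row tibble with columns `clinvar`, `uniprot`, `verdict`,
#'   `outcome`, `provenance`, `label`.
#' @export
decision_table <- function() {
  lv <- c(NA_character_, CLIN_LEVELS)
  grid <- expand.grid(clinvar = lv, uniprot = lv, verdict = c("D", "N", "U"),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  res <- resolve_clinical(grid$clinvar, grid$uniprot, grid$verdict)
  tibble::tibble(
    clinvar = grid$clinvar, uniprot = grid$uniprot, verdict = grid$verdict,
    outcome = res$outcome, provenance = res$provenance,
    label = classify_variant(res$outcome, grid$verdict)
  )
}
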