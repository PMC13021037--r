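# In-silico deleteriousness consensus: per-tool vocabulary normalisation
# and the tri-state verdict (D damaging / N neutral / U undetermined) that
# feeds the classifier.

#' Normalise one tool's native call to the common dichotomy
#'
#' @param tool One of `SIFT`, `PolyPhen`, `FATHMM`, `MutationTaster`,
#'   `MutationAssessor`, `PROVEAN`, `SIFT-indel` (an unknown tool name is an
#'   error).
#' @param raw The tool's native call; vectorised. `NA`, empty, `-` or `.`
#'   are absent; an unrecognised value is absent with a warning.
#' @param vocab Normalisation table from [prediction_vocab()].
#' @return Character vector over `damaging`, `tolerated`, `absent`.
#' @export
normalize_call <- function(tool, raw, vocab = prediction_vocab()) {
  if (!tool %in% names(vocab)) {
    stop("unknown prediction tool: ", tool, call. = FALSE)
  }
  tab <- vocab[[tool]]
  vapply(as.character(raw), function(x) {
    if (is.na(x) || !nzchar(trimws(x)) || trimws(x) %in% c("-", ".")) {
      return("absent")
    }
    hit <- unname(tab[match(trimws(x), names(tab))])
    if (is.na(hit)) {
      warning("unrecognised ", tool, " call '", x, "' treated as absent",
              call. = FALSE)
      return("absent")
    }
    hit
  }, character(1), USE.NAMES = FALSE)
}

# Route a consequence to the applicable consensus rule.
consensus_route <- function(consequence_terms, sift_indel_present) {
  if (any(consequence_terms %in% TRUNCATING_TERMS)) return("truncating")
  if ("frameshift_variant" %in% consequence_terms ||
      (any(consequence_terms %in% INFRAME_TERMS) && sift_indel_present)) {
    return("indel")
  }
  "missense"
}

consensus_one <- function(row, min_tools, cadd_cutoff, vocab) {
  cadd <- row$cadd_phred
  cadd_ok <- if (is.na(cadd)) NA else cadd >= cadd_cutoff
  tool_names <- c(sift = "SIFT", polyphen = "PolyPhen", fathmm = "FATHMM",
                  mutation_taster = "MutationTaster",
                  mutation_assessor = "MutationAssessor",
                  provean = "PROVEAN")
  calls <- vapply(MISSENSE_TOOLS, function(f) {
    normalize_call(tool_names[[f]], row[[f]], vocab)
  }, character(1))
  n_called <- sum(calls != "absent")
  n_damaging <- sum(calls == "damaging")
  si <- normalize_call("SIFT-indel", row$sift_indel, vocab)
  route <- consensus_route(row$consequence_terms[[1]], si != "absent")

  verdict <- switch(route,
    truncating = {
      if (isTRUE(cadd_ok)) "D" else if (isFALSE(cadd_ok)) "N" else "U"
    },
    indel = {
      if (si == "damaging" && (is.na(cadd) || isTRUE(cadd_ok))) "D"
      else if (si == "tolerated") "N"
      else "U"
    },
    missense = {
      if (isTRUE(cadd_ok) && n_damaging >= min_tools) "D"
      else if (isFALSE(cadd_ok) && n_damaging < min_tools &&
               n_called >= min_tools) "N"
      else "U"
    }
  )
  list(verdict = verdict, n_damaging = n_damaging, n_called = n_called,
       cadd_ok = cadd_ok, route = route)
}

#' In-silico deleteriousness consensus verdict
#'
#' Combines the six missense prediction tools, SIFT-indel and the CADD
#' phred score into a tri-state verdict, by consequence route:
#'
#' * missense / in-frame route (the default): `D` iff CADD >=
#'   `cadd_cutoff` **and** at least `min_tools` of the six tools call
#'   damaging; `N` iff CADD is present below the cutoff, fewer than
#'   `min_tools` damaging calls, and at least `min_tools` tools were
#'   callable (no "neutral by missingness"); otherwise `U`.
#' * indel route (frameshift, or in-frame indel with a SIFT-indel call):
#'   `D` iff SIFT-indel is damaging and CADD is absent or above the cutoff;
#'   `N` iff SIFT-indel is neutral; otherwise `U`.
#' * truncating/splice route (stop gained/lost, start lost, canonical
#'   splice): CADD alone decides (most missense tools cannot score these) —
#'   `D` at or above the cutoff, `N` below, `U` when absent.
#'
#' CADD gates the missense route but never votes; `min_tools` counts
#' damaging calls among the six missense tools only.
#'
#' @param variants Annotated variant tibble (or any data frame with the
#'   prediction columns, `cadd_phred`, `sift_indel` and
#'   `consequence_terms`).
#' @param min_tools Minimum damaging tool calls for a missense `D` (and
#'   minimum callable tools for an `N`); default 3.
#' @param cadd_cutoff CADD phred cutoff for deleteriousness; default 20.
#' @param vocab Normalisation table from [prediction_vocab()].
#' @return A tibble with columns `verdict` (`D`/`N`/`U`), `n_damaging`,
#'   `n_called`, `cadd_ok` (logical, `NA` when CADD absent) and `route`.
#' @export
consensus_verdict <- function(variants, min_tools = 3, cadd_cutoff = 20,
                              vocab = prediction_vocab()) {
  n <- nrow(variants)
  res <- lapply(seq_len(n), function(i) {
    consensus_one(variants[i, , drop = FALSE], min_tools, cadd_cutoff,
                  vocab)
  })
  tibble::tibble(
    verdict = vapply(res, `[[`, character(1), "verdict"),
    n_damaging = vapply(res, `[[`, numeric(1), "n_damaging"),
    n_called = vapply(res, `[[`, numeric(1), "n_called"),
    cadd_ok = vapply(res, `[[`, logical(1), "cadd_ok"),
    route = vapply(res, `[[`, character(1), "route")
  )
}
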