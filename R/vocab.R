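# Controlled vocabularies shared across the triage pipeline.

# VEP impact categories, most severe first.
IMPACT_LEVELS <- c("HIGH", "MODERATE", "LOW", "MODIFIER")

# Clinical assertion levels as stored on a variant; composites (P_LP, B_LB)
# sit between their endpoints and are resolved with the in-silico verdict.
CLIN_LEVELS <- c("B", "B_LB", "LB", "US", "LP", "P_LP", "P", "conflicting")

# Pathogenicity rank of a *resolved* (composite-free) clinical level.
CLIN_RANK <- c(B = 1, LB = 2, US = 3, LP = 4, P = 5)

# The six missense prediction tools that vote in the consensus; CADD is a
# gate, not a vote, and SIFT-indel drives the indel route.
MISSENSE_TOOLS <- c("sift", "polyphen", "fathmm", "mutation_taster",
                    "mutation_assessor", "provean")

# HIGH-impact terms routed to the CADD-only (truncating/splice) consensus.
TRUNCATING_TERMS <- c("stop_gained", "stop_lost", "start_lost",
                      "splice_donor_variant", "splice_acceptor_variant")

INFRAME_TERMS <- c("inframe_insertion", "inframe_deletion")

ZYGOSITY_LEVELS <- c("het", "hom", "unknown")

sysfile <- function(...) {
  system.file("extdata", ..., package = "raretriage", mustWork = TRUE)
}

#' Severity rank of a VEP impact category
#'
#' Lower rank means more severe (HIGH = 1, MODIFIER = 4).
#'
#' @param impact Character vector of VEP impact categories.
#' @return Integer vector of ranks; unknown categories are an error.
#' @keywords internal
impact_rank <- function(impact) {
  r <- match(impact, IMPACT_LEVELS)
  if (anyNA(r)) {
    stop("unknown VEP impact category: ",
         paste(unique(impact[is.na(r)]), collapse = ", "), call. = FALSE)
  }
  r
}

#' Protein-coding and canonical-splice consequence terms
#'
#' The Sequence Ontology terms counted as protein-coding-region or
#' canonical-splice-site consequences by the region/impact filter. The
#' default list ships with the package and can be replaced by a plain-text
#' file with one term per line (`#` comments allowed).
#'
#' @param path Optional path to an override term list.
#' @return Character vector of SO terms.
#' @export
coding_terms <- function(path = NULL) {
  path <- path %||% sysfile("coding_terms.txt")
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Consequence term to summary category map
#'
#' Maps Sequence Ontology consequence terms to the reporting categories used
#' in cohort summaries (missense, frameshift, in-frame indel, stop gained,
#' splice, other protein-altering, intronic, synonymous, UTR3, UTR5, other).
#'
#' @param path Optional path to an override two-column TSV (term, category).
#' @return Named character vector: names are SO terms, values categories.
#' @export
consequence_categories <- function(path = NULL) {
  path <- path %||% sysfile("consequence_categories.tsv")
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  stats::setNames(df$category, df$term)
}

#' Prediction-tool vocabulary normalisation table
#'
#' Each in-silico tool's native call vocabulary mapped onto the common
#' damaging / tolerated dichotomy. The shipped YAML table can be overridden.
#'
#' @param path Optional path to an override YAML file (tool -> raw -> call).
#' @return Named list of named character vectors.
#' @export
prediction_vocab <- function(path = NULL) {
  path <- path %||% sysfile("prediction_vocab.yaml")
  tab <- yaml::read_yaml(path)
  lapply(tab, function(m) vapply(m, as.character, character(1)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
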