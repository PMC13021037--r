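# Descriptive over-representation analysis of candidate genes against a
# user-supplied term-gene map (GMT), with an upper-tail hypergeometric test
# per term. Intended as functional annotation of a pre-selected panel gene
# set, not as evidence of enrichment.

#' Read a GMT term-gene file
#'
#' Standard GMT: one term per line, `term<TAB>description<TAB>gene...`.
#' Duplicate genes within a line are deduplicated; lines with fewer than
#' three fields are skipped with a warning.
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `term_id`, `term_name` and list-column
#'   `genes`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 3
  if (any(short)) {
    warning(sum(short), " GMT line(s) with fewer than 3 fields skipped",
            call. = FALSE)
    parts <- parts[!short]
  }
  tibble::tibble(
    term_id = vapply(parts, `[`, character(1), 1),
    term_name = vapply(parts, `[`, character(1), 2),
    genes = lapply(parts, function(p) unique(p[-(1:2)]))
  )
}

#' Hypergeometric over-representation analysis
#'
#' For each term, tests whether the candidate gene set overlaps the term's
#' genes more than expected under hypergeometric sampling from the
#' background universe: `p_raw = P(X >= k)` with `k` candidate genes in the
#' term, term size `K`, candidate-set size `n` and background size `N`
#' (all after intersection with the background). Terms with no overlap are
#' reported with `p_raw = 1`.
#'
#' @param candidate_genes Character vector of candidate gene symbols.
#' @param terms Term-gene map from [read_gmt()] (columns `term_id`,
#'   `term_name`, list-column `genes`).
#' @param background Character vector of background genes, or
#'   `"map-universe"` (default) for the union of all genes in `terms`.
#' @param correction Multiple-testing correction: `"BH"` or
#'   `"bonferroni"`.
#' @return A tibble with columns `term_id`, `term_name`, `k`, `K`, `n`,
#'   `N`, `p_raw`, `p_adj` and list-column `hit_genes`, sorted by `p_adj`
#'   then `term_id`.
#' @export
ora <- function(candidate_genes, terms, background = "map-universe",
                correction = c("BH", "bonferroni")) {
  correction <- match.arg(correction)
  if (identical(background, "map-universe")) {
    background <- unique(unlist(terms$genes, use.names = FALSE))
  }
  background <- unique(background)
  if (length(background) == 0) {
    stop("empty background gene universe", call. = FALSE)
  }
  cand <- intersect(unique(candidate_genes), background)
  N <- length(background)
  n <- length(cand)
  rows <- lapply(seq_len(nrow(terms)), function(i) {
    tg <- intersect(terms$genes[[i]], background)
    hits <- intersect(cand, tg)
    k <- length(hits)
    K <- length(tg)
    p <- if (k == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    list(k = k, K = K, p_raw = p, hits = sort(hits))
  })
  out <- tibble::tibble(
    term_id = terms$term_id,
    term_name = terms$term_name,
    k = vapply(rows, `[[`, numeric(1), "k"),
    K = vapply(rows, `[[`, numeric(1), "K"),
    n = n, N = N,
    p_raw = vapply(rows, `[[`, numeric(1), "p_raw"),
    hit_genes = lapply(rows, `[[`, "hits")
  )
  out$p_adj <- stats::p.adjust(out$p_raw, method = correction)
  out <- out[, c("term_id", "term_name", "k", "K", "n", "N", "p_raw",
                 "p_adj", "hit_genes")]
  out[order(out$p_adj, out$term_id), ]
}
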