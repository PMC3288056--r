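check_margins <- function(k, K, n, N) {
  ok <- !is.na(k) & !is.na(K) & !is.na(n) & !is.na(N) &
    k >= 0 & K >= 0 & n >= 0 & N >= 1 & K <= N & n <= N &
    k <= pmin(n, K)
  if (!all(ok))
    stop("invalid 2x2 margins at position(s): ",
         paste(which(!ok), collapse = ", "),
         " (need 0 <= k <= min(n, K), K <= N, n <= N)")
  invisible(TRUE)
}

#' One-tailed Fisher exact (hypergeometric upper tail)
#'
#' Probability of observing `k` or more list hits for a term annotating
#' `K` of `N` universe proteins when `n` proteins are drawn, i.e. the
#' upper tail of the hypergeometric distribution. All arguments are
#' vectorized.
#'
#' @param k list proteins annotated to the term.
#' @param K universe proteins annotated to the term.
#' @param n proteins in the list.
#' @param N universe size.
#' @return upper-tail probabilities in `[0, 1]`.
#' @export
fisher_exact <- function(k, K, n, N) {
  check_margins(k, K, n, N)
  pmin(1, phyper(k - 1, K, N - K, n, lower.tail = FALSE))
}

#' EASE score (jackknifed one-tailed Fisher exact)
#'
#' The EASE score penalizes terms supported by few list hits: one hit is
#' removed from the list-and-term cell and the upper-tail hypergeometric
#' probability of `>= max(k - 1, 0)` hits is computed against unchanged
#' margins `(K, n, N)`. Terms with `k <= 1` therefore score exactly 1
#' (no spurious significance from singleton hits), and the EASE score is
#' always at least as large (more conservative) as the plain Fisher
#' probability.
#'
#' @inheritParams fisher_exact
#' @return EASE probabilities in `[0, 1]`.
#' @export
ease_score <- function(k, K, n, N) {
  check_margins(k, K, n, N)
  kk <- pmax(k - 1, 0)
  p <- pmin(1, phyper(kk - 1, K, N - K, n, lower.tail = FALSE))
  p[kk == 0] <- 1
  p
}

#' Fold enrichment of a term in a protein list
#'
#' Ratio of the term's frequency in the list to its frequency in the
#' annotation universe: `(k/n) / (K/N)`. This measures over-representation
#' of protein *species* relative to random expression, not protein
#' abundance.
#'
#' @inheritParams fisher_exact
#' @return fold enrichment (>= 0); 1 is the null expectation.
#' @export
fold_enrichment <- function(k, K, n, N) {
  check_margins(k, K, n, N)
  if (any(K == 0) || any(n == 0))
    stop("fold enrichment undefined for K = 0 or n = 0")
  (k / n) / (K / N)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: with p-values sorted
#' ascending, `adj_(i) = min_{j >= i} (p_(j) * M / j)`, capped at 1, and
#' returned in the input order.
#'
#' @param pvals probabilities in `[0, 1]`.
#' @return adjusted probabilities, same order as input.
#' @export
benjamini_hochberg <- function(pvals) {
  if (!length(pvals)) return(numeric())
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Over-representation analysis of a protein list
#'
#' For every annotation term with at least one list hit, computes the
#' 2x2 margins `(k, K, n, N)` against an explicit universe, the EASE
#' score, the plain Fisher probability, fold enrichment, the % count
#' (`100 * k / n`, reported to one decimal), and the Benjamini-Hochberg
#' adjusted EASE score. Adjustment is performed per annotation category
#' over all tested terms *before* filtering, so the reported Benjamini
#' values do not depend on the display thresholds. The returned table
#' keeps only terms with `k >= min_count` and `p_ease <= ease_max`,
#' sorted by EASE score ascending.
#'
#' The universe is an explicit argument because the background materially
#' changes fold values: conventional choices are the union of all GMT
#' members (`universe = NULL`) or the detected proteome.
#'
#' @param list_symbols protein list (gene symbols; normalized). Symbols
#'   outside the universe are dropped with a message.
#' @param terms list of annotation sets ([read_gmt()] /
#'   [annotation_set()]).
#' @param universe character vector of annotatable symbols; `NULL` uses
#'   the union of all term members.
#' @param min_count minimum list hits for a term to be reported.
#' @param ease_max maximum EASE score for a term to be reported.
#' @return data.frame of class `"enrichment_table"` with columns
#'   `term_id`, `term_name`, `category`, `k`, `n`, `K`, `N`, `pct`,
#'   `fold`, `p_ease`, `p_fisher`, `benjamini`. The unfiltered tested
#'   table is attached as attribute `"tested"`.
#' @export
enrich <- function(list_symbols, terms, universe = NULL, min_count = 5,
                   ease_max = 0.1) {
  if (!length(terms)) stop("no annotation terms supplied")
  members <- lapply(terms, `[[`, "members")
  if (is.null(universe)) universe <- unique(unlist(members))
  universe <- unique(normalize_symbols(universe))
  N <- length(universe)
  if (N == 0) stop("empty annotation universe")
  lst <- unique(normalize_symbols(list_symbols))
  outside <- setdiff(lst, universe)
  if (length(outside)) {
    message(length(outside),
            " list symbol(s) outside the universe dropped")
    lst <- intersect(lst, universe)
  }
  n <- length(lst)
  if (n == 0) stop("protein list is empty after universe restriction")

  k <- vapply(members, function(m) sum(lst %in% m), 0L)
  K <- vapply(members, function(m) sum(universe %in% m), 0L)
  tested <- data.frame(
    term_id = vapply(terms, `[[`, "", "term_id"),
    term_name = vapply(terms, `[[`, "", "term_name"),
    category = vapply(terms, function(t)
      if (is.null(t$category)) NA_character_ else t$category, ""),
    k = k, n = n, K = K, N = N, row.names = NULL,
    stringsAsFactors = FALSE)
  tested <- tested[tested$k >= 1L & tested$K >= 1L, , drop = FALSE]
  if (!nrow(tested)) {
    out <- cbind(tested, pct = numeric(), fold = numeric(),
                 p_ease = numeric(), p_fisher = numeric(),
                 benjamini = numeric())
    class(out) <- c("enrichment_table", "data.frame")
    return(out)
  }
  tested$pct <- round_pct(100 * tested$k / tested$n)
  tested$fold <- fold_enrichment(tested$k, tested$K, tested$n, tested$N)
  tested$p_ease <- ease_score(tested$k, tested$K, tested$n, tested$N)
  tested$p_fisher <- fisher_exact(tested$k, tested$K, tested$n, tested$N)
  cat_f <- factor(ifelse(is.na(tested$category), "(none)", tested$category))
  tested$benjamini <- NA_real_
  for (lev in levels(cat_f)) {
    sel <- cat_f == lev
    tested$benjamini[sel] <- benjamini_hochberg(tested$p_ease[sel])
  }
  out <- tested[tested$k >= min_count & tested$p_ease <= ease_max, ,
                drop = FALSE]
  out <- out[order(out$p_ease, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tested") <- tested
  class(out) <- c("enrichment_table", "data.frame")
  out
}
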