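#' Cohen's kappa between two terms' membership vectors
#'
#' Chance-corrected agreement of the two binary membership indicators
#' over a protein list. Degenerate cases where expected agreement is 1
#' (both vectors constant) are defined as 1 when the vectors are
#' identical and 0 otherwise.
#'
#' @param members_a,members_b member symbol vectors of the two terms.
#' @param list_symbols the protein list over which agreement is scored;
#'   both terms must have at least one member in it.
#' @return kappa in `[-1, 1]`.
#' @export
kappa_similarity <- function(members_a, members_b, list_symbols) {
  lst <- unique(as.character(list_symbols))
  a <- lst %in% members_a
  b <- lst %in% members_b
  if (!any(a) || !any(b))
    stop("both terms must have at least one member in the list")
  kappa_binary(a, b)
}

# kappa on two logical vectors (no validation; used on precomputed columns)
kappa_binary <- function(a, b) {
  n <- length(a)
  po <- mean(a == b)
  pa <- mean(a); pb <- mean(b)
  pe <- pa * pb + (1 - pa) * (1 - pb)
  if (pe >= 1) return(if (all(a == b)) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Cluster enrichment score
#'
#' Minus log10 of the geometric mean of the member terms' EASE scores,
#' computed by log-space summation so that p-values around 1e-15 do not
#' underflow. Zero iff the geometric mean is 1.
#'
#' @param pvals member EASE scores in `(0, 1]`.
#' @return non-negative score.
#' @export
enrichment_score <- function(pvals) {
  if (!length(pvals) || anyNA(pvals) || any(pvals <= 0 | pvals > 1))
    stop("p-values must lie in (0, 1]")
  mean(-log10(pvals))
}

stringency_presets <- list(
  low    = list(kappa_threshold = 0.35, seed_min = 2, merge_overlap = 0.50),
  medium = list(kappa_threshold = 0.50, seed_min = 3, merge_overlap = 0.50),
  high   = list(kappa_threshold = 0.85, seed_min = 4, merge_overlap = 0.50)
)

#' Kappa-based functional annotation clustering
#'
#' Groups over-represented terms that annotate largely the same proteins,
#' in the style of seed-and-merge annotation clustering: each term seeds
#' a group consisting of itself and every term whose membership kappa
#' (over the protein list) reaches `kappa_threshold`; seeds with fewer
#' than `seed_min` partners are discarded; groups sharing at least
#' `merge_overlap` of the smaller group's terms are merged iteratively
#' to a fixed point. Each cluster is scored with [enrichment_score()]
#' on its members' EASE scores and clusters are returned sorted by score
#' descending. Terms absent from every cluster come back as singletons.
#'
#' @param records an `"enrichment_table"` from [enrich()] (or any
#'   data.frame with `term_id` and `p_ease` columns).
#' @param memberships named list mapping `term_id` to member symbols.
#' @param list_symbols the protein list over which kappa is computed.
#' @param stringency `"low"`, `"medium"` or `"high"`; presets for the
#'   three tuning knobs (medium: kappa 0.50, seed_min 3, overlap 0.50).
#'   Explicit arguments override the preset.
#' @param kappa_threshold,seed_min,merge_overlap tuning knobs; see above.
#' @return list with `clusters` (list of objects of class
#'   `"term_cluster"`, fields `terms` and `score`) and `singletons`
#'   (character vector of unclustered term ids).
#' @export
cluster_terms <- function(records, memberships, list_symbols,
                          stringency = c("medium", "low", "high"),
                          kappa_threshold = NULL, seed_min = NULL,
                          merge_overlap = NULL) {
  if (!nrow(records)) stop("no enrichment records to cluster")
  preset <- stringency_presets[[match.arg(stringency)]]
  if (is.null(kappa_threshold)) kappa_threshold <- preset$kappa_threshold
  if (is.null(seed_min)) seed_min <- preset$seed_min
  if (is.null(merge_overlap)) merge_overlap <- preset$merge_overlap

  ids <- records$term_id
  absent <- setdiff(ids, names(memberships))
  if (length(absent))
    stop("membership missing for term(s): ", paste(absent, collapse = ", "))
  lst <- unique(as.character(list_symbols))
  M <- vapply(memberships[ids], function(m) lst %in% m,
              logical(length(lst)))
  M <- matrix(M, nrow = length(lst), dimnames = list(NULL, ids))
  keep <- colSums(M) > 0
  ids <- ids[keep]
  M <- M[, keep, drop = FALSE]
  if (!length(ids))
    return(list(clusters = list(), singletons = records$term_id))

  Tn <- length(ids)
  Kmat <- matrix(1, Tn, Tn, dimnames = list(ids, ids))
  if (Tn > 1) {
    for (i in 1:(Tn - 1)) for (j in (i + 1):Tn)
      Kmat[i, j] <- Kmat[j, i] <- kappa_binary(M[, i], M[, j])
  }

  # seed groups
  groups <- list()
  for (i in seq_len(Tn)) {
    partners <- which(Kmat[i, ] >= kappa_threshold)
    partners <- setdiff(partners, i)
    if (length(partners) >= seed_min)
      groups[[length(groups) + 1L]] <- sort(unique(c(i, partners)))
  }
  # iterative merging to a fixed point
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < length(groups)) {
      j <- i + 1L
      while (j <= length(groups)) {
        a <- groups[[i]]; b <- groups[[j]]
        if (length(intersect(a, b)) >=
            merge_overlap * min(length(a), length(b))) {
          groups[[i]] <- sort(unique(c(a, b)))
          groups[[j]] <- NULL
          merged <- TRUE
        } else j <- j + 1L
      }
      i <- i + 1L
    }
    if (!merged) break
  }

  p_by_id <- setNames(records$p_ease, records$term_id)
  clusters <- lapply(groups, function(g) {
    terms <- ids[g]
    structure(list(terms = terms,
                   score = enrichment_score(p_by_id[terms])),
              class = "term_cluster")
  })
  ord <- order(-vapply(clusters, `[[`, 0, "score"))
  clusters <- clusters[ord]
  clustered_ids <- unique(unlist(lapply(clusters, `[[`, "terms")))
  list(clusters = clusters,
       singletons = setdiff(records$term_id, clustered_ids))
}

#' @export
print.term_cluster <- function(x, ...) {
  cat(sprintf("Annotation cluster (%d terms, enrichment score %.2f):\n",
              length(x$terms), x$score))
  cat(" ", paste(x$terms, collapse = ", "), "\n")
  invisible(x)
}

#' Flatten a clustering result to a report table
#'
#' @param clustering output of [cluster_terms()].
#' @return data.frame with columns `cluster`, `enrichment_score`,
#'   `term_id` (singletons get cluster `NA`).
#' @export
clusters_as_table <- function(clustering) {
  rows <- lapply(seq_along(clustering$clusters), function(i) {
    cl <- clustering$clusters[[i]]
    data.frame(cluster = i, enrichment_score = cl$score,
               term_id = cl$terms, stringsAsFactors = FALSE)
  })
  singles <- if (length(clustering$singletons))
    data.frame(cluster = NA_integer_, enrichment_score = NA_real_,
               term_id = clustering$singletons, stringsAsFactors = FALSE)
  do.call(rbind, c(rows, list(singles)))
}
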