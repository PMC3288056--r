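#' Rank the net proteome and take the most abundant proteins
#'
#' Returns all and only proteins with net spectral counts at or above
#' `min_spectra` (the threshold is inclusive), sorted non-increasingly by
#' net count with ties broken lexicographically by symbol. The result is
#' stable under permutation of input rows and idempotent.
#'
#' @param net a [subtract_background()] result.
#' @param min_spectra inclusive spectra threshold (>= 0); 0 returns the
#'   whole net proteome.
#' @return data.frame with columns `symbol`, `net_count`, sorted.
#' @export
top_proteins <- function(net, min_spectra = 400) {
  stopifnot(inherits(net, "net_proteome"))
  if (!is.numeric(min_spectra) || length(min_spectra) != 1L ||
      is.na(min_spectra) || min_spectra < 0)
    stop("min_spectra must be a single non-negative number")
  counts <- net$net_counts[net$net_counts >= min_spectra]
  sym <- names(counts)
  ord <- order(-counts, sym, method = "radix")
  data.frame(symbol = sym[ord], net_count = unname(counts[ord]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Construct a functional group
#'
#' @param name group label.
#' @param members gene symbols (normalized); must be non-empty.
#' @return object of class `"functional_group"`.
#' @export
functional_group <- function(name, members) {
  members <- unique(normalize_symbols(members))
  if (!length(members)) stop("functional group '", name, "' has no members")
  structure(list(name = as.character(name), members = members),
            class = "functional_group")
}

#' Cumulative spectra fraction per functional group
#'
#' For each group, the cumulative net spectra of its members (optionally
#' restricted to a ranked sublist, e.g. the output of [top_proteins()])
#' as a percentage of the total net spectra of the proteome. Groups need
#' not be disjoint; with `partition = TRUE` they are asserted to be
#' disjoint and exhaustive over the net proteome, in which case the
#' fractions sum to 100.
#'
#' @param net a [subtract_background()] result.
#' @param groups list of [functional_group()]s (or annotation sets from
#'   [read_gmt()]; the `members` field is what is used).
#' @param restrict_to optional character vector (or data.frame with a
#'   `symbol` column) restricting which proteins may contribute spectra.
#' @param partition assert groups partition the (restricted) proteome.
#' @return named numeric vector of percentages in `[0, 100]`.
#' @export
group_spectral_fraction <- function(net, groups, restrict_to = NULL,
                                    partition = FALSE) {
  stopifnot(inherits(net, "net_proteome"))
  if (net$total_net_spectra == 0)
    stop("group fraction undefined: total net spectra is 0")
  counts <- net$net_counts
  if (!is.null(restrict_to)) {
    if (is.data.frame(restrict_to)) restrict_to <- restrict_to$symbol
    counts <- counts[names(counts) %in% normalize_symbols(restrict_to)]
  }
  member_list <- lapply(groups, `[[`, "members")
  nm <- vapply(groups, function(g)
    if (!is.null(g$name)) g$name else g$term_id, "")
  missing <- lapply(member_list, setdiff, y = names(net$net_counts))
  n_missing <- sum(lengths(missing))
  if (n_missing)
    message(n_missing, " group member(s) not in the net proteome; ignored")
  if (partition) {
    all_members <- unlist(member_list)
    if (anyDuplicated(all_members))
      stop("partition mode: groups overlap on ",
           paste(unique(all_members[duplicated(all_members)]),
                 collapse = ", "))
    uncovered <- setdiff(names(counts), all_members)
    if (length(uncovered))
      stop("partition mode: proteome member(s) not covered: ",
           paste(head(uncovered, 5), collapse = ", "))
  }
  frac <- vapply(member_list, function(m)
    100 * sum(counts[names(counts) %in% m]) / net$total_net_spectra, 0)
  setNames(frac, nm)
}

#' Net/background share of each protein's gross spectra
#'
#' For selected proteins, splits the gross (pre-subtraction) spectral
#' count into the share surviving background subtraction and the share
#' attributed to background: `net% = 100 * max(0, raw_net) / gcp` and
#' `background% = 100 - net%`. A protein fully explained by background
#' (excluded) has shares (0, 100). The matrix ("laminin") component can
#' be dropped from the background via `include_laminin = FALSE`, in which
#' case only the scaled HSS counts are subtracted for the share.
#'
#' @param table a [spectral_count_table()].
#' @param m background multiplier.
#' @param symbols gene symbols to report (must be present in the table).
#' @param include_laminin count matrix spectra as background (default).
#' @return data.frame with columns `symbol`, `net_pct`, `background_pct`,
#'   `gross` (gross spectra). Proteins with `gcp == 0` are reported with
#'   `NA` shares.
#' @export
gross_share <- function(table, m, symbols, include_laminin = TRUE) {
  stopifnot(inherits(table, "spectral_count_table"))
  ids <- normalize_symbols(symbols)
  idx <- match(ids, table$symbol)
  if (anyNA(idx))
    stop("symbol(s) absent from table: ",
         paste(ids[is.na(idx)], collapse = ", "))
  gcp <- table$gcp[idx]
  raw <- gcp - (if (include_laminin) table$laminin[idx] else 0) -
    m * table$hss[idx]
  net_pct <- ifelse(gcp > 0, 100 * pmax(0, raw) / gcp, NA_real_)
  data.frame(symbol = ids, net_pct = net_pct,
             background_pct = ifelse(gcp > 0, 100 - net_pct, NA_real_),
             gross = gcp, row.names = NULL, stringsAsFactors = FALSE)
}

# Report-facing rounding: percentages to one decimal, full precision kept
# internally everywhere else.
round_pct <- function(x) round(x, 1)
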