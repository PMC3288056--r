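#' Read a proteome-versus-transcriptome family panel
#'
#' A panel is a TSV with columns `symbol`, `net_spectra`,
#' `transcript_detected` (accepted truthy markers: `1`, `TRUE`, `x`,
#' `X`; anything else is falsy), one row per family member.
#'
#' @param path panel TSV.
#' @param family_label label for the panel; defaults to the file name.
#' @return object of class `"transcriptome_panel"` (a data.frame with an
#'   attached `family_label` attribute).
#' @export
read_panel <- function(path, family_label = NULL) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  needed <- c("symbol", "net_spectra", "transcript_detected")
  absent <- setdiff(needed, names(df))
  if (length(absent))
    stop("panel is missing column(s): ", paste(absent, collapse = ", "))
  transcriptome_panel(
    symbol = df$symbol,
    net_spectra = df$net_spectra,
    transcript_detected =
      tolower(trimws(as.character(df$transcript_detected))) %in%
      c("1", "true", "x"),
    family_label = if (is.null(family_label))
      sub("\\.[^.]*$", "", basename(path)) else family_label)
}

#' @rdname read_panel
#' @param symbol,net_spectra,transcript_detected panel columns.
#' @export
transcriptome_panel <- function(symbol, net_spectra, transcript_detected,
                                family_label = "panel") {
  symbol <- normalize_symbols(symbol)
  if (anyDuplicated(symbol))
    stop("duplicate symbol(s) in panel: ",
         paste(unique(symbol[duplicated(symbol)]), collapse = ", "))
  net_spectra <- as.numeric(net_spectra)
  if (anyNA(net_spectra) || any(net_spectra < 0))
    stop("net_spectra must be non-negative numbers")
  out <- data.frame(symbol = symbol, net_spectra = net_spectra,
                    transcript_detected = as.logical(transcript_detected),
                    stringsAsFactors = FALSE)
  attr(out, "family_label") <- as.character(family_label)
  class(out) <- c("transcriptome_panel", "data.frame")
  out
}

#' Proteome-versus-transcriptome overlap of a protein family
#'
#' Cross-tabulates a family panel: how many members are counted as
#' proteome entries, how many have a detected transcript, and the
#' rounded overlap percentage. Published family tables list zero-spectra
#' members when their transcript was detected; the default convention
#' (which reproduces such printed percentages) counts only
#' positive-spectra entries in the denominator while the transcript
#' numerator counts every flagged row. `include_zero = TRUE` keeps
#' zero-spectra rows in the denominator; `numerator = "detected_only"`
#' restricts the numerator to rows that are also proteome entries.
#'
#' @param panel a [transcriptome_panel()].
#' @param include_zero count zero-spectra rows as proteome entries.
#' @param numerator `"all_flagged"` (default) or `"detected_only"`.
#' @return object of class `"overlap_report"`: list with `family_label`,
#'   `n_entries`, `n_proteome`, `n_overlap`, `pct_overlap` (rounded to
#'   the nearest integer percent).
#' @export
overlap_stats <- function(panel, include_zero = FALSE,
                          numerator = c("all_flagged", "detected_only")) {
  stopifnot(inherits(panel, "transcriptome_panel"))
  numerator <- match.arg(numerator)
  if (!nrow(panel)) stop("empty panel")
  detected <- panel$net_spectra > 0
  n_prot <- if (include_zero) nrow(panel) else sum(detected)
  if (n_prot == 0) stop("no proteome entries in panel")
  flagged <- panel$transcript_detected
  n_overlap <- if (numerator == "all_flagged") sum(flagged)
               else sum(flagged & (include_zero | detected))
  structure(list(family_label = attr(panel, "family_label"),
                 n_entries = nrow(panel),
                 n_proteome = n_prot,
                 n_overlap = n_overlap,
                 pct_overlap = round(100 * n_overlap / n_prot)),
            class = "overlap_report")
}

#' @export
as.data.frame.overlap_report <- function(x, ...)
  data.frame(family = x$family_label, entries = x$n_entries,
             proteome = x$n_proteome, overlap = x$n_overlap,
             pct_overlap = x$pct_overlap, stringsAsFactors = FALSE)

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("%s: %d/%d transcript overlap (%d%%)\n", x$family_label,
              x$n_overlap, x$n_proteome, x$pct_overlap))
  invisible(x)
}

#' Rank association between protein abundance and transcript detection
#'
#' Tests whether family members with a detected transcript tend to have
#' higher net spectral counts. The statistic is the rank-biserial
#' association `r = 2U/(n1*n0) - 1` (Mann-Whitney `U` of the
#' transcript-detected group, ties counted half), ranging from -1 to 1
#' with 1 when every flagged member outranks every unflagged one. The
#' p-value is two-sided and comes from a seeded permutation test of the
#' transcript labels.
#'
#' @param panel a [transcriptome_panel()] with at least 3 rows.
#' @param n_perm number of label permutations.
#' @param seed RNG seed for the permutation draw.
#' @return list with `rank_biserial`, `p_value`, `n_detected`,
#'   `n_not_detected`, `n_perm`. If the spectra are constant or one
#'   label class is empty the statistic is undefined and returned as
#'   `NA` with a `reason`.
#' @export
correlation_check <- function(panel, n_perm = 10000, seed = 1) {
  stopifnot(inherits(panel, "transcriptome_panel"))
  if (nrow(panel) < 3) stop("panel must have at least 3 entries")
  x <- panel$net_spectra
  g <- panel$transcript_detected
  n1 <- sum(g); n0 <- sum(!g)
  if (n1 == 0 || n0 == 0 || length(unique(x)) == 1L)
    return(list(rank_biserial = NA_real_, p_value = NA_real_,
                n_detected = n1, n_not_detected = n0, n_perm = 0L,
                reason = "statistic undefined (constant spectra or one-class labels)"))
  r <- rank(x)
  rb <- function(labels) {
    u <- sum(r[labels]) - n1 * (n1 + 1) / 2
    2 * u / (n1 * n0) - 1
  }
  obs <- rb(g)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) rb(sample(g)), 0)
  })
  p <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (n_perm + 1)
  list(rank_biserial = obs, p_value = p, n_detected = n1,
       n_not_detected = n0, n_perm = as.integer(n_perm))
}

#' Bundled protein-family overlap panels
#'
#' Loads the packaged example panels (Rab and Kif family isoforms and
#' proteasome subunits, transcribed from a published cross-tabulation of
#' a growth-cone proteome against an independent growth-cone
#' transcriptome).
#'
#' @return named list of [transcriptome_panel()]s (`rab`, `kif`, `psm`).
#' @export
example_panels <- function() {
  f <- function(name, label)
    read_panel(system.file("extdata", paste0("table3_", name, ".tsv"),
                           package = "gcproteome", mustWork = TRUE),
               family_label = label)
  list(rab = f("rab", "Rab"), kif = f("kif", "Kif"), psm = f("psm", "Psm"))
}
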