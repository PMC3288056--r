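#' Estimate the cytosolic-contamination multiplier from calibration proteins
#'
#' The gross fraction of a plated subcellular preparation carries an unknown
#' admixture of cytosolic protein. Designated calibration proteins that are
#' known contaminants (the study design uses serum albumin and
#' alpha-fetoprotein, which are present in the high-speed supernatant but are
#' not genuine growth-cone components) pin down the admixture: for each one,
#' the multiplier `m_i` is the scaling of its HSS count that makes its net
#' count exactly zero after the matrix ("laminin") counts have been removed,
#'
#'   `m_i = max(0, gcp_i - laminin_i) / hss_i`
#'
#' and the pooled multiplier `m` is the unweighted arithmetic mean of the
#' `m_i` (a spectra-weighted mean is available via `weighted = TRUE`).
#' Matrix counts are removed first by default because the net proteome is
#' defined against the combined background; `include_laminin = FALSE`
#' restores the variant that calibrates on raw gross counts.
#'
#' @param table a [spectral_count_table()].
#' @param calibration_ids gene symbols of the calibration contaminants.
#' @param include_laminin subtract matrix counts before computing `m_i`.
#' @param weighted use an HSS-spectra-weighted mean instead of the
#'   unweighted mean.
#' @return object of class `"calibration_result"`: list with
#'   `per_protein` (named multipliers) and `mean`.
#' @examples
#' tab <- spectral_count_table(c("p1", "p2"), c("Alb", "Afp"),
#'                             gcp = c(29, 34), laminin = c(0, 0),
#'                             hss = c(100, 100))
#' compute_calibration_multipliers(tab, c("Alb", "Afp"))$mean  # 0.315
#' @export
compute_calibration_multipliers <- function(table, calibration_ids,
                                            include_laminin = TRUE,
                                            weighted = FALSE) {
  stopifnot(inherits(table, "spectral_count_table"))
  ids <- normalize_symbols(calibration_ids)
  if (!length(ids)) stop("at least one calibration protein is required")
  idx <- match(ids, table$symbol)
  if (anyNA(idx))
    stop("calibration protein(s) absent from table: ",
         paste(ids[is.na(idx)], collapse = ", "))
  hss <- table$hss[idx]
  if (any(hss == 0))
    stop("multiplier undefined (hss count is 0) for: ",
         paste(ids[hss == 0], collapse = ", "))
  base <- table$gcp[idx] - if (include_laminin) table$laminin[idx] else 0
  m_i <- pmax(0, base) / hss
  m <- if (weighted) sum(m_i * hss) / sum(hss) else mean(m_i)
  structure(list(per_protein = setNames(m_i, ids), mean = m,
                 include_laminin = include_laminin, weighted = weighted),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Calibration multipliers (", length(x$per_protein), " protein",
      if (length(x$per_protein) != 1) "s", "):\n", sep = "")
  print(round(x$per_protein, 4))
  cat("mean multiplier m =", format(x$mean), "\n")
  invisible(x)
}

#' Subtract the combined background from a spectral-count table
#'
#' For each protein the raw net count is
#' `gcp - laminin - m * hss`. Proteins whose gross counts are equal to or
#' lower than the combined background (raw net <= 0) are excluded; the
#' comparison uses exact arithmetic on the raw values, so ties at exactly
#' zero are excluded — in particular every calibration protein under its
#' own multiplier. Excluded proteins are reported with their raw
#' (possibly negative) values before flooring.
#'
#' @param table a [spectral_count_table()].
#' @param m non-negative background multiplier (see
#'   [compute_calibration_multipliers()]).
#' @return object of class `"net_proteome"`: list with
#'   \describe{
#'     \item{net_counts}{named positive net spectra, by symbol}
#'     \item{excluded}{named raw net values (<= 0) of excluded proteins}
#'     \item{raw_net}{raw net for every input protein}
#'     \item{gross}{gross (gcp) counts, for share computations}
#'     \item{total_net_spectra}{sum of net counts}
#'     \item{m}{the multiplier used}
#'   }
#' @export
subtract_background <- function(table, m) {
  stopifnot(inherits(table, "spectral_count_table"))
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 0)
    stop("multiplier m must be a single non-negative number")
  raw <- table$gcp - table$laminin - m * table$hss
  names(raw) <- table$symbol
  keep <- raw > 0
  structure(list(net_counts = raw[keep],
                 excluded = raw[!keep],
                 raw_net = raw,
                 gross = setNames(table$gcp, table$symbol),
                 total_net_spectra = sum(raw[keep]),
                 m = m),
            class = "net_proteome")
}

#' @export
as.data.frame.net_proteome <- function(x, ...) {
  sym <- names(x$raw_net)
  data.frame(symbol = sym,
             net_count = ifelse(x$raw_net > 0, x$raw_net, 0),
             raw_net = x$raw_net,
             excluded_flag = !(x$raw_net > 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.net_proteome <- function(x, ...) {
  cat("Net proteome: ", length(x$net_counts), " proteins retained, ",
      length(x$excluded), " excluded (m = ", format(x$m), ")\n",
      "total net spectra: ", format(x$total_net_spectra), "\n", sep = "")
  invisible(x)
}

#' Report how completely known contaminants were eliminated
#'
#' Given a set of control proteins that should have been removed by
#' background subtraction (e.g. serum proteins), reports for each its
#' status and residual net count, the fraction of control proteins
#' excluded, and the fraction of their gross spectra eliminated (residual
#' net spectra relative to gross spectra). The spectra-weighted fraction
#' is the quantity that tracks "almost complete" elimination: a mean-zero
#' residual can leave a protein marginally positive while removing
#' essentially all of its signal.
#'
#' @param net a [subtract_background()] result.
#' @param control_ids gene symbols of known contaminants.
#' @return object of class `"elimination_report"`: list with a per-protein
#'   `report` data.frame and summary fractions `proteins_eliminated` and
#'   `spectra_eliminated`.
#' @export
validate_elimination <- function(net, control_ids) {
  stopifnot(inherits(net, "net_proteome"))
  if (!length(control_ids)) {
    rep <- data.frame(symbol = character(), status = character(),
                      residual_net = numeric(), raw_net = numeric(),
                      stringsAsFactors = FALSE)
    return(structure(list(report = rep, proteins_eliminated = NA_real_,
                          spectra_eliminated = NA_real_),
                     class = "elimination_report"))
  }
  ids <- normalize_symbols(control_ids)
  present <- ids[ids %in% names(net$raw_net)]
  absent <- setdiff(ids, present)
  raw <- net$raw_net[present]
  excluded <- !(raw > 0)
  rep <- data.frame(symbol = c(present, absent),
                    status = c(ifelse(excluded, "excluded", "retained"),
                               rep("absent", length(absent))),
                    residual_net = c(pmax(0, raw), rep(0, length(absent))),
                    raw_net = c(unname(raw), rep(NA_real_, length(absent))),
                    stringsAsFactors = FALSE)
  gross <- sum(net$gross[present])
  structure(list(report = rep,
                 proteins_eliminated = if (length(present))
                   mean(excluded) else NA_real_,
                 spectra_eliminated = if (length(present) && gross > 0)
                   1 - sum(pmax(0, raw)) / gross else NA_real_),
            class = "elimination_report")
}

#' @export
print.elimination_report <- function(x, ...) {
  print(x$report)
  cat(sprintf("proteins eliminated: %.3f; spectra eliminated: %.3f\n",
              x$proteins_eliminated, x$spectra_eliminated))
  invisible(x)
}
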