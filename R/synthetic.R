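zipf_probs <- function(n, s) {
  p <- seq_len(n)^(-s)
  p / sum(p)
}

#' Ground-truth configuration for the synthetic-data generator
#'
#' Describes a synthetic fractionation experiment with known truth: a
#' pool of genuine proteins of the fraction of interest, a cytosolic
#' (HSS) contaminant pool mixed into the gross fraction at a known share
#' `phi`, a plating-matrix pool observed in the matrix-control fraction,
#' and designated calibration contaminants placed at the top HSS
#' abundance ranks (the analogue of choosing serum albumin and
#' alpha-fetoprotein: abundant, hence low-variance multipliers).
#' Relative abundances within each pool follow a Zipf law; observed
#' counts are multinomial at the configured sequencing depths. The matrix
#' fraction carries a small trace of the true pool (`carryover`) but no
#' contaminants, so the generator's exact zeroing ratio is
#' `phi * depth / depth_hss`.
#'
#' @param n_true,n_contaminant,n_matrix pool sizes.
#' @param phi contamination share of gross spectra, in `[0, 1)`.
#' @param depth,depth_hss,depth_laminin total spectra per fraction.
#' @param carryover share of matrix-fraction spectra drawn from the true
#'   pool (adsorbed genuine protein), in `[0, 1)`.
#' @param zipf_s Zipf exponent for within-pool abundances.
#' @param n_calibration number of calibration contaminants (top HSS
#'   ranks).
#' @param universe_size,list_size,n_terms,term_size annotation-universe
#'   geometry for the planted-enrichment simulation.
#' @param planted_folds numeric vector of planted fold enrichments (one
#'   planted term per element); empty for a null generator.
#' @param seed integer seed governing all draws (per-stage substreams are
#'   derived from it deterministically).
#' @return object of class `"synthetic_truth"`.
#' @export
synthetic_truth <- function(n_true = 2000, n_contaminant = 300,
                            n_matrix = 50, phi = 0.3, depth = 1e5,
                            depth_hss = 1e5, depth_laminin = 5000,
                            carryover = 0.05, zipf_s = 1.1,
                            n_calibration = 2, universe_size = 3000,
                            list_size = 300, n_terms = 100,
                            term_size = 150, planted_folds = 3,
                            seed = 1) {
  stopifnot(phi >= 0, phi < 1, depth > 0, depth_hss > 0,
            depth_laminin >= 0, carryover >= 0, carryover < 1,
            n_calibration >= 1, n_calibration <= n_contaminant,
            zipf_s > 0, universe_size >= n_true || universe_size > 0)
  true_proteome <- sprintf("Gc%04d", seq_len(n_true))
  contaminants <- sprintf("Ct%03d", seq_len(n_contaminant))
  matrix_proteins <- sprintf("Mx%02d", seq_len(n_matrix))
  structure(list(
    n_true = n_true, n_contaminant = n_contaminant, n_matrix = n_matrix,
    true_proteome = true_proteome, contaminants = contaminants,
    matrix_proteins = matrix_proteins,
    calibration_ids = contaminants[seq_len(n_calibration)],
    phi = phi, depth = depth, depth_hss = depth_hss,
    depth_laminin = depth_laminin, carryover = carryover,
    zipf_s = zipf_s, universe_size = universe_size,
    list_size = list_size, n_terms = n_terms, term_size = term_size,
    planted_folds = planted_folds,
    zeroing_ratio = phi * depth / depth_hss,
    seed = as.integer(seed)), class = "synthetic_truth")
}

#' Generate a synthetic dataset with known ground truth
#'
#' Draws a spectral-count table, annotation term sets with planted
#' enrichments, and transcriptome family panels from a
#' [synthetic_truth()] configuration. Gross counts are multinomial over
#' `(1 - phi) * true pool + phi * HSS pool`; HSS counts are multinomial
#' over the contaminant pool; matrix-control counts are multinomial over
#' the matrix pool plus the true-pool carryover. Column sums equal the
#' configured depths exactly, and the whole draw is reproducible from
#' the seed.
#'
#' @param truth a [synthetic_truth()].
#' @return list with `counts` (a [spectral_count_table()] of every
#'   protein observed in any fraction), `annotations` (see
#'   [simulate_annotations()]), `panels` (list of
#'   [transcriptome_panel()]s), and `truth` (the configuration, echoed).
#' @export
generate_dataset <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  p_true <- zipf_probs(truth$n_true, truth$zipf_s)
  p_hss <- zipf_probs(truth$n_contaminant, truth$zipf_s)
  p_matrix <- if (truth$n_matrix > 0)
    zipf_probs(truth$n_matrix, truth$zipf_s) else numeric()

  symbols <- c(truth$true_proteome, truth$contaminants,
               truth$matrix_proteins)
  i_true <- seq_len(truth$n_true)
  i_cont <- truth$n_true + seq_len(truth$n_contaminant)
  i_matx <- truth$n_true + truth$n_contaminant + seq_len(truth$n_matrix)

  gross_p <- numeric(length(symbols))
  gross_p[i_true] <- (1 - truth$phi) * p_true
  gross_p[i_cont] <- truth$phi * p_hss
  lam_p <- numeric(length(symbols))
  if (truth$n_matrix > 0) {
    lam_p[i_true] <- truth$carryover * p_true
    lam_p[i_matx] <- (1 - truth$carryover) * p_matrix
  } else lam_p[i_true] <- p_true

  counts <- with_seed(substream(truth$seed, 1L), {
    gcp <- rmultinom(1, truth$depth, gross_p)[, 1]
    hss <- numeric(length(symbols))
    hss[i_cont] <- rmultinom(1, truth$depth_hss, p_hss)[, 1]
    lam <- if (truth$depth_laminin > 0 && sum(lam_p) > 0)
      rmultinom(1, truth$depth_laminin, lam_p)[, 1]
    else numeric(length(symbols))
    list(gcp = gcp, hss = hss, lam = lam)
  })
  observed <- counts$gcp + counts$hss + counts$lam > 0
  table <- spectral_count_table(symbols[observed], symbols[observed],
                                counts$gcp[observed],
                                counts$lam[observed],
                                counts$hss[observed])

  annotations <- simulate_annotations(
    universe_size = truth$universe_size,
    list_size = truth$list_size,
    n_terms = truth$n_terms,
    term_size = truth$term_size,
    planted_folds = truth$planted_folds,
    base_symbols = truth$true_proteome,
    seed = substream(truth$seed, 2L))

  panels <- with_seed(substream(truth$seed, 3L), {
    pool <- truth$true_proteome[seq_len(min(500, truth$n_true))]
    lapply(setNames(paste0("Family", 1:3), paste0("family", 1:3)),
           function(lab) {
             mem <- sample(pool, 15)
             idx <- match(mem, symbols)
             transcriptome_panel(
               symbol = mem,
               net_spectra = pmax(0, counts$gcp[idx] - counts$lam[idx]),
               transcript_detected = runif(15) < 0.4,
               family_label = lab)
           })
  })
  list(counts = table, annotations = annotations, panels = panels,
       truth = truth)
}

#' Simulate annotation term sets with planted enrichments
#'
#' Builds an annotation universe of `universe_size` symbols containing a
#' designated protein list of `list_size` symbols, then draws `n_terms`
#' null terms (members sampled uniformly from the universe, i.e. fold 1
#' in expectation) plus one planted term per element of `planted_folds`.
#' A term planted at fold `f` receives `round(f * K * n / N)` members
#' from the list and the remainder from outside it, so its realized fold
#' enrichment equals the target up to rounding.
#'
#' @param universe_size,list_size,n_terms,term_size geometry; `term_size`
#'   is `K`, the members per term.
#' @param planted_folds numeric vector of target folds (may be empty).
#' @param base_symbols optional symbols to seed the universe with (the
#'   generator passes the true proteome so list symbols are real
#'   proteins); padded with filler symbols up to `universe_size`.
#' @param seed RNG seed.
#' @return list with `terms` (named list of [annotation_set()]s),
#'   `universe`, `list_symbols`, `planted` (ids of planted terms).
#' @export
simulate_annotations <- function(universe_size = 3000, list_size = 300,
                                 n_terms = 100, term_size = 150,
                                 planted_folds = numeric(),
                                 base_symbols = NULL, seed = 1) {
  if (term_size > universe_size)
    stop("term_size exceeds universe_size")
  base <- unique(as.character(base_symbols))
  if (length(base) > universe_size) base <- base[seq_len(universe_size)]
  filler <- if (universe_size > length(base))
    sprintf("Ux%04d", seq_len(universe_size - length(base))) else character()
  universe <- c(base, filler)
  if (list_size > universe_size)
    stop("list_size exceeds universe_size")
  with_seed(seed, {
    list_symbols <- universe[seq_len(list_size)]
    off_list <- setdiff(universe, list_symbols)
    N <- universe_size; n <- list_size; K <- term_size
    terms <- list()
    planted_ids <- character()
    for (i in seq_along(planted_folds)) {
      f <- planted_folds[[i]]
      k_target <- round(f * K * n / N)
      if (k_target > min(n, K) || (K - k_target) > length(off_list))
        stop("pool sizes inconsistent with requested planted term ",
             "(fold ", f, ", K ", K, ", n ", n, ", N ", N, ")")
      id <- sprintf("PLANT%02d", i)
      members <- c(sample(list_symbols, k_target),
                   sample(off_list, K - k_target))
      terms[[id]] <- annotation_set(id, paste0("planted fold ", f),
                                    members, "simulated")
      planted_ids <- c(planted_ids, id)
    }
    for (i in seq_len(n_terms)) {
      id <- sprintf("T%03d", i)
      terms[[id]] <- annotation_set(id, "null term",
                                    sample(universe, K), "simulated")
    }
    list(terms = terms, universe = universe,
         list_symbols = list_symbols, planted = planted_ids)
  })
}

#' Score pipeline recovery against synthetic ground truth
#'
#' Measures how well each stage recovered the generator's truth:
#' \describe{
#'   \item{multiplier_rel_error}{relative error of the estimated mean
#'     multiplier against the generator's exact zeroing ratio
#'     `phi * depth / depth_hss`.}
#'   \item{contaminant_sensitivity}{fraction of contaminants observed in
#'     the gross fraction that were excluded from the net proteome.}
#'   \item{contaminant_spectra_eliminated}{fraction of the gross
#'     contaminant spectra removed by subtraction (spectra-weighted
#'     elimination).}
#'   \item{true_retention}{fraction of true-pool proteins observed in the
#'     gross fraction that survived into the net proteome.}
#'   \item{planted_recovery}{fraction of planted terms with Benjamini
#'     value below `alpha`.}
#'   \item{false_recovery}{fraction of non-planted tested terms with
#'     Benjamini value below `alpha`.}
#' }
#'
#' @param net [subtract_background()] result on the generated counts.
#' @param calib [compute_calibration_multipliers()] result, or `NULL`.
#' @param enrich_out [enrich()] result on the generated annotations, or
#'   `NULL` to skip term metrics.
#' @param truth the `truth` element of [generate_dataset()] output (the
#'   [synthetic_truth()]), plus the dataset's `annotations` when term
#'   metrics are wanted.
#' @param annotations the `annotations` element of the dataset.
#' @param alpha Benjamini significance cutoff for term recovery.
#' @return list of recovery metrics.
#' @export
evaluate_recovery <- function(net, calib = NULL, enrich_out = NULL,
                              truth, annotations = NULL, alpha = 0.05) {
  stopifnot(inherits(net, "net_proteome"),
            inherits(truth, "synthetic_truth"))
  gross <- net$gross
  contam_seen <- intersect(truth$contaminants,
                           names(gross)[gross > 0])
  true_seen <- intersect(truth$true_proteome, names(gross)[gross > 0])
  retained <- names(net$net_counts)
  out <- list(
    multiplier_rel_error = if (!is.null(calib))
      abs(calib$mean - truth$zeroing_ratio) / truth$zeroing_ratio
    else NA_real_,
    contaminant_sensitivity = if (length(contam_seen))
      mean(!(contam_seen %in% retained)) else NA_real_,
    contaminant_spectra_eliminated = if (length(contam_seen))
      validate_elimination(net, contam_seen)$spectra_eliminated
    else NA_real_,
    true_retention = if (length(true_seen))
      mean(true_seen %in% retained) else NA_real_,
    planted_recovery = NA_real_,
    false_recovery = NA_real_)
  if (!is.null(enrich_out) && !is.null(annotations)) {
    tested <- attr(enrich_out, "tested")
    if (is.null(tested)) tested <- enrich_out
    planted <- annotations$planted
    hit <- tested$term_id[tested$benjamini < alpha]
    if (length(planted))
      out$planted_recovery <- mean(planted %in% hit)
    null_terms <- setdiff(tested$term_id, planted)
    if (length(null_terms))
      out$false_recovery <- mean(null_terms %in% hit)
  }
  out
}
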