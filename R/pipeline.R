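#' Validate a pipeline configuration
#'
#' Collects and validates everything [run_pipeline()] needs. Exactly one
#' of `calibration_ids` (estimate the multiplier from the data) or
#' `multiplier` (use a fixed value) must be supplied. Optional inputs
#' switch their stage on: `groups_gmt` enables the abundance profile,
#' `gmt` the enrichment/clustering stage, `panels` the transcriptome
#' overlap stage.
#'
#' @param counts path to the spectral-count TSV.
#' @param out_dir output directory (created if needed).
#' @param calibration_ids calibration contaminant symbols, or `NULL`.
#' @param multiplier fixed background multiplier, or `NULL`.
#' @param dialect column mapping for [read_count_table()].
#' @param groups_gmt optional GMT of functional groups for the profile.
#' @param gmt optional named character vector of GMT paths, names taken
#'   as annotation categories.
#' @param universe `"gmt_union"` or `"detected"` (net proteome) as the
#'   enrichment background.
#' @param panels optional character vector of panel TSV paths.
#' @param top_threshold inclusive spectra threshold for the ranking.
#' @param term_min_count,ease_max enrichment report filters.
#' @param cluster_stringency `"low"`, `"medium"`, `"high"`.
#' @param include_zero denominator convention for [overlap_stats()].
#' @param seed seed recorded in the manifest and used for any stochastic
#'   stage (the correlation permutation test).
#' @return validated config list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(counts, out_dir,
                            calibration_ids = NULL, multiplier = NULL,
                            dialect = c(protein_id = "protein_id",
                                        symbol = "symbol", gcp = "gcp",
                                        laminin = "laminin", hss = "hss"),
                            groups_gmt = NULL, gmt = NULL,
                            universe = c("gmt_union", "detected"),
                            panels = NULL, top_threshold = 400,
                            term_min_count = 5, ease_max = 0.1,
                            cluster_stringency = "medium",
                            include_zero = FALSE, seed = 1) {
  if (is.null(calibration_ids) && is.null(multiplier))
    stop("config error: supply calibration_ids or a fixed multiplier")
  if (!is.null(multiplier) &&
      (!is.numeric(multiplier) || multiplier < 0))
    stop("config error: multiplier must be non-negative")
  if (top_threshold < 0 || term_min_count <= 0)
    stop("config error: thresholds must be positive")
  if (ease_max <= 0 || ease_max > 1)
    stop("config error: ease_max must lie in (0, 1]")
  structure(list(counts = counts, out_dir = out_dir,
                 calibration_ids = calibration_ids,
                 multiplier = multiplier, dialect = dialect,
                 groups_gmt = groups_gmt, gmt = gmt,
                 universe = match.arg(universe), panels = panels,
                 top_threshold = top_threshold,
                 term_min_count = term_min_count, ease_max = ease_max,
                 cluster_stringency = cluster_stringency,
                 include_zero = include_zero, seed = as.integer(seed)),
            class = "pipeline_config")
}

run_stage <- function(name, timings, expr) {
  t0 <- proc.time()[["elapsed"]]
  result <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  timings[[name]] <- proc.time()[["elapsed"]] - t0
  list(result = result, timings = timings)
}

#' Run the full correction / profiling / enrichment / overlap pipeline
#'
#' Executes the stages in order — background correction, abundance
#' profile, over-representation with annotation clustering, and
#' transcriptome overlap — writing one TSV per product plus a JSON run
#' manifest (config snapshot, seed, input checksums, stage timings).
#' Outputs are written atomically and a failed stage aborts the run with
#' a stage-named error after removing partial outputs. Two runs on the
#' same inputs with the same config are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with every stage product and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  outputs <- character()
  on_failure <- function(e) {
    if (length(outputs)) unlink(outputs)
    stop(e)
  }
  tryCatch({
    st <- run_stage("read", timings,
                    read_count_table(config$counts, config$dialect))
    table <- st$result; timings <- st$timings

    st <- run_stage("correct", timings, {
      calib <- if (is.null(config$multiplier))
        compute_calibration_multipliers(table, config$calibration_ids)
      else NULL
      m <- if (is.null(calib)) config$multiplier else calib$mean
      list(calib = calib, net = subtract_background(table, m))
    })
    calib <- st$result$calib; net <- st$result$net; timings <- st$timings
    out_net <- file.path(config$out_dir, "net_proteome.tsv")
    write_report(net, out_net)
    outputs <- c(outputs, out_net)

    ranked <- NULL; profile_tbl <- NULL
    st <- run_stage("profile", timings, {
      ranked <- top_proteins(net, config$top_threshold)
      prof <- data.frame(symbol = ranked$symbol,
                         net_count = ranked$net_count,
                         stringsAsFactors = FALSE)
      groups_frac <- NULL
      if (!is.null(config$groups_gmt)) {
        groups <- read_gmt(config$groups_gmt)
        groups_frac <- group_spectral_fraction(net, groups,
                                               restrict_to = ranked)
      }
      list(ranked = ranked, prof = prof, groups_frac = groups_frac)
    })
    ranked <- st$result$ranked; timings <- st$timings
    out_prof <- file.path(config$out_dir, "top_proteins.tsv")
    write_report(st$result$prof, out_prof)
    outputs <- c(outputs, out_prof)
    if (!is.null(st$result$groups_frac)) {
      gf <- st$result$groups_frac
      out_gf <- file.path(config$out_dir, "group_fractions.tsv")
      write_report(data.frame(group = names(gf),
                              pct_of_net_spectra = round_pct(unname(gf)),
                              stringsAsFactors = FALSE), out_gf)
      outputs <- c(outputs, out_gf)
    }

    enrichment <- NULL; clustering <- NULL
    if (!is.null(config$gmt)) {
      st <- run_stage("enrich", timings, {
        cats <- names(config$gmt)
        if (is.null(cats)) cats <- rep(NA_character_, length(config$gmt))
        terms <- unlist(lapply(seq_along(config$gmt), function(i)
          read_gmt(config$gmt[[i]], category = cats[[i]])),
          recursive = FALSE)
        uni <- if (config$universe == "detected")
          names(net$net_counts) else NULL
        res <- enrich(names(net$net_counts), terms, universe = uni,
                      min_count = config$term_min_count,
                      ease_max = config$ease_max)
        memberships <- setNames(lapply(terms, `[[`, "members"),
                                vapply(terms, `[[`, "", "term_id"))
        clustering <- if (nrow(res))
          cluster_terms(res, memberships, names(net$net_counts),
                        stringency = config$cluster_stringency)
        else list(clusters = list(), singletons = character())
        list(res = res, clustering = clustering)
      })
      enrichment <- st$result$res; clustering <- st$result$clustering
      timings <- st$timings
      out_enr <- file.path(config$out_dir, "enrichment.tsv")
      write_report(as.data.frame(enrichment), out_enr)
      out_cl <- file.path(config$out_dir, "clusters.tsv")
      ct <- clusters_as_table(clustering)
      if (is.null(ct))
        ct <- data.frame(cluster = integer(), enrichment_score = numeric(),
                         term_id = character())
      write_report(ct, out_cl)
      outputs <- c(outputs, out_enr, out_cl)
    }

    overlaps <- NULL
    if (!is.null(config$panels)) {
      st <- run_stage("overlap", timings, {
        lapply(config$panels, function(p)
          overlap_stats(read_panel(p),
                        include_zero = config$include_zero))
      })
      overlaps <- st$result; timings <- st$timings
      out_ov <- file.path(config$out_dir, "overlap.tsv")
      write_report(do.call(rbind, lapply(overlaps, as.data.frame)),
                   out_ov)
      outputs <- c(outputs, out_ov)
    }

    manifest_path <- file.path(config$out_dir, "manifest.json")
    manifest <- write_manifest(
      config = unclass(config),
      inputs = c(config$counts, config$groups_gmt,
                 unname(unlist(config$gmt)), config$panels),
      outputs = outputs, timings = unlist(timings),
      path = manifest_path)
    invisible(list(table = table, calibration = calib, net = net,
                   ranked = ranked, enrichment = enrichment,
                   clustering = clustering, overlaps = overlaps,
                   manifest = manifest, outputs = outputs,
                   manifest_path = manifest_path))
  }, error = on_failure)
}
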