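#' Normalize gene symbols to a canonical capitalization
#'
#' Symbols coming from different export tools mix conventions (e.g.
#' `Gap43` vs `GAP-43`). To prevent silent membership misses at joins,
#' symbols are normalized case-insensitively: whitespace trimmed, hyphens
#' removed, first character upper-cased and the remainder lower-cased
#' (the rodent gene-symbol convention).
#'
#' @param x character vector of gene symbols.
#' @return character vector of normalized symbols.
#' @examples
#' normalize_symbols(c("GAP-43", "gap43", " Mapt "))
#' @export
normalize_symbols <- function(x) {
  x <- gsub("-", "", trimws(as.character(x)), fixed = TRUE)
  bad <- !nzchar(x) | is.na(x)
  if (any(bad))
    stop("symbol empty after normalization at position(s): ",
         paste(which(bad), collapse = ", "))
  paste0(toupper(substr(x, 1L, 1L)), tolower(substr(x, 2L, nchar(x))))
}

#' Construct a spectral-count table
#'
#' A spectral-count table holds, per protein, the number of identifying
#' MS/MS spectra observed in the gross growth-cone-particle (GCP) fraction
#' and in the two background fractions: the plating-matrix ("laminin")
#' control and the cytosolic high-speed supernatant (HSS). Counts are
#' stored as non-negative reals because scaled subtraction produces
#' fractional values downstream.
#'
#' @param protein_id accession strings, unique after duplicate merging.
#' @param symbol gene symbols (normalized via [normalize_symbols()]).
#' @param gcp,laminin,hss non-negative spectral counts per fraction.
#' @param mol_weight optional molecular weights (kDa).
#' @return a `data.frame` of class `"spectral_count_table"`.
#' @export
spectral_count_table <- function(protein_id, symbol, gcp, laminin, hss,
                                 mol_weight = NA_real_) {
  protein_id <- as.character(protein_id)
  symbol <- normalize_symbols(symbol)
  counts <- list(gcp = gcp, laminin = laminin, hss = hss)
  for (nm in names(counts)) {
    v <- suppressWarnings(as.numeric(counts[[nm]]))
    if (anyNA(v))
      stop("non-numeric ", nm, " count at row(s): ",
           paste(which(is.na(v)), collapse = ", "))
    if (any(v < 0))
      stop("negative ", nm, " count at row(s): ",
           paste(which(v < 0), collapse = ", "))
    counts[[nm]] <- v
  }
  if (anyDuplicated(protein_id))
    stop("duplicate protein_id: ",
         paste(unique(protein_id[duplicated(protein_id)]), collapse = ", "))
  out <- data.frame(protein_id = protein_id, symbol = symbol,
                    mol_weight = as.numeric(mol_weight),
                    gcp = counts$gcp, laminin = counts$laminin,
                    hss = counts$hss, stringsAsFactors = FALSE)
  class(out) <- c("spectral_count_table", "data.frame")
  out
}

#' Read a spectral-count table from TSV
#'
#' Reads a tab-separated export with a header line. Column names in the
#' file are mapped to the canonical fields through `dialect`, so exports
#' with arbitrary headers can be ingested without editing the file.
#' Rows sharing an accession are merged by summing their counts (a warning
#' reports how many were merged).
#'
#' @param path TSV file with a header.
#' @param dialect named character vector mapping canonical fields
#'   (`protein_id`, `symbol`, `gcp`, `laminin`, `hss`, optionally
#'   `mol_weight`) to column names in the file.
#' @param strict_integer if `TRUE`, raw counts must be whole numbers
#'   (fresh instrument exports); the default accepts reals so that
#'   background-subtracted tables round-trip.
#' @return a [spectral_count_table()].
#' @export
read_count_table <- function(path,
                             dialect = c(protein_id = "protein_id",
                                         symbol = "symbol",
                                         gcp = "gcp",
                                         laminin = "laminin",
                                         hss = "hss"),
                             strict_integer = FALSE) {
  if (!file.exists(path)) stop("count table not found: ", path)
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character")
  required <- c("protein_id", "symbol", "gcp", "laminin", "hss")
  missing_map <- setdiff(required, names(dialect))
  if (length(missing_map))
    stop("dialect does not map required column(s): ",
         paste(missing_map, collapse = ", "))
  absent <- setdiff(unname(dialect[required]), names(raw))
  if (length(absent))
    stop("count table is missing column(s): ", paste(absent, collapse = ", "))

  num <- function(field) {
    v <- suppressWarnings(as.numeric(raw[[dialect[[field]]]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("unparseable ", field, " count at data row(s): ",
           paste(bad, collapse = ", "))
    neg <- which(v < 0)
    if (length(neg))
      stop("negative ", field, " count at data row(s): ",
           paste(neg, collapse = ", "))
    if (strict_integer && any(v != round(v)))
      stop("non-integer ", field, " count at data row(s): ",
           paste(which(v != round(v)), collapse = ", "))
    v
  }
  df <- data.frame(protein_id = as.character(raw[[dialect[["protein_id"]]]]),
                   symbol = as.character(raw[[dialect[["symbol"]]]]),
                   gcp = num("gcp"), laminin = num("laminin"),
                   hss = num("hss"), stringsAsFactors = FALSE)
  df$mol_weight <- if ("mol_weight" %in% names(dialect) &&
                       dialect[["mol_weight"]] %in% names(raw))
    suppressWarnings(as.numeric(raw[[dialect[["mol_weight"]]]])) else NA_real_

  if (anyDuplicated(df$protein_id)) {
    n_dup <- sum(duplicated(df$protein_id))
    warning("merged ", n_dup, " duplicate accession row(s) by summing counts")
    agg <- function(v, f) as.numeric(tapply(v, f, sum))
    f <- factor(df$protein_id, levels = unique(df$protein_id))
    df <- data.frame(protein_id = levels(f),
                     symbol = df$symbol[!duplicated(df$protein_id)],
                     gcp = agg(df$gcp, f), laminin = agg(df$laminin, f),
                     hss = agg(df$hss, f),
                     mol_weight = df$mol_weight[!duplicated(df$protein_id)],
                     stringsAsFactors = FALSE)
  }
  spectral_count_table(df$protein_id, df$symbol, df$gcp, df$laminin, df$hss,
                       df$mol_weight)
}

#' Read annotation term sets in GMT format
#'
#' Each line is `term_id <tab> description <tab> member...`. Members are
#' deduplicated and symbol-normalized. The annotation universe is supplied
#' later by the caller (see [enrich()]): a GMT file carries memberships
#' only.
#'
#' @param path GMT file.
#' @param category optional category label (`"cellular_component"`,
#'   `"biological_process"`, `"pathway"`) attached to every term.
#' @return list of annotation sets; each element is a list with
#'   `term_id`, `term_name`, `category`, `members`.
#' @export
read_gmt <- function(path, category = NA_character_) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop("GMT line ", i, " has fewer than 3 tab-separated fields")
    members <- unique(normalize_symbols(fields[-(1:2)]))
    out[[i]] <- annotation_set(fields[[1]], fields[[2]], members, category)
  }
  names(out) <- vapply(out, `[[`, "", "term_id")
  out
}

#' @rdname read_gmt
#' @param term_id,term_name,members components of one annotation set.
#' @export
annotation_set <- function(term_id, term_name, members,
                           category = NA_character_) {
  structure(list(term_id = as.character(term_id),
                 term_name = as.character(term_name),
                 category = as.character(category),
                 members = unique(as.character(members))),
            class = "annotation_set")
}

# ---- report writing ---------------------------------------------------------

write_tsv_atomic <- function(df, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  if (!file.rename(tmp, path)) stop("cannot write report: ", path)
  invisible(path)
}

#' Write a pipeline product to disk
#'
#' Tabular products (count tables, net proteomes, enrichment tables,
#' overlap panels) are written as TSV; writes are atomic (temp file +
#' rename) so a failed run never leaves a truncated report. Output is
#' byte-identical across runs on identical input.
#'
#' @param x a pipeline product.
#' @param path output file path.
#' @param ... passed to methods.
#' @return the path, invisibly.
#' @export
write_report <- function(x, path, ...) UseMethod("write_report")

#' @export
write_report.data.frame <- function(x, path, ...) write_tsv_atomic(x, path)

#' @export
write_report.net_proteome <- function(x, path, ...)
  write_tsv_atomic(as.data.frame(x), path)

#' @export
write_report.overlap_report <- function(x, path, ...)
  write_tsv_atomic(as.data.frame(x), path)

#' @export
write_report.calibration_result <- function(x, path, ...) {
  df <- data.frame(symbol = c(names(x$per_protein), "(mean)"),
                   multiplier = c(unname(x$per_protein), x$mean),
                   stringsAsFactors = FALSE)
  write_tsv_atomic(df, path)
}

#' Write a JSON run manifest
#'
#' Records everything needed to reproduce a run bit-for-bit: the config
#' snapshot, seed, md5 checksums of every input file, the output paths,
#' stage timings, and the package version.
#'
#' @param config configuration list (see [pipeline_config()]).
#' @param inputs character vector of input file paths (checksummed).
#' @param outputs character vector of output file paths.
#' @param timings named numeric vector of stage wall times (seconds).
#' @param path manifest destination (JSON).
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(config, inputs, outputs, timings, path) {
  inputs <- inputs[!vapply(inputs, is.null, TRUE)]
  manifest <- list(
    package = "gcproteome",
    version = as.character(packageVersion("gcproteome")),
    seed = config$seed,
    config = config[setdiff(names(config), "seed")],
    input_md5 = as.list(md5sum(unlist(inputs))),
    outputs = unname(unlist(outputs)),
    stage_seconds = as.list(round(timings, 3))
  )
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
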