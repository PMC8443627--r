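#' Construct a single-island community time series
#'
#' A `community_ts` holds one island's taxon-by-census presence/absence
#' matrix together with the census days. Census days are stored relative to
#' the island's first census (first = 0); only elapsed time enters any
#' downstream computation. Taxa never observed on the island are dropped.
#'
#' @param island_id Island label (length-1 character).
#' @param presence Logical or 0/1 integer matrix, taxa in rows (rownames are
#'   taxon identifiers), censuses in columns, ordered by time.
#' @param census_days Integer vector of sampling days, strictly increasing,
#'   one per census. Rebased so the first census is day 0.
#' @param counts Optional non-negative integer matrix with the same
#'   dimensions as `presence`; retained for depth-related diagnostics.
#'
#' @return An object of class `community_ts` with elements `island_id`,
#'   `taxon_ids`, `census_days`, `presence` (logical matrix) and, when
#'   supplied, `counts`.
#' @export
#' @examples
#' m <- matrix(c(1,1,0, 0,1,1), nrow = 3,
#'             dimnames = list(c("a","b","c"), NULL))
#' ts <- community_ts("TH1", m, census_days = c(0, 14))
#' ts$taxon_ids
community_ts <- function(island_id, presence, census_days, counts = NULL) {
  stopifnot(is.character(island_id), length(island_id) == 1L)
  presence <- as.matrix(presence)
  if (is.null(rownames(presence)))
    stop("presence matrix must have taxon identifiers as rownames")
  if (ncol(presence) < 2L)
    stop("a community time series needs at least 2 censuses")
  if (length(census_days) != ncol(presence))
    stop("census_days length must equal the number of censuses")
  census_days <- as.integer(census_days)
  if (any(diff(census_days) <= 0L))
    stop("census_days must be strictly increasing")
  census_days <- census_days - census_days[1L]
  mode(presence) <- "logical"
  colnames(presence) <- NULL  # censuses are identified by day, not label
  if (anyNA(presence)) stop("presence matrix contains NA")
  empty <- colSums(presence) == 0L
  if (any(empty))
    stop("island '", island_id, "' has censuses with zero observed taxa (",
         paste(which(empty), collapse = ", "), ")")
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    if (!identical(dim(counts), dim(presence)))
      stop("counts and presence dimensions differ")
    if (any(counts < 0)) stop("negative counts")
  }
  keep <- rowSums(presence) > 0L
  presence <- presence[keep, , drop = FALSE]
  if (!is.null(counts)) counts <- counts[keep, , drop = FALSE]
  structure(
    list(island_id = island_id,
         taxon_ids = rownames(presence),
         census_days = census_days,
         presence = presence,
         counts = counts),
    class = "community_ts")
}

#' @export
print.community_ts <- function(x, ...) {
  cat("Community time series: island", x$island_id, "\n")
  cat("  ", length(x$taxon_ids), "taxa x", ncol(x$presence),
      "censuses over", max(x$census_days), "days\n")
  cat("  per-census richness:",
      paste(colSums(x$presence), collapse = " "), "\n")
  invisible(x)
}

n_censuses <- function(ts) ncol(ts$presence)

#' Assemble an archipelago dataset
#'
#' Bundles the per-island time series with island size metadata, the pooled
#' regional taxon list ("regional pool": every taxon observed anywhere in
#' the archipelago over the whole survey) and each taxon's occurrence
#' frequency (number of samples, dataset-wide, in which it occurs). The
#' occurrence frequencies are the default weights of the Raup-Crick null
#' model.
#'
#' @param islands List of [community_ts()] objects, one per island.
#' @param metadata Data frame with one row per island and columns
#'   `island_id`, `area_cm2` (surface area), `volume_ml` (habitat volume),
#'   and optionally `area_sd`, `volume_sd` (per-census variability; 0 when a
#'   single measurement was taken).
#'
#' @return An object of class `archipelago` with elements `islands` (named
#'   list), `metadata`, `regional_pool` (sorted character vector) and
#'   `occurrence_freq` (named integer vector over the pool).
#' @export
archipelago <- function(islands, metadata) {
  stopifnot(is.list(islands), length(islands) >= 1L)
  ids <- vapply(islands, `[[`, "", "island_id")
  if (anyDuplicated(ids)) stop("duplicate island_id among islands")
  names(islands) <- ids
  md <- as.data.frame(metadata)
  req <- c("island_id", "area_cm2", "volume_ml")
  if (!all(req %in% names(md)))
    stop("metadata needs columns: ", paste(req, collapse = ", "))
  if (!all(ids %in% md$island_id))
    stop("metadata missing islands: ",
         paste(setdiff(ids, md$island_id), collapse = ", "))
  md <- md[match(ids, md$island_id), , drop = FALSE]
  rownames(md) <- NULL
  if (any(md$area_cm2 <= 0) || any(md$volume_ml <= 0))
    stop("island area and volume must be positive")
  if (is.null(md$area_sd)) md$area_sd <- 0
  if (is.null(md$volume_sd)) md$volume_sd <- 0

  pool <- sort(unique(unlist(lapply(islands, `[[`, "taxon_ids"),
                             use.names = FALSE)))
  freq <- integer(length(pool))
  names(freq) <- pool
  for (ts in islands) {
    occ <- rowSums(ts$presence)
    freq[names(occ)] <- freq[names(occ)] + occ
  }
  stopifnot(all(freq >= 1L))
  structure(
    list(islands = islands, metadata = md,
         regional_pool = pool, occurrence_freq = freq),
    class = "archipelago")
}

#' @export
print.archipelago <- function(x, ...) {
  cat("Archipelago:", length(x$islands), "islands,",
      length(x$regional_pool), "taxa in the regional pool\n")
  cat("  volumes (mL):",
      paste(signif(sort(x$metadata$volume_ml), 3), collapse = " "), "\n")
  invisible(x)
}

#' Read an archipelago dataset from TSV tables
#'
#' The taxon table is TSV with first column `taxon_id` and one integer
#' column per sample; the metadata table maps every sample column to
#' `island_id`, `day`, `area_cm2`, `volume_ml`. Samples are grouped by
#' island and ordered by day; presence is scored as count >=
#' `presence_threshold`. Island area/volume are averaged over the island's
#' sample rows (their SD is retained), which supports per-census size
#' remeasurement; constant columns give SD 0.
#'
#' @param taxon_table_path Path to the taxon-by-sample TSV.
#' @param metadata_path Path to the sample metadata TSV (columns
#'   `sample_id`, `island_id`, `day`, `area_cm2`, `volume_ml`).
#' @param presence_threshold Minimum count scored as a presence (default 1).
#' @return An [archipelago()] object.
#' @export
read_archipelago <- function(taxon_table_path, metadata_path,
                             presence_threshold = 1L) {
  tab <- utils::read.delim(taxon_table_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1L] != "taxon_id")
    stop("taxon table must have 'taxon_id' as its first column")
  if (anyDuplicated(tab$taxon_id)) stop("duplicate taxon_id rows")
  counts <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(counts) <- tab$taxon_id
  if (anyNA(counts) || any(counts < 0)) stop("negative or missing counts")

  md <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  req <- c("sample_id", "island_id", "day", "area_cm2", "volume_ml")
  if (!all(req %in% names(md)))
    stop("metadata needs columns: ", paste(req, collapse = ", "))
  unknown <- setdiff(md$sample_id, colnames(counts))
  if (length(unknown))
    stop("metadata refers to unknown sample columns: ",
         paste(unknown, collapse = ", "))
  missing <- setdiff(colnames(counts), md$sample_id)
  if (length(missing))
    stop("sample columns without metadata: ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(md[, c("island_id", "day")]))
    stop("duplicate (island_id, day) in metadata")

  islands <- list()
  meta_rows <- list()
  for (isl in unique(md$island_id)) {
    rows <- md[md$island_id == isl, , drop = FALSE]
    rows <- rows[order(rows$day), , drop = FALSE]
    cts <- counts[, rows$sample_id, drop = FALSE]
    pres <- cts >= presence_threshold
    if (any(colSums(pres) == 0L))
      stop("island '", isl, "' has samples with zero observed taxa at ",
           "presence_threshold = ", presence_threshold)
    islands[[isl]] <- community_ts(isl, pres, rows$day, counts = cts)
    meta_rows[[isl]] <- data.frame(
      island_id = isl,
      area_cm2 = mean(rows$area_cm2),
      volume_ml = mean(rows$volume_ml),
      area_sd = stats::sd(rows$area_cm2),
      volume_sd = stats::sd(rows$volume_ml))
  }
  meta <- do.call(rbind, meta_rows)
  meta$area_sd[is.na(meta$area_sd)] <- 0
  meta$volume_sd[is.na(meta$volume_sd)] <- 0
  archipelago(islands, meta)
}

#' Write an archipelago dataset as the TSV pair read_archipelago() reads
#'
#' Presence matrices are written as 0/1 counts (or the stored counts when
#' present). Sample columns are named `<island>_s<k>`.
#'
#' @param dataset An [archipelago()] object.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the two file paths (taxon table, metadata).
#' @export
write_archipelago <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "archipelago"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pool <- dataset$regional_pool
  cols <- list()
  meta <- list()
  for (ts in dataset$islands) {
    m <- if (is.null(ts$counts)) ts$presence * 1L else ts$counts
    full <- matrix(0L, length(pool), ncol(m), dimnames = list(pool, NULL))
    full[rownames(m), ] <- m
    ids <- sprintf("%s_s%02d", ts$island_id, seq_len(ncol(m)))
    colnames(full) <- ids
    cols[[ts$island_id]] <- full
    mrow <- dataset$metadata[dataset$metadata$island_id == ts$island_id, ]
    meta[[ts$island_id]] <- data.frame(
      sample_id = ids, island_id = ts$island_id, day = ts$census_days,
      area_cm2 = mrow$area_cm2, volume_ml = mrow$volume_ml)
  }
  tab <- data.frame(taxon_id = pool, do.call(cbind, cols),
                    check.names = FALSE)
  taxon_path <- file.path(out_dir, "taxon_table.tsv")
  meta_path <- file.path(out_dir, "sample_metadata.tsv")
  write_tsv(tab, taxon_path)
  write_tsv(do.call(rbind, meta), meta_path)
  invisible(c(taxon_table = taxon_path, metadata = meta_path))
}

# Deterministic TSV writer: fixed numeric precision so identical inputs
# give byte-identical files.
write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(x) formatC(x, format = "g",
                                                 digits = 10))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write result tables and a run summary
#'
#' Each element of `tables` is written as `<name>.tsv` with stable column
#' order and fixed floating-point precision; `run_info` (parameters, seeds,
#' package version) is written as `run_summary.json`. Re-running with the
#' same inputs reproduces byte-identical files.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory.
#' @param run_info Named list serialized to `run_summary.json` (optional).
#' @return Invisibly, the written paths.
#' @export
write_results <- function(tables, out_dir, run_info = NULL) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write_tsv(tables[[nm]], p)
    paths <- c(paths, p)
  }
  if (!is.null(run_info)) {
    p <- file.path(out_dir, "run_summary.json")
    jsonlite::write_json(run_info, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
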