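#' Construct a count table
#'
#' The central container of the pipeline: a taxa-by-samples matrix of
#' non-negative integer read counts with a kingdom tag. Taxa are always rows
#' internally; readers auto-detect and transpose the other orientation.
#'
#' @param counts integer matrix, taxa as rows, with unique dimnames.
#' @param kingdom one of "bacteria", "fungi".
#' @return an object of class `count_table`.
#' @export
count_table <- function(counts, kingdom = c("bacteria", "fungi")) {
  kingdom <- match.arg(kingdom)
  counts <- as.matrix(counts)
  if (length(counts) == 0L) abort("empty count table")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort("count table needs taxon (row) and sample (column) names")
  if (anyDuplicated(rownames(counts))) abort("duplicate taxon ids")
  if (anyDuplicated(colnames(counts))) abort("duplicate sample ids")
  if (!is.numeric(counts) || anyNA(counts)) abort("non-numeric cells in count table")
  if (any(counts < 0)) abort("negative counts")
  if (any(counts != round(counts))) abort("non-integer counts")
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, kingdom = kingdom), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d taxa x %d samples (%s), %s total reads\n",
              nrow(x$counts), ncol(x$counts), x$kingdom,
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Taxon and sample registries
#' @param x a `count_table`.
#' @return character vector of ids, in stored order.
#' @export
taxon_ids <- function(x) rownames(x$counts)

#' @rdname taxon_ids
#' @export
sample_ids <- function(x) colnames(x$counts)

#' Read a count table from TSV
#'
#' First column holds ids; remaining columns are numeric. Orientation is
#' auto-detected by default: the axis with more entries is taken as taxa
#' (OTU tables virtually always have more taxa than samples); force it with
#' `orientation` when that heuristic is wrong.
#'
#' @param path TSV file with a header row.
#' @param kingdom kingdom tag for the table.
#' @param orientation "auto", "taxa_rows" or "samples_rows".
#' @return a `count_table` (taxa as rows).
#' @export
read_count_table <- function(path, kingdom = c("bacteria", "fungi"),
                             orientation = c("auto", "taxa_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) abort("empty table: %s", path)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) abort("non-numeric cells in %s", path)
  rownames(m) <- ids
  if (orientation == "samples_rows" ||
      (orientation == "auto" && ncol(m) > nrow(m))) m <- t(m)
  count_table(m, kingdom)
}

#' Write a count table to TSV (taxa as rows)
#' @param x a `count_table`.
#' @param path output path.
#' @export
write_count_table <- function(x, path) {
  df <- data.frame(taxon_id = taxon_ids(x), x$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop low-count taxa
#'
#' Keeps taxa whose total read count is strictly greater than `min_total`
#' (default 20); the sample set is unchanged.
#'
#' @param x a `count_table`.
#' @param min_total non-negative integer threshold.
#' @return filtered `count_table`.
#' @export
filter_low_count <- function(x, min_total = 20L) {
  stopifnot(inherits(x, "count_table"), min_total >= 0)
  keep <- rowSums(x$counts) > min_total
  if (!any(keep)) abort("all %d taxa removed at min_total=%d", nrow(x$counts), min_total)
  count_table(x$counts[keep, , drop = FALSE], x$kingdom)
}

#' Rarefy samples to even depth
#'
#' Subsamples every column without replacement to exactly `depth` reads.
#' Samples whose total is below `depth` are dropped (and logged) rather than
#' erroring, matching common practice.
#'
#' @param x a `count_table`.
#' @param depth target reads per sample (>= 1).
#' @param seed integer seed; the result is deterministic given it.
#' @return rarefied `count_table`.
#' @export
rarefy <- function(x, depth, seed) {
  stopifnot(inherits(x, "count_table"))
  if (depth < 1) abort("rarefaction depth must be >= 1")
  totals <- colSums(x$counts)
  keep <- totals >= depth
  if (!any(keep)) abort("no sample reaches depth %d", depth)
  if (any(!keep))
    log_msg("rarefy: dropping %d sample(s) below depth %d: %s",
            sum(!keep), depth, paste(colnames(x$counts)[!keep], collapse = ", "))
  m <- x$counts[, keep, drop = FALSE]
  set.seed(seed)
  out <- apply(m, 2L, function(col) {
    reads <- rep.int(seq_along(col), col)
    tabulate(sample(reads, depth), nbins = length(col))
  })
  rownames(out) <- rownames(m)
  count_table(out, x$kingdom)
}

#' Read a rooted phylogeny (newick)
#'
#' @param path newick file; must carry branch lengths.
#' @param taxa optional character vector; tip labels must cover these taxa.
#' @return an `ape::phylo` tree.
#' @export
read_tree <- function(path, taxa = NULL) {
  tr <- ape::read.tree(path)
  if (is.null(tr$edge.length)) abort("tree has no branch lengths: %s", path)
  if (any(tr$edge.length < 0)) abort("negative branch lengths in %s", path)
  if (!is.null(taxa)) {
    missing <- setdiff(taxa, tr$tip.label)
    if (length(missing))
      abort("%d taxa missing from tree (e.g. %s)", length(missing), missing[1L])
  }
  tr
}

#' Read sample metadata from TSV
#'
#' Required columns: sample_id, cultivar, resistance (resistant/susceptible),
#' fertilization (control/fertilized), replicate, yield, plus the six soil
#' variables pH, AP, moisture, DOC, NH4N, NO3N.
#'
#' @param path TSV file.
#' @return a data.frame of class `sample_metadata`.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "cultivar", "resistance", "fertilization",
            "replicate", "yield", soil_vars())
  missing <- setdiff(need, names(df))
  if (length(missing)) abort("metadata missing column(s): %s", paste(missing, collapse = ", "))
  as_metadata(df)
}

#' Soil physicochemical variable names
#' @return character vector of the six soil column names.
#' @export
soil_vars <- function() c("pH", "AP", "moisture", "DOC", "NH4N", "NO3N")

as_metadata <- function(df) {
  if (anyDuplicated(df$sample_id)) abort("duplicate sample ids in metadata")
  if (!all(df$resistance %in% c("resistant", "susceptible")))
    abort("resistance must be resistant/susceptible")
  if (!all(df$fertilization %in% c("control", "fertilized")))
    abort("fertilization must be control/fertilized")
  if (any(df$yield < 0)) abort("negative yield")
  if (any(df$replicate < 1)) abort("replicate must be >= 1")
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Derive the four design groups CS/CR/FS/FR
#'
#' C/F = control/fertilized, S/R = susceptible/resistant.
#'
#' @param meta a `sample_metadata`.
#' @return factor with levels CS, CR, FS, FR, one per sample.
#' @export
sample_groups <- function(meta) {
  g <- paste0(ifelse(meta$fertilization == "control", "C", "F"),
              ifelse(meta$resistance == "susceptible", "S", "R"))
  factor(g, levels = c("CS", "CR", "FS", "FR"))
}

#' Write sample metadata to TSV
#' @param meta a `sample_metadata`.
#' @param path output path.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy table from TSV
#'
#' Columns: taxon_id plus the seven ranks domain..species. Rank-prefix
#' dialects ("g__Bacillus") are stripped; case is preserved. Missing ranks
#' may be empty strings.
#'
#' @param path TSV file.
#' @return data.frame of class `taxonomy`, one row per taxon.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("taxon_id", tax_ranks())
  missing <- setdiff(need, names(df))
  if (length(missing)) abort("taxonomy missing column(s): %s", paste(missing, collapse = ", "))
  if (anyDuplicated(df$taxon_id)) abort("duplicate taxon ids in taxonomy")
  for (r in tax_ranks()) {
    v <- as.character(df[[r]])
    v[is.na(v)] <- ""
    df[[r]] <- sub("^[a-zA-Z]__", "", v)
  }
  class(df) <- c("taxonomy", "data.frame")
  df
}

#' Taxonomic rank names (7 levels)
#' @return character vector domain..species.
#' @export
tax_ranks <- function() c("domain", "phylum", "class", "order", "family", "genus", "species")

#' Write a taxonomy table to TSV
#' @param tax a `taxonomy`.
#' @param path output path.
#' @export
write_taxonomy <- function(tax, path) {
  utils::write.table(tax, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a beneficial-taxa list
#'
#' A one-column TSV (header `key`) of taxonomy keys at one rank (default
#' genus). Matching downstream is case-insensitive exact string match.
#'
#' @param path TSV file.
#' @param rank rank level of the keys.
#' @return list of class `beneficial_list` with `keys` and `rank`.
#' @export
read_beneficial <- function(path, rank = "genus") {
  stopifnot(rank %in% tax_ranks())
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"key" %in% names(df)) abort("beneficial list needs a 'key' column")
  keys <- unique(as.character(df$key))
  keys <- keys[nzchar(keys)]
  if (!length(keys)) abort("beneficial list is empty")
  beneficial_list(keys, rank)
}

#' @rdname read_beneficial
#' @param keys character vector of taxonomy keys.
#' @export
beneficial_list <- function(keys, rank = "genus") {
  stopifnot(rank %in% tax_ranks(), length(keys) > 0)
  structure(list(keys = unique(as.character(keys)), rank = rank),
            class = "beneficial_list")
}
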