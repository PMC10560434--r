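#' Read a feature table from TSV
#'
#' The file must have a header row and the first column holding ids. Tables
#' stored features-in-rows (the common export of denoising pipelines) are
#' transposed to the canonical samples-in-rows orientation.
#'
#' @param path path to a tab-separated file.
#' @param orientation `"samples_in_rows"` or `"features_in_rows"`.
#' @param normalized state flag to record on the result (default `"raw"`).
#' @return a [feature_table].
#' @export
read_feature_table <- function(path,
                               orientation = c("samples_in_rows", "features_in_rows"),
                               normalized = "raw") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) est_format_error(sprintf("file not found: %s", path))
  nf <- utils::count.fields(path, sep = "\t", comment.char = "#", quote = "")
  nf <- nf[!is.na(nf)]
  if (length(nf) < 2) est_format_error(sprintf("%s: need a header and at least one row", path))
  if (length(unique(nf)) != 1) {
    bad <- which(nf != nf[1])[1]
    est_format_error(sprintf("%s: ragged row at line %d (%d fields, expected %d)",
                             path, bad, nf[bad], nf[1]))
  }
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE, quote = "")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    est_format_error(sprintf("%s: duplicate row ids: %s", path,
                             paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) est_format_error(sprintf("%s: non-numeric abundance values", path))
  rownames(m) <- ids
  if (anyDuplicated(colnames(m))) {
    est_format_error(sprintf("%s: duplicate column ids", path))
  }
  if (orientation == "features_in_rows") m <- t(m)
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    est_format_error(sprintf("%s: negative value at sample '%s', feature '%s'",
                             path, rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  feature_table(m, normalized = normalized)
}

#' Write a feature table as TSV (samples in rows)
#'
#' A comment line records the normalization state so round-trips preserve it.
#' @param x a [feature_table].
#' @param path output path.
#' @export
write_feature_table <- function(x, path) {
  x <- as_feature_table(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# normalized: %s", x$normalized), con)
  writeLines(paste(c("sample_id", feature_ids(x)), collapse = "\t"), con)
  apply_fmt <- function(v) {
    if (x$normalized %in% c("raw", "rarefied")) format(v, scientific = FALSE, trim = TRUE)
    else format(v, digits = 15, trim = TRUE)
  }
  for (i in seq_len(n_samples(x))) {
    writeLines(paste(c(sample_ids(x)[i], apply_fmt(x$values[i, ])), collapse = "\t"), con)
  }
  invisible(path)
}

#' Taxonomy maps
#'
#' A `taxonomy_map` links feature ids to a ranked lineage and carries the
#' three mutually exclusive domain flags used throughout the analysis:
#' `is_archaeon`, `is_bacterium`, and `is_phytoplankton` (chloroplast 16S
#' reads standing in for eukaryotic phytoplankton). A bacterial feature whose
#' lineage contains "Chloroplast" is flagged phytoplankton, not bacterium.
#'
#' @param df data.frame with columns `feature_id`, `domain`, `phylum`,
#'   `class`, `order`, `family`, `genus`.
#' @return a `taxonomy_map` (data.frame with added logical flag columns).
#' @export
taxonomy_map <- function(df) {
  req <- c("feature_id", "domain", "phylum", "class", "order", "family", "genus")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    est_format_error(sprintf("taxonomy missing columns: %s", paste(missing, collapse = ", ")))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (anyDuplicated(df$feature_id)) {
    est_format_error("taxonomy has duplicate feature ids")
  }
  lineage <- do.call(paste, c(df[c("phylum", "class", "order", "family", "genus")], sep = ";"))
  is_chloro <- grepl("chloroplast", lineage, ignore.case = TRUE)
  df$is_archaeon <- df$domain == "Archaea"
  df$is_phytoplankton <- df$domain == "Bacteria" & is_chloro
  df$is_bacterium <- df$domain == "Bacteria" & !is_chloro
  class(df) <- c("taxonomy_map", "data.frame")
  df
}

#' @rdname taxonomy_map
#' @param path tab-separated taxonomy file with the columns named above.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE, quote = "")
  taxonomy_map(df)
}

#' @rdname taxonomy_map
#' @param x a `taxonomy_map`.
#' @export
write_taxonomy <- function(x, path) {
  utils::write.table(
    x[, c("feature_id", "domain", "phylum", "class", "order", "family", "genus")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample metadata
#'
#' Expects a `sample_id` column plus design factors (`estuary`, `season`,
#' `station`) and numeric environmental covariates. Missing env values are
#' allowed here; modules that cannot handle them (network inference) reject
#' them at their own boundary.
#' @param path tab-separated metadata file.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE, quote = "")
  if (!"sample_id" %in% names(df)) est_format_error("metadata needs a 'sample_id' column")
  if (anyDuplicated(df$sample_id)) est_format_error("metadata has duplicate sample ids")
  df
}

#' @rdname read_sample_metadata
#' @param x metadata data.frame.
#' @export
write_sample_metadata <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an edge list (node_a, node_b, sign) as TSV
#' @param edges data.frame with at least columns node_a, node_b, sign.
#' @param path output path.
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
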