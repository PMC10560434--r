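#' Feature tables
#'
#' A `feature_table` is the package's canonical container for a
#' samples-by-features abundance matrix (ZOTU/ASV counts or normalized
#' values). Samples are always rows; features are always columns. The
#' `normalized` flag records the table's state: `"raw"` and `"rarefied"`
#' tables hold integer counts, `"css"` and `"clr"` tables hold reals.
#'
#' @param values numeric matrix, samples in rows with unique row names
#'   (sample ids) and unique column names (feature ids).
#' @param normalized one of `"raw"`, `"rarefied"`, `"css"`, `"clr"`.
#' @return an object of class `feature_table`.
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("f1", "f2")))
#' ft <- feature_table(m)
#' sample_ids(ft)
#' @export
feature_table <- function(values, normalized = c("raw", "rarefied", "css", "clr")) {
  normalized <- match.arg(normalized)
  if (!is.matrix(values) || !is.numeric(values)) {
    est_invalid("`values` must be a numeric matrix (samples x features)")
  }
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values)))) {
    est_invalid("`values` must carry sample ids (rownames) and feature ids (colnames)")
  }
  if (is.null(dimnames(values))) dimnames(values) <- list(character(0), character(0))
  if (anyDuplicated(rownames(values))) {
    est_invalid(sprintf("duplicate sample ids: %s",
                        paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", ")))
  }
  if (anyDuplicated(colnames(values))) {
    est_invalid(sprintf("duplicate feature ids: %s",
                        paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", ")))
  }
  if (anyNA(values)) est_invalid("`values` must not contain missing values")
  if (normalized != "clr" && any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    est_invalid(sprintf("negative abundance at sample '%s', feature '%s'",
                        rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  if (normalized %in% c("raw", "rarefied") && length(values) &&
      max(abs(values - round(values))) > 1e-8) {
    est_invalid(sprintf("state '%s' requires integer counts", normalized))
  }
  if (normalized %in% c("raw", "rarefied")) storage.mode(values) <- "integer"
  structure(list(values = values, normalized = normalized),
            class = "feature_table")
}

#' @rdname feature_table
#' @param x a `feature_table` (or coercible matrix / data.frame).
#' @export
ft_values <- function(x) {
  x <- as_feature_table(x)
  x$values
}

#' @rdname feature_table
#' @export
sample_ids <- function(x) rownames(ft_values(x))

#' @rdname feature_table
#' @export
feature_ids <- function(x) colnames(ft_values(x))

#' @rdname feature_table
#' @export
n_samples <- function(x) nrow(ft_values(x))

#' @rdname feature_table
#' @export
n_features <- function(x) ncol(ft_values(x))

#' @rdname feature_table
#' @export
normalization_state <- function(x) as_feature_table(x)$normalized

#' Coerce to a feature table
#'
#' Matrices and data frames are interpreted as samples-in-rows raw counts
#' unless a state is given.
#' @inheritParams feature_table
#' @export
as_feature_table <- function(x, normalized = "raw") {
  if (inherits(x, "feature_table")) return(x)
  if (is.data.frame(x)) x <- as.matrix(x)
  feature_table(x, normalized = normalized)
}

#' Replace the value matrix of a feature table, keeping/setting state
#' @noRd
ft_replace <- function(x, values, normalized = x$normalized) {
  feature_table(values, normalized = normalized)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features [%s]\n",
              n_samples(x), n_features(x), x$normalized))
  if (n_samples(x) > 0) {
    depth <- rowSums(x$values)
    cat(sprintf("  per-sample total: min %.4g, mean %.4g, max %.4g\n",
                min(depth), mean(depth), max(depth)))
  }
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Subset a feature table by sample and/or feature ids
#'
#' @param x a `feature_table`.
#' @param samples,features character vectors of ids (default: keep all).
#' @export
ft_subset <- function(x, samples = NULL, features = NULL) {
  x <- as_feature_table(x)
  v <- x$values
  if (!is.null(samples)) {
    missing <- setdiff(samples, rownames(v))
    if (length(missing)) {
      est_key_error(sprintf("unknown sample ids: %s", paste(missing, collapse = ", ")))
    }
    v <- v[samples, , drop = FALSE]
  }
  if (!is.null(features)) {
    missing <- setdiff(features, colnames(v))
    if (length(missing)) {
      est_key_error(sprintf("unknown feature ids: %s", paste(missing, collapse = ", ")))
    }
    v <- v[, features, drop = FALSE]
  }
  ft_replace(x, v)
}

#' Per-sample relative abundances of a feature table
#'
#' @param x a `feature_table` of counts.
#' @return matrix of row-wise proportions (rows sum to 1; all-zero rows stay 0).
#' @export
relative_abundance <- function(x) {
  v <- ft_values(as_feature_table(x))
  depth <- rowSums(v)
  out <- v / ifelse(depth == 0, 1, depth)
  storage.mode(out) <- "double"
  out
}
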