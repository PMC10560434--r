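#' Drop samples with too few reads
#'
#' Removes samples whose total read count is strictly below `min_reads`
#' (archaeal sub-tables from universal-primer surveys are often extremely
#' shallow in some samples; such samples carry no usable compositional
#' signal). Sample order is preserved.
#'
#' @param table a raw-count [feature_table].
#' @param min_reads minimum total reads to keep a sample (default 100).
#' @return the filtered [feature_table].
#' @export
drop_low_depth_samples <- function(table, min_reads = 100) {
  table <- as_feature_table(table)
  if (!table$normalized %in% c("raw", "rarefied")) {
    est_invalid("drop_low_depth_samples expects raw counts")
  }
  keep <- rowSums(table$values) >= min_reads
  if (!any(keep)) {
    est_empty_result(sprintf("all %d samples fall below %d reads", n_samples(table), min_reads))
  }
  ft_replace(table, table$values[keep, , drop = FALSE])
}

#' Abundance/prevalence pre-filter for network inference
#'
#' Keeps a feature iff its total read count across samples is at least
#' `min_total` AND it is detected (count > 0) in at least
#' `ceiling(min_prevalence * n_samples)` samples. Both boundaries are
#' inclusive. The defaults match the standard co-occurrence pre-filter
#' (>= 100 reads, present in >= 15% of samples).
#'
#' @param table a raw-count [feature_table].
#' @param min_total minimum total reads per feature (default 100).
#' @param min_prevalence minimum fraction of samples with a detection
#'   (default 0.15).
#' @return the filtered [feature_table]; warns if no feature survives.
#' @export
filter_for_network <- function(table, min_total = 100, min_prevalence = 0.15) {
  table <- as_feature_table(table)
  if (!table$normalized %in% c("raw", "rarefied")) {
    est_invalid("filter_for_network expects raw counts")
  }
  v <- table$values
  need_samples <- ceiling(min_prevalence * nrow(v))
  keep <- colSums(v) >= min_total & colSums(v > 0) >= need_samples
  if (!any(keep)) {
    warning("filter_for_network: no feature passes the abundance/prevalence filter")
  }
  ft_replace(table, v[, keep, drop = FALSE])
}

#' Restrict a feature table to one domain
#'
#' @param table a [feature_table].
#' @param taxonomy a [taxonomy_map] covering every feature in `table`.
#' @param domain_flag one of `"is_archaeon"`, `"is_bacterium"`,
#'   `"is_phytoplankton"`.
#' @return the [feature_table] restricted to flagged features (counts unchanged).
#' @export
subset_by_domain <- function(table, taxonomy,
                             domain_flag = c("is_archaeon", "is_bacterium", "is_phytoplankton")) {
  domain_flag <- match.arg(domain_flag)
  table <- as_feature_table(table)
  missing <- setdiff(feature_ids(table), taxonomy$feature_id)
  if (length(missing)) {
    est_key_error(sprintf("features absent from taxonomy: %s",
                          paste(utils::head(missing, 10), collapse = ", ")))
  }
  flagged <- taxonomy$feature_id[taxonomy[[domain_flag]]]
  keep <- intersect(feature_ids(table), flagged)
  ft_replace(table, table$values[, keep, drop = FALSE])
}

#' Per-sample relative abundance of a taxonomic group
#'
#' Computes, for each sample, the fraction of reads assigned to a group of
#' features over a chosen denominator — e.g. the share of a genus, or of all
#' archaea, in the whole prokaryotic community.
#'
#' @param table a raw or rarefied [feature_table].
#' @param taxonomy a [taxonomy_map].
#' @param group either `"all"`, a character vector of feature ids, or a named
#'   length-1 character like `c(genus = "Nitrosopumilus")` selecting features
#'   by rank value. A domain flag name (e.g. `"is_archaeon"`) is also accepted.
#' @param denominator `"all_features"` (sample total) or a domain flag name,
#'   in which case the denominator is that flagged subset's reads.
#' @return named numeric vector of per-sample proportions in [0, 1]; `NA`
#'   where the denominator is zero.
#' @export
relative_abundance_of <- function(table, taxonomy, group = "all",
                                  denominator = "all_features") {
  table <- as_feature_table(table)
  if (!table$normalized %in% c("raw", "rarefied")) {
    est_invalid("relative_abundance_of expects count data")
  }
  v <- table$values
  flag_cols <- c("is_archaeon", "is_bacterium", "is_phytoplankton")

  select_features <- function(sel) {
    if (identical(sel, "all") || identical(sel, "all_features")) return(feature_ids(table))
    if (length(sel) == 1 && sel %in% flag_cols) {
      return(intersect(feature_ids(table), taxonomy$feature_id[taxonomy[[sel]]]))
    }
    if (!is.null(names(sel)) && length(sel) == 1 && names(sel) %in%
        c("domain", "phylum", "class", "order", "family", "genus")) {
      rank <- names(sel)
      return(intersect(feature_ids(table),
                       taxonomy$feature_id[taxonomy[[rank]] == sel[[1]]]))
    }
    missing <- setdiff(sel, feature_ids(table))
    if (length(missing)) {
      est_key_error(sprintf("unknown features: %s", paste(missing, collapse = ", ")))
    }
    sel
  }

  num_feats <- select_features(group)
  den_feats <- select_features(denominator)
  num <- rowSums(v[, num_feats, drop = FALSE])
  den <- rowSums(v[, den_feats, drop = FALSE])
  out <- ifelse(den == 0, NA_real_, num / den)
  names(out) <- sample_ids(table)
  out
}

#' Shared and unique feature counts across groups
#'
#' For every nonempty subset of the given groups, counts the features present
#' (nonzero in at least one sample) in exactly those groups — the numbers a
#' Venn diagram displays. Patterns partition the union of detected features.
#'
#' @param tables_by_group named list of [feature_table]s (>= 2 groups).
#' @return data.frame with columns `pattern` (group names joined by `&`),
#'   `n_groups`, and `count`, one row per nonempty membership pattern
#'   (including zero-count patterns).
#' @export
shared_feature_counts <- function(tables_by_group) {
  if (length(tables_by_group) < 2 || is.null(names(tables_by_group))) {
    est_invalid("need a named list of at least two feature tables")
  }
  groups <- names(tables_by_group)
  present <- lapply(tables_by_group, function(t) {
    t <- as_feature_table(t)
    feature_ids(t)[colSums(t$values > 0) > 0]
  })
  universe <- sort(unique(unlist(present)))
  member <- vapply(present, function(f) universe %in% f, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1, dimnames = list(NULL, groups))
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), length(groups)))[-1, , drop = FALSE]
  names(patterns) <- groups
  key <- apply(member, 1, function(row) paste(groups[row], collapse = "&"))
  data.frame(
    pattern = apply(patterns, 1, function(row) paste(groups[as.logical(row)], collapse = "&")),
    n_groups = rowSums(patterns),
    count = vapply(apply(patterns, 1, function(row) paste(groups[as.logical(row)], collapse = "&")),
                   function(p) sum(key == p), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
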