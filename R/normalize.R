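#' Rarefy a count table to even depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' (multivariate hypergeometric draw, via [vegan::rrarefy]). Samples whose
#' total is below `depth` are dropped with a warning, matching the usual
#' workflow of rarefying after discarding shallow samples.
#'
#' @param table a raw-count [feature_table].
#' @param depth target reads per sample.
#' @param seed integer seed; the draw is deterministic given it.
#' @return a [feature_table] with state `"rarefied"`; every row sums to `depth`.
#' @export
rarefy <- function(table, depth, seed = 1) {
  table <- as_feature_table(table)
  if (table$normalized != "raw") est_invalid("rarefy expects raw counts")
  if (length(depth) != 1 || depth <= 0 || depth != round(depth)) {
    est_invalid("`depth` must be a positive integer")
  }
  totals <- rowSums(table$values)
  keep <- totals >= depth
  if (!all(keep)) {
    warning(sprintf("rarefy: dropping %d sample(s) below depth %d: %s",
                    sum(!keep), depth,
                    paste(sample_ids(table)[!keep], collapse = ", ")))
  }
  if (!any(keep)) est_empty_result("rarefy: no sample reaches the requested depth")
  v <- table$values[keep, , drop = FALSE]
  out <- with_seed(seed, withCallingHandlers(
    vegan::rrarefy(v, depth),
    # rrarefy nags when the rarest nonzero count exceeds 1; irrelevant here
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) invokeRestart("muffleWarning")
    }))
  ft_replace(table, out, normalized = "rarefied")
}

#' Cumulative sum scaling parameters
#'
#' @param quantile_l quantile (strictly inside (0,1)) of each sample's
#'   *nonzero* counts up to which counts are cumulated into the scaling
#'   factor. Default 0.5 (the median), fixed rather than searched adaptively.
#' @param scale_constant target scale after division (default 1000,
#'   "per-thousand" reads).
#' @param log_transform if TRUE, apply log2(x + 1) last.
#' @export
css_params <- function(quantile_l = 0.5, scale_constant = 1000, log_transform = FALSE) {
  if (quantile_l <= 0 || quantile_l >= 1) est_invalid("`quantile_l` must be in (0, 1)")
  if (scale_constant <= 0) est_invalid("`scale_constant` must be positive")
  list(quantile_l = quantile_l, scale_constant = scale_constant,
       log_transform = isTRUE(log_transform))
}

#' Cumulative sum scaling (CSS) normalization
#'
#' Per sample j, the scaling factor s_j is the sum of counts c_ij with
#' c_ij <= q_j(l), where q_j(l) is the l-th quantile (linear interpolation,
#' [stats::quantile] type 7) of the sample's nonzero counts. Normalized
#' values are c_ij / s_j * scale_constant. CSS damps the influence of the
#' few dominant features that drive per-sample depth differences, without
#' discarding reads as rarefaction does.
#'
#' @param table a raw-count [feature_table] with at least one nonzero count
#'   per sample.
#' @param params a [css_params] list.
#' @return a [feature_table] with state `"css"`.
#' @export
css_normalize <- function(table, params = css_params()) {
  table <- as_feature_table(table)
  if (table$normalized != "raw") est_invalid("css_normalize expects raw counts")
  v <- table$values
  storage.mode(v) <- "double"
  out <- v
  for (j in seq_len(nrow(v))) {
    cj <- v[j, ]
    nz <- cj[cj > 0]
    if (length(nz) == 0) {
      est_invalid(sprintf("css_normalize: sample '%s' has no nonzero counts",
                          rownames(v)[j]))
    }
    q <- stats::quantile(nz, probs = params$quantile_l, names = FALSE, type = 7)
    s <- sum(cj[cj <= q])
    if (s <= 0) {
      est_invalid(sprintf("css_normalize: zero scaling factor for sample '%s'",
                          rownames(v)[j]))
    }
    out[j, ] <- cj / s * params$scale_constant
  }
  if (params$log_transform) out <- log2(out + 1)
  ft_replace(table, out, normalized = "css")
}
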