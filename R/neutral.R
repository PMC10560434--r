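#' Expected occurrence frequency under the neutral model
#'
#' Under neutral assembly, a taxon with source relative abundance p has a
#' local relative abundance following Beta(Nm p, Nm (1 - p)), where N is the
#' local community size (reads) and m the migration rate. The probability of
#' detecting it at >= d reads is therefore
#' 1 - I(d/N; Nm p, Nm (1 - p)), with I the regularized incomplete beta
#' function (the beta CDF).
#'
#' @param p source relative abundance(s), in [0, 1] (vectorized).
#' @param Nm product of community size and migration rate (> 0).
#' @param N local community size in reads.
#' @param d detection limit in reads (1 <= d <= N).
#' @return expected occurrence frequency in [0, 1]; monotone in p.
#' @examples
#' expected_frequency(c(1e-4, 1e-3, 1e-2), Nm = 1000, N = 10000)
#' @export
expected_frequency <- function(p, Nm, N, d = 1) {
  if (any(p < 0 | p > 1)) est_invalid("`p` must lie in [0, 1]")
  if (Nm <= 0) est_invalid("`Nm` must be positive")
  if (d < 1 || d > N) est_invalid("`d` must satisfy 1 <= d <= N")
  out <- numeric(length(p))
  inner <- p > 0 & p < 1
  out[p >= 1] <- 1
  if (any(inner)) {
    out[inner] <- 1 - stats::pbeta(d / N, Nm * p[inner], Nm * (1 - p[inner]))
  }
  out
}

#' Wilson score interval for a proportion
#' @noRd
wilson_interval <- function(p_hat, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  denom <- 1 + z^2 / n
  center <- (p_hat + z^2 / (2 * n)) / denom
  half <- z / denom * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2))
  list(low = pmax(0, center - half), high = pmin(1, center + half))
}

#' Fit the Sloan neutral community model
#'
#' Estimates Nm by least squares on the occurrence-frequency scale: observed
#' per-taxon detection frequencies in the local samples are regressed on the
#' model curve [expected_frequency] evaluated at each taxon's source
#' abundance p. The 95% envelope is the Wilson score interval around the
#' fitted curve with n = number of local samples; taxa are partitioned into
#' `above` / `neutral` / `below` by strict comparison against the envelope
#' (boundaries count as neutral).
#'
#' Only taxa with p > 0 and observed frequency > 0 contribute points to the
#' fit (a taxon never detected locally has no point on the frequency curve).
#'
#' @param local local-community [feature_table] (raw or rarefied counts,
#'   >= 5 samples).
#' @param source source ("species pool") abundances: a [feature_table] whose
#'   features are a superset of `local`'s, a named numeric vector of relative
#'   abundances, or `NULL` to use the local table's own mean relative
#'   abundance.
#' @param N local community size in reads; `"auto"` (default) uses the
#'   rounded mean local row sum.
#' @param d detection limit in reads (default 1).
#' @param ci_level envelope confidence level (default 0.95).
#' @return an `ncm_fit`: list with `Nm`, `m`, `N`, `d`, `r_squared`,
#'   `n_samples`, and `points` (data.frame taxon_id, p, freq_obs, freq_pred,
#'   ci_low, ci_high, category).
#' @export
fit_ncm <- function(local, source = NULL, N = "auto", d = 1, ci_level = 0.95) {
  local <- as_feature_table(local)
  if (!local$normalized %in% c("raw", "rarefied")) {
    est_invalid("fit_ncm expects count data")
  }
  n_loc <- n_samples(local)
  if (n_loc < 5) est_invalid("fit_ncm needs at least 5 local samples")
  if (identical(N, "auto")) N <- round(mean(rowSums(local$values)))
  N <- as.numeric(N)
  if (N < 1) est_invalid("`N` must be >= 1")

  feats <- feature_ids(local)
  p <- if (is.null(source)) {
    colMeans(relative_abundance(local))
  } else if (inherits(source, "feature_table") || is.matrix(source) || is.data.frame(source)) {
    source <- as_feature_table(source)
    missing <- setdiff(feats, feature_ids(source))
    if (length(missing)) {
      est_key_error(sprintf("local features absent from source: %s",
                            paste(utils::head(missing, 10), collapse = ", ")))
    }
    colMeans(relative_abundance(source))[feats]
  } else if (is.numeric(source)) {
    missing <- setdiff(feats, names(source))
    if (length(missing)) {
      est_key_error(sprintf("local features absent from source vector: %s",
                            paste(utils::head(missing, 10), collapse = ", ")))
    }
    source[feats]
  } else {
    est_invalid("`source` must be a feature table, a named numeric vector, or NULL")
  }

  freq_obs <- colMeans(local$values >= d)
  fit_ncm_curve(p = stats::setNames(as.numeric(p), feats),
                freq_obs = stats::setNames(as.numeric(freq_obs), feats),
                N = N, d = d, n_samples = n_loc, ci_level = ci_level)
}

#' Fit the neutral-model curve to (p, frequency) pairs
#'
#' Lower-level interface behind [fit_ncm], for callers who already hold the
#' per-taxon source abundances and observed occurrence frequencies. Only
#' pairs with p > 0 and freq_obs > 0 enter the least-squares objective; all
#' taxa receive predictions, envelope bounds, and categories.
#'
#' @param p named source relative abundances.
#' @param freq_obs named observed occurrence frequencies (same taxa).
#' @param N local community size in reads.
#' @param d detection limit in reads.
#' @param n_samples number of local samples behind `freq_obs` (sets the
#'   envelope width).
#' @param ci_level envelope confidence level.
#' @return an `ncm_fit` (see [fit_ncm]).
#' @export
fit_ncm_curve <- function(p, freq_obs, N, d = 1, n_samples, ci_level = 0.95) {
  if (length(p) != length(freq_obs)) est_invalid("p and freq_obs must align")
  feats <- names(p)
  if (is.null(feats)) feats <- paste0("t", seq_along(p))
  fit_on <- p > 0 & freq_obs > 0
  pf <- as.numeric(p[fit_on]); ff <- as.numeric(freq_obs[fit_on])
  if (length(unique(ff)) < 3) {
    est_degenerate_fit("fewer than 3 distinct observed frequencies; curve is unidentifiable")
  }

  sse_of <- function(Nm) sum((ff - expected_frequency(pf, Nm, N, d))^2)
  Nm_hat <- tryCatch({
    fit <- minpack.lm::nlsLM(
      ff ~ 1 - pbeta(d / N, Nm * pf, Nm * (1 - pf)),
      start = list(Nm = 0.1 * N), lower = 1e-9, upper = N,
      control = minpack.lm::nls.lm.control(maxiter = 500))
    as.numeric(stats::coef(fit)[["Nm"]])
  }, error = function(e) {
    # deterministic 1-D fallback: golden-section on log(Nm)
    opt <- stats::optimize(function(l) sse_of(exp(l)),
                           interval = c(log(1e-6), log(N)), tol = 1e-10)
    exp(opt$minimum)
  })
  if (!is.finite(Nm_hat) || Nm_hat <= 0) {
    est_fit_error(sprintf("neutral-model fit failed (Nm = %s)", format(Nm_hat)))
  }

  freq_pred <- expected_frequency(as.numeric(p), Nm_hat, N, d)
  sse <- sse_of(Nm_hat)
  sst <- sum((ff - mean(ff))^2)
  r_squared <- 1 - sse / sst

  ci <- wilson_interval(freq_pred, n_samples, ci_level)
  # Discreteness correction at the envelope boundaries: with n samples an
  # observed frequency of exactly 1 (or 0) is not evidence of departure when
  # the fitted model itself gives it probability above alpha/2, yet any
  # sub-1 interval bound would flag it. Widen the envelope to the boundary
  # in that saturated regime; the informative mid-curve region is untouched.
  alpha2 <- (1 - ci_level) / 2
  ci$high[freq_pred^n_samples > alpha2] <- 1
  ci$low[(1 - freq_pred)^n_samples > alpha2] <- 0
  category <- envelope_category(as.numeric(freq_obs), ci$low, ci$high)

  structure(list(
    Nm = Nm_hat, m = Nm_hat / N, N = N, d = d, r_squared = r_squared,
    n_samples = n_samples, ci_level = ci_level,
    points = data.frame(
      taxon_id = feats, p = as.numeric(p), freq_obs = as.numeric(freq_obs),
      freq_pred = freq_pred, ci_low = ci$low, ci_high = ci$high,
      category = category, in_fit = fit_on,
      row.names = NULL, stringsAsFactors = FALSE)
  ), class = "ncm_fit")
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat(sprintf("<ncm_fit> Nm = %.1f, m = %.4g, N = %g, d = %d, R^2 = %.3f (%d samples, %d taxa)\n",
              x$Nm, x$m, x$N, x$d, x$r_squared, x$n_samples, nrow(x$points)))
  cat("  categories:", paste(sprintf("%s=%d", names(table(x$points$category)),
                                     table(x$points$category)), collapse = ", "), "\n")
  invisible(x)
}

#' Three-way partition against the prediction envelope
#'
#' Strict inequalities define departure; a frequency exactly on a boundary
#' is neutral ("within the confidence interval" read inclusively).
#' @noRd
envelope_category <- function(freq_obs, ci_low, ci_high) {
  category <- rep("neutral", length(freq_obs))
  category[freq_obs > ci_high] <- "above"
  category[freq_obs < ci_low] <- "below"
  category
}

#' Classify focal taxa against the neutral envelope
#'
#' @param fit an `ncm_fit` from [fit_ncm].
#' @param focal feature ids to classify (must all be in the fit).
#' @return named character vector of categories
#'   (`above` / `neutral` / `below`).
#' @export
classify_taxa <- function(fit, focal) {
  stopifnot(inherits(fit, "ncm_fit"))
  missing <- setdiff(focal, fit$points$taxon_id)
  if (length(missing)) {
    est_key_error(sprintf("focal taxa absent from fit: %s",
                          paste(utils::head(missing, 10), collapse = ", ")))
  }
  stats::setNames(fit$points$category[match(focal, fit$points$taxon_id)], focal)
}

#' Cumulative relative abundance per assembly category
#'
#' Attributes the focal taxa's reads to the neutral / above / below
#' categories: the share of focal reads carried by neutrally distributed
#' taxa measures the relative importance of stochastic assembly, the rest
#' of selection.
#'
#' @param local local-community [feature_table] (counts).
#' @param categories named character vector (from [classify_taxa]) covering
#'   `focal`.
#' @param focal feature ids over which to partition.
#' @return named numeric `c(neutral=, above=, below=)` summing to 1.
#' @export
partition_abundance <- function(local, categories, focal) {
  local <- as_feature_table(local)
  missing <- setdiff(focal, names(categories))
  if (length(missing)) {
    est_key_error(sprintf("categories missing for: %s", paste(missing, collapse = ", ")))
  }
  missing_tab <- setdiff(focal, feature_ids(local))
  if (length(missing_tab)) {
    est_key_error(sprintf("focal taxa absent from table: %s", paste(missing_tab, collapse = ", ")))
  }
  reads <- colSums(local$values[, focal, drop = FALSE])
  total <- sum(reads)
  if (total == 0) est_empty_result("focal taxa carry zero reads")
  out <- c(neutral = 0, above = 0, below = 0)
  for (cat in names(out)) out[cat] <- sum(reads[categories[focal] == cat]) / total
  out
}
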