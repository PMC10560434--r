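#' Validate / coerce a distance matrix
#' @noRd
as_distance_matrix <- function(D, what = "D") {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (!is.matrix(D) || nrow(D) != ncol(D)) {
    est_invalid(sprintf("`%s` must be a square matrix or dist object", what))
  }
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("s", seq_len(nrow(D)))
  }
  if (max(abs(D - t(D))) > 1e-12) est_invalid(sprintf("`%s` is not symmetric", what))
  if (any(diag(D) != 0)) est_invalid(sprintf("`%s` must have a zero diagonal", what))
  if (any(D < 0)) est_invalid(sprintf("`%s` has negative entries", what))
  D
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = sum|x_i - y_i| / sum(x_i + y_i), computed between all sample
#' pairs of a (count or normalized) feature table.
#'
#' @param table a [feature_table] or samples-by-features matrix with
#'   nonnegative values and no all-zero sample.
#' @return symmetric matrix with zero diagonal, entries in [0, 1], dimnames
#'   = sample ids.
#' @export
bray_curtis <- function(table) {
  v <- if (inherits(table, "feature_table")) ft_values(table) else as.matrix(table)
  if (any(v < 0)) est_invalid("bray_curtis requires nonnegative values")
  zero <- rowSums(v) == 0
  if (any(zero)) {
    est_invalid(sprintf("all-zero sample(s): %s",
                        paste(rownames(v)[zero], collapse = ", ")))
  }
  n <- nrow(v)
  D <- matrix(0, n, n, dimnames = list(rownames(v), rownames(v)))
  for (i in seq_len(n - 1)) {
    xi <- v[i, ]
    for (j in seq(i + 1, n)) {
      D[i, j] <- D[j, i] <- sum(abs(xi - v[j, ])) / sum(xi + v[j, ])
    }
  }
  D
}

#' Gower-centered inner-product matrix of a distance matrix
#' @noRd
gower_center <- function(D) {
  n <- nrow(D)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

#' Principal coordinate analysis
#'
#' Eigendecomposes the Gower-centered matrix -1/2 J D^2 J. Negative
#' eigenvalues (from non-Euclidean dissimilarities such as Bray-Curtis) are
#' reported as-is, not corrected; proportion explained is computed over
#' positive eigenvalues only.
#'
#' @param D distance matrix (square symmetric, zero diagonal) or `dist`.
#' @param n_axes number of axes to return (default: all with positive
#'   eigenvalue).
#' @return list with `coordinates` (samples x axes), `eigenvalues` (all n,
#'   descending), `proportion_explained` (per returned axis).
#' @export
pcoa <- function(D, n_axes = NULL) {
  D <- as_distance_matrix(D)
  n <- nrow(D)
  if (!is.null(n_axes) && n_axes > n) {
    est_invalid(sprintf("n_axes (%d) exceeds the number of samples (%d)", n_axes, n))
  }
  G <- gower_center(D)
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-12 & e$values > 0
  k_pos <- sum(pos)
  k <- if (is.null(n_axes)) k_pos else min(n_axes, k_pos)
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(k)]), k, k)
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("PCo", seq_len(k))
  list(coordinates = coords,
       eigenvalues = e$values,
       proportion_explained = e$values[seq_len(k)] / sum(e$values[pos]))
}

#' Multi-factor PERMANOVA on a distance matrix
#'
#' Partitions the total sum of squares of a distance matrix among design
#' factors and their interactions, with sequential (Type I) sums of squares
#' computed via hat matrices on the Gower-centered matrix. Pseudo-F per term
#' uses the full-model residual; significance comes from free permutation of
#' sample labels with the add-one rule, so p >= 1/(n_perm + 1).
#'
#' @param D distance matrix or `dist` over the samples.
#' @param metadata data.frame with a `sample_id` column (or rownames)
#'   covering every sample in `D`.
#' @param terms character vector of terms in fitting order, e.g.
#'   `c("estuary", "season", "estuary:season")`.
#' @param n_perm number of random permutations (default 999). Ignored when
#'   `permutations` is supplied.
#' @param seed integer seed for the permutations.
#' @param permutations optional matrix of permutations (one per row) for
#'   exact/exhaustive tests.
#' @return a data.frame (class `permanova_result`) with one row per term
#'   plus Residual and Total: df, SS, R2, pseudo_F, p_value.
#' @export
permanova <- function(D, metadata, terms, n_perm = 999, seed = 1, permutations = NULL) {
  D <- as_distance_matrix(D)
  n <- nrow(D)
  ids <- rownames(D)
  meta <- as.data.frame(metadata)
  if ("sample_id" %in% names(meta)) rownames(meta) <- meta$sample_id
  missing <- setdiff(ids, rownames(meta))
  if (length(missing)) {
    est_key_error(sprintf("samples missing from metadata: %s", paste(missing, collapse = ", ")))
  }
  meta <- meta[ids, , drop = FALSE]
  vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  bad <- setdiff(vars, names(meta))
  if (length(bad)) est_key_error(sprintf("unknown factors: %s", paste(bad, collapse = ", ")))
  for (v in vars) meta[[v]] <- factor(meta[[v]])

  G <- gower_center(D)
  total_ss <- sum(diag(G))

  # hat matrix of the cumulative model after k terms (k = 0 is the intercept)
  hats <- vector("list", length(terms) + 1)
  ranks <- integer(length(terms) + 1)
  hats[[1]] <- matrix(1 / n, n, n)
  ranks[1] <- 1
  for (k in seq_along(terms)) {
    f <- stats::as.formula(paste("~", paste(terms[seq_len(k)], collapse = " + ")))
    X <- stats::model.matrix(f, data = meta)
    q <- qr(X)
    ranks[k + 1] <- q$rank
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    hats[[k + 1]] <- tcrossprod(Q)
  }
  df_terms <- diff(ranks)
  if (any(df_terms == 0)) {
    est_design_error(sprintf("aliased term(s): %s",
                             paste(terms[df_terms == 0], collapse = ", ")))
  }
  df_res <- n - ranks[length(ranks)]
  if (df_res <= 0) est_design_error("zero residual degrees of freedom: design is saturated")

  stat_of <- function(M) {
    tr <- vapply(hats, function(H) sum(H * M), numeric(1))
    ss <- diff(tr)
    ss_res <- sum(diag(M)) - tr[length(tr)]
    f <- (ss / df_terms) / (ss_res / df_res)
    list(ss = ss, ss_res = ss_res, f = f)
  }
  obs <- stat_of(G)

  perms <- if (!is.null(permutations)) {
    permutations
  } else {
    with_seed(seed, t(replicate(n_perm, sample.int(n))))
  }
  count_ge <- rep(0L, length(terms))
  for (r in seq_len(nrow(perms))) {
    pm <- perms[r, ]
    fp <- stat_of(G[pm, pm])$f
    count_ge <- count_ge + (fp >= obs$f - 1e-12)
  }
  p <- (1 + count_ge) / (1 + nrow(perms))

  out <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(df_terms, df_res, n - 1),
    SS = c(obs$ss, obs$ss_res, total_ss),
    R2 = c(obs$ss, obs$ss_res, total_ss) / total_ss,
    pseudo_F = c(obs$f, NA, NA),
    p_value = c(p, NA, NA),
    stringsAsFactors = FALSE
  )
  class(out) <- c("permanova_result", "data.frame")
  out
}

#' Off-diagonal (lower-triangle) vector of a distance matrix
#' @noRd
lower_vec <- function(D) D[lower.tri(D)]

#' Mantel test between two distance matrices
#'
#' Correlates the off-diagonal elements of two distance matrices (Spearman
#' by default) and assesses significance by simultaneous row/column
#' permutation of `D2` (one-tailed, positive association).
#'
#' @param D1,D2 distance matrices over the same samples (same order).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @param permutations optional explicit permutation matrix (rows).
#' @return a `mantel_result`: list with `rho`, `p_value`, `n_perm`, `method`.
#' @export
mantel <- function(D1, D2, method = c("spearman", "pearson"), n_perm = 999,
                   seed = 1, permutations = NULL) {
  method <- match.arg(method)
  D1 <- as_distance_matrix(D1, "D1"); D2 <- as_distance_matrix(D2, "D2")
  if (nrow(D1) != nrow(D2)) est_invalid("D1 and D2 must cover the same samples")
  v1 <- lower_vec(D1)
  tr <- if (method == "spearman") rank else identity
  if (stats::sd(v1) == 0 || stats::sd(lower_vec(D2)) == 0) {
    est_undefined_correlation("constant off-diagonal vector; correlation undefined")
  }
  r1 <- tr(v1)
  rho <- stats::cor(r1, tr(lower_vec(D2)))
  perms <- if (!is.null(permutations)) permutations else {
    with_seed(seed, t(replicate(n_perm, sample.int(nrow(D1)))))
  }
  count <- 0L
  for (r in seq_len(nrow(perms))) {
    pm <- perms[r, ]
    rp <- stats::cor(r1, tr(lower_vec(D2[pm, pm])))
    if (rp >= rho - 1e-12) count <- count + 1L
  }
  structure(list(rho = rho, p_value = (1 + count) / (1 + nrow(perms)),
                 n_perm = nrow(perms), method = method, controlled = NULL),
            class = "mantel_result")
}

#' Partial Mantel test
#'
#' Correlation of D1 and D2 off-diagonals after removing (by linear
#' regression, on ranks for Spearman) the part explained by D3; significance
#' by simultaneous row/column permutation of `D2`.
#'
#' @inheritParams mantel
#' @param D3 the controlled distance matrix.
#' @export
partial_mantel <- function(D1, D2, D3, method = c("spearman", "pearson"),
                           n_perm = 999, seed = 1, permutations = NULL) {
  method <- match.arg(method)
  D1 <- as_distance_matrix(D1, "D1"); D2 <- as_distance_matrix(D2, "D2")
  D3 <- as_distance_matrix(D3, "D3")
  tr <- if (method == "spearman") rank else identity
  r1 <- tr(lower_vec(D1)); r3 <- tr(lower_vec(D3))
  resid_on <- function(y, x) stats::lsfit(x, y)$residuals
  e1 <- resid_on(r1, r3)
  e2 <- resid_on(tr(lower_vec(D2)), r3)
  if (stats::sd(e1) < 1e-12 || stats::sd(e2) < 1e-12) {
    est_undefined_correlation("zero residual variance after controlling D3")
  }
  rho <- stats::cor(e1, e2)
  perms <- if (!is.null(permutations)) permutations else {
    with_seed(seed, t(replicate(n_perm, sample.int(nrow(D1)))))
  }
  count <- 0L
  for (r in seq_len(nrow(perms))) {
    pm <- perms[r, ]
    e2p <- resid_on(tr(lower_vec(D2[pm, pm])), r3)
    if (stats::sd(e2p) < 1e-12) next
    if (stats::cor(e1, e2p) >= rho - 1e-12) count <- count + 1L
  }
  structure(list(rho = rho, p_value = (1 + count) / (1 + nrow(perms)),
                 n_perm = nrow(perms), method = method, controlled = "D3"),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("%sMantel (%s): rho = %.4f, p = %.4g (%d permutations)\n",
              if (is.null(x$controlled)) "" else "partial ", x$method,
              x$rho, x$p_value, x$n_perm))
  invisible(x)
}

#' Spearman correlation screen of abundances against covariates
#'
#' @param abundances samples-by-groups matrix/data.frame (e.g. relative
#'   abundances of total archaea and major genera).
#' @param env samples-by-covariates data.frame; missing values are dropped
#'   pairwise.
#' @return data.frame (group, covariate, rho, p_value, n); `rho` is `NA`
#'   where fewer than 4 complete pairs remain or a vector is constant.
#' @export
env_correlations <- function(abundances, env) {
  a <- as.matrix(abundances); e <- as.data.frame(env)
  if (nrow(a) != nrow(e)) est_invalid("abundances and env must cover the same samples")
  out <- expand.grid(group = colnames(a), covariate = names(e),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$rho <- NA_real_; out$p_value <- NA_real_; out$n <- NA_integer_
  for (r in seq_len(nrow(out))) {
    x <- a[, out$group[r]]; y <- e[[out$covariate[r]]]
    ok <- is.finite(x) & is.finite(y)
    out$n[r] <- sum(ok)
    if (sum(ok) < 4 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
    out$rho[r] <- unname(ct$estimate); out$p_value[r] <- ct$p.value
  }
  out
}

#' Great-circle distance matrix from station coordinates (haversine, km)
#'
#' @param lon,lat numeric vectors of coordinates (degrees), same length,
#'   optionally named by sample id.
#' @return symmetric distance matrix in kilometres.
#' @export
geographic_distance <- function(lon, lat) {
  if (length(lon) != length(lat)) est_invalid("lon and lat must have the same length")
  n <- length(lon)
  rad <- pi / 180
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) {
      dlon <- (lon[j] - lon[i]) * rad; dlat <- (lat[j] - lat[i]) * rad
      a <- sin(dlat / 2)^2 + cos(lat[i] * rad) * cos(lat[j] * rad) * sin(dlon / 2)^2
      D[i, j] <- D[j, i] <- 6371 * 2 * asin(pmin(1, sqrt(a)))
    }
  }
  ids <- names(lon)
  if (!is.null(ids)) dimnames(D) <- list(ids, ids)
  D
}
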