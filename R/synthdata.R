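#' Simulate a lognormal source pool
#'
#' Draws a metacommunity ("species pool") relative-abundance vector from a
#' lognormal species-abundance distribution — the canonical shape for
#' amplicon surveys — and assigns each taxon a domain label in the stated
#' fractions. The pool plays the role of the source mean relative abundance
#' p in the neutral model.
#'
#' @param n_taxa number of taxa (>= 2).
#' @param lognormal_sigma standard deviation of log abundance (0 gives a
#'   perfectly even pool).
#' @param domain_fractions named numeric summing to 1 over
#'   `c("archaea", "bacteria", "phytoplankton")` (subset allowed).
#' @param seed integer seed.
#' @return a `source_pool`: list with `taxon_ids`, `rel_abundance`
#'   (sums to 1), `domain_labels`.
#' @export
simulate_source_pool <- function(n_taxa, lognormal_sigma = 2,
                                 domain_fractions = c(archaea = 0.2, bacteria = 0.7, phytoplankton = 0.1),
                                 seed = 1) {
  if (length(n_taxa) != 1 || n_taxa < 2 || n_taxa != round(n_taxa)) {
    est_invalid("`n_taxa` must be an integer >= 2")
  }
  if (lognormal_sigma < 0) est_invalid("`lognormal_sigma` must be >= 0")
  if (abs(sum(domain_fractions) - 1) > 1e-9) {
    est_invalid("`domain_fractions` must sum to 1")
  }
  with_seed(seed, {
    ab <- stats::rlnorm(n_taxa, meanlog = 0, sdlog = lognormal_sigma)
    ab <- ab / sum(ab)
    n_per <- diff(round(cumsum(c(0, domain_fractions)) * n_taxa))
    labels <- sample(rep(names(domain_fractions), times = n_per))
    ids <- sprintf("T%04d", seq_len(n_taxa))
    structure(list(taxon_ids = ids, rel_abundance = stats::setNames(ab, ids),
                   domain_labels = stats::setNames(labels, ids)),
              class = "source_pool")
  })
}

#' Specification for neutral local-community sampling
#'
#' @param n_samples number of local samples.
#' @param community_size_N reads per local community (>= 1).
#' @param migration_m migration rate in (0, 1]: the probability that a local
#'   death is replaced by an immigrant from the source pool.
#' @param detection_d detection threshold in reads (default 1).
#' @param seed integer seed.
#' @export
neutral_sim_spec <- function(n_samples, community_size_N, migration_m,
                             detection_d = 1, seed = 1) {
  if (community_size_N < 1) est_invalid("`community_size_N` must be >= 1")
  if (migration_m <= 0 || migration_m > 1) est_invalid("`migration_m` must be in (0, 1]")
  if (detection_d < 1) est_invalid("`detection_d` must be >= 1")
  if (n_samples < 1) est_invalid("`n_samples` must be >= 1")
  list(n_samples = as.integer(n_samples), community_size_N = as.integer(community_size_N),
       migration_m = migration_m, detection_d = as.integer(detection_d),
       seed = as.integer(seed))
}

#' Sample local communities under the neutral model
#'
#' Realizes the stationary distribution of neutral assembly directly: for
#' taxon i with source abundance p_i, the local relative abundance in each
#' sample is Beta(N m p_i, N m (1 - p_i)). With the default
#' `count_model = "floor"`, counts are `floor(N x)` — the taxon's integer
#' abundance in a local community of N reads — so that detection
#' (count >= d) is *exactly* the event x >= d/N whose probability
#' [expected_frequency] computes. `count_model = "binomial"` instead
#' resamples counts as Binomial(N, x); this adds a read-sampling layer that
#' smooths the detection threshold and makes occurrence frequencies deviate
#' slightly from the closed form for rare taxa. Taxa are drawn
#' independently, matching the independent-taxon approximation of the
#' neutral-model fit, so row sums vary around N rather than equalling it.
#'
#' @param pool a `source_pool` from [simulate_source_pool].
#' @param spec a [neutral_sim_spec].
#' @param count_model `"floor"` (default, exact stationary counterpart) or
#'   `"binomial"`.
#' @return a raw-count [feature_table] (`n_samples` rows).
#' @export
simulate_neutral_samples <- function(pool, spec, count_model = c("floor", "binomial")) {
  count_model <- match.arg(count_model)
  if (!inherits(pool, "source_pool")) est_invalid("`pool` must be a source_pool")
  p <- pool$rel_abundance
  N <- spec$community_size_N
  Nm <- N * spec$migration_m
  if (all(Nm * p == 0)) est_invalid("N*m*p is zero for every taxon")
  n <- spec$n_samples
  S <- length(p)
  with_seed(spec$seed, {
    counts <- matrix(0L, n, S, dimnames = list(sprintf("S%03d", seq_len(n)), names(p)))
    for (i in seq_len(S)) {
      pi <- p[i]
      if (pi <= 0) next
      x <- if (pi >= 1) rep(1, n) else stats::rbeta(n, Nm * pi, Nm * (1 - pi))
      counts[, i] <- if (count_model == "floor") as.integer(floor(N * x)) else {
        stats::rbinom(n, N, x)
      }
    }
    feature_table(counts)
  })
}

#' Plant selected-for / selected-against taxa
#'
#' Edits occurrence frequency — the quantity the neutral-model partition is
#' defined on. Mode `"for"` multiplies a taxon's detection frequency by
#' `min(effect, 1/freq)` (capped at 1) by converting random zero cells into
#' detections, with counts resampled from the taxon's own nonzero counts.
#' Mode `"against"` divides frequency by `effect` (target detections
#' `floor(n_detections / effect)`, so a large effect silences the taxon) by
#' zeroing random detections. Other taxa are untouched.
#'
#' @param table a raw-count [feature_table].
#' @param taxa feature ids to perturb.
#' @param mode `"for"` or `"against"`.
#' @param effect multiplicative effect on occurrence frequency (>= 1).
#' @param seed integer seed.
#' @return the edited [feature_table].
#' @export
plant_selection <- function(table, taxa, mode = c("for", "against"), effect, seed = 1) {
  mode <- match.arg(mode)
  table <- as_feature_table(table)
  if (effect < 1) est_invalid("`effect` must be >= 1")
  missing <- setdiff(taxa, feature_ids(table))
  if (length(missing)) {
    est_key_error(sprintf("unknown taxa: %s", paste(missing, collapse = ", ")))
  }
  v <- table$values
  n <- nrow(v)
  with_seed(seed, {
    for (tx in taxa) {
      col <- v[, tx]
      det <- which(col > 0)
      d0 <- length(det)
      if (mode == "for") {
        if (d0 == 0) next  # nothing to resample detection counts from
        target <- round(min(effect * d0 / n, 1) * n)
        add <- target - d0
        if (add > 0) {
          zeros <- which(col == 0)
          fill <- if (length(zeros) == 1) zeros else sample(zeros, add)
          fill <- fill[seq_len(add)]
          col[fill] <- sample(col[det], add, replace = TRUE)
        }
      } else {
        target <- floor(d0 / effect)
        drop <- d0 - target
        if (drop > 0) {
          kill <- if (d0 == 1) det else sample(det, drop)
          col[kill[seq_len(drop)]] <- 0L
        }
      }
      v[, tx] <- col
    }
    ft_replace(table, v)
  })
}

#' Random sparse association graph with bounded degree
#'
#' Draws `n_edges` distinct taxon pairs subject to a per-node degree cap and
#' samples signed partial-association strengths. The degree cap keeps the
#' implied precision matrix strictly diagonally dominant
#' (`max_degree * max(strength) < 1`), hence positive definite.
#'
#' @param n_taxa number of taxa.
#' @param n_edges number of edges to plant.
#' @param strength_range range of |partial association| per edge.
#' @param prob_negative probability an edge is negative.
#' @param max_degree per-node degree cap (default 2).
#' @param seed integer seed.
#' @return data.frame with columns node_a, node_b, sign (+1/-1), strength.
#' @export
random_planted_graph <- function(n_taxa, n_edges, strength_range = c(0.3, 0.45),
                                 prob_negative = 0.25, max_degree = 2, seed = 1) {
  if (max_degree * max(strength_range) >= 1) {
    est_invalid("max_degree * max(strength_range) must stay below 1 for positive definiteness")
  }
  if (n_edges > floor(n_taxa * max_degree / 2)) {
    est_invalid("too many edges for the degree cap")
  }
  with_seed(seed, {
    deg <- integer(n_taxa)
    chosen <- matrix(0L, 0, 2)
    pairs <- utils::combn(n_taxa, 2)
    ord <- sample(ncol(pairs))
    for (k in ord) {
      a <- pairs[1, k]; b <- pairs[2, k]
      if (deg[a] < max_degree && deg[b] < max_degree) {
        chosen <- rbind(chosen, c(a, b))
        deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L
        if (nrow(chosen) == n_edges) break
      }
    }
    if (nrow(chosen) < n_edges) est_invalid("could not place all edges under the degree cap")
    data.frame(
      node_a = sprintf("T%04d", chosen[, 1]),
      node_b = sprintf("T%04d", chosen[, 2]),
      sign = ifelse(stats::runif(n_edges) < prob_negative, -1, 1),
      strength = stats::runif(n_edges, strength_range[1], strength_range[2]),
      stringsAsFactors = FALSE
    )
  })
}

#' Specification for planted-graph count simulation
#'
#' @param n_taxa number of taxa.
#' @param edges data.frame (node_a, node_b, sign, strength) — the ground-truth
#'   direct associations; strengths in (0,1), no self-loops.
#' @param env_effects data.frame (env_name, taxon, strength) or NULL.
#' @param n_samples number of samples.
#' @param sequencing_depth reads per sample (row sums are exact).
#' @param seed integer seed.
#' @export
planted_graph_spec <- function(n_taxa, edges, env_effects = NULL,
                               n_samples = 200, sequencing_depth = 50000, seed = 1) {
  if (nrow(edges) > 0) {
    if (any(edges$node_a == edges$node_b)) est_invalid("self-loops are not allowed")
    if (any(abs(edges$strength) <= 0 | abs(edges$strength) >= 1)) {
      est_invalid("edge strengths must lie in (0, 1)")
    }
  }
  list(n_taxa = as.integer(n_taxa), edges = edges, env_effects = env_effects,
       n_samples = as.integer(n_samples),
       sequencing_depth = as.integer(sequencing_depth), seed = as.integer(seed))
}

#' Simulate compositional counts with a known direct-association graph
#'
#' Builds a Gaussian graphical model whose precision matrix has nonzero
#' off-diagonals exactly at the planted edges (entry -sign*strength on a
#' unit diagonal, so the latent partial correlation of an edge equals its
#' signed strength). Environmental covariates act as additional latent
#' parents. Latent values are mapped to counts by softmax-to-proportions
#' followed by a multinomial draw at `sequencing_depth`, producing closed
#' compositional counts as real sequencing does.
#'
#' @param spec a [planted_graph_spec].
#' @return list with `table` (raw-count [feature_table], row sums ==
#'   sequencing_depth), `env` (data.frame of covariates, rownames =
#'   sample ids), `truth` (the edge data.frame).
#' @export
simulate_graph_counts <- function(spec) {
  S <- spec$n_taxa
  ids <- sprintf("T%04d", seq_len(S))
  idx <- function(x) {
    i <- match(x, ids)
    if (anyNA(i)) est_invalid(sprintf("edge endpoint not among taxa: %s",
                                      paste(x[is.na(i)], collapse = ", ")))
    i
  }
  omega <- diag(S)
  if (nrow(spec$edges) > 0) {
    ia <- idx(spec$edges$node_a); ib <- idx(spec$edges$node_b)
    for (k in seq_along(ia)) {
      omega[ia[k], ib[k]] <- omega[ib[k], ia[k]] <- -spec$edges$sign[k] * spec$edges$strength[k]
    }
  }
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8) {
    est_invalid(sprintf(
      "planted precision matrix is not positive definite (min eigenvalue %.3g); edge set too dense/strong",
      min(ev)))
  }
  sigma <- chol2inv(chol(omega))
  with_seed(spec$seed, {
    n <- spec$n_samples
    z <- matrix(stats::rnorm(n * S), n, S) %*% chol(sigma)
    env_names <- unique(spec$env_effects$env_name)
    env <- NULL
    if (length(env_names)) {
      env <- matrix(stats::rnorm(n * length(env_names)), n, length(env_names),
                    dimnames = list(sprintf("S%03d", seq_len(n)), env_names))
      for (k in seq_len(nrow(spec$env_effects))) {
        j <- match(spec$env_effects$taxon[k], ids)
        if (is.na(j)) est_invalid("env effect targets unknown taxon")
        z[, j] <- z[, j] + spec$env_effects$strength[k] * env[, spec$env_effects$env_name[k]]
      }
      env <- as.data.frame(env)
    }
    prop <- exp(z)
    prop <- prop / rowSums(prop)
    counts <- t(apply(prop, 1, function(pr) stats::rmultinom(1, spec$sequencing_depth, pr)[, 1]))
    dimnames(counts) <- list(sprintf("S%03d", seq_len(n)), ids)
    list(table = feature_table(counts), env = env, truth = spec$edges)
  })
}

#' Build the full crossed sampling design
#'
#' Sample ids follow the cruise naming scheme: season code, estuary code,
#' underscore, station code, underscore, replicate (e.g. `WYE_L_1` = winter,
#' Yellow River estuary, low-salinity station, replicate 1). Codes are taken
#' from the names of the input vectors (or the values themselves when
#' unnamed).
#'
#' @param estuaries,seasons,stations named character vectors
#'   (`c(YE = "Yellow River", ...)`).
#' @param replicates biological replicates per station (>= 1).
#' @return data.frame with columns sample_id, estuary, season, station,
#'   replicate; one row per sample of the full crossed design.
#' @export
make_design <- function(estuaries = c(YE = "Yellow River", YA = "Yangtze River",
                                      Q = "Qiantang River", P = "Pearl River"),
                        seasons = c(W = "Winter", S = "Summer"),
                        stations = c(L = "Low", M = "Medium"),
                        replicates = 5) {
  if (!length(estuaries) || !length(seasons) || !length(stations)) {
    est_invalid("factor name lists must be nonempty")
  }
  if (replicates < 1) est_invalid("`replicates` must be >= 1")
  code <- function(x) if (is.null(names(x))) stats::setNames(x, x) else x
  estuaries <- code(estuaries); seasons <- code(seasons); stations <- code(stations)
  g <- expand.grid(replicate = seq_len(replicates),
                   station = names(stations), estuary = names(estuaries),
                   season = names(seasons),
                   stringsAsFactors = FALSE)
  data.frame(
    sample_id = sprintf("%s%s_%s_%d", g$season, g$estuary, g$station, g$replicate),
    estuary = unname(estuaries[g$estuary]),
    season = unname(seasons[g$season]),
    station = unname(stations[g$station]),
    replicate = g$replicate,
    stringsAsFactors = FALSE
  )
}

#' Simulate environmental covariates for a design
#'
#' Season drives temperature, station drives salinity, and the remaining
#' covariates vary around estuary-specific baselines — enough structure for
#' correlation screens and env-aware network inference to have signal.
#'
#' @param design a design data.frame from [make_design].
#' @param seed integer seed.
#' @return data.frame of numeric covariates (temperature, salinity, pH, DO,
#'   NO3, COD), rownames = sample ids.
#' @export
simulate_env_covariates <- function(design, seed = 1) {
  with_seed(seed, {
    n <- nrow(design)
    winter <- design$season %in% c("Winter", "W")
    low <- design$station %in% c("Low", "L")
    est_base <- stats::setNames(stats::rnorm(length(unique(design$estuary)), 0, 1),
                                unique(design$estuary))
    out <- data.frame(
      temperature = ifelse(winter, 8, 27) + stats::rnorm(n, 0, 2),
      salinity = ifelse(low, 10, 25) + stats::rnorm(n, 0, 2),
      pH = 8 + 0.1 * est_base[design$estuary] + stats::rnorm(n, 0, 0.1),
      DO = 8 - 0.1 * ifelse(winter, -2, 2) + stats::rnorm(n, 0, 0.5),
      NO3 = exp(1 + 0.5 * est_base[design$estuary] + stats::rnorm(n, 0, 0.3)),
      COD = exp(0.5 + 0.3 * est_base[design$estuary] + stats::rnorm(n, 0, 0.3))
    )
    rownames(out) <- design$sample_id
    out
  })
}
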