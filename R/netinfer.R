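#' Network inference configuration
#'
#' Defaults mirror the sensitive, homogeneous single-habitat setting of
#' constraint-based co-occurrence inference: alpha = 0.001, n_obs_min = 10,
#' conditioning sets up to size 3, clr normalization of counts.
#'
#' @param alpha significance level for (partial-)correlation tests.
#' @param n_obs_min minimum number of samples where both taxa of a pair are
#'   nonzero for the pair to be testable at all.
#' @param max_k maximum conditioning-set size for indirect-edge removal.
#' @param env_names character vector of environmental covariates to include
#'   as network nodes (default: all columns of the env table).
#' @param pseudocount pseudocount for the clr transform.
#' @export
network_config <- function(alpha = 0.001, n_obs_min = 10, max_k = 3,
                           env_names = NULL, pseudocount = 1) {
  if (alpha <= 0 || alpha >= 1) est_invalid("`alpha` must be in (0, 1)")
  if (max_k < 0) est_invalid("`max_k` must be >= 0")
  if (pseudocount <= 0) est_invalid("`pseudocount` must be positive")
  list(alpha = alpha, n_obs_min = as.integer(n_obs_min), max_k = as.integer(max_k),
       env_names = env_names, pseudocount = pseudocount)
}

#' Centered log-ratio transform
#'
#' Per sample: log((c + pseudocount) / geometric mean(c + pseudocount)).
#' Rows of the result sum to zero — the standard transform that moves
#' compositional counts to an unconstrained scale before correlation-based
#' inference.
#'
#' @param table a raw-count [feature_table].
#' @param pseudocount positive value added to every count.
#' @return a [feature_table] with state `"clr"`.
#' @export
clr_transform <- function(table, pseudocount = 1) {
  table <- as_feature_table(table)
  if (pseudocount <= 0) est_invalid("`pseudocount` must be positive")
  if (!table$normalized %in% c("raw", "rarefied")) {
    est_invalid("clr_transform expects count data")
  }
  v <- table$values + pseudocount
  lv <- log(v)
  out <- lv - rowMeans(lv)
  ft_replace(table, out, normalized = "clr")
}

#' Partial correlation of columns i, j given set S, from a correlation matrix
#' @noRd
partial_cor <- function(R, i, j, S) {
  if (length(S) == 0) return(R[i, j])
  idx <- c(i, j, S)
  P <- tryCatch(solve(R[idx, idx]), error = function(e) NULL)
  if (is.null(P)) return(0)
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

#' Fisher-z p-value for a (partial) correlation
#' @noRd
fisher_z_p <- function(r, n, k = 0) {
  df <- n - k - 3
  if (df <= 0) return(1)
  r <- max(min(r, 1 - 1e-12), -1 + 1e-12)
  2 * stats::pnorm(-abs(atanh(r)) * sqrt(df))
}

#' Infer a direct (conditional-independence-filtered) association network
#'
#' Local-to-global constraint-based inference over clr-transformed taxon
#' abundances and standardized environmental covariates. Candidate edges
#' come from pairwise Fisher-z correlation tests at level `alpha`; an edge
#' (i, j) is then removed if any conditioning subset S (|S| <= max_k) of the
#' current neighbor sets of i or of j renders the partial correlation
#' insignificant — so purely correlational (indirect) associations, whether
#' mediated by another taxon or by an environmental covariate, are pruned
#' away. Removal decisions within each conditioning-set size are applied
#' simultaneously (order-stable), making the result invariant to sample and
#' feature order. Taxon pairs that are jointly nonzero in fewer than
#' `n_obs_min` samples are never tested (no edge).
#'
#' @param table a pre-filtered raw-count [feature_table] (see
#'   [filter_for_network]).
#' @param env_table data.frame of environmental covariates (rows = samples,
#'   same order as `table`; no missing values) or NULL for taxa-only.
#' @param config a [network_config].
#' @param seed integer seed (only relevant to tie-break ordering; the
#'   procedure is otherwise deterministic).
#' @return an `association_network`: list with `nodes` (id, kind,
#'   mean_rel_abundance), `edges` (node_a, node_b, weight = pairwise clr
#'   correlation, sign, edge_kind), `config`, `n_samples`.
#' @export
infer_direct_network <- function(table, env_table = NULL, config = network_config(),
                                 seed = 1) {
  table <- as_feature_table(table)
  n <- n_samples(table)
  if (n < config$n_obs_min) {
    est_invalid(sprintf("only %d samples; n_obs_min is %d", n, config$n_obs_min))
  }
  taxa <- feature_ids(table)
  Z <- ft_values(clr_transform(table, config$pseudocount))
  env_names <- character(0)
  if (!is.null(env_table)) {
    env_table <- as.data.frame(env_table)
    env_names <- if (is.null(config$env_names)) names(env_table) else config$env_names
    missing_col <- setdiff(env_names, names(env_table))
    if (length(missing_col)) {
      est_invalid(sprintf("env columns not found: %s", paste(missing_col, collapse = ", ")))
    }
    E <- as.matrix(env_table[, env_names, drop = FALSE])
    if (nrow(E) != n) est_invalid("env table must have one row per sample")
    if (anyNA(E)) {
      bad <- env_names[colSums(is.na(E)) > 0]
      est_invalid(sprintf("missing environmental data not supported (columns: %s)",
                          paste(bad, collapse = ", ")))
    }
    Z <- cbind(Z, scale(E))
  }
  node_ids <- c(taxa, env_names)
  P <- ncol(Z)
  R <- stats::cor(Z)

  # taxa pairs with too few co-detections are never testable
  testable <- matrix(TRUE, P, P)
  if (length(taxa) > 1) {
    pres <- ft_values(table) > 0
    co <- crossprod(pres)  # co-nonzero sample counts
    ti <- seq_along(taxa)
    testable[ti, ti] <- co >= config$n_obs_min
  }

  adj <- matrix(FALSE, P, P)
  for (i in seq_len(P - 1)) for (j in seq(i + 1, P)) {
    if (testable[i, j] && fisher_z_p(R[i, j], n) < config$alpha) {
      adj[i, j] <- adj[j, i] <- TRUE
    }
  }

  # order-stable pruning with growing conditioning sets
  if (config$max_k > 0) {
    for (k in seq_len(config$max_k)) {
      adj_k <- adj  # neighbor sets frozen at the start of this level
      if (!any(rowSums(adj_k) >= k)) break
      to_drop <- matrix(FALSE, P, P)
      for (i in seq_len(P - 1)) for (j in seq(i + 1, P)) {
        if (!adj[i, j]) next
        cand_sets <- list(setdiff(which(adj_k[i, ]), j), setdiff(which(adj_k[j, ]), i))
        removed <- FALSE
        for (cand in cand_sets) {
          if (removed || length(cand) < k) next
          # combn(x, k) on a scalar x would expand to 1:x
          subs <- if (length(cand) == k) list(cand) else utils::combn(cand, k, simplify = FALSE)
          for (S in subs) {
            pc <- partial_cor(R, i, j, S)
            if (fisher_z_p(pc, n, k) >= config$alpha) {
              to_drop[i, j] <- to_drop[j, i] <- TRUE
              removed <- TRUE
              break
            }
          }
        }
      }
      adj <- adj & !to_drop
    }
  }

  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  kind <- c(rep("taxon", length(taxa)), rep("env", length(env_names)))
  edge_kind <- function(a, b) {
    if (kind[a] == "env" || kind[b] == "env") "taxon_env" else "taxon_taxon"
  }
  edges <- data.frame(
    node_a = node_ids[idx[, 1]], node_b = node_ids[idx[, 2]],
    weight = R[idx], sign = ifelse(R[idx] >= 0, "+", "-"),
    edge_kind = mapply(edge_kind, idx[, 1], idx[, 2]),
    stringsAsFactors = FALSE
  )
  if (nrow(edges)) edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
  rownames(edges) <- NULL
  mra <- colMeans(relative_abundance(table))
  nodes <- data.frame(
    id = node_ids, kind = kind,
    mean_rel_abundance = c(mra[taxa], rep(NA_real_, length(env_names))),
    stringsAsFactors = FALSE
  )
  structure(list(nodes = nodes, edges = edges, config = config, n_samples = n),
            class = "association_network")
}

#' @export
print.association_network <- function(x, ...) {
  cat(sprintf("<association_network> %d nodes (%d taxa, %d env), %d edges (%.0f%% positive)\n",
              nrow(x$nodes), sum(x$nodes$kind == "taxon"), sum(x$nodes$kind == "env"),
              nrow(x$edges),
              if (nrow(x$edges)) 100 * mean(x$edges$sign == "+") else 0))
  invisible(x)
}

#' Convert an association network to an igraph graph
#'
#' Vertices are added in sorted id order so downstream deterministic
#' algorithms have a pinned tie-break order; |weight| is carried as the
#' `weight` attribute, the signed value as `signed_weight`.
#' @param network an `association_network`.
#' @export
as_igraph <- function(network) {
  ids <- sort(network$nodes$id)
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (nrow(network$edges)) {
    g <- igraph::add_edges(g, rbind(network$edges$node_a, network$edges$node_b))
    g <- igraph::set_edge_attr(g, "weight", value = abs(network$edges$weight))
    g <- igraph::set_edge_attr(g, "signed_weight", value = network$edges$weight)
  }
  g
}

#' Write an association network to GraphML
#' @param network an `association_network`.
#' @param path output path.
#' @export
write_graphml <- function(network, path) {
  g <- as_igraph(network)
  kind <- network$nodes$kind[match(igraph::V(g)$name, network$nodes$id)]
  g <- igraph::set_vertex_attr(g, "kind", value = kind)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Detect network modules
#'
#' Non-overlapping modules by greedy modularity maximization on absolute
#' edge weights (agglomeration over vertices in sorted id order, so the
#' result is deterministic); isolated nodes form singleton modules.
#'
#' @param network an `association_network`.
#' @param seed unused placeholder kept for interface stability (the
#'   algorithm is deterministic).
#' @return named integer vector: node id -> module id.
#' @export
detect_modules <- function(network, seed = 1) {
  if (nrow(network$nodes) == 0) est_invalid("empty network")
  g <- as_igraph(network)
  if (igraph::ecount(g) == 0) {
    return(stats::setNames(seq_len(igraph::vcount(g)), igraph::V(g)$name))
  }
  cl <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
  stats::setNames(as.integer(igraph::membership(cl)), igraph::V(g)$name)
}

#' Modularity of a partition on absolute edge weights
#' @param network an `association_network`.
#' @param modules named membership vector over all nodes.
#' @export
network_modularity <- function(network, modules) {
  g <- as_igraph(network)
  igraph::modularity(g, modules[igraph::V(g)$name],
                     weights = if (igraph::ecount(g)) igraph::E(g)$weight else NULL)
}

#' Within-module connectivity (Zi) and among-module connectivity (Pi)
#'
#' With k_is the number of edges (unweighted) from node i to module s, and
#' s_i the module of i: Zi standardizes k_{i,s_i} against the within-module
#' degrees of the other members of s_i (Zi = 0 when their sd is 0);
#' Pi = 1 - sum_s (k_is / k_i)^2 (Pi = 0 for isolated nodes).
#'
#' @param network an `association_network`.
#' @param modules named membership vector covering every node.
#' @return data.frame (id, module, degree, Zi, Pi).
#' @export
zi_pi <- function(network, modules) {
  ids <- network$nodes$id
  missing <- setdiff(ids, names(modules))
  if (length(missing)) {
    est_key_error(sprintf("nodes missing a module: %s", paste(missing, collapse = ", ")))
  }
  mods <- modules[ids]
  n <- length(ids)
  A <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (nrow(network$edges)) {
    ia <- match(network$edges$node_a, ids); ib <- match(network$edges$node_b, ids)
    A[cbind(ia, ib)] <- 1L; A[cbind(ib, ia)] <- 1L
  }
  mod_levels <- sort(unique(mods))
  # k_is: edges from node i into module s
  k_to_mod <- vapply(mod_levels,
                     function(s) rowSums(A[, mods == s, drop = FALSE]),
                     numeric(n))
  if (n == 1) k_to_mod <- matrix(k_to_mod, nrow = 1)
  k_tot <- rowSums(k_to_mod)
  own <- match(mods, mod_levels)
  k_within <- k_to_mod[cbind(seq_len(n), own)]
  zi <- numeric(n)
  for (s in seq_along(mod_levels)) {
    members <- which(own == s)
    mu <- mean(k_within[members]); sdv <- stats::sd(k_within[members])
    zi[members] <- if (length(members) < 2 || is.na(sdv) || sdv == 0) 0 else {
      (k_within[members] - mu) / sdv
    }
  }
  pi_v <- ifelse(k_tot == 0, 0, 1 - rowSums((k_to_mod / pmax(k_tot, 1))^2))
  data.frame(id = ids, module = unname(mods), degree = k_tot,
             Zi = zi, Pi = pi_v, row.names = NULL, stringsAsFactors = FALSE)
}

#' Topological role classification from Zi and Pi
#'
#' Thresholds Zi = 2.5 and Pi = 0.62: peripherals (Zi <= 2.5, Pi <= 0.62),
#' connectors (Zi <= 2.5, Pi > 0.62), module hubs (Zi > 2.5, Pi <= 0.62),
#' network hubs (Zi > 2.5, Pi > 0.62). Both boundaries are inclusive on the
#' peripheral side.
#'
#' @param zipi data.frame with columns `Zi` and `Pi` (from [zi_pi]).
#' @return the input with an added `role` column.
#' @export
classify_roles <- function(zipi) {
  if (any(!is.finite(zipi$Zi)) || any(!is.finite(zipi$Pi))) {
    est_invalid("Zi and Pi must be finite")
  }
  hub <- zipi$Zi > 2.5
  conn <- zipi$Pi > 0.62
  zipi$role <- ifelse(hub & conn, "network_hub",
               ifelse(hub, "module_hub",
               ifelse(conn, "connector", "peripheral")))
  zipi
}

#' Cross-domain association summary
#'
#' Classifies every edge by the domains of its endpoints and tabulates
#' counts and percent-positive per class (archaea-archaea, archaea-bacteria,
#' archaea-phytoplankton, taxon-env, other), plus per-genus degree and
#' cross-domain degree for archaeal genera.
#'
#' @param network an `association_network`.
#' @param taxonomy a [taxonomy_map] covering every taxon node.
#' @return list with `network_stats` (node/edge counts), `edge_classes`
#'   (class, n_edges, n_positive, pct_positive), `edges` (per-edge class
#'   labels), `archaeal_genus_degree`.
#' @export
summarize_cross_domain <- function(network, taxonomy) {
  taxa_nodes <- network$nodes$id[network$nodes$kind == "taxon"]
  missing <- setdiff(taxa_nodes, taxonomy$feature_id)
  if (length(missing)) {
    est_key_error(sprintf("taxon nodes absent from taxonomy: %s",
                          paste(utils::head(missing, 10), collapse = ", ")))
  }
  dom_of <- function(id) {
    if (!id %in% taxa_nodes) return("env")
    r <- match(id, taxonomy$feature_id)
    if (taxonomy$is_archaeon[r]) "archaeon"
    else if (taxonomy$is_phytoplankton[r]) "phytoplankton"
    else if (taxonomy$is_bacterium[r]) "bacterium"
    else "other"
  }
  classes <- c("archaea-archaea", "archaea-bacteria", "archaea-phytoplankton",
               "taxon-env", "other")
  edges <- network$edges
  edge_class <- character(nrow(edges))
  if (nrow(edges)) {
    da <- vapply(edges$node_a, dom_of, character(1))
    db <- vapply(edges$node_b, dom_of, character(1))
    for (r in seq_len(nrow(edges))) {
      pair <- sort(c(da[r], db[r]))
      edge_class[r] <-
        if ("env" %in% pair) "taxon-env"
        else if (all(pair == "archaeon")) "archaea-archaea"
        else if (setequal(pair, c("archaeon", "bacterium"))) "archaea-bacteria"
        else if (setequal(pair, c("archaeon", "phytoplankton"))) "archaea-phytoplankton"
        else "other"
    }
    edges$edge_class <- edge_class
  } else {
    edges$edge_class <- character(0)
  }
  by_class <- data.frame(
    class = classes,
    n_edges = vapply(classes, function(cl) sum(edge_class == cl), integer(1)),
    n_positive = vapply(classes, function(cl) sum(edge_class == cl & edges$sign == "+"), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  by_class$pct_positive <- ifelse(by_class$n_edges == 0, NA_real_,
                                  100 * by_class$n_positive / by_class$n_edges)

  arch_ids <- taxonomy$feature_id[taxonomy$is_archaeon]
  arch_nodes <- intersect(taxa_nodes, arch_ids)
  deg <- stats::setNames(rep(0L, length(arch_nodes)), arch_nodes)
  xdeg <- deg
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      for (side in c("node_a", "node_b")) {
        id <- edges[[side]][r]
        if (id %in% arch_nodes) {
          deg[id] <- deg[id] + 1L
          other_id <- edges[[if (side == "node_a") "node_b" else "node_a"]][r]
          if (other_id %in% taxa_nodes && !(other_id %in% arch_ids)) {
            xdeg[id] <- xdeg[id] + 1L
          }
        }
      }
    }
  }
  genus <- taxonomy$genus[match(arch_nodes, taxonomy$feature_id)]
  genus_deg <- if (length(arch_nodes)) {
    stats::aggregate(cbind(degree = deg, cross_domain_degree = xdeg),
                     by = list(genus = genus), FUN = sum)
  } else {
    data.frame(genus = character(0), degree = integer(0), cross_domain_degree = integer(0))
  }
  list(
    network_stats = data.frame(
      n_nodes = nrow(network$nodes), n_taxa = length(taxa_nodes),
      n_env = sum(network$nodes$kind == "env"), n_edges = nrow(edges),
      pct_positive = if (nrow(edges)) 100 * mean(edges$sign == "+") else NA_real_),
    edge_classes = by_class,
    edges = edges,
    archaeal_genus_degree = genus_deg
  )
}
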