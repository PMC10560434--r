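test_that("clr transform has the defining identities", {
  # uniform sample maps to zeros; rows always sum to zero
  u <- feature_table(matrix(7L, 2, 4, dimnames = list(c("a", "b"), paste0("f", 1:4))))
  expect_true(all(ft_values(clr_transform(u)) == 0))

  set.seed(1)
  m <- matrix(rpois(40, 20), 4, 10,
              dimnames = list(paste0("s", 1:4), paste0("f", 1:10)))
  z <- ft_values(clr_transform(feature_table(m)))
  expect_lt(max(abs(rowSums(z))), 1e-9)

  # zero-pseudocount analog on positive counts (1, 3, 9): (-log 3, 0, log 3)
  pos <- feature_table(matrix(c(1L, 3L, 9L), 1, 3,
                              dimnames = list("s", c("a", "b", "c"))))
  z2 <- ft_values(clr_transform(pos, pseudocount = 1e-9))
  expect_equal(as.vector(z2), c(-log(3), 0, log(3)), tolerance = 1e-6)

  expect_error(clr_transform(pos, pseudocount = 0), class = "estuarch_invalid_argument")
})

test_that("indirect chain edges are pruned while direct edges survive", {
  chain <- data.frame(node_a = c("T0001", "T0002"), node_b = c("T0002", "T0003"),
                      sign = 1, strength = 0.45)
  sim <- simulate_graph_counts(planted_graph_spec(30, chain, n_samples = 500,
                                                  sequencing_depth = 50000, seed = 4))
  net <- infer_direct_network(sim$table, NULL, network_config(), seed = 1)
  keys <- edge_key(net$edges$node_a, net$edges$node_b)
  expect_true(all(c("T0001 T0002", "T0002 T0003") %in% keys))
  expect_false("T0001 T0003" %in% keys)
})

test_that("environmental confounding is removed while env links are kept", {
  empty <- data.frame(node_a = character(0), node_b = character(0),
                      sign = numeric(0), strength = numeric(0))
  env_eff <- data.frame(env_name = "temperature", taxon = c("T0001", "T0002"),
                        strength = c(1.2, 1.2))
  sim <- simulate_graph_counts(planted_graph_spec(20, empty, env_eff,
                                                  n_samples = 300,
                                                  sequencing_depth = 50000, seed = 2))
  net <- infer_direct_network(sim$table, sim$env, network_config(), seed = 1)
  keys <- edge_key(net$edges$node_a, net$edges$node_b)
  expect_false("T0001 T0002" %in% keys)
  expect_true(all(c("T0001 temperature", "T0002 temperature") %in% keys))

  # the same data without the covariate leaves the confounded pair connected
  net0 <- infer_direct_network(sim$table, NULL, network_config(), seed = 1)
  keys0 <- edge_key(net0$edges$node_a, net0$edges$node_b)
  expect_true("T0001 T0002" %in% keys0)

  # missing env values are rejected, naming the column
  bad_env <- sim$env; bad_env$temperature[3] <- NA
  expect_error(infer_direct_network(sim$table, bad_env, network_config()),
               class = "estuarch_invalid_argument", regexp = "temperature")
})

test_that("planted 50-taxon graphs are recovered with high precision and recall", {
  truth <- random_planted_graph(50, 40, seed = 3)
  sim <- simulate_graph_counts(planted_graph_spec(50, truth, n_samples = 200,
                                                  sequencing_depth = 50000, seed = 3))
  net <- infer_direct_network(sim$table, NULL, network_config(), seed = 1)
  tt <- net$edges[net$edges$edge_kind == "taxon_taxon", ]
  found <- edge_key(tt$node_a, tt$node_b)
  planted <- edge_key(truth$node_a, truth$node_b)
  expect_gte(mean(found %in% planted), 0.8)   # precision
  expect_gte(mean(planted %in% found), 0.8)   # recall
  # recovered edges carry the planted signs
  m <- match(found, planted)
  hit <- !is.na(m)
  expect_equal((tt$weight[hit] > 0), (truth$sign[m[hit]] > 0))
})

test_that("inference is invariant to sample and feature order", {
  truth <- random_planted_graph(20, 10, seed = 6)
  sim <- simulate_graph_counts(planted_graph_spec(20, truth, n_samples = 120,
                                                  sequencing_depth = 20000, seed = 6))
  net <- infer_direct_network(sim$table, NULL, network_config(), seed = 1)
  v <- ft_values(sim$table)
  set.seed(7)
  shuf <- feature_table(v[sample(nrow(v)), sample(ncol(v))])
  net2 <- infer_direct_network(shuf, NULL, network_config(), seed = 1)
  key <- function(e) sort(edge_key(e$node_a, e$node_b))
  expect_identical(key(net$edges), key(net2$edges))
})

test_that("pairs with few co-detections and short tables are refused", {
  set.seed(9)
  m <- matrix(rpois(60, 5), 6, 10,
              dimnames = list(paste0("s", 1:6), paste0("f", 1:10)))
  expect_error(infer_direct_network(feature_table(m), NULL,
                                    network_config(n_obs_min = 10)),
               class = "estuarch_invalid_argument")

  # two taxa perfectly correlated but never co-detected: no edge allowed
  m2 <- matrix(0L, 20, 3, dimnames = list(paste0("s", 1:20), c("a", "b", "c")))
  m2[1:10, "a"] <- 50L; m2[11:20, "b"] <- 50L; m2[, "c"] <- rpois(20, 20)
  net <- infer_direct_network(feature_table(m2), NULL,
                              network_config(n_obs_min = 10), seed = 1)
  expect_false("a b" %in% edge_key(net$edges$node_a, net$edges$node_b))
})

test_that("module detection separates cliques and beats singleton modularity", {
  mk_net <- function(edges) {
    nodes <- data.frame(id = sort(unique(c(edges$node_a, edges$node_b))),
                        kind = "taxon", mean_rel_abundance = NA_real_,
                        stringsAsFactors = FALSE)
    structure(list(nodes = nodes, edges = edges, config = network_config(),
                   n_samples = 50), class = "association_network")
  }
  clique <- function(ids) {
    pr <- t(combn(ids, 2))
    data.frame(node_a = pr[, 1], node_b = pr[, 2], weight = 0.5, sign = "+",
               edge_kind = "taxon_taxon", stringsAsFactors = FALSE)
  }
  two <- mk_net(rbind(clique(paste0("a", 1:4)), clique(paste0("b", 1:4))))
  mods <- detect_modules(two)
  expect_equal(length(unique(mods[paste0("a", 1:4)])), 1)
  expect_equal(length(unique(mods[paste0("b", 1:4)])), 1)
  expect_false(mods[["a1"]] == mods[["b1"]])

  # partition at least as good as all-singletons, and matches the best
  # partition found by exhaustive search on a small graph
  small <- mk_net(data.frame(node_a = c("a", "a", "c", "d"),
                             node_b = c("b", "c", "b", "e"),
                             weight = c(0.9, 0.2, 0.2, 0.8), sign = "+",
                             edge_kind = "taxon_taxon", stringsAsFactors = FALSE))
  msmall <- detect_modules(small)
  q <- network_modularity(small, msmall)
  singletons <- setNames(seq_len(nrow(small$nodes)), small$nodes$id)
  expect_gte(q, network_modularity(small, singletons))
  # exhaustive search over all partitions of 5 nodes (Bell(5) = 52)
  ids <- small$nodes$id
  best <- -Inf
  part_of <- function(assignment) setNames(assignment, ids)
  gen <- function(assignment, next_id) {
    if (next_id > length(ids)) {
      best <<- max(best, network_modularity(small, part_of(assignment)))
      return(invisible())
    }
    for (g in seq_len(max(assignment, 0) + 1)) gen(c(assignment, g), next_id + 1)
  }
  gen(integer(0), 1)
  expect_equal(q, best, tolerance = 1e-12)

  # isolated nodes become singleton modules
  iso <- mk_net(clique(c("x", "y")))
  iso$nodes <- rbind(iso$nodes, data.frame(id = "lonely", kind = "taxon",
                                           mean_rel_abundance = NA_real_))
  mi <- detect_modules(iso)
  expect_false(mi[["lonely"]] %in% mi[c("x", "y")])
})

test_that("Zi and Pi match a brute-force oracle on a 7-node fixture", {
  # modules: {a1 a2 a3 a4} and {b1 b2 b3}; hub a1; a4 bridges to b1
  edges <- data.frame(
    node_a = c("a1", "a1", "a1", "a2", "a4", "b1", "b1", "b2"),
    node_b = c("a2", "a3", "a4", "a3", "b1", "b2", "b3", "b3"),
    weight = 0.5, sign = "+", edge_kind = "taxon_taxon",
    stringsAsFactors = FALSE)
  nodes <- data.frame(id = c(paste0("a", 1:4), paste0("b", 1:3)), kind = "taxon",
                      mean_rel_abundance = NA_real_, stringsAsFactors = FALSE)
  net <- structure(list(nodes = nodes, edges = edges, config = network_config(),
                        n_samples = 50), class = "association_network")
  modules <- setNames(c(1, 1, 1, 1, 2, 2, 2), nodes$id)
  zp <- zi_pi(net, modules)

  # independent brute-force computation straight from the formulas
  ids <- nodes$id
  adj <- matrix(0, 7, 7, dimnames = list(ids, ids))
  for (r in seq_len(nrow(edges))) {
    adj[edges$node_a[r], edges$node_b[r]] <- 1
    adj[edges$node_b[r], edges$node_a[r]] <- 1
  }
  for (i in ids) {
    k_is <- sapply(1:2, function(s) sum(adj[i, names(modules)[modules == s]]))
    k_i <- sum(adj[i, ])
    mates <- names(modules)[modules == modules[[i]]]
    within_degs <- sapply(mates, function(j) sum(adj[j, mates]))
    zi_oracle <- if (sd(within_degs) == 0) 0 else {
      (sum(adj[i, mates]) - mean(within_degs)) / sd(within_degs)
    }
    pi_oracle <- if (k_i == 0) 0 else 1 - sum((k_is / k_i)^2)
    expect_equal(zp$Zi[zp$id == i], zi_oracle, tolerance = 1e-12)
    expect_equal(zp$Pi[zp$id == i], pi_oracle, tolerance = 1e-12)
  }

  # all nodes in one module: Pi = 0 everywhere
  one <- setNames(rep(1, 7), ids)
  expect_true(all(zi_pi(net, one)$Pi == 0))

  # node with edges split equally across two modules: Pi = 0.5
  half <- setNames(c(1, 1, 2, 2, 2, 2, 2), ids)  # a1: a2 in mod1, a3+a4 in mod2... recompute
  zp_half <- zi_pi(net, setNames(c(1, 1, 1, 2, 2, 2, 2), ids))
  a4 <- zp_half[zp_half$id == "a4", ]  # a4 links a1 (mod 1) and b1 (mod 2)
  expect_equal(a4$Pi, 0.5)

  # Zi has zero mean and unit sd within modules that vary
  for (s in 1:2) {
    zs <- zp$Zi[modules[zp$id] == s]
    if (sd(zs) > 0) {
      expect_equal(mean(zs), 0, tolerance = 1e-12)
      expect_equal(sd(zs), 1, tolerance = 1e-12)
    }
  }

  expect_error(zi_pi(net, modules[-1]), class = "estuarch_key_error")
})

test_that("role thresholds follow the quoted Zi/Pi boundaries", {
  zp <- data.frame(id = paste0("n", 1:5),
                   Zi = c(2.5, 3.0, 0, 2.4, 2.6),
                   Pi = c(0.62, 0.70, 0, 0.63, 0.10))
  roles <- classify_roles(zp)$role
  expect_identical(roles, c("peripheral",   # both exactly on the boundary
                            "network_hub", "peripheral", "connector", "module_hub"))
  expect_error(classify_roles(data.frame(Zi = NaN, Pi = 0)),
               class = "estuarch_invalid_argument")
})

test_that("cross-domain summaries enumerate edge classes correctly", {
  ids <- c("arc1", "arc2", "bac1", "bac2", "phy1")
  tax <- toy_taxonomy(ids, c("Archaea", "Archaea", "Bacteria", "Bacteria", "Chloro"),
                      genera = c("Nitrosopumilus", "Poseidonia", "SAR11", "SAR11", "Chloro_X"))
  edges <- data.frame(
    node_a = c("arc1", "arc1", "arc2", "bac1", "arc1", "phy1", "arc2"),
    node_b = c("arc2", "bac1", "bac2", "bac2", "phy1", "temperature", "temperature"),
    weight = c(0.5, 0.4, -0.3, 0.6, 0.2, 0.3, -0.2),
    sign = c("+", "+", "-", "+", "+", "+", "-"),
    edge_kind = c(rep("taxon_taxon", 5), "taxon_env", "taxon_env"),
    stringsAsFactors = FALSE)
  nodes <- data.frame(id = c(ids, "temperature"),
                      kind = c(rep("taxon", 5), "env"),
                      mean_rel_abundance = NA_real_, stringsAsFactors = FALSE)
  net <- structure(list(nodes = nodes, edges = edges, config = network_config(),
                        n_samples = 30), class = "association_network")
  s <- summarize_cross_domain(net, tax)
  cls <- s$edge_classes
  expect_equal(cls$n_edges[cls$class == "archaea-archaea"], 1)
  expect_equal(cls$n_edges[cls$class == "archaea-bacteria"], 2)
  expect_equal(cls$n_edges[cls$class == "archaea-phytoplankton"], 1)
  expect_equal(cls$n_edges[cls$class == "taxon-env"], 2)
  expect_equal(cls$n_edges[cls$class == "other"], 1)
  expect_equal(cls$pct_positive[cls$class == "archaea-bacteria"], 50)
  expect_equal(cls$pct_positive[cls$class == "archaea-archaea"], 100)
  expect_equal(s$network_stats$pct_positive, 100 * 5 / 7)

  # archaeal genus degrees: arc1 has 3 edges, 2 of them cross-domain taxa
  gd <- s$archaeal_genus_degree
  expect_equal(gd$degree[gd$genus == "Nitrosopumilus"], 3)
  expect_equal(gd$cross_domain_degree[gd$genus == "Nitrosopumilus"], 2)
  expect_equal(gd$cross_domain_degree[gd$genus == "Poseidonia"], 1)

  # no archaeal nodes: all archaeal classes zero
  net2 <- net
  net2$nodes <- nodes[3:6, ]
  net2$edges <- edges[4, ]
  s2 <- summarize_cross_domain(net2, tax)
  expect_true(all(s2$edge_classes$n_edges[grepl("archaea", s2$edge_classes$class)] == 0))
})
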