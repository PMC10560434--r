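test_that("Bray-Curtis follows the definition and matches vegan", {
  m <- matrix(c(2, 0, 1,
                1, 1, 0,
                2, 0, 1), 3, 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:3), paste0("f", 1:3)))
  D <- bray_curtis(m)
  expect_equal(D["s1", "s2"], 0.6)   # (1+1+1)/(3+2)
  expect_equal(D["s1", "s3"], 0)     # identical samples
  disj <- matrix(c(3, 0, 0, 5), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(bray_curtis(disj)["a", "b"], 1)  # disjoint supports

  set.seed(5)
  big <- matrix(rpois(200, 10), 10, 20,
                dimnames = list(paste0("s", 1:10), paste0("f", 1:20)))
  expect_equal(bray_curtis(big), as.matrix(vegan::vegdist(big, "bray")),
               tolerance = 1e-12, ignore_attr = TRUE)

  withzero <- rbind(big, zero = 0)
  expect_error(bray_curtis(withzero), class = "estuarch_invalid_argument",
               regexp = "zero")
})

test_that("PCoA recovers planted configurations and satisfies the trace identity", {
  # collinear points: one positive eigenvalue carries everything
  line <- cbind(c(0, 1, 3, 7), 0)
  res <- pcoa(planar_distances(line))
  pos <- res$eigenvalues[res$eigenvalues > 1e-10]
  expect_equal(length(pos), 1)
  expect_equal(res$proportion_explained[1], 1)
  expect_equal(sort(abs(diff(sort(res$coordinates[, 1])))),
               sort(abs(diff(sort(line[, 1])))), tolerance = 1e-10,
               ignore_attr = TRUE)

  # planar configuration: reconstructed distances match input within 1e-8
  set.seed(8)
  xy <- matrix(rnorm(24), 12, 2)
  D <- planar_distances(xy)
  res2 <- pcoa(D, n_axes = 2)
  Dhat <- as.matrix(dist(res2$coordinates))
  expect_lt(max(abs(Dhat - D)), 1e-8)

  # agreement with the classical-scaling reference implementation
  ref <- cmdscale(D, k = 2)
  expect_equal(abs(res2$coordinates), abs(ref), tolerance = 1e-8,
               ignore_attr = TRUE)

  # regular simplex: all positive eigenvalues equal
  n <- 5
  Ds <- matrix(1, n, n) - diag(n)
  dimnames(Ds) <- list(paste0("s", 1:n), paste0("s", 1:n))
  ev <- pcoa(Ds)$eigenvalues
  expect_equal(max(ev[1:(n - 1)]) - min(ev[1:(n - 1)]), 0, tolerance = 1e-10)

  # signed eigenvalue sum equals the trace of the Gower-centered matrix
  set.seed(9)
  counts <- matrix(rpois(120, 6), 8, 15,
                   dimnames = list(paste0("s", 1:8), paste0("f", 1:15)))
  Db <- bray_curtis(counts)
  G <- estuarch:::gower_center(Db)
  expect_equal(sum(pcoa(Db)$eigenvalues), sum(diag(G)), tolerance = 1e-9)

  expect_error(pcoa(Db, n_axes = 100), class = "estuarch_invalid_argument")
})

test_that("PERMANOVA matches the algebraic one-factor oracle and vegan", {
  set.seed(21)
  counts <- matrix(rpois(160, 12), 8, 20,
                   dimnames = list(paste0("s", 1:8), paste0("f", 1:20)))
  D <- bray_curtis(counts)
  meta <- data.frame(sample_id = paste0("s", 1:8),
                     grp = rep(c("a", "b"), each = 4),
                     other = rep(c("x", "y"), 4))
  res <- permanova(D, meta, "grp", n_perm = 99, seed = 1)
  f_oracle <- oneway_f_oracle(D, meta$grp)
  expect_equal(res$pseudo_F[1], f_oracle, tolerance = 1e-9)

  # independent reference implementation agrees on SS, R2, F
  ref <- vegan::adonis2(D ~ grp + other, data = meta, permutations = 99, by = "terms")
  res2 <- permanova(D, meta, c("grp", "other"), n_perm = 99, seed = 1)
  expect_equal(res2$SS[1:2], ref$SumOfSqs[1:2], tolerance = 1e-9)
  expect_equal(res2$pseudo_F[1:2], ref$F[1:2], tolerance = 1e-9)
  expect_equal(res2$R2, c(ref$R2[1:3], 1), tolerance = 1e-9)

  # R2 sums to one; SS additivity
  expect_equal(sum(res2$R2[1:3]), 1, tolerance = 1e-9)
  expect_equal(sum(res2$SS[1:3]), res2$SS[4], tolerance = 1e-9)
})

test_that("PERMANOVA permutation p-values are exact under exhaustive relabeling", {
  set.seed(33)
  counts <- matrix(rpois(60, 15), 6, 10,
                   dimnames = list(paste0("s", 1:6), paste0("f", 1:10)))
  D <- bray_curtis(counts)
  meta <- data.frame(sample_id = paste0("s", 1:6), grp = rep(c("a", "b"), each = 3))
  perms <- all_perms(6)
  res <- permanova(D, meta, "grp", permutations = perms)

  # brute-force oracle: recompute F for every relabeling from first principles
  f_of <- function(ord) oneway_f_oracle(D[ord, ord], meta$grp)
  f_all <- apply(perms, 1, f_of)
  f_obs <- oneway_f_oracle(D, meta$grp)
  p_oracle <- (1 + sum(f_all >= f_obs - 1e-12)) / (1 + nrow(perms))
  expect_equal(res$p_value[1], p_oracle)
  expect_gte(res$p_value[1], 1 / (nrow(perms) + 1))
})

test_that("PERMANOVA flags degenerate designs and perfect separation", {
  D <- matrix(1, 4, 4) - diag(4)
  dimnames(D) <- list(paste0("s", 1:4), paste0("s", 1:4))
  meta <- data.frame(sample_id = paste0("s", 1:4),
                     grp = c("a", "a", "b", "b"), dup = c("a", "a", "b", "b"))
  # aliased duplicate factor
  expect_error(permanova(D, meta, c("grp", "dup"), n_perm = 9),
               class = "estuarch_design_error")
  # saturated design
  meta$id4 <- paste0("g", 1:4)
  expect_error(permanova(D, meta, "id4", n_perm = 9),
               class = "estuarch_design_error")

  # duplicated identical samples in two groups: residual SS 0, F infinite
  Dsep <- matrix(c(0, 0, 1, 1,
                   0, 0, 1, 1,
                   1, 1, 0, 0,
                   1, 1, 0, 0), 4, 4)
  dimnames(Dsep) <- dimnames(D)
  res <- permanova(Dsep, meta, "grp", n_perm = 9, seed = 1)
  expect_equal(res$R2[1], 1, tolerance = 1e-12)
  expect_true(is.infinite(res$pseudo_F[1]) || res$pseudo_F[1] > 1e12)
})

test_that("term order changes sequential SS but not the total", {
  set.seed(44)
  counts <- matrix(rpois(300, 10), 15, 20,
                   dimnames = list(paste0("s", 1:15), paste0("f", 1:20)))
  D <- bray_curtis(counts)
  # unbalanced two-factor design
  meta <- data.frame(sample_id = paste0("s", 1:15),
                     f1 = c(rep("a", 8), rep("b", 7)),
                     f2 = c(rep("x", 3), rep("y", 5), rep("x", 4), rep("y", 3)))
  r12 <- permanova(D, meta, c("f1", "f2"), n_perm = 19, seed = 1)
  r21 <- permanova(D, meta, c("f2", "f1"), n_perm = 19, seed = 1)
  expect_false(isTRUE(all.equal(r12$SS[1], r21$SS[2])))
  expect_equal(r12$SS[4], r21$SS[4], tolerance = 1e-9)
})

test_that("Mantel statistics and exact permutation p-values are correct", {
  set.seed(55)
  counts <- matrix(rpois(50, 10), 5, 10,
                   dimnames = list(paste0("s", 1:5), paste0("f", 1:10)))
  D1 <- bray_curtis(counts)
  expect_equal(mantel(D1, D1, n_perm = 19, seed = 1)$rho, 1)
  # rank invariance under positive affine transforms
  expect_equal(mantel(D1, 0.5 * D1 + 0.1 * (1 - diag(5)), n_perm = 19, seed = 1)$rho, 1)

  # exhaustive permutation p at n = 5 against a brute-force oracle
  counts2 <- matrix(rpois(50, 10), 5, 10,
                    dimnames = list(paste0("s", 1:5), paste0("f", 1:10)))
  D2 <- bray_curtis(counts2)
  perms <- all_perms(5)
  res <- mantel(D1, D2, permutations = perms)
  v1 <- rank(D1[lower.tri(D1)])
  rho_all <- apply(perms, 1, function(ord) {
    cor(v1, rank(D2[ord, ord][lower.tri(D2)]))
  })
  rho_obs <- cor(v1, rank(D2[lower.tri(D2)]))
  expect_equal(res$rho, rho_obs)
  expect_equal(res$p_value, (1 + sum(rho_all >= rho_obs - 1e-12)) / (1 + nrow(perms)))

  # vegan agreement on the statistic
  ref <- vegan::mantel(as.dist(D1), as.dist(D2), method = "spearman", permutations = 19)
  expect_equal(res$rho, unname(ref$statistic), tolerance = 1e-12)

  expect_error(mantel(D1, 0 * D1), class = "estuarch_undefined_correlation")
})

test_that("partial Mantel removes a shared driver and errors on self-control", {
  # latent driver: samples on a gradient g; D1 and D2 both driven by g.
  # the fixture is linear in the driver, so conditional independence holds
  # exactly on the raw scale and the Pearson variant is the sharp check
  set.seed(66)
  n <- 25
  g <- sort(runif(n, 0, 10))
  ids <- paste0("s", 1:n)
  Dg <- abs(outer(g, g, "-")); dimnames(Dg) <- list(ids, ids)
  noise_mat <- function(seed) {
    set.seed(seed)
    x <- runif(n, 0, 10)
    Dx <- abs(outer(x, x, "-")); dimnames(Dx) <- list(ids, ids)
    Dx
  }
  D1 <- 0.8 * Dg + 0.2 * noise_mat(1)
  D2 <- 0.8 * Dg + 0.2 * noise_mat(2)
  plain <- mantel(D1, D2, method = "pearson", n_perm = 99, seed = 3)
  expect_gt(plain$rho, 0.5)
  ctrl <- partial_mantel(D1, D2, Dg, method = "pearson", n_perm = 99, seed = 3)
  expect_lt(abs(ctrl$rho), 0.1)

  # controlling an unrelated matrix leaves the statistic roughly unchanged
  Dind <- noise_mat(7)
  ctrl2 <- partial_mantel(D1, D2, Dind, method = "pearson", n_perm = 99, seed = 3)
  expect_lt(abs(ctrl2$rho - plain$rho), 0.1)

  # vegan cross-check of both the partial and the rank-based statistic
  ref <- vegan::mantel.partial(as.dist(D1), as.dist(D2), as.dist(Dg),
                               method = "pearson", permutations = 19)
  expect_equal(ctrl$rho, unname(ref$statistic), tolerance = 1e-6)
  ref_sp <- vegan::mantel.partial(as.dist(D1), as.dist(D2), as.dist(Dg),
                                  method = "spearman", permutations = 19)
  ctrl_sp <- partial_mantel(D1, D2, Dg, n_perm = 19, seed = 3)
  expect_equal(ctrl_sp$rho, unname(ref_sp$statistic), tolerance = 0.02)

  expect_error(partial_mantel(D1, D1, D1), class = "estuarch_undefined_correlation")
})

test_that("environmental Spearman screen matches hand-ranked computation", {
  ab <- cbind(grp1 = c(1, 2, 3, 4, 5, 6))
  env <- data.frame(mono = c(2, 4, 9, 16, 30, 50),
                    anti = -c(1, 3, 5, 7, 9, 11),
                    tied = c(5, 5, 7, 7, 9, 9),
                    with_na = c(1, NA, 3, 4, 5, 6))
  out <- env_correlations(ab, env)
  expect_equal(out$rho[out$covariate == "mono"], 1)
  expect_equal(out$rho[out$covariate == "anti"], -1)
  # tie-aware rank correlation, checked against cor() on hand ranks
  expect_equal(out$rho[out$covariate == "tied"],
               cor(rank(ab[, 1]), rank(env$tied)))
  # pairwise NA dropping
  expect_equal(out$n[out$covariate == "with_na"], 5)
  expect_equal(out$rho[out$covariate == "with_na"], 1)

  # constant covariate reported as missing
  out2 <- env_correlations(ab, data.frame(flat = rep(3, 6)))
  expect_true(is.na(out2$rho))
})

test_that("haversine distances match a known city pair and metric axioms", {
  # Shanghai (121.47E, 31.23N) to Guangzhou (113.26E, 23.13N): ~1200 km
  D <- geographic_distance(c(121.47, 113.26, 121.47), c(31.23, 23.13, 31.23))
  expect_lt(abs(D[1, 2] - 1200), 30)
  expect_equal(D[1, 3], 0)
  expect_equal(D, t(D))
})
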