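# Shared fixture builders. Everything is generated in code; no stored data.

count_matrix <- function(values, samples, features) {
  matrix(as.integer(values), length(samples), length(features), byrow = TRUE,
         dimnames = list(samples, features))
}

# 4 samples x 3 features toy table with known totals
toy_table <- function() {
  feature_table(count_matrix(
    c(5, 0, 3,
      2, 2, 2,
      0, 0, 9,
      1, 4, 0),
    paste0("s", 1:4), paste0("f", 1:3)))
}

# mixed-domain taxonomy; domains: "Archaea", "Bacteria", or "Chloro"
# ("Chloro" = chloroplast read, i.e. phytoplankton proxy inside Bacteria)
toy_taxonomy <- function(ids, domains, genera = NULL) {
  n <- length(ids)
  taxonomy_map(data.frame(
    feature_id = ids,
    domain = ifelse(domains == "Chloro", "Bacteria", domains),
    phylum = rep("P", n), class = rep("C", n),
    order = ifelse(domains == "Chloro", "Chloroplast", "O"),
    family = rep("F", n),
    genus = if (is.null(genera)) rep("G", n) else genera,
    stringsAsFactors = FALSE
  ))
}

# distance matrix from planar points (Euclidean)
planar_distances <- function(xy) {
  D <- as.matrix(stats::dist(xy))
  dimnames(D) <- list(paste0("s", seq_len(nrow(xy))), paste0("s", seq_len(nrow(xy))))
  D
}

# all permutations of 1..n as a matrix (one per row)
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

# explicit group-sum pseudo-F for a one-factor design (algebraic oracle,
# independent of the hat-matrix route used by the package)
oneway_f_oracle <- function(D, groups) {
  n <- nrow(D)
  ss_tot <- sum(D[lower.tri(D)]^2) / n
  ss_within <- sum(vapply(unique(groups), function(g) {
    i <- groups == g
    sum(D[i, i][lower.tri(D[i, i])]^2) / sum(i)
  }, numeric(1)))
  a <- length(unique(groups))
  ((ss_tot - ss_within) / (a - 1)) / (ss_within / (n - a))
}
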