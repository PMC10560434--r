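#!/usr/bin/env Rscript
# Stage 4: distance-based community statistics.
#
# PCoA of the CSS-normalized archaeal table on Bray-Curtis dissimilarity;
# PERMANOVA of estuary, season, station and their two-way interactions;
# Mantel and partial-Mantel tests of archaeal composition against
# environmental distance and bacterial composition.

suppressPackageStartupMessages(library(estuarch))

dat <- "results/data"
out <- "results/commstats"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

counts <- read_feature_table(file.path(dat, "counts.tsv"))
taxonomy <- read_taxonomy(file.path(dat, "taxonomy.tsv"))
metadata <- read_sample_metadata(file.path(dat, "metadata.tsv"))
rownames(metadata) <- metadata$sample_id
css <- read_feature_table("results/prepare/archaea_css.tsv", normalized = "css")
meta <- metadata[sample_ids(css), ]

D <- bray_curtis(css)
ord <- pcoa(D, n_axes = 2)
utils::write.table(
  data.frame(sample_id = rownames(ord$coordinates), ord$coordinates,
             meta[, c("estuary", "season", "station")]),
  file.path(out, "pcoa_coordinates.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("PCoA axes 1-2 explain %.1f%% and %.1f%% of positive inertia\n",
            100 * ord$proportion_explained[1], 100 * ord$proportion_explained[2]))

terms <- c("estuary", "season", "station",
           "estuary:season", "estuary:station", "season:station")
pmv <- permanova(D, meta, terms, n_perm = 999, seed = 1)
utils::write.table(pmv, file.path(out, "permanova.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nPERMANOVA on Bray-Curtis (sequential SS):\n")
print(pmv, row.names = FALSE, digits = 3)

# drivers: environmental distance and bacterial community composition
env_vars <- c("temperature", "salinity", "pH", "DO", "NO3", "COD")
envz <- scale(meta[, env_vars])
Denv <- as.matrix(dist(envz)); dimnames(Denv) <- list(rownames(meta), rownames(meta))
bact <- subset_by_domain(ft_subset(counts, samples = rownames(meta)),
                         taxonomy, "is_bacterium")
Dbac <- bray_curtis(bact)

rows <- list(
  cbind(test = "mantel", D2 = "env_distance",
        as.data.frame(unclass(mantel(D, Denv, n_perm = 999, seed = 2))[c("rho", "p_value")])),
  cbind(test = "mantel", D2 = "bacterial_bray",
        as.data.frame(unclass(mantel(D, Dbac, n_perm = 999, seed = 3))[c("rho", "p_value")])),
  cbind(test = "partial_mantel_ctrl_bacteria", D2 = "env_distance",
        as.data.frame(unclass(partial_mantel(D, Denv, Dbac, n_perm = 999,
                                             seed = 4))[c("rho", "p_value")])),
  cbind(test = "partial_mantel_ctrl_env", D2 = "bacterial_bray",
        as.data.frame(unclass(partial_mantel(D, Dbac, Denv, n_perm = 999,
                                             seed = 5))[c("rho", "p_value")]))
)
mr <- do.call(rbind, rows)
utils::write.table(mr, file.path(out, "mantel.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nMantel tests (Spearman):\n")
print(mr, row.names = FALSE, digits = 3)

# Spearman screen: archaeal genus abundances vs environmental covariates
genera <- unique(taxonomy$genus[taxonomy$is_archaeon])
ab <- vapply(genera, function(g) {
  relative_abundance_of(ft_subset(counts, samples = rownames(meta)),
                        taxonomy, group = c(genus = g))
}, numeric(nrow(meta)))
screen <- env_correlations(ab, meta[, env_vars])
utils::write.table(screen, file.path(out, "env_correlations.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
sig <- screen[!is.na(screen$p_value) & screen$p_value < 0.01, ]
cat(sprintf("\nenv screen: %d of %d genus-covariate pairs with p < 0.01\n",
            nrow(sig), nrow(screen)))
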