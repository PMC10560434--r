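#!/usr/bin/env Rscript
# Stage 2: table preparation.
#
# Separates the archaeal sub-table from the whole-community counts, drops
# archaeal samples under 100 reads, CSS-normalizes the survivors for the
# ordination/PERMANOVA stage, and counts shared/unique archaeal taxa across
# estuaries within each season (the Venn numbers).

suppressPackageStartupMessages(library(estuarch))

dat <- "results/data"
out <- "results/prepare"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

counts <- read_feature_table(file.path(dat, "counts.tsv"))
taxonomy <- read_taxonomy(file.path(dat, "taxonomy.tsv"))
metadata <- read_sample_metadata(file.path(dat, "metadata.tsv"))
rownames(metadata) <- metadata$sample_id

arch <- subset_by_domain(counts, taxonomy, "is_archaeon")
arch_kept <- drop_low_depth_samples(arch, 100)
cat(sprintf("archaeal sub-table: %d samples kept of %d (dropping < 100 reads)\n",
            n_samples(arch_kept), n_samples(arch)))

css <- css_normalize(arch_kept, css_params(quantile_l = 0.5, scale_constant = 1000))
write_feature_table(css, file.path(out, "archaea_css.tsv"))

# per-sample archaeal share of the prokaryotic community
arch_share <- relative_abundance_of(counts, taxonomy, group = "is_archaeon")
utils::write.table(data.frame(sample_id = names(arch_share), archaeal_fraction = arch_share),
                   file.path(out, "archaeal_fraction.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("archaeal fraction of prokaryotic reads: %.3f-%.3f (median %.3f)\n",
            min(arch_share), max(arch_share), median(arch_share)))

# shared/unique archaeal taxa across estuaries, by season
meta_kept <- metadata[sample_ids(arch_kept), ]
for (season in unique(meta_kept$season)) {
  tabs <- lapply(split(rownames(meta_kept)[meta_kept$season == season],
                       meta_kept$estuary[meta_kept$season == season]),
                 function(ids) ft_subset(arch_kept, samples = ids))
  venn <- shared_feature_counts(tabs)
  utils::write.table(venn, file.path(out, sprintf("venn_%s.tsv", season)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  all_shared <- venn$count[venn$n_groups == length(tabs)]
  cat(sprintf("%s: %d archaeal taxa shared across all %d estuaries (of %d detected)\n",
              season, all_shared, length(tabs), sum(venn$count)))
}
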