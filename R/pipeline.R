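#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis (simulate or load ->
#' filter/normalize -> neutral model -> community statistics -> networks ->
#' summaries) with the documented defaults. All randomness derives from
#' `seed`.
#'
#' @param mode `"simulate"` (default; generate the full multi-estuary study
#'   in silico) or `"load"` (read tables from `paths`).
#' @param paths named list with `table`, `taxonomy`, `metadata`, and
#'   optionally `env` (TSV paths) — required in load mode.
#' @param sim named list of simulation settings; see Details.
#' @param min_reads per-sample read floor for the focal-domain sub-table.
#' @param rarefaction_depth depth for the whole-community rarefied table
#'   (`NULL` to skip).
#' @param css a [css_params] list.
#' @param ncm list: `d` (detection limit), `ci_level`, `source_mode`
#'   (`"local"` fits each stratum against its own pooled abundances,
#'   `"all"` against the pooled table across estuaries within a season).
#' @param permanova_terms character vector of PERMANOVA terms.
#' @param n_perm permutations for PERMANOVA.
#' @param network a [network_config]; `env_vars` names the metadata
#'   covariates carried into networks.
#' @param env_vars environmental covariates used as network nodes.
#' @param out_dir output directory.
#' @param seed master seed.
#' @details `sim` defaults emulate the study design: 4 estuaries x 2
#'   seasons x 2 stations x 5 replicates (80 samples), a lognormal source
#'   pool, estuary-specific migration rates, and a handful of planted
#'   selected-for/against taxa per season.
#' @export
pipeline_config <- function(mode = c("simulate", "load"), paths = NULL,
                            sim = list(), min_reads = 100,
                            rarefaction_depth = NULL, css = css_params(),
                            ncm = list(d = 1, ci_level = 0.95, source_mode = "local"),
                            permanova_terms = c("estuary", "season", "station",
                                                "estuary:season", "estuary:station",
                                                "season:station"),
                            n_perm = 999,
                            network = network_config(),
                            env_vars = c("temperature", "salinity", "pH"),
                            out_dir = tempfile("estuarch_run_"), seed = 1) {
  mode <- match.arg(mode)
  sim_defaults <- list(
    n_taxa = 400, lognormal_sigma = 2,
    domain_fractions = c(archaea = 0.3, bacteria = 0.6, phytoplankton = 0.1),
    community_size = 8000,
    migration = c("Yellow River" = 0.4, "Yangtze River" = 0.15,
                  "Qiantang River" = 0.1, "Pearl River" = 0.05),
    replicates = 5, n_selected = 8, selection_effect = 3
  )
  sim <- utils::modifyList(sim_defaults, sim)
  if (mode == "load") {
    need <- c("table", "taxonomy", "metadata")
    missing <- setdiff(need, names(paths))
    if (length(missing)) est_invalid(sprintf("load mode needs paths: %s",
                                             paste(missing, collapse = ", ")))
    for (p in unlist(paths)) if (!file.exists(p)) est_invalid(sprintf("path not found: %s", p))
  }
  list(mode = mode, paths = paths, sim = sim, min_reads = min_reads,
       rarefaction_depth = rarefaction_depth, css = css, ncm = ncm,
       permanova_terms = permanova_terms, n_perm = n_perm, network = network,
       env_vars = env_vars, out_dir = out_dir, seed = as.integer(seed))
}

#' Derive a per-stage seed from the master seed
#' @noRd
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset * 9973) %% 2147483000)
}

#' Synthetic taxonomy for a simulated source pool
#'
#' Assigns each pool taxon a plausible lineage consistent with its domain
#' label (archaeal genera drawn from the dominant planktonic groups,
#' chloroplast lineages for the phytoplankton fraction). Synthetic: names
#' are field-realistic labels, not reference-database assignments.
#'
#' @param pool a `source_pool`.
#' @param seed integer seed.
#' @return a [taxonomy_map].
#' @export
synthetic_taxonomy <- function(pool, seed = 1) {
  arch_genera <- c("Nitrosopumilus", "Nitrosopelagicus", "Poseidonia",
                   "MGIIb", "Halococcus", "Woesearchaeales")
  bact_genera <- c("Synechococcus", "SAR11_clade", "SAR86_clade", "Nitrospina",
                   "Flavobacterium", "Roseobacter", "Polaribacter", "Vibrio")
  phyto_genera <- c("Skeletonema", "Thalassiosira", "Chaetoceros", "Micromonas")
  with_seed(seed, {
    lab <- pool$domain_labels
    n <- length(lab)
    genus <- character(n)
    genus[lab == "archaea"] <- sample(arch_genera, sum(lab == "archaea"), replace = TRUE)
    genus[lab == "bacteria"] <- sample(bact_genera, sum(lab == "bacteria"), replace = TRUE)
    genus[lab == "phytoplankton"] <- sample(phyto_genera, sum(lab == "phytoplankton"), replace = TRUE)
    taxonomy_map(data.frame(
      feature_id = pool$taxon_ids,
      domain = c(archaea = "Archaea", bacteria = "Bacteria",
                 phytoplankton = "Bacteria")[lab],
      phylum = c(archaea = "Thermoproteota", bacteria = "Proteobacteria",
                 phytoplankton = "Cyanobacteria")[lab],
      class = c(archaea = "Nitrososphaeria", bacteria = "Gammaproteobacteria",
                phytoplankton = "Cyanobacteriia")[lab],
      order = c(archaea = "Nitrosopumilales", bacteria = "Pseudomonadales",
                phytoplankton = "Chloroplast")[lab],
      family = c(archaea = "Nitrosopumilaceae", bacteria = "Pseudomonadaceae",
                 phytoplankton = "Chloroplast_fam")[lab],
      genus = genus,
      stringsAsFactors = FALSE
    ))
  })
}

#' Simulate the full multi-estuary study
#'
#' One source pool; per estuary x season stratum, neutral local communities
#' at the stratum's migration rate; planted selected-for and
#' selected-against archaeal taxa; environmental covariates tied to the
#' design.
#'
#' @param config a [pipeline_config] in simulate mode.
#' @return list: `table` (raw counts, all samples), `taxonomy`, `metadata`
#'   (design + env), `pool`, `planted` (list of for/against taxon ids).
#' @export
simulate_study <- function(config = pipeline_config()) {
  sim <- config$sim
  pool <- simulate_source_pool(sim$n_taxa, sim$lognormal_sigma,
                               sim$domain_fractions,
                               seed = stage_seed(config$seed, 1))
  taxonomy <- synthetic_taxonomy(pool, seed = stage_seed(config$seed, 2))
  design <- make_design(replicates = sim$replicates)
  env <- simulate_env_covariates(design, seed = stage_seed(config$seed, 3))
  strata <- unique(design[, c("estuary", "season")])
  counts <- NULL
  offset <- 10L
  for (r in seq_len(nrow(strata))) {
    rows <- design$estuary == strata$estuary[r] & design$season == strata$season[r]
    spec <- neutral_sim_spec(sum(rows), sim$community_size,
                             sim$migration[[strata$estuary[r]]],
                             seed = stage_seed(config$seed, offset + r))
    ftab <- simulate_neutral_samples(pool, spec)
    v <- ft_values(ftab)
    rownames(v) <- design$sample_id[rows]
    counts <- rbind(counts, v)
  }
  counts <- counts[design$sample_id, , drop = FALSE]
  table <- feature_table(counts)
  arch <- pool$taxon_ids[pool$domain_labels == "archaea"]
  freq <- colMeans(counts[, arch, drop = FALSE] > 0)
  eligible <- arch[freq > 0.05 & freq < 0.5]
  planted <- list(selected_for = character(0), selected_against = character(0))
  if (length(eligible) >= 2 * sim$n_selected) {
    pick <- with_seed(stage_seed(config$seed, 4),
                      sample(eligible, 2 * sim$n_selected))
    planted$selected_for <- pick[seq_len(sim$n_selected)]
    planted$selected_against <- pick[-seq_len(sim$n_selected)]
    table <- plant_selection(table, planted$selected_for, "for",
                             sim$selection_effect, seed = stage_seed(config$seed, 5))
    table <- plant_selection(table, planted$selected_against, "against",
                             sim$selection_effect, seed = stage_seed(config$seed, 6))
  }
  metadata <- cbind(design, env)
  list(table = table, taxonomy = taxonomy, metadata = metadata,
       pool = pool, planted = planted)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input simulation (or loading), focal-domain
#' sub-setting and low-depth sample dropping, CSS normalization, per-stratum
#' neutral-model fits with category abundance partitions, PCoA and
#' PERMANOVA on Bray-Curtis distances, per-stratum direct-association
#' networks with module/role analysis and cross-domain summaries. All stage
#' outputs are written as TSV under `config$out_dir`, together with a JSON
#' manifest (config snapshot, input hashes, per-stage dimensions).
#' Strata with too few usable samples are skipped with a warning.
#'
#' @param config a [pipeline_config].
#' @return the manifest, invisibly (list; also written as `manifest.json`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  manifest <- list(config = config[setdiff(names(config), "network")],
                   stages = list())

  ## stage 1: inputs
  if (config$mode == "simulate") {
    study <- simulate_study(config)
    table <- study$table; taxonomy <- study$taxonomy; metadata <- study$metadata
    write_feature_table(table, out("counts.tsv"))
    write_taxonomy(taxonomy, out("taxonomy.tsv"))
    write_sample_metadata(metadata, out("metadata.tsv"))
    manifest$stages$inputs <- list(mode = "simulate",
                                   n_samples = n_samples(table),
                                   n_features = n_features(table),
                                   planted = study$planted)
  } else {
    table <- read_feature_table(config$paths$table)
    taxonomy <- read_taxonomy(config$paths$taxonomy)
    metadata <- read_sample_metadata(config$paths$metadata)
    manifest$stages$inputs <- list(
      mode = "load",
      hashes = as.list(tools::md5sum(unlist(config$paths))),
      n_samples = n_samples(table), n_features = n_features(table))
  }
  rownames(metadata) <- metadata$sample_id

  ## stage 2: preparation — focal (archaeal) sub-table, depth filter, CSS
  arch <- subset_by_domain(table, taxonomy, "is_archaeon")
  arch <- drop_low_depth_samples(arch, config$min_reads)
  css <- css_normalize(arch, config$css)
  write_feature_table(css, out("archaea_css.tsv"))
  manifest$stages$prep <- list(n_archaeal_features = n_features(arch),
                               n_samples_kept = n_samples(arch),
                               n_samples_dropped = n_samples(table) - n_samples(arch))

  meta_kept <- metadata[sample_ids(arch), , drop = FALSE]
  strata <- unique(meta_kept[, c("estuary", "season")])

  ## stage 3: neutral model per stratum
  ncm_rows <- list()
  for (r in seq_len(nrow(strata))) {
    sel <- meta_kept$estuary == strata$estuary[r] & meta_kept$season == strata$season[r]
    ids <- rownames(meta_kept)[sel]
    if (length(ids) < 5) {
      warning(sprintf("skipping NCM for %s/%s: only %d samples",
                      strata$estuary[r], strata$season[r], length(ids)))
      next
    }
    season_ids <- rownames(meta_kept)[meta_kept$season == strata$season[r]]
    local <- ft_subset(table, samples = ids)
    source <- if (identical(config$ncm$source_mode, "all")) {
      ft_subset(table, samples = season_ids)
    } else NULL
    fit <- tryCatch(
      fit_ncm(local, source, d = config$ncm$d, ci_level = config$ncm$ci_level),
      estuarch_error = function(e) e)
    if (inherits(fit, "condition")) {
      warning(sprintf("NCM failed for %s/%s: %s", strata$estuary[r],
                      strata$season[r], conditionMessage(fit)))
      next
    }
    focal <- intersect(feature_ids(local),
                       taxonomy$feature_id[taxonomy$is_archaeon])
    focal <- focal[focal %in% fit$points$taxon_id &
                     colSums(ft_values(local)[, focal, drop = FALSE]) > 0]
    cats <- classify_taxa(fit, focal)
    part <- partition_abundance(local, cats, focal)
    ncm_rows[[r]] <- data.frame(
      estuary = strata$estuary[r], season = strata$season[r],
      n_samples = length(ids), Nm = fit$Nm, m = fit$m, N = fit$N,
      r_squared = fit$r_squared,
      frac_neutral = part[["neutral"]], frac_above = part[["above"]],
      frac_below = part[["below"]], stringsAsFactors = FALSE)
  }
  ncm_summary <- do.call(rbind, ncm_rows)
  if (!is.null(ncm_summary)) {
    utils::write.table(ncm_summary, out("ncm_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  manifest$stages$ncm <- list(n_strata_fit = length(Filter(Negate(is.null), ncm_rows)))

  ## stage 4: community statistics on the CSS table
  D <- bray_curtis(css)
  ord <- pcoa(D, n_axes = 2)
  coords <- data.frame(sample_id = rownames(ord$coordinates), ord$coordinates)
  utils::write.table(coords, out("pcoa_coordinates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pmv <- permanova(D, meta_kept, config$permanova_terms,
                   n_perm = config$n_perm, seed = stage_seed(config$seed, 40))
  utils::write.table(pmv, out("permanova.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest$stages$commstats <- list(
    pcoa_prop_explained = unname(ord$proportion_explained[1:2]),
    permanova_terms = nrow(pmv) - 2)

  ## stage 5: networks per stratum (whole community, env-aware)
  net_rows <- list()
  for (r in seq_len(nrow(strata))) {
    sel <- meta_kept$estuary == strata$estuary[r] & meta_kept$season == strata$season[r]
    ids <- rownames(meta_kept)[sel]
    if (length(ids) < config$network$n_obs_min) {
      warning(sprintf("skipping network for %s/%s: only %d samples",
                      strata$estuary[r], strata$season[r], length(ids)))
      next
    }
    missing_env <- setdiff(config$env_vars, names(meta_kept))
    if (length(missing_env)) {
      est_invalid(sprintf("network stage: env column(s) missing from metadata: %s",
                          paste(missing_env, collapse = ", ")))
    }
    sub <- filter_for_network(ft_subset(table, samples = ids))
    if (n_features(sub) < 2) next
    env_sub <- meta_kept[ids, config$env_vars, drop = FALSE]
    net <- infer_direct_network(sub, env_sub, config$network,
                                seed = stage_seed(config$seed, 60 + r))
    mods <- detect_modules(net)
    roles <- classify_roles(zi_pi(net, mods))
    summ <- summarize_cross_domain(net, taxonomy)
    tag <- sprintf("%s_%s", gsub(" ", "", strata$estuary[r]), strata$season[r])
    write_edge_list(summ$edges, out(sprintf("network_%s_edges.tsv", tag)))
    utils::write.table(roles, out(sprintf("network_%s_nodes.tsv", tag)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    net_rows[[r]] <- cbind(estuary = strata$estuary[r], season = strata$season[r],
                           summ$network_stats)
  }
  net_summary <- do.call(rbind, net_rows)
  if (!is.null(net_summary)) {
    utils::write.table(net_summary, out("network_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  manifest$stages$networks <- list(n_strata = length(Filter(Negate(is.null), net_rows)))

  manifest$versions <- list(estuarch = as.character(utils::packageVersion("estuarch")),
                            R = R.version.string)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE)
  invisible(manifest)
}
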