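#' Pipeline configuration
#'
#' Either paths to the three input tables or a simulation block must be
#' given (not neither).
#'
#' @param otu_path,taxonomy_path,metadata_path Tab-separated input tables
#'   (see [read_otu_table()] and friends), or `NULL` when simulating.
#' @param simulate A [sim_config()] to generate the study instead of
#'   reading it.
#' @param mic A [mic_config()] (its `seed` is overridden by the derived
#'   per-stage seed).
#' @param keystone A [keystone_criteria()] applied to every network level.
#' @param group_col Metadata column defining the networks' grouping.
#' @param rarefy_depth Rarefaction depth applied when a sample exceeds it
#'   (simulated tables already sum to the target depth).
#' @param alpha Edge-calling FDR level.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @param seed Global seed; per-stage seeds are derived as
#'   `seed * 100 + stage` so stages are independently reproducible.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(otu_path = NULL, taxonomy_path = NULL,
                            metadata_path = NULL, simulate = NULL,
                            mic = mic_config(), keystone = keystone_criteria(),
                            group_col = "system", rarefy_depth = 1000,
                            alpha = 0.05, out_dir = NULL, seed = 1L) {
  if (is.null(simulate) && is.null(otu_path))
    stop("configuration error: provide either input paths or a simulate block")
  structure(list(otu_path = otu_path, taxonomy_path = taxonomy_path,
                 metadata_path = metadata_path, simulate = simulate,
                 mic = mic, keystone = keystone, group_col = group_col,
                 rarefy_depth = rarefy_depth, alpha = alpha,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full co-occurrence analysis pipeline
#'
#' Simulate (or read) the study, filter and rarefy the OTU table, fit the
#' pooled meta-network on all samples and one network per group, select
#' keystone taxa at each level, compare group networks (KS on node
#' attributes), relate per-farm connectivity to agricultural intensity,
#' attribute keystone abundance to soil covariates by random-forest
#' permutation importance, and compute alpha/beta diversity and indicator
#' species.  Deterministic given the global seed.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result` with elements `meta`
#'   (pooled `micnet` fit), `groups` (per-group fits), `keystones`,
#'   `diversity`, `permanova`, `permdisp`, `indicators`, `comparisons`,
#'   `connectivity`, `drivers`, `truth` (when simulated) and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed_for <- function(stage) config$seed * 100L + stage

  # ---- stage 1: inputs -------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_cfg <- config$simulate
    sim_cfg$seed <- seed_for(1L)
    study <- simulate_study(sim_cfg)
    otu <- study$otu
    taxonomy <- study$taxonomy
    metadata <- study$metadata
    truth <- study$truth
  } else {
    otu <- read_otu_table(config$otu_path)
    taxonomy <- if (!is.null(config$taxonomy_path))
      read_taxonomy(config$taxonomy_path) else NULL
    metadata <- read_metadata(config$metadata_path)
    truth <- NULL
  }
  groups <- metadata[[config$group_col]]
  if (is.null(groups)) stop("grouping column '", config$group_col,
                            "' missing from metadata")

  # ---- stage 2: filtering / rarefaction --------------------------------
  otu <- filter_low_abundance(otu)
  if (any(rowSums(otu) > config$rarefy_depth))
    otu <- rarefy(otu, config$rarefy_depth, seed = seed_for(2L))
  otu <- prevalence_filter(otu, 2)

  # ---- stage 3: community statistics -----------------------------------
  div <- alpha_diversity(otu)
  bc <- bray_curtis(otu)
  pa <- permanova(bc, groups, n_perm = 999, seed = seed_for(3L))
  pd <- permdisp(bc, groups, n_perm = 999, seed = seed_for(3L))
  ind <- indicator_species(otu, groups, n_perm = 999, seed = seed_for(3L))

  # ---- stage 4: networks (pooled + per group) --------------------------
  cfg_meta <- config$mic
  cfg_meta$alpha <- config$alpha
  cfg_meta$seed <- seed_for(4L)
  meta_fit <- micnet(otu, taxonomy, cfg_meta, config$keystone)
  group_fits <- list()
  for (g in unique(groups)) {
    rows <- groups == g
    tab_g <- prevalence_filter(otu[rows, , drop = FALSE], 2)
    cfg_g <- cfg_meta
    cfg_g$seed <- seed_for(4L) + match(g, unique(groups))
    group_fits[[g]] <- micnet(tab_g, taxonomy, cfg_g, config$keystone)
  }

  keystones <- lapply(group_fits, function(f)
    if (is.null(f$keystones)) character(0) else f$keystones$otu)

  # ---- stage 5: network comparison and connectivity --------------------
  comparisons <- list()
  gl <- names(group_fits)
  for (i in seq_along(gl)) for (j in seq_len(i - 1L)) {
    a <- group_fits[[gl[i]]]; b <- group_fits[[gl[j]]]
    if (is.null(a$nodes) || is.null(b$nodes)) next
    cmp <- compare_node_attributes(a$nodes, b$nodes)
    cmp$pair <- paste(gl[j], gl[i], sep = " vs ")
    comparisons[[length(comparisons) + 1L]] <- cmp
  }
  comparisons <- if (length(comparisons)) do.call(rbind, comparisons) else NULL
  if (!is.null(comparisons))
    comparisons$p_adjusted <- p.adjust(comparisons$p_value, "BH")

  conn <- do.call(rbind, lapply(gl, function(g) {
    rows <- groups == g
    farm_subgraph_connectivity(group_fits[[g]]$network,
                               otu[rows, , drop = FALSE],
                               metadata[rows, , drop = FALSE])
  }))
  conn_fit <- tryCatch(connectivity_vs_intensity(conn),
                       error = function(e) NULL)

  # ---- stage 6: drivers ------------------------------------------------
  all_keystones <- unique(unlist(keystones))
  drivers <- NULL
  covar_cols <- intersect(c("total_P", "olsen_P", "pH", "bulk_density",
                            "amf_colonization", "amf_plfa"),
                          colnames(metadata))
  if (length(all_keystones) > 0 && length(covar_cols) >= 2) {
    y <- keystone_abundance_response(otu, all_keystones)
    X <- metadata[rownames(otu), covar_cols, drop = FALSE]
    drivers <- tryCatch(
      rf_permutation_significance(X, y, n_trees = 1500, n_perm = 99,
                                  alpha = 0.01, seed = seed_for(6L)),
      error = function(e) NULL)
  }

  manifest <- list(
    seed = config$seed,
    stage_seeds = setNames(seed_for(1:6), paste0("stage", 1:6)),
    n_samples = nrow(otu), n_otus = ncol(otu),
    groups = as.list(tapply(rownames(otu), groups, identity)),
    alpha = config$alpha,
    mic = unclass(config$mic),
    keystone = unclass(config$keystone),
    timestamp = NULL)

  res <- structure(list(meta = meta_fit, groups = group_fits,
                        keystones = keystones, diversity = div,
                        permanova = pa, permdisp = pd, indicators = ind,
                        comparisons = comparisons, connectivity = conn,
                        connectivity_fit = conn_fit, drivers = drivers,
                        truth = truth, manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(res, config$out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("rhizonet pipeline result\n")
  cat(sprintf("  meta-network: %d nodes, %d edges\n",
              x$meta$topology$n_nodes, x$meta$topology$n_edges))
  for (g in names(x$groups))
    cat(sprintf("  %s: %d nodes, %d edges, %d keystones\n", g,
                x$groups[[g]]$topology$n_nodes,
                x$groups[[g]]$topology$n_edges,
                length(x$keystones[[g]])))
  if (!is.null(x$connectivity_fit))
    cat(sprintf("  connectivity ~ intensity: slope %.3f, R2 %.3f, p %.3g\n",
                x$connectivity_fit$slope, x$connectivity_fit$r_squared,
                x$connectivity_fit$p_value))
  if (!is.null(x$drivers))
    cat("  drivers:", paste(x$drivers$drivers, collapse = ", "), "\n")
  invisible(x)
}

write_pipeline_result <- function(res, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(d, f) write.table(d, file.path(dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  wt(res$diversity, "alpha_diversity.tsv")
  wt(res$indicators, "indicator_species.tsv")
  if (!is.null(res$comparisons)) wt(res$comparisons, "ks_comparisons.tsv")
  wt(res$connectivity, "farm_connectivity.tsv")
  wt(res$meta$assoc, "meta_associations.tsv")
  write_network(res$meta$network, file.path(dir, "meta_network.graphml"))
  write_network(res$meta$network, file.path(dir, "meta_network.sif"), "sif")
  for (g in names(res$groups)) {
    fit <- res$groups[[g]]
    if (igraph::vcount(fit$network) > 0) {
      write_network(fit$network, file.path(dir, paste0(g, "_network.graphml")))
      write_network(fit$network, file.path(dir, paste0(g, "_network.sif")),
                    "sif")
    }
    if (!is.null(fit$keystones) && nrow(fit$keystones))
      wt(fit$keystones, paste0(g, "_keystones.tsv"))
  }
  if (!is.null(res$drivers)) wt(res$drivers$importance, "drivers.tsv")
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
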