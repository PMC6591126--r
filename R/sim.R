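#' Synthetic study configuration
#'
#' Parameters of the synthetic root-microbiome study generator.  The
#' defaults emulate a 3-system field survey (20 farms per system, one
#' sample per farm, 1000 reads per sample after rarefaction) in which the
#' low-intensity system harbours many network hub taxa, the intermediate
#' system few, and the high-intensity system none.
#'
#' Dependence is induced on latent log-abundances through shared Gaussian
#' factors and converted to counts by softmax + multinomial sampling, so
#' every sample sums exactly to `reads_per_sample`.  Each hub guild has one
#' latent factor per system sample block: hub OTUs load `sqrt(hub_loading)`
#' on it and partner OTUs load `sqrt(within_guild_correlation)`, giving
#' hub-partner latent correlation `sqrt(hub_loading *
#' within_guild_correlation)` and partner-partner correlation
#' `within_guild_correlation` inside the block and independence outside it.
#' Background guilds span all samples and provide system-independent
#' co-occurrence visible in the pooled meta-network.
#'
#' @param n_samples_per_system Samples (farms) per farming system.
#' @param n_otus Total OTU pool size.
#' @param reads_per_sample Sequencing depth after rarefaction.
#' @param n_hubs_per_system Named integer vector, hubs planted per system;
#'   names define the systems.  A system's hubs share one guild latent
#'   factor per sample block.
#' @param hub_partner_count Size of the partner OTU pool attached to each
#'   system's hub guild.  The pool is shared across systems: a partner OTU
#'   follows each system's guild factor within that system's sample block,
#'   so the same taxa are networked everywhere while the number of hubs
#'   differs by system.
#' @param within_guild_correlation Latent pairwise correlation between
#'   ordinary (partner) members of a guild, in (0, 1).  Hub-partner
#'   correlation is `sqrt(hub_loading * within_guild_correlation)`.
#' @param hub_loading Squared latent loading of hub OTUs on their guild
#'   factor, in (0, 1].
#' @param n_bg_guilds,bg_guild_size Background (cross-system) guilds and
#'   their size; these span all samples and give the pooled meta-network
#'   its system-independent co-occurrence.
#' @param noise_dispersion Standard deviation of the latent log-abundance
#'   noise (unitless, > 0).
#' @param latent_sd Standard deviation of the structured latent signal.
#' @param guild_mu_boost Baseline log-abundance of guild OTUs.
#' @param noise_mu Baseline log-abundance of the noise pool.  Keeping the
#'   noise pool's total read share substantial is essential: relative
#'   abundances are compositional, so a latent factor shared by OTUs that
#'   dominate the read budget is cancelled by closure; guild taxa must
#'   bloom against a stable background for their co-occurrence to be
#'   visible in counts.
#' @param covariate_effects Named vector of standardised effect sizes
#'   linking each soil covariate to summed hub relative abundance
#'   (`covariate = beta * scale(hub_ra) + N(0, 1)` before rescaling to
#'   field units, so R-squared is `beta^2 / (beta^2 + 1)`).
#' @param intensity_by_system Named vector of mean agricultural-intensity
#'   index per system.
#' @param intensity_sd Within-system standard deviation of the index.
#' @param seed Integer seed; all randomness derives from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_samples_per_system = 20,
                       n_otus = 100,
                       reads_per_sample = 1000,
                       n_hubs_per_system = c(conventional = 0, no_till = 2,
                                             organic = 10),
                       hub_partner_count = 30,
                       within_guild_correlation = 0.85,
                       hub_loading = 0.99,
                       n_bg_guilds = 2,
                       bg_guild_size = 8,
                       noise_dispersion = 1,
                       latent_sd = 2.4,
                       guild_mu_boost = 0.7,
                       noise_mu = 1.2,
                       covariate_effects = c(total_P = -1, olsen_P = -1,
                                             pH = 1, bulk_density = -1,
                                             amf_colonization = 1.1,
                                             amf_plfa = 1),
                       intensity_by_system = c(conventional = 1.6,
                                               no_till = 1.1, organic = 0.6),
                       intensity_sd = 0.18,
                       seed = 1L) {
  stopifnot(n_samples_per_system >= 2, n_otus >= 2, reads_per_sample > 0,
            within_guild_correlation > 0, within_guild_correlation < 1,
            hub_loading > 0, hub_loading <= 1,
            noise_dispersion > 0,
            length(n_hubs_per_system) >= 1,
            !is.null(names(n_hubs_per_system)),
            all(names(n_hubs_per_system) %in% names(intensity_by_system)))
  guild_otus <- sum(n_hubs_per_system) +
    (if (any(n_hubs_per_system > 0)) hub_partner_count else 0) +
    n_bg_guilds * bg_guild_size
  if (guild_otus > n_otus)
    stop("infeasible configuration: guild structure needs ", guild_otus,
         " OTUs but n_otus = ", n_otus)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic root-microbiome study
#'
#' Produces an OTU count table, taxonomy, sample metadata and the planted
#' ground truth for a multi-system study drawn from [sim_config()].
#' Running twice with the same configuration gives byte-identical output.
#'
#' @param config A [sim_config()].
#' @return A list of class `synthetic_study` with elements `otu` (count
#'   matrix, samples x OTUs, rows summing to `reads_per_sample`),
#'   `taxonomy` (data frame), `metadata` (data frame), and `truth` (hub
#'   ids per system, guild membership, dependent pairs, covariate effects).
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  systems <- names(cfg$n_hubs_per_system)
  ns <- cfg$n_samples_per_system
  n_total <- ns * length(systems)

  withr_seed(cfg$seed, {
    otu_ids <- sprintf("OTU_%03d", seq_len(cfg$n_otus))
    sample_ids <- sprintf("S%02d", seq_len(n_total))
    sys_of_sample <- rep(systems, each = ns)
    blocks <- split(seq_len(n_total), factor(sys_of_sample, levels = systems))

    # ---- assign OTUs to roles ------------------------------------------
    pool <- seq_len(cfg$n_otus)
    take <- function(k) {
      ix <- pool[seq_len(k)]
      pool <<- pool[-seq_len(k)]
      ix
    }
    hubs <- list()          # per system: integer OTU indices
    guild_of <- rep(NA_character_, cfg$n_otus)
    role <- rep("noise", cfg$n_otus)
    for (s in systems) {
      nh <- cfg$n_hubs_per_system[[s]]
      hubs[[s]] <- if (nh > 0) take(nh) else integer(0)
      role[hubs[[s]]] <- "hub"
      guild_of[hubs[[s]]] <- paste0(s, "_guild")
    }
    partner_pool <- if (any(cfg$n_hubs_per_system > 0))
      take(cfg$hub_partner_count) else integer(0)
    role[partner_pool] <- "partner"
    guild_of[partner_pool] <- "partner_pool"
    guilds <- list()        # per hub system: list(system, hubs, partners)
    max_nh <- max(cfg$n_hubs_per_system)
    for (s in systems) {
      nh <- cfg$n_hubs_per_system[[s]]
      if (nh == 0) next
      # the breadth of the networked partner pool scales with the number
      # of hubs a system supports (hub-poor systems recruit fewer guild
      # members into their block's co-occurrence structure)
      n_p <- ceiling(cfg$hub_partner_count * nh / max_nh)
      guilds[[paste0(s, "_guild")]] <-
        list(system = s, hubs = hubs[[s]],
             partners = partner_pool[seq_len(n_p)])
    }
    bg_guilds <- list()
    for (g in seq_len(cfg$n_bg_guilds)) {
      gid <- paste0("bg_guild", g)
      m <- take(cfg$bg_guild_size)
      guild_of[m] <- gid
      role[m] <- "background"
      bg_guilds[[gid]] <- m
    }

    # ---- latent log-abundances -----------------------------------------
    # noise OTUs get a stable, boosted baseline that anchors the read
    # budget; guild OTUs bloom against it when their factor is high, so
    # the planted co-occurrence survives compositional closure
    mu <- rnorm(cfg$n_otus, 0, ifelse(role == "noise", 0.5, 0.25)) +
      ifelse(role == "noise", cfg$noise_mu, cfg$guild_mu_boost)
    lam_hub <- sqrt(cfg$hub_loading)
    lam_par <- sqrt(cfg$within_guild_correlation)
    z <- matrix(rnorm(n_total * cfg$n_otus), n_total, cfg$n_otus)  # unit noise
    for (gid in names(guilds)) {
      g <- guilds[[gid]]
      rows <- blocks[[g$system]]
      f <- rnorm(length(rows))
      for (j in g$hubs)
        z[rows, j] <- lam_hub * f + sqrt(1 - lam_hub^2) * z[rows, j]
      for (j in g$partners)
        z[rows, j] <- lam_par * f + sqrt(1 - lam_par^2) * z[rows, j]
    }
    for (gid in names(bg_guilds)) {
      f <- rnorm(n_total)
      for (j in bg_guilds[[gid]])
        z[, j] <- lam_par * f + sqrt(1 - lam_par^2) * z[, j]
    }
    scale_of <- ifelse(role == "noise", cfg$noise_dispersion, cfg$latent_sd)
    z <- sweep(z, 2, scale_of, `*`)
    z <- sweep(z, 2, mu, `+`)

    # ---- softmax composition + multinomial counts ----------------------
    counts <- matrix(0L, n_total, cfg$n_otus,
                     dimnames = list(sample_ids, otu_ids))
    for (i in seq_len(n_total)) {
      p <- exp(z[i, ] - max(z[i, ]))
      counts[i, ] <- as.integer(rmultinom(1, cfg$reads_per_sample, p / sum(p)))
    }

    # ---- covariates driven by summed hub relative abundance ------------
    all_hubs <- unlist(hubs, use.names = FALSE)
    hub_ra <- if (length(all_hubs) > 0)
      rowSums(counts[, all_hubs, drop = FALSE]) / cfg$reads_per_sample
    else rep(0, n_total)
    v <- if (sd(hub_ra) > 0) as.numeric(scale(hub_ra)) else rep(0, n_total)
    cov_std <- sapply(names(cfg$covariate_effects), function(k)
      cfg$covariate_effects[[k]] * v + rnorm(n_total))
    units <- list(total_P = c(800, 120), olsen_P = c(25, 8), pH = c(6.5, 0.4),
                  bulk_density = c(1.35, 0.12),
                  amf_colonization = c(40, 15), amf_plfa = c(12, 4))
    covars <- sapply(colnames(cov_std), function(k) {
      u <- if (k %in% names(units)) units[[k]] else c(0, 1)
      x <- u[1] + u[2] * cov_std[, k]
      if (k == "amf_colonization") x <- pmin(pmax(x, 0), 100)
      x
    })

    intensity <- cfg$intensity_by_system[sys_of_sample] +
      rnorm(n_total, 0, cfg$intensity_sd)

    metadata <- data.frame(
      sample_id = sample_ids,
      farm = sprintf("F%02d", seq_len(n_total)),
      system = sys_of_sample,
      region = rep_len(c("east", "central", "west"), n_total),
      intensity_index = as.numeric(intensity),
      covars,
      stringsAsFactors = FALSE)
    rownames(metadata) <- sample_ids

    taxonomy <- synth_taxonomy(otu_ids, role)

    # ---- ground truth ---------------------------------------------------
    pair_rows <- list()
    add_pairs <- function(a, b, kind, scope) {
      if (length(a) == 0 || length(b) == 0) return()
      g <- expand.grid(i = a, j = b, stringsAsFactors = FALSE)
      g <- g[g$i < g$j, , drop = FALSE]
      if (nrow(g))
        pair_rows[[length(pair_rows) + 1]] <<- data.frame(
          otu_a = otu_ids[g$i], otu_b = otu_ids[g$j],
          kind = kind, scope = scope, stringsAsFactors = FALSE)
    }
    for (gid in names(guilds)) {
      g <- guilds[[gid]]
      for (h in g$hubs) add_pairs(rep(h, length(g$partners)), g$partners,
                                  "hub_partner", g$system)
      add_pairs(rep(g$hubs, each = length(g$hubs)), rep(g$hubs, length(g$hubs)),
                "hub_hub", g$system)
      add_pairs(rep(g$partners, each = length(g$partners)),
                rep(g$partners, length(g$partners)), "within_guild", g$system)
    }
    for (gid in names(bg_guilds)) {
      m <- bg_guilds[[gid]]
      add_pairs(rep(m, each = length(m)), rep(m, length(m)),
                "within_guild", "global")
    }
    dependent <- if (length(pair_rows)) do.call(rbind, pair_rows) else
      data.frame(otu_a = character(0), otu_b = character(0),
                 kind = character(0), scope = character(0))
    dependent <- unique(dependent)

    truth <- list(
      hub_otus = lapply(hubs, function(ix) otu_ids[ix]),
      guild_membership = setNames(guild_of, otu_ids),
      pairwise_dependent = dependent,
      true_covariate_effects = cfg$covariate_effects,
      role = setNames(role, otu_ids))

    structure(list(otu = counts, taxonomy = taxonomy, metadata = metadata,
                   truth = truth, config = cfg),
              class = "synthetic_study")
  })
}

# deterministic synthetic taxonomy: hubs get mycorrhizal orders, the rest
# cycle through a fixed pool of root-associated fungal orders
synth_taxonomy <- function(otu_ids, role) {
  amf <- data.frame(
    phylum = "Glomeromycota", class = "Glomeromycetes",
    order = c("Glomerales", "Paraglomerales", "Diversisporales"))
  other_orders <- c("Sordariales", "Agaricales", "Cantharellales",
                    "Mortierellales", "Tremellales", "Hypocreales",
                    "Sebacinales", "Malasseziales", "Helotiales",
                    "Pleosporales", "Capnodiales", "Filobasidiales")
  n <- length(otu_ids)
  ord <- character(n)
  hub_ix <- which(role == "hub")
  ord[hub_ix] <- amf$order[((seq_along(hub_ix) - 1) %% 3) + 1]
  rest <- which(role != "hub")
  ord[rest] <- other_orders[((seq_along(rest) - 1) %% length(other_orders)) + 1]
  data.frame(
    otu_id = otu_ids,
    kingdom = "Fungi",
    phylum = ifelse(ord %in% amf$order, "Glomeromycota", "Ascomycota"),
    class = ifelse(ord %in% amf$order, "Glomeromycetes", "Incertae_sedis"),
    order = ord,
    family = paste0(ord, "_fam"),
    genus = "",
    stringsAsFactors = FALSE,
    row.names = otu_ids)
}

#' Write a synthetic study to disk
#'
#' Writes the OTU, taxonomy and metadata tables as tab-separated files and
#' the ground truth as JSON.
#'
#' @param study A `synthetic_study` from [simulate_study()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("otu_table.tsv", "taxonomy.tsv",
                            "metadata.tsv", "truth.json"))
  write_otu_table(study$otu, paths[1])
  write_taxonomy(study$taxonomy, paths[2])
  write_metadata(study$metadata, paths[3])
  jsonlite::write_json(study$truth, paths[4], auto_unbox = TRUE,
                       dataframe = "columns", digits = NA)
  invisible(paths)
}
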