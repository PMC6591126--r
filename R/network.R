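#' Build a co-occurrence network from significant associations
#'
#' Edges are the unordered OTU pairs with `q < alpha`; nodes are the OTUs
#' incident to at least one such edge (isolated OTUs are excluded from the
#' graph).  The graph is undirected and simple.
#'
#' @param assoc An `association_set` with q-values (see [classify_edges()]).
#' @param alpha Significance level on the FDR-adjusted q-values.
#' @param taxonomy Optional taxonomy data frame (row names = OTU ids); the
#'   `order` column is attached as a node attribute, `"Unclassified"` where
#'   missing.
#' @return An `igraph` object with edge attributes `mic`, `r`,
#'   `relationship`, `low_support` and node attribute `order`.
#' @export
build_network <- function(assoc, alpha = 0.05, taxonomy = NULL) {
  stopifnot(inherits(assoc, "association_set"))
  if (is.null(assoc$q)) stop("q-values missing; run classify_edges() first")
  sig <- assoc[assoc$q < alpha, , drop = FALSE]
  if (nrow(sig) == 0) {
    warning("no significant edges; returning an empty network")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  g <- igraph::graph_from_data_frame(
    sig[, c("otu_a", "otu_b", "mic", "r", "relationship", "low_support")],
    directed = FALSE)
  g <- igraph::simplify(g, edge.attr.comb = "first")
  ord <- rep("Unclassified", igraph::vcount(g))
  if (!is.null(taxonomy)) {
    m <- taxonomy$order[match(igraph::V(g)$name, rownames(taxonomy))]
    ord <- ifelse(is.na(m) | m == "", "Unclassified", m)
  }
  igraph::V(g)$order <- ord
  g
}

#' Per-node centralities
#'
#' Degree, closeness, betweenness and local clustering coefficient.
#' Closeness is the reciprocal of the mean shortest-path length to the
#' other nodes of the node's connected component; betweenness is the
#' fraction of all shortest paths within the component that pass through
#' the node, normalised by `(N - 1)(N - 2) / 2` with `N` the component
#' size; local clustering is `2 e / (k (k - 1))` over the node's
#' neighbourhood for degree `k >= 2`, else 0.
#'
#' @param net An `igraph` network.
#' @return Data frame with columns `otu`, `degree`, `closeness`,
#'   `betweenness`, `local_clustering`, `component`.
#' @export
node_centralities <- function(net) {
  if (igraph::vcount(net) == 0) stop("empty network")
  comp <- igraph::components(net)
  out <- data.frame(otu = igraph::V(net)$name,
                    degree = as.integer(igraph::degree(net)),
                    closeness = NA_real_, betweenness = NA_real_,
                    local_clustering = 0, component = comp$membership,
                    stringsAsFactors = FALSE)
  lc <- igraph::transitivity(net, type = "localundirected", isolates = "zero")
  out$local_clustering <- ifelse(is.nan(lc), 0, lc)
  for (ci in seq_len(comp$no)) {
    vs <- which(comp$membership == ci)
    sub <- igraph::induced_subgraph(net, vs)
    n <- length(vs)
    if (n == 1) {
      out$closeness[vs] <- NA_real_
      out$betweenness[vs] <- 0
      next
    }
    d <- igraph::distances(sub)
    out$closeness[vs] <- (n - 1) / rowSums(d)
    btw <- igraph::betweenness(sub, directed = FALSE)
    denom <- if (n > 2) (n - 1) * (n - 2) / 2 else 1
    out$betweenness[vs] <- btw / denom
  }
  rownames(out) <- out$otu
  out
}

#' Whole-network topology summary
#'
#' Diameter and mean shortest path are computed over connected node pairs
#' (disconnection is ignored, as in NetworkAnalyzer on fragmented graphs);
#' the clustering coefficient averages local clustering over all nodes
#' with degree-below-2 nodes contributing 0; `avg_neighbors` is the mean
#' degree.  A power-law fit to the degree distribution is included when
#' defined.
#'
#' @param net An `igraph` network.
#' @return A list of class `topology_summary`.
#' @export
topology_summary <- function(net) {
  n <- igraph::vcount(net)
  if (n == 0)
    return(structure(list(n_nodes = 0, n_edges = 0, diameter = NA,
                          avg_neighbors = NA, clustering_coefficient = NA,
                          mean_shortest_path = NA, powerlaw_gamma = NA,
                          powerlaw_r2 = NA), class = "topology_summary"))
  d <- igraph::distances(net)
  finite <- d[upper.tri(d)][is.finite(d[upper.tri(d)])]
  attrs <- node_centralities(net)
  pl <- powerlaw_fit(attrs$degree)
  structure(list(
    n_nodes = n,
    n_edges = igraph::ecount(net),
    diameter = if (length(finite)) max(finite) else NA,
    avg_neighbors = mean(attrs$degree),
    clustering_coefficient = mean(attrs$local_clustering),
    mean_shortest_path = if (length(finite)) mean(finite) else NA,
    powerlaw_gamma = pl[["gamma"]],
    powerlaw_r2 = pl[["r2"]]), class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat("Network topology\n")
  cat(sprintf("  nodes: %d  edges: %d\n", x$n_nodes, x$n_edges))
  cat(sprintf("  diameter: %s  mean shortest path: %s\n",
              format(x$diameter), format(round_or_na(x$mean_shortest_path))))
  cat(sprintf("  avg neighbors: %s  clustering coefficient: %s\n",
              format(round_or_na(x$avg_neighbors)),
              format(round_or_na(x$clustering_coefficient))))
  if (!is.na(x$powerlaw_gamma))
    cat(sprintf("  power-law fit: gamma = %.2f (R2 = %.2f)\n",
                x$powerlaw_gamma, x$powerlaw_r2))
  invisible(x)
}

round_or_na <- function(x, digits = 3) if (is.na(x)) NA else round(x, digits)

#' Power-law fit to a degree distribution
#'
#' Least-squares fit of `log P(k)` against `log k` over observed degrees
#' `k >= 1` (the NetworkAnalyzer convention), returning the exponent
#' `gamma` (so `P(k) ~ k^-gamma`) and the fit R-squared.  Undefined (NA)
#' with fewer than 3 distinct positive degrees.
#'
#' @param degree_sequence Integer vector of node degrees.
#' @return Named vector `c(gamma, r2)`.
#' @export
powerlaw_fit <- function(degree_sequence) {
  k <- degree_sequence[degree_sequence >= 1]
  tab <- table(k)
  if (length(tab) < 3) return(c(gamma = NA_real_, r2 = NA_real_))
  kk <- as.numeric(names(tab))
  pk <- as.numeric(tab) / length(k)
  fit <- lm(log(pk) ~ log(kk))
  c(gamma = -unname(coef(fit)[2]),
    r2 = summary(fit)$r.squared)
}

#' Barabasi-Albert preferential-attachment graph
#'
#' Starts from a complete seed graph on `m_attach + 1` nodes; each new
#' node attaches `m_attach` edges to distinct existing nodes with
#' probability proportional to their current degree (no multi-edges).
#' The edge count is therefore exactly
#' `choose(m_attach + 1, 2) + (n_nodes - m_attach - 1) * m_attach`.
#'
#' @param n_nodes Total number of nodes.
#' @param m_attach Edges added per new node; `1 <= m_attach < n_nodes`.
#' @param seed Integer seed.
#' @return An `igraph` object.
#' @export
barabasi_albert <- function(n_nodes, m_attach, seed = 1L) {
  if (m_attach < 1 || m_attach >= n_nodes)
    stop("m_attach must satisfy 1 <= m_attach < n_nodes")
  withr_seed(seed, {
    deg <- integer(n_nodes)
    seed_n <- m_attach + 1
    edges <- combn(seq_len(seed_n), 2)
    deg[seq_len(seed_n)] <- seed_n - 1
    el <- vector("list", n_nodes)
    el[[1]] <- edges
    for (v in (seed_n + 1):n_nodes) {
      if (v > n_nodes) break
      existing <- seq_len(v - 1)
      targets <- sample(existing, m_attach, prob = deg[existing])
      # degree-proportional draws without replacement
      el[[v]] <- rbind(rep(v, m_attach), targets)
      deg[targets] <- deg[targets] + 1
      deg[v] <- m_attach
    }
    g <- igraph::make_empty_graph(n_nodes, directed = FALSE)
    igraph::add_edges(g, unlist(el))
  })
}

#' Compare a network to degree-matched random models
#'
#' Generates `n_rand` Barabasi-Albert graphs (with `m` chosen as
#' `max(1, round(E/N))` so the edge count approximately matches) and
#' `n_rand` Erdos-Renyi G(n, m) graphs with equal node and edge counts,
#' and reports where the observed clustering coefficient and mean shortest
#' path fall within each null distribution.
#'
#' @param net An `igraph` network.
#' @param n_rand Number of random graphs per model (> 0).
#' @param seed Integer seed.
#' @return A list with the observed values, the null samples, and the
#'   observed percentile within each null.
#' @export
compare_to_random <- function(net, n_rand = 100, seed = 1L) {
  if (igraph::vcount(net) == 0) stop("empty network")
  if (n_rand <= 0) stop("n_rand must be positive")
  n <- igraph::vcount(net)
  e <- igraph::ecount(net)
  m <- max(1, round(e / n))
  obs <- topology_summary(net)
  withr_seed(seed, {
    ba <- lapply(seq_len(n_rand), function(i)
      barabasi_albert(n, m, seed = sample.int(.Machine$integer.max, 1)))
    er <- lapply(seq_len(n_rand), function(i)
      igraph::sample_gnm(n, e))
    null_stats <- function(gs) {
      cc <- vapply(gs, function(g) {
        lc <- igraph::transitivity(g, type = "localundirected",
                                   isolates = "zero")
        mean(ifelse(is.nan(lc), 0, lc))
      }, numeric(1))
      sp <- vapply(gs, function(g) igraph::mean_distance(g), numeric(1))
      list(clustering = cc, mean_path = sp)
    }
    ba_null <- null_stats(ba)
    er_null <- null_stats(er)
    pct <- function(x, null) mean(null <= x)
    list(observed = list(clustering = obs$clustering_coefficient,
                         mean_path = obs$mean_shortest_path),
         ba_null = ba_null, er_null = er_null,
         percentile = list(
           clustering_ba = pct(obs$clustering_coefficient,
                               ba_null$clustering),
           clustering_er = pct(obs$clustering_coefficient,
                               er_null$clustering),
           mean_path_ba = pct(obs$mean_shortest_path, ba_null$mean_path),
           mean_path_er = pct(obs$mean_shortest_path, er_null$mean_path)))
  })
}

#' Export a network as GraphML or SIF
#'
#' @param net An `igraph` network.
#' @param path Output file.
#' @param format `"graphml"` or `"sif"` (Cytoscape simple interaction
#'   format; the relationship class is used as the interaction type).
#' @export
write_network <- function(net, path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(net)
    rel <- igraph::E(net)$relationship
    if (is.null(rel)) rel <- rep("assoc", nrow(el))
    writeLines(paste(el[, 1], rel, el[, 2], sep = "\t"), path)
  }
  invisible(path)
}
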