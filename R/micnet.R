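#' Fit a MIC co-occurrence network to an OTU table
#'
#' The package's central model fit: scores every unordered OTU pair with
#' the maximal information coefficient, attaches permutation p-values from
#' a shared null, adjusts them by Benjamini-Hochberg, keeps the pairs
#' significant at `alpha` as edges, and computes per-node centralities and
#' whole-network topology.
#'
#' @param table OTU count table, samples x OTUs (normally rarefied and
#'   prevalence-filtered).
#' @param taxonomy Optional taxonomy data frame (row names = OTU ids).
#' @param cfg A [mic_config()]; `cfg$alpha` is the edge-calling level.
#' @param keystone A [keystone_criteria()] or `NULL` to skip keystone
#'   selection.
#' @return An object of class `micnet`: a list with `assoc`
#'   (the classified association set), `network` (igraph), `nodes`
#'   (centralities), `topology`, `keystones` and `call`.
#' @examples
#' study <- simulate_study(sim_config(seed = 1))
#' org <- study$otu[study$metadata$system == "organic", ]
#' fit <- micnet(prevalence_filter(org), study$taxonomy,
#'               cfg = mic_config(n_permutations = 999, seed = 1))
#' print(fit)
#' @export
micnet <- function(table, taxonomy = NULL, cfg = mic_config(),
                   keystone = keystone_criteria()) {
  assoc <- associations(table, cfg)
  net <- suppressWarnings(build_network(assoc, cfg$alpha, taxonomy))
  empty <- igraph::vcount(net) == 0
  nodes <- if (empty) NULL else node_centralities(net)
  topo <- topology_summary(net)
  ks <- if (empty || is.null(keystone)) NULL else
    select_keystones(nodes, keystone, taxonomy)
  structure(list(assoc = assoc, network = net, nodes = nodes,
                 topology = topo, keystones = ks, cfg = cfg,
                 n_samples = nrow(table), call = match.call()),
            class = "micnet")
}

#' @export
print.micnet <- function(x, ...) {
  cat("MIC co-occurrence network fit\n")
  cat(sprintf("  %d samples, %d OTUs scored (%d pairs)\n", x$n_samples,
              ceiling((1 + sqrt(1 + 8 * nrow(x$assoc))) / 2), nrow(x$assoc)))
  cat(sprintf("  edges at q < %.3g: %d on %d nodes\n", x$cfg$alpha,
              x$topology$n_edges, x$topology$n_nodes))
  if (!is.null(x$keystones))
    cat(sprintf("  keystone taxa: %d\n", nrow(x$keystones)))
  invisible(x)
}

#' @export
summary.micnet <- function(object, ...) {
  rel <- table(object$assoc$relationship[!is.na(object$assoc$relationship)])
  out <- list(topology = object$topology, relationships = rel,
              keystones = object$keystones,
              null_quantiles = quantile(attr(object$assoc, "null_mic"),
                                        c(0.5, 0.95, 0.99, 0.999)))
  class(out) <- "summary.micnet"
  out
}

#' @export
print.summary.micnet <- function(x, ...) {
  print(x$topology)
  cat("edge relationships:\n")
  print(x$relationships)
  cat("shared null MIC quantiles:\n")
  print(round(x$null_quantiles, 3))
  if (!is.null(x$keystones) && nrow(x$keystones)) {
    cat("keystone taxa:\n")
    print(x$keystones[, c("otu", "degree", "closeness", "betweenness",
                          "order")], row.names = FALSE)
  }
  invisible(x)
}

#' Plot a fitted co-occurrence network
#'
#' Left panel: the network with keystone taxa emphasised; right panel: the
#' degree distribution on log-log axes with the power-law fit.
#'
#' @param x A `micnet` object.
#' @param ... Passed to `igraph::plot.igraph`.
#' @export
plot.micnet <- function(x, ...) {
  if (igraph::vcount(x$network) == 0) {
    warning("empty network; nothing to plot")
    return(invisible(x))
  }
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  ks <- if (is.null(x$keystones)) character(0) else x$keystones$otu
  vcol <- ifelse(igraph::V(x$network)$name %in% ks, "tomato", "steelblue")
  vsz <- ifelse(igraph::V(x$network)$name %in% ks, 6, 3)
  plot(x$network, vertex.label = NA, vertex.color = vcol,
       vertex.size = vsz, main = "co-occurrence network", ...)
  deg <- x$nodes$degree
  tab <- table(deg[deg >= 1])
  plot(as.numeric(names(tab)), as.numeric(tab) / sum(tab), log = "xy",
       xlab = "degree k", ylab = "P(k)", main = "degree distribution",
       pch = 19)
  pl <- powerlaw_fit(deg)
  if (!is.na(pl[["gamma"]])) {
    kk <- as.numeric(names(tab))
    lines(kk, kk^(-pl[["gamma"]]) *
            exp(mean(log(as.numeric(tab) / sum(tab)) +
                     pl[["gamma"]] * log(kk))), lty = 2)
  }
  invisible(x)
}
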