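#' Keystone selection criteria
#'
#' Either joint centrality thresholds (`mode = "threshold"`: all three
#' inequalities strict) or the intersection of the top-`k` nodes on each
#' attribute (`mode = "top_k"`, ties broken by OTU id).  The per-system
#' defaults follow the convention of requiring degree above 10, closeness
#' above 0.28 and betweenness below 0.18; an overall-network variant uses
#' 50 / 0.44 / 0.12.
#'
#' @param mode `"threshold"` or `"top_k"`.
#' @param min_degree,min_closeness,max_betweenness Threshold-mode cut-offs.
#' @param k Top-k mode rank depth.
#' @return An object of class `keystone_criteria`.
#' @export
keystone_criteria <- function(mode = c("threshold", "top_k"),
                              min_degree = 10, min_closeness = 0.28,
                              max_betweenness = 0.18, k = 10) {
  mode <- match.arg(mode)
  stopifnot(min_degree > 0, min_closeness > 0, max_betweenness > 0, k > 0)
  structure(list(mode = mode, min_degree = min_degree,
                 min_closeness = min_closeness,
                 max_betweenness = max_betweenness, k = as.integer(k)),
            class = "keystone_criteria")
}

#' Select keystone taxa
#'
#' Keystones are nodes with jointly high degree, high closeness and low
#' betweenness.  In threshold mode a node qualifies iff
#' `degree > min_degree` and `closeness > min_closeness` and
#' `betweenness < max_betweenness`; in top-k mode it must lie in the
#' intersection of the `k` best-ranked nodes on all three attributes.
#'
#' @param attrs Node attribute table from [node_centralities()].
#' @param criteria A [keystone_criteria()].
#' @param taxonomy Optional taxonomy (row names = OTU ids) for order
#'   annotation of the report.
#' @return A `keystone_report`: data frame of keystone OTUs with their
#'   centralities and taxonomic order, plus attribute `order_counts`.
#' @export
select_keystones <- function(attrs, criteria = keystone_criteria(),
                             taxonomy = NULL) {
  stopifnot(inherits(criteria, "keystone_criteria"))
  if (nrow(attrs) == 0) {
    rep <- attrs
  } else if (criteria$mode == "threshold") {
    rep <- attrs[attrs$degree > criteria$min_degree &
                 attrs$closeness > criteria$min_closeness &
                 attrs$betweenness < criteria$max_betweenness &
                 !is.na(attrs$closeness), , drop = FALSE]
  } else {
    topk <- function(v, decreasing) {
      o <- order(v, attrs$otu, decreasing = c(decreasing, FALSE),
                 method = "radix")
      attrs$otu[o][seq_len(min(criteria$k, length(o)))]
    }
    sel <- Reduce(intersect, list(topk(attrs$degree, TRUE),
                                  topk(attrs$closeness, TRUE),
                                  topk(attrs$betweenness, FALSE)))
    rep <- attrs[attrs$otu %in% sel, , drop = FALSE]
  }
  if (!is.null(taxonomy) && nrow(rep) > 0) {
    m <- taxonomy$order[match(rep$otu, rownames(taxonomy))]
    rep$order <- ifelse(is.na(m) | m == "", "Unclassified", m)
  } else if (nrow(rep) > 0) {
    rep$order <- "Unclassified"
  }
  oc <- if (nrow(rep)) table(rep$order) else table(character(0))
  structure(rep, order_counts = oc, criteria = criteria,
            class = c("keystone_report", "data.frame"))
}

#' Proportional influence of taxonomic orders
#'
#' For each order present in the network, the ratio between the number of
#' edges incident to at least one node of that order (`E_order`) and the
#' number of nodes of that order (`N_order`).  The default orientation is
#' `E/N` (connections per member node, higher = more influential); the
#' literal `N/E` orientation is available with `orientation = "n_over_e"`.
#' Orders whose nodes have no edges score 0.
#'
#' @param net An `igraph` network with a node attribute `order` (see
#'   [build_network()]).
#' @param taxonomy Optional taxonomy used if the attribute is missing.
#' @param orientation `"e_over_n"` (default) or `"n_over_e"`.
#' @return Named numeric vector, one value per order.
#' @export
proportional_influence <- function(net, taxonomy = NULL,
                                   orientation = c("e_over_n", "n_over_e")) {
  orientation <- match.arg(orientation)
  if (igraph::vcount(net) == 0) return(setNames(numeric(0), character(0)))
  ord <- igraph::V(net)$order
  if (is.null(ord)) {
    ord <- rep("Unclassified", igraph::vcount(net))
    if (!is.null(taxonomy)) {
      m <- taxonomy$order[match(igraph::V(net)$name, rownames(taxonomy))]
      ord <- ifelse(is.na(m) | m == "", "Unclassified", m)
    }
  }
  el <- igraph::as_edgelist(net, names = FALSE)
  orders <- sort(unique(ord))
  vapply(setNames(orders, orders), function(o) {
    nodes <- which(ord == o)
    n_o <- length(nodes)
    e_o <- sum(el[, 1] %in% nodes | el[, 2] %in% nodes)
    if (e_o == 0) return(0)
    if (orientation == "e_over_n") e_o / n_o else n_o / e_o
  }, numeric(1))
}

#' Remove keystone taxa and summarise the remaining network
#'
#' Deletes the keystone nodes, recomputes the full topology summary on the
#' induced subgraph, and reports the change in edge count and clustering
#' coefficient.
#'
#' @param net An `igraph` network.
#' @param keystones Character vector of keystone OTU ids (must be a subset
#'   of the network's nodes).
#' @return A list with `summary` (the reduced network's
#'   [topology_summary()]), `delta_edges`, `delta_clustering`, and the
#'   reduced graph itself as `network`.
#' @export
remove_keystones_and_summarize <- function(net, keystones) {
  if (!all(keystones %in% igraph::V(net)$name))
    stop("keystones must be a subset of network nodes")
  before <- topology_summary(net)
  sub <- igraph::delete_vertices(net, keystones)
  # drop nodes isolated by the removal, mirroring network construction
  sub <- igraph::delete_vertices(sub, which(igraph::degree(sub) == 0))
  if (igraph::vcount(sub) == 0) {
    warning("keystone removal emptied the network")
    after <- topology_summary(sub)
  } else {
    after <- topology_summary(sub)
  }
  list(summary = after,
       delta_edges = after$n_edges - before$n_edges,
       delta_clustering = if (is.na(after$clustering_coefficient)) NA else
         after$clustering_coefficient - before$clustering_coefficient,
       network = sub)
}
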