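#' Bootstrap a node attribute
#'
#' `n_iter` resamples with replacement of the full attribute vector, with
#' a mean and percentile confidence interval.
#'
#' @param values Numeric vector (e.g. node degrees).
#' @param n_iter Bootstrap iterations (default 10000).
#' @param seed Integer seed.
#' @param conf Confidence level for the percentile interval.
#' @return List with `means` (the bootstrap distribution of the mean),
#'   `mean`, `ci` and `n_iter`.
#' @export
bootstrap_attribute <- function(values, n_iter = 10000, seed = 1L,
                                conf = 0.95) {
  if (length(values) == 0) stop("empty attribute vector")
  withr_seed(seed, {
    n <- length(values)
    means <- vapply(seq_len(n_iter),
                    function(i) mean(values[sample.int(n, n, replace = TRUE)]),
                    numeric(1))
    a <- (1 - conf) / 2
    list(means = means, mean = mean(means),
         ci = quantile(means, c(a, 1 - a), names = FALSE), n_iter = n_iter)
  })
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |F_a - F_b|` with the asymptotic p-value from the Kolmogorov
#' distribution at effective size `n_a n_b / (n_a + n_b)`.
#'
#' @param a,b Numeric vectors.
#' @return List of class `ks_result` with `d_statistic`, `p_value`, `n_a`,
#'   `n_b`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("both samples must be non-empty")
  kt <- suppressWarnings(ks.test(a, b, exact = FALSE))
  structure(list(d_statistic = unname(kt$statistic),
                 p_value = kt$p.value,
                 n_a = length(a), n_b = length(b)),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("two-sample KS: D = %.4f, p = %.4g (n = %d, %d)\n",
              x$d_statistic, x$p_value, x$n_a, x$n_b))
  invisible(x)
}

#' Compare node attributes between two networks
#'
#' KS tests on degree, closeness and betweenness.  By default the raw
#' per-node attribute vectors are compared; `bootstrap = TRUE` reproduces
#' the bootstrap-then-KS variant (note that bootstrapping inflates the
#' effective sample size and deflates p-values; the raw comparison is the
#' statistically conservative default).
#'
#' @param attrs_a,attrs_b Node attribute tables from [node_centralities()].
#' @param bootstrap Compare bootstrap distributions of the attributes
#'   instead of the raw vectors.
#' @param n_iter Bootstrap iterations when `bootstrap = TRUE`.
#' @param seed Integer seed.
#' @return Data frame with one row per attribute: `attribute`,
#'   `d_statistic`, `p_value`.
#' @export
compare_node_attributes <- function(attrs_a, attrs_b, bootstrap = FALSE,
                                    n_iter = 10000, seed = 1L) {
  out <- lapply(c("degree", "closeness", "betweenness"), function(at) {
    a <- attrs_a[[at]]; b <- attrs_b[[at]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (bootstrap) {
      a <- bootstrap_attribute(a, n_iter, seed)$means
      b <- bootstrap_attribute(b, n_iter, seed + 1)$means
    }
    ks <- ks_two_sample(a, b)
    data.frame(attribute = at, d_statistic = ks$d_statistic,
               p_value = ks$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-farm subgraph connectivity
#'
#' For each farm (sample), the induced subgraph of the network on the OTUs
#' with nonzero counts in that farm; connectivity is the mean node degree
#' within that subgraph (0 for farms containing no networked OTUs or no
#' edges).
#'
#' @param net An `igraph` network (normally the farm's group network).
#' @param table Rarefied OTU count table containing the farm's sample row.
#' @param metadata Sample metadata with `farm`, `system` and
#'   `intensity_index` columns (row names = sample ids).
#' @param farms Optional subset of farm ids; defaults to all farms whose
#'   samples appear in `table`.
#' @return Data frame with columns `farm`, `system`, `intensity_index`,
#'   `n_nodes`, `mean_degree`.
#' @export
farm_subgraph_connectivity <- function(net, table, metadata, farms = NULL) {
  m <- as_count_matrix(table, allow_numeric = TRUE)
  meta <- metadata[rownames(m), , drop = FALSE]
  if (anyNA(meta$farm)) stop("farm(s) missing from metadata")
  if (is.null(farms)) farms <- unique(meta$farm)
  if (!all(farms %in% meta$farm))
    stop("farm(s) absent from metadata: ",
         paste(setdiff(farms, meta$farm), collapse = ", "))
  nodes <- if (igraph::vcount(net)) igraph::V(net)$name else character(0)
  out <- lapply(farms, function(f) {
    rows <- which(meta$farm == f)
    present <- colnames(m)[colSums(m[rows, , drop = FALSE]) > 0]
    keep <- intersect(nodes, present)
    md <- if (length(keep) == 0) 0 else {
      sub <- igraph::induced_subgraph(net, keep)
      if (igraph::ecount(sub) == 0) 0 else mean(igraph::degree(sub))
    }
    data.frame(farm = f, system = meta$system[rows[1]],
               intensity_index = meta$intensity_index[rows[1]],
               n_nodes = length(keep), mean_degree = md,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Regress farm connectivity on agricultural intensity
#'
#' Ordinary least squares of per-farm mean degree on the intensity index.
#'
#' @param conn Output of [farm_subgraph_connectivity()] (possibly pooled
#'   over systems).
#' @return List with `slope`, `r_squared`, `p_value`, `n` and the fitted
#'   `lm` object.
#' @export
connectivity_vs_intensity <- function(conn) {
  ok <- is.finite(conn$mean_degree) & is.finite(conn$intensity_index)
  d <- conn[ok, , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 farms with finite values")
  if (sd(d$intensity_index) == 0) stop("intensity index has zero variance")
  fit <- lm(mean_degree ~ intensity_index, data = d)
  s <- summary(fit)
  list(slope = unname(coef(fit)[2]),
       r_squared = s$r.squared,
       p_value = s$coefficients[2, 4],
       n = nrow(d), fit = fit)
}
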