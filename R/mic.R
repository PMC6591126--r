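#' MIC engine configuration
#'
#' Settings for maximal-information-coefficient association inference.
#'
#' @param b_exponent Grid-resolution exponent: grids (kx, ky) are searched
#'   subject to `kx * ky <= B(n) = max(floor(n^b_exponent), 4)`.  The
#'   conventional MINE default is 0.6.
#' @param max_clumps_factor Cap on the number of candidate column clumps
#'   considered by the dynamic program, as a multiple of the column budget;
#'   only triggers (as a documented approximation) for large sample sizes.
#' @param n_permutations Size of the shared permutation null used for edge
#'   p-values.  Must be at least 99.
#' @param alpha FDR level used when calling edges.
#' @param tau Nonlinearity threshold: a significant pair is classed
#'   `nonlinear` when `mic - r^2 > tau`, otherwise `positive`/`negative` by
#'   the sign of the Pearson correlation.
#' @param min_nonzero Pairs in which either OTU has fewer nonzero samples
#'   than this are flagged `low_support` (still scored).
#' @param seed Integer seed driving the permutation null.
#' @return An object of class `mic_config` (a named list).
#' @export
mic_config <- function(b_exponent = 0.6, max_clumps_factor = 15,
                       n_permutations = 99999, alpha = 0.05, tau = 0.2,
                       min_nonzero = 4, seed = 1L) {
  stopifnot(b_exponent > 0, b_exponent < 1, max_clumps_factor >= 1,
            alpha > 0, alpha < 1, tau >= 0)
  if (n_permutations < 99)
    stop("n_permutations must be at least 99")
  structure(list(b_exponent = b_exponent,
                 max_clumps_factor = as.integer(max_clumps_factor),
                 n_permutations = as.integer(n_permutations),
                 alpha = alpha, tau = tau,
                 min_nonzero = as.integer(min_nonzero),
                 seed = as.integer(seed)),
            class = "mic_config")
}

#' Maximal information coefficient of two vectors
#'
#' Computes the MIC characteristic matrix: for every grid (kx, ky) with
#' `kx * ky <= B(n)` and both at least 2, one axis is equipartitioned by
#' rank (tied values are never split across bins) and the other is cut by a
#' dynamic program maximising mutual information; the entry is
#' `I* / log2(min(kx, ky))` and MIC is the maximum over the matrix and both
#' axis orientations.  MIC is 1 on any noiseless monotone relationship and
#' is exactly invariant under strictly increasing transforms of either
#' variable, since only rank order enters the binning.
#'
#' @param x,y Numeric vectors of equal length `n >= 8`, each with at least
#'   two distinct values.
#' @param cfg A [mic_config()].
#' @return A list with elements `mic` (scalar in `[0, 1]`), `matrix` (the
#'   characteristic matrix, `NA` outside the searched grid region), and `B`
#'   (the grid bound used).
#' @export
mic_score <- function(x, y, cfg = mic_config()) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 8) stop("MIC requires at least 8 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("association with a constant vector is undefined")
  res <- mic_cpp(x, y, cfg$b_exponent, cfg$max_clumps_factor)
  # rows/columns are indexed by bin count (0 and 1 never hold values)
  dimnames(res$matrix) <- list(kx = 0:(nrow(res$matrix) - 1),
                               ky = 0:(ncol(res$matrix) - 1))
  res
}

#' Pairwise MIC scores for an OTU table
#'
#' Scores every unordered OTU pair on per-sample abundances.  Also records
#' the Pearson correlation (used later for relationship classification) and
#' a low-support flag for zero-heavy OTUs.
#'
#' @param table OTU count table, samples x OTUs (matrix or data frame with
#'   sample rows and OTU columns).
#' @param cfg A [mic_config()].
#' @return An `association_set`: a data frame with one row per unordered
#'   pair and columns `otu_a`, `otu_b`, `mic`, `r`, `low_support`.
#' @export
mic_matrix <- function(table, cfg = mic_config()) {
  m <- as_count_matrix(table, allow_numeric = TRUE)
  if (ncol(m) < 2) stop("at least 2 OTUs are required")
  if (nrow(m) < 8) stop("MIC requires at least 8 samples")
  const <- apply(m, 2, function(v) length(unique(v)) < 2)
  if (any(const))
    stop("constant OTU columns: ", paste(colnames(m)[const], collapse = ", "))
  mic <- mic_pairs_cpp(m, cfg$b_exponent, cfg$max_clumps_factor)
  pr <- cor(m)
  idx <- which(upper.tri(pr), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  nz <- colSums(m != 0)
  out <- data.frame(
    otu_a = colnames(m)[idx[, 1]],
    otu_b = colnames(m)[idx[, 2]],
    mic = mic,
    r = pr[idx],
    low_support = nz[idx[, 1]] < cfg$min_nonzero |
      nz[idx[, 2]] < cfg$min_nonzero,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_samples") <- nrow(m)
  class(out) <- c("association_set", "data.frame")
  out
}

#' Shared permutation null for MIC scores
#'
#' Builds one null MIC distribution for the table's sample size by scoring
#' `n_permutations` independently shuffled column pairs drawn from the table
#' itself (so the null reflects the tables' marginal tie structure), then
#' assigns each observed pair `p = (1 + #(null >= observed)) /
#' (1 + n_permutations)`.
#'
#' @param assoc An `association_set` from [mic_matrix()].
#' @param table The same OTU table the scores were computed from.
#' @param cfg A [mic_config()].
#' @return `assoc` with a `p` column added (and the null distribution in
#'   attribute `null_mic`).
#' @export
permutation_pvalues <- function(assoc, table, cfg = mic_config()) {
  stopifnot(inherits(assoc, "association_set"))
  if (cfg$n_permutations < 99) stop("n_permutations must be at least 99")
  m <- as_count_matrix(table, allow_numeric = TRUE)
  null <- mic_null_distribution(m, cfg)
  assoc$p <- p_from_null(assoc$mic, null)
  attr(assoc, "null_mic") <- null
  assoc
}

mic_null_distribution <- function(m, cfg) {
  n <- nrow(m); p <- ncol(m)
  withr_seed(cfg$seed, {
    cols <- cbind(sample.int(p, cfg$n_permutations, replace = TRUE),
                  sample.int(p, cfg$n_permutations, replace = TRUE))
    perms <- t(replicate(cfg$n_permutations, sample.int(n)))
    mic_null_cpp(m, cols, perms, cfg$b_exponent, cfg$max_clumps_factor)
  })
}

p_from_null <- function(obs, null) {
  # right-tail permutation p with +1 correction, vectorised over obs
  s <- sort(null)
  n_ge <- length(null) - findInterval(obs, s, left.open = TRUE)
  (1 + n_ge) / (1 + length(null))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment `q_(i) = min_(j >= i) p_(j) * m / j`, capped at 1,
#' returned in the original order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  p.adjust(p, method = "BH")
}

#' Classify significant associations
#'
#' Adds `q` (BH-adjusted p) and, for pairs with `q < alpha`, a relationship
#' class: `nonlinear` when `mic - r^2 > tau` (or the correlation is
#' undefined), otherwise `positive` / `negative` by the sign of `r`.
#' Non-significant pairs get `NA`.
#'
#' @param assoc An `association_set` with a `p` column.
#' @param cfg A [mic_config()].
#' @return `assoc` with `q` and `relationship` columns.
#' @export
classify_edges <- function(assoc, cfg = mic_config()) {
  stopifnot(inherits(assoc, "association_set"), !is.null(assoc$p))
  assoc$q <- bh_fdr(assoc$p)
  rel <- rep(NA_character_, nrow(assoc))
  sig <- assoc$q < cfg$alpha
  nl <- is.na(assoc$r) | (assoc$mic - ifelse(is.na(assoc$r), 0,
                                             assoc$r^2) > cfg$tau)
  rel[sig & nl] <- "nonlinear"
  rel[sig & !nl & assoc$r > 0] <- "positive"
  rel[sig & !nl & assoc$r <= 0] <- "negative"
  assoc$relationship <- rel
  assoc
}

#' Score, test and classify all OTU pairs
#'
#' Convenience composition of [mic_matrix()], [permutation_pvalues()] and
#' [classify_edges()].
#'
#' @inheritParams mic_matrix
#' @return A complete `association_set` with `mic`, `r`, `p`, `q`,
#'   `relationship` and `low_support` columns.
#' @export
associations <- function(table, cfg = mic_config()) {
  assoc <- mic_matrix(table, cfg)
  assoc <- permutation_pvalues(assoc, table, cfg)
  classify_edges(assoc, cfg)
}

# evaluate expr with a local RNG state seeded by `seed`
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
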