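#' Alpha diversity indices
#'
#' Per-sample OTU richness, Shannon-Weaver index (natural log) and Sheldon
#' evenness `exp(H) / S`.  Pielou's `H / ln(S)` is available with
#' `evenness = "pielou"`.
#'
#' @param table OTU count table (normally rarefied), samples x OTUs.
#' @param evenness `"sheldon"` (default) or `"pielou"`.
#' @return Data frame with columns `sample`, `richness`, `shannon`,
#'   `evenness`.
#' @export
alpha_diversity <- function(table, evenness = c("sheldon", "pielou")) {
  evenness <- match.arg(evenness)
  m <- as_count_matrix(table)
  if (any(rowSums(m) == 0))
    stop("empty sample(s): ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  rich <- rowSums(m > 0)
  h <- apply(m, 1, function(x) {
    p <- x[x > 0] / sum(x)
    -sum(p * log(p))
  })
  ev <- switch(evenness,
               sheldon = exp(h) / rich,
               pielou = ifelse(rich > 1, h / log(rich), 1))
  data.frame(sample = rownames(m), richness = as.integer(rich),
             shannon = h, evenness = ev, row.names = rownames(m),
             stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity
#'
#' `d(a, b) = sum |x_ai - x_bi| / sum (x_ai + x_bi)`, in `[0, 1]` with 0 on
#' identical rows and 1 on disjoint rows.
#'
#' @param table OTU count table, samples x OTUs.
#' @return A `dist` object over samples.
#' @export
bray_curtis <- function(table) {
  m <- as_count_matrix(table, allow_numeric = TRUE)
  vegan::vegdist(m, method = "bray")
}

#' One-way PERMANOVA
#'
#' Permutational multivariate analysis of variance on a distance matrix:
#' pseudo-F from the partition of squared inter-point distances into
#' between- and within-group components, with an unrestricted permutation
#' of group labels; `p = (1 + #(permuted F >= observed)) / (1 + n_perm)`.
#'
#' @param dist A `dist` object (e.g. from [bray_curtis()]).
#' @param groups Group labels, one per sample.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return A list of class `perm_test` with `statistic` (pseudo-F),
#'   `p_value`, `n_permutations` and `explained_variation` (percent,
#'   `100 * SS_between / SS_total`).
#' @export
permanova <- function(dist, groups, n_perm = 999, seed = 1L) {
  groups <- check_groups(dist, groups)
  df <- data.frame(g = groups)
  # explicit permutation matrix keeps the p-value contract
  # p = (1 + #(F* >= F)) / (1 + n_perm) at every sample size
  fit <- withr_seed(seed, {
    n <- length(groups)
    pm <- t(replicate(n_perm, sample.int(n)))
    vegan::adonis2(dist ~ g, data = df, permutations = pm)
  })
  structure(list(statistic = fit$F[1], p_value = fit$`Pr(>F)`[1],
                 n_permutations = n_perm,
                 explained_variation = 100 * fit$R2[1],
                 method = "PERMANOVA"),
            class = "perm_test")
}

#' PERMDISP: homogeneity of multivariate dispersions
#'
#' Embeds the samples by principal-coordinates analysis (negative
#' eigenvalues handled by the standard imaginary-part correction), measures
#' each sample's distance to its group spatial centroid, and tests equality
#' of mean dispersion across groups by permutation of least-squares
#' residuals.
#'
#' @inheritParams permanova
#' @return A `perm_test` with the dispersion F statistic and permutation p.
#' @export
permdisp <- function(dist, groups, n_perm = 999, seed = 1L) {
  groups <- check_groups(dist, groups)
  # betadisper routinely notes the negative-eigenvalue correction on
  # Bray-Curtis embeddings; that correction is part of this contract
  bd <- withCallingHandlers(
    vegan::betadisper(dist, groups, type = "centroid"),
    warning = function(w) {
      if (grepl("negative.*changed to zero", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  pt <- withr_seed(seed, {
    n <- length(groups)
    pm <- t(replicate(n_perm, sample.int(n)))
    vegan::permutest(bd, permutations = pm)
  })
  structure(list(statistic = pt$tab$F[1],
                 p_value = pt$tab$`Pr(>F)`[1],
                 n_permutations = n_perm,
                 explained_variation = NA_real_,
                 method = "PERMDISP"),
            class = "perm_test")
}

check_groups <- function(dist, groups) {
  if (!inherits(dist, "dist")) stop("dist must be a 'dist' object")
  groups <- as.factor(groups)
  if (length(groups) != attr(dist, "Size"))
    stop("one group label per sample is required")
  if (nlevels(droplevels(groups)) < 2) stop("at least 2 groups are required")
  if (any(table(groups) < 2))
    stop("every group needs at least 2 samples")
  if (all(as.vector(dist) == 0)) stop("degenerate all-zero distance matrix")
  droplevels(groups)
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%d permutations)\n",
              x$method, x$statistic, x$p_value, x$n_permutations))
  if (!is.na(x$explained_variation))
    cat(sprintf("  explained variation = %.2f%%\n", x$explained_variation))
  invisible(x)
}

#' Indicator species analysis (IndVal)
#'
#' For OTU `i` and group `g`: specificity `A` is the mean abundance of `i`
#' in `g` divided by the sum of its group mean abundances (the
#' group-equalised convention, robust to unbalanced designs; the raw
#' variant divides total abundance in `g` by the grand total); fidelity `B`
#' is the fraction of `g`'s samples where `i` is present; the indicator
#' value is `sqrt(A * B)`.  Significance of each OTU's best group is
#' assessed by permuting group labels and comparing the maximum IndVal.
#'
#' @param table OTU count table, samples x OTUs.
#' @param groups Group labels, one per sample.
#' @param n_perm Permutations for the max-IndVal test (default 999).
#' @param seed Integer seed.
#' @param variant `"group_equalised"` (default) or `"raw"` specificity.
#' @return Data frame with one row per OTU: `otu`, `best_group`, `A`, `B`,
#'   `indval` (for the best group), `p_value`, plus the full IndVal matrix
#'   in attribute `indval_matrix`.
#' @export
indicator_species <- function(table, groups, n_perm = 999, seed = 1L,
                              variant = c("group_equalised", "raw")) {
  variant <- match.arg(variant)
  m <- as_count_matrix(table, allow_numeric = TRUE)
  groups <- as.factor(groups)
  if (length(groups) != nrow(m)) stop("one group label per sample")
  if (nlevels(groups) < 2) stop("at least 2 groups are required")

  iv_matrix <- function(g) {
    means <- apply(m, 2, function(x) tapply(x, g, mean))       # G x OTU
    A <- if (variant == "group_equalised") {
      sweep(means, 2, colSums(means), `/`)
    } else {
      tot <- apply(m, 2, function(x) tapply(x, g, sum))
      sweep(tot, 2, colSums(tot), `/`)
    }
    pres <- apply(m > 0, 2, function(x) tapply(x, g, mean))    # B
    A[is.nan(A)] <- 0
    sqrt(A * pres)
  }

  iv <- iv_matrix(groups)
  obs_max <- apply(iv, 2, max)
  best <- rownames(iv)[apply(iv, 2, which.max)]

  exceed <- withr_seed(seed, {
    cnt <- numeric(ncol(m))
    for (b in seq_len(n_perm)) {
      ivp <- iv_matrix(sample(groups))
      cnt <- cnt + (apply(ivp, 2, max) >= obs_max)
    }
    cnt
  })
  res <- data.frame(otu = colnames(m), best_group = best,
                    A = NA_real_, B = NA_real_,
                    indval = obs_max,
                    p_value = (1 + exceed) / (1 + n_perm),
                    row.names = colnames(m), stringsAsFactors = FALSE)
  # A and B reported for each OTU's best group
  means <- apply(m, 2, function(x) tapply(x, groups, mean))
  Afull <- if (variant == "group_equalised")
    sweep(means, 2, colSums(means), `/`) else {
      tot <- apply(m, 2, function(x) tapply(x, groups, sum))
      sweep(tot, 2, colSums(tot), `/`)
    }
  Afull[is.nan(Afull)] <- 0
  Bfull <- apply(m > 0, 2, function(x) tapply(x, groups, mean))
  res$A <- Afull[cbind(best, colnames(m))]
  res$B <- Bfull[cbind(best, colnames(m))]
  attr(res, "indval_matrix") <- iv
  res
}
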