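#' Keystone abundance response
#'
#' Summed relative abundance of the keystone OTUs per sample (the default
#' response for driver analysis); `mode = "presence"` counts the keystones
#' present instead.
#'
#' @param table Rarefied OTU count table, samples x OTUs.
#' @param keystones Non-empty character vector of keystone OTU ids.
#' @param mode `"abundance"` (default) or `"presence"`.
#' @return Named numeric vector, one value per sample.
#' @export
keystone_abundance_response <- function(table, keystones,
                                        mode = c("abundance", "presence")) {
  mode <- match.arg(mode)
  if (length(keystones) == 0) stop("keystone set is empty")
  m <- as_count_matrix(table)
  keep <- intersect(keystones, colnames(m))
  sub <- m[, keep, drop = FALSE]
  if (mode == "abundance") rowSums(sub) / rowSums(m)
  else rowSums(sub > 0)
}

#' Random-forest importance of covariates
#'
#' Regression forest (fully grown trees, `mtry = ceiling(p/3)`) with
#' out-of-bag permutation importance (%IncMSE) and node-impurity decrease.
#'
#' @param X Data frame or matrix of covariates (n x p, p >= 2).
#' @param y Numeric response of length n (>= 10).
#' @param n_trees Number of trees (default 999).
#' @param seed Integer seed.
#' @return List of class `rf_report` with `importance` (data frame:
#'   `predictor`, `pct_inc_mse`, `inc_node_purity`), `oob_r_squared`,
#'   `n_trees` and the fitted forest.
#' @export
rf_importance <- function(X, y, n_trees = 999, seed = 1L) {
  X <- as.data.frame(X)
  if (ncol(X) < 2) stop("at least 2 predictors are required")
  if (length(y) < 10) stop("at least 10 observations are required")
  if (length(y) != nrow(X)) stop("X and y sizes differ")
  if (sd(y) == 0) stop("constant response")
  fit <- withr_seed(seed,
    randomForest::randomForest(X, y, ntree = n_trees,
                               mtry = max(1, ceiling(ncol(X) / 3)),
                               importance = TRUE))
  imp <- randomForest::importance(fit)
  structure(list(
    importance = data.frame(predictor = rownames(imp),
                            pct_inc_mse = imp[, "%IncMSE"],
                            inc_node_purity = imp[, "IncNodePurity"],
                            row.names = rownames(imp),
                            stringsAsFactors = FALSE),
    oob_r_squared = fit$rsq[n_trees],
    n_trees = n_trees, forest = fit), class = "rf_report")
}

#' Permutation significance of random-forest importance
#'
#' Refits the forest on `n_perm` response-permuted datasets to build a null
#' distribution of each predictor's %IncMSE;
#' `p = (1 + #(null >= observed)) / (1 + n_perm)`.  Predictors significant
#' at the `alpha` level (`p <= alpha`; the attainable floor of a
#' permutation p-value is `1/(n_perm + 1)`, so the boundary is included)
#' are reported as drivers.
#'
#' @inheritParams rf_importance
#' @param n_perm Number of response permutations (> 0; default 999).
#' @param alpha Driver selection level (default 0.01).
#' @return An `rf_report` whose `importance` table gains a `p_value`
#'   column, plus `drivers` (selected predictor names) and `alpha`.
#' @export
rf_permutation_significance <- function(X, y, n_trees = 999, n_perm = 999,
                                        alpha = 0.01, seed = 1L) {
  if (n_perm <= 0) stop("n_perm must be positive")
  base <- rf_importance(X, y, n_trees, seed)
  obs <- base$importance$pct_inc_mse
  exceed <- withr_seed(seed + 1, {
    cnt <- numeric(length(obs))
    for (b in seq_len(n_perm)) {
      yp <- sample(y)
      fitp <- randomForest::randomForest(as.data.frame(X), yp,
                                         ntree = n_trees,
                                         mtry = max(1, ceiling(ncol(X) / 3)),
                                         importance = TRUE)
      impp <- randomForest::importance(fitp)[, "%IncMSE"]
      cnt <- cnt + (impp >= obs)
    }
    cnt
  })
  base$importance$p_value <- (1 + exceed) / (1 + n_perm)
  base$drivers <- base$importance$predictor[base$importance$p_value <= alpha]
  base$alpha <- alpha
  base$n_perm <- n_perm
  base
}

#' @export
print.rf_report <- function(x, ...) {
  cat(sprintf("random forest (%d trees), OOB R2 = %.3f\n",
              x$n_trees, x$oob_r_squared))
  imp <- x$importance[order(-x$importance$pct_inc_mse), ]
  print(imp, row.names = FALSE)
  if (!is.null(x$drivers))
    cat("drivers at alpha =", x$alpha, ":",
        paste(x$drivers, collapse = ", "), "\n")
  invisible(x)
}
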