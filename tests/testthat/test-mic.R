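cfg_fast <- mic_config(n_permutations = 999, seed = 42)

test_that("MIC is 1 on noiseless monotone relations and respects bounds", {
  x <- c(3, 7, 1, 9, 4, 12, 5, 8, 2, 11, 6, 10, 13, 0, 14, 15, 16, 17, 18, 19)
  expect_equal(mic_score(x, x, cfg_fast)$mic, 1)
  expect_equal(mic_score(x, -2 * x + 5, cfg_fast)$mic, 1)      # decreasing
  expect_equal(mic_score(x, exp(x / 5), cfg_fast)$mic, 1)      # convex monotone
  set.seed(1)
  for (i in 1:20) {
    a <- rnorm(15); b <- rnorm(15)
    m <- mic_score(a, b, cfg_fast)$mic
    expect_gte(m, 0); expect_lte(m, 1)
    expect_equal(m, mic_score(b, a, cfg_fast)$mic)             # symmetry
  }
})

test_that("MIC is exactly invariant under strictly increasing transforms", {
  set.seed(7)
  for (i in 1:10) {
    x <- rnorm(20); y <- x + rnorm(20)
    m0 <- mic_score(x, y, cfg_fast)$mic
    expect_identical(m0, mic_score(rank(x), y, cfg_fast)$mic)
    expect_identical(m0, mic_score(exp(x), y, cfg_fast)$mic)
    expect_identical(m0, mic_score(x, y^3 + 2 * y, cfg_fast)$mic)
  }
})

test_that("DP characteristic matrix equals the exhaustive oracle", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(8:12, 1)
    x <- if (i %% 3 == 0) sample(1:4, n, replace = TRUE) else rnorm(n)
    y <- if (i %% 4 == 0) sample(1:3, n, replace = TRUE) else rnorm(n)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    for (b in c(0.6, 0.85)) {
      res <- mic_score(x, y, mic_config(b_exponent = b,
                                        n_permutations = 999))
      B <- res$B
      Mo <- oracle_char_matrix(x, y, B)
      Mi <- res$matrix
      expect_equal(dim(Mi), dim(Mo))
      expect_equal(Mi[!is.na(Mo)], Mo[!is.na(Mo)], tolerance = 1e-9)
      expect_equal(res$mic, max(Mo, na.rm = TRUE), tolerance = 1e-9)
    }
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(mic_score(rep(1, 10), rnorm(10)), "constant")
  expect_error(mic_score(rnorm(5), rnorm(5)), "at least 8")
  expect_error(mic_score(rnorm(9), rnorm(8)), "equal length")
  expect_error(mic_config(n_permutations = 50), "at least 99")
})

test_that("mic_matrix agrees with pairwise mic_score calls", {
  set.seed(3)
  tab <- matrix(rpois(20 * 5, 20), 20, 5,
                dimnames = list(paste0("S", 1:20), paste0("O", 1:5)))
  assoc <- mic_matrix(tab, cfg_fast)
  expect_equal(nrow(assoc), 10)
  for (k in seq_len(nrow(assoc))) {
    expect_equal(assoc$mic[k],
                 mic_score(tab[, assoc$otu_a[k]], tab[, assoc$otu_b[k]],
                           cfg_fast)$mic)
  }
  # duplicated column (distinct per-sample values) scores exactly 1
  tab2 <- cbind(tab, u = sample(101:120), dup = 0L)
  tab2[, "dup"] <- tab2[, "u"]
  a2 <- mic_matrix(tab2, cfg_fast)
  expect_equal(a2$mic[a2$otu_a == "u" & a2$otu_b == "dup"], 1)
  # invariance to column order up to pair relabeling
  perm <- c(3, 1, 5, 2, 4)
  a3 <- mic_matrix(tab[, perm], cfg_fast)
  key <- function(a) setNames(a$mic, paste(pmin(a$otu_a, a$otu_b),
                                           pmax(a$otu_a, a$otu_b)))
  expect_equal(sort(names(key(assoc))), sort(names(key(a3))))
  expect_equal(key(a3)[names(key(assoc))], key(assoc))
})

test_that("permutation p-values hit their bounds and are seeded", {
  set.seed(5)
  tab <- matrix(rpois(20 * 6, 15), 20, 6)
  assoc <- mic_matrix(tab, cfg_fast)
  assoc <- permutation_pvalues(assoc, tab, cfg_fast)
  null <- attr(assoc, "null_mic")
  expect_length(null, 999)
  # manufactured observations at the extremes
  expect_equal(p_from_null(max(null) + 1, null), 1 / 1000)
  expect_equal(p_from_null(min(null) - 1, null), 1)
  # monotone: higher MIC never gets larger p
  o <- order(assoc$mic)
  expect_true(all(diff(assoc$p[o]) <= 0))
  assoc2 <- permutation_pvalues(assoc, tab, cfg_fast)
  expect_identical(assoc$p, assoc2$p)
})

test_that("BH q-values match the hand-computed step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.3), 0.3)
  set.seed(2)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(q >= p))                       # q >= p after BH
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))         # monotone in sorted p
  # Bonferroni dominance
  expect_gte(sum(q < 0.05), sum(p < 0.05 / 50))
})

test_that("edge classification separates positive, negative and nonlinear", {
  n <- 20
  x <- seq_len(n)
  make <- function(y) {
    tab <- cbind(x = x, y = y)
    assoc <- mic_matrix(tab, cfg_fast)
    assoc$p <- 1 / 1000                          # force significance
    classify_edges(assoc, cfg_fast)$relationship
  }
  expect_equal(make(2 * x), "positive")
  expect_equal(make(max(x) + 1 - x), "negative")
  expect_equal(make((x - mean(x))^2), "nonlinear")          # r ~ 0, mic - r^2 > tau
  # non-significant pairs stay unclassified
  assoc <- mic_matrix(cbind(x = x, y = 2 * x), cfg_fast)
  assoc$p <- 0.9
  expect_true(is.na(classify_edges(assoc, cfg_fast)$relationship))
})
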