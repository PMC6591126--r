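mk <- function(...) {
  m <- rbind(...)
  rownames(m) <- paste0("S", seq_len(nrow(m)))
  colnames(m) <- paste0("O", seq_len(ncol(m)))
  m
}

test_that("alpha diversity matches the closed-form cases", {
  m <- mk(c(10, 10, 10, 10), c(40, 0, 0, 0), c(50, 30, 20, 0))
  d <- alpha_diversity(m)
  expect_equal(d$richness, c(4L, 1L, 3L))
  expect_equal(d$shannon[1], log(4))
  expect_equal(d$evenness[1], 1)
  expect_equal(d$shannon[2], 0)
  expect_equal(d$evenness[2], 1)
  # hand-summed formula for {50, 30, 20}
  p <- c(0.5, 0.3, 0.2)
  expect_equal(d$shannon[3], -sum(p * log(p)))
  expect_equal(d$evenness[3], exp(-sum(p * log(p))) / 3)
  # Pielou variant
  dp <- alpha_diversity(m, evenness = "pielou")
  expect_equal(dp$evenness[3], -sum(p * log(p)) / log(3))
  expect_error(alpha_diversity(mk(c(0, 0), c(1, 1))), "empty")
})

test_that("Shannon is maximal at uniform composition", {
  set.seed(8)
  for (i in 1:20) {
    x <- rmultinom(1, 500, runif(6))[, 1]
    h <- alpha_diversity(mk(x + 1))$shannon   # +1 avoids zero classes
    expect_lte(h, log(6) + 1e-12)
  }
})

test_that("Bray-Curtis matches hand computation and its bounds", {
  m <- mk(c(6, 4), c(2, 8))
  d <- as.matrix(bray_curtis(m))
  expect_equal(d["S1", "S2"], 0.4)            # 8 / 20
  m2 <- mk(c(5, 5, 0), c(5, 5, 0), c(0, 0, 9))
  d2 <- as.matrix(bray_curtis(m2))
  expect_equal(d2["S1", "S2"], 0)
  expect_equal(d2["S1", "S3"], 1)
})

test_that("PERMANOVA pseudo-F equals a from-scratch sum-of-squares oracle", {
  set.seed(12)
  m <- mk(c(10, 0, 5), c(8, 1, 6), c(9, 2, 4), c(0, 9, 1), c(1, 8, 2),
          c(2, 10, 0))
  g <- rep(c("a", "b"), each = 3)
  d <- bray_curtis(m)
  res <- permanova(d, g, n_perm = 199, seed = 1)
  # oracle: SS_total = sum d^2 / n; SS_within via group blocks
  dm <- as.matrix(d)^2
  n <- nrow(dm)
  ss_total <- sum(dm[upper.tri(dm)]) / n
  ss_within <- 0
  for (gr in unique(g)) {
    ix <- which(g == gr)
    ss_within <- ss_within +
      sum(dm[ix, ix][upper.tri(dm[ix, ix])]) / length(ix)
  }
  ss_between <- ss_total - ss_within
  f_oracle <- (ss_between / 1) / (ss_within / (n - 2))
  expect_equal(res$statistic, f_oracle, tolerance = 1e-10)
  expect_equal(res$explained_variation, 100 * ss_between / ss_total,
               tolerance = 1e-10)
  expect_gte(res$p_value, 1 / 200)
})

test_that("PERMANOVA reaches the minimal p on maximally separated groups", {
  a <- cbind(100 - 0:9, 0:9, 0)
  b <- cbind(0, 9:0, 91 + 0:9)
  m <- mk(a[1, ], a[2, ], a[3, ], a[4, ], a[5, ], a[6, ], a[7, ], a[8, ],
          a[9, ], a[10, ], b[1, ], b[2, ], b[3, ], b[4, ], b[5, ], b[6, ],
          b[7, ], b[8, ], b[9, ], b[10, ])
  res <- permanova(bray_curtis(m), rep(c("x", "y"), each = 10),
                   n_perm = 99, seed = 1)
  expect_equal(res$p_value, 1 / 100)
})

test_that("PERMDISP detects unequal dispersion and rejects degenerate input", {
  set.seed(3)
  tight <- matrix(rep(c(50, 50, 0), 6), 6, 3, byrow = TRUE) +
    matrix(rpois(18, 1), 6, 3)
  loose <- matrix(rpois(18, 30), 6, 3)
  m <- rbind(tight, loose)
  rownames(m) <- paste0("S", 1:12)
  colnames(m) <- paste0("O", 1:3)
  g <- rep(c("tight", "loose"), each = 6)
  res <- permdisp(bray_curtis(m), g, n_perm = 999, seed = 1)
  expect_lte(res$p_value, 0.05)
  # one sample per group: dispersion undefined by contract
  expect_error(permdisp(bray_curtis(m), paste0("g", 1:12), n_perm = 99),
               "at least 2 samples")
})

test_that("IndVal matches hand evaluation and its boundary cases", {
  # 3 groups x 2 samples; O1 perfect indicator of g1; O2 absent from g1
  m <- mk(c(5, 0), c(7, 0), c(0, 3), c(0, 2), c(0, 4), c(0, 1))
  g <- rep(c("g1", "g2", "g3"), each = 2)
  res <- indicator_species(m, g, n_perm = 99, seed = 1)
  expect_equal(res["O1", "indval"], 1)          # exclusive and faithful
  expect_equal(res["O1", "best_group"], "g1")
  iv <- attr(res, "indval_matrix")
  expect_equal(iv["g1", "O2"], 0)               # absent from g1
  # hand evaluation for O2 in g2: A = 2.5/(2.5+2.5), B = 1
  expect_equal(iv["g2", "O2"], sqrt(0.5 * 1))
  expect_true(all(iv >= 0 & iv <= 1))
})

test_that("IndVal is monotone in fidelity at fixed specificity", {
  # O1 and O2 have identical group mean profile shape (A equal) but O2
  # is present in fewer of g1's samples
  m <- mk(c(4, 8), c(4, 0), c(4, 4), c(0, 0), c(0, 0), c(0, 0))
  g <- rep(c("g1", "g2"), each = 3)
  res <- indicator_species(m, g, n_perm = 99, seed = 1)
  iv <- attr(res, "indval_matrix")
  expect_gt(iv["g1", "O1"], iv["g1", "O2"])
})
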