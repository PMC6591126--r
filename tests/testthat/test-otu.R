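toy_table <- function(counts, n_samples = NULL) {
  m <- as.matrix(counts)
  rownames(m) <- paste0("S", seq_len(nrow(m)))
  colnames(m) <- paste0("O", seq_len(ncol(m)))
  m
}

test_that("low-abundance filter applies the joint removal rule", {
  # OTU kept: fails both removal conditions (global 0.002, sample max 0.006)
  m <- toy_table(rbind(c(2, 998), c(6, 994)))
  f <- filter_low_abundance(m, 0.001, 0.005)
  expect_true("O1" %in% colnames(f))
  # OTU removed: global 0.0005 and within-sample max 0.004
  m2 <- toy_table(rbind(c(1, 999), c(0, 1000)))
  f2 <- filter_low_abundance(m2, 0.001, 0.005)
  expect_false("O1" %in% colnames(f2))
  expect_error(filter_low_abundance(toy_table(rbind(c(0, 0), c(1, 2)))),
               "zero total")
})

test_that("low-abundance filter matches brute-force enumeration on a toy table", {
  set.seed(4)
  m <- toy_table(matrix(rpois(3 * 5, 3) * rbinom(15, 1, 0.7) +
                        matrix(c(500, 0, 0, 0, 0), 3, 5, byrow = TRUE), 3, 5))
  gf <- 0.01; sf <- 0.05
  f <- filter_low_abundance(m, gf, sf)
  keep_brute <- vapply(seq_len(ncol(m)), function(j) {
    glob <- sum(m[, j]) / sum(m)
    within <- m[, j] / rowSums(m)
    !(glob < gf && all(within < sf))
  }, logical(1))
  expect_identical(colnames(f), colnames(m)[keep_brute])
  # idempotence
  expect_identical(filter_low_abundance(f, gf, sf), f)
  # OR mode is at least as strict
  f_or <- tryCatch(filter_low_abundance(m, gf, sf, mode = "or"),
                   error = function(e) m[, 0, drop = FALSE])
  expect_true(all(colnames(f_or) %in% colnames(f)))
})

test_that("rarefaction subsamples without replacement to exact depth", {
  set.seed(9)
  m <- toy_table(matrix(rpois(4 * 6, 50), 4, 6))
  r <- rarefy(m, 100, seed = 1)
  expect_true(all(rowSums(r) == 100))
  expect_true(all(r <= m))                       # without replacement
  expect_identical(rarefy(m, 100, seed = 1), r)  # reproducible
  # a sample already at depth is returned unchanged
  m2 <- toy_table(rbind(c(60, 40), c(70, 60)))
  r2 <- rarefy(m2, 100, seed = 1)
  expect_identical(r2[1, ], m2[1, ])
  # undersized sample errors, naming it
  expect_error(rarefy(toy_table(rbind(c(5, 5), c(60, 60))), 100), "S1")
})

test_that("rarefied counts follow the hypergeometric expectation", {
  m <- toy_table(rbind(c(900, 100)))
  draws <- vapply(1:3000, function(s) rarefy(m, 100, seed = s)[1, 2],
                  numeric(1))
  # hypergeometric mean 10, variance 100*0.1*0.9*(900/999)
  se <- sqrt(100 * 0.1 * 0.9 * (900 / 999) / 3000)
  expect_lt(abs(mean(draws) - 10), 3 * se)
})

test_that("prevalence filter retains OTUs present in enough samples", {
  m <- toy_table(rbind(c(5, 3, 0), c(0, 2, 0), c(0, 4, 7)))
  f <- prevalence_filter(m, 2)
  expect_identical(colnames(f), "O2")
  set.seed(6)
  big <- toy_table(matrix(rpois(10 * 8, 0.5), 10, 8))
  keep <- colSums(big > 0) >= 3
  expect_identical(colnames(prevalence_filter(big, 3)), colnames(big)[keep])
})

test_that("relative abundance closes rows to 1 and is idempotent up to scale", {
  m <- toy_table(rbind(c(5, 5), c(2, 8)))
  ra <- relative_abundance(m)
  expect_equal(unname(ra[1, ]), c(0.5, 0.5))
  expect_equal(unname(rowSums(ra)), c(1, 1))
  expect_equal(relative_abundance(ra), ra)
  expect_error(relative_abundance(toy_table(rbind(c(0, 0), c(1, 1)))),
               "zero-sum")
})

test_that("OTU, taxonomy and metadata tables round-trip through disk", {
  st <- simulate_study(sim_config(n_otus = 30, n_bg_guilds = 1,
                                  hub_partner_count = 10, seed = 2))
  d <- tempfile("study")
  dir.create(d)
  on.exit(unlink(d, recursive = TRUE))
  write_study(st, d)
  back <- read_otu_table(file.path(d, "otu_table.tsv"))
  expect_identical(back, st$otu)
  tax <- read_taxonomy(file.path(d, "taxonomy.tsv"))
  expect_identical(tax$order, st$taxonomy$order)
  meta <- read_metadata(file.path(d, "metadata.tsv"))
  expect_identical(meta$system, st$metadata$system)
  expect_equal(meta$intensity_index, st$metadata$intensity_index,
               tolerance = 1e-12)
  # transpose dialect
  tm <- t(st$otu)
  tf <- file.path(d, "otu_t.tsv")
  write.table(data.frame(otu_id = rownames(tm), tm, check.names = FALSE),
              tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_identical(read_otu_table(tf, transpose = TRUE), st$otu)
})
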