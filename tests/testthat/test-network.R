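test_that("networks are built from q < alpha pairs only", {
  a <- fake_assoc(c("A", "B", "C", "A"), c("B", "C", "D", "D"),
                  q = c(0.01, 0.2, 0.04, 0.9))
  net <- build_network(a, 0.05)
  expect_equal(igraph::ecount(net), 2)
  expect_setequal(igraph::V(net)$name, c("A", "B", "C", "D"))
  expect_warning(net0 <- build_network(fake_assoc("A", "B", 1), 0.05),
                 "no significant")
  expect_equal(igraph::vcount(net0), 0)
  expect_error(build_network(fake_assoc("A", "B", NA)[, -7], 0.05), "q-value")
})

test_that("centralities match closed forms on star and cycle graphs", {
  star <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(star)$name <- paste0("v", 1:6)
  at <- node_centralities(star)
  expect_equal(at$degree[1], 5L)
  expect_equal(at$closeness[1], 1)
  expect_equal(at$betweenness[1], 1)
  expect_equal(at$closeness[2], 5 / 9)          # 1 + 2*4 hops over 5 nodes
  expect_equal(at$betweenness[2], 0)
  ring <- igraph::make_ring(5)
  igraph::V(ring)$name <- paste0("v", 1:5)
  atr <- node_centralities(ring)
  expect_true(all(atr$betweenness == atr$betweenness[1]))  # symmetry
  expect_true(all(atr$degree == 2))
})

test_that("centralities equal the brute-force oracle on random small graphs", {
  set.seed(19)
  for (i in 1:60) {
    n <- sample(3:8, 1)
    A <- random_graph_adj(n, runif(1, 0.25, 0.7))
    if (sum(A) == 0) next
    g <- adj_to_igraph(A)
    g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
    if (igraph::vcount(g) == 0) next
    keep <- as.integer(sub("v", "", igraph::V(g)$name))
    at <- node_centralities(g)
    orc <- oracle_centralities(A[keep, keep, drop = FALSE])
    expect_equal(at$degree, orc$degree, ignore_attr = TRUE)
    expect_equal(at$closeness, orc$closeness, ignore_attr = TRUE,
                 tolerance = 1e-10)
    expect_equal(at$betweenness, orc$betweenness, ignore_attr = TRUE,
                 tolerance = 1e-10)
    expect_equal(at$local_clustering, orc$local_clustering,
                 ignore_attr = TRUE, tolerance = 1e-10)
    expect_equal(sum(at$degree), 2 * igraph::ecount(g))
  }
})

test_that("topology summaries match closed forms and are label-invariant", {
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- paste0("v", 1:4)
  t4 <- topology_summary(k4)
  expect_equal(t4$clustering_coefficient, 1)
  expect_equal(t4$diameter, 1)
  expect_equal(t4$avg_neighbors, 3)
  p4 <- igraph::make_ring(4, circular = FALSE)
  igraph::V(p4)$name <- paste0("v", 1:4)
  tp <- topology_summary(p4)
  expect_equal(tp$clustering_coefficient, 0)
  expect_equal(tp$diameter, 3)
  expect_gte(tp$diameter, tp$mean_shortest_path)
  # node relabeling leaves the summary unchanged
  p4b <- igraph::permute(p4, c(3, 1, 4, 2))
  expect_equal(unclass(topology_summary(p4b))[c("n_nodes", "n_edges",
               "diameter", "avg_neighbors", "clustering_coefficient",
               "mean_shortest_path")],
               unclass(tp)[c("n_nodes", "n_edges", "diameter",
               "avg_neighbors", "clustering_coefficient",
               "mean_shortest_path")])
})

test_that("topology summary equals an adjacency-matrix oracle on an ER graph", {
  set.seed(23)
  g <- igraph::sample_gnp(30, 0.15)
  igraph::V(g)$name <- paste0("v", 1:30)
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  ts <- topology_summary(g)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  D <- floyd_warshall(A)
  fin <- D[upper.tri(D)][is.finite(D[upper.tri(D)])]
  expect_equal(ts$diameter, max(fin))
  expect_equal(ts$mean_shortest_path, mean(fin))
  expect_equal(ts$avg_neighbors, mean(rowSums(A)))
  expect_equal(ts$clustering_coefficient,
               mean(oracle_centralities(A)$local_clustering))
})

test_that("power-law fit recovers an exact synthetic law and handles NA", {
  k <- 1:10
  pk <- k^-2 / sum(k^-2)
  counts <- round(pk * 1e5)
  degs <- rep(k, counts)
  fit <- powerlaw_fit(degs)
  expect_equal(unname(fit["gamma"]), 2, tolerance = 1e-4)
  expect_equal(unname(fit["r2"]), 1, tolerance = 1e-4)
  expect_true(all(is.na(powerlaw_fit(rep(4, 50)))))   # uniform degrees
})

test_that("the preferential-attachment generator honors its edge-count contract", {
  g <- barabasi_albert(10, 2, seed = 1)
  expect_equal(igraph::ecount(g), 3 + 7 * 2)
  expect_equal(igraph::vcount(g), 10)
  expect_true(igraph::is_simple(g))
  expect_error(barabasi_albert(10, 10), "m_attach")
  # determinism
  g2 <- barabasi_albert(10, 2, seed = 1)
  expect_identical(igraph::as_edgelist(g), igraph::as_edgelist(g2))
  # hub emergence: max degree far above median over seeds
  ratios <- vapply(1:5, function(s) {
    d <- igraph::degree(barabasi_albert(300, 2, seed = s))
    max(d) / median(d)
  }, numeric(1))
  expect_true(all(ratios > 4))
  # fitted exponent in the expected band for BA graphs
  gam <- vapply(1:5, function(s)
    powerlaw_fit(igraph::degree(barabasi_albert(500, 4, seed = s)))["gamma"],
    numeric(1))
  expect_true(all(gam > 1.5 & gam < 3.8))
})

test_that("random-model comparison calibrates on its own null", {
  set.seed(31)
  er <- igraph::sample_gnm(60, 120)
  igraph::V(er)$name <- paste0("v", 1:60)
  rep <- compare_to_random(er, n_rand = 100, seed = 2)
  expect_gte(rep$percentile$clustering_er, 0.025)
  expect_lte(rep$percentile$clustering_er, 0.975)
  # a clique-rich graph exceeds the ER null clustering
  cliq <- igraph::disjoint_union(lapply(1:6, function(i)
    igraph::make_full_graph(6)))
  igraph::V(cliq)$name <- paste0("v", 1:36)
  rep2 <- compare_to_random(cliq, n_rand = 100, seed = 3)
  expect_gte(rep2$percentile$clustering_er, 0.99)
  expect_gte(rep2$percentile$clustering_ba, 0.99)
  expect_error(compare_to_random(er, n_rand = 0), "positive")
})

test_that("network export writes GraphML and SIF", {
  a <- fake_assoc(c("A", "B"), c("B", "C"), q = c(0.01, 0.02))
  net <- build_network(a, 0.05)
  f1 <- tempfile(fileext = ".graphml"); f2 <- tempfile(fileext = ".sif")
  write_network(net, f1)
  write_network(net, f2, "sif")
  g2 <- igraph::read_graph(f1, format = "graphml")
  expect_equal(igraph::ecount(g2), 2)
  lines <- readLines(f2)
  expect_length(lines, 2)
  expect_true(all(grepl("\t", lines)))
  unlink(c(f1, f2))
})
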