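# Independent oracles used across the suite.  These deliberately avoid the
# package's own computational paths: the MIC oracle enumerates every cut
# partition explicitly, and the graph oracle works from the adjacency
# matrix with Floyd-Warshall distances and combinatorial path counting.

# rank-equipartition of a sorted vector into at most q bins, never
# splitting ties (the binning rule both implementations share)
equipartition_r <- function(v_sorted, q) {
  n <- length(v_sorted)
  bin <- integer(n)
  desired <- n / q
  i <- 1L; curr <- 0L; in_curr <- 0L
  while (i <= n) {
    j <- i
    while (j < n && v_sorted[j + 1] == v_sorted[i]) j <- j + 1L
    S <- j - i + 1L
    if (in_curr != 0L && curr < q - 1L &&
        abs(in_curr + S - desired) >= abs(in_curr - desired)) {
      curr <- curr + 1L
      in_curr <- 0L
      desired <- (n - i + 1) / (q - curr)
    }
    bin[i:j] <- curr
    in_curr <- in_curr + S
    i <- j + 1L
  }
  bin
}

mi_bits <- function(col, row) {  # mutual information in bits
  tab <- table(col, row)
  n <- sum(tab)
  p <- tab / n
  px <- rowSums(p); py <- colSums(p)
  keep <- p > 0
  sum(p[keep] * log2(p[keep] /
        (outer(px, py)[keep])))
}

# exhaustive characteristic matrix: for each orientation and row count q,
# enumerate EVERY subset of cut points between distinct column values
oracle_char_matrix <- function(x, y, B) {
  n <- length(x)
  kmax <- B %/% 2
  M <- matrix(NA_real_, kmax + 1, kmax + 1)
  for (orient in 1:2) {
    rv <- if (orient == 1) y else x
    cv <- if (orient == 1) x else y
    ro <- order(rv)
    rbin_sorted <- NULL
    co <- order(cv)
    cs <- cv[co]
    cut_pos <- which(diff(cs) != 0)       # allowed cut positions
    for (q in 2:kmax) {
      p_max <- B %/% q
      if (p_max < 2) break
      rbin <- integer(n)
      rbin[ro] <- equipartition_r(rv[ro], q)
      best <- rep(-Inf, p_max)            # best I for <= p columns
      for (k in 0:(p_max - 1)) {
        if (k > length(cut_pos)) break
        combs <- if (k == 0) matrix(integer(0), 0, 1) else
          combn(cut_pos, k)
        for (ci in seq_len(ncol(combs))) {
          cuts <- combs[, ci]
          colbin <- integer(n)
          colbin[co] <- findInterval(seq_len(n) - 1, cuts)
          I <- mi_bits(colbin, rbin)
          p_used <- k + 1
          for (p in p_used:p_max) best[p] <- max(best[p], I)
        }
      }
      for (p in 2:p_max) {
        val <- best[p] / log2(min(p, q))
        a <- if (orient == 1) p else q
        b <- if (orient == 1) q else p
        if (is.na(M[a + 1, b + 1]) || val > M[a + 1, b + 1])
          M[a + 1, b + 1] <- val
      }
    }
  }
  M
}

oracle_mic <- function(x, y, B) {
  M <- oracle_char_matrix(x, y, B)
  max(M, na.rm = TRUE)
}

# ---- brute-force graph centralities from an adjacency matrix ------------
floyd_warshall <- function(A) {
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

count_shortest_paths <- function(A, D) {
  n <- nrow(A)
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  for (s in seq_len(n)) {
    ds <- D[s, ]
    for (d in sort(unique(ds[is.finite(ds) & ds > 0]))) {
      for (t in which(ds == d)) {
        preds <- which(A[, t] > 0 & ds == d - 1)
        sigma[s, t] <- sum(sigma[s, preds])
      }
    }
  }
  sigma
}

oracle_centralities <- function(A) {
  n <- nrow(A)
  D <- floyd_warshall(A)
  sigma <- count_shortest_paths(A, D)
  comp <- integer(n); c0 <- 0
  for (v in seq_len(n)) if (comp[v] == 0) {
    c0 <- c0 + 1
    comp[is.finite(D[v, ])] <- c0
  }
  deg <- rowSums(A)
  clo <- btw <- lc <- numeric(n)
  for (v in seq_len(n)) {
    same <- which(comp == comp[v])
    others <- setdiff(same, v)
    clo[v] <- if (length(others)) length(others) / sum(D[v, others]) else NA
    # betweenness: fraction of shortest paths through v, per component
    tot <- 0
    if (length(others) >= 2) {
      prs <- combn(others, 2)
      for (pi in seq_len(ncol(prs))) {
        s <- prs[1, pi]; t <- prs[2, pi]
        if (D[s, v] + D[v, t] == D[s, t])
          tot <- tot + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
    N <- length(same)
    btw[v] <- if (N > 2) tot / ((N - 1) * (N - 2) / 2) else 0
    nb <- which(A[v, ] > 0)
    lc[v] <- if (deg[v] >= 2)
      sum(A[nb, nb]) / (deg[v] * (deg[v] - 1)) else 0
  }
  data.frame(degree = deg, closeness = clo, betweenness = btw,
             local_clustering = lc)
}

random_graph_adj <- function(n, p = 0.4) {
  A <- matrix(0, n, n)
  up <- upper.tri(A)
  A[up] <- rbinom(sum(up), 1, p)
  A + t(A)
}

adj_to_igraph <- function(A) {
  dimnames(A) <- list(paste0("v", seq_len(nrow(A))),
                      paste0("v", seq_len(nrow(A))))
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

# small helper: association_set with hand-set q values for network tests
fake_assoc <- function(a, b, q, mic = 0.9, r = 0.5) {
  d <- data.frame(otu_a = a, otu_b = b, mic = mic, r = r,
                  low_support = FALSE, p = q, q = q,
                  relationship = ifelse(q < 0.05, "positive", NA),
                  stringsAsFactors = FALSE)
  class(d) <- c("association_set", "data.frame")
  d
}
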