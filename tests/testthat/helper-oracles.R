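# Independently coded brute-force oracles. These deliberately use naive
# loops/enumeration rather than the package's vectorized implementations.

# step-up BH from the definition: q_i = min over thresholds t >= rank(p_i)
# of m * p_(t) / t
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) m * ps[j] / j, numeric(1))
    q[i] <- min(cand, 1)
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# upper-tail hypergeometric by direct enumeration of draw counts
oracle_hyper_upper <- function(k, size_a, size_b, n_universe) {
  tot <- choose(n_universe, size_b)
  s <- 0
  for (i in seq(k, min(size_a, size_b))) {
    s <- s + choose(size_a, i) * choose(n_universe - size_a, size_b - i)
  }
  s / tot
}

# exact k nearest neighbors by full scan with id tie-break
oracle_knn1 <- function(query, ref, ids) {
  out <- character(nrow(query))
  for (i in seq_len(nrow(query))) {
    d <- sqrt(rowSums((ref - matrix(query[i, ], nrow(ref), ncol(ref),
                                    byrow = TRUE))^2))
    best <- which(d == min(d))
    out[i] <- sort(ids[best])[1]
  }
  out
}

# per-type degree centrality and transitivity by triple enumeration
oracle_centrality <- function(adj, labels) {
  types <- sort(unique(labels))
  n <- nrow(adj)
  res <- list()
  for (t in types) {
    int <- which(labels == t); ext <- which(labels != t)
    touched <- 0
    for (v in ext) if (any(adj[v, int])) touched <- touched + 1
    dc <- if (length(ext)) touched / length(ext) else NA_real_
    tri <- 0; triples <- 0
    if (length(int) >= 3) {
      for (a in int) for (b in int) for (cc in int) {
        if (a < b && adj[a, b]) {
          if (cc != a && cc != b && adj[a, cc] && adj[b, cc] && b < cc)
            tri <- tri + 1
        }
      }
      # connected triples: center node with two distinct neighbors in type
      for (a in int) {
        deg <- sum(adj[a, int])
        triples <- triples + choose(deg, 2)
      }
    }
    cc_val <- if (triples > 0) 3 * tri / triples else 0
    res[[t]] <- c(dc = dc, cc = cc_val)
  }
  do.call(rbind, res)
}

# gene activity raw sums by interval double loop (0-based half-open logic)
oracle_activity <- function(counts, peak_start0, peak_end0, gene_start0,
                            gene_end0, strand, upstream = 2000) {
  n_gene <- length(gene_start0)
  out <- matrix(0, n_gene, ncol(counts))
  for (g in seq_len(n_gene)) {
    lo <- if (strand[g] == "+") gene_start0[g] - upstream else gene_start0[g]
    hi <- if (strand[g] == "+") gene_end0[g] else gene_end0[g] + upstream
    for (p in seq_len(nrow(counts))) {
      if (peak_start0[p] < hi && peak_end0[p] > lo)
        out[g, ] <- out[g, ] + counts[p, ]
    }
  }
  out
}

# rank-sum test, normal approximation with tie correction and continuity
# correction (recoded from the definition)
oracle_ranksum_p <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sig2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- w - mu
  z <- z - sign(z) * 0.5
  z <- z / sqrt(sig2)
  2 * stats::pnorm(-abs(z))
}

# Jensen-Shannon divergence recoded directly (base-2)
oracle_jsd <- function(p, q) {
  p <- unname(p); q <- unname(q)
  m <- (p + q) / 2
  f <- function(a, b) {
    s <- 0
    for (i in seq_along(a)) if (a[i] > 0) s <- s + a[i] * log2(a[i] / b[i])
    s
  }
  (f(p, m) + f(q, m)) / 2
}

# nearest-rank percentile by sorting
oracle_nearest_rank <- function(x, frac) {
  sort(x)[ceiling(frac * length(x))]
}
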