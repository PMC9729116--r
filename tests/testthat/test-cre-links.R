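test_that("candidate pairing follows nearest-TSS with window and tie rules", {
  ann <- gene_annotation(c("gB", "gA", "gC"), "chr1",
                         c(10000, 30000, 400000),
                         c(15000, 35000, 405000), c("+", "+", "+"))
  mk_peaks <- function(mid) {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(mid - 49, mid + 50))
    names(gr) <- sprintf("p%02d", seq_along(mid))
    gr
  }
  # p01 equidistant between gB (TSS 10001) and gA (TSS 30001): tie -> gA
  # (lexicographically first), flagged
  peaks <- mk_peaks(c(20001, 650002, 12000))
  pairs <- candidate_pairs(peaks, ann)
  expect_identical(pairs$gene[pairs$peak == "p01"], "gA")
  expect_true("p01" %in% attr(pairs, "ties"))
  # p02 is 250,001 bp past gC's TSS -> excluded
  expect_false("p02" %in% pairs$peak)
  expect_identical(pairs$gene[pairs$peak == "p03"], "gB")
  # restricting the expressed universe reroutes the peak
  pairs2 <- candidate_pairs(peaks, ann, expressed_genes = c("gB", "gC"))
  expect_identical(pairs2$gene[pairs2$peak == "p01"], "gB")
  expect_error(candidate_pairs(peaks, ann[0]), "empty")
})

test_that("candidate pairing equals brute-force distance minimization", {
  set.seed(31)
  n_gene <- 25; n_peak <- 120
  gs <- sort(sample.int(2e6, n_gene))
  ann <- gene_annotation(sprintf("g%02d", 1:n_gene), "chrX", gs, gs + 2000,
                         sample(c("+", "-"), n_gene, TRUE))
  pos <- sample.int(2e6, n_peak)
  peaks <- GenomicRanges::GRanges("chrX", IRanges::IRanges(pos, pos + 99))
  names(peaks) <- sprintf("p%03d", 1:n_peak)
  pairs <- candidate_pairs(peaks, ann, window = 250000)
  tss <- tss_positions(ann)
  mid <- floor((GenomicRanges::start(peaks) + GenomicRanges::end(peaks)) / 2)
  for (i in seq_len(n_peak)) {
    d <- abs(tss - mid[i])
    if (min(d) > 250000) {
      expect_false(names(peaks)[i] %in% pairs$peak)
    } else {
      row <- pairs[pairs$peak == names(peaks)[i], ]
      expect_identical(row$gene, sort(names(d)[d == min(d)])[1])
      expect_equal(row$distance, unname(min(d)))
    }
  }
})

test_that("link correlation matches cor.test and handles edge cases", {
  set.seed(32)
  n <- 20
  P <- named_mat(rpois(10 * n, 50), 10, n, rpre = "p", cpre = "pb")
  G <- named_mat(rnorm(10 * n, 100, 20), 10, n, rpre = "g", cpre = "pb")
  pairs <- data.frame(peak = rownames(P), gene = rownames(G),
                      distance = 1000)
  lk <- link_correlation(P, G, pairs)
  for (i in seq_len(nrow(lk))) {
    ct <- stats::cor.test(P[lk$peak[i], ], G[lk$gene[i], ])
    expect_equal(lk$pcc[i], unname(ct$estimate), tolerance = 1e-10)
    expect_equal(lk$p[i], ct$p.value, tolerance = 1e-10)
  }
  # identical vectors: r = 1, p -> 0
  P2 <- rbind(P, gdup = G[1, ])
  rownames(P2)[11] <- "pdup"
  lk2 <- link_correlation(P2, G, data.frame(peak = "pdup", gene = "g001",
                                            distance = 0))
  expect_equal(lk2$pcc, 1)
  expect_equal(lk2$p, 0)
  # constructed exact-zero correlation: p = 1
  x <- c(1, 2, 3, 4, 5)
  y <- c(1, -1, 0, 1, -1)
  y <- resid(lm(y ~ x))  # orthogonal to x
  P3 <- matrix(x, 1, 5, dimnames = list("px", paste0("pb", 1:5)))
  G3 <- matrix(y + 10, 1, 5, dimnames = list("gy", paste0("pb", 1:5)))
  lk3 <- link_correlation(P3, G3, data.frame(peak = "px", gene = "gy",
                                             distance = 0))
  expect_equal(lk3$p, 1, tolerance = 1e-12)
  # zero-variance profile dropped with warning
  G4 <- G; G4["g001", ] <- 7
  expect_warning(lk4 <- link_correlation(P, G4, pairs), "zero-variance")
  expect_false("g001" %in% lk4$gene)
  expect_error(link_correlation(P[, 1:2], G[, 1:2], pairs), "at least 3")
})

test_that("BH adjustment equals the brute-force step-up on small inputs", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(33)
  for (m in c(2, 5, 8, 12)) {
    p <- runif(m)
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
    # permutation stability: q follows its p
    perm <- sample(m)
    expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("link filtering applies strict thresholds after global BH", {
  links <- data.frame(peak = paste0("p", 1:4), gene = paste0("g", 1:4),
                      distance = 0,
                      pcc = c(0.2, 0.5, -0.3, 0.9),
                      p = c(1e-4, 1e-4, 0.2, 1e-6))
  out <- filter_links(links)
  expect_false(out$passes[1])   # |PCC| exactly 0.2 -> excluded
  expect_true(out$passes[2])
  expect_false(out$passes[3])   # q above threshold after BH
  q_exact <- bh_adjust(links$p)
  expect_equal(out$q, q_exact)
  # q exactly at alpha is excluded
  links2 <- data.frame(peak = "p", gene = "g", distance = 0, pcc = 0.5,
                       p = 0.05)
  expect_false(filter_links(links2)$passes)
})

test_that("GPC threshold is the nearest-rank 95th percentile, strict >", {
  links <- data.frame(peak = sprintf("p%04d", 1:5050),
                      gene = rep(sprintf("g%03d", 1:100), times = 1:100),
                      distance = 0, pcc = 0.5, p = 1e-8)
  links$passes <- TRUE
  gp <- gpc_genes(links)
  expect_equal(gp$threshold, 95)
  expect_length(gp$gpc_genes, 5)
  expect_setequal(gp$gpc_genes, sprintf("g%03d", 96:100))
  expect_equal(gp$threshold,
               oracle_nearest_rank(as.numeric(gp$counts), 0.95))
  # equal counts: empty GPC set
  links_eq <- data.frame(peak = sprintf("p%d", 1:30),
                         gene = rep(sprintf("g%d", 1:10), each = 3),
                         distance = 0, pcc = 0.5, p = 1e-8, passes = TRUE)
  expect_length(gpc_genes(links_eq)$gpc_genes, 0)
  # gene-order invariance
  gp2 <- gpc_genes(links[sample(nrow(links)), ])
  expect_identical(gp$gpc_genes, gp2$gpc_genes)
  expect_error(gpc_genes(data.frame(gene = "g", passes = FALSE)),
               "no passing")
})

test_that("hypergeometric overlap matches exhaustive enumeration", {
  u <- sprintf("x%02d", 1:10)
  res <- hypergeom_overlap(u[1:5], u[1:5], u)
  expect_equal(res$overlap, 5)
  expect_equal(res$p_one_sided, 1 / choose(10, 5), tolerance = 1e-12)
  # A = universe: p = 1 for any B
  expect_equal(hypergeom_overlap(u, u[3:7], u)$p_one_sided, 1)
  # all small instances against the enumeration oracle
  set.seed(34)
  for (rep in 1:25) {
    N <- sample(4:12, 1)
    un <- sprintf("y%02d", seq_len(N))
    A <- sample(un, sample.int(N, 1))
    B <- sample(un, sample.int(N, 1))
    k <- length(intersect(A, B))
    got <- hypergeom_overlap(A, B, un)
    expect_equal(got$p_one_sided,
                 oracle_hyper_upper(k, length(A), length(B), N),
                 tolerance = 1e-12)
    expect_equal(got$p_two_sided, min(1, 2 * got$p_one_sided))
  }
  expect_error(hypergeom_overlap(c("a", "zz"), u[1:2], u), "subsets")
})

test_that("link recovery improves with planted link strength", {
  rec <- sapply(c(0.3, 0.45, 0.6), function(ls) {
    mean(sapply(1:3, function(s)
      evaluate_link_recovery(small_cfg(s, link_strength = ls),
                             n_pb = 150)$recall))
  })
  expect_true(all(diff(rec) >= -0.02))
})
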