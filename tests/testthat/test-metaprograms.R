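test_that("rank-1 NMF recovers the planted loading vector", {
  set.seed(3)
  w <- abs(rnorm(40)); h <- abs(rnorm(25))
  A <- outer(w, h)
  dimnames(A) <- list(sprintf("g%03d", 1:40), sprintf("c%03d", 1:25))
  fit <- nmf_factorize(A, 1)
  cosine <- sum(fit$W[, 1] * w) / sqrt(sum(fit$W^2) * sum(w^2))
  expect_gte(cosine, 0.99)
})

test_that("degenerate NMF inputs are rejected or skipped", {
  A <- named_mat(0, 10, 8)
  expect_error(nmf_factorize(A, 2), "all-zero")
  Er <- named_mat(-abs(rnorm(80)), 10, 8)  # all-negative -> clips to zero
  expect_warning(run_sample_nmf(Er, rownames(Er), k = 2), "all-zero")
  expect_warning(
    out <- run_sample_nmf(named_mat(abs(rnorm(30)), 10, 3),
                          sprintf("g%03d", 1:10), k = 6),
    "fewer than")
  expect_length(out, 0)
})

test_that("per-sample NMF programs align with planted signatures", {
  # at the default cohort, some program's top 30 must cover >= 20 of each
  # planted 30-gene signature, over 3 seeds
  recovered <- sapply(c(42, 7, 11), function(s) {
    mp <- if (s == 42) cached("mp_eval_42",
                              evaluate_metaprogram_recovery(
                                sim_config(seed = 42)))
      else evaluate_metaprogram_recovery(sim_config(seed = s))
    min(vapply(mp$truth$signatures, function(g)
      max(vapply(mp$programs, function(p)
        length(intersect(p$genes, g)), integer(1))), integer(1)))
  })
  expect_true(all(recovered >= 20))
})

test_that("program scoring delegates to signature scoring", {
  sim <- default_sim()
  tr <- transform_expression(sim$mat)
  p1 <- structure(list(sample_id = "S01", factor = 1,
                       genes = rownames(tr$Er)[5],
                       weights = 1), class = "nmf_program")
  sc <- score_programs(tr$Er, list(p1))
  expect_equal(unname(sc[, 1]), unname(tr$Er[5, ]))
  expect_identical(sc, score_programs(tr$Er, list(p1)))  # reproducible
})

test_that("identical programs merge first; merging is order-invariant", {
  set.seed(5)
  Er <- named_mat(rnorm(200 * 60), 200, 60)
  mk <- function(genes, w, s, f) structure(
    list(sample_id = s, factor = f, genes = genes,
         weights = sort(w, decreasing = TRUE)), class = "nmf_program")
  gA <- rownames(Er)[1:30]; gB <- rownames(Er)[31:60]
  programs <- list(mk(gA, runif(30), "S1", 1),
                   mk(gA, runif(30), "S2", 1),   # duplicate gene set
                   mk(gB, runif(30), "S1", 2),
                   mk(rownames(Er)[61:90], runif(30), "S2", 2))
  sc <- score_programs(Er, programs)
  metas <- cluster_and_merge(programs, sc, n_meta = 3)
  cl <- metas$clusters
  expect_identical(cl[["S1.f1"]], cl[["S2.f1"]])  # identical sets merged
  # permutation invariance of the merged gene sets
  perm <- c(3, 1, 4, 2)
  metas2 <- cluster_and_merge(programs[perm], sc, n_meta = 3)
  sets1 <- lapply(metaprogram_signatures(metas), sort)
  sets2 <- lapply(metaprogram_signatures(metas2), sort)
  expect_setequal(unname(vapply(sets1, paste, character(1), collapse = ",")),
                  unname(vapply(sets2, paste, character(1), collapse = ",")))
})

test_that("absent genes contribute zero weight to the consensus", {
  Er <- named_mat(abs(rnorm(40 * 20)), 40, 20)
  mk <- function(genes, w, s) structure(
    list(sample_id = s, factor = 1, genes = genes, weights = w),
    class = "nmf_program")
  # gene g001 has weight 10 in one of two member programs -> average 5;
  # g002 has weight 6 in both -> average 6 and must outrank g001
  pA <- mk(c("g001", "g002"), c(10, 6), "S1")
  pB <- mk(c("g002", "g003"), c(6, 1), "S2")
  sc <- matrix(rnorm(40), 20, 2,
               dimnames = list(colnames(Er), c("S1.f1", "S2.f1")))
  sc[, 2] <- sc[, 1] + rnorm(20, 0, 0.01)  # force the two into one cluster
  metas <- cluster_and_merge(list(pA, pB), sc, n_meta = 1, top_n = 2)
  m <- metas$metaprograms[[1]]
  expect_identical(m$genes[1], "g002")
  expect_equal(m$weights[1], 6)
  expect_equal(m$weights[2], 5)  # 10 averaged with implicit 0
})

test_that("two-state synthetic programs split cleanly at n_meta = 2", {
  cfg <- small_cfg(8, states = c("OPC-like", "AC-like"),
                   frac_noise_cells = 0, frac_true_links = 0.02)
  sim <- gen_expression(cfg)
  tr <- transform_expression(sim$mat)
  od <- suppressWarnings(select_overdispersed_genes(sim$mat, 1000))
  programs <- list()
  for (sm in unique(sim$mat$cells$sample_id)) {
    cs <- sim$mat$cells$cell_id[sim$mat$cells$sample_id == sm]
    programs <- c(programs,
                  run_sample_nmf(tr$Er[, cs], od, k = 2, sample_id = sm))
  }
  sc <- score_programs(tr$Er, programs)
  metas <- cluster_and_merge(programs, sc, n_meta = 2)
  ov <- sapply(metaprogram_signatures(metas), function(m)
    sapply(sim$truth$signatures, function(g) length(intersect(m, g))))
  # each metaprogram matches exactly one planted state
  expect_true(all(apply(ov, 2, function(x) sort(x)[1] <= 2 && max(x) >= 15)))
})

test_that("metaprograms are robust to the chosen number of NMF factors", {
  # consensus gene sets from k in {4, 6, 8} stay similar (Jaccard >= 0.6)
  # on the default cohort
  mp <- cached("mp_eval_42",
               evaluate_metaprogram_recovery(sim_config(seed = 42)))
  run_k <- function(k) {
    programs <- list()
    for (sm in unique(mp$mat$cells$sample_id)) {
      cs <- mp$mat$cells$cell_id[mp$mat$cells$sample_id == sm]
      programs <- c(programs,
                    run_sample_nmf(mp$transforms$Er[, cs], mp$overdispersed,
                                   k = k, sample_id = sm))
    }
    sc <- score_programs(mp$transforms$Er, programs)
    metaprogram_signatures(
      cluster_and_merge(programs, sc,
                        n_meta = length(mp$truth$signatures)))
  }
  ref <- metaprogram_signatures(mp$metaprograms)
  for (k in c(4, 8)) {
    alt <- run_k(k)
    jac <- vapply(ref, function(r)
      max(vapply(alt, function(a)
        length(intersect(r, a)) / length(union(r, a)), numeric(1))),
      numeric(1))
    expect_gte(min(jac), 0.6)
  }
})

test_that("cross-set matching recovers identity and permutations", {
  sim <- default_sim()
  tr <- transform_expression(sim$mat)
  mk_meta <- function(genes, nm) list(name = nm, genes = genes,
                                      weights = rep(1, length(genes)),
                                      members = nm)
  sets <- lapply(seq_along(sim$truth$signatures), function(i)
    mk_meta(sim$truth$signatures[[i]], paste0("M", i)))
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  A <- structure(list(metaprograms = sets), class = "metaprogram_set")
  # identical sets: identity pairing at correlation 1
  m <- crossmodal_match(A, A, tr$Er)
  expect_equal(unname(diag(m$correlation)), rep(1, length(sets)))
  expect_identical(m$pairing$a, m$pairing$b)
  # permuted duplicate set: pairing recovers the permutation
  perm <- c(3, 1, 2, 5, 4)
  B <- structure(list(metaprograms = stats::setNames(
    lapply(seq_along(perm), function(i)
      mk_meta(sets[[perm[i]]]$genes, paste0("N", i))),
    paste0("N", seq_along(perm)))), class = "metaprogram_set")
  m2 <- crossmodal_match(A, B, tr$Er)
  expect_identical(m2$pairing$b[match(paste0("M", perm), m2$pairing$a)],
                   paste0("N", seq_along(perm)))
})

test_that("fresh- and frozen-derived metaprograms pair by planted state", {
  cfg <- small_cfg(12)
  mp <- evaluate_metaprogram_recovery(cfg, qc = FALSE)
  fresh <- mp$mat$cells$protocol == "fresh"
  run_side <- function(sel) {
    programs <- list()
    for (sm in unique(mp$mat$cells$sample_id[sel])) {
      cs <- mp$mat$cells$cell_id[mp$mat$cells$sample_id == sm]
      programs <- c(programs,
                    run_sample_nmf(mp$transforms$Er[, cs],
                                   suppressWarnings(
                                     select_overdispersed_genes(mp$mat, 1000)),
                                   k = 6, sample_id = sm))
    }
    sc <- score_programs(mp$transforms$Er, programs)
    cluster_and_merge(programs, sc, n_meta = length(cfg$states))
  }
  ma <- run_side(fresh); mb <- run_side(!fresh)
  m <- crossmodal_match(ma, mb, mp$transforms$Er)
  sig <- mp$truth$signatures
  map_a <- map_side <- function(metas) vapply(metaprogram_signatures(metas),
    function(g) names(which.max(vapply(sig, function(s)
      length(intersect(g, s)), integer(1)))), character(1))
  la <- map_side(ma); lb <- map_side(mb)
  agree <- la[m$pairing$a] == lb[m$pairing$b]
  expect_gte(mean(agree), 0.8)
})

test_that("the gene-prefix exclusion removes ribosomal-style genes", {
  set.seed(60)
  Er <- matrix(abs(rnorm(40 * 30)), 40, 30,
               dimnames = list(c(sprintf("RPL%02d", 1:10),
                                 sprintf("g%03d", 1:30)),
                               sprintf("c%03d", 1:30)))
  pr <- run_sample_nmf(Er, rownames(Er), k = 2, sample_id = "S1",
                       exclude_prefix = "^RP[SL]")
  expect_false(any(grepl("^RPL", unlist(lapply(pr, `[[`, "genes")))))
})
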