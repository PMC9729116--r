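make_qc_fixture <- function() {
  # 12 cells crossing every QC rule boundary; 2500 genes so the fresh
  # detected-gene rule has room on both sides
  n_genes <- 2500
  tpm <- matrix(0, n_genes, 12,
                dimnames = list(sprintf("g%04d", 1:n_genes),
                                sprintf("c%02d", 1:12)))
  hk <- rownames(tpm)[1:5]
  fill <- function(j, n_detected, hk_tpm) {
    tpm[seq_len(n_detected), j] <<- 5
    tpm[1:5, j] <<- hk_tpm
  }
  # fresh cells: detected genes 1999 / 2000 / 2500; hk E boundary
  fill(1, 1999, 100)   # removed: < 2000 genes
  fill(2, 2000, 100)   # kept (boundary)
  fill(3, 2500, 100)   # kept
  fill(4, 2500, 10 * (2^2.5 - 1))  # hk E exactly 2.5 -> kept
  fill(5, 2500, 10 * (2^2.4 - 1))  # hk E 2.4 -> removed
  fill(6, 2500, 100)   # kept
  # frozen cells: detected genes 999 / 1000; alignment 0.39 / 0.4
  for (j in 7:12) fill(j, 1200, 100)
  tpm[, 7] <- 0; tpm[seq_len(999), 7] <- 5    # removed: < 1000
  tpm[, 8] <- 0; tpm[seq_len(1000), 8] <- 5   # kept (boundary)
  cells <- data.frame(
    cell_id = colnames(tpm),
    sample_id = "S1",
    protocol = rep(c("fresh", "frozen"), each = 6),
    alignment_rate = c(rep(0.9, 6), 0.9, 0.9, 0.39, 0.4, 0.9, 0.9),
    stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = rownames(tpm),
                      housekeeping = rownames(tpm) %in% hk,
                      stringsAsFactors = FALSE)
  expression_matrix(tpm, cells, genes)
}

test_that("cell QC applies all four rules with strict-removal boundaries", {
  mat <- make_qc_fixture()
  out <- qc_filter_cells(mat)
  kept <- out$cells$cell_id
  expect_false("c01" %in% kept)  # 1999 detected genes
  expect_true("c02" %in% kept)   # exactly 2000
  expect_true("c04" %in% kept)   # hk E exactly 2.5
  expect_false("c05" %in% kept)  # hk E 2.4
  expect_false("c07" %in% kept)  # frozen, 999 genes
  expect_true("c08" %in% kept)   # frozen, exactly 1000
  expect_false("c09" %in% kept)  # alignment 0.39
  expect_true("c10" %in% kept)   # alignment exactly 0.4
  expect_identical(nrow(out$tpm), nrow(mat$tpm))  # gene set unchanged
  # idempotence
  again <- qc_filter_cells(out)
  expect_identical(out$tpm, again$tpm)
  # frozen cell without alignment rate errors
  mat2 <- mat
  mat2$cells$alignment_rate[7] <- NA
  expect_error(qc_filter_cells(mat2), "alignment_rate")
})

test_that("gene QC keeps genes with TPM > 16 in at least 10 cells", {
  set.seed(1)
  tpm <- named_mat(runif(50 * 30, 0, 40), 50, 30)
  tpm["g001", ] <- c(rep(20, 10), rep(0, 20))  # exactly 10 cells -> kept
  tpm["g002", ] <- 16                          # never > 16 -> removed
  tpm["g003", ] <- c(rep(20, 9), rep(1, 21))   # 9 cells -> removed
  mat <- tiny_expr(tpm)
  out <- qc_filter_genes(mat)
  expect_true("g001" %in% rownames(out$tpm))
  expect_false("g002" %in% rownames(out$tpm))
  expect_false("g003" %in% rownames(out$tpm))
  # brute-force recount oracle over the whole fixture
  keep_oracle <- apply(tpm, 1, function(x) sum(x > 16) >= 10)
  expect_identical(rownames(out$tpm), rownames(tpm)[keep_oracle])
  expect_identical(qc_filter_genes(out)$tpm, out$tpm)  # idempotent
})

test_that("expression transforms follow their closed forms", {
  tpm <- named_mat(c(0, 5, 10, 5, 30, 5, 70, 5), 2, 4)  # column-major
  tr <- transform_expression(tiny_expr(tpm))
  expect_equal(tr$E["g001", "c001"], 0)             # TPM 0 -> E 0
  expect_equal(tr$E["g001", "c002"], 1)             # TPM 10 -> log2(2)
  expect_equal(unname(tr$Ea["g002"]), log2(5 + 1))
  expect_equal(tr$Er["g002", ], rep(0, 4),
               ignore_attr = TRUE)                   # constant row centered
  expect_lt(max(abs(rowSums(tr$Er))), 1e-9 * ncol(tpm))
  expect_error(tiny_expr(named_mat(numeric(0), 2, 0)),
               "rownames and cell colnames")
})

test_that("over-dispersion ranking puts a high-variance gene first", {
  set.seed(7)
  base <- 2^rnorm(60, 5, 0.1)
  tpm <- t(vapply(base, function(m) m * 2^rnorm(80, 0, 0.3), numeric(80)))
  tpm[1, ] <- base[1] * 2^rnorm(80, 0, 1.5)  # same mean, 5x the log-sd
  dimnames(tpm) <- list(sprintf("g%03d", 1:60), sprintf("c%03d", 1:80))
  od <- suppressWarnings(select_overdispersed_genes(tiny_expr(tpm), 60))
  expect_identical(od[1], "g001")
  # requesting every gene returns every usable gene
  expect_setequal(od, rownames(tpm))
})

test_that("signature scoring is the mean relative expression of the set", {
  sim <- default_sim()
  tr <- transform_expression(sim$mat)
  # constant matrix scores 0
  const <- tr$Er * 0
  expect_equal(as.numeric(score_signature(const, rownames(const)[1:5])),
               rep(0, ncol(const)))
  # single-gene set equals that row
  g <- rownames(tr$Er)[100]
  expect_equal(as.numeric(score_signature(tr$Er, g)),
               unname(tr$Er[g, ]))
  expect_error(score_signature(tr$Er, "absent_gene"), "no signature gene")
  # planted-state cells score their own signature above the others
  sc <- score_signatures(tr$Er, sim$truth$signatures)
  st <- sim$truth$cell_states[rownames(sc)]
  signal <- st %in% colnames(sc)
  own_best <- colnames(sc)[max.col(sc[signal, ])] == st[signal]
  expect_gte(mean(own_best), 0.95)
})

test_that("state assignment uses the 0.2 threshold and first-column ties", {
  sc <- rbind(c(0.19, 0.10), c(0.5, 0.3), c(0.5, 0.5), c(-1, 0.25))
  dimnames(sc) <- list(paste0("c", 1:4), c("A", "B"))
  lab <- assign_state(sc)
  expect_equal(unname(lab), c("score_too_low", "A", "A", "B"),
               ignore_attr = TRUE)
  expect_identical(attr(lab, "ties"), "c3")
  # boundary: exactly 0.2 is assigned
  b <- matrix(c(0.2, 0), 1, 2, dimnames = list("c1", c("A", "B")))
  expect_identical(unname(assign_state(b)[1]), "A")
})

test_that("marker detection matches a brute-force oracle on a small fixture", {
  set.seed(11)
  n_g <- 20; n_c <- 60
  E <- named_mat(abs(rnorm(n_g * n_c, 1, 0.5)), n_g, n_c)
  labels <- rep(c("A", "B", "C"), each = 20)
  E["g001", labels == "A"] <- E["g001", labels == "A"] + 2   # marker of A
  E["g002", labels == "B"] <- E["g002", labels == "B"] + 2   # marker of B
  E["g003", ] <- 0
  E["g003", which(labels == "A")[1:5]] <- 3  # detected in 25% of A: excluded
  res <- detect_markers(E, labels, min_frac = 0.3, min_lfc = 0.5,
                        alpha = 0.05)
  expect_true(any(res$label == "A" & res$gene == "g001"))
  expect_true(any(res$label == "B" & res$gene == "g002"))
  expect_false(any(res$gene == "g003"))
  # independent brute-force application of the three rules
  oracle <- list()
  n_tests <- 0
  cand_all <- list()
  for (l in c("A", "B", "C")) {
    ing <- labels == l
    for (g in rownames(E)) {
      if (mean(E[g, ing] > 0) >= 0.3 &&
          mean(E[g, ing]) - mean(E[g, !ing]) >= 0.5) {
        cand_all[[paste(l, g)]] <- oracle_ranksum_p(E[g, ing], E[g, !ing])
      }
    }
  }
  m <- length(cand_all)
  keep <- names(cand_all)[vapply(cand_all, function(p) min(p * m, 1) < 0.05,
                                 logical(1))]
  expect_setequal(paste(res$label, res$gene), keep)
})

test_that("small-group labels are skipped with a warning", {
  E <- named_mat(rnorm(10 * 12), 10, 12)
  labels <- c(rep("A", 10), "B", "B")
  expect_warning(detect_markers(E, labels), "fewer than 3")
})

test_that("TAM classification is argmax of the two scores with tie fallback", {
  Er <- named_mat(0, 4, 3)
  Er[1:2, 1] <- 1    # microglia markers up in cell 1
  Er[3:4, 2] <- 1    # macrophage markers up in cell 2
  lab <- classify_tams(Er, microglia_set = c("g001", "g002"),
                       macrophage_set = c("g003", "g004"))
  expect_identical(unname(lab), c("microglia", "macrophage", "unclassified"))
})

test_that("TAM classification separates planted populations", {
  cfg <- small_cfg(9, states = c("microglia", "macrophage"),
                   frac_noise_cells = 0, frac_true_links = 0.01)
  sim <- gen_expression(cfg)
  tr <- transform_expression(sim$mat)
  lab <- classify_tams(tr$Er, sim$truth$signatures$microglia,
                       sim$truth$signatures$macrophage)
  truth <- sim$truth$cell_states[names(lab)]
  expect_gte(mean(lab == truth), 0.95)
})
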