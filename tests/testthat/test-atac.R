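make_atac_fixture <- function() {
  set.seed(21)
  counts <- matrix(rpois(40 * 20, 2), 40, 20,
                   dimnames = list(sprintf("p%03d", 1:40),
                                   sprintf("n%03d", 1:20)))
  peaks <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq(1, by = 1000, length.out = 40), width = 400))
  names(peaks) <- rownames(counts)
  qc <- data.frame(nucleus_id = colnames(counts),
                   peak_region_fragments = 5000,
                   pct_reads_in_peaks = 40, blacklist_ratio = 0.001,
                   nucleosome_signal = 1, tss_enrichment = 8,
                   stringsAsFactors = FALSE)
  list(mat = peak_matrix(counts, peaks), qc = qc)
}

test_that("snATAC QC boundaries follow the printed thresholds", {
  fx <- make_atac_fixture()
  qc <- fx$qc
  qc$tss_enrichment[1] <- 4        # exactly 4 -> removed (strict >)
  qc$peak_region_fragments[2] <- 1500   # inclusive -> kept
  qc$peak_region_fragments[3] <- 15000  # inclusive -> kept
  qc$peak_region_fragments[4] <- 1499   # removed
  qc$pct_reads_in_peaks[5] <- 15   # exactly 15 -> removed (strict >)
  qc$blacklist_ratio[6] <- 0.02    # exactly 0.02 -> removed (strict <)
  qc$nucleosome_signal[7] <- 2     # exactly 2 -> removed (strict <)
  out <- qc_filter_atac(fx$mat, qc, min_peaks = 10, min_nuclei_per_peak = 1)
  kept <- colnames(out$counts)
  expect_false(any(c("n001", "n004", "n005", "n006", "n007") %in% kept))
  expect_true(all(c("n002", "n003", "n008") %in% kept))
  # manual rule application over the full fixture
  manual <- with(qc, peak_region_fragments >= 1500 &
                   peak_region_fragments <= 15000 & pct_reads_in_peaks > 15 &
                   blacklist_ratio < 0.02 & nucleosome_signal < 2 &
                   tss_enrichment > 4)
  expect_identical(kept, colnames(fx$mat$counts)[manual])
  # idempotence and nucleus-coverage error
  expect_identical(as.matrix(qc_filter_atac(out, qc, min_peaks = 10,
                                            min_nuclei_per_peak = 1)$counts),
                   as.matrix(out$counts))
  expect_error(qc_filter_atac(fx$mat, qc[-1, ]), "cover")
})

test_that("low-coverage nuclei and rare peaks are removed", {
  fx <- make_atac_fixture()
  counts <- as.matrix(fx$mat$counts)
  counts[, 1] <- 0; counts[1:5, 1] <- 1   # 5 detected peaks < 200 rule
  counts[2, ] <- 0; counts[2, 1:3] <- 1   # peak in 3 nuclei < 10 rule
  mat <- peak_matrix(counts, fx$mat$peaks)
  out <- qc_filter_atac(mat, fx$qc, min_peaks = 10, min_nuclei_per_peak = 10)
  expect_false("n001" %in% colnames(out$counts))
  expect_false("p002" %in% rownames(out$counts))
})

test_that("TF-IDF embedding is deterministic and respects proportionality", {
  fx <- make_atac_fixture()
  counts <- as.matrix(fx$mat$counts)
  counts[, 2] <- counts[, 1]  # identical profile and depth
  mat <- peak_matrix(counts, fx$mat$peaks)
  emb <- tfidf_lsi(mat, d = 5, top_frac = 1)
  expect_lt(max(abs(emb$coords[1, ] - emb$coords[2, ])), 1e-8)
  emb2 <- tfidf_lsi(mat, d = 5, top_frac = 1)
  expect_identical(emb$coords, emb2$coords)  # sign convention fixed
  # peak reordering leaves nucleus geometry unchanged
  perm <- sample(nrow(counts))
  mat_p <- peak_matrix(counts[perm, ], fx$mat$peaks[perm])
  emb_p <- tfidf_lsi(mat_p, d = 5, top_frac = 1)
  expect_equal(as.matrix(dist(emb$coords)), as.matrix(dist(emb_p$coords)),
               tolerance = 1e-8)
  expect_error(tfidf_lsi(mat, d = 100), "exceeds")
})

test_that("depth-confounded components are flagged and dropped", {
  set.seed(4)
  # nucleus depth spans 30x; every peak scales with depth
  depth <- exp(seq(log(1), log(30), length.out = 40))
  base <- runif(60, 0.5, 2)
  counts <- matrix(rpois(60 * 40, outer(base, depth)), 60, 40,
                   dimnames = list(sprintf("p%03d", 1:60),
                                   sprintf("n%03d", 1:40)))
  peaks <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq(1, by = 1000, length.out = 60), width = 400))
  names(peaks) <- rownames(counts)
  emb <- tfidf_lsi(peak_matrix(counts, peaks), d = 10, top_frac = 1)
  expect_true(1 %in% emb$dropped)
  expect_gt(abs(emb$depth_cor[1]), 0.5)
})

test_that("gene activity equals the brute-force interval-overlap sum", {
  # 5 genes / 8 peaks with promoter-boundary cases (0-based half-open)
  gene_s0 <- c(10000, 30000, 50000, 70000, 90000)
  gene_e0 <- gene_s0 + 5000
  strand <- c("+", "-", "+", "-", "+")
  ann <- gene_annotation(sprintf("G%d", 1:5), "chr1", gene_s0, gene_e0,
                         strand)
  peak_s0 <- c(9999, 7999, 7998, 36999, 12000, 48500, 69999, 200000)
  peak_e0 <- peak_s0 + c(1, 1, 1, 1, 500, 3000, 1, 100)
  counts <- matrix(1:16, 8, 2,
                   dimnames = list(sprintf("p%d", 1:8), c("n1", "n2")))
  peaks <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(peak_s0 + 1, peak_e0))
  names(peaks) <- rownames(counts)
  act <- gene_activity(peak_matrix(counts, peaks), ann)
  raw <- as.matrix(act$raw)
  # p1: 1 bp upstream of +-strand TSS of G1 -> included
  expect_equal(raw["G1", "n1"], counts["p1", "n1"] + counts["p5", "n1"])
  # p2 starts exactly 2,001 bp upstream -> excluded; p3 overlaps the
  # 2 kb window by its last base -> included? (ends at 7999 = window start
  # 8000 is not reached, so excluded too)
  expect_false(any(raw["G1", ] ==
                     counts["p1", ] + counts["p2", ] + counts["p5", ]))
  # p4: 1 bp inside the downstream 2 kb window of --strand G2
  expect_equal(raw["G2", "n2"], counts["p4", "n2"])
  # p6 entirely inside G3's body
  expect_equal(raw["G3", ], counts["p6", ], ignore_attr = TRUE)
  # full brute-force oracle
  oracle <- oracle_activity(counts, peak_s0, peak_e0, gene_s0, gene_e0,
                            strand)
  expect_equal(unname(raw), unname(oracle))
})

test_that("unknown chromosomes are skipped with a warning", {
  ann <- gene_annotation("G1", "chr1", 1000, 2000, "+")
  counts <- matrix(c(3, 4), 1, 2,
                   dimnames = list("p1", c("n1", "n2")))
  peaks <- GenomicRanges::GRanges("chrUn", IRanges::IRanges(1500, 1600))
  names(peaks) <- "p1"
  expect_warning(act <- gene_activity(peak_matrix(counts, peaks), ann),
                 "unknown")
  expect_equal(sum(act$raw), 0)
})

test_that("activity conserves totals when gene regions tile all peaks", {
  set.seed(9)
  # genes laid far apart; peaks strictly inside bodies
  gene_s0 <- seq(0, by = 50000, length.out = 4)
  ann <- gene_annotation(sprintf("G%d", 1:4), "chr1", gene_s0,
                         gene_s0 + 10000, rep("+", 4))
  peak_pos <- unlist(lapply(gene_s0, function(s) s + c(3000, 6000)))
  counts <- matrix(rpois(8 * 5, 4), 8, 5,
                   dimnames = list(sprintf("p%d", 1:8),
                                   sprintf("n%d", 1:5)))
  peaks <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(peak_pos + 1,
                                                   peak_pos + 200))
  names(peaks) <- rownames(counts)
  act <- gene_activity(peak_matrix(counts, peaks), ann)
  expect_equal(Matrix::colSums(act$raw), Matrix::colSums(counts),
               ignore_attr = TRUE)
})
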