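#' Construct a peak x nucleus accessibility matrix
#'
#' @param counts nonnegative integer matrix (sparse or dense), peaks x nuclei,
#'   with unique peak rownames and nucleus colnames.
#' @param peaks a `GRanges` of peak intervals (one per row of `counts`).
#'   On-disk BED interchange is 0-based half-open; in memory the usual 1-based
#'   `GRanges` convention is used.
#' @return object of class `peak_matrix`.
#' @export
peak_matrix <- function(counts, peaks) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("peak_matrix: counts needs peak rownames and nucleus colnames")
  if (anyDuplicated(rownames(counts)))
    stop("peak_matrix: peak ids must be unique")
  if (length(peaks) != nrow(counts))
    stop("peak_matrix: one interval per peak required")
  if (any(GenomicRanges::width(peaks) < 1))
    stop("peak_matrix: malformed peak intervals")
  if (any(counts@x < 0)) stop("peak_matrix: negative counts")
  names(peaks) <- rownames(counts)
  structure(list(counts = counts, peaks = peaks,
                 nuclei = colnames(counts)),
            class = "peak_matrix")
}

#' @export
print.peak_matrix <- function(x, ...) {
  cat("peak_matrix:", nrow(x$counts), "peaks x", ncol(x$counts), "nuclei\n")
  invisible(x)
}

#' Build a gene annotation on genomic coordinates
#'
#' @param gene_id,chrom,start,end,strand vectors describing gene bodies;
#'   `start`/`end` are 0-based half-open (BED convention) and converted to the
#'   1-based `GRanges` representation internally.
#' @return `GRanges` with `gene_id` metadata; the TSS is the 5' end
#'   (strand-aware).
#' @export
gene_annotation <- function(gene_id, chrom, start, end, strand) {
  stopifnot(all(start < end), all(strand %in% c("+", "-")))
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start + 1L, end),
                               strand = strand)
  S4Vectors::mcols(gr)$gene_id <- gene_id
  names(gr) <- gene_id
  gr
}

#' Strand-aware TSS positions (1-based) of a gene annotation
#' @param annotation `GRanges` gene annotation.
#' @return named integer vector of TSS coordinates.
#' @export
tss_positions <- function(annotation) {
  pos <- ifelse(as.character(GenomicRanges::strand(annotation)) == "+",
                GenomicRanges::start(annotation),
                GenomicRanges::end(annotation))
  stats::setNames(as.integer(pos), names(annotation))
}

#' Quality-control filter for snATAC nuclei and peaks
#'
#' Nuclei are kept iff: detected peaks >= `min_peaks`; peak-region fragments
#' within `[frag_lo, frag_hi]` (inclusive); percent reads in peaks >
#' `min_pct`; blacklist ratio < `max_blacklist`; nucleosome signal <
#' `max_nucleosome`; TSS enrichment > `min_tss`. Peaks detected in fewer than
#' `min_nuclei_per_peak` surviving nuclei are then removed. Per-rule removal
#' counts are attached as `"qc_log"`.
#'
#' @param mat a [peak_matrix()].
#' @param qc data.frame with one row per nucleus (`nucleus_id`,
#'   `peak_region_fragments`, `pct_reads_in_peaks`, `blacklist_ratio`,
#'   `nucleosome_signal`, `tss_enrichment`).
#' @param min_peaks,min_nuclei_per_peak,frag_lo,frag_hi,min_pct,max_blacklist,max_nucleosome,min_tss
#'   thresholds (defaults 200, 10, 1500, 15000, 15, 0.02, 2, 4).
#' @return the filtered [peak_matrix()].
#' @export
qc_filter_atac <- function(mat, qc, min_peaks = 200, min_nuclei_per_peak = 10,
                           frag_lo = 1500, frag_hi = 15000, min_pct = 15,
                           max_blacklist = 0.02, max_nucleosome = 2,
                           min_tss = 4) {
  stopifnot(inherits(mat, "peak_matrix"))
  if (!all(mat$nuclei %in% qc$nucleus_id))
    stop("qc_filter_atac: QC table does not cover all nuclei")
  qc <- qc[match(mat$nuclei, qc$nucleus_id), , drop = FALSE]
  detected <- Matrix::colSums(mat$counts > 0)
  rules <- cbind(low_peaks = detected < min_peaks,
                 fragments = qc$peak_region_fragments < frag_lo |
                   qc$peak_region_fragments > frag_hi,
                 pct_reads = !(qc$pct_reads_in_peaks > min_pct),
                 blacklist = !(qc$blacklist_ratio < max_blacklist),
                 nucleosome = !(qc$nucleosome_signal < max_nucleosome),
                 tss = !(qc$tss_enrichment > min_tss))
  keep_nuc <- rowSums(rules) == 0
  counts <- mat$counts[, keep_nuc, drop = FALSE]
  keep_peak <- Matrix::rowSums(counts > 0) >= min_nuclei_per_peak
  out <- peak_matrix(counts[keep_peak, , drop = FALSE],
                     mat$peaks[keep_peak])
  attr(out, "qc_log") <- c(colSums(rules),
                           peaks_removed = sum(!keep_peak))
  out
}

## Truncated SVD of a (possibly sparse) matrix X via the eigendecomposition
## of the smaller Gram matrix; returns U (rows of X), d, V (cols of X).
truncated_svd <- function(X, d) {
  n <- ncol(X); m <- nrow(X)
  if (d > min(n, m)) stop("truncated_svd: d exceeds matrix rank bound")
  if (n <= m) {
    G <- as.matrix(Matrix::crossprod(X))
    eg <- eigen(G, symmetric = TRUE)
    dv <- sqrt(pmax(eg$values[seq_len(d)], 0))
    V <- eg$vectors[, seq_len(d), drop = FALSE]
    U <- as.matrix(X %*% V) %*% diag(1 / pmax(dv, 1e-12), d)
  } else {
    G <- as.matrix(Matrix::tcrossprod(X))
    eg <- eigen(G, symmetric = TRUE)
    dv <- sqrt(pmax(eg$values[seq_len(d)], 0))
    U <- eg$vectors[, seq_len(d), drop = FALSE]
    V <- as.matrix(Matrix::crossprod(X, U)) %*% diag(1 / pmax(dv, 1e-12), d)
  }
  ## sign convention: the largest-|loading| row entry of each component is
  ## positive (deterministic across runs and row orderings)
  for (j in seq_len(d)) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) { U[, j] <- -U[, j]; V[, j] <- -V[, j] }
  }
  list(u = U, d = dv, v = V)
}

#' TF-IDF normalization and LSI embedding of a peak matrix
#'
#' Restricts to the top 25% of peaks by total accessibility, computes
#' `ln(1 + (count / nucleus_total) * (n_nuclei / peak_nucleus_count) * scale)`
#' and embeds nuclei with a truncated SVD (`d` components, nucleus
#' coordinates scaled by the singular values). Components whose absolute
#' Pearson correlation with log total counts exceeds `drop_depth_corr` are
#' dropped (sequencing-depth components; typically the first).
#'
#' @param mat a filtered [peak_matrix()].
#' @param d number of SVD components to compute.
#' @param scale TF-IDF scale factor.
#' @param drop_depth_corr absolute correlation threshold for dropping
#'   depth-associated components.
#' @param top_frac fraction of peaks retained as features (by total counts).
#' @return list of class `lsi_embedding`: `coords` (nucleus x kept components),
#'   `kept`, `dropped`, `depth_cor`, `features`.
#' @export
tfidf_lsi <- function(mat, d = 30, scale = 1e4, drop_depth_corr = 0.5,
                      top_frac = 0.25) {
  stopifnot(inherits(mat, "peak_matrix"))
  totals <- Matrix::rowSums(mat$counts)
  ord <- order(-totals, rownames(mat$counts))
  n_feat <- max(2L, ceiling(top_frac * nrow(mat$counts)))
  feats <- rownames(mat$counts)[ord[seq_len(n_feat)]]
  X <- mat$counts[feats, , drop = FALSE]
  nuc_tot <- Matrix::colSums(X)
  if (any(nuc_tot == 0))
    stop("tfidf_lsi: nuclei with zero counts in the feature set")
  nbin <- Matrix::rowSums(X > 0)
  keep <- nbin > 0
  X <- X[keep, , drop = FALSE]; feats <- feats[keep]; nbin <- nbin[keep]
  if (d > min(dim(X))) stop("tfidf_lsi: d exceeds matrix dimensions")
  Xt <- methods::as(X, "TsparseMatrix")
  val <- log1p((Xt@x / nuc_tot[Xt@j + 1L]) *
                 (ncol(X) / nbin[Xt@i + 1L]) * scale)
  V <- Matrix::sparseMatrix(i = Xt@i + 1L, j = Xt@j + 1L, x = val,
                            dims = dim(X), dimnames = dimnames(X))
  sv <- truncated_svd(V, d)
  coords <- sv$v %*% diag(sv$d, d)
  rownames(coords) <- colnames(X)
  depth <- log(Matrix::colSums(mat$counts))
  dc <- apply(coords, 2, function(z) {
    if (stats::sd(z) == 0 || stats::sd(depth) == 0) return(0)
    stats::cor(z, depth)
  })
  kept <- which(abs(dc) <= drop_depth_corr)
  dropped <- setdiff(seq_len(d), kept)
  structure(list(coords = coords[, kept, drop = FALSE],
                 kept = kept, dropped = dropped, depth_cor = dc,
                 features = feats),
            class = "lsi_embedding")
}

#' Gene activity scores from peak counts
#'
#' A peak counts toward a gene iff its interval overlaps the gene body
#' extended `upstream` bp beyond the strand-aware TSS (half-open overlap,
#' nonempty intersection); peaks overlapping several gene regions count
#' toward each. Per-nucleus totals are scaled to the median total, then
#' `log(1 + x)` transformed.
#'
#' @param mat a [peak_matrix()].
#' @param annotation a [gene_annotation()] `GRanges`.
#' @param upstream promoter extension upstream of the TSS (bp, default 2000).
#' @return list with `activity` (normalized log activities, genes x nuclei)
#'   and `raw` (summed counts).
#' @export
gene_activity <- function(mat, annotation, upstream = 2000) {
  stopifnot(inherits(mat, "peak_matrix"))
  known <- as.character(GenomicRanges::seqnames(mat$peaks)) %in%
    as.character(GenomicRanges::seqnames(annotation))
  if (!all(known)) {
    warning("gene_activity: ", sum(!known),
            " peak(s) on unknown chromosomes skipped")
  }
  region <- suppressWarnings(
    GenomicRanges::trim(GenomicRanges::resize(
      annotation, GenomicRanges::width(annotation) + upstream, fix = "end")))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(region, mat$peaks[known],
                                ignore.strand = TRUE))
  peak_idx <- which(known)[S4Vectors::subjectHits(hits)]
  O <- Matrix::sparseMatrix(i = S4Vectors::queryHits(hits), j = peak_idx,
                            x = 1,
                            dims = c(length(annotation), nrow(mat$counts)),
                            dimnames = list(names(annotation),
                                            rownames(mat$counts)))
  raw <- O %*% mat$counts
  tot <- Matrix::colSums(raw)
  med <- stats::median(tot)
  scl <- ifelse(tot > 0, med / tot, 0)
  act <- raw %*% Matrix::Diagonal(x = scl)
  act@x <- log1p(act@x)
  colnames(act) <- colnames(raw)
  list(activity = act, raw = raw)
}
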