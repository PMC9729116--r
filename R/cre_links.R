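#' Candidate peak-gene pairs by the nearest-TSS rule
#'
#' Each peak is paired with the minimum-|midpoint - TSS| gene on its
#' chromosome among `expressed_genes` (the genes actually profiled by RNA),
#' provided that distance is at most `window`. Distance ties break by gene id
#' order (tied peaks are recorded in the `"ties"` attribute); peaks with no
#' gene in range are excluded.
#'
#' @param peaks `GRanges` of peaks (names = peak ids).
#' @param annotation a [gene_annotation()] `GRanges`.
#' @param expressed_genes genes eligible as link targets; defaults to all
#'   annotated genes.
#' @param window maximum distance in bp (default 250000).
#' @return data.frame with columns peak, gene, distance.
#' @export
candidate_pairs <- function(peaks, annotation, expressed_genes = NULL,
                            window = 250000) {
  if (length(annotation) == 0) stop("candidate_pairs: empty annotation")
  if (is.null(expressed_genes)) expressed_genes <- names(annotation)
  ann <- annotation[names(annotation) %in% expressed_genes]
  if (length(ann) == 0) stop("candidate_pairs: no expressed annotated gene")
  tss <- tss_positions(ann)
  tss_chr <- as.character(GenomicRanges::seqnames(ann))
  mid <- floor((GenomicRanges::start(peaks) + GenomicRanges::end(peaks)) / 2)
  pk_chr <- as.character(GenomicRanges::seqnames(peaks))
  out <- vector("list", length(peaks))
  ties <- character(0)
  for (ch in unique(pk_chr)) {
    gsel <- which(tss_chr == ch)
    if (!length(gsel)) next
    gt <- tss[gsel]
    ord <- order(gt, names(gt))
    gt <- gt[ord]
    psel <- which(pk_chr == ch)
    pos <- findInterval(mid[psel], gt)
    for (ii in seq_along(psel)) {
      i <- psel[ii]
      lo <- pos[ii]; hi <- lo + 1L
      cand <- c(if (lo >= 1) lo, if (hi <= length(gt)) hi)
      ## step outwards over equal TSS coordinates to catch all ties
      dmin <- min(abs(gt[cand] - mid[i]))
      if (dmin > window) next
      at_min <- which(abs(gt - mid[i]) == dmin)
      gene <- sort(names(gt)[at_min])[1]
      if (length(at_min) > 1) ties <- c(ties, names(peaks)[i])
      out[[i]] <- data.frame(peak = names(peaks)[i], gene = gene,
                             distance = dmin, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(peak = character(0), gene = character(0),
                      distance = numeric(0))
  rownames(res) <- NULL
  attr(res, "ties") <- unique(ties)
  res
}

#' Pearson correlation tests for candidate peak-gene pairs over pseudobulks
#'
#' For each pair, the Pearson correlation between peak CPM and gene TPM
#' across pseudobulks, with a two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom.
#' Zero-variance vectors make the correlation undefined; such pairs are
#' dropped with a warning.
#'
#' @param peak_cpm peaks x pseudobulks matrix.
#' @param gene_tpm genes x pseudobulks matrix.
#' @param pairs data.frame from [candidate_pairs()].
#' @return data.frame peak, gene, distance, pcc, p.
#' @export
link_correlation <- function(peak_cpm, gene_tpm, pairs) {
  n <- ncol(peak_cpm)
  if (n < 3) stop("link_correlation: need at least 3 pseudobulks")
  stopifnot(ncol(gene_tpm) == n)
  keep <- pairs$peak %in% rownames(peak_cpm) &
    pairs$gene %in% rownames(gene_tpm)
  pairs <- pairs[keep, , drop = FALSE]
  P <- peak_cpm[pairs$peak, , drop = FALSE]
  G <- gene_tpm[pairs$gene, , drop = FALSE]
  P <- P - rowMeans(P); G <- G - rowMeans(G)
  sp <- sqrt(rowSums(P^2)); sg <- sqrt(rowSums(G^2))
  ok <- sp > 0 & sg > 0
  if (!all(ok))
    warning("link_correlation: dropping ", sum(!ok),
            " pair(s) with zero-variance profiles")
  r <- rowSums(P[ok, , drop = FALSE] * G[ok, , drop = FALSE]) /
    (sp[ok] * sg[ok])
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) == 1] <- 0
  out <- pairs[ok, , drop = FALSE]
  out$pcc <- r
  out$p <- p
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement; each q-value follows its p-value
#' under permutation of the input.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("bh_adjust: p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Flag and retain high-confidence peak-gene links
#'
#' q-values are computed over *all* tested pairs (before any correlation
#' filtering); a link passes iff `|PCC| > min_abs_r` (strict) and
#' `q < alpha` (strict).
#'
#' @param links data.frame from [link_correlation()].
#' @param min_abs_r,alpha thresholds (defaults 0.2, 0.05).
#' @return `links` with added `q` and `passes` columns; the retained subset
#'   is in the `"passing"` attribute and counts in `"counts"`.
#' @export
filter_links <- function(links, min_abs_r = 0.2, alpha = 0.05) {
  links$q <- bh_adjust(links$p)
  links$passes <- abs(links$pcc) > min_abs_r & links$q < alpha
  attr(links, "passing") <- links[links$passes, , drop = FALSE]
  attr(links, "counts") <- c(tested = nrow(links),
                             passing = sum(links$passes))
  links
}

#' Genes with predictive chromatin (GPCs)
#'
#' Counts passing links per gene (over genes with at least one passing
#' link), takes the nearest-rank `(1 - top_frac)` percentile of the count
#' distribution as the threshold, and calls GPC every gene whose count is
#' strictly greater than the threshold.
#'
#' @param links output of [filter_links()] (or any data.frame with `gene`
#'   and `passes`).
#' @param top_frac upper tail defining the threshold (default 0.05).
#' @return list of class `gpc_set`: `counts` (named per-gene), `threshold`,
#'   `gpc_genes`.
#' @export
gpc_genes <- function(links, top_frac = 0.05) {
  passing <- links[links$passes, , drop = FALSE]
  if (nrow(passing) == 0) stop("gpc_genes: no passing link")
  counts <- table(passing$gene)
  counts <- stats::setNames(as.integer(counts), names(counts))
  srt <- sort(counts)
  rank <- ceiling((1 - top_frac) * length(srt))
  thr <- as.numeric(srt[rank])
  structure(list(counts = counts, threshold = thr,
                 gpc_genes = sort(names(counts)[counts > thr])),
            class = "gpc_set")
}

#' @export
print.gpc_set <- function(x, ...) {
  cat("gpc_set:", length(x$gpc_genes), "GPC genes ( >", x$threshold,
      "linked CREs; top-5% nearest-rank threshold over",
      length(x$counts), "linked genes )\n")
  invisible(x)
}

#' Hypergeometric overlap test between two gene sets
#'
#' Over-representation tail of the overlap of `setA` and `setB` drawn from
#' `universe`; the two-sided variant doubles the smaller tail and caps at 1.
#'
#' @param setA,setB character vectors, subsets of `universe`.
#' @param universe character vector of all eligible genes.
#' @return list with `overlap`, `p_one_sided` (over-representation),
#'   `p_two_sided`.
#' @export
hypergeom_overlap <- function(setA, setB, universe) {
  setA <- unique(setA); setB <- unique(setB); universe <- unique(universe)
  if (!all(setA %in% universe) || !all(setB %in% universe))
    stop("hypergeom_overlap: sets must be subsets of the universe")
  k <- length(intersect(setA, setB))
  m <- length(setA); nB <- length(setB); N <- length(universe)
  p_upper <- stats::phyper(k - 1, m, N - m, nB, lower.tail = FALSE)
  list(overlap = k,
       p_one_sided = p_upper,
       p_two_sided = min(1, 2 * p_upper))
}
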