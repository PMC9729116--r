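#' Construct an expression matrix container
#'
#' Holds a nonnegative gene x cell TPM matrix plus per-cell and per-gene
#' metadata. Cell metadata must carry `cell_id`, `sample_id` and
#' `protocol` (`"fresh"` or `"frozen"`); an `alignment_rate` column in
#' `[0, 1]` is required for frozen cells before QC. Gene metadata carries a
#' `housekeeping` flag used by the fresh-cell QC rule.
#'
#' @param tpm numeric matrix, genes x cells, with unique dimnames.
#' @param cells data.frame of per-cell metadata (one row per column of `tpm`).
#' @param genes optional data.frame of per-gene metadata; a default with an
#'   all-FALSE housekeeping flag is built when omitted.
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(tpm, cells, genes = NULL) {
  tpm <- as.matrix(tpm)
  if (is.null(rownames(tpm)) || is.null(colnames(tpm)))
    stop("expression_matrix: tpm needs gene rownames and cell colnames")
  if (anyDuplicated(rownames(tpm)) || anyDuplicated(colnames(tpm)))
    stop("expression_matrix: gene and cell identifiers must be unique")
  if (any(tpm < 0)) stop("expression_matrix: negative TPM values")
  if (!all(c("cell_id", "sample_id", "protocol") %in% names(cells)))
    stop("expression_matrix: cell metadata needs cell_id, sample_id, protocol")
  if (nrow(cells) != ncol(tpm))
    stop("expression_matrix: metadata row count must equal cell count")
  if (!all(cells$cell_id == colnames(tpm)))
    cells <- cells[match(colnames(tpm), cells$cell_id), , drop = FALSE]
  if (anyNA(cells$cell_id))
    stop("expression_matrix: metadata does not cover all cells")
  if (!all(cells$protocol %in% c("fresh", "frozen")))
    stop("expression_matrix: protocol must be 'fresh' or 'frozen'")
  if (is.null(genes))
    genes <- data.frame(gene_id = rownames(tpm), housekeeping = FALSE,
                        stringsAsFactors = FALSE)
  if (!all(genes$gene_id == rownames(tpm)))
    genes <- genes[match(rownames(tpm), genes$gene_id), , drop = FALSE]
  rownames(cells) <- NULL
  rownames(genes) <- NULL
  structure(list(tpm = tpm, cells = cells, genes = genes),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$tpm), "genes x", ncol(x$tpm), "cells (",
      sum(x$cells$protocol == "fresh"), "fresh /",
      sum(x$cells$protocol == "frozen"), "frozen )\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$tpm)

subset_cells <- function(mat, keep) {
  expression_matrix(mat$tpm[, keep, drop = FALSE],
                    mat$cells[keep, , drop = FALSE], mat$genes)
}

#' Quality-control filter for cells
#'
#' Fresh cells are kept iff they detect at least `fresh_min_genes` genes
#' (TPM > 0) and their mean housekeeping expression `E = log2(TPM/10 + 1)` is
#' at least `fresh_min_hk`. Frozen cells are kept iff they detect at least
#' `frozen_min_genes` genes and their alignment rate is at least
#' `frozen_min_align`. All thresholds are strict-removal: a cell exactly at a
#' threshold is kept. The per-rule removal counts are attached as the
#' `"qc_log"` attribute.
#'
#' @param mat an [expression_matrix()].
#' @param housekeeping_set optional character vector of housekeeping genes;
#'   defaults to the genes flagged in the gene metadata.
#' @param fresh_min_genes,fresh_min_hk,frozen_min_genes,frozen_min_align
#'   QC thresholds (defaults 2000, 2.5, 1000, 0.4).
#' @return the filtered [expression_matrix()] (gene set unchanged).
#' @export
qc_filter_cells <- function(mat, housekeeping_set = NULL,
                            fresh_min_genes = 2000, fresh_min_hk = 2.5,
                            frozen_min_genes = 1000, frozen_min_align = 0.4) {
  stopifnot(inherits(mat, "expression_matrix"))
  if (is.null(housekeeping_set))
    housekeeping_set <- mat$genes$gene_id[mat$genes$housekeeping]
  hk <- intersect(housekeeping_set, rownames(mat$tpm))
  fresh <- mat$cells$protocol == "fresh"
  if (any(fresh) && length(hk) == 0)
    stop("qc_filter_cells: no housekeeping genes present for fresh-cell QC")
  frozen <- !fresh
  if (any(frozen)) {
    ar <- mat$cells$alignment_rate[frozen]
    if (is.null(ar) || anyNA(ar))
      stop("qc_filter_cells: frozen cells require an alignment_rate")
  }
  detected <- colSums(mat$tpm > 0)
  keep <- rep(TRUE, ncol(mat$tpm))
  log <- c(fresh_low_genes = 0L, fresh_low_hk = 0L,
           frozen_low_genes = 0L, frozen_low_align = 0L)
  if (any(fresh)) {
    hkE <- colMeans(log2(mat$tpm[hk, fresh, drop = FALSE] / 10 + 1))
    f1 <- detected[fresh] < fresh_min_genes
    f2 <- hkE < fresh_min_hk
    log["fresh_low_genes"] <- sum(f1)
    log["fresh_low_hk"] <- sum(f2)
    keep[fresh] <- !(f1 | f2)
  }
  if (any(frozen)) {
    f1 <- detected[frozen] < frozen_min_genes
    f2 <- mat$cells$alignment_rate[frozen] < frozen_min_align
    log["frozen_low_genes"] <- sum(f1)
    log["frozen_low_align"] <- sum(f2)
    keep[frozen] <- !(f1 | f2)
  }
  out <- subset_cells(mat, keep)
  attr(out, "qc_log") <- log
  out
}

#' Quality-control filter for genes
#'
#' A gene is kept iff it reaches TPM > 16 in at least 10 cells (strict `>` on
#' expression, strict `<` removal on the cell count, as printed).
#'
#' @param mat an [expression_matrix()] (cell QC already applied).
#' @param min_tpm,min_cells the rule's two constants.
#' @return the filtered [expression_matrix()].
#' @export
qc_filter_genes <- function(mat, min_tpm = 16, min_cells = 10) {
  stopifnot(inherits(mat, "expression_matrix"))
  keep <- rowSums(mat$tpm > min_tpm) >= min_cells
  out <- expression_matrix(mat$tpm[keep, , drop = FALSE], mat$cells,
                           mat$genes[keep, , drop = FALSE])
  attr(out, "qc_log") <- c(genes_removed = sum(!keep))
  out
}

#' Expression transforms: E, Ea and relative expression Er
#'
#' Computes `E = log2(TPM/10 + 1)` per gene and cell, the per-gene aggregate
#' `Ea = log2(mean(TPM) + 1)`, and the centered relative expression
#' `Er = E - rowMeans(E)`.
#'
#' @param mat an [expression_matrix()] with at least one gene and cell.
#' @return list of class `expr_transforms` with matrices `E`, `Er` and the
#'   vector `Ea`.
#' @export
transform_expression <- function(mat) {
  stopifnot(inherits(mat, "expression_matrix"))
  if (nrow(mat$tpm) == 0 || ncol(mat$tpm) == 0)
    stop("transform_expression: empty matrix")
  E <- log2(mat$tpm / 10 + 1)
  Ea <- log2(rowMeans(mat$tpm) + 1)
  Er <- E - rowMeans(E)
  structure(list(E = E, Er = Er, Ea = Ea), class = "expr_transforms")
}

#' Rank genes by over-dispersion
#'
#' Regresses per-gene log variance of `E` on a quadratic in per-gene log mean
#' and ranks genes by the (positive) residual, returning the top `n`.
#' Zero-variance genes are never selected; ties break by gene id.
#'
#' @param mat an [expression_matrix()].
#' @param n number of genes to return (all, with a warning, when fewer are
#'   usable).
#' @return character vector of gene ids, most over-dispersed first.
#' @export
select_overdispersed_genes <- function(mat, n = 10000) {
  stopifnot(inherits(mat, "expression_matrix"))
  E <- log2(mat$tpm / 10 + 1)
  mu <- rowMeans(E)
  v <- apply(E, 1, stats::var)
  usable <- which(v > 0 & mu > 0)
  if (length(usable) < n) {
    warning("select_overdispersed_genes: only ", length(usable),
            " usable genes for n = ", n)
    n <- length(usable)
  }
  lm_ <- stats::lm(lv ~ stats::poly(lm, 2),
                   data = data.frame(lv = log(v[usable]),
                                     lm = log(mu[usable])))
  resid <- stats::residuals(lm_)
  ids <- rownames(mat$tpm)[usable]
  ord <- order(-resid, ids)
  ids[ord][seq_len(n)]
}

#' Score cells with a gene signature
#'
#' The score of a cell is the mean relative expression (`Er`) over the
#' signature genes present in the matrix. Genes missing from the matrix are
#' reported in the `"missing_genes"` attribute.
#'
#' @param Er relative-expression matrix (genes x cells) or an
#'   `expr_transforms` object.
#' @param gene_set character vector of signature genes.
#' @return named numeric vector of per-cell scores.
#' @export
score_signature <- function(Er, gene_set) {
  if (inherits(Er, "expr_transforms")) Er <- Er$Er
  found <- intersect(gene_set, rownames(Er))
  if (length(found) == 0)
    stop("score_signature: no signature gene present in the matrix")
  s <- colMeans(Er[found, , drop = FALSE])
  attr(s, "missing_genes") <- setdiff(gene_set, found)
  s
}

#' Score cells with several signatures at once
#'
#' @param Er relative-expression matrix or `expr_transforms`.
#' @param signatures named list of gene sets.
#' @return cell x signature numeric matrix.
#' @export
score_signatures <- function(Er, signatures) {
  if (inherits(Er, "expr_transforms")) Er <- Er$Er
  stopifnot(length(signatures) >= 1, !is.null(names(signatures)))
  out <- vapply(signatures, function(g) as.numeric(score_signature(Er, g)),
                numeric(ncol(Er)))
  if (is.null(dim(out))) out <- matrix(out, nrow = ncol(Er))
  dimnames(out) <- list(colnames(Er), names(signatures))
  out
}

#' Assign cells to the highest-scoring signature
#'
#' A cell is labeled with the argmax signature when its maximum score is at
#' least `threshold`, and `"score_too_low"` otherwise. Exact ties break by
#' signature column order; tied cells are listed in the `"ties"` attribute.
#'
#' @param scores cell x signature score matrix.
#' @param threshold minimum score for assignment (default 0.2).
#' @return named character vector of labels.
#' @export
assign_state <- function(scores, threshold = 0.2) {
  scores <- as.matrix(scores)
  if (ncol(scores) < 1) stop("assign_state: need at least one signature")
  if (is.null(colnames(scores)))
    colnames(scores) <- paste0("sig", seq_len(ncol(scores)))
  best <- max.col(scores, ties.method = "first")
  mx <- scores[cbind(seq_len(nrow(scores)), best)]
  lab <- ifelse(mx >= threshold, colnames(scores)[best], "score_too_low")
  names(lab) <- rownames(scores)
  tie <- rowSums(scores == mx) > 1 & mx >= threshold
  attr(lab, "ties") <- rownames(scores)[tie]
  lab
}

#' Detect differential markers per label
#'
#' For each label, tests genes detected (`E > 0`) in at least `min_frac` of
#' the in-group cells whose in-group minus out-group mean `E` is at least
#' `min_lfc`, with a two-sided Wilcoxon rank-sum test, Bonferroni-corrected
#' over all tested (gene, label) combinations; markers require adjusted
#' p < `alpha`. The snATAC variant on gene activities uses
#' `min_frac = 0.2, min_lfc = 0.1`.
#'
#' @param E expression (or gene-activity) matrix, genes x cells.
#' @param labels per-cell labels (length = ncol(E)).
#' @param min_frac,min_lfc,alpha the three marker rules.
#' @return data.frame with columns label, gene, frac_in, lfc, p, p_adj.
#' @export
detect_markers <- function(E, labels, min_frac = 0.3, min_lfc = 0.5,
                           alpha = 0.05) {
  E <- as.matrix(E)
  stopifnot(length(labels) == ncol(E))
  tab <- table(labels)
  if (length(tab) < 2) stop("detect_markers: need at least two labels")
  use_labels <- names(tab)[tab >= 3]
  for (l in setdiff(names(tab), use_labels))
    warning("detect_markers: label '", l, "' has fewer than 3 cells; skipped")
  rows <- list()
  for (l in use_labels) {
    ing <- labels == l
    frac_in <- rowMeans(E[, ing, drop = FALSE] > 0)
    lfc <- rowMeans(E[, ing, drop = FALSE]) -
      rowMeans(E[, !ing, drop = FALSE])
    cand <- which(frac_in >= min_frac & lfc >= min_lfc)
    if (!length(cand)) next
    p <- vapply(cand, function(i) {
      stats::wilcox.test(E[i, ing], E[i, !ing], exact = FALSE)$p.value
    }, numeric(1))
    rows[[l]] <- data.frame(label = l, gene = rownames(E)[cand],
                            frac_in = frac_in[cand], lfc = lfc[cand],
                            p = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(label = character(0), gene = character(0),
                      frac_in = numeric(0), lfc = numeric(0),
                      p = numeric(0), p_adj = numeric(0)))
  out$p_adj <- pmin(out$p * nrow(out), 1)  # Bonferroni
  out <- out[out$p_adj < alpha, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify tumor-associated myeloid cells as microglia or macrophages
#'
#' Scores every cell with a microglia and a macrophage signature
#' (mean relative expression) and labels it with the larger score; exact ties
#' give `"unclassified"`.
#'
#' @param Er relative-expression matrix or `expr_transforms`.
#' @param microglia_set,macrophage_set marker gene sets.
#' @return named character vector of labels.
#' @export
classify_tams <- function(Er, microglia_set, macrophage_set) {
  if (inherits(Er, "expr_transforms")) Er <- Er$Er
  smic <- score_signature(Er, microglia_set)
  smac <- score_signature(Er, macrophage_set)
  lab <- ifelse(smic > smac, "microglia",
                ifelse(smac > smic, "macrophage", "unclassified"))
  names(lab) <- colnames(Er)
  lab
}
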