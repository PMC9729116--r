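#' Remove per-sample offsets from an embedding
#'
#' Subtracts each sample's mean coordinate per dimension (a linear batch
#' correction of the embedding). With a single sample this equals global
#' centering.
#'
#' @param embedding numeric matrix, observations x dimensions.
#' @param sample_ids per-row sample labels.
#' @return centered matrix of the same shape.
#' @export
center_by_sample <- function(embedding, sample_ids) {
  embedding <- as.matrix(embedding)
  stopifnot(length(sample_ids) == nrow(embedding))
  for (s in unique(sample_ids)) {
    i <- sample_ids == s
    embedding[i, ] <- sweep(embedding[i, , drop = FALSE], 2,
                            colMeans(embedding[i, , drop = FALSE]))
  }
  embedding
}

l2_normalize_rows <- function(M) {
  nrm <- sqrt(rowSums(M^2))
  nrm[nrm == 0] <- 1
  M / nrm
}

#' Joint diagonal-CCA embedding of expression and gene activity
#'
#' Both modalities are restricted to `shared_genes`, standardized per gene
#' (mean 0, sd 1 across their own cells; zero-variance genes dropped with a
#' warning), and the cross-product of the standardized matrices is reduced by
#' truncated SVD. The two singular-vector sides give the nucleus and cell
#' coordinates in the joint space; rows are L2-normalized.
#'
#' Canonical dimensions without true cross-modality covariance ("noise"
#' pairs) let strong modality-private factors leak into the matched cells
#' and corrupt downstream pseudobulk correlations. With
#' `dim_select = TRUE` the singular-value spectrum is truncated at its tail
#' plateau (dimensions whose singular value exceeds `scree_margin` times
#' the median of the lower half of the spectrum are kept, at least
#' `min_dims`).
#'
#' @param rna_E expression matrix (genes x cells), typically `E`.
#' @param atac_activity gene-activity matrix (genes x nuclei).
#' @param shared_genes genes used for the cross-product.
#' @param d joint dimensions computed (default 20).
#' @param dim_select truncate the spectrum at its noise plateau.
#' @param scree_margin multiple of the tail-plateau median defining a
#'   "real" dimension.
#' @param min_dims lower bound on retained dimensions when selecting.
#' @return list of class `joint_embedding` with `rna_coords`, `atac_coords`
#'   (unit-norm rows), `singular_values`, `kept_dims`, `genes_used`.
#' @export
joint_cca <- function(rna_E, atac_activity, shared_genes, d = 20,
                      dim_select = FALSE, scree_margin = 1.25,
                      min_dims = 2L) {
  rna_E <- as.matrix(rna_E); atac_activity <- as.matrix(atac_activity)
  shared_genes <- intersect(intersect(shared_genes, rownames(rna_E)),
                            rownames(atac_activity))
  Xr <- rna_E[shared_genes, , drop = FALSE]
  Xa <- atac_activity[shared_genes, , drop = FALSE]
  sd_r <- apply(Xr, 1, stats::sd); sd_a <- apply(Xa, 1, stats::sd)
  usable <- sd_r > 0 & sd_a > 0
  if (!all(usable))
    warning("joint_cca: dropping ", sum(!usable), " zero-variance gene(s)")
  if (sum(usable) < d)
    stop("joint_cca: fewer than d usable shared genes")
  Xr <- (Xr[usable, , drop = FALSE] - rowMeans(Xr[usable, , drop = FALSE])) /
    sd_r[usable]
  Xa <- (Xa[usable, , drop = FALSE] - rowMeans(Xa[usable, , drop = FALSE])) /
    sd_a[usable]
  g <- nrow(Xr)
  product_svd <- function(Xa, Xr, d) {
    if (g < min(ncol(Xa), ncol(Xr))) {
      ## product-form SVD of C = t(Xa) %*% Xr without materializing C:
      ## thin QR of both cell-loading matrices, then SVD of the small
      ## g x g core (cost O(n g^2) instead of O(n^3))
      qa <- qr(t(Xa)); qb <- qr(t(Xr))
      M <- qr.R(qa) %*% t(qr.R(qb))
      sv0 <- svd(M, nu = d, nv = d)
      U <- qr.Q(qa) %*% sv0$u
      V <- qr.Q(qb) %*% sv0$v
      for (j in seq_len(d)) {
        i <- which.max(abs(U[, j]))
        if (U[i, j] < 0) { U[, j] <- -U[, j]; V[, j] <- -V[, j] }
      }
      list(u = U, d = sv0$d[seq_len(d)], v = V)
    } else {
      C <- crossprod(Xa, Xr)  # nuclei x cells
      truncated_svd(C, d)
    }
  }
  sv <- product_svd(Xa, Xr, d)
  kept <- seq_len(d)
  if (dim_select) {
    plateau <- stats::median(sv$d[seq(floor(d / 2) + 1, d)])
    kept <- which(sv$d > scree_margin * plateau)
    if (length(kept) < min_dims) kept <- seq_len(min_dims)
    kept <- seq_len(max(kept))  # keep a contiguous leading block
  }
  atac <- l2_normalize_rows(sv$u[, kept, drop = FALSE])
  rna <- l2_normalize_rows(sv$v[, kept, drop = FALSE])
  rownames(atac) <- colnames(atac_activity)
  rownames(rna) <- colnames(rna_E)
  structure(list(rna_coords = rna, atac_coords = atac,
                 singular_values = sv$d, kept_dims = kept,
                 genes_used = rownames(Xr)),
            class = "joint_embedding")
}

## exact nearest neighbors with deterministic id-order tie-breaking;
## returns for each row of `query` the indices of the k nearest `ref` rows
knn_index <- function(query, ref, k, exclude_self = FALSE) {
  q2 <- rowSums(query^2); r2 <- rowSums(ref^2)
  D2 <- outer(q2, r2, "+") - 2 * query %*% t(ref)
  D2[D2 < 0] <- 0
  ids <- rownames(ref)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(ref)))
  res <- vapply(seq_len(nrow(query)), function(i) {
    d <- D2[i, ]
    if (exclude_self) d[i] <- Inf
    order(d, ids)[seq_len(k)]
  }, integer(k))
  if (k == 1L) matrix(res, ncol = 1L) else t(res)
}

#' Match each ATAC nucleus to its nearest RNA cell in the joint space
#'
#' Euclidean nearest-neighbor search in the L2-normalized joint embedding;
#' RNA cells may be reused by several nuclei. Exact ties break by cell id
#' order (tied nuclei are recorded in the `"ties"` attribute).
#'
#' @param joint a `joint_embedding` from [joint_cca()].
#' @return named character vector: nucleus id -> matched cell id.
#' @export
match_modalities <- function(joint) {
  stopifnot(inherits(joint, "joint_embedding"))
  if (nrow(joint$rna_coords) == 0)
    stop("match_modalities: empty RNA side")
  nn <- knn_index(joint$atac_coords, joint$rna_coords, 1L)
  m <- rownames(joint$rna_coords)[nn[, 1]]
  names(m) <- rownames(joint$atac_coords)
  m
}

#' Build cross-modality pseudobulks
#'
#' Samples `n_seeds` seed nuclei uniformly without replacement; each
#' pseudobulk aggregates the seed with its `k_neighbors` nearest nuclei in
#' the (batch-corrected) ATAC embedding. Peak counts are summed and
#' CPM-normalized; the member nuclei are mapped through `match` to RNA cells
#' (a multiset) whose TPM profiles are summed and rescaled to 1e6.
#'
#' @param atac_embedding corrected ATAC embedding (nuclei x dims, rownames =
#'   nucleus ids).
#' @param peak_mat a [peak_matrix()] over the same nuclei.
#' @param match nucleus -> cell map from [match_modalities()].
#' @param rna_tpm gene x cell TPM matrix.
#' @param n_seeds number of pseudobulks (reduced with a warning when fewer
#'   nuclei exist).
#' @param k_neighbors neighbors joined to each seed (pseudobulk size is
#'   `k_neighbors + 1`).
#' @param seed RNG seed for the seed-nucleus draw.
#' @return list of class `pseudobulk_set`: `peak_cpm` (peaks x pseudobulks),
#'   `gene_tpm` (genes x pseudobulks), `members` (list of nucleus ids),
#'   `rna_members`, `seed_nuclei`.
#' @export
build_pseudobulks <- function(atac_embedding, peak_mat, match, rna_tpm,
                              n_seeds = 200, k_neighbors = 99, seed = 1L) {
  stopifnot(inherits(peak_mat, "peak_matrix"))
  emb <- as.matrix(atac_embedding)
  nuc <- rownames(emb)
  stopifnot(!is.null(nuc), all(nuc %in% colnames(peak_mat$counts)),
            all(nuc %in% names(match)))
  if (k_neighbors + 1 > nrow(emb))
    stop("build_pseudobulks: fewer nuclei than the pseudobulk size")
  if (n_seeds > nrow(emb)) {
    warning("build_pseudobulks: reducing n_seeds to ", nrow(emb))
    n_seeds <- nrow(emb)
  }
  set.seed(seed)
  seeds <- sort(sample.int(nrow(emb), n_seeds))
  nn <- knn_index(emb[seeds, , drop = FALSE], emb, k_neighbors + 1L)
  members <- lapply(seq_along(seeds), function(i) {
    idx <- nn[i, ]
    idx <- idx[idx != seeds[i]][seq_len(k_neighbors)]
    if (k_neighbors == 0) idx <- integer(0)
    nuc[c(seeds[i], idx)]
  })
  pb_ids <- sprintf("pb%04d", seq_along(seeds))
  names(members) <- pb_ids
  G <- Matrix::sparseMatrix(
    i = match(unlist(members), colnames(peak_mat$counts)),
    j = rep(seq_along(members), lengths(members)), x = 1,
    dims = c(ncol(peak_mat$counts), length(members)))
  peak_sum <- as.matrix(peak_mat$counts %*% G)
  colnames(peak_sum) <- pb_ids
  peak_cpm <- sweep(peak_sum, 2, colSums(peak_sum), "/") * 1e6
  rna_members <- lapply(members, function(m) unname(match[m]))
  Gr <- Matrix::sparseMatrix(
    i = match(unlist(rna_members), colnames(rna_tpm)),
    j = rep(seq_along(rna_members), lengths(rna_members)), x = 1,
    dims = c(ncol(rna_tpm), length(rna_members)))
  gene_sum <- as.matrix(rna_tpm %*% Gr)
  colnames(gene_sum) <- pb_ids
  gene_tpm <- sweep(gene_sum, 2, colSums(gene_sum), "/") * 1e6
  structure(list(peak_cpm = peak_cpm, gene_tpm = gene_tpm,
                 members = members, rna_members = rna_members,
                 seed_nuclei = nuc[seeds]),
            class = "pseudobulk_set")
}

#' @export
print.pseudobulk_set <- function(x, ...) {
  cat("pseudobulk_set:", length(x$members), "pseudobulks of",
      length(x$members[[1]]), "cells\n")
  invisible(x)
}
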