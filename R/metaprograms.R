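#' Derive NMF expression programs for one sample
#'
#' Relative expression restricted to the supplied gene list and to the
#' sample's cells is clipped at zero (`max(Er, 0)`) and factorized with a
#' deterministic rank-`k` NMF; each factor is reduced to its top 30 genes by
#' NMF weight (weights sorted nonincreasing, ties by gene id).
#'
#' @param Er relative-expression matrix (genes x cells) for the sample's
#'   cells, or an `expr_transforms` object plus `cells` selection.
#' @param genes character vector (e.g. over-dispersed genes) to factorize on.
#' @param k number of factors (default 6).
#' @param sample_id label stored in the programs.
#' @param top_n genes retained per program.
#' @param exclude_prefix optional regular expression; matching genes are
#'   removed from the factorization gene list (the ribosomal-protein guard
#'   used for frozen material, e.g. `"^RP[SL]"`).
#' @return list of `nmf_program` objects (`sample_id`, `factor`, `genes`,
#'   `weights`), or an empty list with a warning when the sample has fewer
#'   than `k` cells.
#' @export
run_sample_nmf <- function(Er, genes, k = 6, sample_id = "sample",
                           top_n = 30, exclude_prefix = NULL) {
  if (inherits(Er, "expr_transforms")) Er <- Er$Er
  genes <- intersect(genes, rownames(Er))
  if (!is.null(exclude_prefix))
    genes <- genes[!grepl(exclude_prefix, genes)]
  if (length(genes) < k)
    stop("run_sample_nmf: fewer usable genes than factors")
  if (ncol(Er) < k) {
    warning("run_sample_nmf: sample '", sample_id, "' has fewer than ", k,
            " cells; skipped")
    return(list())
  }
  A <- pmax(Er[genes, , drop = FALSE], 0)
  if (all(A == 0)) {
    warning("run_sample_nmf: all-zero clipped matrix for '", sample_id,
            "'; skipped")
    return(list())
  }
  fit <- nmf_factorize(A, k)
  lapply(seq_len(k), function(j) {
    w <- fit$W[, j]
    ord <- order(-w, names(w))[seq_len(min(top_n, length(w)))]
    structure(list(sample_id = sample_id, factor = j,
                   genes = names(w)[ord],
                   weights = unname(w[ord])),
              class = "nmf_program")
  })
}

program_name <- function(p) paste0(p$sample_id, ".f", p$factor)

#' Score all cells with a list of NMF programs
#'
#' Delegates to [score_signature()] on each program's top genes; columns are
#' ordered by (sample, factor).
#'
#' @param Er relative-expression matrix over all cells.
#' @param programs list of `nmf_program` objects.
#' @return cell x program score matrix.
#' @export
score_programs <- function(Er, programs) {
  if (inherits(Er, "expr_transforms")) Er <- Er$Er
  stopifnot(length(programs) >= 1)
  nm <- vapply(programs, program_name, character(1))
  ord <- order(nm)
  programs <- programs[ord]
  out <- vapply(programs,
                function(p) as.numeric(score_signature(Er, p$genes)),
                numeric(ncol(Er)))
  dimnames(out) <- list(colnames(Er), nm[ord])
  out
}

## average silhouette width for a flat clustering from a distance matrix
silhouette_width <- function(D, cl) {
  D <- as.matrix(D)
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(cl == cl[i]); own <- setdiff(own, i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(cl), cl[i]),
                    function(k) mean(D[i, cl == k]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Cluster NMF programs and merge them into consensus metaprograms
#'
#' Programs are compared by the Pearson correlation of their cell-score
#' columns; hierarchical clustering (distance `1 - correlation`, Ward
#' linkage) is cut into `n_meta` clusters, and each cluster is merged into a
#' metaprogram by taking the top 30 genes with the highest average NMF weight
#' across member programs (a gene absent from a member's top list contributes
#' weight 0). When `n_meta` is `NULL` the cut maximizing the average
#' silhouette width over 2..10 clusters is chosen (choice recorded in the
#' result).
#'
#' @param programs list of `nmf_program` objects (>= `n_meta`).
#' @param program_scores cell x program matrix from [score_programs()].
#' @param n_meta number of metaprograms, or `NULL` for the silhouette choice.
#' @param top_n genes per metaprogram.
#' @return list of class `metaprogram_set`: `metaprograms` (each with `name`,
#'   `genes`, `weights`, `members`), `clusters`, `hclust`, `n_meta`,
#'   `n_meta_auto`.
#' @export
cluster_and_merge <- function(programs, program_scores, n_meta = NULL,
                              top_n = 30) {
  nm <- vapply(programs, program_name, character(1))
  ord <- order(nm)
  programs <- programs[ord]; nm <- nm[ord]
  program_scores <- program_scores[, nm, drop = FALSE]
  if (!is.null(n_meta) && length(programs) < n_meta)
    stop("cluster_and_merge: fewer programs than requested metaprograms")
  sds <- apply(program_scores, 2, stats::sd)
  if (any(sds == 0))
    warning("cluster_and_merge: constant score column(s); ",
            "correlations with them set to 0")
  C <- suppressWarnings(stats::cor(program_scores))
  C[!is.finite(C)] <- 0
  diag(C) <- 1
  D <- stats::as.dist(1 - C)
  hc <- stats::hclust(D, method = "ward.D2")
  auto <- FALSE
  if (is.null(n_meta)) {
    ks <- 2:min(10, length(programs) - 1)
    sil <- vapply(ks, function(k) silhouette_width(D, stats::cutree(hc, k)),
                  numeric(1))
    n_meta <- ks[which.max(sil)]
    auto <- TRUE
  }
  cl <- stats::cutree(hc, n_meta)
  metas <- lapply(seq_len(n_meta), function(k) {
    members <- programs[cl == k]
    allg <- sort(unique(unlist(lapply(members, `[[`, "genes"))))
    wsum <- stats::setNames(numeric(length(allg)), allg)
    for (p in members) wsum[p$genes] <- wsum[p$genes] + p$weights
    wavg <- wsum / length(members)  # absent gene contributes weight 0
    ordg <- order(-wavg, names(wavg))[seq_len(min(top_n, length(wavg)))]
    list(name = sprintf("MP%d", k),
         genes = names(wavg)[ordg],
         weights = unname(wavg[ordg]),
         members = vapply(members, program_name, character(1)))
  })
  names(metas) <- vapply(metas, `[[`, character(1), "name")
  structure(list(metaprograms = metas, clusters = cl, hclust = hc,
                 n_meta = n_meta, n_meta_auto = auto),
            class = "metaprogram_set")
}

#' @export
print.metaprogram_set <- function(x, ...) {
  cat("metaprogram_set:", x$n_meta, "metaprograms from",
      length(x$clusters), "programs",
      if (x$n_meta_auto) "(silhouette-chosen cut)" else "", "\n")
  invisible(x)
}

#' Gene sets of a metaprogram set
#' @param metas a `metaprogram_set` (or plain list of metaprograms).
#' @return named list of gene vectors.
#' @export
metaprogram_signatures <- function(metas) {
  if (inherits(metas, "metaprogram_set")) metas <- metas$metaprograms
  lapply(metas, `[[`, "genes")
}

#' Match two metaprogram sets by score correlation
#'
#' Scores both sets on the shared cells of `Er`, computes the Pearson
#' correlation between the two sets' score columns, and reports a greedy
#' highest-correlation pairing (ties broken by name order).
#'
#' @param metas_a,metas_b `metaprogram_set`s (e.g. fresh- and frozen-derived).
#' @param Er relative-expression matrix over the shared cells.
#' @return list with `correlation` (A x B matrix) and `pairing` data.frame.
#' @export
crossmodal_match <- function(metas_a, metas_b, Er) {
  if (inherits(Er, "expr_transforms")) Er <- Er$Er
  if (ncol(Er) == 0) stop("crossmodal_match: no shared cells")
  sa <- score_signatures(Er, metaprogram_signatures(metas_a))
  sb <- score_signatures(Er, metaprogram_signatures(metas_b))
  M <- stats::cor(sa, sb)
  A <- M
  pairs <- list()
  while (nrow(A) > 0 && ncol(A) > 0) {
    best <- which(A == max(A), arr.ind = TRUE)
    best <- best[order(rownames(A)[best[, 1]], colnames(A)[best[, 2]]),
                 , drop = FALSE][1, ]
    pairs[[length(pairs) + 1L]] <-
      data.frame(a = rownames(A)[best[1]], b = colnames(A)[best[2]],
                 correlation = A[best[1], best[2]],
                 stringsAsFactors = FALSE)
    A <- A[-best[1], -best[2], drop = FALSE]
  }
  list(correlation = M, pairing = do.call(rbind, pairs))
}
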