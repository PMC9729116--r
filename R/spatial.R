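#' Gate cells into malignant / nonmalignant / ambiguous by IF intensity
#'
#' Intensity >= `min_malignant` is malignant, <= `max_nonmalignant` is
#' nonmalignant, and strictly between the thresholds is ambiguous (excluded
#' from downstream statistics). Per-class counts are attached as
#' `"class_counts"`.
#'
#' @param cells data.frame with an `intensity` column.
#' @param min_malignant,max_nonmalignant the two gating thresholds.
#' @return `cells` with an added `class` column.
#' @export
if_gate <- function(cells, min_malignant, max_nonmalignant) {
  if (min_malignant < max_nonmalignant)
    stop("if_gate: min_malignant must be >= max_nonmalignant")
  cls <- ifelse(cells$intensity >= min_malignant, "malignant",
                ifelse(cells$intensity <= max_nonmalignant,
                       "nonmalignant", "ambiguous"))
  cells$class <- cls
  attr(cells, "class_counts") <- table(factor(
    cls, levels = c("malignant", "nonmalignant", "ambiguous")))
  cells
}

#' Type nonmalignant cells by their dominant key marker
#'
#' Each nonmalignant cell is assigned the type whose key marker has the
#' maximum read count; all-zero cells and exact ties give `"unassigned"`
#' (tied cells flagged in the `"ties"` attribute).
#'
#' @param cells data.frame of cells (rows aligned with `reads`).
#' @param reads cells x marker-gene count matrix.
#' @param marker_map named character vector or list: type -> key marker
#'   gene(s); with several markers per type their counts are summed.
#' @return character vector of type labels, one per row of `cells`.
#' @export
type_nonmalignant <- function(cells, reads, marker_map) {
  if (length(marker_map) == 0) stop("type_nonmalignant: empty marker map")
  reads <- as.matrix(reads)
  score <- vapply(marker_map, function(mk) {
    mk <- intersect(mk, colnames(reads))
    if (!length(mk)) return(rep(0, nrow(reads)))
    rowSums(reads[, mk, drop = FALSE])
  }, numeric(nrow(reads)))
  if (is.null(dim(score))) score <- matrix(score, nrow = nrow(reads))
  colnames(score) <- names(marker_map)
  best <- max.col(score, ties.method = "first")
  mx <- score[cbind(seq_len(nrow(score)), best)]
  n_at_max <- rowSums(score == mx)
  lab <- ifelse(mx == 0 | n_at_max > 1, "unassigned",
                colnames(score)[best])
  attr(lab, "ties") <- which(n_at_max > 1 & mx > 0)
  lab
}

#' Radius neighbor graph of a spatial cell map
#'
#' Undirected edge between two cells iff their Euclidean distance is at most
#' `radius` (inclusive); no self-edges.
#'
#' @param cells data.frame with `x` and `y` coordinates (micrometers).
#' @param radius neighborhood radius in micrometers (default 50).
#' @return an `igraph` graph with one vertex per cell (names = row order or
#'   `cell_id` when present) and a `radius` attribute.
#' @export
build_graph <- function(cells, radius = 50) {
  if (nrow(cells) < 2) stop("build_graph: need at least 2 cells")
  if (any(!is.finite(cells$x)) || any(!is.finite(cells$y)))
    stop("build_graph: coordinates must be finite")
  ids <- if ("cell_id" %in% names(cells)) as.character(cells$cell_id) else
    as.character(seq_len(nrow(cells)))
  D <- as.matrix(stats::dist(cells[, c("x", "y")]))
  A <- D <= radius
  diag(A) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::V(g)$name <- ids
  g$radius <- radius
  g
}

## per-permutation unordered type-pair edge counts, vectorized across pairs
pair_edge_counts <- function(ends_i, ends_j, labels, pair_levels) {
  a <- labels[ends_i]; b <- labels[ends_j]
  key <- ifelse(a <= b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
  tab <- table(factor(key, levels = pair_levels))
  as.numeric(tab)
}

#' Permutation neighborhood enrichment between cell types
#'
#' The observed statistic for an unordered type pair is the number of graph
#' edges joining the two types (within-type edges for a = b). Labels are
#' permuted uniformly `n_perm` times; the z-score is
#' `(observed - permutation mean) / permutation sd` (flagged undefined when
#' the permutation sd is 0). The conditional colocalization ratio for an
#' ordered pair (a, b) is the mean over a-cells with neighbors of the
#' fraction of their neighbors of type b, divided by the global fraction of
#' b cells.
#'
#' @param graph an `igraph` graph from [build_graph()].
#' @param labels per-vertex type labels.
#' @param n_perm number of permutations (default 100).
#' @param seed RNG seed for the permutations.
#' @return list of class `enrichment_result`: `z` data.frame per unordered
#'   pair (observed, perm_mean, perm_sd, z, z_defined) and
#'   `conditional_ratio` (ordered type x type matrix).
#' @export
neighborhood_enrichment <- function(graph, labels, n_perm = 100, seed = 1L) {
  n <- igraph::vcount(graph)
  if (length(labels) != n)
    stop("neighborhood_enrichment: labels do not match the graph")
  types <- sort(unique(labels))
  if (length(types) < 2)
    stop("neighborhood_enrichment: need at least two types")
  el <- igraph::as_edgelist(graph, names = FALSE)
  pair_grid <- expand.grid(a = types, b = types, stringsAsFactors = FALSE)
  pair_grid <- pair_grid[pair_grid$a <= pair_grid$b, ]
  pair_levels <- paste(pair_grid$a, pair_grid$b, sep = "|")
  obs <- pair_edge_counts(el[, 1], el[, 2], labels, pair_levels)
  set.seed(seed)
  perm <- matrix(0, n_perm, length(pair_levels))
  for (p in seq_len(n_perm)) {
    perm[p, ] <- pair_edge_counts(el[, 1], el[, 2],
                                  sample(labels), pair_levels)
  }
  mu <- colMeans(perm)
  sdv <- apply(perm, 2, stats::sd)
  z <- ifelse(sdv > 0, (obs - mu) / sdv, NA_real_)
  ztab <- data.frame(type_a = pair_grid$a, type_b = pair_grid$b,
                     observed = obs, perm_mean = mu, perm_sd = sdv,
                     z = z, z_defined = sdv > 0,
                     stringsAsFactors = FALSE)
  ## conditional colocalization ratio (ordered)
  adj <- igraph::as_adj_list(graph)
  ratio <- matrix(NA_real_, length(types), length(types),
                  dimnames = list(types, types))
  glob <- table(factor(labels, levels = types)) / n
  for (a in types) {
    ia <- which(labels == a)
    nb <- adj[ia]
    has <- lengths(nb) > 0
    if (!any(has)) next
    fr <- vapply(types, function(b) {
      mean(vapply(nb[has], function(v)
        mean(labels[as.integer(v)] == b), numeric(1)))
    }, numeric(1))
    ratio[a, ] <- fr / as.numeric(glob)
  }
  structure(list(z = ztab, conditional_ratio = ratio, n_perm = n_perm),
            class = "enrichment_result")
}

#' Per-type graph centrality statistics
#'
#' Degree centrality of a type T is the fraction of non-T cells adjacent to
#' at least one T cell; the clustering coefficient of T is the transitivity
#' (3 x triangles / connected triples) of the subgraph induced by T's cells,
#' 0 when the subgraph has no connected triple. A type containing every cell
#' gets an undefined (NA) degree centrality.
#'
#' @param graph an `igraph` graph.
#' @param labels per-vertex type labels.
#' @param per_node use the average local clustering coefficient of the
#'   induced subgraph instead of its global transitivity.
#' @return data.frame type, degree_centrality, clustering_coefficient.
#' @export
centrality_scores <- function(graph, labels, per_node = FALSE) {
  n <- igraph::vcount(graph)
  stopifnot(length(labels) == n)
  types <- sort(unique(labels))
  A <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
  out <- lapply(types, function(t) {
    int <- which(labels == t); ext <- which(labels != t)
    dc <- if (!length(ext)) NA_real_ else {
      touched <- Matrix::rowSums(A[ext, int, drop = FALSE]) > 0
      sum(touched) / length(ext)
    }
    sub <- igraph::induced_subgraph(graph, int)
    cc <- igraph::transitivity(sub,
                               type = if (per_node) "localaverage"
                                 else "global")
    if (is.nan(cc) || is.na(cc)) cc <- 0
    data.frame(type = t, degree_centrality = dc,
               clustering_coefficient = cc, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare per-sample type proportions between two groups
#'
#' Two-sided Welch t-test on per-sample proportions of a named type.
#'
#' @param per_sample_proportions named numeric vector (one value per sample).
#' @param group_labels factor/character of the same length with two levels.
#' @return list with `statistic`, `p`, `group_means`, `df`.
#' @export
compare_group_proportions <- function(per_sample_proportions, group_labels) {
  stopifnot(length(per_sample_proportions) == length(group_labels))
  groups <- sort(unique(as.character(group_labels)))
  if (length(groups) != 2)
    stop("compare_group_proportions: exactly two groups required")
  x <- per_sample_proportions[group_labels == groups[1]]
  y <- per_sample_proportions[group_labels == groups[2]]
  if (length(x) < 2 || length(y) < 2)
    stop("compare_group_proportions: each group needs at least 2 samples")
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p = tt$p.value,
       group_means = stats::setNames(c(mean(x), mean(y)), groups),
       df = unname(tt$parameter))
}
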