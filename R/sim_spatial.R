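#' Generate a synthetic in situ cell map with planted niches
#'
#' Malignant cells carry the state labels of `cfg$states`; nonmalignant
#' types are oligodendrocyte, endothelial, pericyte, astrocyte, TAM and
#' neuron, each with a dominant key marker (MBP, ESAM, MYL9, GFAP, CD74,
#' DLG4). Types named in `cfg$niche_pairs` are drawn around shared Gaussian
#' blob centers; all other cells are uniform on the square field. Malignant
#' cells get IF intensity `Normal(if_high_mean, if_sd)`, nonmalignant cells
#' `Normal(if_low_mean, if_sd)` truncated at 0. Marker read counts are
#' Poisson with a type-specific dominant marker.
#'
#' @param cfg a [sim_config()].
#' @param truth optional ground-truth list to extend.
#' @return list with `cells` (data.frame: cell_id, x, y, intensity,
#'   true_type, true_malignant), `reads` (cells x marker counts),
#'   `marker_map`, and `truth` extended with `spatial_types`.
#' @export
gen_spatial <- function(cfg, truth = list()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(sim_seed(cfg, "spatial"))
  marker_map <- c(oligodendrocyte = "MBP", endothelial = "ESAM",
                  pericyte = "MYL9", astrocyte = "GFAP",
                  TAM = "CD74", neuron = "DLG4")
  mal_types <- cfg$states
  nonmal_types <- names(marker_map)
  if (any(mal_types %in% nonmal_types))
    stop("gen_spatial: overlapping malignant/nonmalignant type names")
  types <- c(mal_types, nonmal_types)
  for (pr in cfg$niche_pairs)
    if (!all(pr %in% types))
      stop("gen_spatial: niche pair names unknown type")

  n <- cfg$spatial_n_cells
  prob <- c(rep(0.5 / length(mal_types), length(mal_types)),
            rep(0.5 / length(nonmal_types), length(nonmal_types)))
  type <- sample(types, n, replace = TRUE, prob = prob)

  x <- stats::runif(n, 0, cfg$field_size)
  y <- stats::runif(n, 0, cfg$field_size)
  niche_types <- unique(unlist(cfg$niche_pairs))
  if (length(niche_types)) {
    m <- 3 * cfg$blob_sd
    centers <- cbind(stats::runif(cfg$n_blobs, m, cfg$field_size - m),
                     stats::runif(cfg$n_blobs, m, cfg$field_size - m))
    in_niche <- which(type %in% niche_types)
    pick <- sample.int(cfg$n_blobs, length(in_niche), replace = TRUE)
    x[in_niche] <- pmin(pmax(
      stats::rnorm(length(in_niche), centers[pick, 1], cfg$blob_sd), 0),
      cfg$field_size)
    y[in_niche] <- pmin(pmax(
      stats::rnorm(length(in_niche), centers[pick, 2], cfg$blob_sd), 0),
      cfg$field_size)
  }

  malignant <- type %in% mal_types
  intensity <- numeric(n)
  intensity[malignant] <- stats::rnorm(sum(malignant), cfg$if_high_mean,
                                       cfg$if_sd)
  ## Normal truncated at 0 via inverse-CDF sampling
  nm <- sum(!malignant)
  if (nm > 0) {
    lo <- stats::pnorm(0, cfg$if_low_mean, max(cfg$if_sd, 1e-12))
    u <- stats::runif(nm, lo, 1)
    intensity[!malignant] <- if (cfg$if_sd > 0)
      stats::qnorm(u, cfg$if_low_mean, cfg$if_sd) else cfg$if_low_mean
  }

  markers <- unname(marker_map)
  reads <- matrix(stats::rpois(n * length(markers), 0.2), n,
                  length(markers), dimnames = list(NULL, markers))
  for (t in nonmal_types) {
    i <- type == t
    if (any(i))
      reads[i, marker_map[[t]]] <- stats::rpois(sum(i), 5)
  }

  cells <- data.frame(cell_id = sprintf("sc%05d", seq_len(n)),
                      x = x, y = y, intensity = intensity,
                      true_type = type, true_malignant = malignant,
                      stringsAsFactors = FALSE)
  rownames(reads) <- cells$cell_id
  truth$spatial_types <- stats::setNames(type, cells$cell_id)
  list(cells = cells, reads = reads, marker_map = as.list(marker_map),
       truth = truth)
}
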