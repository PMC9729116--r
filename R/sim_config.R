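#' Configuration for the synthetic multimodal generator
#'
#' Bundles every knob of the planted-truth simulator: cohort layout, expression
#' signal/noise, chromatin geometry and coupling, motif probabilities, and the
#' spatial field. Defaults are the study conditions used throughout the test
#' suite and the acceptance script; see the methods vignette for the rationale
#' behind each value.
#'
#' @param n_samples number of tumors (samples) in the cohort.
#' @param cells_per_sample cells (and snATAC nuclei) generated per sample.
#' @param n_genes total genes in the expression matrix.
#' @param states cell-state names; each gets a planted signature and one TF.
#' @param signature_size genes per planted state signature.
#' @param effect_size log2-expression shift added to a signature gene in cells
#'   of its own state.
#' @param batch_sd standard deviation of per-sample, per-gene log2 offsets.
#' @param noise_sd residual log2 noise standard deviation.
#' @param dropout_p probability that a gene x cell TPM value is zeroed after
#'   normalization (Smart-seq2 style zero inflation); attenuated
#'   exponentially with expression on the scale `dropout_tau`.
#' @param dropout_tau TPM scale of the dropout attenuation (highly expressed
#'   genes are essentially never zeroed).
#' @param frac_noise_cells fraction of cells carrying no state signature
#'   ("none" in the ground truth); these are expected to score below the
#'   assignment threshold.
#' @param n_hk number of housekeeping genes emitted at high baseline.
#' @param rna_qc_fail_frac fraction of cells planted to fail expression QC.
#' @param n_peaks total snATAC peaks.
#' @param frac_true_links fraction of peaks planted as true distal CREs whose
#'   accessibility is coupled to their target gene's state.
#' @param link_strength target Pearson correlation of planted peak-gene pairs
#'   at pseudobulk level (drives the closed-form Poisson-coupling calibration).
#' @param n_gpc_hubs_per_state signature genes per state that receive many
#'   linked CREs (planted high regulatory complexity).
#' @param motif_fg_p,motif_bg_p motif-hit probabilities in a state TF's own
#'   CREs versus all other peaks.
#' @param n_decoy_tfs TFs with random regulons and background motif rates.
#' @param atac_qc_fail_frac fraction of nuclei planted to fail each snATAC QC
#'   criterion (independently per criterion).
#' @param atac_gradient_sd loading scale of the continuous per-nucleus
#'   accessibility gradient carried by background peaks (within-population
#'   heterogeneity; 0 disables it).
#' @param pb_cells nominal pseudobulk size used by the coupling calibration
#'   (seed nucleus + neighbors).
#' @param gene_spacing,gene_length,peak_width geometry (bp) of the single
#'   synthetic chromosome: gene start spacing, gene body length, peak width.
#' @param niche_pairs list of length-2 character vectors of spatial types
#'   planted as colocalized around shared niche centers.
#' @param spatial_n_cells,field_size,n_blobs,blob_sd spatial field layout:
#'   cell count, square field side (micrometers), niche center count and
#'   Gaussian blob standard deviation.
#' @param if_high_mean,if_low_mean,if_sd immunofluorescence intensity
#'   distribution parameters for malignant / nonmalignant cells.
#' @param seed integer random seed; together with the config it fully
#'   determines every generated object.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 6,
                       cells_per_sample = 400,
                       n_genes = 4000,
                       states = c("cycling", "OPC-like", "AC-like",
                                  "OC-like", "MES-like"),
                       signature_size = 30,
                       effect_size = 2,
                       batch_sd = 0.3,
                       noise_sd = 0.5,
                       dropout_p = 0.3,
                       dropout_tau = 100,
                       frac_noise_cells = 0.1,
                       n_hk = 50,
                       rna_qc_fail_frac = 0.05,
                       n_peaks = 5000,
                       frac_true_links = 0.04,
                       link_strength = 0.6,
                       n_gpc_hubs_per_state = 2,
                       motif_fg_p = 0.8,
                       motif_bg_p = 0.05,
                       n_decoy_tfs = 15,
                       atac_qc_fail_frac = 0.02,
                       atac_gradient_sd = 0.3,
                       pb_cells = 100,
                       gene_spacing = 1e5,
                       gene_length = 1.5e5,
                       peak_width = 500,
                       niche_pairs = list(c("OPC-like", "OC-like")),
                       spatial_n_cells = 2000,
                       field_size = 1000,
                       n_blobs = 4,
                       blob_sd = 30,
                       if_high_mean = 10,
                       if_low_mean = 2,
                       if_sd = 1,
                       seed = 1L) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  probs <- c("dropout_p", "frac_noise_cells", "rna_qc_fail_frac",
             "frac_true_links", "motif_fg_p", "motif_bg_p",
             "atac_qc_fail_frac")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("sim_config: '%s' must be a probability in [0, 1]", p))
  }
  counts <- c("n_samples", "cells_per_sample", "n_genes", "signature_size",
              "n_hk", "n_peaks", "pb_cells", "spatial_n_cells", "n_blobs")
  for (p in counts) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 ||
        v != round(v))
      stop(sprintf("sim_config: '%s' must be a positive count", p))
  }
  if (anyDuplicated(cfg$states))
    stop("sim_config: state names must be unique")
  if (cfg$signature_size * length(cfg$states) >
      cfg$n_genes - cfg$n_hk - 10L)
    stop("sim_config: signature_size x number of states exceeds the ",
         "available (non-housekeeping) gene universe")
  for (pr in cfg$niche_pairs) {
    if (length(pr) != 2L || pr[1] == pr[2])
      stop("sim_config: each niche pair must name two distinct types")
  }
  if (abs(cfg$seed) >= 2^31)
    stop("sim_config: seed must be a 32-bit integer")
  if (cfg$link_strength <= 0 || cfg$link_strength >= 1)
    stop("sim_config: link_strength must lie in (0, 1)")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_samples, "samples x", x$cells_per_sample,
      "cells,", x$n_genes, "genes,", x$n_peaks, "peaks\n")
  cat("  states:", paste(x$states, collapse = ", "),
      sprintf("(signature %d genes, effect %.2g log2)",
              x$signature_size, x$effect_size), "\n")
  cat(sprintf("  links: %.3g of peaks true, target r = %.2f; seed %d\n",
              x$frac_true_links, x$link_strength, x$seed))
  invisible(x)
}

## Deterministic per-stage seed substreams derived from the one config seed;
## all below 2^31.
sim_seed <- function(cfg, stage) {
  offs <- c(expression = 101L, atac = 211L, motifs = 307L, spatial = 401L,
            pseudobulk = 503L, enrichment = 601L, pipeline = 701L)
  if (!stage %in% names(offs)) stop("unknown seed stage: ", stage)
  (as.integer(cfg$seed) %% 2000000L) * 1000L + offs[[stage]]
}

## Allocation of planted true-link CREs to signature genes: hub genes first
## (8, 9, 10, ... CREs each), then one CRE per remaining signature gene,
## cycling if the budget exceeds the gene count.
plan_true_links <- function(cfg, signatures) {
  n_true <- round(cfg$frac_true_links * cfg$n_peaks)
  if (n_true == 0L)
    return(list(n_true = 0L, gene = character(0), hubs = character(0)))
  sig_genes <- unlist(lapply(signatures, function(s) s), use.names = FALSE)
  ## hubs interleaved across states (first hub of every state before any
  ## second hub) so a trimmed hub budget stays state-balanced
  hubs <- character(0)
  for (h in seq_len(cfg$n_gpc_hubs_per_state)) {
    for (st in names(signatures)) {
      g <- signatures[[st]]
      # first gene per state is the TF; hubs come after it
      if (length(g) >= 1L + h) hubs <- c(hubs, g[1L + h])
    }
  }
  hub_sizes <- integer(0)
  if (length(hubs)) {
    hub_sizes <- 8L + seq_along(hubs) - 1L
    # keep only as many hubs as the budget can fill while leaving one CRE
    # for most remaining signature genes
    while (length(hub_sizes) > 0 &&
           sum(hub_sizes) > max(n_true - length(sig_genes) %/% 2L, 0L)) {
      hub_sizes <- hub_sizes[-length(hub_sizes)]
    }
    hubs <- hubs[seq_along(hub_sizes)]
  }
  gene_of_link <- rep(hubs, times = hub_sizes)
  rest <- setdiff(sig_genes, hubs)
  need <- n_true - length(gene_of_link)
  if (need > 0) {
    gene_of_link <- c(gene_of_link,
                      rep(rest, length.out = need))
  } else if (need < 0) {
    gene_of_link <- gene_of_link[seq_len(n_true)]
  }
  list(n_true = n_true, gene = gene_of_link, hubs = hubs)
}
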