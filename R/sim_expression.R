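#' Generate a synthetic single-cell TPM expression matrix with planted states
#'
#' Expression is built in log2 space as
#' `baseline + effect_size * 1[gene in cell's state signature] +
#'  batch offset + Normal(0, noise_sd)`,
#' back-transformed through the inverse of `E = log2(TPM/10 + 1)`,
#' renormalized so each cell's TPM sums to 1e6, then subjected to dropout.
#' Housekeeping genes are emitted at high baseline; a configurable fraction of
#' cells is planted to fail the expression QC rules (few detected genes,
#' suppressed housekeeping expression, low alignment rate).
#'
#' @param cfg a [sim_config()].
#' @return list with `mat` (an [expression_matrix()]) and `truth` (ground-truth
#'   list: per-cell states, per-state signature gene sets, TF genes, GPC hub
#'   genes, planted QC-fail cells).
#' @export
gen_expression <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_sim_config(cfg)
  set.seed(sim_seed(cfg, "expression"))

  n_cells <- cfg$n_samples * cfg$cells_per_sample
  gene_ids <- sprintf("g%05d", seq_len(cfg$n_genes))
  hk_genes <- gene_ids[seq_len(cfg$n_hk)]

  ## signature genes: spaced along the gene index (= along the synthetic
  ## chromosome) so neighbours of signature genes are non-signature genes,
  ## never at the chromosome ends; pairwise disjoint by construction
  need <- cfg$signature_size * length(cfg$states)
  pool <- seq(cfg$n_hk + 5L, cfg$n_genes - 5L, by = 3L)
  if (length(pool) < need)
    stop("gen_expression: not enough genes to host the planted signatures")
  sel <- pool[round(seq(1, length(pool), length.out = need))]
  sel <- unique(sel)
  if (length(sel) < need) sel <- pool[seq_len(need)]
  signatures <- split(gene_ids[sel],
                      rep(cfg$states, length.out = need))[cfg$states]
  tf_genes <- vapply(signatures, `[`, character(1), 1L)

  samples <- sprintf("S%02d", seq_len(cfg$n_samples))
  protocol <- ifelse(seq_len(cfg$n_samples) <= ceiling(cfg$n_samples / 2),
                     "fresh", "frozen")
  cell_sample <- rep(samples, each = cfg$cells_per_sample)
  cell_protocol <- rep(protocol, each = cfg$cells_per_sample)
  cell_ids <- sprintf("c%05d", seq_len(n_cells))

  state_draw <- sample(c(cfg$states, "none"), n_cells, replace = TRUE,
                       prob = c(rep((1 - cfg$frac_noise_cells) /
                                      length(cfg$states),
                                    length(cfg$states)),
                                cfg$frac_noise_cells))

  ## library composition mirrors real cells: a housekeeping/ribosomal tier
  ## dominates the library, state markers sit in the low-TPM tier. Keeping
  ## the state-coupled share of each library small (~1%) keeps the
  ## TPM-renormalization coupling between flat genes and cell state well
  ## below the link-detection threshold, as in genome-scale data where
  ## signature genes are a tiny fraction of the transcriptome.
  baseline <- stats::runif(cfg$n_genes, 2, 6)
  baseline[seq_len(cfg$n_hk)] <- stats::runif(cfg$n_hk, 7, 9)
  baseline[sel] <- stats::runif(length(sel), 1, 2)

  batch <- matrix(stats::rnorm(cfg$n_genes * cfg$n_samples, 0, cfg$batch_sd),
                  cfg$n_genes, cfg$n_samples, dimnames = list(NULL, samples))

  L <- matrix(stats::rnorm(cfg$n_genes * n_cells, 0, cfg$noise_sd),
              cfg$n_genes, n_cells)
  L <- L + baseline + batch[, cell_sample]
  for (st in cfg$states) {
    idx <- match(signatures[[st]], gene_ids)
    in_state <- state_draw == st
    if (any(in_state))
      L[idx, in_state] <- L[idx, in_state] + cfg$effect_size
  }
  L[L < 0] <- 0

  tpm <- 10 * (2^L - 1)
  tpm <- sweep(tpm, 2, colSums(tpm), "/") * 1e6

  if (cfg$dropout_p > 0) {
    ## expression-dependent zero inflation: dropout_p is the zeroing
    ## probability in the low-expression limit, attenuated exponentially
    ## with the TPM value (scale dropout_tau), as in Smart-seq2 data where
    ## highly expressed genes are essentially never lost
    p_drop <- cfg$dropout_p * exp(-tpm / cfg$dropout_tau)
    keep <- matrix(stats::runif(length(tpm)) >= p_drop,
                   nrow(tpm), ncol(tpm))
    tpm <- tpm * keep
  }

  align <- stats::runif(n_cells, 0.7, 0.95)
  bad <- character(0)
  n_bad <- floor(cfg$rna_qc_fail_frac * n_cells)
  if (n_bad > 0) {
    bad_idx <- sample.int(n_cells, n_bad)
    bad <- cell_ids[bad_idx]
    ## leave ~15% of genes detected (fails both gene-count thresholds),
    ## suppress housekeeping expression, and sink the alignment rate
    for (j in bad_idx) {
      drop <- sample.int(cfg$n_genes, round(0.85 * cfg$n_genes))
      tpm[drop, j] <- 0
      tpm[seq_len(cfg$n_hk), j] <- 0
    }
    align[bad_idx] <- 0.3
  }

  dimnames(tpm) <- list(gene_ids, cell_ids)
  cells <- data.frame(cell_id = cell_ids,
                      sample_id = cell_sample,
                      protocol = cell_protocol,
                      alignment_rate = align,
                      stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = gene_ids,
                      housekeeping = gene_ids %in% hk_genes,
                      stringsAsFactors = FALSE)
  mat <- expression_matrix(tpm, cells, genes)

  truth <- list(baseline_log2 = stats::setNames(baseline, gene_ids),
                cell_states = stats::setNames(state_draw, cell_ids),
                signatures = signatures,
                tf_genes = tf_genes,
                hub_genes = plan_true_links(cfg, signatures)$hubs,
                housekeeping = hk_genes,
                qc_fail_cells = bad)
  list(mat = mat, truth = truth)
}
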