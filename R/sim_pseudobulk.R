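#' Generate pseudobulk-scale link data with exact planted correlations
#'
#' Draws `n_pb` pseudobulk profiles directly from the generative model that
#' the aggregation pipeline targets: each pseudobulk is a state-pure group
#' of `cfg$pb_cells` cells/nuclei whose members are drawn *fresh* (no
#' membership reuse between pseudobulks). Peak counts are Poisson with the
#' planted state coupling (calibrated to `link_strength`); gene TPM values
#' are Gaussian around the model's per-(gene, state) mean with the
#' cell-level standard deviation divided by `sqrt(pb_cells)`, both computed
#' in closed form from the generative parameters (lognormal expression
#' noise, expression-dependent dropout, library renormalization), then
#' renormalized to 1e6. This is the operative regime of genome-scale data,
#' where pseudobulk member draws are a vanishing fraction of the population
#' and unplanted pairs are exchangeable; the end-to-end aggregation path on
#' a desk-scale cohort shares members across pseudobulks and is exercised
#' separately (see the methods vignette).
#'
#' @param cfg a [sim_config()].
#' @param n_pb number of pseudobulks (default 200).
#' @return list with `peak_cpm` (peaks x pseudobulks), `gene_tpm`
#'   (genes x pseudobulks), `annotation`, `peaks` (`GRanges`), `pb_states`,
#'   and `truth` (as from [gen_atac()]).
#' @export
gen_pseudobulk_links <- function(cfg, n_pb = 200) {
  stopifnot(inherits(cfg, "sim_config"))
  sim <- gen_expression(cfg)
  atac <- gen_atac(cfg, sim$truth)
  truth <- atac$truth
  set.seed(sim_seed(cfg, "pseudobulk"))

  states_all <- c(cfg$states, "none")
  ## closed-form per-(gene, state) mean and cell-level sd of TPM under the
  ## generative model: lognormal factor from the log2-normal noise and
  ## batch spread, expected expression-dependent dropout, then library
  ## renormalization to 1e6
  b <- truth$baseline_log2
  sig2_log2 <- cfg$noise_sd^2 + cfg$batch_sd^2
  e2 <- exp((log(2)^2) * sig2_log2 / 2)
  cv2 <- exp((log(2)^2) * sig2_log2) - 1
  m <- sdm <- matrix(0, length(b), length(states_all),
                     dimnames = list(names(b), states_all))
  for (si in seq_along(states_all)) {
    s <- states_all[si]
    L <- b
    if (s %in% names(truth$signatures))
      L[truth$signatures[[s]]] <- L[truth$signatures[[s]]] + cfg$effect_size
    m0 <- 10 * (2^L * e2 - 1)
    tpm0 <- m0 / sum(m0) * 1e6
    p_drop <- cfg$dropout_p * exp(-tpm0 / cfg$dropout_tau)
    m1 <- tpm0 * (1 - p_drop)
    scl <- 1e6 / sum(m1)
    m[, si] <- m1 * scl
    sdm[, si] <- sqrt((1 - p_drop) * cv2 * tpm0^2 +
                        p_drop * (1 - p_drop) * tpm0^2) * scl
  }

  pb_states <- sample(states_all, n_pb, replace = TRUE,
                      prob = c(rep((1 - cfg$frac_noise_cells) /
                                     length(cfg$states), length(cfg$states)),
                               cfg$frac_noise_cells))
  pb_ids <- sprintf("pb%04d", seq_len(n_pb))

  si <- match(pb_states, states_all)
  gene_tpm <- m[, si, drop = FALSE] +
    matrix(stats::rnorm(nrow(m) * n_pb), nrow(m), n_pb) *
      (sdm[, si, drop = FALSE] / sqrt(cfg$pb_cells))
  gene_tpm[gene_tpm < 0] <- 0
  gene_tpm <- sweep(gene_tpm, 2, colSums(gene_tpm), "/") * 1e6
  dimnames(gene_tpm) <- list(rownames(sim$mat$tpm), pb_ids)

  state_of_gene <- stats::setNames(
    rep(names(truth$signatures), lengths(truth$signatures)),
    unlist(truth$signatures, use.names = FALSE))
  rate <- truth$peak_base_rate
  A <- outer(rate * cfg$pb_cells, rep(1, n_pb))
  peak_state <- rep(NA_character_, length(rate))
  is_cre <- truth$peak_kind == "cre"
  is_drv <- truth$peak_kind == "driver"
  peak_state[is_cre] <-
    state_of_gene[truth$true_links$gene[match(names(rate)[is_cre],
                                              truth$true_links$peak)]]
  peak_state[is_drv] <-
    state_of_gene[truth$promoter_links$gene[match(names(rate)[is_drv],
                                                  truth$promoter_links$peak)]]
  on_state <- outer(peak_state, pb_states, "==")
  on_state[is.na(on_state)] <- FALSE
  mult <- matrix(1, length(rate), n_pb)
  mult[is_cre, ] <- 1
  mult[on_state & is_cre] <- 1 + truth$link_beta
  mult[on_state & is_drv] <- 5
  counts <- matrix(stats::rpois(length(A), A * mult), nrow(A), n_pb)
  peak_cpm <- sweep(counts, 2, colSums(counts), "/") * 1e6
  dimnames(peak_cpm) <- list(names(rate), pb_ids)

  list(peak_cpm = peak_cpm, gene_tpm = gene_tpm,
       annotation = atac$annotation, peaks = atac$mat$peaks,
       pb_states = stats::setNames(pb_states, pb_ids), truth = truth)
}
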