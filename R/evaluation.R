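## Benchmarking drivers: run a pipeline stage on synthetic data and score it
## against the planted ground truth. Ground truth is used for scoring only,
## never as a method input. These power the test suite, the acceptance
## script and the analysis drivers.

## map each metaprogram to the planted state with maximal gene overlap
## ("junk" when it overlaps no signature)
map_metaprograms <- function(metas, signatures) {
  vapply(metaprogram_signatures(metas), function(m) {
    ov <- vapply(signatures, function(g) length(intersect(m, g)), integer(1))
    if (max(ov) == 0) "junk" else names(signatures)[which.max(ov)]
  }, character(1))
}

#' Metaprogram recovery benchmark
#'
#' Runs expression QC, transforms, over-dispersed gene selection, per-sample
#' NMF, consensus merging and state assignment on a synthetic cohort, then
#' scores signature recovery, assignment accuracy (on QC-surviving cells
#' with a planted state) and the flag rate of pure-noise cells.
#'
#' @param cfg a [sim_config()].
#' @param n_overdispersed genes used for NMF.
#' @param k NMF factors per sample.
#' @param n_meta consensus metaprograms (default: number of states).
#' @param qc apply the expression QC filters first (default TRUE; disable
#'   for reduced-gene-count configurations where the full-scale detected-
#'   gene thresholds do not apply).
#' @return list with `signature_recovery` (per state, fraction of the
#'   planted genes recovered by the best metaprogram), `accuracy`,
#'   `noise_flag_rate`, plus the fitted objects.
#' @export
evaluate_metaprogram_recovery <- function(cfg, n_overdispersed = 1000,
                                          k = 6, n_meta = NULL, qc = TRUE) {
  sim <- gen_expression(cfg)
  mat <- sim$mat
  if (qc) mat <- qc_filter_genes(qc_filter_cells(mat))
  tr <- transform_expression(mat)
  od <- suppressWarnings(select_overdispersed_genes(mat, n_overdispersed))
  programs <- list()
  for (s in unique(mat$cells$sample_id)) {
    cs <- mat$cells$cell_id[mat$cells$sample_id == s]
    programs <- c(programs,
                  run_sample_nmf(tr$Er[, cs, drop = FALSE], od, k = k,
                                 sample_id = s))
  }
  if (is.null(n_meta)) n_meta <- length(cfg$states)
  scores <- score_programs(tr$Er, programs)
  metas <- cluster_and_merge(programs, scores, n_meta = n_meta)
  mscore <- score_signatures(tr$Er, metaprogram_signatures(metas))
  labels <- assign_state(mscore)
  mp_map <- map_metaprograms(metas, sim$truth$signatures)
  truth_lab <- sim$truth$cell_states[names(labels)]
  pred <- ifelse(labels == "score_too_low", "none", mp_map[labels])
  signal <- truth_lab %in% cfg$states
  recovery <- vapply(sim$truth$signatures, function(g)
    max(vapply(metaprogram_signatures(metas), function(m)
      length(intersect(m, g)), integer(1))) / length(g), numeric(1))
  list(signature_recovery = recovery,
       accuracy = mean(pred[signal] == truth_lab[signal]),
       noise_flag_rate = mean(labels[truth_lab == "none"] ==
                                "score_too_low"),
       metaprograms = metas, programs = programs, overdispersed = od,
       labels = labels, transforms = tr,
       truth = sim$truth, mat = mat, mp_map = mp_map)
}

## links scored against planted couplings; recall and link strength are
## measured on the distal CREs, FDP against all planted couplings
## (distal CREs + promoter drivers)
score_links <- function(links, truth) {
  key <- paste(links$peak, links$gene)
  tkey <- paste(truth$true_links$peak, truth$true_links$gene)
  pkey <- c(tkey, paste(truth$promoter_links$peak,
                        truth$promoter_links$gene))
  distal <- key %in% tkey
  planted <- key %in% pkey
  disc <- links$passes
  list(recall = if (sum(tkey %in% key)) sum(disc & distal) /
         sum(tkey %in% key) else NA_real_,
       fdp = if (sum(disc)) sum(disc & !planted) / sum(disc) else 0,
       n_discoveries = sum(disc),
       mean_planted_pcc = if (any(distal)) mean(links$pcc[distal])
         else NA_real_)
}

#' Peak-gene link recovery benchmark
#'
#' Generates pseudobulk-scale data with [gen_pseudobulk_links()], runs
#' candidate pairing, correlation testing and link filtering, and scores
#' recall / realized false discovery proportion against the planted truth.
#'
#' @param cfg a [sim_config()].
#' @param n_pb number of pseudobulks.
#' @return list with `recall`, `fdp`, `n_discoveries`, `mean_planted_pcc`,
#'   `links`, `truth`, `gpc` (when any link passes).
#' @export
evaluate_link_recovery <- function(cfg, n_pb = 200) {
  pbl <- gen_pseudobulk_links(cfg, n_pb = n_pb)
  pairs <- candidate_pairs(pbl$peaks, pbl$annotation,
                           expressed_genes = rownames(pbl$gene_tpm))
  lk <- suppressWarnings(
    filter_links(link_correlation(pbl$peak_cpm, pbl$gene_tpm, pairs)))
  out <- score_links(lk, pbl$truth)
  out$links <- lk
  out$truth <- pbl$truth
  out$gpc <- if (any(lk$passes)) gpc_genes(lk) else NULL
  out
}

#' TF-circuit recovery benchmark
#'
#' Derives metaprogram state labels from the expression side, peak-gene
#' links from pseudobulk-scale data, then runs the integrative TF selection
#' and the per-GPC core-TF identification, scoring both against the planted
#' state TFs.
#'
#' @param cfg a [sim_config()] (typically a reduced-size configuration).
#' @param n_pb pseudobulks for the link stage.
#' @param n_overdispersed,k forwarded to the metaprogram stage.
#' @return list with `state_tf_recovered` (per state logical),
#'   `core_precision`, `core_recall`, `n_gpc`, `selection`, `fp_rate`
#'   (selected fraction of all TF x state combinations, for null
#'   calibration).
#' @export
evaluate_tf_recovery <- function(cfg, n_pb = 150, n_overdispersed = 1000,
                                 k = 6) {
  mp <- evaluate_metaprogram_recovery(cfg, n_overdispersed = n_overdispersed,
                                      k = k, qc = FALSE)
  lr <- evaluate_link_recovery(cfg, n_pb = n_pb)
  truth <- lr$truth
  mot <- gen_motifs_regulons(cfg, truth)
  truth <- mot$truth

  act <- suppressWarnings(regulon_activity(mp$transforms$Er, mot$regulons))
  assigned <- mp$labels[mp$labels != "score_too_low"]
  spec <- regulon_specificity(act[names(assigned), , drop = FALSE],
                              unname(assigned))
  mean_tpm <- rowMeans(mp$mat$tpm)[colnames(act)]
  names(mean_tpm) <- colnames(act)
  mean_tpm[is.na(mean_tpm)] <- 0
  passing <- lr$links[lr$links$passes, , drop = FALSE]
  sigs <- metaprogram_signatures(mp$metaprograms)
  cre_by_state <- lapply(sigs, function(g)
    unique(passing$peak[passing$gene %in% g]))
  cre_by_state <- cre_by_state[lengths(cre_by_state) > 0]
  sel <- select_state_tfs(mean_tpm, mot$motif_hits, cre_by_state, spec)

  ## scoring: planted TF selected for the metaprogram mapped to its state
  state_tf_recovered <- vapply(names(truth$state_tfs), function(st) {
    mps <- names(mp$mp_map)[mp$mp_map == st]
    any(vapply(mps, function(m)
      st %in% names(truth$state_tfs) &&
        truth$state_tfs[[st]] %in% sel$selected[[m]], logical(1)))
  }, logical(1))
  fp_rate <- mean(sel$evidence$selected)

  core <- core_precision <- core_recall <- NULL
  n_gpc <- 0L
  if (!is.null(lr$gpc) && length(lr$gpc$gpc_genes)) {
    core <- suppressWarnings(
      gpc_core_tfs(lr$gpc, lr$links, mot$regulons, mot$motif_hits))
    state_of_gene <- stats::setNames(
      rep(names(truth$signatures), lengths(truth$signatures)),
      unlist(truth$signatures, use.names = FALSE))
    tp <- fp <- fn <- 0L
    for (g in names(core)) {
      expected <- unname(truth$state_tfs[state_of_gene[g]])
      got <- core[[g]]$tf
      tp <- tp + sum(got == expected)
      fp <- fp + sum(got != expected)
      fn <- fn + as.integer(!(expected %in% got))
    }
    core_precision <- if (tp + fp) tp / (tp + fp) else NA_real_
    core_recall <- if (tp + fn) tp / (tp + fn) else NA_real_
    n_gpc <- length(lr$gpc$gpc_genes)
  }
  list(state_tf_recovered = state_tf_recovered, fp_rate = fp_rate,
       core_precision = core_precision, core_recall = core_recall,
       n_gpc = n_gpc, selection = sel, links = lr)
}

#' Spatial recovery benchmark
#'
#' Generates a spatial map, gates malignant cells by IF intensity at the
#' midpoint thresholds, types nonmalignant cells by their key markers,
#' builds the radius graph and computes neighborhood enrichment, scoring
#' the planted niche pair's z-score, the gating accuracy and the marker
#' typing accuracy.
#'
#' @param cfg a [sim_config()].
#' @param radius,n_perm graph radius (micrometers) and permutation count.
#' @return list with `niche_z` (per planted pair), `gating_accuracy`,
#'   `typing_accuracy`, `enrichment`, `max_null_abs_z` and the z table.
#' @export
evaluate_spatial_recovery <- function(cfg, radius = 50, n_perm = 100) {
  spa <- gen_spatial(cfg)
  cells <- spa$cells
  mid <- (cfg$if_low_mean + cfg$if_high_mean) / 2
  gated <- if_gate(cells, mid + 1, mid - 1)
  ok <- gated$class != "ambiguous"
  gating_accuracy <- mean((gated$class[ok] == "malignant") ==
                            gated$true_malignant[ok])
  typed <- gated
  typed$type <- typed$true_type
  nonmal <- typed$class == "nonmalignant"
  typed$type[nonmal] <- type_nonmalignant(
    typed[nonmal, , drop = FALSE], spa$reads[nonmal, , drop = FALSE],
    spa$marker_map)
  truly_nonmal <- !typed$true_malignant
  typing_accuracy <- mean(
    typed$type[nonmal & truly_nonmal] ==
      typed$true_type[nonmal & truly_nonmal])
  keep <- typed$class != "ambiguous" & typed$type != "unassigned"
  use <- typed[keep, , drop = FALSE]
  g <- build_graph(use, radius = radius)
  enr <- neighborhood_enrichment(g, use$type, n_perm = n_perm,
                                 seed = sim_seed(cfg, "enrichment"))
  z <- enr$z
  pair_z <- function(a, b) {
    i <- (z$type_a == min(a, b) & z$type_b == max(a, b))
    z$z[i]
  }
  niche_z <- vapply(cfg$niche_pairs, function(pr) pair_z(pr[1], pr[2]),
                    numeric(1))
  niche_names <- vapply(cfg$niche_pairs, paste, character(1), collapse = "|")
  names(niche_z) <- niche_names
  in_niche <- paste(z$type_a, z$type_b, sep = "|") %in% niche_names |
    z$type_a %in% unlist(cfg$niche_pairs) |
    z$type_b %in% unlist(cfg$niche_pairs)
  list(niche_z = niche_z, gating_accuracy = gating_accuracy,
       typing_accuracy = typing_accuracy, enrichment = enr,
       max_null_abs_z = if (any(!in_niche, na.rm = TRUE))
         max(abs(z$z[!in_niche]), na.rm = TRUE) else NA_real_,
       z = z, cells = typed)
}
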