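#' Default pipeline configuration
#'
#' All stage parameters at their published defaults: expression QC
#' 2000 genes / housekeeping E 2.5 (fresh) and 1000 genes / alignment 0.4
#' (frozen); gene filter TPM > 16 in < 10 cells; 10,000 over-dispersed
#' genes; NMF k = 6 with top-30 gene programs; assignment threshold 0.2;
#' snATAC QC 200 peaks / 10 nuclei / fragments 1500-15000 / 15% reads in
#' peaks / blacklist 0.02 / nucleosome 2 / TSS enrichment 4; 200 pseudobulks
#' of 1 + 99 cells; 250 kb candidate window; link filter |PCC| > 0.2 and
#' q < 0.05; GPC top 5%; TF filter mean TPM > 4 and top-30 specificity;
#' spatial radius 50 um with 100 permutations.
#'
#' @param seed global seed; every stochastic stage derives its stream from
#'   it.
#' @param sim a [sim_config()] describing the synthetic cohort (its seed is
#'   overridden by `seed`).
#' @return nested configuration list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1L, sim = NULL) {
  if (is.null(sim)) sim <- sim_config(seed = seed)
  sim$seed <- as.integer(seed)
  cfg <- list(
    seed = as.integer(seed),
    sim = sim,
    stages = c("simulate", "rna", "metaprograms", "atac", "integrate",
               "links", "tfs", "spatial"),
    rna = list(fresh_min_genes = 2000, fresh_min_hk = 2.5,
               frozen_min_genes = 1000, frozen_min_align = 0.4,
               gene_min_tpm = 16, gene_min_cells = 10),
    metaprograms = list(n_overdispersed = 10000, k = 6, top_n = 30,
                        n_meta = length(sim$states),
                        assign_threshold = 0.2,
                        frozen_exclude_prefix = "^RP[SL]"),
    atac = list(min_peaks = 200, min_nuclei_per_peak = 10,
                frag_lo = 1500, frag_hi = 15000, min_pct = 15,
                max_blacklist = 0.02, max_nucleosome = 2, min_tss = 4,
                lsi_d = 30, drop_depth_corr = 0.5, top_frac = 0.25,
                upstream = 2000),
    integrate = list(cca_d = 20, cca_var_genes = 1000, n_seeds = 200,
                     k_neighbors = 99),
    links = list(window = 250000, min_abs_r = 0.2, alpha = 0.05,
                 gpc_top_frac = 0.05),
    tfs = list(tpm_min = 4, top_n = 30, alpha = 0.05),
    spatial = list(radius = 50, n_perm = 100,
                   if_min_malignant = NA_real_,
                   if_max_nonmalignant = NA_real_))
  class(cfg) <- "pipeline_config"
  cfg
}

validate_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (sec in c("rna", "metaprograms", "atac", "integrate", "links",
                "tfs")) {
    for (nm in names(config[[sec]])) {
      if (grepl("prefix", nm)) next  # character-valued options
      if (!is.numeric(config[[sec]][[nm]]))
        stop("run_pipeline: all stage thresholds must be numeric (",
             sec, "$", nm, ")")
    }
  }
  invisible(config)
}

stage_out <- function(run_dir, stage) {
  d <- file.path(run_dir, stage)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

write_provenance <- function(dir, stage, params, seed, inputs = character(0)) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  jsonlite::write_json(list(stage = stage, params = params, seed = seed,
                            input_md5 = hashes),
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full synthetic-cohort pipeline
#'
#' Executes the stages in dependency order (simulate, expression QC and
#' transforms, metaprograms and state assignment, snATAC QC/LSI/activity,
#' cross-modality integration and pseudobulks, CRE-gene links and GPCs, TF
#' circuits, spatial analysis), writing each stage's outputs and a JSON
#' provenance record (parameters, seed, input hashes) under `run_dir`.
#' Reruns with the same config are bit-reproducible.
#'
#' @param config a `pipeline_config` from [default_config()].
#' @param run_dir output directory (created).
#' @return (invisibly) a list with every stage's in-memory results.
#' @export
run_pipeline <- function(config, run_dir) {
  validate_config(config)
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = config)
  on <- function(s) s %in% config$stages

  if (on("simulate")) {
    sim <- gen_expression(config$sim)
    atac <- gen_atac(config$sim, sim$truth)
    mot <- gen_motifs_regulons(config$sim, atac$truth)
    spa <- gen_spatial(config$sim, mot$truth)
    res$truth <- spa$truth
    res$expr <- sim$mat
    res$atac_raw <- atac
    res$regulons <- mot$regulons
    res$motif_hits <- mot$motif_hits
    res$spatial_raw <- spa
    d <- stage_out(run_dir, "simulate")
    write_mtx(res$expr$tpm, file.path(d, "tpm"))
    write_tsv(res$expr$cells, file.path(d, "cells.tsv"))
    write_tsv(res$expr$genes, file.path(d, "genes.tsv"))
    write_mtx(atac$mat$counts, file.path(d, "peak_counts"))
    write_bed(atac$mat$peaks, file.path(d, "peaks.bed"))
    write_bed(atac$annotation, file.path(d, "genes.bed"))
    utils::write.csv(atac$qc, file.path(d, "atac_qc.csv"),
                     row.names = FALSE)
    utils::write.csv(spa$cells, file.path(d, "spatial_cells.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(signatures = res$truth$signatures,
           state_tfs = as.list(res$truth$state_tfs),
           true_links = res$truth$true_links),
      file.path(d, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
    write_provenance(d, "simulate", unclass(config$sim), config$sim$seed)
  }

  if (on("rna")) {
    if (is.null(res$expr)) stop("run_pipeline: stage 'rna' needs 'simulate'")
    p <- config$rna
    filt <- qc_filter_cells(res$expr,
                            fresh_min_genes = p$fresh_min_genes,
                            fresh_min_hk = p$fresh_min_hk,
                            frozen_min_genes = p$frozen_min_genes,
                            frozen_min_align = p$frozen_min_align)
    filt <- qc_filter_genes(filt, p$gene_min_tpm, p$gene_min_cells)
    res$expr_qc <- filt
    res$transforms <- transform_expression(filt)
    d <- stage_out(run_dir, "rna")
    write_tsv(filt$cells, file.path(d, "cells_kept.tsv"))
    write_provenance(d, "rna", p, config$seed)
  }

  if (on("metaprograms")) {
    if (is.null(res$transforms))
      stop("run_pipeline: stage 'metaprograms' needs 'rna'")
    p <- config$metaprograms
    od <- suppressWarnings(
      select_overdispersed_genes(res$expr_qc, p$n_overdispersed))
    programs <- list()
    for (s in unique(res$expr_qc$cells$sample_id)) {
      sel <- res$expr_qc$cells$sample_id == s
      cells_s <- res$expr_qc$cells$cell_id[sel]
      frozen <- all(res$expr_qc$cells$protocol[sel] == "frozen")
      pr <- run_sample_nmf(res$transforms$Er[, cells_s, drop = FALSE],
                           od, k = p$k, sample_id = s, top_n = p$top_n,
                           exclude_prefix = if (frozen)
                             p$frozen_exclude_prefix else NULL)
      programs <- c(programs, pr)
    }
    scores <- score_programs(res$transforms$Er, programs)
    metas <- cluster_and_merge(programs, scores, n_meta = p$n_meta,
                               top_n = p$top_n)
    mscore <- score_signatures(res$transforms$Er,
                               metaprogram_signatures(metas))
    labels <- assign_state(mscore, threshold = p$assign_threshold)
    res$programs <- programs
    res$metaprograms <- metas
    res$state_scores <- mscore
    res$state_labels <- labels
    d <- stage_out(run_dir, "metaprograms")
    jsonlite::write_json(metas$metaprograms,
                         file.path(d, "metaprograms.json"),
                         auto_unbox = TRUE, digits = NA)
    write_tsv(data.frame(cell_id = names(labels), state = unname(labels)),
              file.path(d, "state_labels.tsv"))
    write_newick(metas$hclust, file.path(d, "program_dendrogram.nwk"))
    write_provenance(d, "metaprograms", p, config$seed)
  }

  if (on("atac")) {
    if (is.null(res$atac_raw))
      stop("run_pipeline: stage 'atac' needs 'simulate'")
    p <- config$atac
    am <- qc_filter_atac(res$atac_raw$mat, res$atac_raw$qc,
                         min_peaks = p$min_peaks,
                         min_nuclei_per_peak = p$min_nuclei_per_peak,
                         frag_lo = p$frag_lo, frag_hi = p$frag_hi,
                         min_pct = p$min_pct,
                         max_blacklist = p$max_blacklist,
                         max_nucleosome = p$max_nucleosome,
                         min_tss = p$min_tss)
    res$atac_qc_mat <- am
    res$lsi <- tfidf_lsi(am, d = p$lsi_d,
                         drop_depth_corr = p$drop_depth_corr,
                         top_frac = p$top_frac)
    res$activity <- gene_activity(am, res$atac_raw$annotation,
                                  upstream = p$upstream)
    d <- stage_out(run_dir, "atac")
    write_mtx(res$activity$activity, file.path(d, "gene_activity"))
    utils::write.table(round(res$lsi$coords, 10),
                       file.path(d, "lsi_coords.tsv"),
                       sep = "\t", quote = FALSE, col.names = FALSE)
    write_provenance(d, "atac", p, config$seed)
  }

  if (on("integrate")) {
    if (is.null(res$lsi) || is.null(res$transforms))
      stop("run_pipeline: stage 'integrate' needs 'rna' and 'atac'")
    p <- config$integrate
    ## per-gene per-sample centering of both modalities before CCA: the
    ## linear stand-in for the Harmony correction used upstream of matching
    Ec <- t(center_by_sample(t(res$transforms$E),
                             res$expr_qc$cells$sample_id))
    A <- as.matrix(res$activity$activity)
    Ac <- t(center_by_sample(t(A),
                             res$truth$nucleus_samples[colnames(A)]))
    shared <- intersect(rownames(Ec), rownames(Ac))
    ## CCA on the union of the most variable genes of each modality
    vr <- apply(Ec[shared, , drop = FALSE], 1, stats::var)
    va <- apply(Ac[shared, , drop = FALSE], 1, stats::var)
    take <- min(p$cca_var_genes, length(shared))
    cca_genes <- union(shared[order(-vr)][seq_len(take)],
                       shared[order(-va)][seq_len(take)])
    res$joint <- joint_cca(Ec, Ac, cca_genes, d = p$cca_d,
                           dim_select = TRUE)
    res$match <- match_modalities(res$joint)
    nuc_samples <- res$truth$nucleus_samples[rownames(res$lsi$coords)]
    corrected <- center_by_sample(res$lsi$coords, nuc_samples)
    res$atac_corrected <- corrected
    res$pseudobulks <- build_pseudobulks(
      corrected, res$atac_qc_mat, res$match, res$expr_qc$tpm,
      n_seeds = p$n_seeds, k_neighbors = p$k_neighbors,
      seed = sim_seed(config$sim, "pseudobulk"))
    d <- stage_out(run_dir, "integrate")
    jsonlite::write_json(res$pseudobulks$members,
                         file.path(d, "pseudobulk_members.json"),
                         auto_unbox = FALSE)
    write_mtx(res$pseudobulks$peak_cpm, file.path(d, "pseudobulk_peak_cpm"))
    write_provenance(d, "integrate", p, config$seed)
  }

  if (on("links")) {
    if (is.null(res$pseudobulks))
      stop("run_pipeline: stage 'links' needs 'integrate'")
    p <- config$links
    pairs <- candidate_pairs(res$atac_qc_mat$peaks,
                             res$atac_raw$annotation,
                             expressed_genes = rownames(res$expr_qc$tpm),
                             window = p$window)
    lk <- link_correlation(res$pseudobulks$peak_cpm,
                           res$pseudobulks$gene_tpm, pairs)
    lk <- filter_links(lk, min_abs_r = p$min_abs_r, alpha = p$alpha)
    res$links <- lk
    res$gpc <- if (any(lk$passes))
      gpc_genes(lk, top_frac = p$gpc_top_frac) else NULL
    d <- stage_out(run_dir, "links")
    write_tsv(lk, file.path(d, "links.tsv"))
    if (!is.null(res$gpc)) {
      jsonlite::write_json(list(threshold = res$gpc$threshold,
                                gpc_genes = res$gpc$gpc_genes,
                                counts = as.list(res$gpc$counts)),
                           file.path(d, "gpc.json"),
                           auto_unbox = TRUE, digits = NA)
      passing <- lk[lk$passes, , drop = FALSE]
      write_bed(res$atac_qc_mat$peaks[unique(passing$peak)],
                file.path(d, "passing_cres.bed"))
    }
    write_provenance(d, "links", p, config$seed)
  }

  if (on("tfs")) {
    if (is.null(res$links) || is.null(res$state_labels))
      stop("run_pipeline: stage 'tfs' needs 'links' and 'metaprograms'")
    p <- config$tfs
    act <- suppressWarnings(
      regulon_activity(res$transforms$Er, res$regulons))
    assigned <- res$state_labels[res$state_labels != "score_too_low"]
    spec <- regulon_specificity(act[names(assigned), , drop = FALSE],
                                unname(assigned))
    mean_tpm <- rowMeans(res$expr_qc$tpm)[colnames(act)]
    names(mean_tpm) <- colnames(act)
    mean_tpm[is.na(mean_tpm)] <- 0  # TF gene removed by gene QC
    passing <- res$links[res$links$passes, , drop = FALSE]
    sigs <- metaprogram_signatures(res$metaprograms)
    cre_by_state <- lapply(sigs, function(g)
      unique(passing$peak[passing$gene %in% g]))
    cre_by_state <- cre_by_state[lengths(cre_by_state) > 0]
    res$regulon_activity <- act
    res$regulon_spec <- spec
    res$tf_selection <- select_state_tfs(
      mean_tpm, res$motif_hits[rownames(res$atac_qc_mat$counts), ,
                               drop = FALSE],
      cre_by_state, spec, tpm_min = p$tpm_min, top_n = p$top_n,
      alpha = p$alpha)
    res$core_tfs <- if (!is.null(res$gpc))
      gpc_core_tfs(res$gpc, res$links, res$regulons,
                   res$motif_hits[rownames(res$atac_qc_mat$counts), ,
                                  drop = FALSE], alpha = p$alpha)
      else NULL
    d <- stage_out(run_dir, "tfs")
    write_tsv(res$tf_selection$evidence, file.path(d, "tf_evidence.tsv"))
    jsonlite::write_json(lapply(res$regulons, identity),
                         file.path(d, "regulons.json"), auto_unbox = FALSE)
    write_provenance(d, "tfs", p, config$seed)
  }

  if (on("spatial")) {
    if (is.null(res$spatial_raw))
      stop("run_pipeline: stage 'spatial' needs 'simulate'")
    p <- config$spatial
    cells <- res$spatial_raw$cells
    lo <- if (is.na(p$if_max_nonmalignant))
      (config$sim$if_low_mean + config$sim$if_high_mean) / 2 - 1 else
        p$if_max_nonmalignant
    hi <- if (is.na(p$if_min_malignant))
      (config$sim$if_low_mean + config$sim$if_high_mean) / 2 + 1 else
        p$if_min_malignant
    gated <- if_gate(cells, hi, lo)
    typed <- gated
    nonmal <- typed$class == "nonmalignant"
    typed$type <- typed$true_type
    typed$type[nonmal] <- type_nonmalignant(
      typed[nonmal, , drop = FALSE],
      res$spatial_raw$reads[nonmal, , drop = FALSE],
      res$spatial_raw$marker_map)
    keep <- typed$class != "ambiguous" & typed$type != "unassigned"
    use <- typed[keep, , drop = FALSE]
    g <- build_graph(use, radius = p$radius)
    enr <- neighborhood_enrichment(g, use$type, n_perm = p$n_perm,
                                   seed = sim_seed(config$sim, "enrichment"))
    cent <- centrality_scores(g, use$type)
    res$spatial <- list(cells = typed, graph = g, enrichment = enr,
                        centrality = cent)
    d <- stage_out(run_dir, "spatial")
    write_tsv(enr$z, file.path(d, "neighborhood_z.tsv"))
    write_tsv(cent, file.path(d, "centrality.tsv"))
    utils::write.csv(typed, file.path(d, "typed_cells.csv"),
                     row.names = FALSE)
    write_provenance(d, "spatial", p, config$seed)
  }

  invisible(res)
}
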