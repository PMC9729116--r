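## Closed-form calibration of the Poisson state coupling for planted CREs.
##
## A pseudobulk of n_cells members, state-pure with probability p per state,
## has summed true-CRE counts T ~ Pois(A (1 + beta X)) with A = n_cells * mu0
## and X the pseudobulk-state indicator. Solving
##   corr(T, X)^2 = r^2  with  Var(T) = A(1+beta p) + A^2 beta^2 p(1-p)
## for beta gives the positive root of
##   A p (1-p) (1 - r^2) beta^2 - r^2 p beta - r^2 = 0.
## The gene side of a planted pair is nearly noise-free at 100-cell
## aggregation, so the pair correlation lands close to r = link_strength.
calibrate_link_beta <- function(link_strength, p_state, n_cells, mu0) {
  r2 <- link_strength^2
  A <- n_cells * mu0
  a <- A * p_state * (1 - p_state) * (1 - r2)
  b <- -r2 * p_state
  cc <- -r2
  (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
}

## Distance from a position to every TSS; returns the nearest gene(s).
nearest_tss_gene <- function(pos, tss) {
  d <- abs(tss - pos)
  names(tss)[d == min(d)]
}

#' Generate a synthetic snATAC dataset coupled to the expression ground truth
#'
#' Genes are placed on one synthetic chromosome at fixed spacing with
#' alternating strand. Three peak families are planted: (1) distal true-link
#' CREs within 250 kb of their target gene's TSS (and nearest to it), with a
#' Poisson rate coupled to the nucleus' state so the planted pair reaches
#' `link_strength` at pseudobulk level; (2) promoter-proximal "driver" peaks
#' inside the bodies of half of each state's signature genes with strongly
#' state-coupled accessibility -- these model marker-gene promoter
#' accessibility, feed the gene-activity/LSI/CCA embeddings, and are
#' themselves genuinely linked to their host gene (recorded in the ground
#' truth as `promoter_links`); (3) uncoupled background peaks carrying the
#' bulk of the library, so that state-coupled counts stay a sub-percent
#' fraction of totals and CPM normalization does not imprint cell state on
#' unrelated peaks. The QC table is populated so that about
#' `atac_qc_fail_frac` of nuclei fail each paper threshold, independently
#' per criterion.
#'
#' @param cfg a [sim_config()].
#' @param truth ground truth from [gen_expression()].
#' @return list with `mat` ([peak_matrix()]), `annotation`
#'   ([gene_annotation()]), `qc` (per-nucleus QC table), and `truth` extended
#'   with nucleus states and the planted peak-gene link table.
#' @export
gen_atac <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(sim_seed(cfg, "atac"))

  gene_ids <- sprintf("g%05d", seq_len(cfg$n_genes))
  start0 <- (seq_len(cfg$n_genes) - 1) * cfg$gene_spacing
  strand <- rep(c("+", "-"), length.out = cfg$n_genes)
  ann <- gene_annotation(gene_ids, "chrS", start0, start0 + cfg$gene_length,
                         strand)
  tss <- tss_positions(ann)
  chrom_len <- max(start0) + cfg$gene_spacing + cfg$gene_length

  plan <- plan_true_links(cfg, truth$signatures)
  ## promoter drivers sit on every other signature gene of each state
  driver_genes <- unlist(lapply(truth$signatures, function(g)
    g[seq(1, length(g), by = 2)]), use.names = FALSE)
  n_driver <- length(driver_genes)
  n_true <- plan$n_true
  if (cfg$n_peaks < n_driver + n_true + 10L)
    stop("gen_atac: n_peaks too small to host the planted peaks")

  place_near_tss <- function(gene, max_off = 20000) {
    for (i in 1:50) {
      pos <- round(tss[gene] + stats::runif(1, -max_off, max_off))
      if (identical(nearest_tss_gene(pos, tss)[1], gene) &&
          length(nearest_tss_gene(pos, tss)) == 1) return(pos)
    }
    stop("gen_atac: could not place a CRE near ", gene)
  }
  ## promoter-proximal, inside the gene body (drives the activity score),
  ## own TSS guaranteed nearest
  place_promoter <- function(gene) {
    g <- ann[gene]
    plus <- as.character(GenomicRanges::strand(g)) == "+"
    for (i in 1:50) {
      off <- round(stats::runif(1, 500, 15000))
      pos <- if (plus) tss[gene] + off else tss[gene] - off
      if (identical(nearest_tss_gene(pos, tss)[1], gene) &&
          length(nearest_tss_gene(pos, tss)) == 1 &&
          pos > GenomicRanges::start(g) && pos < GenomicRanges::end(g))
        return(pos)
    }
    stop("gen_atac: could not place a promoter driver for ", gene)
  }

  true_pos <- vapply(plan$gene, place_near_tss, numeric(1))
  driver_pos <- vapply(driver_genes, place_promoter, numeric(1))
  n_bg <- cfg$n_peaks - n_true - n_driver
  bg_pos <- round(stats::runif(n_bg, 1000, chrom_len - 1000))

  centers <- c(true_pos, driver_pos, bg_pos)
  kind <- c(rep("cre", n_true), rep("driver", n_driver), rep("bg", n_bg))
  target <- c(plan$gene, driver_genes, rep(NA_character_, n_bg))
  half <- cfg$peak_width %/% 2
  peaks <- GenomicRanges::GRanges("chrS",
                                  IRanges::IRanges(centers - half,
                                                   centers + half - 1))
  peak_ids <- sprintf("peak%05d", seq_len(cfg$n_peaks))
  names(peaks) <- peak_ids

  ## nucleus cohort mirrors the expression cohort layout
  n_nuc <- cfg$n_samples * cfg$cells_per_sample
  nuc_ids <- sprintf("n%05d", seq_len(n_nuc))
  nuc_sample <- rep(sprintf("S%02d", seq_len(cfg$n_samples)),
                    each = cfg$cells_per_sample)
  nuc_state <- sample(c(cfg$states, "none"), n_nuc, replace = TRUE,
                      prob = c(rep((1 - cfg$frac_noise_cells) /
                                     length(cfg$states), length(cfg$states)),
                               cfg$frac_noise_cells))
  depth <- exp(stats::rnorm(n_nuc, 0, 0.3))

  state_of_gene <- stats::setNames(
    rep(names(truth$signatures), lengths(truth$signatures)),
    unlist(truth$signatures, use.names = FALSE))
  p_state <- mean(nuc_state == cfg$states[1]) * 0 +
    (1 - cfg$frac_noise_cells) / length(cfg$states)
  mu0_cre <- 0.5
  beta <- calibrate_link_beta(cfg$link_strength, p_state, cfg$pb_cells,
                              mu0_cre)

  ## background carries most of the library (state-coupled peaks stay a
  ## small fraction of total counts, as at genome scale)
  base_rate <- numeric(cfg$n_peaks)
  base_rate[kind == "bg"] <- stats::rlnorm(n_bg, log(1), 0.5)
  base_rate[kind == "cre"] <- mu0_cre
  base_rate[kind == "driver"] <- 1

  ## rate matrix: base * depth, with state multipliers for planted peaks
  lam <- outer(base_rate, depth)
  mult <- matrix(1, cfg$n_peaks, n_nuc)
  for (st in cfg$states) {
    in_state <- nuc_state == st
    if (!any(in_state)) next
    cre_rows <- which(kind == "cre" & state_of_gene[target] == st)
    drv_rows <- which(kind == "driver" & state_of_gene[target] == st)
    if (length(cre_rows))
      mult[cre_rows, in_state] <- 1 + beta
    if (length(drv_rows))
      mult[drv_rows, in_state] <- 5
  }
  ## continuous, modality-private accessibility gradient across nuclei
  ## (cell stress / cycle-like variation): every background peak carries a
  ## random loading on a per-nucleus latent factor. This reproduces the
  ## within-population heterogeneity of real snATAC data; without it,
  ## same-state pseudobulks are near-replicates of each other and the
  ## fixed finite count draws masquerade as between-state structure in
  ## every background peak.
  t_nuc <- stats::rnorm(n_nuc)
  s_pk <- numeric(cfg$n_peaks)
  if (cfg$atac_gradient_sd > 0 && n_bg > 0) {
    bg_rows <- which(kind == "bg")
    s_pk[bg_rows] <- stats::rnorm(n_bg, 0, cfg$atac_gradient_sd)
    lam[bg_rows, ] <- lam[bg_rows, ] *
      exp(outer(s_pk[bg_rows], t_nuc) - 0.5 * s_pk[bg_rows]^2)
  }
  counts <- matrix(stats::rpois(length(lam), lam * mult),
                   cfg$n_peaks, n_nuc, dimnames = list(peak_ids, nuc_ids))
  mat <- peak_matrix(Matrix::Matrix(counts, sparse = TRUE), peaks)

  ## synthetic QC metrics: passing draws plus planted failures per criterion
  n_fail <- floor(cfg$atac_qc_fail_frac * n_nuc)
  fail_set <- function() if (n_fail > 0) sample.int(n_nuc, n_fail) else
    integer(0)
  frags <- round(stats::rlnorm(n_nuc, log(5000), 0.25))
  frags <- pmin(pmax(frags, 1600), 14000)
  frags[fail_set()] <- 500
  pct <- stats::runif(n_nuc, 20, 80); pct[fail_set()] <- 10
  bl <- stats::runif(n_nuc, 0, 0.015); bl[fail_set()] <- 0.05
  ns <- stats::runif(n_nuc, 0.3, 1.5); ns[fail_set()] <- 3
  te <- stats::runif(n_nuc, 5, 12); te[fail_set()] <- 3
  qc <- data.frame(nucleus_id = nuc_ids, sample_id = nuc_sample,
                   peak_region_fragments = frags, pct_reads_in_peaks = pct,
                   blacklist_ratio = bl, nucleosome_signal = ns,
                   tss_enrichment = te, stringsAsFactors = FALSE)

  truth$nucleus_states <- stats::setNames(nuc_state, nuc_ids)
  truth$nucleus_samples <- stats::setNames(nuc_sample, nuc_ids)
  truth$true_links <- data.frame(peak = peak_ids[kind == "cre"],
                                 gene = target[kind == "cre"],
                                 stringsAsFactors = FALSE)
  ## promoter drivers are genuinely state-coupled peaks at their host
  ## gene's promoter: their peak-gene correlations are true positives
  truth$promoter_links <- data.frame(peak = peak_ids[kind == "driver"],
                                     gene = target[kind == "driver"],
                                     stringsAsFactors = FALSE)
  truth$link_beta <- beta
  truth$atac_gradient <- stats::setNames(t_nuc, nuc_ids)
  truth$peak_gradient_loading <- stats::setNames(s_pk, peak_ids)
  truth$peak_base_rate <- stats::setNames(base_rate, peak_ids)
  truth$peak_kind <- stats::setNames(kind, peak_ids)
  truth$p_state <- p_state
  list(mat = mat, annotation = ann, qc = qc, truth = truth)
}

#' Generate planted TF regulons and a peak x TF motif-hit matrix
#'
#' One TF per state (the first gene of the state's signature) with regulon
#' targets equal to that state's signature genes; motif hits are
#' Bernoulli(`motif_fg_p`) in the true CREs linked to the TF's state genes
#' and Bernoulli(`motif_bg_p`) elsewhere. Decoy TFs with random regulons get
#' background rates everywhere.
#'
#' @param cfg a [sim_config()].
#' @param truth ground truth from [gen_atac()] (needs `true_links`).
#' @return list with `regulons` (named list TF -> targets), `motif_hits`
#'   (sparse logical peaks x TFs) and `truth` extended with `state_tfs`.
#' @export
gen_motifs_regulons <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(truth$true_links))
    stop("gen_motifs_regulons: run gen_atac first")
  set.seed(sim_seed(cfg, "motifs"))
  peak_ids <- sprintf("peak%05d", seq_len(cfg$n_peaks))
  gene_ids <- sprintf("g%05d", seq_len(cfg$n_genes))

  state_tfs <- truth$tf_genes
  regulons <- stats::setNames(truth$signatures[names(state_tfs)],
                              unname(state_tfs))
  sig_genes <- unlist(truth$signatures, use.names = FALSE)
  decoys <- character(0)
  if (cfg$n_decoy_tfs > 0) {
    nonsig <- setdiff(setdiff(gene_ids, sig_genes), truth$housekeeping)
    decoys <- sample(nonsig, cfg$n_decoy_tfs)
    for (d in decoys)
      regulons[[d]] <- sample(setdiff(nonsig, d),
                              min(25L, length(nonsig) - 1L))
  }
  tfs <- names(regulons)

  state_of_gene <- stats::setNames(
    rep(names(truth$signatures), lengths(truth$signatures)),
    sig_genes)
  hits <- matrix(stats::runif(cfg$n_peaks * length(tfs)) < cfg$motif_bg_p,
                 cfg$n_peaks, length(tfs),
                 dimnames = list(peak_ids, tfs))
  linked <- rbind(truth$true_links, truth$promoter_links)
  for (st in names(state_tfs)) {
    cre <- linked$peak[state_of_gene[linked$gene] == st]
    if (length(cre))
      hits[cre, state_tfs[[st]]] <-
        stats::runif(length(cre)) < cfg$motif_fg_p
  }
  truth$state_tfs <- state_tfs
  truth$decoy_tfs <- decoys
  list(regulons = regulons,
       motif_hits = Matrix::Matrix(hits, sparse = TRUE),
       truth = truth)
}
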