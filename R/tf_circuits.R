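#' Regulon activity per cell
#'
#' Activity of a TF regulon in a cell is the mean relative expression of the
#' regulon's target genes ([score_signature()]); TFs whose targets are absent
#' from the matrix are dropped with a warning.
#'
#' @param Er relative-expression matrix or `expr_transforms`.
#' @param regulons named list: TF -> character vector of targets.
#' @return cell x TF activity matrix.
#' @export
regulon_activity <- function(Er, regulons) {
  if (inherits(Er, "expr_transforms")) Er <- Er$Er
  stopifnot(length(regulons) >= 1, !is.null(names(regulons)))
  ok <- vapply(regulons,
               function(g) length(intersect(g, rownames(Er))) > 0,
               logical(1))
  if (!all(ok))
    warning("regulon_activity: dropping TF(s) with no targets in matrix: ",
            paste(names(regulons)[!ok], collapse = ", "))
  score_signatures(Er, regulons[ok])
}

## Jensen-Shannon divergence between two distributions, base-2 logs
jsd <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Regulon specificity scores (RSS)
#'
#' Each TF's activity vector is shifted to be nonnegative and normalized to
#' a distribution over cells; the specificity for a state is
#' `1 - sqrt(JSD(activity distribution, uniform indicator of the state's
#' cells))` with base-2 logarithms, so scores lie in `[0, 1]`. A constant
#' activity vector is treated as uniform over cells.
#'
#' @param activity cell x TF matrix from [regulon_activity()].
#' @param labels per-cell state labels.
#' @return TF x state specificity matrix.
#' @export
regulon_specificity <- function(activity, labels) {
  activity <- as.matrix(activity)
  stopifnot(length(labels) == nrow(activity))
  states <- sort(unique(labels))
  if (length(states) < 2)
    stop("regulon_specificity: need at least two states")
  if (any(table(labels) == 0)) stop("regulon_specificity: empty state")
  out <- matrix(NA_real_, ncol(activity), length(states),
                dimnames = list(colnames(activity), states))
  n <- nrow(activity)
  for (tf in seq_len(ncol(activity))) {
    a <- activity[, tf] - min(activity[, tf])
    p <- if (sum(a) > 0) a / sum(a) else rep(1 / n, n)
    for (s in seq_along(states)) {
      q <- as.numeric(labels == states[s])
      q <- q / sum(q)
      out[tf, s] <- 1 - sqrt(jsd(p, q))
    }
  }
  out
}

## one-sided (over-representation) hypergeometric p for motif counts
motif_enrichment_p <- function(hit_in_fg, n_fg, hit_in_universe, n_universe) {
  stats::phyper(hit_in_fg - 1, hit_in_universe,
                n_universe - hit_in_universe, n_fg, lower.tail = FALSE)
}

#' Select state-specific transcription factors
#'
#' A TF is selected for a state iff (1) its mean expression exceeds
#' `tpm_min` TPM (strict), (2) its motif is over-represented in the state's
#' CRE peaks against the all-CRE background (one-sided hypergeometric,
#' BH-adjusted across TFs within the state, q < `alpha`), and (3) its
#' specificity rank within the state is at most `top_n`.
#'
#' @param mean_tpm named vector of per-TF mean TPM.
#' @param motif_hits logical/sparse peaks x TF matrix.
#' @param cre_peaks_by_state named list: state -> peak ids of its CREs.
#' @param activity_spec TF x state matrix from [regulon_specificity()].
#' @param tpm_min,top_n,alpha thresholds (defaults 4, 30, 0.05).
#' @return list of class `tf_selection`: `selected` (state -> TFs) and
#'   `evidence` (per TF x state table).
#' @export
select_state_tfs <- function(mean_tpm, motif_hits, cre_peaks_by_state,
                             activity_spec, tpm_min = 4, top_n = 30,
                             alpha = 0.05) {
  tfs <- intersect(intersect(names(mean_tpm), colnames(motif_hits)),
                   rownames(activity_spec))
  if (!length(tfs)) stop("select_state_tfs: no TF covered by all inputs")
  states <- intersect(names(cre_peaks_by_state), colnames(activity_spec))
  universe <- unique(unlist(cre_peaks_by_state, use.names = FALSE))
  M <- as.matrix(motif_hits[universe, tfs, drop = FALSE]) > 0
  hit_tot <- colSums(M)
  ev <- list()
  selected <- stats::setNames(vector("list", length(states)), states)
  for (st in states) {
    fg <- intersect(cre_peaks_by_state[[st]], universe)
    hit_fg <- colSums(M[fg, , drop = FALSE])
    p <- motif_enrichment_p(hit_fg, length(fg), hit_tot, length(universe))
    q <- bh_adjust(p)
    rank_spec <- rank(-activity_spec[tfs, st], ties.method = "min")
    pass <- mean_tpm[tfs] > tpm_min & q < alpha & rank_spec <= top_n
    selected[[st]] <- tfs[pass]
    ev[[st]] <- data.frame(state = st, tf = tfs,
                           mean_tpm = unname(mean_tpm[tfs]),
                           n_cre = length(fg),
                           n_cre_with_motif = unname(hit_fg),
                           enrichment_q = unname(q),
                           specificity = unname(activity_spec[tfs, st]),
                           specificity_rank = unname(rank_spec),
                           selected = unname(pass),
                           stringsAsFactors = FALSE)
  }
  structure(list(selected = selected, evidence = do.call(rbind, ev)),
            class = "tf_selection")
}

#' Restrict passing CREs to a TSS-proximal window
#'
#' Subsets the passing links of [filter_links()] to CREs within `max_dist`
#' bp of their gene's TSS -- the promoter-proximal motif scope variant used
#' when enrichment should be computed over TSS +/- 10 kb elements only.
#'
#' @param links output of [filter_links()] (needs `distance` and `passes`).
#' @param max_dist maximum peak-midpoint-to-TSS distance in bp.
#' @return the links data.frame with `passes` set to FALSE outside the
#'   window.
#' @export
filter_cres_by_distance <- function(links, max_dist = 10000) {
  links$passes <- links$passes & links$distance <= max_dist
  links
}

#' Core TFs per gene with predictive chromatin
#'
#' For each GPC gene, a TF is "core" iff the gene belongs to the TF's
#' regulon targets *and* the TF's motif is enriched in the CREs linked to
#' that gene against the all-CRE background (one-sided hypergeometric,
#' BH-adjusted across the TFs tested for the gene, q < `alpha`).
#'
#' @param gpc a `gpc_set` from [gpc_genes()].
#' @param links output of [filter_links()].
#' @param regulons named list TF -> targets.
#' @param motif_hits peaks x TF matrix.
#' @param alpha q-value threshold (default 0.05).
#' @return named list: GPC gene -> data.frame of core TFs with evidence
#'   (`tf`, `n_linked_cre`, `n_with_motif`, `q`).
#' @export
gpc_core_tfs <- function(gpc, links, regulons, motif_hits, alpha = 0.05) {
  stopifnot(inherits(gpc, "gpc_set"))
  passing <- links[links$passes, , drop = FALSE]
  universe <- unique(passing$peak)
  M <- as.matrix(motif_hits[universe, , drop = FALSE]) > 0
  hit_tot <- colSums(M)
  targets_of <- regulons
  out <- list()
  for (g in gpc$gpc_genes) {
    cre <- unique(passing$peak[passing$gene == g])
    if (!length(cre)) {
      warning("gpc_core_tfs: GPC gene ", g, " has no passing link; skipped")
      next
    }
    tfs <- names(targets_of)[vapply(targets_of, function(t) g %in% t,
                                    logical(1))]
    if (!length(tfs)) {
      out[[g]] <- data.frame(tf = character(0), n_linked_cre = integer(0),
                             n_with_motif = integer(0), q = numeric(0))
      next
    }
    hit_fg <- colSums(M[cre, tfs, drop = FALSE])
    p <- motif_enrichment_p(hit_fg, length(cre), hit_tot[tfs],
                            length(universe))
    q <- bh_adjust(p)
    core <- q < alpha
    out[[g]] <- data.frame(tf = tfs[core],
                           n_linked_cre = rep(length(cre), sum(core)),
                           n_with_motif = unname(hit_fg[core]),
                           q = unname(q[core]),
                           stringsAsFactors = FALSE)
  }
  out
}
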