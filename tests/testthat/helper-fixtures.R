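# Shared fixtures and scaled study configurations, built in code.

# reduced-size configuration used by multi-seed recovery/null benchmarks
small_cfg <- function(seed, ...) {
  args <- list(seed = seed, n_samples = 4, cells_per_sample = 200,
               n_genes = 1500, signature_size = 20, n_peaks = 1500,
               frac_true_links = 100 / 1500, n_hk = 30,
               rna_qc_fail_frac = 0, spatial_n_cells = 800)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# tiny expression fixture with hand-settable TPM
tiny_expr <- function(tpm, protocol = "fresh", hk = character(0),
                      alignment = 0.9, sample_id = "S1") {
  cells <- data.frame(cell_id = colnames(tpm),
                      sample_id = rep_len(sample_id, ncol(tpm)),
                      protocol = rep_len(protocol, ncol(tpm)),
                      alignment_rate = rep_len(alignment, ncol(tpm)),
                      stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = rownames(tpm),
                      housekeeping = rownames(tpm) %in% hk,
                      stringsAsFactors = FALSE)
  expression_matrix(tpm, cells, genes)
}

named_mat <- function(data, nr, nc, rpre = "g", cpre = "c") {
  matrix(data, nr, nc,
         dimnames = list(sprintf("%s%03d", rpre, seq_len(nr)),
                         sprintf("%s%03d", cpre, seq_len(nc))))
}

# cached expensive runs, shared across test files within one session
.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

default_sim <- function() cached("default_sim", {
  gen_expression(sim_config(seed = 42))
})

default_atac <- function() cached("default_atac", {
  gen_atac(sim_config(seed = 42), default_sim()$truth)
})
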