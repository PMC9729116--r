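# dmgatlas

Multimodal dissection of H3-K27M diffuse midline glioma (DMG): an R package
implementing, as one tested pipeline, the computational core of a single-cell
multi-omics tumor atlas — who the cells are (expression metaprograms), what
chromatin drives them (CRE–gene links and transcription-factor circuits), and
where they sit in the tissue (spatial niches). It is written for
computational biologists who want each of these steps as callable, tested
functions rather than one-off scripts, and it ships a synthetic-data
generator with planted ground truth so the whole pipeline can be validated
without access to patient data.

## What it computes

* **Expression states.** From a gene × cell TPM matrix: QC (fresh cells
  ≥ 2,000 detected genes and mean housekeeping `E ≥ 2.5`; frozen cells
  ≥ 1,000 genes and alignment ≥ 0.4; genes with TPM > 16 in ≥ 10 cells), the
  transforms `E = log2(TPM/10 + 1)`, `Ea = log2(mean TPM + 1)`,
  `Er = E − rowMeans(E)`; per-sample rank-6 NMF on over-dispersed genes
  (deterministic NNDSVD + multiplicative updates), consensus metaprograms by
  Ward clustering of program scores on `1 − r`, top-30 genes by average NMF
  weight; cell-state assignment by argmax score with the 0.2
  `score_too_low` threshold; Wilcoxon/Bonferroni marker detection; TAM
  microglia/macrophage classification.
* **Chromatin.** snATAC QC (fragments 1,500–15,000, > 15% reads in peaks,
  blacklist < 0.02, nucleosome signal < 2, TSS enrichment > 4), log-TF-IDF +
  LSI on the top 25% of peaks with depth-correlated components dropped, and
  gene-activity scores over gene body + 2 kb promoter.
* **Links.** Diagonal-CCA matching of nuclei to cells, 200 pseudobulks of
  1 + 99 nearest neighbors (peak CPM / gene TPM), Pearson correlation with
  `t = r·sqrt((n−2)/(1−r²))`, BH over all candidate nearest-gene pairs
  within 250 kb, high-confidence links at `|PCC| > 0.2, q < 0.05`, and genes
  with predictive chromatin (GPCs) above the nearest-rank top-5% threshold
  of linked-CRE counts.
* **TF circuits.** Regulon activity (mean target `Er`), regulon specificity
  `1 − sqrt(JSD)`, state TFs by mean TPM > 4 + motif over-representation in
  state CREs + top-30 specificity, and per-GPC core TFs.
* **Space.** IF-intensity gating, key-marker typing, 50 µm neighbor graphs,
  100-permutation neighborhood z-scores, conditional colocalization,
  per-type degree centrality / clustering coefficient, Welch tests on
  per-sample proportions.

## Worked example

```r
library(dmgatlas)

# a 6-sample x 400-cell synthetic cohort with 5 planted states
res <- evaluate_metaprogram_recovery(sim_config(seed = 1))
round(res$signature_recovery, 2)
#  cycling OPC-like  AC-like  OC-like MES-like
#     1.00     1.00     1.00     1.00     1.00
res$accuracy          # 1            (state assignment on planted cells)
res$noise_flag_rate   # 1            (pure-noise cells hitting score_too_low)

# peak-gene link recovery at the published pseudobulk design
lr <- evaluate_link_recovery(sim_config(seed = 1))
c(recall = lr$recall, fdp = lr$fdp, pcc = lr$mean_planted_pcc)
#  recall     fdp     pcc
#   1.000   0.048   0.585
lr$gpc
# gpc_set: 6 GPC genes ( > 11 linked CREs; top-5% nearest-rank threshold
#          over 129 linked genes )
```

Recall is the fraction of the 200 planted distal CREs recovered at
`|PCC| > 0.2, q < 0.05`; `fdp` the realized false discovery proportion
against all planted couplings; `pcc` the mean correlation of planted links
(target 0.6, set by the generator's closed-form Poisson calibration). The
GPC set should contain the planted high-complexity "hub" genes.

The full pipeline, with every stage writing outputs and a JSON provenance
record, runs as

```r
run_pipeline(default_config(seed = 1), "results/run")
```

and the numbered drivers under `analysis/` tell the same story stage by
stage (`01_simulate.R` … `06_spatial.R`), writing tables under `results/`.

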