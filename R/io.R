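## On-disk interchange: MTX + row/col TSV for matrices, BED (0-based
## half-open) for peaks, TSV for tables, JSON for nested objects, Newick for
## dendrograms.

#' Write a matrix as MTX with row/column id sidecars
#' @param m matrix (sparse or dense).
#' @param prefix file prefix; writes `<prefix>.mtx`, `<prefix>.rows.tsv`,
#'   `<prefix>.cols.tsv`.
#' @export
write_mtx <- function(m, prefix) {
  sm <- methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                "CsparseMatrix"), "generalMatrix")
  Matrix::writeMM(sm, paste0(prefix, ".mtx"))
  writeLines(rownames(m), paste0(prefix, ".rows.tsv"))
  writeLines(colnames(m), paste0(prefix, ".cols.tsv"))
  invisible(prefix)
}

#' Read a matrix written by [write_mtx()]
#' @param prefix file prefix.
#' @return sparse matrix with dimnames.
#' @export
read_mtx <- function(prefix) {
  m <- Matrix::readMM(paste0(prefix, ".mtx"))
  dimnames(m) <- list(readLines(paste0(prefix, ".rows.tsv")),
                      readLines(paste0(prefix, ".cols.tsv")))
  methods::as(m, "CsparseMatrix")
}

#' Write genomic intervals as BED (0-based half-open)
#' @param gr named `GRanges`.
#' @param path output file.
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = names(gr),
                   score = 0L,
                   strand = as.character(GenomicRanges::strand(gr)))
  df$strand[df$strand == "*"] <- "."
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file into a `GRanges`
#' @param path BED file (>= 3 columns; name/strand used when present).
#' @return `GRanges` (1-based internal coordinates).
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  strand <- if (ncol(df) >= 6) ifelse(df[[6]] %in% c("+", "-"), df[[6]], "*")
    else "*"
  gr <- GenomicRanges::GRanges(df[[1]],
                               IRanges::IRanges(df[[2]] + 1L, df[[3]]),
                               strand = strand)
  if (ncol(df) >= 4) names(gr) <- df[[4]]
  gr
}

#' Write a table as TSV
#' @param df data.frame.
#' @param path output file.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an hclust dendrogram as Newick
#' @param hc an `hclust` object.
#' @param path output file.
#' @export
write_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), path)
  invisible(path)
}
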