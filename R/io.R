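#' Write a sparse contact matrix as 3-column text
#'
#' Upper-triangle triplets "bin_i bin_j count" (1-based bins, tab-separated)
#' plus a binning sidecar `<path>.bins` with chrom/start/end per bin when a
#' binning is supplied. Round-trips through [read_sparse_matrix()].
#'
#' @param M sparse symmetric matrix.
#' @param path output file.
#' @param binning optional [genome_binning()] for the sidecar.
#' @export
write_sparse_matrix <- function(M, path, binning = NULL) {
  T <- methods::as(Matrix::triu(M), "TsparseMatrix")
  dt <- data.table::data.table(bin_i = T@i + 1L, bin_j = T@j + 1L, count = T@x)
  data.table::setorder(dt, bin_i, bin_j)
  data.table::fwrite(dt, path, sep = "\t")
  if (!is.null(binning)) {
    data.table::fwrite(data.table::data.table(
      chrom = binning$chrom, start = binning$start, end = binning$end),
      paste0(path, ".bins"), sep = "\t")
  }
  invisible(path)
}

#' Read a sparse contact matrix written by [write_sparse_matrix()]
#' @param path file path.
#' @param n matrix dimension (default: largest bin index present).
#' @return sparse symmetric matrix (dgCMatrix).
#' @export
read_sparse_matrix <- function(path, n = NULL) {
  dt <- data.table::fread(path)
  n <- n %||% max(dt$bin_i, dt$bin_j)
  sym_sparse(dt$bin_i, dt$bin_j, dt$count, n)
}

#' Write intervals as BED (0-based, half-open)
#' @param intervals data.frame with chrom, start, end and optional extra
#'   columns (name/score/class).
#' @param path output file.
#' @export
write_bed <- function(intervals, path) {
  data.table::fwrite(data.table::as.data.table(intervals), path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Write a per-bin track as bedGraph
#' @param binning a [genome_binning()].
#' @param values numeric per bin (NA bins skipped).
#' @param path output file.
#' @export
write_bedgraph <- function(binning, values, path) {
  keep <- !is.na(values)
  data.table::fwrite(data.table::data.table(
    chrom = binning$chrom[keep], start = binning$start[keep],
    end = binning$end[keep], value = values[keep]),
    path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write promoter-enhancer pairs as BEDPE
#' @param peis `pei_set` table.
#' @param binning a [genome_binning()] (bins interpreted globally).
#' @param path output file.
#' @export
write_bedpe <- function(peis, binning, path) {
  b <- function(idx) list(chrom = binning$chrom[idx],
                          start = binning$start[idx],
                          end = binning$end[idx])
  p <- b(peis$promoter_bin); e <- b(peis$enhancer_bin)
  data.table::fwrite(data.table::data.table(
    chrom1 = p$chrom, start1 = p$start, end1 = p$end,
    chrom2 = e$chrom, start2 = e$start, end2 = e$end,
    name = peis$gene, score = peis$oe),
    path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write a phased variant table as minimal VCF-like TSV
#' @param variant_table data.frame: chrom, pos (0-based), ref, alt, gt
#'   (phased, e.g. "0|1").
#' @param path output file.
#' @export
write_vcf_like <- function(variant_table, path) {
  dt <- data.table::data.table(
    CHROM = variant_table$chrom, POS = variant_table$pos + 1L,
    REF = variant_table$ref, ALT = variant_table$alt,
    GT = variant_table$gt)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
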