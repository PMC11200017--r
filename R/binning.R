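#' Genome binning
#'
#' Partition a genome into fixed-width bins. Coordinates are 0-based,
#' half-open throughout the package. The last bin of each chromosome may be
#' partial; partial bins are kept and flagged so that normalization
#' statistics can exclude them.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param bin_size bin width in bp.
#' @return A `genome_binning` object: a list with per-bin `chrom`, `start`,
#'   `end`, `partial` flag, per-chromosome offsets into the global bin
#'   index, and `bin_size`.
#' @export
genome_binning <- function(chrom_lengths, bin_size = 20000L) {
  stopifnot(length(chrom_lengths) >= 1, all(chrom_lengths > 0), bin_size > 0)
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  nb <- as.integer(ceiling(chrom_lengths / bin_size))
  offsets <- c(0L, cumsum(nb))
  chrom <- rep(names(chrom_lengths), nb)
  local_idx <- unlist(lapply(nb, seq_len)) - 1L
  start <- local_idx * bin_size
  end <- pmin(start + bin_size, rep(unname(chrom_lengths), nb))
  structure(list(
    chrom_lengths = chrom_lengths,
    bin_size = as.integer(bin_size),
    n_bins = sum(nb),
    n_bins_per_chrom = stats::setNames(nb, names(chrom_lengths)),
    offsets = stats::setNames(offsets[seq_along(nb)], names(chrom_lengths)),
    chrom = chrom, start = start, end = end,
    partial = (end - start) < bin_size
  ), class = "genome_binning")
}

#' Map genomic positions to global bin indices
#'
#' @param binning a `genome_binning`.
#' @param chrom,pos vectors of chromosome names and 0-based positions.
#' @return integer vector of 1-based global bin indices.
#' @export
bin_index <- function(binning, chrom, pos) {
  stopifnot(inherits(binning, "genome_binning"))
  bad <- !(chrom %in% names(binning$chrom_lengths))
  if (any(bad)) {
    stop("unknown chromosome(s): ", paste(unique(chrom[bad]), collapse = ", "))
  }
  oob <- pos < 0 | pos >= binning$chrom_lengths[chrom]
  if (any(oob)) stop("position(s) outside chromosome bounds")
  unname(binning$offsets[chrom]) + pos %/% binning$bin_size + 1L
}

#' Global bin index range of one chromosome
#' @param binning a `genome_binning`.
#' @param chrom chromosome name.
#' @return integer vector of global bin indices.
#' @export
chrom_bins <- function(binning, chrom) {
  o <- binning$offsets[[chrom]]
  seq.int(o + 1L, o + binning$n_bins_per_chrom[[chrom]])
}

#' @export
print.genome_binning <- function(x, ...) {
  cat("genome_binning:", length(x$chrom_lengths), "chromosome(s),",
      x$n_bins, "bins of", x$bin_size, "bp\n")
  invisible(x)
}
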