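#' Assign a haplotype label from informative SNV votes
#'
#' Unanimous votes give that haplotype; no votes give `unknown`; mixed votes
#' give `conflict`. Vectorized over read ends when given vote counts.
#'
#' @param h1,h2 integer vectors: votes for haplotype 1 and 2 per read end.
#' @return character vector in `{"hap1", "hap2", "unknown", "conflict"}`.
#' @export
assign_allele <- function(h1, h2) {
  out <- rep("unknown", length(h1))
  out[h1 > 0 & h2 == 0] <- "hap1"
  out[h2 > 0 & h1 == 0] <- "hap2"
  out[h1 > 0 & h2 > 0] <- "conflict"
  out
}

#' Phase binned contact records into diploid matrices
#'
#' Combines the two end labels of each contact: both ends (or one end, the
#' other unknown) on one haplotype route the contact to that intra-haplotype
#' matrix; opposite haplotypes on the same chromosome form an inter-homolog
#' contact; contacts bridging different chromosomes with any haplotype
#' evidence are heterologs; both-unknown intra-chromosomal contacts enter
#' the unphased pool for local imputation; any conflicted end discards the
#' record. Single-end evidence is accepted for intra-chromosomal pairs
#' because cis contacts dominate diploid Hi-C maps.
#'
#' @param records data.table as from [simulate_contacts()] (columns chrom1,
#'   pos1, chrom2, pos2, e1_h1, e1_h2, e2_h1, e2_h2; truth columns ignored).
#' @param binning a [genome_binning()].
#' @return a `phased_contact_map`: sparse symmetric matrices `M11`, `M22`
#'   (intra-haplotype), `M12` (inter-homolog, same chromosome), `heterolog`
#'   table, `unphased` pool (bin-pair table), and `stats` (counts and
#'   fractions over {intra_phased, inter_homolog, heterolog, unphased,
#'   conflict}).
#' @export
phase_contacts <- function(records, binning) {
  stopifnot(inherits(binning, "genome_binning"))
  b1 <- bin_index(binning, records$chrom1, records$pos1)
  b2 <- bin_index(binning, records$chrom2, records$pos2)
  l1 <- assign_allele(records$e1_h1, records$e1_h2)
  l2 <- assign_allele(records$e2_h1, records$e2_h2)
  same_chrom <- records$chrom1 == records$chrom2
  conflict <- l1 == "conflict" | l2 == "conflict"

  lab1 <- ifelse(l1 == "hap1", 1L, ifelse(l1 == "hap2", 2L, 0L))
  lab2 <- ifelse(l2 == "hap1", 1L, ifelse(l2 == "hap2", 2L, 0L))
  any_ev <- lab1 > 0L | lab2 > 0L
  both_ev <- lab1 > 0L & lab2 > 0L

  cls <- rep("unphased", nrow(records))
  cls[conflict] <- "conflict"
  ok <- !conflict
  # same-chromosome: intra-haplotype if evidence agrees (or single-ended,
  # assumed cis), inter-homolog if both ends phased to opposite haplotypes
  cls[ok & same_chrom & any_ev & !(both_ev & lab1 != lab2)] <- "intra_phased"
  cls[ok & same_chrom & both_ev & lab1 != lab2] <- "inter_homolog"
  cls[ok & !same_chrom & any_ev] <- "heterolog"
  # both-unknown inter-chromosomal pairs are unassignable and stay unphased

  n <- binning$n_bins
  hap_of <- ifelse(lab1 > 0L, lab1, lab2)
  sel11 <- cls == "intra_phased" & hap_of == 1L
  sel22 <- cls == "intra_phased" & hap_of == 2L
  M11 <- sym_sparse(b1[sel11], b2[sel11], rep(1, sum(sel11)), n)
  M22 <- sym_sparse(b1[sel22], b2[sel22], rep(1, sum(sel22)), n)
  sel12 <- cls == "inter_homolog"
  M12 <- sym_sparse(b1[sel12], b2[sel12], rep(1, sum(sel12)), n)
  het <- data.table::data.table(
    chrom1 = records$chrom1, bin1 = b1, hap1 = lab1,
    chrom2 = records$chrom2, bin2 = b2, hap2 = lab2)[cls == "heterolog"]
  unph <- data.table::data.table(bin1 = b1, bin2 = b2,
                                 same_chrom = same_chrom)[cls == "unphased"]

  counts <- c(intra_phased = sum(cls == "intra_phased"),
              inter_homolog = sum(cls == "inter_homolog"),
              heterolog = sum(cls == "heterolog"),
              unphased = sum(cls == "unphased"),
              conflict = sum(cls == "conflict"))
  structure(list(M11 = M11, M22 = M22, M12 = M12,
                 heterolog = het, unphased = unph, binning = binning,
                 stats = list(counts = counts,
                              fractions = counts / max(sum(counts), 1))),
            class = "phased_contact_map")
}

#' @export
print.phased_contact_map <- function(x, ...) {
  cat("phased_contact_map:",
      sprintf("%d phased cis, %d inter-homolog, %d heterolog, %d unphased, %d conflict\n",
              x$stats$counts["intra_phased"], x$stats$counts["inter_homolog"],
              x$stats$counts["heterolog"], x$stats$counts["unphased"],
              x$stats$counts["conflict"]))
  invisible(x)
}

#' Locally impute unphased cis contacts
#'
#' Each unphased intra-chromosomal contact is allocated to M11 or M22 with
#' probability proportional to the phased counts in the window (i +/- w,
#' j +/- w) around its anchors; the integer allocation uses stochastic
#' rounding under the session RNG so the expectation is preserved and the
#' pool total is conserved. Windows with no phased signal split 50/50.
#'
#' @param pcm a `phased_contact_map`.
#' @param window_bins half-width of the imputation window (default 5).
#' @return the map with augmented `M11`/`M22` and the pool cleared;
#'   `stats$imputed` records the allocation.
#' @export
impute_local <- function(pcm, window_bins = 5L) {
  stopifnot(inherits(pcm, "phased_contact_map"))
  pool <- pcm$unphased[pcm$unphased$same_chrom]
  if (nrow(pool) == 0L) return(pcm)
  n <- nrow(pcm$M11)
  w <- window_bins
  # window sums over [i-w, i+w] x [j-w, j+w] for all (i, j) at once:
  # S = B M B with B the 0/1 band matrix of half-width w
  B <- Matrix::bandSparse(n, k = -w:w,
                          diagonals = lapply(-w:w, function(k) rep(1, n - abs(k))))
  S11 <- B %*% pcm$M11 %*% B
  S22 <- B %*% pcm$M22 %*% B
  # collapse duplicate bin pairs first: one lookup per unique pair
  agg <- data.table::data.table(bin1 = pool$bin1, bin2 = pool$bin2)
  agg <- agg[, list(m = .N), by = c("bin1", "bin2")]
  s11 <- S11[cbind(agg$bin1, agg$bin2)]
  s22 <- S22[cbind(agg$bin1, agg$bin2)]
  p11 <- ifelse(s11 + s22 > 0, s11 / (s11 + s22), 0.5)
  n11 <- stochastic_round(agg$m * p11)
  n11 <- pmin(n11, agg$m)
  n22 <- agg$m - n11
  add <- function(M, x) {
    keep <- x > 0
    if (!any(keep)) return(M)
    M + sym_sparse(agg$bin1[keep], agg$bin2[keep], x[keep], n)
  }
  pcm$M11 <- add(pcm$M11, n11)
  pcm$M22 <- add(pcm$M22, n22)
  pcm$unphased <- pcm$unphased[!pcm$unphased$same_chrom]
  pcm$stats$imputed <- c(to_M11 = sum(n11), to_M22 = sum(n22))
  pcm
}

#' Map resolution from per-bin read coverage
#'
#' The map resolution is the smallest candidate bin size at which at least
#' 80% of bins contain a minimum of 1000 reads. Read ends are counted per
#' bin at each candidate size.
#'
#' @param chrom,pos vectors of read-end chromosome names and 0-based
#'   positions (both ends of every contact).
#' @param chrom_lengths named lengths in bp.
#' @param candidate_sizes bin sizes in bp to test (sorted internally).
#' @param min_reads,min_fraction the rule's constants (1000 reads, 0.80).
#' @return a `resolution_report`: per-candidate fractions and
#'   `selected` (smallest passing size, or `NA` if none passes).
#' @export
map_resolution <- function(chrom, pos, chrom_lengths, candidate_sizes,
                           min_reads = 1000L, min_fraction = 0.80) {
  candidate_sizes <- sort(candidate_sizes)
  frac <- vapply(candidate_sizes, function(bs) {
    nb <- ceiling(chrom_lengths / bs)
    if (length(pos) == 0L) return(0)
    gbin <- cumsum(c(0, nb))[match(chrom, names(chrom_lengths))] +
      pos %/% bs + 1
    counts <- tabulate(gbin, nbins = sum(nb))
    mean(counts >= min_reads)
  }, numeric(1))
  passing <- candidate_sizes[frac >= min_fraction]
  structure(list(candidate_sizes = candidate_sizes, fractions = frac,
                 selected = if (length(passing)) min(passing) else NA_integer_),
            class = "resolution_report")
}

#' @export
print.resolution_report <- function(x, ...) {
  for (k in seq_along(x$candidate_sizes)) {
    cat(sprintf("  %8d bp: %.1f%% of bins covered\n",
                x$candidate_sizes[k], 100 * x$fractions[k]))
  }
  cat(if (is.na(x$selected)) "no candidate passes at tested sizes\n"
      else sprintf("selected resolution: %d bp\n", x$selected))
  invisible(x)
}
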