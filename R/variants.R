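#' Identity score of a region between two haplotypes
#'
#' IDS = 1 - mismatched_bases / region_length, floored at 0. Mismatched
#' bases count one per differing SNV site plus the length of each indel
#' clipped to the region; insertions contribute their inserted length at
#' the anchor point.
#'
#' @param region_start,region_end region bounds (0-based half-open).
#' @param variants data.frame: pos (0-based), type in {"snv", "del",
#'   "ins"}, length (1 for SNVs; event length for indels). Deletions span
#'   `[pos, pos + length)`; insertions anchor at `pos`.
#' @return IDS in [0, 1].
#' @export
identity_score <- function(region_start, region_end, variants) {
  len <- region_end - region_start
  if (len <= 0) stop("region length must be positive")
  if (is.null(variants) || nrow(variants) == 0L) return(1)
  mism <- 0
  for (k in seq_len(nrow(variants))) {
    type <- variants$type[k]; pos <- variants$pos[k]; L <- variants$length[k]
    if (type == "snv") {
      if (pos >= region_start && pos < region_end) mism <- mism + 1
    } else if (type == "del") {
      ov <- min(pos + L, region_end) - max(pos, region_start)
      if (ov > 0) mism <- mism + ov
    } else if (type == "ins") {
      if (pos >= region_start && pos < region_end) mism <- mism + L
    } else stop("unknown variant type: ", type)
  }
  max(0, 1 - mism / len)
}

#' Per-site Weir-Cockerham FST between two populations
#'
#' The 1984 variance-components estimator theta = a / (a + b + c) for
#' biallelic sites from diploid genotype dosages; indel presence/absence
#' genotypes are handled identically. Monomorphic sites, and sites where a
#' population has no called genotypes, are reported as missing. A weighted
#' genome-wide estimate (ratio of summed components, the standard
#' multi-site summary) accompanies the per-site values.
#'
#' @param geno_a,geno_b integer matrices (sites x individuals) of allele
#'   dosages 0/1/2; NA = missing genotype.
#' @return list: `fst` per site (NA where undefined), `weighted` (sum(a) /
#'   sum(a+b+c) over defined sites), `components` (a, b, c per site).
#' @export
weir_cockerham_fst <- function(geno_a, geno_b) {
  stopifnot(nrow(geno_a) == nrow(geno_b))
  r <- 2
  comp_pop <- function(G) {
    if (is.null(dim(G))) G <- matrix(G, nrow = 1)
    n <- rowSums(!is.na(G))                      # called diploids
    p <- rowSums(G, na.rm = TRUE) / (2 * n)      # alt-allele frequency
    h <- rowSums(G == 1L, na.rm = TRUE) / n      # observed het frequency
    list(n = n, p = p, h = h)
  }
  A <- comp_pop(geno_a); B <- comp_pop(geno_b)
  n1 <- A$n; n2 <- B$n
  valid <- n1 > 0 & n2 > 0
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * A$p + n2 * B$p) / (r * nbar)
  s2 <- (n1 * (A$p - pbar)^2 + n2 * (B$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * A$h + n2 * B$h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  denom <- a + b + cc
  fst <- a / denom
  mono <- pbar <= 0 | pbar >= 1
  fst[!valid | mono | denom == 0] <- NA_real_
  def <- !is.na(fst)
  list(fst = fst,
       weighted = if (any(def)) sum(a[def]) / sum(denom[def]) else NA_real_,
       components = data.frame(a = a, b = b, c = cc))
}

#' Enrichment of high-FST enhancer variants in differential-RPS genes
#'
#' Partitions genes by whether any high-FST site (FST >= `fst_threshold`)
#' falls in one of their enhancers, then reports: a Wilcoxon rank-sum test
#' of |Delta RPS| between partitions, a Fisher exact test of partition
#' membership against differential-RPS membership, a Wilcoxon test of
#' per-gene enhancer counts (contact redundancy), and, when expression
#' differences are supplied, a Wilcoxon test of those. Tests are reported
#' raw, mirroring figure-wise testing.
#'
#' @param genes character vector of gene ids.
#' @param fst_sites data.frame: pos, fst (per site).
#' @param enhancer_map data.frame: gene, start, end (enhancer intervals,
#'   0-based half-open).
#' @param delta_rps named |Delta RPS| per gene.
#' @param differential_genes character vector of differential-RPS gene ids.
#' @param expression_diff optional named |Delta expression| per gene.
#' @param fst_threshold high-FST cutoff (default 0.75, sites at the
#'   threshold retained).
#' @return list: `high_fst_genes`, `fisher` (odds ratio and p), `wilcox_rps`,
#'   `wilcox_redundancy`, `wilcox_expression` (NULL if not supplied).
#' @export
high_fst_enrichment <- function(genes, fst_sites, enhancer_map, delta_rps,
                                differential_genes, expression_diff = NULL,
                                fst_threshold = 0.75) {
  hi <- fst_sites$pos[!is.na(fst_sites$fst) & fst_sites$fst >= fst_threshold]
  em <- data.table::as.data.table(enhancer_map)
  has_hi <- vapply(genes, function(g) {
    e <- em[em$gene == g]
    if (nrow(e) == 0L) return(FALSE)
    any(vapply(hi, function(p) any(p >= e$start & p < e$end), logical(1)))
  }, logical(1))
  high_fst_genes <- genes[has_hi]
  if (length(high_fst_genes) == 0L || all(has_hi)) {
    warning("one gene partition is empty; tests skipped")
    return(list(high_fst_genes = high_fst_genes, fisher = NULL,
                wilcox_rps = NULL, wilcox_redundancy = NULL,
                wilcox_expression = NULL))
  }
  tab <- table(factor(has_hi, c(TRUE, FALSE)),
               factor(genes %in% differential_genes, c(TRUE, FALSE)))
  ft <- stats::fisher.test(tab)
  wr <- stats::wilcox.test(delta_rps[genes[has_hi]], delta_rps[genes[!has_hi]])
  n_enh <- vapply(genes, function(g) sum(em$gene == g), 0L)
  wd <- stats::wilcox.test(n_enh[has_hi], n_enh[!has_hi])
  we <- if (!is.null(expression_diff)) {
    stats::wilcox.test(expression_diff[genes[has_hi]],
                       expression_diff[genes[!has_hi]])
  }
  list(high_fst_genes = high_fst_genes,
       fisher = list(table = tab, odds_ratio = unname(ft$estimate),
                     p = ft$p.value),
       wilcox_rps = list(statistic = unname(wr$statistic), p = wr$p.value),
       wilcox_redundancy = list(statistic = unname(wd$statistic), p = wd$p.value),
       wilcox_expression = if (!is.null(we))
         list(statistic = unname(we$statistic), p = we$p.value))
}
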