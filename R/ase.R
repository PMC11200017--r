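#' Aggregate SNV-level allelic counts to genes
#'
#' Sums haplotype-resolved read counts over the exonic heterozygous SNVs of
#' each gene. Genes without informative exonic SNVs are marked untestable.
#' An SNV mapping to two genes is counted for both and flagged.
#'
#' @param snv_counts data.frame: chrom, pos (0-based), hap1_count,
#'   hap2_count.
#' @param gene_model data.frame: gene_id, chrom, start, end (exonic span,
#'   0-based half-open).
#' @return data.table: gene_id, hap1, hap2, n_snvs, multi_gene flag.
#' @export
gene_allelic_counts <- function(snv_counts, gene_model) {
  sc <- data.table::as.data.table(snv_counts)
  gm <- data.table::as.data.table(gene_model)
  hits <- data.table::rbindlist(lapply(seq_len(nrow(gm)), function(g) {
    sel <- sc$chrom == gm$chrom[g] & sc$pos >= gm$start[g] & sc$pos < gm$end[g]
    if (!any(sel)) return(NULL)
    data.table::data.table(gene_id = gm$gene_id[g], snv = which(sel),
                           hap1 = sc$hap1_count[sel], hap2 = sc$hap2_count[sel])
  }))
  shared <- if (!is.null(hits) && nrow(hits)) {
    dup <- hits[, list(n = length(unique(gene_id))), by = "snv"][n > 1L]$snv
    unique(hits$gene_id[hits$snv %in% dup])
  } else character(0)
  out <- gm[, c("gene_id"), with = FALSE]
  if (!is.null(hits) && nrow(hits)) {
    agg <- hits[, list(hap1 = sum(hap1), hap2 = sum(hap2), n_snvs = .N),
                by = "gene_id"]
    out <- merge(out, agg, by = "gene_id", all.x = TRUE, sort = FALSE)
  } else {
    out$hap1 <- NA_integer_; out$hap2 <- NA_integer_; out$n_snvs <- NA_integer_
  }
  out$hap1[is.na(out$hap1)] <- 0L
  out$hap2[is.na(out$hap2)] <- 0L
  out$n_snvs[is.na(out$n_snvs)] <- 0L
  out$untestable <- out$n_snvs == 0L
  out$multi_gene <- out$gene_id %in% shared
  out[]
}

#' Test genes for allelic expression bias
#'
#' Per gene, a two-sided exact binomial test of the hap1 fraction against
#' 0.5, BH-adjusted across testable genes. A gene is biased when q < `fdr`
#' and its allelic ratio falls outside [0.3, 0.7]; genes below `min_total`
#' informative reads, below 0.5 TPM in every sample, or without exonic
#' SNVs are untestable.
#'
#' @param table data.frame with hap1, hap2 count columns (as from
#'   [gene_allelic_counts()]).
#' @param max_tpm per-gene maximum TPM across samples (same order);
#'   `NULL` skips the expression filter.
#' @param min_total minimum informative reads to test (default 20).
#' @param fdr BH threshold (default 0.05).
#' @param ratio_window biallelic ratio window (default c(0.3, 0.7)).
#' @param tpm_threshold minimum max-TPM for testability (default 0.5).
#' @return the table with ratio, p, q and category in {hap1_biased,
#'   hap2_biased, biallelic, untestable}.
#' @export
allelic_bias_test <- function(table, max_tpm = NULL, min_total = 20L,
                              fdr = 0.05, ratio_window = c(0.3, 0.7),
                              tpm_threshold = 0.5) {
  tb <- data.table::as.data.table(table)
  total <- tb$hap1 + tb$hap2
  testable <- total >= min_total & !(tb$untestable %||% FALSE)
  if (!is.null(max_tpm)) testable <- testable & max_tpm >= tpm_threshold
  tb$ratio <- ifelse(total > 0, tb$hap1 / total, NA_real_)
  p <- rep(NA_real_, nrow(tb))
  idx <- which(testable)
  p[idx] <- vapply(idx, function(k) {
    stats::binom.test(tb$hap1[k], total[k], p = 0.5)$p.value
  }, numeric(1))
  q <- rep(NA_real_, nrow(tb))
  q[idx] <- stats::p.adjust(p[idx], method = "BH")
  cat <- rep("untestable", nrow(tb))
  cat[idx] <- "biallelic"
  biased <- testable & !is.na(q) & q < fdr &
    (tb$ratio < ratio_window[1] | tb$ratio > ratio_window[2])
  cat[biased & tb$ratio > 0.5] <- "hap1_biased"
  cat[biased & tb$ratio < 0.5] <- "hap2_biased"
  tb$p <- p; tb$q <- q; tb$category <- cat
  tb[]
}

#' Screen for parent-of-origin (imprinting) vs breed effects
#'
#' Uses the reciprocal-cross design: a gene is an imprinting candidate only
#' if it is significantly biased toward the same parental role (maternal or
#' paternal) in both cross directions; a gene biased toward the same breed
#' haplotype in both directions is classified as a breed effect and
#' excluded. Bias per direction is taken from pooled counts across that
#' direction's families.
#'
#' @param tables named list of bias tables (from [allelic_bias_test()] run
#'   on per-sample tables whose hap1 is the maternal haplotype), one per
#'   sample.
#' @param sample_table data.frame: sample_id, cross (two levels),
#'   hap1_breed (maternal breed).
#' @param fdr,min_total,ratio_window forwarded to the per-direction pooled
#'   test.
#' @return data.table per gene: direction-wise categories, and
#'   classification in {imprinting_candidate_maternal,
#'   imprinting_candidate_paternal, breed_effect, none}.
#' @export
imprinting_screen <- function(tables, sample_table, fdr = 0.05,
                              min_total = 20L, ratio_window = c(0.3, 0.7)) {
  st <- data.table::as.data.table(sample_table)
  dirs <- unique(st$cross)
  if (length(dirs) < 2L) stop("need both cross directions")
  pool_dir <- function(dir) {
    ids <- st$sample_id[st$cross == dir]
    pooled <- data.table::rbindlist(tables[ids])[, list(
      hap1 = sum(hap1), hap2 = sum(hap2), untestable = all(untestable)),
      by = "gene_id"]
    allelic_bias_test(pooled, min_total = min_total, fdr = fdr,
                      ratio_window = ratio_window)
  }
  b1 <- pool_dir(dirs[1]); b2 <- pool_dir(dirs[2])
  m <- merge(b1[, c("gene_id", "category", "ratio")],
             b2[, c("gene_id", "category", "ratio")],
             by = "gene_id", suffixes = c("_fwd", "_rev"))
  # hap1 = maternal in every sample, so hap1 bias = maternal bias;
  # the breed of the maternal haplotype differs between the two directions
  same_parent_mat <- m$category_fwd == "hap1_biased" & m$category_rev == "hap1_biased"
  same_parent_pat <- m$category_fwd == "hap2_biased" & m$category_rev == "hap2_biased"
  # same breed in both directions: maternal-biased in one, paternal in other
  breed_eff <- (m$category_fwd == "hap1_biased" & m$category_rev == "hap2_biased") |
    (m$category_fwd == "hap2_biased" & m$category_rev == "hap1_biased")
  cls <- rep("none", nrow(m))
  cls[breed_eff] <- "breed_effect"
  cls[same_parent_mat] <- "imprinting_candidate_maternal"
  cls[same_parent_pat] <- "imprinting_candidate_paternal"
  m$classification <- cls
  m[]
}
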