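#' Run the full synthetic diploid Hi-C pipeline
#'
#' Orchestrates every stage on one simulated dataset: truth generation,
#' contact simulation, phasing with local imputation, KR balancing, homolog
#' pairing scores and tightly-paired regions, A/B compartment profiles,
#' TAD calling, PEI calling with per-gene regulatory potential scores,
#' allelic expression with the reciprocal-cross imprinting screen, and
#' two-breed FST. All stage outputs are written as plain-text formats
#' (sparse matrix triplets, BED/bedGraph/BEDPE, TSV) plus a summary table
#' of the three-axis differential statistics. Re-running with the same
#' config (and its seed) is byte-identical.
#'
#' Pinned thresholds applied and logged: |Delta A-B index| 1.0 (stage) /
#' 0.3 (breed, parent); |Delta LBS| 0.2; |Delta RPS| 3 (stage) / 0.3
#' (breed, parent); FST >= 0.75; TPM >= 0.5; paired t-test p < 0.05.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if missing).
#' @return invisibly, a list with the main in-memory results (`truth`,
#'   `phased`, `balanced`, `pairing`, `compartments`, `tads`, `peis`,
#'   `rps`, `ase`, `fst`, `summary`).
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("diplohic pipeline; seed=%d", config$seed)
  logf("thresholds: AB stage=1.0 breed/parent=0.3; LBS=0.2; RPS stage=3 breed/parent=0.3; FST>=0.75; TPM>=0.5; paired t p<0.05")

  truth <- make_truth(config)
  binning <- truth$binning
  write_vcf_like(truth$variant_table, file.path(outdir, "variants.tsv"))
  logf("truth: %d variants, %d bins", nrow(truth$variant_table), binning$n_bins)

  records <- simulate_contacts(truth, config)
  phased <- phase_contacts(records, binning)
  phased <- impute_local(phased)
  write_sparse_matrix(phased$M11, file.path(outdir, "M11.txt"), binning)
  write_sparse_matrix(phased$M22, file.path(outdir, "M22.txt"), binning)
  write_sparse_matrix(phased$M12, file.path(outdir, "M12.txt"), binning)
  fr <- phased$stats$fractions
  logf("phasing: %s", paste(sprintf("%s=%.4f", names(fr), fr), collapse = " "))

  chroms <- names(config$chrom_lengths)
  per_chrom <- lapply(chroms, function(ch) {
    cb <- chrom_bins(binning, ch)
    M11 <- phased$M11[cb, cb]; M22 <- phased$M22[cb, cb]
    b11 <- kr_balance(M11); b22 <- kr_balance(M22)
    list(chrom = ch, M11 = M11, M22 = M22, b11 = b11, b22 = b22,
         M12 = phased$M12[cb, cb])
  })
  names(per_chrom) <- chroms

  ## homolog pairing
  tracks <- lapply(per_chrom, function(pc) hps_track(pc$M12))
  tight <- call_tight_regions(tracks)
  for (k in seq_along(chroms)) {
    write_bedgraph(genome_binning(config$chrom_lengths[chroms[k]],
                                  config$bin_size),
                   tracks[[k]]$hps,
                   file.path(outdir, sprintf("hps_%s.bedGraph", chroms[k])))
  }
  logf("pairing: threshold=%.4f, %d tight regions", tight$threshold,
       nrow(tight$regions))

  ## compartments per haplotype
  prof <- lapply(c("b11", "b22"), function(h) {
    ab_index(lapply(per_chrom, function(pc) pc[[h]]$matrix), truth$covariate)
  })
  write_bedgraph(binning, prof[[1]]$index, file.path(outdir, "ab_index_hap1.bedGraph"))
  write_bedgraph(binning, prof[[2]]$index, file.path(outdir, "ab_index_hap2.bedGraph"))
  logf("compartments: hap1 %d A bins / %d B bins",
       sum(prof[[1]]$label == "A", na.rm = TRUE),
       sum(prof[[1]]$label == "B", na.rm = TRUE))

  ## TADs per chromosome (haplotype 1 map)
  tads <- lapply(per_chrom, function(pc) {
    di <- directionality_index(pc$b11$matrix, bin_size = config$bin_size)
    isx <- insulation_index(pc$b11$matrix, bin_size = config$bin_size)
    call_tads(di, isx)
  })
  tad_bed <- data.table::rbindlist(lapply(chroms, function(ch) {
    d <- tads[[ch]]$domains
    data.table::data.table(chrom = ch, start = (d$from - 1L) * config$bin_size,
                           end = d$to * config$bin_size)
  }))
  write_bed(tad_bed, file.path(outdir, "tads.bed"))
  logf("tads: %d domains", nrow(tad_bed))

  ## PEIs + RPS on the raw (count-scale) hap maps
  peis <- lapply(chroms, function(ch) {
    pc <- per_chrom[[ch]]
    gm <- truth$genes[truth$genes$chrom == ch]
    prom <- stats::setNames(bin_index(binning, gm$chrom, gm$start) -
                              binning$offsets[[ch]], gm$gene_id)
    model <- fit_expected(pc$M11, tads[[ch]])
    call_peis(pc$M11, model, prom, bin_size = config$bin_size)
  })
  names(peis) <- chroms
  all_peis <- data.table::rbindlist(peis)
  rps <- compute_rps(all_peis, genes = truth$genes$gene_id)
  data.table::fwrite(data.table::data.table(gene = names(rps), rps = rps),
                     file.path(outdir, "rps.tsv"), sep = "\t")
  logf("pei: %d called, %d genes with RPS > 0", nrow(all_peis), sum(rps > 0))

  ## allelic expression + imprinting screen + FST
  ep <- simulate_expression_and_population(truth, config)
  expr <- ep$expression
  gene_tabs <- split(
    data.table::data.table(gene_id = expr$gene_id, hap1 = expr$maternal,
                           hap2 = expr$paternal, untestable = FALSE),
    expr$sample_id)
  scr <- imprinting_screen(gene_tabs, truth$sample_table)
  data.table::fwrite(scr, file.path(outdir, "imprinting_screen.tsv"), sep = "\t")
  n_cand <- sum(grepl("^imprinting", scr$classification))
  logf("ase: %d imprinting candidates, %d breed-effect genes", n_cand,
       sum(scr$classification == "breed_effect"))

  fst <- weir_cockerham_fst(ep$genotypes$broiler, ep$genotypes$layer)
  data.table::fwrite(data.table::data.table(site = seq_along(fst$fst),
                                            fst = fst$fst),
                     file.path(outdir, "fst.tsv"), sep = "\t")
  logf("fst: weighted=%.4f, %d high-FST sites", fst$weighted,
       sum(fst$fst >= 0.75, na.rm = TRUE))

  summary <- data.table::data.table(
    quantity = c("phased_cis_fraction", "inter_homolog_fraction",
                 "tight_paired_regions", "tad_count", "pei_count",
                 "imprinting_candidates", "high_fst_sites"),
    value = c(fr[["intra_phased"]], fr[["inter_homolog"]],
              nrow(tight$regions), nrow(tad_bed), nrow(all_peis),
              n_cand, sum(fst$fst >= 0.75, na.rm = TRUE)))
  data.table::fwrite(summary, file.path(outdir, "summary.tsv"), sep = "\t")

  invisible(list(truth = truth, phased = phased, per_chrom = per_chrom,
                 pairing = tight, compartments = prof, tads = tads,
                 peis = all_peis, rps = rps, screen = scr, fst = fst,
                 summary = summary))
}
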