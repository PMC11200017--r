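#' Simulation configuration for synthetic diploid Hi-C data
#'
#' Defines the generating model for a diploid genome with planted,
#' recoverable structure: heterozygous SNVs at a given density, power-law
#' contact distance decay, a compartment checkerboard, TAD blocks, promoter-
#' enhancer peaks, inter-homolog pairing blocks, allelic expression effects,
#' and two-population allele-frequency divergence. One seed fixes all
#' randomness; identical configs give byte-identical outputs.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param bin_size bin width in bp (default 20 kb).
#' @param snv_density heterozygous SNVs per kb (default 4.42, the density
#'   observed in broiler x layer F1 hybrids).
#' @param decay_exponent power-law slope of contact frequency vs genomic
#'   distance (default -1.0).
#' @param compartment_block_bp width of alternating A/B blocks (default 2 Mb).
#' @param compartment_strength multiplicative enrichment of same-compartment
#'   contacts (>= 1; 1 disables the checkerboard).
#' @param tad_sizes_bp list (per chromosome) of domain sizes in bp tiling the
#'   chromosome from 0, or `NULL` to draw sizes uniformly from
#'   `tad_size_range` (rounded to bin multiples).
#' @param tad_size_range range domains are drawn from when `tad_sizes_bp` is
#'   `NULL` (default 200-800 kb).
#' @param tad_strength within-domain contact enrichment factor (>= 1).
#' @param pairing_blocks data.frame (chrom, start, end, fold) of intervals
#'   whose inter-homolog near-diagonal is elevated `fold`-fold, or `NULL`.
#' @param pairing_window bins around the aligned diagonal that the pairing
#'   elevation applies to (default 2).
#' @param pei_truth data.frame (chrom, promoter_bin, enhancer_bin, fold) of
#'   planted promoter-enhancer peaks (1-based bin indices local to the
#'   chromosome), or `NULL`.
#' @param n_contacts total contacts to simulate.
#' @param inter_homolog_fraction fraction of contacts routed between
#'   homologs (default 0.0462, the fraction observed in hybrid chicken).
#' @param heterolog_fraction fraction connecting non-homologous chromosomes
#'   (default 0.0026).
#' @param random_ligation_fraction uniform background fraction of cis
#'   contacts (default 0.02).
#' @param read_span bp spanned by each read end when collecting SNV votes
#'   (default 150, paired-end 150 sequencing).
#' @param vote_error probability that one SNV vote reports the wrong
#'   haplotype (default 0.001).
#' @param stages,crosses,reps_per_cross replicate design: developmental
#'   stages, reciprocal cross directions (`"BxL"` = broiler dam x layer
#'   sire), and families per direction per stage.
#' @param n_genes genes per chromosome (evenly spaced; `NULL` = 1 per 100 kb).
#' @param gene_length_bp gene span in bp (exonic over its whole span).
#' @param expr_base_mean mean total informative read count per gene.
#' @param breed_effect data.frame (gene, fold) of planted broiler:layer
#'   expression folds, or `NULL`.
#' @param imprint_effect data.frame (gene, fold, parent) of planted
#'   parent-of-origin folds (`parent` in `"maternal"`/`"paternal"`); default
#'   `NULL`: no imprinting, the avian null.
#' @param enhancer_expression_boost per-planted-enhancer multiplicative
#'   boost to a gene's expression mean (couples expression to PEI truth).
#' @param n_pop_sites,n_per_pop,target_fst population-genotype block: number
#'   of biallelic sites, diploid individuals per breed, and per-site target
#'   FST (scalar or per-site vector) for the Balding-Nichols draw.
#' @param seed integer seed fixing all randomness.
#' @return a `sim_config` object (validated list).
#' @export
sim_config <- function(chrom_lengths,
                       bin_size = 20000L,
                       snv_density = 4.42,
                       decay_exponent = -1.0,
                       compartment_block_bp = 2e6,
                       compartment_strength = 1,
                       tad_sizes_bp = NULL,
                       tad_size_range = c(2e5, 8e5),
                       tad_strength = 1,
                       pairing_blocks = NULL,
                       pairing_window = 2L,
                       pei_truth = NULL,
                       n_contacts = 1e6,
                       inter_homolog_fraction = 0.0462,
                       heterolog_fraction = 0.0026,
                       random_ligation_fraction = 0.02,
                       read_span = 150L,
                       vote_error = 0.001,
                       stages = c("E15", "D1", "D30"),
                       crosses = c("BxL", "LxB"),
                       reps_per_cross = 2L,
                       n_genes = NULL,
                       gene_length_bp = 10000L,
                       expr_base_mean = 100,
                       breed_effect = NULL,
                       imprint_effect = NULL,
                       enhancer_expression_boost = 1.5,
                       n_pop_sites = 2000L,
                       n_per_pop = 12L,
                       target_fst = 0.5,
                       seed = 1L) {
  stopifnot(all(chrom_lengths > 0), bin_size > 0, snv_density >= 0,
            compartment_strength >= 1, tad_strength >= 1,
            inter_homolog_fraction >= 0, heterolog_fraction >= 0,
            inter_homolog_fraction + heterolog_fraction < 1,
            vote_error >= 0, vote_error < 0.5,
            enhancer_expression_boost >= 1)
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  if (!is.null(pairing_blocks)) {
    stopifnot(all(c("chrom", "start", "end", "fold") %in% names(pairing_blocks)),
              all(pairing_blocks$fold >= 1))
    if (any(pairing_blocks$end > chrom_lengths[pairing_blocks$chrom]) ||
        any(pairing_blocks$start < 0)) {
      stop("pairing block outside chromosome bounds")
    }
  }
  if (!is.null(pei_truth)) {
    stopifnot(all(c("chrom", "promoter_bin", "enhancer_bin", "fold") %in%
                    names(pei_truth)),
              all(pei_truth$fold >= 1))
    nb <- ceiling(chrom_lengths / bin_size)
    if (any(pei_truth$promoter_bin < 1 | pei_truth$enhancer_bin < 1 |
            pei_truth$promoter_bin > nb[pei_truth$chrom] |
            pei_truth$enhancer_bin > nb[pei_truth$chrom])) {
      stop("planted PEI outside chromosome bounds")
    }
  }
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

#' Generate planted truth for a simulation
#'
#' Draws the phased variant table (SNV count per chromosome is
#' Poisson(length_kb x snv_density)), the per-bin compartment labels, TAD
#' boundaries, tightly-paired bin set, planted PEIs, gene models with
#' planted expression effects, and two-breed population allele frequencies.
#' Deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @return a `synthetic_truth` object with elements `binning`,
#'   `variant_table`, `compartment_truth`, `covariate` (GC-like orientation
#'   track, higher in A), `tad_truth` (per chromosome: boundary bins and a
#'   per-bin domain id), `pairing_truth` (flagged bin indices per
#'   chromosome), `pei_truth`, `genes`, `sample_table`,
#'   `population_freq_truth`, and the generating `config`.
#' @export
make_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  binning <- genome_binning(config$chrom_lengths, config$bin_size)
  chroms <- names(config$chrom_lengths)

  ## phased heterozygous variants
  vt <- lapply(chroms, function(ch) {
    len <- config$chrom_lengths[[ch]]
    n <- stats::rpois(1L, len / 1000 * config$snv_density)
    if (n == 0L) {
      return(data.table::data.table(chrom = character(0), pos = integer(0),
                                    ref = character(0), alt = character(0),
                                    gt = character(0)))
    }
    pos <- sort(sample.int(len, n, replace = FALSE)) - 1L  # 0-based
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
    # phased GT: hap1 allele | hap2 allele; hap1 carries ref or alt at random
    gt <- sample(c("0|1", "1|0"), n, replace = TRUE)
    data.table::data.table(chrom = ch, pos = pos, ref = ref, alt = alt, gt = gt)
  })
  variant_table <- data.table::rbindlist(vt)

  ## compartment checkerboard + orientation covariate (GC-like, higher in A)
  block <- floor(binning$start / config$compartment_block_bp)
  comp <- ifelse(block %% 2 == 0, "A", "B")
  covariate <- stats::rnorm(binning$n_bins, mean = ifelse(comp == "A", 0.48, 0.40),
                            sd = 0.015)

  ## TAD tiling per chromosome
  tad_truth <- lapply(chroms, function(ch) {
    len <- config$chrom_lengths[[ch]]
    sizes <- if (is.list(config$tad_sizes_bp)) config$tad_sizes_bp[[ch]]
             else config$tad_sizes_bp
    if (is.null(sizes)) {
      sizes <- c()
      while (sum(sizes) < len) {
        s <- stats::runif(1, config$tad_size_range[1], config$tad_size_range[2])
        sizes <- c(sizes, round(s / config$bin_size) * config$bin_size)
      }
      sizes <- sizes[cumsum(sizes) <= len]
    } else if (sum(sizes) > len) {
      stop("planted TADs exceed chromosome length on ", ch)
    }
    ends_bp <- cumsum(sizes)
    nb <- binning$n_bins_per_chrom[[ch]]
    boundary_bins <- unique(pmin(ends_bp %/% config$bin_size + 1L, nb))
    boundary_bins <- boundary_bins[boundary_bins < nb]
    domain_id <- findInterval(seq_len(nb) - 1L, c(0, ends_bp %/% config$bin_size))
    # bins beyond the last planted domain form a trailing domain of their own
    domains <- data.frame(
      from = vapply(seq_len(max(domain_id)), function(k) min(which(domain_id == k)), 0L),
      to = vapply(seq_len(max(domain_id)), function(k) max(which(domain_id == k)), 0L))
    list(boundary_bins = boundary_bins, domain_id = domain_id,
         domains = domains, sizes_bp = sizes)
  })
  names(tad_truth) <- chroms

  ## pairing truth: flagged bins per chromosome
  pairing_truth <- lapply(chroms, function(ch) {
    pb <- config$pairing_blocks
    if (is.null(pb)) return(integer(0))
    pb <- pb[pb$chrom == ch, , drop = FALSE]
    if (nrow(pb) == 0) return(integer(0))
    sort(unique(unlist(lapply(seq_len(nrow(pb)), function(k) {
      seq.int(pb$start[k] %/% config$bin_size + 1L,
              (pb$end[k] - 1L) %/% config$bin_size + 1L)
    }))))
  })
  names(pairing_truth) <- chroms

  ## gene models on an even grid; exonic over the whole span
  genes <- data.table::rbindlist(lapply(chroms, function(ch) {
    len <- config$chrom_lengths[[ch]]
    ng <- config$n_genes %||% max(1L, floor(len / 1e5))
    spacing <- len / ng
    start <- floor((seq_len(ng) - 1L) * spacing)
    end <- pmin(start + config$gene_length_bp, len)
    data.table::data.table(
      gene_id = sprintf("%s_g%03d", ch, seq_len(ng)),
      chrom = ch, start = start, end = end, strand = "+")
  }))
  # couple expression to planted enhancers
  n_enh <- integer(nrow(genes))
  if (!is.null(config$pei_truth)) {
    gprom <- bin_index(binning, genes$chrom, genes$start)
    pei_glob <- unname(binning$offsets[config$pei_truth$chrom]) +
      config$pei_truth$promoter_bin
    n_enh <- as.integer(tabulate(match(pei_glob, gprom), nbins = nrow(genes)))
  }
  genes$n_enhancers <- n_enh
  genes$base_mean <- config$expr_base_mean *
    config$enhancer_expression_boost^n_enh
  genes$breed_fold <- 1
  if (!is.null(config$breed_effect)) {
    m <- match(config$breed_effect$gene, genes$gene_id)
    if (anyNA(m)) stop("breed_effect names unknown gene(s)")
    genes$breed_fold[m] <- config$breed_effect$fold
  }
  genes$imprint_fold <- 1
  genes$imprint_parent <- NA_character_
  if (!is.null(config$imprint_effect)) {
    m <- match(config$imprint_effect$gene, genes$gene_id)
    if (anyNA(m)) stop("imprint_effect names unknown gene(s)")
    genes$imprint_fold[m] <- config$imprint_effect$fold
    genes$imprint_parent[m] <- config$imprint_effect$parent
  }

  ## replicate design: stage x cross x family; hap1 = dam (maternal)
  st <- expand.grid(rep = seq_len(config$reps_per_cross),
                    cross = config$crosses, stage = config$stages,
                    stringsAsFactors = FALSE)
  sample_table <- data.table::data.table(
    sample_id = sprintf("%s_%s_r%d", st$stage, st$cross, st$rep),
    stage = st$stage, cross = st$cross, rep = st$rep,
    hap1_breed = ifelse(st$cross == "BxL", "broiler", "layer"),
    hap2_breed = ifelse(st$cross == "BxL", "layer", "broiler"),
    hap1_parent = "maternal", hap2_parent = "paternal")

  ## two-breed allele frequencies (Balding-Nichols around an ancestral freq)
  fst <- rep_len(config$target_fst, config$n_pop_sites)
  p_anc <- stats::runif(config$n_pop_sites, 0.05, 0.95)
  draw_pop <- function() {
    p <- p_anc
    pos <- fst > 0
    a <- p_anc[pos] * (1 - fst[pos]) / fst[pos]
    b <- (1 - p_anc[pos]) * (1 - fst[pos]) / fst[pos]
    p[pos] <- stats::rbeta(sum(pos), a, b)
    p
  }
  population_freq_truth <- data.table::data.table(
    site = seq_len(config$n_pop_sites),
    p_anc = p_anc, target_fst = fst,
    p_broiler = draw_pop(), p_layer = draw_pop())

  structure(list(binning = binning, variant_table = variant_table,
                 compartment_truth = comp, covariate = covariate,
                 tad_truth = tad_truth, pairing_truth = pairing_truth,
                 pei_truth = config$pei_truth, genes = genes,
                 sample_table = sample_table,
                 population_freq_truth = population_freq_truth,
                 config = config),
            class = "synthetic_truth")
}

# upper-triangle (i <= j) pair grid with all planted structure applied;
# returns data.table(i, j, w) with w summing to 1 within the chromosome
cis_pair_weights <- function(truth, chrom) {
  config <- truth$config
  nb <- truth$binning$n_bins_per_chrom[[chrom]]
  i <- rep.int(seq_len(nb), nb - seq_len(nb) + 1L)
  j <- sequence(nb - seq_len(nb) + 1L, from = seq_len(nb))
  # exact power law at bin-multiple distances; the diagonal sits at half a bin
  d_bp <- pmax(j - i, 0.5) * config$bin_size
  w <- d_bp^config$decay_exponent
  cb <- chrom_bins(truth$binning, chrom)
  lab <- truth$compartment_truth[cb]
  if (config$compartment_strength > 1) {
    w <- w * ifelse(lab[i] == lab[j], config$compartment_strength, 1)
  }
  if (config$tad_strength > 1) {
    dom <- truth$tad_truth[[chrom]]$domain_id
    w <- w * ifelse(dom[i] == dom[j], config$tad_strength, 1)
  }
  pt <- truth$pei_truth
  if (!is.null(pt)) {
    pt <- pt[pt$chrom == chrom, , drop = FALSE]
    if (nrow(pt)) {
      a <- pmin(pt$promoter_bin, pt$enhancer_bin)
      b <- pmax(pt$promoter_bin, pt$enhancer_bin)
      # linear index into the (i <= j) grid: row a starts after
      # sum_{k<a} (nb - k + 1) entries
      idx <- (a - 1L) * (nb + 1L) - a * (a - 1L) %/% 2L + (b - a + 1L)
      w[idx] <- w[idx] * pt$fold
    }
  }
  rl <- config$random_ligation_fraction
  w <- (1 - rl) * w / sum(w) + rl / length(w)
  data.table::data.table(i = i, j = j, w = w)
}

# inter-homolog pair weights: cis decay with near-diagonal pairing elevation
trans_pair_weights <- function(truth, chrom) {
  config <- truth$config
  pw <- cis_pair_weights(truth, chrom)
  blk <- truth$pairing_truth[[chrom]]
  if (length(blk)) {
    pb <- config$pairing_blocks
    pb <- pb[pb$chrom == chrom, , drop = FALSE]
    for (k in seq_len(nrow(pb))) {
      bins <- seq.int(pb$start[k] %/% config$bin_size + 1L,
                      (pb$end[k] - 1L) %/% config$bin_size + 1L)
      sel <- pw$i %in% bins & pw$j %in% bins &
        (pw$j - pw$i) <= config$pairing_window
      pw$w[sel] <- pw$w[sel] * pb$fold[k]
    }
  }
  pw$w <- pw$w / sum(pw$w)
  pw
}

#' Simulate a binned cis contact matrix directly
#'
#' Matrix-level shortcut sharing the same structural model as
#' [simulate_contacts()]: per-pair counts are Poisson with mean proportional
#' to the planted pair weights. Useful when record-level haplotype votes are
#' not needed (compartment/TAD/PEI recovery studies).
#'
#' @param truth a `synthetic_truth`.
#' @param chrom chromosome name.
#' @param n_contacts expected total count (default from config).
#' @param inter_homolog if `TRUE`, use the inter-homolog weight grid (cis
#'   decay plus pairing-block diagonal elevation).
#' @param poisson draw Poisson counts (default); `FALSE` returns the
#'   noise-free expected counts themselves (model self-consistency checks).
#' @return sparse symmetric matrix (`Matrix::dgCMatrix`) of counts over the
#'   chromosome's bins.
#' @export
simulate_cis_matrix <- function(truth, chrom, n_contacts = NULL,
                                inter_homolog = FALSE, poisson = TRUE) {
  config <- truth$config
  n <- n_contacts %||% config$n_contacts
  if (n <= 0) stop("n_contacts must be positive")
  pw <- if (inter_homolog) trans_pair_weights(truth, chrom)
        else cis_pair_weights(truth, chrom)
  cnt <- if (poisson) stats::rpois(nrow(pw), n * pw$w) else n * pw$w
  keep <- cnt > 0
  sym_sparse(pw$i[keep], pw$j[keep], cnt[keep],
             truth$binning$n_bins_per_chrom[[chrom]])
}

#' Simulate allele-tagged Hi-C contact records
#'
#' Draws `n_contacts` ligation events: intra-haplotype cis contacts follow
#' the planted structural model, a configured fraction is routed between
#' homologs (with pairing-block elevation), and a small fraction connects
#' non-homologous chromosomes. Each read end spans `read_span` bp and
#' collects one haplotype vote per overlapping heterozygous SNV; each vote
#' flips to the wrong haplotype with probability `vote_error`. True
#' haplotype labels are retained for benchmarking.
#'
#' @param truth a `synthetic_truth`.
#' @param config the same [sim_config()] the truth was generated from.
#' @return `data.table` with columns chrom1, pos1, chrom2, pos2 (0-based),
#'   e1_h1, e1_h2, e2_h1, e2_h2 (vote counts per end), true1, true2
#'   (haplotype of origin, 1 or 2).
#' @export
simulate_contacts <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (config$n_contacts <= 0) stop("n_contacts must be positive")
  set.seed(config$seed + 1L)
  chroms <- names(config$chrom_lengths)
  n_total <- config$n_contacts
  n_het <- stats::rbinom(1L, n_total, config$heterolog_fraction)
  n_trans <- stats::rbinom(1L, n_total - n_het,
                           config$inter_homolog_fraction /
                             (1 - config$heterolog_fraction))
  n_cis <- n_total - n_het - n_trans
  clen <- config$chrom_lengths

  sample_pairs <- function(n, trans) {
    if (n == 0L) {
      return(data.table::data.table(chrom = character(0), i = integer(0),
                                    j = integer(0)))
    }
    per_chrom <- drop(stats::rmultinom(1L, n, clen / sum(clen)))
    data.table::rbindlist(lapply(seq_along(chroms), function(k) {
      if (per_chrom[k] == 0L) return(NULL)
      pw <- if (trans) trans_pair_weights(truth, chroms[k])
            else cis_pair_weights(truth, chroms[k])
      cnt <- drop(stats::rmultinom(1L, per_chrom[k], pw$w))
      keep <- cnt > 0L
      data.table::data.table(chrom = chroms[k],
                             i = rep.int(pw$i[keep], cnt[keep]),
                             j = rep.int(pw$j[keep], cnt[keep]))
    }))
  }

  cis <- sample_pairs(n_cis, trans = FALSE)
  trans <- sample_pairs(n_trans, trans = TRUE)

  bs <- config$bin_size
  pos_in_bin <- function(chrom, bin) {
    lo <- (bin - 1L) * bs
    hi <- pmin(lo + bs, clen[chrom])
    as.integer(floor(lo + stats::runif(length(bin)) * (hi - lo)))
  }
  rec <- data.table::rbindlist(list(
    data.table::data.table(chrom1 = cis$chrom, pos1 = pos_in_bin(cis$chrom, cis$i),
                           chrom2 = cis$chrom, pos2 = pos_in_bin(cis$chrom, cis$j),
                           kind = "cis"),
    data.table::data.table(chrom1 = trans$chrom, pos1 = pos_in_bin(trans$chrom, trans$i),
                           chrom2 = trans$chrom, pos2 = pos_in_bin(trans$chrom, trans$j),
                           kind = "trans")
  ))
  if (n_het > 0L && length(chroms) >= 2L) {
    c1 <- sample(chroms, n_het, replace = TRUE, prob = clen / sum(clen))
    c2 <- vapply(c1, function(ch) sample(setdiff(chroms, ch), 1L), "")
    rec <- data.table::rbindlist(list(rec, data.table::data.table(
      chrom1 = c1, pos1 = as.integer(floor(stats::runif(n_het) * clen[c1])),
      chrom2 = c2, pos2 = as.integer(floor(stats::runif(n_het) * clen[c2])),
      kind = "het")))
  }

  ## true haplotype labels
  n <- nrow(rec)
  h <- sample.int(2L, n, replace = TRUE)
  rec$true1 <- h
  rec$true2 <- data.table::fifelse(rec$kind == "cis", h,
                                   data.table::fifelse(rec$kind == "trans",
                                                       3L - h,
                                                       sample.int(2L, n, replace = TRUE)))
  rec$kind <- NULL

  ## SNV votes per end: count variants overlapping [pos, pos + read_span)
  vpos <- split(truth$variant_table$pos, truth$variant_table$chrom)
  count_overlaps <- function(chrom, pos) {
    nv <- integer(length(pos))
    for (ch in unique(chrom)) {
      v <- vpos[[ch]]
      sel <- chrom == ch
      if (is.null(v) || length(v) == 0L) next
      nv[sel] <- findInterval(pos[sel] + config$read_span - 0.5, v) -
        findInterval(pos[sel] - 0.5, v)
    }
    nv
  }
  add_votes <- function(nv, true_hap) {
    flips <- stats::rbinom(length(nv), nv, config$vote_error)
    h1 <- data.table::fifelse(true_hap == 1L, nv - flips, flips)
    list(h1 = h1, h2 = nv - h1)
  }
  v1 <- add_votes(count_overlaps(rec$chrom1, rec$pos1), rec$true1)
  v2 <- add_votes(count_overlaps(rec$chrom2, rec$pos2), rec$true2)
  rec$e1_h1 <- v1$h1; rec$e1_h2 <- v1$h2
  rec$e2_h1 <- v2$h1; rec$e2_h2 <- v2$h2
  data.table::setcolorder(rec, c("chrom1", "pos1", "chrom2", "pos2",
                                 "e1_h1", "e1_h2", "e2_h1", "e2_h2",
                                 "true1", "true2"))
  rec[]
}

#' Simulate allelic expression counts and population genotypes
#'
#' Per-gene maternal/paternal informative read counts are drawn for every
#' sample in the replicate design with planted breed effects (a fold
#' favouring the broiler haplotype) and, only if explicitly planted,
#' parent-of-origin effects — the default carries none, the avian null.
#' Two-breed diploid genotypes are drawn binomially from the
#' Balding-Nichols population frequencies in the truth.
#'
#' @param truth a `synthetic_truth`.
#' @param config the generating [sim_config()].
#' @param depth_factor multiplier on every gene's expected count.
#' @return list with `expression`: data.table (sample_id, gene_id, maternal,
#'   paternal, tpm, plus sample metadata), and `genotypes`: list of two
#'   integer matrices (sites x individuals, minor-allele dosage 0/1/2) named
#'   broiler and layer.
#' @export
simulate_expression_and_population <- function(truth, config = truth$config,
                                               depth_factor = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (depth_factor <= 0) stop("depth must be positive")
  set.seed(config$seed + 2L)
  st <- truth$sample_table
  genes <- truth$genes
  expr <- data.table::rbindlist(lapply(seq_len(nrow(st)), function(s) {
    total <- stats::rpois(nrow(genes), genes$base_mean * depth_factor)
    # broiler:layer fold -> probability that a read is maternal
    bf <- genes$breed_fold
    p_broiler <- bf / (bf + 1)
    p_mat <- if (st$hap1_breed[s] == "broiler") p_broiler else 1 - p_broiler
    # parent-of-origin fold applies to the maternal allele irrespective of cross
    imf <- data.table::fifelse(is.na(genes$imprint_parent), 1,
                               data.table::fifelse(genes$imprint_parent == "maternal",
                                                   genes$imprint_fold,
                                                   1 / genes$imprint_fold))
    odds <- p_mat / (1 - p_mat) * imf
    p_mat <- odds / (1 + odds)
    maternal <- stats::rbinom(nrow(genes), total, p_mat)
    tpm <- total / max(sum(total), 1) * 1e6
    data.table::data.table(sample_id = st$sample_id[s], gene_id = genes$gene_id,
                           maternal = maternal, paternal = total - maternal,
                           tpm = tpm)
  }))
  expr <- merge(expr, st, by = "sample_id", sort = FALSE)

  pf <- truth$population_freq_truth
  draw_geno <- function(p) {
    matrix(stats::rbinom(length(p) * config$n_per_pop, 2L, rep(p, config$n_per_pop)),
           nrow = length(p), ncol = config$n_per_pop)
  }
  list(expression = expr,
       genotypes = list(broiler = draw_geno(pf$p_broiler),
                        layer = draw_geno(pf$p_layer)))
}
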