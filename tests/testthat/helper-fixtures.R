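# shared fixture builders; everything is generated in code

# small one-chromosome config for fast module tests
tiny_config <- function(..., chrom_lengths = c(chr1 = 2e6), n_contacts = 2e4,
                        seed = 101) {
  sim_config(chrom_lengths = chrom_lengths, n_contacts = n_contacts,
             seed = seed, ...)
}

# symmetric random sparse count matrix with positive diagonal band
random_contact_matrix <- function(n, seed = 1, density = 0.3) {
  set.seed(seed)
  npair <- n * (n + 1) / 2
  i <- rep.int(seq_len(n), n - seq_len(n) + 1L)
  j <- sequence(n - seq_len(n) + 1L, from = seq_len(n))
  keep <- runif(npair) < density | (j - i) <= 1  # keep band so no empty rows
  x <- rpois(sum(keep), 20) + 1
  m <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = x, dims = c(n, n),
                            symmetric = TRUE)
  methods::as(m, "generalMatrix")
}

# planted-TAD genome used by TAD and PEI tests
tad_genome <- function(seed = 9, sizes = c(4e5, 2e5, 6e5, 8e5, 3e5,
                                           5e5, 2e5, 7e5, 4e5, 6e5),
                       tad_strength = 4, n_contacts = 2e6) {
  cfg <- sim_config(c(chr1 = sum(sizes)), tad_sizes_bp = list(chr1 = sizes),
                    tad_strength = tad_strength, n_contacts = n_contacts,
                    seed = seed)
  tr <- make_truth(cfg)
  M <- simulate_cis_matrix(tr, "chr1")
  list(config = cfg, truth = tr, matrix = M)
}

# expression tables split per sample, as imprinting_screen expects
expression_tables <- function(truth, ep) {
  e <- ep$expression
  split(data.table::data.table(gene_id = e$gene_id, hap1 = e$maternal,
                               hap2 = e$paternal, untestable = FALSE),
        e$sample_id)
}
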