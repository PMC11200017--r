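# one simulated PEI genome: 5-Mb chromosome, 5-kb bins, planted 5x peaks
pei_genome <- function(seed, n_contacts = 8e6, fold = 5) {
  set.seed(seed * 1000)
  chrlen <- 5e6; bs <- 5000; nb <- chrlen / bs
  gene_start <- seq(0, chrlen - 1e5, by = 1e5)
  prom_bin <- gene_start %/% bs + 1
  pick <- seq(1, 45, by = 2)
  enh_off <- sample(10:30, length(pick), replace = TRUE)
  pei <- data.frame(chrom = "chr1", promoter_bin = prom_bin[pick],
                    enhancer_bin = pmin(prom_bin[pick] + enh_off, nb),
                    fold = fold)
  cfg <- sim_config(c(chr1 = chrlen), bin_size = bs, pei_truth = pei,
                    tad_strength = 2, n_contacts = n_contacts, n_genes = 50,
                    seed = seed)
  tr <- make_truth(cfg)
  names(prom_bin) <- sprintf("g%02d", seq_along(prom_bin))
  list(config = cfg, truth = tr, matrix = simulate_cis_matrix(tr, "chr1"),
       promoters = prom_bin, planted = pei, bin_size = bs)
}

test_that("expected model is self-consistent and scale-equivariant", {
  g <- pei_genome(3, fold = 1)  # no peaks: matrix follows the model exactly
  exact <- simulate_cis_matrix(g$truth, "chr1", poisson = FALSE)
  model <- fit_expected(exact, g$truth$tad_truth$chr1$domains)
  T <- methods::as(Matrix::triu(exact, k = 5), "TsparseMatrix")
  sel <- (T@j - T@i) <= 200
  oe <- T@x[sel] / model$expected(T@i[sel] + 1L, T@j[sel] + 1L)
  expect_lt(mean(abs(log2(oe[oe > 0]))), 0.05)
  # doubling the matrix doubles the expectation
  model2 <- fit_expected(exact * 2, g$truth$tad_truth$chr1$domains)
  expect_equal(model2$expected(1L, 30L) / model$expected(1L, 30L), 2,
               tolerance = 0.01)
})

test_that("domain enrichment raises the domain fit above background", {
  g <- pei_genome(4)
  model <- fit_expected(g$matrix, g$truth$tad_truth$chr1$domains)
  fits <- Filter(Negate(is.null), model$domain_fits)
  mid_d <- 10
  dom_at <- vapply(fits, function(f) {
    exp(f["intercept"]) * mid_d^f["exponent"] + f["floor"]
  }, numeric(1))
  bgf <- model$background
  bg_at <- exp(bgf["intercept"]) * mid_d^bgf["exponent"] + bgf["floor"]
  expect_gt(stats::median(dom_at), bg_at)
})

test_that("no enrichment means no calls; close pairs are never tested", {
  g <- pei_genome(5, fold = 1)
  model <- fit_expected(g$matrix, g$truth$tad_truth$chr1$domains)
  called <- call_peis(g$matrix, model, g$promoters, bin_size = g$bin_size)
  expect_lte(nrow(called), 2)  # BH at FDR 0.05 under the null
  # the 25-kb lower bound excludes a 10-kb candidate
  called2 <- call_peis(g$matrix, model, g$promoters[1],
                       candidates = g$promoters[1] + 2L,
                       bin_size = g$bin_size)
  expect_equal(nrow(called2), 0)
  expect_warning(call_peis(g$matrix, model, c(gX = 5000L),
                           bin_size = g$bin_size), "outside")
})

test_that("planted peaks are recovered at controlled FDR", {
  stats <- vapply(1:5, function(seed) {
    g <- pei_genome(seed)
    model <- fit_expected(g$matrix, g$truth$tad_truth$chr1$domains)
    called <- call_peis(g$matrix, model, g$promoters, bin_size = g$bin_size)
    tk <- paste(g$planted$promoter_bin, g$planted$enhancer_bin)
    ck <- paste(called$promoter_bin, called$enhancer_bin)
    c(tp = sum(ck %in% tk), fp = sum(!(ck %in% tk)), nt = length(tk))
  }, numeric(3))
  expect_gte(sum(stats["tp", ]) / sum(stats["nt", ]), 0.8)
  expect_lte(sum(stats["fp", ]) / max(sum(stats["tp", ] + stats["fp", ]), 1),
             0.10)
})

test_that("called PEIs stay inside TADs when planted there", {
  # plant every peak within its promoter's domain
  set.seed(606)
  chrlen <- 5e6; bs <- 5000; nb <- chrlen / bs
  base_cfg <- sim_config(c(chr1 = chrlen), bin_size = bs, tad_strength = 2,
                         n_contacts = 8e6, n_genes = 50, seed = 6)
  dom <- make_truth(base_cfg)$tad_truth$chr1
  prom_bin <- seq(0, chrlen - 1e5, by = 1e5) %/% bs + 1
  planted <- do.call(rbind, lapply(prom_bin, function(p) {
    d <- dom$domain_id[p]
    hi <- dom$domains$to[d]
    if (hi - p < 6) return(NULL)  # needs >= 25 kb of room in-domain
    data.frame(chrom = "chr1", promoter_bin = p,
               enhancer_bin = sample(seq(p + 5, hi), 1), fold = 5)
  }))
  cfg <- sim_config(c(chr1 = chrlen), bin_size = bs, pei_truth = planted,
                    tad_strength = 2, n_contacts = 8e6, n_genes = 50, seed = 6)
  tr <- make_truth(cfg)
  M <- simulate_cis_matrix(tr, "chr1")
  model <- fit_expected(M, tr$tad_truth$chr1$domains)
  names(prom_bin) <- sprintf("g%02d", seq_along(prom_bin))
  called <- call_peis(M, model, prom_bin, bin_size = bs)
  intra <- tr$tad_truth$chr1$domain_id[called$promoter_bin] ==
    tr$tad_truth$chr1$domain_id[called$enhancer_bin]
  expect_gte(mean(intra), 0.95)
})

test_that("RPS follows its closed form and monotonicity", {
  empty <- data.table::data.table()
  data.table::setattr(empty, "class", c("pei_set", "data.table", "data.frame"))
  expect_equal(unname(compute_rps(empty, genes = "g1")), 0)
  one <- data.table::data.table(gene = "g1", promoter_bin = 1L,
                                enhancer_bin = 10L, observed = 50,
                                oe = 5)
  expect_equal(unname(compute_rps(one)), log2(1 + 4), tolerance = 1e-12)
  two <- rbind(one, data.table::data.table(gene = "g1", promoter_bin = 1L,
                                           enhancer_bin = 20L, observed = 30,
                                           oe = 2))
  expect_gt(compute_rps(two)["g1"], compute_rps(one)["g1"])
})

test_that("differential RPS applies the axis thresholds", {
  genes <- paste0("g", 1:4)
  a <- matrix(c(5, 5, 5, 5,   1, 1.05, 0.95, 1,  2, 2, 2, 2,  1, 6, 0, 5),
              4, 4, byrow = TRUE, dimnames = list(genes, NULL))
  b <- a
  b[1, ] <- a[1, ] - 3.5   # stage-sized effect, consistent
  b[2, ] <- a[2, ] - 0.4   # breed-sized effect, consistent
  b[4, ] <- a[4, ] - c(5, -5, 5, -5)  # big but inconsistent
  stage <- differential_rps(a, b, axis_threshold = 3)
  expect_identical(stage$flagged, c(TRUE, FALSE, FALSE, FALSE))
  breed <- differential_rps(a, b, axis_threshold = 0.3)
  expect_true(breed$flagged[2])
  expect_false(breed$flagged[4])
  expect_error(differential_rps(a[, 1, drop = FALSE], b[, 1, drop = FALSE],
                                3), "replicates")
})

test_that("same-stage PEI merging is a union with provenance", {
  mk <- function(pb, eb) data.table::data.table(
    gene = paste0("g", pb), promoter_bin = pb, enhancer_bin = eb,
    oe = 2 + pb / 10)
  a <- mk(1:10, 21:30)
  b <- mk(6:20, 26:40)  # overlap of 5 pairs
  m <- merge_stage_peis(list(a, b))
  expect_equal(nrow(m), 10 + 15 - 5)
  expect_equal(sum(m$n_samples == 2), 5)
  expect_equal(nrow(merge_stage_peis(list(a, a))), nrow(a))
  dis <- merge_stage_peis(list(mk(1:10, 21:30), mk(41:55, 61:75)))
  expect_equal(nrow(dis), 25)
})
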