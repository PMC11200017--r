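test_that("SNV counts aggregate additively to genes", {
  snv <- data.frame(chrom = "chr1", pos = c(100, 200, 5000),
                    hap1_count = c(10, 20, 7), hap2_count = c(5, 15, 2))
  gm <- data.frame(gene_id = c("gA", "gB", "gC"), chrom = "chr1",
                   start = c(0, 4000, 8000), end = c(1000, 6000, 9000))
  tab <- gene_allelic_counts(snv, gm)
  expect_equal(tab$hap1[tab$gene_id == "gA"], 30)
  expect_equal(tab$hap2[tab$gene_id == "gA"], 20)
  expect_equal(tab$hap1[tab$gene_id == "gB"], 7)
  expect_true(tab$untestable[tab$gene_id == "gC"])
  # SNV shared by two overlapping genes counts for both and is flagged
  gm2 <- rbind(gm, data.frame(gene_id = "gA2", chrom = "chr1", start = 0,
                              end = 300))
  tab2 <- gene_allelic_counts(snv, gm2)
  expect_equal(tab2$hap1[tab2$gene_id == "gA2"], 30)
  expect_true(all(tab2$multi_gene[tab2$gene_id %in% c("gA", "gA2")]))
})

test_that("binomial bias test matches the exact oracle and categories", {
  tab <- data.frame(gene_id = c("even", "biased", "shallow"),
                    hap1 = c(50L, 90L, 5L), hap2 = c(50L, 10L, 3L),
                    untestable = FALSE)
  out <- allelic_bias_test(tab)
  expect_equal(out$category, c("biallelic", "hap1_biased", "untestable"))
  # oracle: exact binomial enumeration
  p_oracle <- sum(stats::dbinom(0:100, 100, 0.5)[
    stats::dbinom(0:100, 100, 0.5) <= stats::dbinom(90, 100, 0.5)])
  q_oracle <- stats::p.adjust(c(stats::binom.test(50, 100)$p.value, p_oracle),
                              method = "BH")[2]
  expect_equal(out$q[2], q_oracle, tolerance = 1e-10)
  expect_equal(out$p[2], p_oracle, tolerance = 1e-10)
})

test_that("low TPM makes genes untestable regardless of counts", {
  tab <- data.frame(gene_id = c("g1", "g2"), hap1 = c(900L, 900L),
                    hap2 = c(100L, 100L), untestable = FALSE)
  out <- allelic_bias_test(tab, max_tpm = c(0.3, 2))
  expect_equal(out$category, c("untestable", "hap1_biased"))
})

test_that("ratio window keeps significant-but-mild bias biallelic", {
  # 580/1000: q tiny but ratio 0.58 inside [0.3, 0.7]
  tab <- data.frame(gene_id = "g", hap1 = 580L, hap2 = 420L,
                    untestable = FALSE)
  expect_equal(allelic_bias_test(tab)$category, "biallelic")
})

test_that("imprinting screen separates parent-of-origin from breed effects", {
  st <- data.frame(sample_id = c("f1", "f2", "r1", "r2"),
                   cross = c("BxL", "BxL", "LxB", "LxB"),
                   hap1_breed = c("broiler", "broiler", "layer", "layer"))
  mk <- function(h1, h2) data.table::data.table(
    gene_id = c("imprinted", "breedy", "plain"),
    hap1 = h1, hap2 = h2, untestable = FALSE)
  # imprinted: maternal-biased in both directions;
  # breedy: broiler-biased (maternal fwd, paternal rev); plain: none
  tabs <- list(
    f1 = mk(c(90L, 85L, 50L), c(10L, 15L, 50L)),
    f2 = mk(c(88L, 80L, 45L), c(12L, 20L, 55L)),
    r1 = mk(c(92L, 18L, 52L), c(8L, 82L, 48L)),
    r2 = mk(c(87L, 15L, 49L), c(13L, 85L, 51L)))
  scr <- imprinting_screen(tabs, st)
  expect_equal(scr$classification[scr$gene_id == "imprinted"],
               "imprinting_candidate_maternal")
  expect_equal(scr$classification[scr$gene_id == "breedy"], "breed_effect")
  expect_equal(scr$classification[scr$gene_id == "plain"], "none")
  expect_error(imprinting_screen(tabs[1:2], st[1:2, ]), "cross directions")
})

test_that("label swap maps maternal candidates to paternal exactly", {
  st <- data.frame(sample_id = c("f1", "f2", "r1", "r2"),
                   cross = c("BxL", "BxL", "LxB", "LxB"),
                   hap1_breed = c("broiler", "broiler", "layer", "layer"))
  mk <- function(h1, h2) data.table::data.table(
    gene_id = c("gM", "gP"), hap1 = h1, hap2 = h2, untestable = FALSE)
  tabs <- list(f1 = mk(c(90L, 10L), c(10L, 90L)),
               f2 = mk(c(85L, 12L), c(15L, 88L)),
               r1 = mk(c(92L, 9L), c(8L, 91L)),
               r2 = mk(c(88L, 14L), c(12L, 86L)))
  swap <- lapply(tabs, function(t) data.table::data.table(
    gene_id = t$gene_id, hap1 = t$hap2, hap2 = t$hap1, untestable = FALSE))
  scr <- imprinting_screen(tabs, st)
  scr_sw <- imprinting_screen(swap, st)
  expect_equal(scr$classification,
               c("imprinting_candidate_maternal", "imprinting_candidate_paternal"))
  expect_equal(scr_sw$classification,
               c("imprinting_candidate_paternal", "imprinting_candidate_maternal"))
})

test_that("planted imprinting is detected when simulated", {
  cfg <- tiny_config(n_genes = 20, expr_base_mean = 300,
                     imprint_effect = data.frame(gene = "chr1_g005", fold = 8,
                                                 parent = "maternal"))
  tr <- make_truth(cfg)
  ep <- simulate_expression_and_population(tr)
  scr <- imprinting_screen(expression_tables(tr, ep), tr$sample_table)
  expect_equal(scr$classification[scr$gene_id == "chr1_g005"],
               "imprinting_candidate_maternal")
})
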