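test_that("allele assignment follows the unanimity rule", {
  expect_equal(assign_allele(c(2L, 0L, 1L, 0L), c(0L, 0L, 1L, 3L)),
               c("hap1", "unknown", "conflict", "hap2"))
})

test_that("contact classes route to the right matrices", {
  binning <- genome_binning(c(chr1 = 1e5, chr2 = 1e5), 20000)
  mk <- function(n, c1, p1, c2, p2, v1h1, v1h2, v2h1, v2h2) {
    data.table::data.table(chrom1 = rep(c1, n), pos1 = rep(p1, n),
                           chrom2 = rep(c2, n), pos2 = rep(p2, n),
                           e1_h1 = rep(v1h1, n), e1_h2 = rep(v1h2, n),
                           e2_h1 = rep(v2h1, n), e2_h2 = rep(v2h2, n))
  }
  # 100 unanimous-hap1 cis records -> all M11, none M12
  pcm <- phase_contacts(mk(100, "chr1", 5000, "chr1", 45000, 2, 0, 1, 0), binning)
  expect_equal(contact_total(pcm$M11), 100)
  expect_equal(contact_total(pcm$M12), 0)
  # opposite ends same chromosome -> M12
  pcm <- phase_contacts(mk(1, "chr1", 5000, "chr1", 45000, 1, 0, 0, 1), binning)
  expect_equal(contact_total(pcm$M12), 1)
  # single-end evidence accepted as cis
  pcm <- phase_contacts(mk(1, "chr1", 5000, "chr1", 45000, 0, 0, 0, 2), binning)
  expect_equal(contact_total(pcm$M22), 1)
  # different chromosomes with evidence -> heterolog
  pcm <- phase_contacts(mk(3, "chr1", 5000, "chr2", 5000, 1, 0, 0, 0), binning)
  expect_equal(nrow(pcm$heterolog), 3)
  # conflict end discards the record
  pcm <- phase_contacts(mk(2, "chr1", 5000, "chr1", 45000, 1, 1, 1, 0), binning)
  expect_equal(unname(pcm$stats$counts["conflict"]), 2)
  expect_equal(contact_total(pcm$M11) + contact_total(pcm$M22), 0)
  # unknown chromosome errors
  expect_error(phase_contacts(mk(1, "chrX", 0, "chr1", 0, 1, 0, 1, 0), binning),
               "unknown chromosome")
})

test_that("class counts conserve the input and fractions sum to one", {
  cfg <- tiny_config(chrom_lengths = c(chr1 = 2e6, chr2 = 2e6), n_contacts = 3e4)
  tr <- make_truth(cfg)
  rec <- simulate_contacts(tr)
  pcm <- phase_contacts(rec, tr$binning)
  expect_equal(sum(pcm$stats$counts), nrow(rec))
  expect_equal(sum(pcm$stats$fractions), 1)
})

test_that("swapping haplotype labels swaps M11 and M22 exactly", {
  cfg <- tiny_config(n_contacts = 2e4)
  tr <- make_truth(cfg)
  rec <- simulate_contacts(tr)
  swapped <- data.table::copy(rec)
  data.table::setnames(swapped, c("e1_h1", "e1_h2", "e2_h1", "e2_h2"),
                       c("e1_h2", "e1_h1", "e2_h2", "e2_h1"))
  a <- phase_contacts(rec, tr$binning)
  b <- phase_contacts(swapped, tr$binning)
  expect_equal(a$M11, b$M22)
  expect_equal(a$M22, b$M11)
  expect_equal(a$M12, b$M12)
})

test_that("imputation conserves totals and follows window ratios", {
  binning <- genome_binning(c(chr1 = 2e5), 20000)
  # phased signal only in M11 near bins 2-4
  rec11 <- data.table::data.table(
    chrom1 = "chr1", pos1 = c(30000, 50000, 70000),
    chrom2 = "chr1", pos2 = c(50000, 70000, 90000),
    e1_h1 = 1L, e1_h2 = 0L, e2_h1 = 1L, e2_h2 = 0L)
  unph <- data.table::data.table(
    chrom1 = "chr1", pos1 = rep(50000, 10), chrom2 = "chr1",
    pos2 = rep(70000, 10), e1_h1 = 0L, e1_h2 = 0L, e2_h1 = 0L, e2_h2 = 0L)
  pcm <- phase_contacts(rbind(rec11, unph), binning)
  before <- contact_total(pcm$M11) + contact_total(pcm$M22)
  pool <- sum(pcm$unphased$same_chrom)
  set.seed(1)
  out <- impute_local(pcm)
  # window ratio 100:0 -> everything to M11
  expect_equal(contact_total(out$M11), before + pool)
  expect_equal(contact_total(out$M22), 0)
})

test_that("imputation splits 50/50 in expectation with balanced windows", {
  binning <- genome_binning(c(chr1 = 2e5), 20000)
  base <- data.table::data.table(
    chrom1 = "chr1", pos1 = c(30000, 30000), chrom2 = "chr1",
    pos2 = c(70000, 70000),
    e1_h1 = c(1L, 0L), e1_h2 = c(0L, 1L), e2_h1 = c(1L, 0L), e2_h2 = c(0L, 1L))
  unph <- data.table::data.table(
    chrom1 = "chr1", pos1 = rep(50000, 400), chrom2 = "chr1",
    pos2 = rep(50000, 400), e1_h1 = 0L, e1_h2 = 0L, e2_h1 = 0L, e2_h2 = 0L)
  pcm <- phase_contacts(rbind(base, unph), binning)
  set.seed(42)
  out <- impute_local(pcm)
  added11 <- contact_total(out$M11) - contact_total(pcm$M11)
  expect_equal(added11 + (contact_total(out$M22) - contact_total(pcm$M22)), 400)
  expect_lt(abs(added11 - 200), 4 * sqrt(100))  # binomial(400, .5) within 4 SD
})

test_that("imputation improves the haplotype-difference signal", {
  # haplotype-asymmetric contacts: left half hap1-rich, right half hap2-rich;
  # only half the records carry an informative vote
  set.seed(19)
  binning <- genome_binning(c(chr1 = 4e6), 20000)
  n <- 20000
  pos1 <- sample(0L:(4e6 - 2e4), n, replace = TRUE)
  pos2 <- pmin(pos1 + sample(2e4:2e5, n, replace = TRUE), 4e6 - 1L)
  p_hap1 <- ifelse(pos1 < 2e6, 0.8, 0.2)
  hap <- ifelse(runif(n) < p_hap1, 1L, 2L)
  informative <- runif(n) < 0.5
  rec <- data.table::data.table(
    chrom1 = "chr1", pos1 = pos1, chrom2 = "chr1", pos2 = pos2,
    e1_h1 = as.integer(informative & hap == 1L),
    e1_h2 = as.integer(informative & hap == 2L),
    e2_h1 = 0L, e2_h2 = 0L, true1 = hap, true2 = hap)
  pcm <- phase_contacts(rec, binning)
  set.seed(7)
  out <- impute_local(pcm)
  # truth per-bin difference in cis contact load, all records
  tmarg <- function(h) {
    idx <- c(bin_index(binning, rec$chrom1[rec$true1 == h], rec$pos1[rec$true1 == h]),
             bin_index(binning, rec$chrom2[rec$true2 == h], rec$pos2[rec$true2 == h]))
    tabulate(idx, nbins = binning$n_bins)
  }
  truth_diff <- tmarg(1L) - tmarg(2L)
  diff_of <- function(p) Matrix::rowSums(p$M11) - Matrix::rowSums(p$M22)
  r_without <- cor(diff_of(pcm), truth_diff)
  r_with <- cor(diff_of(out), truth_diff)
  expect_gt(r_with, r_without)
})

test_that("map resolution picks the smallest size passing the 80% rule", {
  set.seed(3)
  chrlen <- c(chr1 = 50000)
  # 8 of 10 5-kb bins get >=1000 reads; 2-kb bins mostly fail
  pos <- c(unlist(lapply(0:7, function(b) sample(b * 5000 + 0:4999, 1000, TRUE))),
           rep(40001, 10))
  rep_chr <- rep("chr1", length(pos))
  r <- map_resolution(rep_chr, pos, chrlen, c(2000, 5000, 10000))
  expect_equal(r$selected, 5000)
  # all bins saturated -> smallest candidate
  pos2 <- unlist(lapply(0:9, function(b) sample(b * 5000 + 0:4999, 3000, TRUE)))
  r2 <- map_resolution(rep("chr1", length(pos2)), pos2, chrlen, c(2500, 5000))
  expect_equal(r2$selected, 2500)
  # no reads -> nothing passes
  r3 <- map_resolution(character(0), integer(0), chrlen, c(5000))
  expect_true(is.na(r3$selected))
})
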