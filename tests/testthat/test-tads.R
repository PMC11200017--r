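test_that("directionality index matches the hand-evaluated formula", {
  # bin 2 sees A = 10 upstream, B = 30 downstream -> E = 20, DI = +10
  M <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 3), x = c(10, 30),
                            dims = c(3, 3), symmetric = TRUE)
  di <- directionality_index(methods::as(M, "generalMatrix"),
                             window_bp = 20000, bin_size = 20000)
  expect_equal(di$di[2], 10)
  # symmetric neighbourhood -> 0
  Ms <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 3), x = c(10, 10),
                             dims = c(3, 3), symmetric = TRUE)
  expect_equal(directionality_index(methods::as(Ms, "generalMatrix"),
                                    20000, 20000)$di[2], 0)
})

test_that("mirror-reversing the matrix negates DI", {
  M <- random_contact_matrix(30, seed = 21)
  di <- directionality_index(M, window_bp = 1e5, bin_size = 20000)
  Mr <- M[30:1, 30:1]
  dir <- directionality_index(Mr, window_bp = 1e5, bin_size = 20000)
  expect_equal(di$di, -rev(dir$di), tolerance = 1e-12)
})

test_that("insulation is flat on uniform maps and dips at block junctions", {
  n <- 30
  i <- rep.int(seq_len(n), n - seq_len(n) + 1L)
  j <- sequence(n - seq_len(n) + 1L, from = seq_len(n))
  U <- methods::as(Matrix::sparseMatrix(i = i, j = j, x = rep(4, length(i)),
                                        dims = c(n, n), symmetric = TRUE),
                   "generalMatrix")
  isu <- insulation_index(U, square_bp = 1e5, bin_size = 20000)
  expect_true(all(abs(isu$is[!is.na(isu$is)]) < 1e-9))
  # two blocks with zero cross-talk -> global minimum at the junction
  blk <- ifelse((i <= 15) == (j <= 15), 10, 0)
  B <- methods::as(Matrix::sparseMatrix(i = i, j = j, x = blk, dims = c(n, n),
                                        symmetric = TRUE), "generalMatrix")
  isb <- insulation_index(B, square_bp = 1e5, bin_size = 20000)
  expect_equal(which.min(isb$is), 15L, tolerance = 1)
  # scaling invariance
  expect_equal(insulation_index(B * 5, 1e5, 20000)$is, isb$is)
})

test_that("planted TAD boundaries are recovered within one bin", {
  g <- tad_genome()
  b <- kr_balance(g$matrix)
  di <- directionality_index(b$matrix)
  isx <- insulation_index(b$matrix)
  part <- call_tads(di, isx)
  truthb <- g$truth$tad_truth$chr1$boundary_bins
  hit <- vapply(truthb, function(x) any(abs(part$boundaries - x) <= 1),
                logical(1))
  expect_gte(mean(hit), 0.9)
  # identical input -> identical partition
  part2 <- call_tads(di, isx)
  expect_identical(part$domains, part2$domains)
  # uniform matrix -> single domain
  n <- 50
  i <- rep.int(seq_len(n), n - seq_len(n) + 1L)
  j <- sequence(n - seq_len(n) + 1L, from = seq_len(n))
  U <- methods::as(Matrix::sparseMatrix(i = i, j = j, x = rep(3, length(i)),
                                        dims = c(n, n), symmetric = TRUE),
                   "generalMatrix")
  pu <- call_tads(directionality_index(U), insulation_index(U))
  expect_equal(nrow(pu$domains), 1)
})

test_that("local boundary score spans its extremes", {
  n <- 40
  i <- rep.int(seq_len(n), n - seq_len(n) + 1L)
  j <- sequence(n - seq_len(n) + 1L, from = seq_len(n))
  # perfect boundary at 20: no cross-block contact
  blk <- ifelse((i <= 20) == (j <= 20), 8, 0)
  B <- methods::as(Matrix::sparseMatrix(i = i, j = j, x = blk, dims = c(n, n),
                                        symmetric = TRUE), "generalMatrix")
  expect_equal(local_boundary_score(B, 20, window_bins = 10), 1)
  # uniform -> 0
  U <- methods::as(Matrix::sparseMatrix(i = i, j = j, x = rep(8, length(i)),
                                        dims = c(n, n), symmetric = TRUE),
                   "generalMatrix")
  expect_equal(local_boundary_score(U, 20, window_bins = 10), 0)
  # incomplete window -> NA
  expect_true(is.na(local_boundary_score(U, 3, window_bins = 10)))
})

test_that("merging planted blocks lowers the junction LBS by > 0.2", {
  n <- 60
  i <- rep.int(seq_len(n), n - seq_len(n) + 1L)
  j <- sequence(n - seq_len(n) + 1L, from = seq_len(n))
  decay <- pmax(j - i, 0.5)^-1
  set.seed(4)
  mk <- function(contrast) {
    w <- decay * ifelse((i <= 30) == (j <= 30), contrast, 1)
    x <- rpois(length(w), 2e5 * w / sum(w))
    methods::as(Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n),
                                     symmetric = TRUE), "generalMatrix")
  }
  lbs_split <- local_boundary_score(mk(4), 30, window_bins = 5)
  lbs_merged <- local_boundary_score(mk(1), 30, window_bins = 5)
  expect_gt(lbs_split - lbs_merged, 0.2)
})

test_that("shifted boundaries need both effect size and consistency", {
  set.seed(8)
  a <- matrix(0.7 + rnorm(12, sd = 0.02), 3, 4)  # 3 bins x 4 replicates
  b <- a
  b[1, ] <- a[1, ] - 0.25              # consistent shift
  b[2, ] <- a[2, ] - c(0.5, -0.5, 0.5, -0.5)  # large but inconsistent
  res <- shifted_boundaries(a, b, bins = 1:3)
  expect_true(res$shifted[1])
  expect_false(res$shifted[2])
  expect_false(res$shifted[3])
  expect_error(shifted_boundaries(a[, 1, drop = FALSE], b[, 1, drop = FALSE]),
               "replicates")
})

test_that("partition similarity obeys its closed forms and symmetry", {
  P <- data.frame(from = 1, to = 12)
  Q <- data.frame(from = c(1, 5, 9), to = c(4, 8, 12))
  s <- partition_similarity(P, Q)
  expect_equal(s$moc, 0)
  expect_equal(s$vi, log(3))
  s2 <- partition_similarity(Q, Q)
  expect_equal(s2$moc, 1)
  expect_equal(s2$vi, 0)
  sflip <- partition_similarity(Q, P)
  expect_equal(sflip$moc, s$moc)
  expect_equal(sflip$vi, s$vi)
  expect_equal(partition_similarity(P, P)$moc, 1)  # 1-vs-1 pinned to 1
  expect_error(partition_similarity(P, data.frame(from = integer(0),
                                                  to = integer(0))), "empty")
})
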