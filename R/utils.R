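## internal helpers shared across modules

# data.table [.data.table semantics inside this namespace
.datatable.aware <- TRUE

# symmetric sparse matrix from triplets (i, j, x); accumulates duplicates
sym_sparse <- function(i, j, x, n) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  m <- Matrix::sparseMatrix(i = lo, j = hi, x = x, dims = c(n, n), symmetric = TRUE)
  methods::as(m, "generalMatrix")  # dgCMatrix, both triangles materialized
}

# Type-7 quartiles; pinned because Q3 + 1.5*IQR is threshold-sensitive.
tukey_upper_fence <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE, na.rm = TRUE)
  q[2] + 1.5 * (q[2] - q[1])
}

# stochastic rounding: floor(x) + Bernoulli(frac(x)); vectorized
stochastic_round <- function(x) {
  f <- floor(x)
  as.integer(f + (stats::runif(length(x)) < (x - f)))
}

# paired two-sided t-test p-value per row of delta matrix (rows = units,
# cols = pairs). Zero-variance rows are the limiting cases: a perfectly
# consistent nonzero difference -> 0, identical groups -> 1.
row_paired_t_p <- function(delta) {
  n <- ncol(delta)
  m <- rowMeans(delta)
  s <- apply(delta, 1L, stats::sd)
  tstat <- m / (s / sqrt(n))
  p <- 2 * stats::pt(abs(tstat), df = n - 1, lower.tail = FALSE)
  p[s == 0 & m != 0] <- 0
  p[s == 0 & m == 0] <- 1
  p[is.na(m) | is.na(s)] <- NA_real_
  p
}

# merge runs of consecutive integers (already sorted) into [from, to] pairs,
# joining runs separated by gaps that are entirely `bridge`-able indices
merge_runs <- function(idx, bridge = integer(0)) {
  if (length(idx) == 0) {
    return(data.frame(from = integer(0), to = integer(0)))
  }
  idx <- sort(unique(idx))
  brk <- c(TRUE, diff(idx) > 1)
  # allow joining across gaps fully covered by `bridge` indices
  if (length(bridge)) {
    for (k in which(brk)[-1]) {
      gap <- seq.int(idx[k - 1] + 1L, idx[k] - 1L)
      if (all(gap %in% bridge)) brk[k] <- FALSE
    }
  }
  grp <- cumsum(brk)
  data.frame(from = tapply(idx, grp, min), to = tapply(idx, grp, max),
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
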