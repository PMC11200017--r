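#' Total contacts in a symmetric matrix
#'
#' Sum over the upper triangle including the diagonal, i.e. each contact
#' counted once.
#' @param M symmetric matrix.
#' @return numeric scalar.
#' @export
contact_total <- function(M) {
  sum(Matrix::triu(M))
}

#' Knight-Ruiz matrix balancing
#'
#' Balances a symmetric non-negative matrix to constant row sums (1) by the
#' Knight-Ruiz algorithm: an inexact Newton method with inner conjugate-
#' gradient solves for the scaling vector x with x_i (Mx)_i = 1, followed by
#' a damped fixed-point refinement that drives the row-sum coefficient of
#' variation below tolerance. Bins with zero marginal are masked before
#' balancing and carry no scaling.
#'
#' @param M sparse symmetric non-negative matrix.
#' @param tol convergence tolerance on the balancing residual (default 1e-8).
#' @param max_iter iteration cap for the refinement stage.
#' @return a `balanced_matrix`: `matrix` (balanced, masked bins zero),
#'   `scaling` (vector, `NA` on masked bins), `mask` (logical, TRUE =
#'   usable bin), `iterations`, `residual` (final row-sum CV on the mask).
#' @export
kr_balance <- function(M, tol = 1e-8, max_iter = 1000L) {
  stopifnot(nrow(M) == ncol(M))
  M <- methods::as(methods::as(Matrix::Matrix(M, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  if (any(M@x < 0)) stop("matrix must be non-negative")
  n <- nrow(M)
  marg <- Matrix::rowSums(M)
  mask <- marg > 0
  A <- M[mask, mask, drop = FALSE]
  m <- nrow(A)
  if (m == 0L) stop("matrix has no usable bins")

  x <- rep(1, m)
  ## Knight-Ruiz inexact Newton with inner CG (bnewt)
  delta <- 0.1; Delta <- 3
  g <- 0.9; etamax <- 0.1; eta <- etamax
  rt <- tol^2
  v <- x * as.numeric(A %*% x); rk <- 1 - v
  rho_km1 <- sum(rk * rk); rout <- rho_km1; rold <- rout
  i <- 0L
  while (rout > rt && i < 50L) {
    i <- i + 1L
    k <- 0L; y <- rep(1, m)
    innertol <- max(eta^2 * rout, rt)
    Z <- p <- NULL; rho_km2 <- NA_real_
    rho_in <- rho_km1
    while (rho_in > innertol && k < 200L) {
      k <- k + 1L
      if (k == 1L) {
        Z <- rk / v; p <- Z; rho_in <- sum(rk * Z)
      } else {
        beta <- rho_in / rho_km2
        p <- Z + beta * p
      }
      w <- x * as.numeric(A %*% (x * p)) + v * p
      alpha <- rho_in / sum(p * w)
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        if (delta == 0) break
        ind <- ap < 0
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- ynew > Delta
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_in
      Z <- rk / v
      rho_in <- sum(rk * Z)
    }
    x <- x * y
    v <- x * as.numeric(A %*% x)
    rk <- 1 - v
    rho_km1 <- sum(rk * rk)
    rout <- rho_km1
    ## eta heuristic from the published scheme
    rat <- rout / rold; rold <- rout
    eta <- g * rat
    if (g * etamax^2 > 0.1) eta <- max(eta, g * etamax^2)
    eta <- max(min(eta, etamax), 0.5 * tol / sqrt(max(rout, rt)))
  }

  ## damped fixed-point refinement: guarantees row-sum CV below tolerance
  it <- 0L
  repeat {
    rs <- x * as.numeric(A %*% x)
    cv <- if (length(rs) == 1L) 0 else stats::sd(rs) / mean(rs)
    if (!is.finite(cv) || cv < tol || it >= max_iter) break
    x <- x / sqrt(rs)
    it <- it + 1L
  }
  if (!is.finite(cv) || cv >= max(tol, 1e-6)) {
    stop(sprintf("KR balancing did not converge: row-sum CV %.3g", cv))
  }

  scaling <- rep(NA_real_, n)
  scaling[mask] <- x
  Bal <- M
  s0 <- ifelse(is.na(scaling), 0, scaling)
  Bal <- Matrix::Diagonal(n, s0) %*% Bal %*% Matrix::Diagonal(n, s0)
  Bal <- methods::as(methods::as(Bal, "generalMatrix"), "CsparseMatrix")
  structure(list(matrix = Bal, scaling = scaling, mask = mask,
                 iterations = i + it, residual = cv),
            class = "balanced_matrix")
}

#' Distance-stratified quantile normalization across samples
#'
#' Within each genomic-distance stratum (or globally when unstratified), the
#' nonzero contact values of every sample are mapped onto the mean order
#' statistics of all samples, so the per-stratum value distributions become
#' identical while each sample's rank order is preserved. Applying the map
#' twice equals applying it once.
#'
#' @param matrices list of sparse symmetric matrices on identical binning.
#' @param stratify_by_distance normalize within each |i - j| stratum
#'   (default TRUE; cross-sample comparability of decay-confounded values).
#' @return list of normalized matrices in the same order.
#' @export
quantile_normalize <- function(matrices, stratify_by_distance = TRUE) {
  dims <- vapply(matrices, nrow, 0L)
  if (length(unique(dims)) != 1L ||
      length(unique(vapply(matrices, ncol, 0L))) != 1L) {
    stop("matrices must share one binning")
  }
  tri <- lapply(matrices, function(M) {
    T <- methods::as(Matrix::triu(M), "TsparseMatrix")
    data.table::data.table(i = T@i + 1L, j = T@j + 1L, x = T@x,
                           d = if (stratify_by_distance) T@j - T@i else 0L)
  })
  strata <- sort(unique(unlist(lapply(tri, function(t) unique(t$d)))))
  for (d in strata) {
    vals <- lapply(tri, function(t) t$x[t$d == d])
    ns <- lengths(vals)
    if (all(ns == 0L)) next
    ref_n <- max(ns)
    probs <- if (ref_n == 1L) 0.5 else seq(0, 1, length.out = ref_n)
    # reference: mean of per-sample quantile functions on a common grid
    qs <- matrix(vapply(vals[ns > 0L], function(v) {
      stats::quantile(v, probs, type = 7, names = FALSE)
    }, numeric(ref_n)), nrow = ref_n)
    ref <- rowMeans(qs)
    for (s in seq_along(tri)) {
      if (ns[s] == 0L) next
      sel <- tri[[s]]$d == d
      v <- tri[[s]]$x[sel]
      if (ref_n == 1L) {
        tri[[s]]$x[sel] <- ref
        next
      }
      # "first" keeps the output multiset identical across equal-length
      # samples even when tie patterns differ
      r <- rank(v, ties.method = "first")
      p <- if (ns[s] == 1L) 0.5 else (r - 1) / (ns[s] - 1)
      tri[[s]]$x[sel] <- stats::approx(probs, ref, xout = p, rule = 2)$y
    }
  }
  lapply(tri, function(t) {
    n <- dims[1]
    sym_sparse(t$i, t$j, t$x, n)
  })
}

#' Mean contact by distance and fitted power-law exponent
#'
#' @param M symmetric matrix (one chromosome).
#' @param fit_range distances (bp) included in the log-log least-squares
#'   fit; default all distances > 0.
#' @param bin_size bp per bin (for bp-scale distances; default 1 = bin units).
#' @return list: `distance`, `mean_contact` (per distance, masked-bin pairs
#'   excluded by passing a masked matrix), `exponent`, `intercept`.
#' @export
expected_by_distance <- function(M, fit_range = NULL, bin_size = 1L) {
  n <- nrow(M)
  T <- methods::as(Matrix::triu(M), "TsparseMatrix")
  d <- (T@j - T@i)
  sums <- tapply(T@x, d, sum)
  dist_bins <- as.integer(names(sums))
  n_pairs <- n - dist_bins
  mean_contact <- as.numeric(sums) / n_pairs
  # include empty distances? distances never observed keep mean 0 (dropped in log fit)
  dist_bp <- dist_bins * bin_size
  sel <- dist_bins > 0 & mean_contact > 0
  if (!is.null(fit_range)) {
    sel <- sel & dist_bp >= fit_range[1] & dist_bp <= fit_range[2]
  }
  if (sum(sel) < 3L) stop("fewer than 3 usable distance points")
  fit <- stats::lm(log(mean_contact[sel]) ~ log(dist_bp[sel]))
  list(distance = dist_bp, mean_contact = mean_contact,
       exponent = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

#' GenomeDISCO-style concordance of two contact maps
#'
#' Both matrices are row-normalized to random-walk transition matrices; the
#' score is `1 - d` with `d = sum |R1^t - R2^t| / mean(nnz)` where `nnz` is
#' the number of nonzero rows of each input. Identical inputs score exactly
#' 1; the score is symmetric in its arguments.
#'
#' @param m1,m2 sparse symmetric matrices on the same binning.
#' @param t random-walk steps (default 3).
#' @return a `concordance_score` list: `score`, `t`.
#' @export
genomedisco_score <- function(m1, m2, t = 3L) {
  if (!all(dim(m1) == dim(m2))) stop("matrices must share one binning")
  if (sum(m1) == 0 || sum(m2) == 0) stop("empty matrix")
  walk <- function(M) {
    rs <- Matrix::rowSums(M)
    inv <- ifelse(rs > 0, 1 / rs, 0)
    R <- Matrix::Diagonal(nrow(M), inv) %*% M
    P <- R
    for (k in seq_len(t - 1L)) P <- P %*% R
    P
  }
  d <- sum(abs(walk(m1) - walk(m2)))
  nnz <- function(M) sum(Matrix::rowSums(M != 0) > 0)
  denom <- mean(c(nnz(m1), nnz(m2)))
  structure(list(score = 1 - d / denom, t = t), class = "concordance_score")
}
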