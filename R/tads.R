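#' Directionality index track
#'
#' For each bin, A is the summed contact with the upstream window and B
#' with the downstream window; with E = (A + B) / 2 the index is
#' sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E), zero when A = B or
#' E = 0. Windows truncated by the chromosome end are flagged.
#'
#' @param M balanced symmetric matrix (one chromosome).
#' @param window_bp window span in bp (default 500 kb).
#' @param bin_size bp per bin.
#' @return list: `di` (numeric per bin), `truncated` (logical per bin).
#' @export
directionality_index <- function(M, window_bp = 5e5, bin_size = 20000L) {
  n <- nrow(M)
  w <- max(1L, as.integer(round(window_bp / bin_size)))
  Md <- as.matrix(M)
  di <- numeric(n)
  truncated <- logical(n)
  for (i in seq_len(n)) {
    up <- max(1L, i - w):(i - 1L)
    dn <- (i + 1L):min(n, i + w)
    truncated[i] <- (i - w < 1L) || (i + w > n)
    A <- if (i > 1L) sum(Md[i, up]) else 0
    B <- if (i < n) sum(Md[i, dn]) else 0
    E <- (A + B) / 2
    di[i] <- if (E == 0 || A == B) 0 else
      sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)
  }
  list(di = di, truncated = truncated)
}

#' Insulation index track
#'
#' For each bin, the mean contact in the square crossing it (pairs at
#' offsets 1..s on each side), expressed as the log2 ratio to the
#' chromosome-wide mean of the statistic. Edge bins with incomplete
#' windows are masked.
#'
#' @param M balanced symmetric matrix (one chromosome).
#' @param square_bp square side in bp (default 100 kb).
#' @param bin_size bp per bin.
#' @return list: `is` (numeric per bin, NA at masked edges), `square_bins`.
#' @export
insulation_index <- function(M, square_bp = 1e5, bin_size = 20000L) {
  n <- nrow(M)
  s <- max(1L, as.integer(round(square_bp / bin_size)))
  Md <- as.matrix(M)
  raw <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - s < 1L || i + s > n) next
    raw[i] <- mean(Md[(i - s):(i - 1L), (i + 1L):(i + s)])
  }
  mu <- mean(raw, na.rm = TRUE)
  isx <- if (is.finite(mu) && mu > 0) log2(raw / mu) else raw * 0
  isx[is.infinite(isx)] <- NA_real_
  list(is = isx, square_bins = s)
}

# windowed local minima of x with prominence >= prom: x[i] is the minimum
# of its +/- span window and the lower of the two flanking window maxima
# exceeds it by >= prom
local_minima <- function(x, prom = 0.1, span = 5L) {
  n <- length(x)
  out <- integer(0)
  for (i in seq_len(n)) {
    if (is.na(x[i])) next
    lw <- x[max(1L, i - span):max(1L, i - 1L)]
    rw <- x[min(n, i + 1L):min(n, i + span)]
    if (i == 1L) lw <- NA_real_
    if (i == n) rw <- NA_real_
    nbr <- c(lw, rw)
    if (all(is.na(nbr))) next
    if (any(nbr < x[i], na.rm = TRUE)) next
    # plateau tie-break: keep only the leftmost of equal minima
    if (any(!is.na(lw) & lw == x[i])) next
    lmax <- suppressWarnings(max(lw, na.rm = TRUE))
    rmax <- suppressWarnings(max(rw, na.rm = TRUE))
    if (!is.finite(lmax) || !is.finite(rmax)) next
    if (min(lmax, rmax) - x[i] >= prom) out <- c(out, i)
  }
  out
}

#' Call TADs from directionality and insulation
#'
#' Boundary candidates are insulation minima with prominence >= `prom`;
#' a candidate is retained if the directionality index switches from a
#' negative to a positive regime within +/- `di_gate_bins` bins (the end of
#' one domain followed by the start of the next). Domains are the intervals
#' between retained boundaries, dropping domains shorter than
#' `min_domain_bins`.
#'
#' @param di output of [directionality_index()].
#' @param is output of [insulation_index()].
#' @param prom insulation prominence threshold (default 0.1).
#' @param di_gate_bins half-window for the DI sign-change gate (default 2).
#' @param min_domain_bins minimum domain size in bins (default 3).
#' @return a `tad_partition`: `domains` (data.frame from, to in bins),
#'   `boundaries` (bin indices), `di`, `is`.
#' @export
call_tads <- function(di, is, prom = 0.1, di_gate_bins = 2L,
                      min_domain_bins = 3L) {
  n <- length(di$di)
  cand <- local_minima(is$is, prom = prom)
  keep <- vapply(cand, function(b) {
    lo <- max(1L, b - di_gate_bins); hi <- min(n, b + di_gate_bins)
    any(di$di[lo:b] < 0) && any(di$di[b:hi] > 0)
  }, logical(1))
  bounds <- cand[keep]
  cuts <- sort(unique(c(0L, bounds, n)))
  from <- utils::head(cuts, -1L) + 1L
  to <- utils::tail(cuts, -1L)
  ok <- (to - from + 1L) >= min_domain_bins
  domains <- data.frame(from = from[ok], to = to[ok])
  if (nrow(domains) == 0L) domains <- data.frame(from = 1L, to = n)
  structure(list(domains = domains, boundaries = bounds,
                 di = di$di, is = is$is, n_bins = n),
            class = "tad_partition")
}

#' Local boundary score
#'
#' LBS = 1 - mean(cross-boundary contacts in the w x w square) /
#' mean(within-side contacts, averaged over the two flanking triangles,
#' diagonal excluded), clipped to [0, 1]. Near 1 = strong boundary, near 0
#' = no insulation. Bins without full windows or with zero flanking signal
#' are undefined.
#'
#' @param M balanced symmetric matrix.
#' @param bins bin indices to score.
#' @param window_bins window half-width w (default 10).
#' @return numeric vector of scores (NA where undefined).
#' @export
local_boundary_score <- function(M, bins, window_bins = 10L) {
  n <- nrow(M)
  w <- window_bins
  Md <- as.matrix(M)
  vapply(bins, function(b) {
    if (b - w < 1L || b + w > n) return(NA_real_)
    up <- (b - w):(b - 1L); dn <- (b + 1L):(b + w)
    cross <- mean(Md[up, dn])
    tri <- function(idx) {
      sub <- Md[idx, idx]
      mean(sub[upper.tri(sub)])
    }
    within <- (tri(up) + tri(dn)) / 2
    if (!is.finite(within) || within <= 0) return(NA_real_)
    min(1, max(0, 1 - cross / within))
  }, numeric(1))
}

#' Shifted TAD boundaries between two sample groups
#'
#' Boundary bins present in either group are scored by LBS in every
#' replicate; bins with |mean paired LBS difference| >= `delta_threshold`
#' and paired t-test p < 0.05 are flagged as shifted.
#'
#' @param lbs_a,lbs_b numeric matrices of LBS values (rows = candidate
#'   boundary bins, columns = paired replicates).
#' @param bins bin indices labelling the rows.
#' @param delta_threshold |Delta LBS| threshold (default 0.2).
#' @param p_threshold paired t-test threshold (default 0.05).
#' @return data.frame: bin, delta, p, shifted.
#' @export
shifted_boundaries <- function(lbs_a, lbs_b, bins = seq_len(nrow(lbs_a)),
                               delta_threshold = 0.2, p_threshold = 0.05) {
  lbs_a <- as.matrix(lbs_a); lbs_b <- as.matrix(lbs_b)
  if (!all(dim(lbs_a) == dim(lbs_b))) stop("groups must be paired")
  if (ncol(lbs_a) < 2L) stop("need at least 2 paired replicates")
  delta <- rowMeans(lbs_a - lbs_b)
  p <- row_paired_t_p(lbs_a - lbs_b)
  data.frame(bin = bins, delta = delta, p = p,
             shifted = !is.na(delta) & abs(delta) >= delta_threshold &
               !is.na(p) & p < p_threshold)
}

#' Similarity of two genome partitions (MoC and VI)
#'
#' The Measure of Concordance is
#' `MoC = (1 / (sqrt(Np * Nq) - 1)) * (sum_ij Fij^2 / (|Pi| * |Qj|) - 1)`
#' with `Fij` the overlap length of domains Pi and Qj, defined as 1 when
#' both partitions are a single domain. The Variation of Information is
#' `H(P) + H(Q) - 2 MI` over length-weighted domain distributions (natural
#' log). Identical partitions give MoC 1 and VI 0.
#'
#' @param p,q `tad_partition` objects or data.frames with from/to bin
#'   columns covering the same span.
#' @return list: `moc`, `vi`.
#' @export
partition_similarity <- function(p, q) {
  dom <- function(x) if (inherits(x, "tad_partition")) x$domains else x
  P <- dom(p); Q <- dom(q)
  if (nrow(P) == 0L || nrow(Q) == 0L) stop("empty partition")
  lp <- P$to - P$from + 1
  lq <- Q$to - Q$from + 1
  np <- nrow(P); nq <- nrow(Q)
  # overlap matrix
  OV <- outer(seq_len(np), seq_len(nq), Vectorize(function(i, j) {
    max(0, min(P$to[i], Q$to[j]) - max(P$from[i], Q$from[j]) + 1)
  }))
  if (np == 1L && nq == 1L) {
    moc <- 1
  } else {
    moc <- (sum(OV^2 / outer(lp, lq)) - 1) / (sqrt(np * nq) - 1)
  }
  tot <- sum(OV)
  pij <- OV / tot
  pi_ <- rowSums(pij); qj_ <- colSums(pij)
  H <- function(x) { x <- x[x > 0]; -sum(x * log(x)) }
  mi <- sum(ifelse(pij > 0, pij * log(pij / outer(pi_, qj_)), 0))
  vi <- H(pi_) + H(qj_) - 2 * mi
  list(moc = moc, vi = max(0, vi))
}
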