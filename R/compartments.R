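#' A/B compartment profile via the A-B index
#'
#' Per chromosome, the balanced matrix is transformed to observed/expected
#' by distance, the Pearson correlation matrix of O/E is computed, and its
#' first principal component taken. The sign is oriented so that bins with
#' a higher orientation covariate (gene density or GC content) load
#' positive, i.e. positive = A, the accessible, actively transcribed
#' compartment. If PC1 tracks the covariate poorly (|r| < 0.2, e.g. it
#' captures chromosome arms), PC2 is substituted and flagged. Chromosome
#' tracks are concatenated and scaled to genome-wide SD 1, the unit in
#' which the differential thresholds are expressed.
#'
#' @param matrices list of balanced sparse matrices, one per chromosome (or
#'   a single matrix).
#' @param covariate numeric per-bin orientation covariate, concatenated in
#'   chromosome order.
#' @param min_bins chromosomes with fewer usable bins are skipped with a
#'   warning (default 10).
#' @return a `compartment_profile`: `index` (per bin, genome-wide SD 1, NA
#'   on masked/skipped bins), `label` ("A" iff index > 0), `meta`
#'   (per-chromosome PC used and covariate correlation).
#' @export
ab_index <- function(matrices, covariate, min_bins = 10L) {
  if (!is.list(matrices)) matrices <- list(matrices)
  nb <- vapply(matrices, nrow, 0L)
  stopifnot(length(covariate) == sum(nb))
  offs <- cumsum(c(0L, nb))
  raw <- rep(NA_real_, sum(nb))
  meta <- vector("list", length(matrices))
  for (k in seq_along(matrices)) {
    M <- matrices[[k]]
    cov_k <- covariate[(offs[k] + 1L):offs[k + 1L]]
    usable <- Matrix::rowSums(M) > 0
    if (sum(usable) < min_bins) {
      warning("chromosome ", k, " has fewer than ", min_bins,
              " usable bins; skipped")
      meta[[k]] <- list(pc = NA_integer_, cor = NA_real_)
      next
    }
    A <- as.matrix(M[usable, usable, drop = FALSE])
    n <- nrow(A)
    # observed / expected by distance
    d <- abs(row(A) - col(A))
    exp_d <- tapply(A, d, mean)
    E <- matrix(exp_d[as.character(d)], n, n)
    OE <- ifelse(E > 0, A / E, 0)
    C <- suppressWarnings(stats::cor(OE))
    C[!is.finite(C)] <- 0
    eg <- eigen(C, symmetric = TRUE)
    pc1 <- eg$vectors[, 1]
    r1 <- suppressWarnings(stats::cor(pc1, cov_k[usable]))
    if (is.na(r1)) r1 <- 0
    if (abs(r1) < 0.2 && ncol(eg$vectors) >= 2) {
      pc <- eg$vectors[, 2]
      r <- suppressWarnings(stats::cor(pc, cov_k[usable]))
      if (is.na(r)) r <- 0
      used <- 2L
    } else {
      pc <- pc1; r <- r1; used <- 1L
    }
    if (r < 0) pc <- -pc
    v <- rep(NA_real_, nb[k])
    v[usable] <- pc
    raw[(offs[k] + 1L):offs[k + 1L]] <- v
    meta[[k]] <- list(pc = used, cor = abs(r))
  }
  s <- stats::sd(raw, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("degenerate A-B index (zero variance)")
  idx <- raw / s
  structure(list(index = idx,
                 label = ifelse(is.na(idx), NA_character_,
                                ifelse(idx > 0, "A", "B")),
                 meta = meta),
            class = "compartment_profile")
}

#' Differential compartments between two sample groups
#'
#' Per bin, with paired replicate profiles in each group, Delta = mean(A
#' group) - mean(B group). Bins where the two group means carry opposite
#' signs (both exceeding 0.1 in magnitude, to keep sign flips within noise
#' out) are "switched"; bins with the same sign, |Delta| above the axis
#' threshold and paired t-test p < 0.05 are "variable". Adjacent same-class
#' bins are merged into regions.
#'
#' @param profiles_a,profiles_b lists of `compartment_profile` (or plain
#'   index vectors), paired by position.
#' @param axis_threshold |Delta A-B index| threshold: 1.0 between
#'   neighboring stages, 0.3 between breeds or parents of origin.
#' @param bin_size bp per bin, used to report region sizes.
#' @param p_threshold paired t-test threshold (default 0.05).
#' @param min_abs_mean magnitude both group means must exceed for a
#'   switched call (default 0.1).
#' @return a `compartment_diff`: per-bin table (`delta`, `p`, `class`), and
#'   `regions` (merged intervals with class and Mb).
#' @export
differential_compartments <- function(profiles_a, profiles_b, axis_threshold,
                                      bin_size = 20000L, p_threshold = 0.05,
                                      min_abs_mean = 0.1) {
  getidx <- function(p) if (inherits(p, "compartment_profile")) p$index else p
  A <- vapply(profiles_a, getidx, numeric(length(getidx(profiles_a[[1]]))))
  B <- vapply(profiles_b, getidx, numeric(nrow(A)))
  if (ncol(A) != ncol(B)) stop("groups must be paired (equal replicates)")
  if (ncol(A) < 2L) stop("need at least 2 paired replicates")
  ma <- rowMeans(A); mb <- rowMeans(B)
  delta <- ma - mb
  p <- row_paired_t_p(A - B)
  cls <- rep("none", nrow(A))
  switched <- !is.na(ma) & !is.na(mb) & sign(ma) != sign(mb) &
    abs(ma) > min_abs_mean & abs(mb) > min_abs_mean
  variable <- !is.na(delta) & !switched & sign(ma) == sign(mb) &
    abs(delta) > axis_threshold & !is.na(p) & p < p_threshold
  cls[switched] <- "switched"
  cls[variable] <- "variable"
  regions <- data.table::rbindlist(lapply(c("switched", "variable"), function(cl) {
    r <- merge_runs(which(cls == cl))
    if (nrow(r) == 0L) return(NULL)
    data.table::data.table(class = cl, from = r$from, to = r$to,
                           mb = (r$to - r$from + 1) * bin_size / 1e6)
  }))
  structure(list(table = data.table::data.table(bin = seq_len(nrow(A)),
                                                delta = delta, p = p,
                                                class = cls),
                 regions = regions, axis_threshold = axis_threshold),
            class = "compartment_diff")
}
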