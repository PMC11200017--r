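#' Homolog pairing score track
#'
#' Quantifies per-bin homolog co-localization from the inter-homolog map:
#' for bin i, the local intensity is the sum of M12 over the aligned-
#' diagonal window (i +/- w) x (i +/- w); the score is the log2 ratio of
#' local intensity to the chromosome-wide mean of such windows. A
#' pseudocount of one contact is applied after depth-normalizing the matrix
#' to a canonical total of 1e6 contacts, so the track is exactly invariant
#' to rescaling of M12.
#'
#' @param M12 sparse symmetric inter-homolog matrix (one chromosome, aligned
#'   homolog binning).
#' @param window_bins half-width of the diagonal window (default 2).
#' @param mask optional logical vector, `FALSE` = masked bin.
#' @return a `pairing_track`: `hps` (numeric per bin, `NA` on masked bins),
#'   `window_bins`, `mask`.
#' @export
hps_track <- function(M12, window_bins = 2L, mask = NULL) {
  n <- nrow(M12)
  mask <- mask %||% rep(TRUE, n)
  tot <- sum(Matrix::triu(M12))
  if (tot == 0) {
    return(structure(list(hps = ifelse(mask, 0, NA_real_),
                          window_bins = window_bins, mask = mask),
                     class = "pairing_track"))
  }
  M <- M12 * (1e6 / tot)  # canonical depth; makes the track scale-invariant
  w <- window_bins
  B <- Matrix::bandSparse(n, k = -w:w,
                          diagonals = lapply(-w:w, function(k) rep(1, n - abs(k))))
  S <- Matrix::diag(B %*% M %*% B)  # window sums on the aligned diagonal
  # chromosome-end bins have truncated, higher-variance windows: masked
  len <- Matrix::rowSums(B)
  mask <- mask & len == (2 * w + 1)
  S[!mask] <- NA_real_
  hps <- log2((S + 1) / (mean(S, na.rm = TRUE) + 1))
  structure(list(hps = hps, window_bins = window_bins, mask = mask),
            class = "pairing_track")
}

#' Call tightly-paired regions
#'
#' Tightly-paired loci are bins whose pairing score exceeds Q3 + 1.5 x IQR
#' of the genome-wide score distribution (quartiles by linear
#' interpolation, type 7). Flagged bins separated by at most one masked bin
#' are merged into regions.
#'
#' @param tracks a `pairing_track` or list of them (one per chromosome).
#' @return a `tight_region_set`: `regions` (data.frame chrom_index, from,
#'   to in bin units), `threshold`, `flagged` (global logical per bin list).
#' @export
call_tight_regions <- function(tracks) {
  if (inherits(tracks, "pairing_track")) tracks <- list(tracks)
  all_vals <- unlist(lapply(tracks, function(t) t$hps[t$mask]))
  if (sum(!is.na(all_vals)) < 4L) stop("need at least 4 non-masked bins")
  thr <- tukey_upper_fence(all_vals)
  regions <- data.table::rbindlist(lapply(seq_along(tracks), function(k) {
    t <- tracks[[k]]
    flag <- which(!is.na(t$hps) & t$hps > thr)
    r <- merge_runs(flag, bridge = which(!t$mask))
    if (nrow(r) == 0L) return(NULL)
    data.table::data.table(chrom_index = k, from = r$from, to = r$to)
  }))
  flagged <- lapply(tracks, function(t) !is.na(t$hps) & t$hps > thr)
  structure(list(regions = if (is.null(regions)) data.frame() else regions,
                 threshold = thr, flagged = flagged),
            class = "tight_region_set")
}

#' Feature enrichment in region bins
#'
#' Binary features: Fisher's exact test on the 2x2 table of bins (inside vs
#' outside regions x overlapping vs not overlapping the feature).
#' Continuous per-bin features (e.g. GC content): Wilcoxon rank-sum test of
#' inside vs outside bin values.
#'
#' @param in_region logical per bin: bin belongs to a called region.
#' @param feature logical per bin (binary mode) or numeric per bin
#'   (continuous mode).
#' @return list: for binary, `table`, `odds_ratio` (sample OR; `Inf` for a
#'   zero cell), `p`; for continuous, `statistic`, `p`.
#' @export
feature_enrichment <- function(in_region, feature) {
  if (!any(in_region)) stop("empty region set")
  if (is.logical(feature)) {
    tab <- table(factor(in_region, c(TRUE, FALSE)),
                 factor(feature, c(TRUE, FALSE)))
    ft <- stats::fisher.test(tab)
    or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
    list(mode = "binary", table = tab, odds_ratio = or, p = ft$p.value)
  } else {
    wt <- stats::wilcox.test(feature[in_region], feature[!in_region])
    list(mode = "continuous", statistic = unname(wt$statistic), p = wt$p.value)
  }
}
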