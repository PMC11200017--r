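#' Two-level distance-decay expected model
#'
#' Fits a power law of mean contact vs genomic distance separately inside
#' each TAD (domain-aware local background) and genome-wide for pairs not
#' sharing a domain. The expected value of a pair is its domain's fit when
#' both anchors lie in the same domain (falling back to the background fit
#' for domains with too few pair observations), else the background fit.
#'
#' @param M symmetric count matrix (one chromosome, count scale).
#' @param tads `tad_partition` or data.frame (from, to) in bin units.
#' @param min_pairs minimum intra-domain pair observations for a private
#'   fit (default 20).
#' @return an `expected_model` closure set: `expected(i, j)` vectorized,
#'   plus the per-domain and background coefficients.
#' @export
fit_expected <- function(M, tads, min_pairs = 20L) {
  n <- nrow(M)
  dom <- if (inherits(tads, "tad_partition")) tads$domains else tads
  domain_of <- rep(0L, n)
  for (k in seq_len(nrow(dom))) domain_of[dom$from[k]:dom$to[k]] <- k
  T <- methods::as(Matrix::triu(M, k = 1), "TsparseMatrix")
  i <- T@i + 1L; j <- T@j + 1L; x <- T@x
  d <- j - i
  same <- domain_of[i] > 0L & domain_of[i] == domain_of[j]
  # distance means must count zero pairs too: sums / eligible pairs.
  # decay model: mu(d) = exp(a) * d^b + c, the additive constant absorbing
  # uniform (random-ligation) background that a pure power law misfits at
  # both ends of the distance range
  fit_from <- function(ii, jj, xx, pair_count) {
    # pair_count: named vector distance -> total eligible pairs
    dd <- jj - ii
    sums <- tapply(xx, dd, sum)
    dist <- as.integer(names(sums))
    npair <- pair_count[as.character(dist)]
    mu <- as.numeric(sums) / npair
    sel <- is.finite(mu) & mu > 0 & dist > 0
    if (sum(sel) < 3L) return(NULL)
    cf <- stats::coef(stats::lm(log(mu[sel]) ~ log(dist[sel])))
    out <- c(intercept = unname(cf[1]), exponent = unname(cf[2]), floor = 0)
    fit <- tryCatch(suppressWarnings(
      stats::nls(m ~ exp(a) * d^b + cc,
                 data = data.frame(m = mu[sel], d = dist[sel]),
                 start = list(a = cf[1], b = cf[2], cc = min(mu[sel]) / 2),
                 weights = as.numeric(npair[sel]),
                 algorithm = "port", lower = c(-Inf, -10, 0),
                 control = stats::nls.control(maxiter = 200, warnOnly = TRUE))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf2 <- stats::coef(fit)
      out <- c(intercept = unname(cf2["a"]), exponent = unname(cf2["b"]),
               floor = unname(cf2["cc"]))
    }
    out
  }
  # background: all cross-domain (or unassigned) pairs;
  # eligible pair counts per distance = total pairs minus same-domain pairs
  tot_pairs <- stats::setNames(n - seq_len(n - 1L), seq_len(n - 1L))
  same_pairs_at <- function(dd_levels) {
    cnt <- stats::setNames(numeric(length(dd_levels)), dd_levels)
    for (k in seq_len(nrow(dom))) {
      L <- dom$to[k] - dom$from[k] + 1L
      dd <- as.integer(dd_levels)
      add <- pmax(0L, L - dd)
      cnt <- cnt + add
    }
    cnt
  }
  lev <- names(tot_pairs)
  sp <- same_pairs_at(lev)
  bg_count <- pmax(tot_pairs - sp, 0)
  bg <- fit_from(i[!same], j[!same], x[!same], bg_count)
  if (is.null(bg)) {
    # degenerate: fall back to the all-pairs fit
    bg <- fit_from(i, j, x, tot_pairs)
    if (is.null(bg)) stop("cannot fit distance decay (too few distances)")
  }
  dom_fits <- vector("list", nrow(dom))
  for (k in seq_len(nrow(dom))) {
    sel <- same & domain_of[i] == k
    L <- dom$to[k] - dom$from[k] + 1L
    pc <- stats::setNames(pmax(L - seq_len(max(L - 1L, 1L)), 0L),
                          seq_len(max(L - 1L, 1L)))
    if (sum(sel) >= min_pairs) dom_fits[[k]] <- fit_from(i[sel], j[sel], x[sel], pc)
  }
  eval_fit <- function(f, dd) {
    exp(f["intercept"]) * pmax(dd, 1)^f["exponent"] + f["floor"]
  }
  expected_fun <- function(ii, jj) {
    dd <- abs(jj - ii)
    out <- eval_fit(bg, dd)
    kk <- ifelse(domain_of[ii] > 0L & domain_of[ii] == domain_of[jj],
                 domain_of[ii], 0L)
    for (k in unique(kk[kk > 0L])) {
      f <- dom_fits[[k]]
      if (is.null(f)) next
      sel <- kk == k
      out[sel] <- eval_fit(f, dd[sel])
    }
    unname(out)
  }
  structure(list(expected = expected_fun, background = bg,
                 domain_fits = dom_fits, domain_of = domain_of),
            class = "expected_model")
}

#' Call promoter-enhancer interactions
#'
#' For every promoter bin and candidate enhancer bin at a bridging distance
#' of 25 kb to 1 Mb, the observed contact is tested against the two-level
#' expected model with a Poisson upper tail; p-values are BH-adjusted
#' across all tested pairs and pairs below the FDR threshold are retained.
#'
#' @param M symmetric count matrix (one chromosome).
#' @param model an `expected_model` from [fit_expected()].
#' @param promoters integer bin indices of gene promoters (TSS +/- 2.5 kb
#'   at 5-kb binning), named by gene id if available.
#' @param candidates integer bin indices of candidate enhancers (default:
#'   all non-promoter bins).
#' @param fdr FDR threshold (default 0.05).
#' @param bin_size bp per bin (default 5000).
#' @param min_dist,max_dist bridging-distance window in bp (25 kb - 1 Mb).
#' @return a `pei_set` data.table: gene, promoter_bin, enhancer_bin,
#'   distance_bp, observed, expected, oe, p, q; retained rows only.
#' @export
call_peis <- function(M, model, promoters, candidates = NULL, fdr = 0.05,
                      bin_size = 5000L, min_dist = 25000L, max_dist = 1e6) {
  n <- nrow(M)
  gene_ids <- names(promoters) %||% paste0("gene", seq_along(promoters))
  keep <- promoters >= 1L & promoters <= n
  if (any(!keep)) warning(sum(!keep), " promoter(s) outside binning; skipped")
  promoters <- promoters[keep]; gene_ids <- gene_ids[keep]
  candidates <- candidates %||% setdiff(seq_len(n), promoters)
  lo <- as.integer(ceiling(min_dist / bin_size))
  hi <- as.integer(floor(max_dist / bin_size))
  tests <- data.table::rbindlist(lapply(seq_along(promoters), function(g) {
    p <- promoters[g]
    cand <- candidates[abs(candidates - p) >= lo & abs(candidates - p) <= hi]
    if (length(cand) == 0L) return(NULL)
    data.table::data.table(gene = gene_ids[g], promoter_bin = p,
                           enhancer_bin = cand)
  }))
  if (is.null(tests) || nrow(tests) == 0L) {
    return(structure(data.table::data.table(), class = c("pei_set", "data.table",
                                                         "data.frame")))
  }
  obs <- M[cbind(tests$promoter_bin, tests$enhancer_bin)]
  expv <- model$expected(tests$promoter_bin, tests$enhancer_bin)
  p <- stats::ppois(obs - 1, expv, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.table::data.table(
    tests,
    distance_bp = abs(tests$enhancer_bin - tests$promoter_bin) * bin_size,
    observed = obs, expected = expv, oe = obs / pmax(expv, .Machine$double.eps),
    p = p, q = q)[q <= fdr]
  data.table::setattr(out, "class", c("pei_set", "data.table", "data.frame"))
  out
}

#' Regulatory potential score of a gene
#'
#' `RPS = log2(1 + sum over the gene's PEIs of max(O/E - 1, 0))`: a
#' monotone aggregate of the excess contact intensity a promoter receives
#' from its called enhancers. Genes with no PEIs score 0.
#'
#' @param peis a `pei_set` (one haplotype/sample).
#' @param genes gene ids to score (default: genes present in `peis`).
#' @param use_raw_intensity sum raw observed intensities instead of O/E
#'   excess (alternative aggregation; default FALSE).
#' @return named numeric vector of scores.
#' @export
compute_rps <- function(peis, genes = NULL, use_raw_intensity = FALSE) {
  genes <- genes %||% (if (nrow(peis)) sort(unique(peis$gene)) else character(0))
  rps <- stats::setNames(numeric(length(genes)), genes)
  if (nrow(peis) == 0L) return(rps)
  val <- if (use_raw_intensity) peis$observed else pmax(peis$oe - 1, 0)
  agg <- tapply(val, peis$gene, sum)
  hit <- intersect(names(agg), genes)
  rps[hit] <- log2(1 + agg[hit])
  rps
}

#' Differential regulatory potential between paired sample groups
#'
#' Genes with |mean paired RPS difference| above the axis threshold (3
#' between neighboring stages; 0.3 between breeds or parents of origin)
#' and paired t-test p < 0.05 are flagged.
#'
#' @param rps_a,rps_b numeric matrices (rows = genes, columns = paired
#'   replicates) of RPS values.
#' @param axis_threshold 3 for the stage axis, 0.3 for breed/parent axes.
#' @param p_threshold paired t-test threshold (default 0.05).
#' @return data.frame: gene, delta, p, flagged.
#' @export
differential_rps <- function(rps_a, rps_b, axis_threshold,
                             p_threshold = 0.05) {
  rps_a <- as.matrix(rps_a); rps_b <- as.matrix(rps_b)
  if (!all(dim(rps_a) == dim(rps_b))) stop("groups must be paired")
  if (ncol(rps_a) < 2L) stop("need at least 2 paired replicates")
  delta <- rowMeans(rps_a - rps_b)
  p <- row_paired_t_p(rps_a - rps_b)
  data.frame(gene = rownames(rps_a) %||% seq_len(nrow(rps_a)),
             delta = delta, p = p,
             flagged = !is.na(delta) & abs(delta) > axis_threshold &
               !is.na(p) & p < p_threshold,
             row.names = NULL)
}

#' Merge same-stage PEI sets
#'
#' Union by (promoter bin, enhancer bin); the intensity of a merged pair is
#' the mean O/E of the contributing samples, and the number of contributing
#' samples is retained as provenance.
#'
#' @param pei_sets list of `pei_set` objects on the same binning.
#' @return data.table: gene, promoter_bin, enhancer_bin, oe (mean),
#'   n_samples.
#' @export
merge_stage_peis <- function(pei_sets) {
  all <- data.table::rbindlist(pei_sets)
  if (nrow(all) == 0L) return(all)
  out <- all[, list(gene = gene[1], oe = mean(oe), n_samples = .N),
             by = c("promoter_bin", "enhancer_bin")]
  data.table::setcolorder(out, c("gene", "promoter_bin", "enhancer_bin",
                                 "oe", "n_samples"))
  out[]
}
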