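# ---------------------------------------------------------------------------
# Distal (trans) QTL mapping: a genome-wide nominal scan excluding the cis
# neighbourhood, followed by one of two multiple-testing corrections:
# the full permutation scheme (all phenotypes co-permuted, FDR by direct
# counting) or the approximate scheme (beta-fitted null of genome-wide
# minima from single-phenotype permutations, then Storey q-values).
# ---------------------------------------------------------------------------

# TRUE where the (variant, phenotype) pair is tested: different chromosome,
# or distance from the anchor strictly greater than the exclusion radius.
trans_test_mask <- function(g, p, cis_exclusion = 5e6) {
  anchors <- phenotype_anchor(p$phenotypes)
  V <- nrow(g$variants); P <- nrow(p$phenotypes)
  mask <- matrix(TRUE, V, P)
  for (j in seq_len(P)) {
    same <- g$variants$chrom == p$phenotypes$chrom[j]
    mask[same, j] <- abs(g$variants$pos[same] - anchors[j]) > cis_exclusion
  }
  mask
}

hist_breaks <- function(bin = 0.1, range_max = 20) {
  seq(0, range_max, by = bin)
}

# Fixed-width histogram of -log10(p) (bin 0.1 over 0..20; overflow goes to
# the last bin) so the full p-value distribution survives thresholded output.
bin_pvalues <- function(pv, bin = 0.1, range_max = 20) {
  lg <- pmin(-log10(pmax(pv, 10^(-range_max))), range_max - 1e-9)
  tabulate(floor(lg / bin) + 1L, nbins = as.integer(range_max / bin))
}

#' Genome-wide nominal trans scan
#'
#' Tests every phenotype x variant pair whose distance exceeds the cis
#' exclusion radius (same-chromosome pairs only; inter-chromosomal pairs
#' are always tested). Detailed rows are emitted only for p-values at or
#' below `report_threshold`; every tested p-value is also accumulated into
#' a fixed-width histogram of -log10(p) (bin 0.1, range 0-20) for QQ
#' plotting, so rows + bins conserve the total test count.
#'
#' @param g a `genotype_matrix` (samples harmonized with `p`).
#' @param p a `phenotype_set`.
#' @param covariates optional `covariate_set`.
#' @param cis_exclusion exclusion radius in bp (default 5 Mb).
#' @param report_threshold report rows with `p_nominal <= report_threshold`
#'   (default 1e-5).
#' @param normalize rank-normalize phenotypes first.
#' @param keep_pvalues keep the full p-value matrix (variants x
#'   phenotypes, `NA` where untested) as element `pvalues` — needed by the
#'   permutation FDR schemes.
#' @return List with `hits` (data.frame phenotype_id, variant_id, r,
#'   p_nominal), `histogram` (data.frame bin_start, count of -log10 p),
#'   `n_tests`, `df`, and optionally `pvalues`.
#' @export
trans_nominal <- function(g, p, covariates = NULL, cis_exclusion = 5e6,
                          report_threshold = 1e-5, normalize = TRUE,
                          keep_pvalues = FALSE) {
  prep <- prepare_mapping(g, p, covariates, normalize)
  mask <- trans_test_mask(g, p, cis_exclusion)
  ysd <- standardize_columns(prep$ys)
  r <- corr_matrix(prep$gs, ysd)
  pv <- corr_pvalue(r, prep$df)
  pv[!mask] <- NA_real_
  tested <- which(mask)
  hits_idx <- tested[pv[tested] <= report_threshold]
  hits <- data.frame(
    phenotype_id = p$phenotypes$phenotype_id[(hits_idx - 1L) %/% nrow(pv) + 1L],
    variant_id = g$variants$variant_id[(hits_idx - 1L) %% nrow(pv) + 1L],
    r = r[hits_idx], p_nominal = pv[hits_idx], stringsAsFactors = FALSE)
  hits <- hits[order(hits$p_nominal), ]
  rownames(hits) <- NULL
  out <- list(hits = hits,
              histogram = data.frame(bin_start = hist_breaks()[-201],
                                     count = bin_pvalues(pv[tested])),
              n_tests = length(tested), df = prep$df)
  if (keep_pvalues) { out$pvalues <- pv; out$mask <- mask; out$r <- r }
  out
}

#' FDR table from the permutation counting rule
#'
#' Given the ranked nominal p-values and the pooled p-values from B
#' permuted genome-wide scans, the FDR of the i strongest associations is
#' `(# permuted p <= p_(i)) / (i * B)`. Ties count as smaller.
#'
#' @param nominal_p nominal p-values (will be sorted increasingly).
#' @param permuted_p pooled p-values from all permutation scans.
#' @param B number of permutation scans.
#' @param max_rank report at most this many ranks (default all).
#' @return data.frame `rank`, `p_nominal`, `m_permuted` (cumulative count),
#'   `fdr`, and `fdr_monotone` (step-up smoothed), restricted to rows with
#'   `fdr <= 1`.
#' @export
trans_fdr_table <- function(nominal_p, permuted_p, B,
                            max_rank = length(nominal_p)) {
  ps <- sort(nominal_p)
  ps <- ps[seq_len(min(max_rank, length(ps)))]
  m <- findInterval(ps, sort(permuted_p))
  fdr <- m / (seq_along(ps) * B)
  keep <- fdr <= 1
  fdr_mono <- rev(cummin(rev(fdr)))
  data.frame(rank = seq_along(ps), p_nominal = ps, m_permuted = m,
             fdr = fdr, fdr_monotone = fdr_mono)[keep, ]
}

#' Trans mapping with the full permutation scheme
#'
#' Repeats the genome-wide nominal scan on B datasets in which all
#' phenotypes are co-permuted with the same index sequence (their
#' correlation structure is preserved; only the genotype-phenotype link is
#' broken), then estimates the FDR of the top nominal associations by
#' direct counting.
#'
#' @inheritParams trans_nominal
#' @param B number of genome-wide permutations (default 100).
#' @param seed global seed.
#' @param fdr target FDR for the reported discovery set.
#' @param max_rank cap on the number of ranked associations tabled.
#' @return List with `table` (see [trans_fdr_table()]), `hits` (the ranked
#'   nominal pairs with their FDR), `discoveries` (subset at the target
#'   FDR via the step-up rule), `n_tests`, `B`.
#' @export
trans_full_fdr <- function(g, p, covariates = NULL, cis_exclusion = 5e6,
                           B = 100, seed = 1, fdr = 0.05,
                           normalize = TRUE, max_rank = 10000) {
  nom <- trans_nominal(g, p, covariates, cis_exclusion,
                       report_threshold = 0, normalize = normalize,
                       keep_pvalues = TRUE)
  pv <- nom$pvalues
  tested <- which(nom$mask)
  ord <- tested[order(pv[tested])]
  ord <- ord[seq_len(min(max_rank, length(ord)))]
  ps <- pv[ord]
  rs <- abs(nom$r[ord])
  prep <- prepare_mapping(g, p, covariates, normalize)
  ysd <- standardize_columns(prep$ys)
  n <- nrow(ysd)
  m <- integer(length(ps))
  for (b in seq_len(B)) {
    idx <- with_seed(unit_seed(seed, paste0("trans_full_", b)), sample.int(n))
    rp <- corr_matrix(prep$gs, ysd[idx, , drop = FALSE])
    # p <= p_(i) iff |r| >= |r_(i)| at fixed df: count on the r scale to
    # avoid evaluating the t tail for every permuted pair
    m <- m + findInterval(-rs, sort(-abs(rp[nom$mask])))
  }
  fdr_vec <- m / (seq_along(ps) * B)
  fdr_mono <- rev(cummin(rev(fdr_vec)))
  hits <- data.frame(
    rank = seq_along(ord),
    phenotype_id = p$phenotypes$phenotype_id[(ord - 1L) %/% nrow(pv) + 1L],
    variant_id = g$variants$variant_id[(ord - 1L) %% nrow(pv) + 1L],
    p_nominal = ps, m_permuted = m, fdr = fdr_vec,
    fdr_monotone = fdr_mono, stringsAsFactors = FALSE)
  i_star <- which(fdr_mono <= fdr)
  discoveries <- if (length(i_star)) hits[seq_len(max(i_star)), ] else hits[0, ]
  list(table = hits[hits$fdr <= 1,
                    c("rank", "p_nominal", "m_permuted", "fdr", "fdr_monotone")],
       hits = hits, discoveries = discoveries,
       n_tests = nom$n_tests, B = B)
}

#' Trans mapping with the approximate permutation scheme
#'
#' Assumes phenotypes are independent and (rank-)normalized, so the null
#' distribution of the genome-wide minimum p-value is shared across
#' phenotypes. Each of `n_perm` draws permutes one randomly chosen
#' phenotype, scans it against all trans variants and stores the smallest
#' p-value. A beta distribution fitted to the minima adjusts every nominal
#' p-value for the number of variants tested; Storey q-values on the best
#' adjusted p per phenotype then correct for the number of phenotypes, and
#' the adjusted-p threshold at the target FDR is back-propagated to flag
#' every genome-wide-significant pair.
#'
#' @inheritParams trans_nominal
#' @param n_perm number of single-phenotype permutation draws (default
#'   1000).
#' @param seed global seed.
#' @param fdr target FDR.
#' @return List with `per_phenotype` (best variant, p_nominal, p_adjusted,
#'   q_value per phenotype), `significant` (all pairs whose adjusted p
#'   passes the back-propagated threshold), `beta` (fit), `pi0`,
#'   `adjusted_threshold`, `n_tests`.
#' @export
trans_approx <- function(g, p, covariates = NULL, cis_exclusion = 5e6,
                         n_perm = 1000, seed = 1, fdr = 0.05,
                         normalize = TRUE) {
  nom <- trans_nominal(g, p, covariates, cis_exclusion,
                       report_threshold = 0, normalize = normalize,
                       keep_pvalues = TRUE)
  pv <- nom$pvalues
  prep <- prepare_mapping(g, p, covariates, normalize)
  ysd <- standardize_columns(prep$ys)
  n <- nrow(ysd); P <- ncol(ysd)
  pick <- with_seed(unit_seed(seed, "trans_approx_pick"),
                    sample.int(P, n_perm, replace = TRUE))
  minima <- numeric(n_perm)
  chunk <- max(1L, floor(2e7 / nrow(prep$gs) / 8))
  for (s in seq(1L, n_perm, by = chunk)) {
    e <- min(s + chunk - 1L, n_perm)
    yperm <- vapply(s:e, function(b) {
      idx <- with_seed(unit_seed(seed, paste0("trans_approx_", b)),
                       sample.int(n))
      ysd[idx, pick[b]]
    }, numeric(n))
    rr <- abs(corr_matrix(prep$gs, yperm))
    for (j in seq_len(e - s + 1L)) {
      ok <- nom$mask[, pick[s + j - 1L]]
      minima[s + j - 1L] <- corr_pvalue(max(rr[ok, j]), prep$df)
    }
  }
  bf <- fit_beta(minima)
  padj <- pbeta(pv, bf$shape1, bf$shape2)
  padj <- pmin(pmax(padj, P_FLOOR), 1)
  padj[!nom$mask] <- NA_real_
  best_idx <- apply(padj, 2, which.min)
  best_adj <- padj[cbind(best_idx, seq_len(P))]
  qv <- suppressWarnings(qvalues(best_adj))
  per_phen <- data.frame(
    phenotype_id = p$phenotypes$phenotype_id,
    best_variant = g$variants$variant_id[best_idx],
    p_nominal = pv[cbind(best_idx, seq_len(P))],
    p_adjusted = best_adj, q_value = qv$qvalue, stringsAsFactors = FALSE)
  thr_adj <- adjusted_pvalue_threshold(best_adj, qv$qvalue, fdr)
  sig_idx <- which(nom$mask & padj <= thr_adj)
  significant <- data.frame(
    phenotype_id = p$phenotypes$phenotype_id[(sig_idx - 1L) %/% nrow(pv) + 1L],
    variant_id = g$variants$variant_id[(sig_idx - 1L) %% nrow(pv) + 1L],
    p_nominal = pv[sig_idx], p_adjusted = padj[sig_idx],
    stringsAsFactors = FALSE)
  significant <- significant[order(significant$p_adjusted), ]
  rownames(significant) <- NULL
  list(per_phenotype = per_phen, significant = significant, beta = bf,
       pi0 = qv$pi0, adjusted_threshold = thr_adj, n_tests = nom$n_tests,
       null_minima = minima)
}
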