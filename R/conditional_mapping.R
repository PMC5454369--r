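# ---------------------------------------------------------------------------
# Conditional analysis: discover multiple independent cis signals per
# phenotype. Initialization converts the genome-wide adjusted-p
# significance bar into a per-phenotype nominal threshold through the
# fitted beta quantile function; a forward stepwise pass learns the number
# of independent signals; a backward pass assigns every significant
# variant to the signal it best explains.
# ---------------------------------------------------------------------------

#' Adjusted p-value significance threshold at a target FDR
#'
#' The cutoff is the midpoint between the largest significant and the
#' smallest non-significant adjusted p-value under the q-values attached
#' to a cis scan.
#'
#' @param p_adjusted adjusted p-values across phenotypes.
#' @param q_value matching q-values.
#' @param fdr target FDR level (default 0.05).
#' @return The adjusted-p threshold; 0 when nothing is significant.
#' @export
adjusted_pvalue_threshold <- function(p_adjusted, q_value, fdr = 0.05) {
  sig <- q_value <= fdr
  if (!any(sig)) return(0)
  hi <- max(p_adjusted[sig])
  lo <- if (any(!sig)) min(p_adjusted[!sig]) else 1
  (hi + lo) / 2
}

#' Per-phenotype nominal p-value threshold
#'
#' Feeds the genome-wide adjusted-p threshold through the beta quantile
#' function of one phenotype's fitted permutation null, yielding the
#' nominal significance bar for that phenotype's cis window. When the beta
#' fit is flagged degenerate the threshold falls back to the empirical
#' quantile of the stored permutation minima.
#'
#' @param unit one element of the `"units"` attribute of
#'   [cis_permutation_scan()] (carries beta parameters and minima).
#' @param adjusted_threshold genome-wide adjusted-p cutoff in (0, 1).
#' @return Nominal p-value threshold.
#' @export
nominal_threshold <- function(unit, adjusted_threshold) {
  stopifnot(adjusted_threshold > 0, adjusted_threshold < 1)
  if (isTRUE(unit$beta_converged))
    qbeta(adjusted_threshold, unit$beta_shape1, unit$beta_shape2)
  else as.numeric(stats::quantile(unit$perm_minima, adjusted_threshold,
                                  type = 1))
}

#' Forward stepwise signal discovery
#'
#' Starting from the phenotype quantifications, repeatedly finds the most
#' associated cis variant; while its nominal p-value passes the
#' per-phenotype threshold, the variant is recorded as an independent
#' signal and its genotypes are residualized out of the phenotype, until
#' no further variant passes (or `max_signals` is hit).
#'
#' @param G dosage matrix of the cis variants (samples x L), missing
#'   entries allowed.
#' @param y phenotype vector (already normalized/residualized as in the
#'   permutation pass).
#' @param threshold nominal p-value threshold from [nominal_threshold()].
#' @param variant_ids ids for the columns of `G`.
#' @param dist_abs |variant position - anchor| used for tie-breaking.
#' @param n_covariates covariates already residualized out of `y`.
#' @param max_signals cap on the number of signals (default 10).
#' @return data.frame of signals in discovery order: `rank`, `variant_id`,
#'   `p_at_discovery`; zero rows when nothing passes.
#' @export
forward_pass <- function(G, y, threshold, variant_ids,
                         dist_abs = rep(0, ncol(G)), n_covariates = 0,
                         max_signals = 10) {
  G <- apply(as.matrix(G), 2, impute_mean)
  n <- nrow(G)
  yr <- as.numeric(y)
  chosen <- integer(0)
  pvals <- numeric(0)
  repeat {
    k <- length(chosen)
    df <- n - 2L - as.integer(n_covariates) - k
    if (df < 1) break
    gs <- standardize_dosages(G)
    if (k) {
      # residualize candidate genotypes out of the remaining variants too,
      # so perfect proxies of discovered signals cannot re-enter
      gs <- standardize_dosages(residualize(G, G[, chosen, drop = FALSE]))
    }
    r <- abs(as.vector(corr_matrix(gs, standardize_columns(matrix(yr)))))
    r[!is.finite(r)] <- 0
    r[chosen] <- 0
    pv <- corr_pvalue(r, df)
    best <- order(pv, dist_abs, variant_ids)[1]
    if (pv[best] > threshold || r[best] == 0) break
    chosen <- c(chosen, best)
    pvals <- c(pvals, pv[best])
    yr <- as.numeric(residualize(matrix(yr), G[, chosen, drop = FALSE]))
    if (length(chosen) >= max_signals) break
  }
  data.frame(rank = seq_along(chosen), variant_id = variant_ids[chosen],
             variant_idx = chosen, p_at_discovery = pvals,
             stringsAsFactors = FALSE)
}

#' Backward assignment of variants to independent signals
#'
#' With R candidate signals Q_1..Q_R from the forward pass, every other
#' cis variant v is tested R times in the joint model that contains all
#' candidates but with Q_i replaced by v. The R resulting p-values are
#' collected; v is assigned to the signal with the smallest p-value when
#' that p-value passes the per-phenotype threshold. Candidates are
#' assigned to their own signal with their joint-model p-value.
#'
#' @inheritParams forward_pass
#' @param signals output of [forward_pass()] with R >= 1 rows.
#' @return data.frame `variant_id`, `signal`, `p`, `is_best_candidate` for
#'   all variants passing the threshold.
#' @export
backward_pass <- function(G, y, signals, threshold, variant_ids,
                          n_covariates = 0) {
  stopifnot(nrow(signals) >= 1)
  G <- apply(as.matrix(G), 2, impute_mean)
  n <- nrow(G)
  y <- as.numeric(y)
  cand <- signals$variant_idx
  R <- length(cand)
  L <- ncol(G)
  pmat <- matrix(NA_real_, L, R)  # p of variant v when substituted in signal i
  df <- n - 1L - R - as.integer(n_covariates)
  for (i in seq_len(R)) {
    fixed <- G[, cand[-i], drop = FALSE]
    for (v in seq_len(L)) {
      if (v %in% cand[-i]) next
      X <- cbind(1, fixed, G[, v])
      fit <- tryCatch(qr(X), error = function(e) NULL)
      if (is.null(fit) || fit$rank < ncol(X)) next  # collinear: skip
      beta <- qr.coef(fit, y)
      res <- qr.resid(fit, y)
      s2 <- sum(res^2) / df
      XtXinv_vv <- chol2inv(qr.R(fit))[ncol(X), ncol(X)]
      tt <- beta[ncol(X)] / sqrt(s2 * XtXinv_vv)
      pmat[v, i] <- max(2 * pt(abs(tt), df, lower.tail = FALSE), P_FLOOR)
    }
  }
  out <- lapply(seq_len(L), function(v) {
    if (v %in% cand) {
      i <- which(cand == v)
      data.frame(variant_id = variant_ids[v], signal = i, p = pmat[v, i],
                 is_best_candidate = 1L, stringsAsFactors = FALSE)
    } else {
      pv <- pmat[v, ]
      if (all(is.na(pv))) return(NULL)
      i <- which.min(pv)
      if (pv[i] > threshold) return(NULL)
      data.frame(variant_id = variant_ids[v], signal = i, p = pv[i],
                 is_best_candidate = 0L, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out[!vapply(out, is.null, TRUE)])
}

#' Conditional cis mapping over a whole dataset
#'
#' Runs [cis_permutation_scan()] (or reuses a supplied one), derives the
#' adjusted-p threshold at the target FDR, and applies the
#' forward/backward procedure to each significant phenotype.
#'
#' @inheritParams cis_permutation_scan
#' @param fdr target FDR level.
#' @param scan optional precomputed result of [cis_permutation_scan()].
#' @param max_signals per-phenotype cap on independent signals.
#' @return data.frame with one row per (phenotype, assigned variant):
#'   `phenotype_id`, `signal_rank`, `variant_id`, `p`, `is_best_candidate`.
#'   Attribute `"n_signals"` maps phenotype id to its discovered R.
#' @export
conditional_scan <- function(g, p, covariates = NULL, window = 1e6,
                             n_perm = 1000, seed = 1, fdr = 0.05,
                             normalize = TRUE, scan = NULL,
                             max_signals = 10) {
  # conditional mapping operates per phenotype: ignore grouping throughout
  p$phenotypes$group_id <- p$phenotypes$phenotype_id
  if (is.null(scan))
    scan <- cis_permutation_scan(g, p, covariates, window, n_perm, seed,
                                 grouped = "none", normalize = normalize)
  thr_adj <- adjusted_pvalue_threshold(scan$p_adjusted, scan$q_value, fdr)
  if (thr_adj <= 0) {
    res <- data.frame(phenotype_id = character(0), signal_rank = integer(0),
                      variant_id = character(0), p = numeric(0),
                      is_best_candidate = integer(0))
    attr(res, "n_signals") <- integer(0)
    return(res)
  }
  prep <- prepare_mapping(g, p, covariates, normalize)
  scans <- cis_pairs(g, p, window)
  names(scans) <- vapply(scans, `[[`, "", "group_id")
  units <- attr(scan, "units")
  rows <- list()
  n_signals <- integer(0)
  for (u in units) {
    if (u$p_adjusted > thr_adj) next
    sc <- scans[[u$unit_id]]
    thr_nom <- nominal_threshold(u, thr_adj)
    G <- prep$gs[, sc$variant_idx, drop = FALSE]  # covariate-residualized
    yv <- prep$ys[, sc$member_idx[1]]
    dist_abs <- abs(g$variants$pos[sc$variant_idx] - sc$anchors[1])
    vids <- g$variants$variant_id[sc$variant_idx]
    fw <- forward_pass(G, yv, thr_nom, vids, dist_abs,
                       n_covariates = prep$n_cov, max_signals = max_signals)
    n_signals[u$unit_id] <- nrow(fw)
    if (!nrow(fw)) next
    bw <- backward_pass(G, yv, fw, thr_nom, vids,
                        n_covariates = prep$n_cov)
    if (is.null(bw) || !nrow(bw)) next
    bw$phenotype_id <- u$unit_id
    rows[[u$unit_id]] <- bw[, c("phenotype_id", "signal", "variant_id", "p",
                                "is_best_candidate")]
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(phenotype_id = character(0), signal = integer(0),
               variant_id = character(0), p = numeric(0),
               is_best_candidate = integer(0))
  names(res)[names(res) == "signal"] <- "signal_rank"
  rownames(res) <- NULL
  attr(res, "n_signals") <- n_signals
  attr(res, "adjusted_threshold") <- thr_adj
  res
}
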