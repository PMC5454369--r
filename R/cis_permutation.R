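# ---------------------------------------------------------------------------
# Cis permutation scheme with beta approximation.
#
# For each phenotype (or phenotype group) the best nominal association in
# cis is re-evaluated against an empirical null built by permuting the
# phenotype R times and retaining the best association of each permuted
# scan. A beta distribution fitted to the R minima makes the null
# continuous; the adjusted p-value is the beta CDF at the observed best
# nominal p. Groups permute all members with the same index sequence so
# their inner correlation structure is untouched.
# ---------------------------------------------------------------------------

# Counter-based seeding: each analysis unit draws its permutations from a
# stream keyed by (global seed, unit id), so results do not depend on how
# phenotypes are chunked across runs.
unit_seed <- function(seed, id) {
  h <- 0
  for (k in utf8ToInt(as.character(id))) h <- (h * 131 + k) %% 2147483647
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate permutation index matrix for one analysis unit
#'
#' Deterministic given `(seed, id)`: column b is the b-th uniform random
#' permutation of `1:n`. All members of a phenotype group are permuted with
#' the same columns, which preserves their correlation matrix exactly.
#'
#' @param n number of samples.
#' @param n_perm number of permutations.
#' @param seed global seed.
#' @param id analysis-unit identifier (phenotype or group id).
#' @return n x n_perm integer matrix of permutation indices.
#' @export
permutation_indices <- function(n, n_perm, seed, id) {
  with_seed(unit_seed(seed, id),
            matrix(replicate(n_perm, sample.int(n)), nrow = n))
}

#' Apply a permutation to a phenotype vector or group matrix
#'
#' @param y vector or samples x members matrix.
#' @param idx permutation of `1:nrow(y)`.
#' @return Permuted copy; rows reordered identically across members.
#' @export
permute_phenotype <- function(y, idx) {
  if (is.matrix(y)) y[idx, , drop = FALSE] else y[idx]
}

# Best pair over an L x M correlation matrix under the membership mask.
# Ties on p are broken by smaller |distance to the member's anchor|, then
# lexicographically smaller variant id.
best_pair <- function(abs_r, mask, dist_abs, variant_ids, member_ids) {
  a <- abs_r
  a[!mask] <- -1
  m <- max(a)
  if (m < 0) return(NULL)
  cand <- which(a >= m - 1e-15, arr.ind = TRUE)
  if (nrow(cand) > 1L) {
    d <- dist_abs[cand]
    cand <- cand[order(d, variant_ids[cand[, 1]]), , drop = FALSE]
  }
  list(variant = variant_ids[cand[1, 1]], member = member_ids[cand[1, 2]],
       vrow = cand[1, 1], mcol = cand[1, 2], abs_r = m)
}

#' Best nominal association of a cis scan
#'
#' Scans all member x variant pairs of one phenotype group and returns the
#' pair with the smallest nominal p-value (largest |r|), with ties broken
#' by distance to the anchor then variant id.
#'
#' @param gs standardized dosage matrix (samples x L).
#' @param ys residualized member matrix (samples x M), will be standardized.
#' @param mask L x M logical membership matrix (variant in member's window).
#' @param dist_abs L x M |variant position - member anchor|.
#' @param variant_ids,member_ids identifier vectors.
#' @param df residual degrees of freedom.
#' @return List with `variant`, `member`, `r`, `p`, or `NULL` if nothing is
#'   testable.
#' @export
scan_best <- function(gs, ys, mask, dist_abs, variant_ids, member_ids, df) {
  r <- corr_matrix(gs, standardize_columns(as.matrix(ys)))
  bp <- best_pair(abs(r), mask, dist_abs, variant_ids, member_ids)
  if (is.null(bp)) return(NULL)
  bp$r <- r[bp$vrow, bp$mcol]
  bp$p <- corr_pvalue(bp$abs_r, df)
  bp
}

#' Fit a beta distribution to permutation minima
#'
#' Maximum likelihood on the two-parameter beta, initialized by the method
#' of moments and refined by Newton-Raphson on the log-likelihood
#' (convergence when the log-likelihood moves by < 1e-8, at most 100
#' iterations). Falls back to the moment estimate when Newton fails.
#'
#' @param p vector of p-values in (0, 1), length >= 50.
#' @return List with `shape1`, `shape2`, `converged`.
#' @export
fit_beta <- function(p) {
  if (length(p) < 50) stop("fit_beta needs >= 50 values")
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  m <- mean(p); v <- var(p)
  k <- m * (1 - m) / v - 1
  a <- max(m * k, 1e-3); b <- max((1 - m) * k, 1e-3)
  slp <- sum(log(p)); slq <- sum(log1p(-p)); n <- length(p)
  loglik <- function(a, b)
    (a - 1) * slp + (b - 1) * slq - n * lbeta(a, b)
  ll <- loglik(a, b)
  converged <- FALSE
  for (it in seq_len(100)) {
    dab <- digamma(a + b)
    gr <- c(slp - n * (digamma(a) - dab), slq - n * (digamma(b) - dab))
    tab <- trigamma(a + b)
    H <- -n * matrix(c(trigamma(a) - tab, -tab, -tab, trigamma(b) - tab), 2)
    step <- tryCatch(solve(H, gr), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      a2 <- a - lam * step[1]; b2 <- b - lam * step[2]
      if (a2 > 0 && b2 > 0) {
        ll2 <- loglik(a2, b2)
        if (is.finite(ll2) && ll2 >= ll - 1e-12) break
      }
      lam <- lam / 2
      if (lam < 1e-8) { a2 <- a; b2 <- b; ll2 <- ll; break }
    }
    moved <- abs(ll2 - ll)
    a <- a2; b <- b2; ll <- ll2
    if (moved < 1e-8) { converged <- TRUE; break }
  }
  if (!converged && it >= 100) converged <- FALSE
  if (!converged) {
    k <- m * (1 - m) / v - 1
    list(shape1 = max(m * k, 1e-3), shape2 = max((1 - m) * k, 1e-3),
         converged = FALSE)
  } else list(shape1 = a, shape2 = b, converged = TRUE)
}

# Permutation minima of |r| for one unit, vectorized over permutations.
# ys: samples x M residualized members (standardized inside);
# mask: L x M membership. Returns vector of length n_perm with the maximal
# masked |r| of each permuted scan.
perm_max_abs_r <- function(gs, ys, mask, idx) {
  n <- nrow(gs); L <- ncol(gs); M <- ncol(ys); R <- ncol(idx)
  ysd <- standardize_columns(ys)
  maskv <- as.vector(mask)  # length L*M, recycled down columns
  chunk <- max(1L, floor(2e6 / (as.numeric(n) * M)))
  out <- numeric(R)
  for (s in seq(1L, R, by = chunk)) {
    e <- min(s + chunk - 1L, R)
    bs <- e - s + 1L
    B <- idx[, rep(s:e, each = M), drop = FALSE] +
      matrix(rep((seq_len(M) - 1L) * n, times = bs), n, M * bs, byrow = TRUE)
    yperm <- matrix(ysd[B], n, M * bs)
    r <- abs(crossprod(gs, yperm)) / (n - 1)  # L x (M*bs)
    r <- matrix(as.vector(r) * maskv, nrow = L * M)
    out[s:e] <- apply(r, 2, max)
  }
  out
}

#' Permutation pass for one phenotype or phenotype group
#'
#' Runs the full scheme on one analysis unit: nominal best pair, R permuted
#' re-scans retaining the best association each, beta fit on the R minima,
#' and the beta-adjusted p-value of the nominal best. The empirical
#' p-value uses the add-one estimator `(1 + k) / (1 + R)`.
#'
#' @inheritParams scan_best
#' @param n_perm number of permutations (>= 50; default 1000).
#' @param seed global seed.
#' @param unit_id identifier keying this unit's permutation stream.
#' @return List with ids, best pair, `p_nominal`, `p_empirical`,
#'   `beta_shape1`, `beta_shape2`, `p_adjusted`, `effective_tests`,
#'   `n_perm`, `perm_minima`, `beta_converged`; `NULL` if untestable.
#' @export
permutation_pass <- function(gs, ys, mask, dist_abs, variant_ids, member_ids,
                             df, n_perm = 1000, seed = 1,
                             unit_id = member_ids[1]) {
  stopifnot(n_perm >= 50)
  ys <- as.matrix(ys)
  best <- scan_best(gs, ys, mask, dist_abs, variant_ids, member_ids, df)
  if (is.null(best)) return(NULL)
  idx <- permutation_indices(nrow(gs), n_perm, seed, unit_id)
  null_max_r <- perm_max_abs_r(gs, ys, mask, idx)
  perm_min_p <- corr_pvalue(null_max_r, df)
  p_emp <- (1 + sum(perm_min_p <= best$p)) / (1 + n_perm)
  bf <- fit_beta(perm_min_p)
  p_adj <- pbeta(best$p, bf$shape1, bf$shape2)
  p_adj <- min(max(p_adj, P_FLOOR), 1)
  list(unit_id = unit_id, n_members = ncol(ys),
       n_variants = length(variant_ids),
       best_variant_id = best$variant, best_member_id = best$member,
       r = best$r, p_nominal = best$p, p_empirical = p_emp,
       beta_shape1 = bf$shape1, beta_shape2 = bf$shape2,
       beta_converged = bf$converged,
       p_adjusted = p_adj, effective_tests = bf$shape2,
       n_perm = n_perm, perm_minima = perm_min_p)
}

#' Collapse a phenotype group to its first principal component
#'
#' Members are centred and scaled, a PCA is run across members, and the
#' per-sample scores on PC1 are returned as the group's quantification.
#' The sign is fixed so that the score correlates positively with the
#' member mean (falling back to a positive leading loading when the member
#' mean is degenerate).
#'
#' @param Y samples x M matrix, M >= 2.
#' @return Numeric vector of PC1 scores (one per sample).
#' @export
group_pca_collapse <- function(Y) {
  Y <- as.matrix(Y)
  if (ncol(Y) < 2) stop("group PCA collapse needs M >= 2 members")
  if (nrow(Y) < 3) stop("group PCA collapse needs >= 3 samples")
  pc <- prcomp(Y, center = TRUE, scale. = TRUE)
  s <- pc$x[, 1]
  mm <- rowMeans(scale(Y))
  cc <- suppressWarnings(cor(s, mm))
  if (is.na(cc) || abs(cc) < 1e-12) {
    ld <- pc$rotation[, 1]
    if (ld[which.max(abs(ld))] < 0) s <- -s
  } else if (cc < 0) s <- -s
  s
}

#' Storey-Tibshirani q-values
#'
#' Estimates the null proportion pi0 on the lambda grid 0.05, 0.10, ...,
#' 0.95 via a cubic smoothing spline evaluated at the largest lambda, then
#' computes q-values monotone in p. With fewer than 100 p-values the grid
#' is unstable and pi0 is forced to 1 (with a warning). `method = "bh"`
#' gives Benjamini-Hochberg (pi0 = 1).
#'
#' @param p vector of p-values in (0, 1].
#' @param method `"storey"` (default) or `"bh"`.
#' @return List with `qvalue` (same order as `p`) and `pi0`.
#' @export
qvalues <- function(p, method = c("storey", "bh")) {
  method <- match.arg(method)
  stopifnot(all(p > 0 & p <= 1))
  n <- length(p)
  if (method == "bh") {
    return(list(qvalue = p.adjust(p, "BH"), pi0 = 1))
  }
  if (n < 100) {
    warning("fewer than 100 p-values: pi0 forced to 1")
    pi0 <- 1
  } else {
    lam <- seq(0.05, 0.95, by = 0.05)
    pi0_lam <- vapply(lam, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- smooth.spline(lam, pi0_lam, df = 3)
    pi0 <- predict(fit, x = max(lam))$y
    pi0 <- min(max(pi0, 1e-8), 1)
  }
  o <- order(p, decreasing = TRUE)
  q <- numeric(n)
  q[o] <- cummin(pi0 * n * p[o] / rank(p, ties.method = "max")[o])
  q <- pmin(q, 1)
  list(qvalue = q, pi0 = pi0)
}

#' Cis permutation scan over a whole dataset
#'
#' Runs the permutation pass for every phenotype group and attaches Storey
#' q-values across units. Grouping modes: `"best"` scans all members of a
#' group jointly under the extended permutation scheme; `"pca1"` collapses
#' each group to its first principal component; `"mean"` collapses to the
#' member mean (the aggregate-quantification route); `"none"` ignores
#' groups and maps each phenotype separately.
#'
#' @param g a `genotype_matrix` (samples harmonized with `p`).
#' @param p a `phenotype_set`.
#' @param covariates optional `covariate_set`.
#' @param window cis window half-width in bp.
#' @param n_perm permutations per unit.
#' @param seed global seed.
#' @param grouped grouping mode, see above.
#' @param normalize rank-normalize phenotypes first.
#' @param fdr_method q-value method passed to [qvalues()].
#' @return data.frame with one row per testable unit (id, n_members,
#'   n_variants, best variant, distance, p_nominal, beta parameters,
#'   p_empirical, p_adjusted, q_value). The full per-unit results (with
#'   permutation minima) are attached as attribute `"units"`.
#' @export
cis_permutation_scan <- function(g, p, covariates = NULL, window = 1e6,
                                 n_perm = 1000, seed = 1,
                                 grouped = c("best", "pca1", "mean", "none"),
                                 normalize = TRUE,
                                 fdr_method = c("storey", "bh")) {
  grouped <- match.arg(grouped)
  fdr_method <- match.arg(fdr_method)
  if (grouped %in% c("pca1", "mean")) p <- collapse_groups(p, grouped)
  if (grouped == "none") p$phenotypes$group_id <- p$phenotypes$phenotype_id
  prep <- prepare_mapping(g, p, covariates, normalize)
  scans <- cis_pairs(g, p, window)
  units <- vector("list", length(scans))
  for (i in seq_along(scans)) {
    sc <- scans[[i]]
    if (!length(sc$variant_idx)) next
    gs <- prep$gs[, sc$variant_idx, drop = FALSE]
    ys <- prep$ys[, sc$member_idx, drop = FALSE]
    dist_abs <- abs(outer(g$variants$pos[sc$variant_idx], sc$anchors, "-"))
    units[[i]] <- permutation_pass(
      gs, ys, sc$member_windows, dist_abs,
      g$variants$variant_id[sc$variant_idx], sc$member_ids,
      df = prep$df, n_perm = n_perm, seed = seed, unit_id = sc$group_id)
    if (!is.null(units[[i]])) {
      vv <- match(units[[i]]$best_variant_id, g$variants$variant_id)
      mm <- match(units[[i]]$best_member_id, sc$member_ids)
      units[[i]]$distance <- g$variants$pos[vv] - sc$anchors[mm]
    }
  }
  units <- units[!vapply(units, is.null, TRUE)]
  if (!length(units)) stop("no testable phenotype in the cis scan")
  tab <- data.frame(
    group_id = vapply(units, `[[`, "", "unit_id"),
    n_members = vapply(units, `[[`, 0L, "n_members"),
    n_variants = vapply(units, `[[`, 0L, "n_variants"),
    best_member = vapply(units, `[[`, "", "best_member_id"),
    best_variant = vapply(units, `[[`, "", "best_variant_id"),
    distance = vapply(units, `[[`, 0, "distance"),
    r = vapply(units, `[[`, 0, "r"),
    p_nominal = vapply(units, `[[`, 0, "p_nominal"),
    beta_shape1 = vapply(units, `[[`, 0, "beta_shape1"),
    beta_shape2 = vapply(units, `[[`, 0, "beta_shape2"),
    p_empirical = vapply(units, `[[`, 0, "p_empirical"),
    p_adjusted = vapply(units, `[[`, 0, "p_adjusted"),
    stringsAsFactors = FALSE)
  qv <- suppressWarnings(qvalues(tab$p_adjusted, fdr_method))
  tab$q_value <- qv$qvalue
  attr(tab, "pi0") <- qv$pi0
  attr(tab, "units") <- units
  tab
}

# Replace each multi-member group by a single collapsed phenotype anchored
# at the first member's coordinates.
collapse_groups <- function(p, how = c("pca1", "mean")) {
  how <- match.arg(how)
  ph <- p$phenotypes
  gids <- unique(ph$group_id)
  vals <- matrix(0, nrow(p$values), length(gids),
                 dimnames = list(p$sample_id, gids))
  meta <- ph[match(gids, ph$group_id), ]
  for (k in seq_along(gids)) {
    idx <- which(ph$group_id == gids[k])
    Y <- p$values[, idx, drop = FALSE]
    vals[, k] <- if (length(idx) == 1L) Y[, 1]
    else if (how == "pca1") group_pca_collapse(Y) else rowMeans(Y)
  }
  phenotype_set(vals, phenotype_id = gids, chrom = meta$chrom,
                start = meta$start, end = meta$end, strand = meta$strand,
                group_id = gids, sample_id = p$sample_id)
}
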