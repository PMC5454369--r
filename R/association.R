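# ---------------------------------------------------------------------------
# The elementary association machinery shared by every mapping mode:
# covariate residualization, rank-normal transform, and the Pearson
# correlation test whose p-value equals the t-test of the corresponding
# OLS slope. Permutation passes only need correlations, which keeps them
# inside BLAS matrix products.
# ---------------------------------------------------------------------------

P_FLOOR <- 1e-300  # numerical floor for reported p-values

#' Residualize a matrix against covariates
#'
#' Ordinary least-squares projection: each column of `values` is replaced by
#' its residual after regression on the covariates plus an intercept.
#' Residual columns are orthogonal to every covariate column and to the
#' intercept.
#'
#' @param values numeric matrix (samples x K) or vector.
#' @param covariates a `covariate_set`, a plain numeric matrix
#'   (samples x covariates), or `NULL` for intercept-only (mean-centering).
#' @return Matrix of residuals with the dimensions of `values`.
#' @export
residualize <- function(values, covariates = NULL) {
  v <- as.matrix(values)
  X <- covariate_design(covariates, nrow(v))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    drop <- setdiff(seq_len(ncol(X)), qr_x$pivot[seq_len(qr_x$rank)])
    stop("covariate design is rank deficient; collinear column(s): ",
         paste(colnames(X)[drop], collapse = ", "))
  }
  res <- qr.resid(qr_x, v)
  dimnames(res) <- dimnames(v)
  res
}

covariate_design <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1, dimnames = list(NULL, "intercept")))
  cv <- if (inherits(covariates, "covariate_set")) covariates$values else as.matrix(covariates)
  stopifnot(nrow(cv) == n)
  cbind(intercept = 1, cv)
}

n_covariates_of <- function(covariates) {
  if (is.null(covariates)) return(0L)
  if (inherits(covariates, "covariate_set")) return(ncol(covariates$values))
  ncol(as.matrix(covariates))
}

#' Rank-based inverse normal transform
#'
#' Maps values to normal quantiles of their ranks with mid-ranks for ties:
#' `qnorm((rank - 0.5) / n)`. Enforces the (approximate) normality assumed
#' by the beta-approximated permutation schemes.
#'
#' @param values numeric vector (>= 3 non-missing values); `NA`s preserved.
#' @return Transformed vector of the same length.
#' @export
rank_normalize <- function(values) {
  ok <- !is.na(values)
  v <- values[ok]
  if (length(v) < 3) stop("rank_normalize needs >= 3 non-missing values")
  if (max(v) == min(v)) stop("cannot rank-normalize a constant vector")
  out <- values
  out[ok] <- qnorm((rank(v, ties.method = "average") - 0.5) / length(v))
  out
}

rank_normalize_matrix <- function(m) {
  apply(m, 2, rank_normalize)
}

#' Two-sided p-value for a Pearson correlation
#'
#' `t = r * sqrt(df / (1 - r^2))` referred to a t distribution with `df`
#' degrees of freedom; values are floored at 1e-300.
#'
#' @param r correlation(s).
#' @param df residual degrees of freedom (`n - 2 - n_covariates`).
#' @return p-values, same shape as `r`.
#' @export
corr_pvalue <- function(r, df) {
  r2 <- pmin(r * r, 1)
  tt <- abs(r) * sqrt(df / pmax(1 - r2, .Machine$double.eps))
  p <- 2 * pt(tt, df, lower.tail = FALSE)
  pmax(pmin(p, 1), P_FLOOR)
}

#' Test a single variant-phenotype pair
#'
#' Pearson correlation between a (mean-imputed) dosage vector and a
#' residualized phenotype vector, with slope, standard error and the
#' two-sided p-value of the corresponding regression t-test. Degrees of
#' freedom are reduced by the number of covariates residualized out.
#'
#' @param g dosage vector (missing entries mean-imputed).
#' @param y residualized phenotype vector of the same length.
#' @param n_covariates number of covariates already removed from `y` (and
#'   `g`, if any).
#' @return A list with `r`, `slope`, `se_slope`, `df`, `p_nominal`, or
#'   `NULL` when the genotype is monomorphic after imputation.
#' @export
test_pair <- function(g, y, n_covariates = 0) {
  stopifnot(length(g) == length(y))
  g <- impute_mean(g)
  n <- length(g)
  df <- n - 2L - as.integer(n_covariates)
  if (df < 1) stop("not enough degrees of freedom: df = ", df)
  sg <- sd(g)
  if (sg == 0) return(NULL)  # monomorphic variant: pair is skipped
  r <- as.numeric(cor(g, y))
  slope <- r * sd(y) / sg
  se <- if (abs(r) >= 1) 0 else
    abs(slope) * sqrt((1 - r^2) / df) / max(abs(r), .Machine$double.eps)
  list(r = r, slope = slope, se_slope = se, df = df,
       p_nominal = corr_pvalue(r, df))
}

impute_mean <- function(g) {
  if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
  g
}

# Mean-impute missing dosages and standardize columns to zero mean / unit
# sd (denominator n - 1). Constant columns get sd NA and correlate to 0.
standardize_dosages <- function(m) {
  m <- apply(m, 2, impute_mean)
  mu <- colMeans(m)
  m <- sweep(m, 2, mu)
  s <- sqrt(colSums(m * m) / (nrow(m) - 1))
  bad <- s <= 0
  s[bad] <- NA_real_
  m <- sweep(m, 2, s, "/")
  m[, bad] <- 0
  attr(m, "monomorphic") <- bad
  m
}

standardize_columns <- function(m) {
  mu <- colMeans(m)
  m <- sweep(m, 2, mu)
  s <- sqrt(colSums(m * m) / (nrow(m) - 1))
  sweep(m, 2, s, "/")
}

# Correlation of every column of standardized G with every column of
# standardized Y: the permutation workhorse.
corr_matrix <- function(gs, ys) {
  crossprod(gs, ys) / (nrow(gs) - 1)
}

#' Enumerate cis windows
#'
#' For each phenotype group (singletons when no grouping), lists the
#' variants whose 1-based position lies within `window` bp of the
#' phenotype's anchor (the BED start coordinate), inclusive at both ends.
#' For a multi-member group the union of the member windows is used and
#' per-member membership is retained.
#'
#' @param g a `genotype_matrix`.
#' @param p a `phenotype_set` (samples already harmonized with `g`).
#' @param window window half-width in bp (default 1 Mb).
#' @return A list of cis scans, one per group: each has `group_id`,
#'   `member_ids`, `variant_idx` (column indices into `g$dosages`), and
#'   `member_windows` (per-member logical membership over `variant_idx`).
#' @export
cis_pairs <- function(g, p, window = 1e6) {
  stopifnot(window > 0)
  ph <- p$phenotypes
  anchors <- phenotype_anchor(ph)
  groups <- split(seq_len(nrow(ph)), ph$group_id)
  # preserve first-appearance order of groups
  groups <- groups[unique(ph$group_id)]
  vr <- g$variants
  lapply(names(groups), function(gid) {
    idx <- groups[[gid]]
    per_member <- lapply(idx, function(i) {
      which(vr$chrom == ph$chrom[i] & abs(vr$pos - anchors[i]) <= window)
    })
    vidx <- sort(unique(unlist(per_member)))
    member_windows <- vapply(per_member, function(w) vidx %in% w,
                             logical(length(vidx)))
    if (length(vidx) == 1L) member_windows <- matrix(member_windows, nrow = 1)
    list(group_id = gid,
         member_ids = ph$phenotype_id[idx],
         member_idx = idx,
         anchors = anchors[idx],
         variant_idx = vidx,
         member_windows = member_windows)
  })
}

# The cis anchor is the BED start coordinate translated to the 1-based
# system (start + 1), regardless of strand by default.
phenotype_anchor <- function(ph, use_strand = FALSE) {
  a <- ph$start + 1L
  if (use_strand) a <- ifelse(ph$strand == "-", ph$end, a)
  a
}

#' Nominal cis pass
#'
#' Tests every variant-phenotype pair within the cis window and returns one
#' row per testable pair.
#'
#' @inheritParams cis_pairs
#' @param covariates optional `covariate_set`; residualized out of both
#'   phenotypes and genotypes before testing.
#' @param normalize rank-normalize phenotypes first (default `TRUE`).
#' @return data.frame with phenotype_id, group_id, variant_id, distance,
#'   r, slope, p_nominal.
#' @export
cis_nominal <- function(g, p, covariates = NULL, window = 1e6,
                        normalize = TRUE) {
  prep <- prepare_mapping(g, p, covariates, normalize)
  scans <- cis_pairs(g, p, window)
  out <- lapply(scans, function(sc) {
    if (!length(sc$variant_idx)) return(NULL)
    gs <- prep$gs[, sc$variant_idx, drop = FALSE]
    ys <- prep$ys[, sc$member_idx, drop = FALSE]
    r <- corr_matrix(gs, standardize_columns(ys))
    pm <- corr_pvalue(r, prep$df)
    slope <- r * rep(apply(ys, 2, sd), each = nrow(r)) /
      rep(prep$g_sd[sc$variant_idx], nrow(r))
    data.frame(
      phenotype_id = rep(sc$member_ids, each = length(sc$variant_idx)),
      group_id = sc$group_id,
      variant_id = g$variants$variant_id[sc$variant_idx],
      distance = rep(g$variants$pos[sc$variant_idx], length(sc$member_idx)) -
        rep(sc$anchors, each = length(sc$variant_idx)),
      r = as.vector(r), slope = as.vector(slope),
      p_nominal = as.vector(pm), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Shared preprocessing: rank-normalize (optional), residualize phenotypes
# and genotypes against the covariates, standardize genotypes.
prepare_mapping <- function(g, p, covariates, normalize) {
  stopifnot(identical(g$sample_id, p$sample_id))
  y <- p$values
  if (normalize) y <- rank_normalize_matrix(y)
  n_cov <- n_covariates_of(covariates)
  gm <- apply(g$dosages, 2, impute_mean)
  if (n_cov > 0) {
    y <- residualize(y, covariates)
    gm <- residualize(gm, covariates)
  }
  g_sd <- apply(gm, 2, sd)
  n <- nrow(y)
  list(ys = y, gs = standardize_dosages(gm), g_sd = g_sd,
       df = n - 2L - n_cov, n_cov = n_cov, n = n)
}
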