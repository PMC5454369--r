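# ---------------------------------------------------------------------------
# Sample-level QC: genotype-vs-sequence concordance (mislabelling /
# contamination detection from per-site allele read counts) and PCA for
# stratification covariates.
# ---------------------------------------------------------------------------

#' Genotype-vs-sequence concordance matching
#'
#' Scores every (sequence sample, genotype sample) pair over the variants
#' with read coverage at or above `min_cov`. At sites where the genotype
#' is heterozygous, a site is concordant when both alleles are seen with
#' at least one read and the minor-allele read fraction is at least
#' `hom_tol`; at homozygous sites, when the fraction of reads carrying the
#' genotype allele is at least `1 - hom_tol`. Low values of either rate
#' indicate mislabelling, contamination or amplification bias; the
#' best-matching genotype sample per sequence sample is reported.
#'
#' @param counts an `allele_count_table` (sequence samples).
#' @param g a `genotype_matrix` with hard genotypes (dosages rounded to
#'   0/1/2).
#' @param min_cov minimum total read coverage per site (default 10).
#' @param hom_tol allowed error fraction in \[0, 0.5) (default 0.1).
#' @return List with `pairs` (data.frame seq_sample, geno_sample,
#'   het_concordance, hom_concordance, overall, n_het_sites, n_hom_sites,
#'   informative) and `best_match` (data.frame seq_sample, geno_sample,
#'   overall).
#' @export
match_samples <- function(counts, g, min_cov = 10, hom_tol = 0.1) {
  stopifnot(min_cov >= 1, hom_tol >= 0, hom_tol < 0.5)
  vmatch <- match(counts$variant_id, g$variants$variant_id)
  if (anyNA(vmatch))
    stop("allele-count variant id(s) not present in the genotype matrix: ",
         counts$variant_id[which(is.na(vmatch))[1]])
  cov <- counts$ref_count + counts$alt_count
  keep <- cov >= min_cov
  cts <- counts[keep, , drop = FALSE]
  vmatch <- vmatch[keep]
  seq_samples <- unique(cts$sample_id)
  dos <- round(g$dosages)
  pairs <- list()
  for (s in seq_samples) {
    rows <- which(cts$sample_id == s)
    vr <- vmatch[rows]
    rc <- cts$ref_count[rows]; ac <- cts$alt_count[rows]
    tot <- rc + ac
    alt_frac <- ac / tot
    minor_frac <- pmin(rc, ac) / tot
    for (t in seq_along(g$sample_id)) {
      gt <- dos[t, vr]
      het <- which(gt == 1 & !is.na(gt))
      hom <- which((gt == 0 | gt == 2) & !is.na(gt))
      het_ok <- rc[het] >= 1 & ac[het] >= 1 & minor_frac[het] >= hom_tol
      hom_match_frac <- ifelse(gt[hom] == 0, 1 - alt_frac[hom], alt_frac[hom])
      hom_ok <- hom_match_frac >= 1 - hom_tol
      n_sites <- length(het) + length(hom)
      pairs[[length(pairs) + 1L]] <- data.frame(
        seq_sample = s, geno_sample = g$sample_id[t],
        het_concordance = if (length(het)) mean(het_ok) else NA_real_,
        hom_concordance = if (length(hom)) mean(hom_ok) else NA_real_,
        overall = if (n_sites) (sum(het_ok) + sum(hom_ok)) / n_sites
                  else NA_real_,
        n_het_sites = length(het), n_hom_sites = length(hom),
        informative = n_sites > 0, stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, pairs)
  best <- do.call(rbind, lapply(split(pairs, pairs$seq_sample), function(d) {
    d <- d[d$informative, , drop = FALSE]
    if (!nrow(d)) return(NULL)
    d[which.max(d$overall), c("seq_sample", "geno_sample", "overall")]
  }))
  rownames(best) <- NULL
  list(pairs = pairs, best_match = best)
}

#' Principal component analysis for stratification covariates
#'
#' Covariance-eigendecomposition PCA (via the SVD of the centred and
#' optionally unit-scaled data) of a samples x features matrix, e.g.
#' expression quantifications or standardized genotype dosages. Scores on
#' the top components are commonly used as latent covariates in the
#' mapping passes. The sign of each component is fixed by making its
#' largest-magnitude loading positive.
#'
#' @param values samples x features numeric matrix.
#' @param k number of components.
#' @param scale. scale features to unit variance (constant features are
#'   dropped with a warning).
#' @return List with `scores` (samples x k), `variance_explained`
#'   (fractions, non-increasing) and `loadings`.
#' @export
pca_covariates <- function(values, k, scale. = TRUE) {
  values <- as.matrix(values)
  if (scale.) {
    s <- apply(values, 2, sd)
    if (any(s == 0)) {
      warning(sum(s == 0), " constant feature(s) dropped before scaling")
      values <- values[, s > 0, drop = FALSE]
    }
  }
  stopifnot(k <= min(nrow(values) - 1, ncol(values)))
  pc <- prcomp(values, center = TRUE, scale. = scale.)
  flip <- vapply(seq_len(k), function(j) {
    ld <- pc$rotation[, j]
    if (ld[which.max(abs(ld))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, "*")
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores,
       variance_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
       loadings = sweep(pc$rotation[, seq_len(k), drop = FALSE], 2, flip, "*"))
}
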