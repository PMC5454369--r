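#' @importFrom stats pt qnorm pnorm pbeta qbeta rnorm rbinom runif sd cor
#'   complete.cases fisher.test integrate uniroot smooth.spline predict
#'   p.adjust prcomp rpois var
#' @importFrom utils head
NULL

# ---------------------------------------------------------------------------
# Core containers. These are light S3 classes over plain matrices so that all
# heavy lifting can stay in vectorized BLAS calls.
# ---------------------------------------------------------------------------

#' Construct a genotype matrix
#'
#' Holds a samples x variants dosage matrix (values in \[0, 2\], `NA` for
#' missing) together with variant coordinates (1-based, as in VCF) and the
#' minor allele frequency computed from non-missing dosages. Variants are
#' stored sorted by (chromosome, position).
#'
#' @param dosages numeric matrix, samples in rows, variants in columns;
#'   entries in \[0, 2\] or `NA`.
#' @param variant_id character vector of variant identifiers (column names).
#' @param chrom character vector of chromosome labels per variant.
#' @param pos integer vector of 1-based variant positions.
#' @param sample_id character vector of sample identifiers (row names).
#' @return An object of class `genotype_matrix` with fields `dosages`,
#'   `variants` (a data.frame with `variant_id`, `chrom`, `pos`, `maf`) and
#'   `sample_id`.
#' @export
genotype_matrix <- function(dosages, variant_id, chrom, pos, sample_id) {
  dosages <- as.matrix(dosages)
  stopifnot(ncol(dosages) == length(variant_id),
            length(variant_id) == length(chrom),
            length(chrom) == length(pos),
            nrow(dosages) == length(sample_id))
  rng <- range(dosages, na.rm = TRUE)
  if (length(dosages) && (rng[1] < -1e-9 || rng[2] > 2 + 1e-9))
    stop("dosage values must lie in [0, 2]")
  ord <- order(chrom, pos)
  dosages <- dosages[, ord, drop = FALSE]
  variant_id <- variant_id[ord]; chrom <- chrom[ord]; pos <- pos[ord]
  dimnames(dosages) <- list(sample_id, variant_id)
  maf <- apply(dosages, 2, dosage_maf)
  structure(list(
    dosages = dosages,
    variants = data.frame(variant_id = variant_id, chrom = chrom,
                          pos = as.integer(pos), maf = maf,
                          stringsAsFactors = FALSE, row.names = NULL),
    sample_id = sample_id
  ), class = "genotype_matrix")
}

dosage_maf <- function(d) {
  d <- d[!is.na(d)]
  if (!length(d)) return(NA_real_)
  af <- mean(d) / 2
  min(af, 1 - af)
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants\n",
              length(x$sample_id), nrow(x$variants)))
  invisible(x)
}

#' Construct a phenotype set
#'
#' Molecular phenotypes (expression, chromatin, ...) as a samples x
#' phenotypes matrix with genomic anchors. Coordinates follow the BED
#' convention: 0-based, half-open `[start, end)`. `group_id` ties member
#' phenotypes (e.g. exons) into a higher-order group (e.g. gene); a `"."`
#' group id means the phenotype forms its own singleton group.
#'
#' @param values numeric matrix, samples x phenotypes.
#' @param phenotype_id,chrom,start,end,strand,group_id per-phenotype
#'   metadata vectors; `strand` and `group_id` optional.
#' @param sample_id character vector of sample identifiers.
#' @return An object of class `phenotype_set` with fields `values`,
#'   `phenotypes` (data.frame) and `sample_id`.
#' @export
phenotype_set <- function(values, phenotype_id, chrom, start, end,
                          strand = rep("+", length(phenotype_id)),
                          group_id = NULL, sample_id) {
  values <- as.matrix(values)
  stopifnot(ncol(values) == length(phenotype_id),
            nrow(values) == length(sample_id))
  if (anyDuplicated(phenotype_id))
    stop("duplicate phenotype id: ",
         phenotype_id[duplicated(phenotype_id)][1])
  if (any(start >= end))
    stop("start >= end for phenotype row(s): ",
         paste(which(start >= end), collapse = ", "))
  if (is.null(group_id)) group_id <- rep(".", length(phenotype_id))
  group_id <- ifelse(group_id == "." | is.na(group_id), phenotype_id, group_id)
  dimnames(values) <- list(sample_id, phenotype_id)
  structure(list(
    values = values,
    phenotypes = data.frame(phenotype_id = phenotype_id, chrom = chrom,
                            start = as.integer(start), end = as.integer(end),
                            strand = strand, group_id = group_id,
                            stringsAsFactors = FALSE, row.names = NULL),
    sample_id = sample_id
  ), class = "phenotype_set")
}

#' @exportS3Method base::print
print.phenotype_set <- function(x, ...) {
  cat(sprintf("phenotype_set: %d samples x %d phenotypes (%d groups)\n",
              length(x$sample_id), nrow(x$phenotypes),
              length(unique(x$phenotypes$group_id))))
  invisible(x)
}

#' Construct a covariate set
#'
#' @param values numeric matrix, samples x covariates; no missing values.
#' @param covariate_id,sample_id identifier vectors.
#' @return An object of class `covariate_set`.
#' @export
covariate_set <- function(values, covariate_id, sample_id) {
  values <- as.matrix(values)
  stopifnot(ncol(values) == length(covariate_id),
            nrow(values) == length(sample_id))
  if (anyNA(values)) stop("covariates must not contain missing values")
  dimnames(values) <- list(sample_id, covariate_id)
  structure(list(values = values, covariate_id = covariate_id,
                 sample_id = sample_id), class = "covariate_set")
}

#' Construct an annotation track
#'
#' A set of (possibly overlapping) genomic intervals in 0-based half-open
#' coordinates, each carrying a non-empty label.
#'
#' @param chrom,start,end,label per-interval vectors.
#' @return An object of class `annotation_track` (a data.frame).
#' @export
annotation_track <- function(chrom, start, end, label) {
  stopifnot(length(chrom) == length(start), length(start) == length(end),
            length(end) == length(label))
  if (any(start >= end)) stop("annotation intervals require start < end")
  if (any(!nzchar(label))) stop("annotation labels must be non-empty")
  structure(data.frame(chrom = chrom, start = as.integer(start),
                       end = as.integer(end), label = label,
                       stringsAsFactors = FALSE),
            class = c("annotation_track", "data.frame"))
}

#' Construct an allele count table
#'
#' Per-(variant, sample) reference and alternate read counts, used by the
#' genotype-vs-sequence concordance check.
#'
#' @param variant_id,sample_id,ref_count,alt_count parallel vectors.
#' @return An object of class `allele_count_table` (a data.frame).
#' @export
allele_count_table <- function(variant_id, sample_id, ref_count, alt_count) {
  ref_count <- as.integer(ref_count); alt_count <- as.integer(alt_count)
  if (any(ref_count < 0) || any(alt_count < 0))
    stop("allele counts must be non-negative")
  structure(data.frame(variant_id = variant_id, sample_id = sample_id,
                       ref_count = ref_count, alt_count = alt_count,
                       stringsAsFactors = FALSE),
            class = c("allele_count_table", "data.frame"))
}

#' Restrict genotypes, phenotypes and covariates to shared samples
#'
#' Intersects the sample sets of the three containers and reorders each to a
#' single canonical order (the genotype order restricted to the
#' intersection). Downstream mapping code assumes this harmonization has run.
#'
#' @param g a `genotype_matrix`.
#' @param p a `phenotype_set`.
#' @param covariates a `covariate_set` or `NULL`.
#' @return A list with the three harmonized objects plus `dropped`, the
#'   sample ids removed from at least one input.
#' @export
harmonize_samples <- function(g, p, covariates = NULL) {
  common <- intersect(g$sample_id, p$sample_id)
  if (!is.null(covariates)) common <- intersect(common, covariates$sample_id)
  if (!length(common)) stop("no samples shared between inputs")
  common <- g$sample_id[g$sample_id %in% common]  # canonical order
  dropped <- setdiff(unique(c(g$sample_id, p$sample_id,
                              if (!is.null(covariates)) covariates$sample_id)),
                     common)
  g$dosages <- g$dosages[common, , drop = FALSE]
  g$sample_id <- common
  g$variants$maf <- apply(g$dosages, 2, dosage_maf)
  p$values <- p$values[common, , drop = FALSE]
  p$sample_id <- common
  if (!is.null(covariates)) {
    covariates$values <- covariates$values[common, , drop = FALSE]
    covariates$sample_id <- common
  }
  list(genotypes = g, phenotypes = p, covariates = covariates,
       dropped = dropped)
}
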