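# ---------------------------------------------------------------------------
# Deterministic simulator: genotypes (binomial, optional AR(1) LD via a
# thresholded latent Gaussian calibrated so that the *genotype*
# correlation between adjacent variants matches the requested rho),
# phenotypes with planted effects, grouped members sharing a latent
# structure, covariate factors, annotations and allele read counts. Every
# module of the toolkit can be exercised against the returned truth table
# without any external data.
# ---------------------------------------------------------------------------

#' Specify a simulated QTL dataset
#'
#' @param n_samples number of samples.
#' @param n_variants number of variants (one region on `variant_chrom`,
#'   spaced `variant_spacing` bp apart).
#' @param maf_range minor-allele-frequency bounds (uniform draw).
#' @param ld_rho AR(1) genotype correlation between adjacent variants
#'   (0 = independent).
#' @param group_sizes integer vector of phenotype-group sizes; the number
#'   of phenotypes is `sum(group_sizes)`.
#' @param effects data.frame with columns `phenotype` (index), `variant`
#'   (index) and `beta` (effect size in phenotype SD units per SD of
#'   dosage).
#' @param group_latent_sd SD of the latent factor shared by the members of
#'   a group (drives their inner correlation).
#' @param n_factors number of global latent factors (confounders) loading
#'   on every phenotype.
#' @param factor_sd SD of the factor loadings.
#' @param noise_sd residual noise SD.
#' @param variant_chrom,variant_spacing,variant_start variant placement.
#' @param phenotype_chrom chromosome for phenotype anchors; defaults to
#'   `variant_chrom` (cis layout). Use another chromosome for a trans
#'   layout.
#' @param coverage mean read coverage for simulated allele counts.
#' @param seq_error per-read sequencing error rate.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_samples = 200, n_variants = 50,
                            maf_range = c(0.05, 0.5), ld_rho = 0,
                            group_sizes = rep(1L, 20),
                            effects = data.frame(phenotype = integer(0),
                                                 variant = integer(0),
                                                 beta = numeric(0)),
                            group_latent_sd = 0, n_factors = 0,
                            factor_sd = 0.5, noise_sd = 1,
                            variant_chrom = "1", variant_spacing = 1000,
                            variant_start = 100000,
                            phenotype_chrom = variant_chrom,
                            coverage = 30, seq_error = 0.01) {
  n_phen <- sum(group_sizes)
  if (nrow(effects)) {
    if (any(effects$variant < 1 | effects$variant > n_variants))
      stop("effect placed on a non-existent variant")
    if (any(effects$phenotype < 1 | effects$phenotype > n_phen))
      stop("effect placed on a non-existent phenotype")
  }
  structure(list(n_samples = n_samples, n_variants = n_variants,
                 maf_range = maf_range, ld_rho = ld_rho,
                 group_sizes = as.integer(group_sizes), effects = effects,
                 group_latent_sd = group_latent_sd, n_factors = n_factors,
                 factor_sd = factor_sd, noise_sd = noise_sd,
                 variant_chrom = variant_chrom,
                 variant_spacing = variant_spacing,
                 variant_start = variant_start,
                 phenotype_chrom = phenotype_chrom,
                 coverage = coverage, seq_error = seq_error),
            class = "simulation_spec")
}

# Latent correlation r such that two standard-normal variables thresholded
# at qnorm(p1), qnorm(p2) yield binary variables with correlation rho.
# Memoized on the rounded maf pair.
latent_ld_env <- new.env(parent = emptyenv())

latent_corr_for <- function(rho, p1, p2) {
  key <- sprintf("%.17g_%.17g_%.17g", rho, p1, p2)
  hit <- latent_ld_env[[key]]
  if (!is.null(hit)) return(hit)
  t1 <- qnorm(p1); t2 <- qnorm(p2)
  p11 <- function(r) {
    integrate(function(x) dnorm(x) * pnorm((t2 - r * x) / sqrt(1 - r^2)),
              -Inf, t1, rel.tol = 1e-9)$value
  }
  phi <- function(r) (p11(r) - p1 * p2) /
    sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  # the binary correlation is bounded above when the two MAFs differ;
  # clamp at the (near-)maximal achievable value in that case
  r <- if (phi(0.995) <= rho) 0.995 else
    uniroot(function(r) phi(r) - rho, c(1e-6, 0.995), tol = 1e-7)$root
  latent_ld_env[[key]] <- r
  r
}

sim_genotypes <- function(spec) {
  n <- spec$n_samples; V <- spec$n_variants
  maf <- runif(V, spec$maf_range[1], spec$maf_range[2])
  if (spec$ld_rho <= 0) {
    d <- matrix(rbinom(n * V, 2, rep(maf, each = n)), n, V)
  } else {
    thr <- qnorm(maf)
    rlat <- c(NA, vapply(seq_len(V - 1), function(j)
      latent_corr_for(spec$ld_rho, maf[j], maf[j + 1]), numeric(1)))
    hap <- function() {
      z <- matrix(0, n, V)
      z[, 1] <- rnorm(n)
      for (j in 2:V)
        z[, j] <- rlat[j] * z[, j - 1] + sqrt(1 - rlat[j]^2) * rnorm(n)
      sweep(z, 2, thr, "<") + 0
    }
    d <- hap() + hap()
  }
  pos <- spec$variant_start + (seq_len(V) - 1L) * spec$variant_spacing
  genotype_matrix(d, variant_id = sprintf("var%04d", seq_len(V)),
                  chrom = rep(spec$variant_chrom, V), pos = pos,
                  sample_id = sprintf("S%03d", seq_len(n)))
}

#' Simulate a complete QTL dataset
#'
#' Fully reproducible given `(spec, seed)`. Genotypes are Binomial(2, maf)
#' draws (optionally with AR(1) LD); each phenotype is the sum of its
#' planted effects on standardized dosages, a group-shared latent factor,
#' global confounding factors and Gaussian noise. Phenotype anchors sit at
#' the centre of the variant region (or on `phenotype_chrom` for trans
#' layouts). Allele counts are drawn per site and sample from the sample's
#' own genotype; annotations can be placed at planted-variant positions
#' with [simulate_annotations()].
#'
#' @param spec a `simulation_spec`.
#' @param seed integer seed.
#' @return List with `genotypes`, `phenotypes`, `covariates` (`NULL` when
#'   `n_factors` is 0; otherwise the true factors), `truth` (planted
#'   effects with ids) and `spec`.
#' @export
simulate_dataset <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(seed, {
    g <- sim_genotypes(spec)
    n <- spec$n_samples
    n_phen <- sum(spec$group_sizes)
    gs <- standardize_dosages(g$dosages)
    fac <- if (spec$n_factors > 0)
      matrix(rnorm(n * spec$n_factors), n) else NULL
    group_id <- rep(seq_along(spec$group_sizes), spec$group_sizes)
    u <- matrix(rnorm(n * length(spec$group_sizes)), n)
    Y <- matrix(0, n, n_phen)
    loadings <- if (!is.null(fac))
      matrix(rnorm(spec$n_factors * n_phen, 0, spec$factor_sd),
             spec$n_factors) else NULL
    for (j in seq_len(n_phen)) {
      mu <- rep(0, n)
      ef <- spec$effects[spec$effects$phenotype == j, , drop = FALSE]
      if (nrow(ef))
        mu <- mu + as.vector(gs[, ef$variant, drop = FALSE] %*% ef$beta)
      if (spec$group_latent_sd > 0)
        mu <- mu + spec$group_latent_sd * u[, group_id[j]]
      if (!is.null(fac)) mu <- mu + as.vector(fac %*% loadings[, j])
      Y[, j] <- mu + rnorm(n, 0, spec$noise_sd)
    }
    mid <- spec$variant_start +
      floor(spec$n_variants / 2) * spec$variant_spacing
    anchors0 <- rep(mid - 1L, n_phen)  # BED start (0-based)
    pheno_ids <- sprintf("phen%04d", seq_len(n_phen))
    p <- phenotype_set(Y, phenotype_id = pheno_ids,
                       chrom = rep(spec$phenotype_chrom, n_phen),
                       start = anchors0, end = anchors0 + 1L,
                       group_id = sprintf("grp%03d", group_id),
                       sample_id = g$sample_id)
    covariates <- if (!is.null(fac))
      covariate_set(fac, sprintf("factor%d", seq_len(spec$n_factors)),
                    g$sample_id) else NULL
    truth <- spec$effects
    if (nrow(truth)) {
      truth$phenotype_id <- pheno_ids[truth$phenotype]
      truth$variant_id <- g$variants$variant_id[truth$variant]
      truth$group_id <- sprintf("grp%03d", group_id[truth$phenotype])
    }
    list(genotypes = g, phenotypes = p, covariates = covariates,
         truth = truth, spec = spec)
  })
}

#' Simulate per-site allele read counts from genotypes
#'
#' Coverage is Poisson(`coverage`) per site and sample; alternate-allele
#' reads are Binomial(coverage, f) with f = error, 0.5 or 1 - error for
#' genotypes 0/1/2. Optionally the counts of some samples are generated
#' from another sample's genotype (mislabelling) or as a 50:50 mixture
#' (contamination).
#'
#' @param g a `genotype_matrix`.
#' @param seed integer seed.
#' @param coverage mean coverage.
#' @param seq_error per-read error rate.
#' @param source_of named vector: for sequence sample s,
#'   `source_of[s]` is the genotype sample its reads come from (default
#'   identity).
#' @param mix_with optional named vector: sequence samples whose reads are
#'   a 50:50 mix of their source and the named second sample.
#' @return An `allele_count_table` covering every (variant, sample).
#' @export
simulate_allele_counts <- function(g, seed = 1, coverage = 30,
                                   seq_error = 0.01, source_of = NULL,
                                   mix_with = NULL) {
  if (is.null(source_of))
    source_of <- stats::setNames(g$sample_id, g$sample_id)
  with_seed(seed, {
    d <- round(g$dosages)
    frac_of <- function(gt) c(seq_error, 0.5, 1 - seq_error)[gt + 1]
    out <- lapply(names(source_of), function(s) {
      gt <- d[source_of[[s]], ]
      f <- frac_of(gt)
      if (!is.null(mix_with) && s %in% names(mix_with))
        f <- (f + frac_of(d[mix_with[[s]], ])) / 2
      cov <- rpois(length(f), coverage)
      alt <- rbinom(length(f), cov, f)
      data.frame(variant_id = g$variants$variant_id, sample_id = s,
                 ref_count = cov - alt, alt_count = alt,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    allele_count_table(out$variant_id, out$sample_id, out$ref_count,
                       out$alt_count)
  })
}

#' Simulate an annotation track around (optionally) planted QTLs
#'
#' Places `n_random` intervals uniformly over the variant region and, when
#' `at` positions are given, one interval of width `width` centred on each
#' (creating a known enrichment).
#'
#' @param spec a `simulation_spec` (for the region bounds).
#' @param seed integer seed.
#' @param n_random number of random background intervals.
#' @param width interval width in bp.
#' @param at optional 1-based positions to annotate deterministically.
#' @return An `annotation_track`.
#' @export
simulate_annotations <- function(spec, seed = 1, n_random = 50,
                                 width = 200, at = NULL) {
  lo <- spec$variant_start
  hi <- spec$variant_start + spec$n_variants * spec$variant_spacing
  with_seed(seed, {
    s <- sort(sample(lo:hi, n_random))
    start <- c(s, if (length(at)) at - width %/% 2)
    chrom <- rep(spec$variant_chrom, length(start))
    lab <- c(rep("background", n_random),
             if (length(at)) rep("planted", length(at)))
    annotation_track(chrom, start, start + width, lab)
  })
}
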