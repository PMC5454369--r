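# Small in-code fixtures shared across test files.

# Write a toy VCF and return its path.
toy_vcf <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "toy.vcf")
  writeLines(lines, path)
  path
}

vcf_header <- function(samples) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

vcf_row <- function(chrom, pos, id, alt, gts, ref = "A") {
  paste(c(chrom, pos, id, ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

# Deterministic toy genotype matrix without simulation machinery.
toy_genotypes <- function(n = 8, V = 4, seed = 1, chrom = "1",
                          pos = seq(1000, by = 1000, length.out = V)) {
  set.seed(seed)
  d <- matrix(rbinom(n * V, 2, 0.4), n, V)
  genotype_matrix(d, variant_id = paste0("v", seq_len(V)),
                  chrom = rep(chrom, V), pos = pos,
                  sample_id = paste0("S", seq_len(n)))
}

toy_phenotypes <- function(n = 8, K = 2, seed = 2, chrom = "1",
                           start = rep(1999, K), group_id = NULL) {
  set.seed(seed)
  phenotype_set(matrix(rnorm(n * K), n, K),
                phenotype_id = paste0("p", seq_len(K)),
                chrom = rep(chrom, K), start = start, end = start + 1,
                group_id = group_id, sample_id = paste0("S", seq_len(n)))
}

# Independent OLS oracle: full multiple regression via normal equations.
ols_oracle <- function(y, x, covariates = NULL) {
  X <- cbind(1, covariates, x)
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * solve(XtX)[ncol(X), ncol(X)])
  tt <- beta[ncol(X)] / se
  list(slope = as.numeric(beta[ncol(X)]), se = as.numeric(se),
       t = as.numeric(tt), df = df,
       p = 2 * pt(abs(tt), df, lower.tail = FALSE))
}
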