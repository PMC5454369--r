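test_that("genotype matrix validates dosages, sorts variants and stores MAF", {
  d <- matrix(c(0, 1, 2, 2, NA, 0), 3, 2)
  g <- genotype_matrix(d, variant_id = c("b", "a"), chrom = c("1", "1"),
                       pos = c(500, 100), sample_id = c("S1", "S2", "S3"))
  expect_equal(g$variants$variant_id, c("a", "b"))  # sorted by position
  expect_equal(g$variants$pos, c(100L, 500L))
  # MAF of column "a" (was col 2): dosages 2, NA, 0 -> af = 0.5
  expect_equal(g$variants$maf[1], 0.5, tolerance = 1e-12)
  expect_equal(g$variants$maf[2], min(mean(c(0, 1, 2)) / 2,
                                      1 - mean(c(0, 1, 2)) / 2),
               tolerance = 1e-12)
  expect_error(genotype_matrix(matrix(3, 1, 1), "v", "1", 1, "S1"),
               "0, 2")
})

test_that("phenotype set enforces start < end, unique ids and group rules", {
  expect_error(toy_phenotypes(start = c(10, 20)), NA)
  expect_error(
    phenotype_set(matrix(0, 2, 1), "p1", "1", start = 5, end = 5,
                  sample_id = c("a", "b")), "start >= end")
  expect_error(
    phenotype_set(matrix(0, 2, 2), c("p1", "p1"), c("1", "1"), c(1, 2),
                  c(5, 6), sample_id = c("a", "b")), "duplicate")
  # "." group ids become singleton groups named after the phenotype
  p <- toy_phenotypes(K = 3, group_id = c(".", ".", "."))
  expect_equal(p$phenotypes$group_id, p$phenotypes$phenotype_id)
})

test_that("VCF reading filters by MAF and allele count, GT encodes additively", {
  samples <- paste0("S", 1:5)
  # MAFs: v1 0.0, v2 0.1, v3 0.3, v4 triallelic
  lines <- c(vcf_header(samples),
             vcf_row("1", 100, "v1", "G", rep("0/0", 5)),
             vcf_row("1", 200, "v2", "G", c("0/1", "0/0", "0/0", "0/0", "0/0")),
             vcf_row("1", 300, "v3", "G", c("0/1", "1/1", "0/0", "0/0", "0/0")),
             vcf_row("1", 400, "v4", "G,T", c("0/1", "0/2", "0/0", "1/1", "0/0")))
  g <- read_genotypes(toy_vcf(lines), maf_min = 0.05, biallelic_only = TRUE)
  expect_equal(g$variants$variant_id, c("v2", "v3"))
  expect_equal(attr(g, "n_kept"), 2L)
  expect_equal(attr(g, "n_dropped"), 2L)
  expect_equal(unname(g$dosages[, "v3"]), c(1, 2, 0, 0, 0))
  # stricter MAF keeps only v3
  g2 <- read_genotypes(toy_vcf(lines), maf_min = 0.2)
  expect_equal(g2$variants$variant_id, "v3")
  # nothing survives -> explicit empty signal
  expect_warning(e <- read_genotypes(toy_vcf(lines), maf_min = 0.45),
                 "no variants")
  expect_s3_class(e, "empty_genotypes")
  # missing genotypes retained as NA
  lines_na <- c(vcf_header(samples),
                vcf_row("1", 100, "m1", "G", c("./.", "0/1", "1/1", "0/0", "0/1")))
  gna <- read_genotypes(toy_vcf(lines_na), maf_min = 0)
  expect_true(is.na(gna$dosages[1, 1]))
  expect_equal(gna$variants$maf[1], 0.5)
})

test_that("phenotype BED round-trips and rejects malformed input", {
  p <- toy_phenotypes(n = 4, K = 2, group_id = c("g1", "g1"))
  path <- withr::local_tempfile(fileext = ".bed")
  write_phenotypes(p, path)
  p2 <- read_phenotypes(path)
  expect_equal(p2$values, p$values)
  expect_equal(p2$phenotypes, p$phenotypes)
  expect_equal(p2$sample_id, p$sample_id)

  # malformed rows
  tab <- data.frame(chr = "1", start = 10, end = 5, id = "p1", gid = ".",
                    strand = "+", S1 = 1, S2 = 2)
  bad <- withr::local_tempfile(fileext = ".bed")
  write.table(tab, bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_phenotypes(bad), "start >= end")
  tab$end <- 20; tab$S1 <- "x"
  write.table(tab, bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_phenotypes(bad), "non-numeric")
})

test_that("annotation and allele-count tables round-trip exactly", {
  tr <- annotation_track(c("1", "2"), c(10, 50), c(20, 80), c("tf", "dnase"))
  path <- withr::local_tempfile(fileext = ".bed")
  write_annotations(tr, path)
  expect_equal(as.data.frame(read_annotations(path)), as.data.frame(tr))

  ct <- allele_count_table(c("v1", "v1"), c("S1", "S2"), c(10, 3), c(0, 7))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_allele_counts(ct, path2)
  expect_equal(as.data.frame(read_allele_counts(path2)), as.data.frame(ct))

  g <- toy_genotypes(n = 4, V = 3)
  path3 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(g, path3)
  g2 <- read_genotypes(path3, maf_min = 0)
  expect_equal(g2$dosages, g$dosages)
  expect_equal(g2$variants$pos, g$variants$pos)
})

test_that("harmonize restricts to shared samples in canonical order", {
  g <- toy_genotypes(n = 3)                       # S1 S2 S3
  p <- toy_phenotypes(n = 4)                      # S1..S4
  p$values <- p$values[c(2, 3, 4, 1), ]           # scramble
  p$sample_id <- paste0("S", c(2, 3, 4, 1))
  rownames(p$values) <- p$sample_id
  cv <- covariate_set(matrix(1:4, 4), "c1", paste0("S", c(4, 3, 2, 1)))
  h <- harmonize_samples(g, p, cv)
  expect_equal(h$genotypes$sample_id, c("S1", "S2", "S3"))
  expect_equal(h$phenotypes$sample_id, c("S1", "S2", "S3"))
  expect_equal(h$covariates$sample_id, c("S1", "S2", "S3"))
  expect_equal(rownames(h$phenotypes$values), c("S1", "S2", "S3"))
  expect_setequal(h$dropped, "S4")

  p2 <- toy_phenotypes(n = 2)
  p2$sample_id <- c("X1", "X2"); rownames(p2$values) <- p2$sample_id
  expect_error(harmonize_samples(g, p2), "no samples shared")
})

test_that("VCF 1-based position vs BED half-open interval bridge", {
  # variant at POS p overlaps [s, e) iff s < p <= e
  inside <- function(pos, s, e) s < pos & pos <= e
  expect_false(inside(10, 10, 20))   # pos == start: outside (BED start is 0-based)
  expect_true(inside(11, 10, 20))
  expect_true(inside(20, 10, 20))
  expect_false(inside(21, 10, 20))
  # the same convention drives QTL-annotation overlap
  expect_false(molqtl:::point_in_intervals(10, 10, 20))
  expect_true(molqtl:::point_in_intervals(20, 10, 20))
})
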