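# ---------------------------------------------------------------------------
# Readers/writers for the external formats: VCF genotypes, phenotype BED,
# covariate TSV, annotation BED, allele-count TSV. All coordinates are kept
# in their native convention (VCF 1-based, BED 0-based half-open).
# ---------------------------------------------------------------------------

#' Read genotypes from a VCF file
#'
#' Parses a (plain or bgzipped) VCF and returns dosages. The DS FORMAT field
#' is used when present (imputed data); otherwise dosage is the additive GT
#' encoding, i.e. the count of ALT alleles. Missing genotypes are retained
#' as `NA` and mean-imputed per variant only at test time, so allele
#' frequencies stay faithful to the observed data.
#'
#' @param path path to a VCF file.
#' @param maf_min minimum minor allele frequency; variants below it are
#'   dropped (computed on non-missing dosages).
#' @param biallelic_only drop records with more than one ALT allele.
#' @return A `genotype_matrix`; attributes `n_kept` and `n_dropped` report
#'   the variant filtering outcome.
#' @export
read_genotypes <- function(path, maf_min = 0.05, biallelic_only = TRUE) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("malformed VCF '", path, "': ",
                                           conditionMessage(e)))
  fx <- vcf@fix
  n_total <- nrow(fx)
  if (n_total == 0) stop("VCF contains no variant records")
  keep <- rep(TRUE, n_total)
  if (biallelic_only) keep <- keep & !grepl(",", fx[, "ALT"], fixed = TRUE)
  ids <- fx[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fx[noid, "CHROM"], ":", fx[noid, "POS"])

  fmt <- vcf@gt[, 1]
  has_ds <- all(grepl("(^|:)DS(:|$)", fmt))
  if (has_ds) {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    ds <- apply(gt, 2, gt_to_dosage)
    dim(ds) <- dim(gt); dimnames(ds) <- dimnames(gt)
  }
  ds <- t(ds)  # samples x variants
  maf <- apply(ds, 2, dosage_maf)
  keep <- keep & !is.na(maf) & maf >= maf_min
  if (!any(keep)) {
    res <- structure(list(empty = TRUE, n_kept = 0L, n_dropped = n_total),
                     class = c("empty_genotypes", "list"))
    warning("no variants survive the MAF/biallelic filters")
    return(res)
  }
  g <- genotype_matrix(ds[, keep, drop = FALSE], variant_id = ids[keep],
                       chrom = fx[keep, "CHROM"],
                       pos = as.integer(fx[keep, "POS"]),
                       sample_id = colnames(vcf@gt)[-1])
  attr(g, "n_kept") <- sum(keep)
  attr(g, "n_dropped") <- n_total - sum(keep)
  g
}

gt_to_dosage <- function(gt) {
  a <- sub("^([^:]*).*$", "\\1", gt)
  out <- rep(NA_real_, length(a))
  known <- c("0/0" = 0, "0|0" = 0, "0/1" = 1, "1/0" = 1, "0|1" = 1,
             "1|0" = 1, "1/1" = 2, "1|1" = 2, "0" = 0, "1" = 1)
  hit <- a %in% names(known)
  out[hit] <- known[a[hit]]
  out
}

#' Read molecular phenotypes from a BED-like TSV
#'
#' Expected layout: a header line, six leading columns
#' `chr start end id gid strand` (BED coordinates, 0-based half-open),
#' then one numeric column per sample. A `gid` of `"."` means the phenotype
#' is its own singleton group.
#'
#' @param path path to the phenotype BED file.
#' @return A `phenotype_set`.
#' @export
read_phenotypes <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t",
                          data.table = FALSE, check.names = FALSE)
  if (ncol(dt) < 7) stop("phenotype BED needs >= 6 leading columns plus samples")
  meta <- dt[, 1:6]
  vals <- as.matrix(dt[, -(1:6), drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(dt[, -(1:6), drop = FALSE], is.numeric, TRUE))[1]
    cell <- which(is.na(suppressWarnings(as.numeric(dt[[6 + bad]]))))[1]
    stop(sprintf("non-numeric phenotype value at row %d, sample column '%s'",
                 cell, colnames(dt)[6 + bad]))
  }
  all_missing <- apply(vals, 1, function(z) all(is.na(z)))
  if (any(all_missing)) {
    warning(sum(all_missing), " phenotype row(s) with all-missing values dropped")
    meta <- meta[!all_missing, , drop = FALSE]
    vals <- vals[!all_missing, , drop = FALSE]
  }
  phenotype_set(t(vals), phenotype_id = meta[[4]], chrom = as.character(meta[[1]]),
                start = meta[[2]], end = meta[[3]], strand = as.character(meta[[6]]),
                group_id = as.character(meta[[5]]),
                sample_id = colnames(dt)[-(1:6)])
}

#' Write a phenotype set in the BED-like TSV layout read by
#' [read_phenotypes()]
#' @param p a `phenotype_set`.
#' @param path output path.
#' @export
write_phenotypes <- function(p, path) {
  ph <- p$phenotypes
  gid <- ifelse(ph$group_id == ph$phenotype_id, ".", ph$group_id)
  out <- data.frame(`#chr` = ph$chrom, start = ph$start, end = ph$end,
                    id = ph$phenotype_id, gid = gid, strand = ph$strand,
                    check.names = FALSE)
  out <- cbind(out, as.data.frame(t(p$values)))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read covariates from a TSV (covariate x sample)
#'
#' First column holds covariate ids; remaining columns are samples.
#' @param path input path.
#' @return A `covariate_set`.
#' @export
read_covariates <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t",
                          data.table = FALSE, check.names = FALSE)
  vals <- as.matrix(dt[, -1, drop = FALSE])
  covariate_set(t(vals), covariate_id = as.character(dt[[1]]),
                sample_id = colnames(dt)[-1])
}

#' Write covariates in the TSV layout read by [read_covariates()]
#' @param covariates a `covariate_set`.
#' @param path output path.
#' @export
write_covariates <- function(covariates, path) {
  out <- data.frame(id = covariates$covariate_id,
                    as.data.frame(t(covariates$values)), check.names = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read an annotation track from a BED file (chrom, start, end, label)
#' @param path input path (no header).
#' @return An `annotation_track`.
#' @export
read_annotations <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          data.table = FALSE)
  if (ncol(dt) < 4) stop("annotation BED needs 4 columns: chrom,start,end,label")
  annotation_track(as.character(dt[[1]]), dt[[2]], dt[[3]], as.character(dt[[4]]))
}

#' Write an annotation track as 4-column BED
#' @param track an `annotation_track`.
#' @param path output path.
#' @export
write_annotations <- function(track, path) {
  data.table::fwrite(as.data.frame(track)[, c("chrom", "start", "end", "label")],
                     path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read per-site allele read counts (variant, sample, ref_count, alt_count)
#' @param path input TSV path with header.
#' @return An `allele_count_table`.
#' @export
read_allele_counts <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
  allele_count_table(as.character(dt[[1]]), as.character(dt[[2]]),
                     dt[[3]], dt[[4]])
}

#' Write an allele count table as TSV
#' @param counts an `allele_count_table`.
#' @param path output path.
#' @export
write_allele_counts <- function(counts, path) {
  data.table::fwrite(as.data.frame(counts), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write a genotype matrix as a minimal VCF (GT encoded from rounded dosage)
#'
#' Intended for simulator output; hard dosages only.
#' @param g a `genotype_matrix`.
#' @param path output path.
#' @export
write_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", g$sample_id), collapse = "\t")), con)
  code <- c("0/0", "0/1", "1/1")
  d <- round(g$dosages)
  for (j in seq_len(nrow(g$variants))) {
    gt <- ifelse(is.na(d[, j]), "./.", code[d[, j] + 1])
    writeLines(paste(c(g$variants$chrom[j], g$variants$pos[j],
                       g$variants$variant_id[j], "A", "G", ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}
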