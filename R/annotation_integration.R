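# ---------------------------------------------------------------------------
# Integration of QTLs with functional annotations: binned density of
# annotations around QTL positions, and an enrichment test comparing the
# observed QTL-annotation overlap frequency with the frequency expected
# after permuting annotation lists across phenotypes.
# ---------------------------------------------------------------------------

# A 1-based variant position p overlaps a 0-based half-open interval
# [s, e) iff s < p <= e.
point_in_intervals <- function(pos, start, end) {
  any(start < pos & pos <= end)
}

#' Density of annotations around QTL positions
#'
#' For every QTL, annotations within `window` bp are enumerated and each
#' contributes +1 to every `bin`-bp bin it overlaps (half-open interval vs
#' bin semantics); profiles are summed over QTLs, indexed by signed offset
#' from the QTL position.
#'
#' @param qtl_chrom,qtl_pos QTL coordinates (1-based positions).
#' @param track an `annotation_track`.
#' @param window half-width in bp (default 1 Mb); must be divisible by
#'   `bin`.
#' @param bin bin width in bp (default 1 kb).
#' @return data.frame `offset` (bin start relative to the QTL position)
#'   and `count`.
#' @export
annotation_density <- function(qtl_chrom, qtl_pos, track, window = 1e6,
                               bin = 1000) {
  stopifnot(window %% bin == 0, length(qtl_chrom) == length(qtl_pos))
  nb <- as.integer(2 * window / bin)
  counts <- integer(nb)
  offsets <- seq(-window, window - bin, by = bin)
  for (k in seq_along(qtl_pos)) {
    sel <- track$chrom == qtl_chrom[k] &
      track$end > qtl_pos[k] - window & track$start < qtl_pos[k] + window
    if (!any(sel)) next
    s <- track$start[sel] - qtl_pos[k]  # annotation rel. to QTL
    e <- track$end[sel] - qtl_pos[k]
    for (a in seq_along(s)) {
      first <- max(1L, as.integer(floor((s[a] + window) / bin)) + 1L)
      last <- min(nb, as.integer(ceiling((e[a] + window) / bin)))
      if (last >= first) counts[first:last] <- counts[first:last] + 1L
    }
  }
  data.frame(offset = offsets, count = counts)
}

# Annotation lists per phenotype: annotations within +/- window of the
# anchor, stored as offsets relative to the anchor so a list can be
# re-anchored on another phenotype during permutation.
annotation_lists <- function(p, track, window = 1e6) {
  anchors <- phenotype_anchor(p$phenotypes)
  lapply(seq_len(nrow(p$phenotypes)), function(i) {
    sel <- track$chrom == p$phenotypes$chrom[i] &
      track$end > anchors[i] - window & track$start < anchors[i] + window
    list(start = track$start[sel] - anchors[i],
         end = track$end[sel] - anchors[i])
  })
}

#' Permutation enrichment of QTLs within functional annotations
#'
#' Each of the X phenotypes owns the list of annotations within `window`
#' of its anchor (stored as anchor-relative offsets). For the subset of Y
#' phenotypes with a significant QTL, `f_obs` is the fraction of QTLs
#' whose variant position falls inside at least one annotation of its own
#' phenotype's list. The lists are then permuted across all X phenotypes
#' B times (uniform random label permutation; re-anchored on the receiving
#' phenotype) and the overlap recounted, giving `f_exp`. Observed and
#' expected counts are compared with a two-sided Fisher exact test on the
#' table `[[obs, Y - obs], [sum_exp, B*Y - sum_exp]]`; this permutation
#' preserves both the distribution of annotations and of QTLs around
#' phenotypes.
#'
#' @param p a `phenotype_set` (all X quantified phenotypes).
#' @param qtl_phenotype ids of the Y phenotypes with a significant QTL.
#' @param qtl_pos 1-based variant position of each QTL.
#' @param track an `annotation_track`.
#' @param window half-width in bp for list construction (default 1 Mb).
#' @param B number of permutations (default 1000).
#' @param seed random seed.
#' @return List with `n_phenotypes`, `n_qtls`, `f_obs`, `f_exp`,
#'   `odds_ratio`, `p_two_sided`, `n_permutations`, `table`.
#' @export
annotation_enrichment <- function(p, qtl_phenotype, qtl_pos, track,
                                  window = 1e6, B = 1000, seed = 1) {
  X <- nrow(p$phenotypes)
  qidx <- match(qtl_phenotype, p$phenotypes$phenotype_id)
  if (anyNA(qidx)) stop("QTL phenotype id not found in the phenotype set")
  Y <- length(qidx)
  if (Y == 0) stop("enrichment needs at least one significant QTL")
  lists <- annotation_lists(p, track, window)
  anchors <- phenotype_anchor(p$phenotypes)
  qtl_off <- qtl_pos - anchors[qidx]  # QTL offsets, invariant under permutation
  if (!sum(lengths(lapply(lists, `[[`, "start")))) {
    return(list(n_phenotypes = X, n_qtls = Y, f_obs = 0, f_exp = 0,
                odds_ratio = NA_real_, p_two_sided = 1, n_permutations = B,
                table = matrix(0, 2, 2)))
  }
  overlap_count <- function(assign) {
    # assign[i]: which phenotype's list phenotype i carries
    sum(vapply(seq_len(Y), function(k) {
      l <- lists[[assign[qidx[k]]]]
      point_in_intervals(qtl_off[k], l$start, l$end)
    }, logical(1)))
  }
  obs <- overlap_count(seq_len(X))
  exp_counts <- with_seed(unit_seed(seed, "fenrich"),
                          vapply(seq_len(B),
                                 function(b) overlap_count(sample.int(X)),
                                 numeric(1)))
  exp_total <- sum(exp_counts)
  tab <- matrix(c(obs, Y - obs, exp_total, B * Y - exp_total), 2,
                byrow = TRUE)
  orr <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  pv <- fisher.test(tab)$p.value
  list(n_phenotypes = X, n_qtls = Y, f_obs = obs / Y,
       f_exp = exp_total / (B * Y), odds_ratio = orr, p_two_sided = pv,
       n_permutations = B, table = tab)
}
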