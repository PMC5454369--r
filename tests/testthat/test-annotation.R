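test_that("density counts annotation-bin overlaps around QTLs", {
  # one QTL at 10,000; annotation [9999, 10001) straddles the centre
  tr <- annotation_track("1", 9999, 10001, "a")
  d <- annotation_density("1", 10000, tr, window = 2000, bin = 1000)
  expect_equal(nrow(d), 4)
  expect_equal(d$offset, c(-2000, -1000, 0, 1000))
  expect_equal(d$count, c(0, 1, 1, 0))
  # an annotation spanning 3 bins adds 1 to each
  tr2 <- annotation_track("1", 9000, 11200, "a")
  d2 <- annotation_density("1", 10000, tr2, window = 2000, bin = 1000)
  expect_equal(d2$count, c(0, 1, 1, 1))
  expect_equal(sum(d2$count), 3)
})

test_that("uniform random annotations give a flat density profile", {
  set.seed(60)
  qtl_pos <- sample(2e5:8e5, 1000, replace = TRUE)
  s <- sample(1:1e6, 10000, replace = TRUE)
  tr <- annotation_track(rep("1", 10000), s, s + 100, rep("a", 10000))
  d <- annotation_density(rep("1", 1000), qtl_pos, tr, window = 20000,
                          bin = 2000)
  expect_lt(max(d$count) / min(d$count), 1.5)
})

test_that("constructed enrichment yields f_obs 1 and a huge odds ratio", {
  set.seed(61)
  X <- 40
  anchors0 <- seq(1e5, by = 1e5, length.out = X)
  p <- phenotype_set(matrix(rnorm(3 * X), 3, X), sprintf("p%02d", 1:X),
                     rep("1", X), anchors0, anchors0 + 1,
                     sample_id = paste0("S", 1:3))
  qidx <- 1:10
  qpos <- anchors0[qidx] + 1 + 500
  # annotations exactly at the QTLs of the significant phenotypes
  tr <- annotation_track(rep("1", 10), qpos - 1, qpos + 1, rep("a", 10))
  en <- annotation_enrichment(p, sprintf("p%02d", qidx), qpos, tr,
                              window = 5e4, B = 200, seed = 1)
  expect_equal(en$f_obs, 1)
  expect_lt(en$f_exp, 0.5)
  expect_gt(en$odds_ratio, 5)
  expect_lt(en$p_two_sided, 1e-4)
})

test_that("identical annotation lists are exchangeable: f_obs equals f_exp", {
  X <- 20
  anchors0 <- seq(1e5, by = 1e5, length.out = X)
  p <- phenotype_set(matrix(rnorm(3 * X), 3, X), sprintf("p%02d", 1:X),
                     rep("1", X), anchors0, anchors0 + 1,
                     sample_id = paste0("S", 1:3))
  # same offsets near every phenotype: permutation changes nothing
  tr <- annotation_track(rep("1", X), anchors0 + 200, anchors0 + 400,
                         rep("a", X))
  qidx <- seq(1, X, by = 2)
  # half the QTLs inside the shared interval, half outside
  qpos <- anchors0[qidx] + 1 + rep(c(300, 600), length.out = length(qidx))
  en <- annotation_enrichment(p, sprintf("p%02d", qidx), qpos, tr,
                              window = 5e4, B = 100, seed = 2)
  expect_equal(en$f_obs, en$f_exp)
  expect_equal(en$odds_ratio, 1)
})

test_that("enrichment matches a brute-force contingency oracle", {
  set.seed(62)
  X <- 30; Y <- 10; B <- 200
  anchors0 <- sort(sample(1:5e6, X))
  p <- phenotype_set(matrix(rnorm(3 * X), 3, X), sprintf("p%02d", 1:X),
                     rep("1", X), anchors0, anchors0 + 1,
                     sample_id = paste0("S", 1:3))
  s <- sample(1:5e6, 150)
  tr <- annotation_track(rep("1", 150), s, s + sample(100:2000, 150, TRUE),
                         rep("a", 150))
  qidx <- sample(X, Y)
  qpos <- anchors0[qidx] + 1 + sample(-2e4:2e4, Y, TRUE)
  en <- annotation_enrichment(p, sprintf("p%02d", qidx), qpos, tr,
                              window = 5e4, B = B, seed = 7)

  # oracle: recompute obs and the permutation-expected count by explicit
  # loops over phenotypes, annotations and permutations
  anchors1 <- anchors0 + 1
  lists <- lapply(1:X, function(i) {
    sel <- tr$end > anchors1[i] - 5e4 & tr$start < anchors1[i] + 5e4
    cbind(tr$start[sel] - anchors1[i], tr$end[sel] - anchors1[i])
  })
  overlap1 <- function(off, l) {
    if (!nrow(l)) return(FALSE)
    any(l[, 1] < off & off <= l[, 2])
  }
  offs <- qpos - anchors1[qidx]
  obs_oracle <- sum(mapply(function(o, i) overlap1(o, lists[[i]]),
                           offs, qidx))
  exp_oracle <- 0
  perm_env <- new.env()
  assign <- molqtl:::with_seed(molqtl:::unit_seed(7, "fenrich"),
                               replicate(B, sample.int(X)))
  for (b in 1:B) {
    ab <- assign[, b]
    exp_oracle <- exp_oracle +
      sum(mapply(function(o, i) overlap1(o, lists[[ab[i]]]), offs, qidx))
  }
  tab_oracle <- matrix(c(obs_oracle, Y - obs_oracle,
                         exp_oracle, B * Y - exp_oracle), 2, byrow = TRUE)
  ft <- fisher.test(tab_oracle)
  expect_equal(en$f_obs, obs_oracle / Y)
  expect_equal(en$f_exp, exp_oracle / (B * Y))
  expect_equal(en$p_two_sided, ft$p.value)
  expect_equal(en$odds_ratio,
               tab_oracle[1, 1] * tab_oracle[2, 2] /
                 (tab_oracle[1, 2] * tab_oracle[2, 1]))
})

test_that("permutation preserves both marginal distributions", {
  # the multiset of list sizes and the QTL offsets never change: a direct
  # consequence of permuting whole lists, checked on the list machinery
  set.seed(63)
  X <- 15
  anchors0 <- sort(sample(1:1e6, X))
  p <- phenotype_set(matrix(rnorm(3 * X), 3, X), sprintf("p%02d", 1:X),
                     rep("1", X), anchors0, anchors0 + 1,
                     sample_id = paste0("S", 1:3))
  s <- sample(1:1e6, 60)
  tr <- annotation_track(rep("1", 60), s, s + 500, rep("a", 60))
  lists <- molqtl:::annotation_lists(p, tr, window = 5e4)
  sizes <- sort(lengths(lapply(lists, `[[`, "start")))
  for (i in 1:5) {
    perm <- sample(X)
    expect_equal(sort(lengths(lapply(lists[perm], `[[`, "start"))), sizes)
  }
})

test_that("central enrichment shows up in both density and odds ratio", {
  set.seed(64)
  X <- 60
  anchors0 <- seq(2e5, by = 1e5, length.out = X)
  p <- phenotype_set(matrix(rnorm(3 * X), 3, X), sprintf("p%02d", 1:X),
                     rep("1", X), anchors0, anchors0 + 1,
                     sample_id = paste0("S", 1:3))
  qidx <- 1:30
  qpos <- anchors0[qidx] + 1
  # annotations piled near the QTLs plus sparse background
  s_bg <- sample(1:7e6, 30)
  tr <- annotation_track(rep("1", 60), c(qpos - 250, s_bg),
                         c(qpos + 250, s_bg + 500), rep("a", 60))
  d <- annotation_density(rep("1", 30), qpos, tr, window = 10000, bin = 500)
  centre <- d$count[d$offset %in% c(-500, 0)]
  flank <- d$count[abs(d$offset) > 5000]
  expect_gt(min(centre), max(flank))
  en <- annotation_enrichment(p, sprintf("p%02d", qidx), qpos, tr,
                              window = 5e4, B = 100, seed = 3)
  expect_gt(en$odds_ratio, 1)
})
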