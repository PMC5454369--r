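test_that("group permutation preserves the inner correlation structure", {
  set.seed(20)
  n <- 40
  Y <- matrix(rnorm(n * 5), n)
  Y[, 2] <- Y[, 1]  # two identical members
  idx <- permutation_indices(n, 1, seed = 9, id = "grpA")[, 1]
  Yp <- permute_phenotype(Y, idx)
  expect_identical(Yp[, 1], Yp[, 2])
  expect_equal(cor(Yp), cor(Y), tolerance = 1e-12)
  # determinism: same (seed, id) -> same permutations
  expect_identical(permutation_indices(n, 10, 9, "grpA"),
                   permutation_indices(n, 10, 9, "grpA"))
  expect_false(identical(permutation_indices(n, 10, 9, "grpA"),
                         permutation_indices(n, 10, 9, "grpB")))
})

test_that("scan_best picks the strongest pair with the distance tie rule", {
  set.seed(21)
  n <- 50
  g <- matrix(rbinom(n * 3, 2, 0.4), n, 3)
  g[, 3] <- g[, 1]  # perfect LD copy, further from the anchor
  y <- rnorm(n) + 0.8 * g[, 1]
  gs <- molqtl:::standardize_dosages(g)
  mask <- matrix(TRUE, 3, 1)
  dist_abs <- matrix(c(100, 5000, 9000), 3, 1)
  got <- scan_best(gs, matrix(y), mask, dist_abs, c("a", "b", "c"), "p1",
                   df = n - 2)
  expect_equal(got$variant, "a")  # tie with "c" broken by distance
  # single variant, single phenotype: that pair trivially
  got1 <- scan_best(gs[, 2, drop = FALSE], matrix(y), matrix(TRUE, 1, 1),
                    matrix(0, 1, 1), "b", "p1", df = n - 2)
  expect_equal(got1$variant, "b")
})

test_that("scan_best finds a planted effect against null variants", {
  set.seed(22)
  hits <- 0
  n_rep <- 100
  for (i in seq_len(n_rep)) {
    n <- 200
    g <- matrix(rbinom(n * 100, 2, 0.3), n, 100)
    gstar <- scale(g[, 37])
    # target correlation ~0.9
    y <- as.numeric(0.9 * gstar + sqrt(1 - 0.81) * rnorm(n))
    gs <- molqtl:::standardize_dosages(g)
    got <- scan_best(gs, matrix(y), matrix(TRUE, 100, 1),
                     matrix(0, 100, 1), sprintf("v%03d", 1:100), "p1",
                     df = n - 2)
    if (got$variant == "v037") hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.99)
})

test_that("beta fitting recovers known null distributions", {
  set.seed(23)
  # Uniform(0,1) = Beta(1,1)
  f1 <- fit_beta(runif(10000))
  expect_equal(f1$shape1, 1, tolerance = 0.05)
  expect_equal(f1$shape2, 1, tolerance = 0.05)
  # minimum of 10 iid uniforms ~ Beta(1, 10)
  mins <- apply(matrix(runif(10000 * 10), ncol = 10), 1, min)
  f2 <- fit_beta(mins)
  expect_equal(f2$shape1, 1, tolerance = 0.05)
  expect_equal(f2$shape2, 10, tolerance = 10 * 0.05)
  # correlated tests: effective number of tests below the nominal 50
  n <- 120
  mins_ld <- replicate(400, {
    z <- rnorm(n)
    g <- matrix(rbinom(n * 5, 2, 0.4), n, 5)
    G <- g[, rep(1:5, each = 10)]  # 50 columns, 5 independent
    gs <- molqtl:::standardize_dosages(G)
    r <- molqtl:::corr_matrix(gs, molqtl:::standardize_columns(matrix(z)))
    min(corr_pvalue(abs(r), n - 2))
  })
  f3 <- fit_beta(mins_ld)
  expect_lt(f3$shape2, 50)
})

test_that("effective tests grow linearly with the number of independent variants", {
  set.seed(24)
  n <- 100
  shape2 <- vapply(c(5, 10, 20, 40), function(L) {
    mins <- replicate(400, {
      g <- matrix(rbinom(n * L, 2, 0.4), n, L)
      gs <- molqtl:::standardize_dosages(g)
      r <- molqtl:::corr_matrix(gs, molqtl:::standardize_columns(matrix(rnorm(n))))
      min(corr_pvalue(abs(r), n - 2))
    })
    fit_beta(mins)$shape2
  }, numeric(1))
  fit <- lm(shape2 ~ c(5, 10, 20, 40))
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.15)
})

test_that("permutation pass: single-variant scans need no correction", {
  set.seed(25)
  n <- 80
  g <- matrix(rbinom(n, 2, 0.4), n, 1)
  y <- matrix(rnorm(n), n)
  res <- permutation_pass(molqtl:::standardize_dosages(g), y,
                          matrix(TRUE, 1, 1), matrix(0, 1, 1), "v1", "p1",
                          df = n - 2, n_perm = 1000, seed = 5)
  expect_equal(res$p_adjusted, res$p_nominal, tolerance = 0.05)
  expect_equal(res$effective_tests, 1, tolerance = 0.35)
})

test_that("empirical p-value uses the add-one rule", {
  set.seed(26)
  n <- 60
  g <- matrix(rbinom(n * 5, 2, 0.4), n, 5)
  y <- matrix(0.9 * scale(g[, 2]) + 0.3 * rnorm(n), n)
  res <- permutation_pass(molqtl:::standardize_dosages(g), y,
                          matrix(TRUE, 5, 1), matrix(0, 5, 1),
                          paste0("v", 1:5), "p1", df = n - 2,
                          n_perm = 999, seed = 2)
  # observed far below every permutation minimum
  expect_equal(res$p_empirical, 1 / 1000)
})

test_that("group PCA collapse is deterministic and captures shared structure", {
  set.seed(27)
  n <- 200
  # identical members: PC1 is the member itself
  m <- rnorm(n)
  s <- group_pca_collapse(cbind(m, m))
  expect_equal(abs(cor(s, m)), 1, tolerance = 1e-10)
  expect_gt(cor(s, m), 0)  # sign follows the member mean
  # opposite members: all variance on PC1, deterministic sign
  s2 <- group_pca_collapse(cbind(m, -m))
  expect_equal(abs(cor(s2, m)), 1, tolerance = 1e-10)
  expect_identical(s2, group_pca_collapse(cbind(m, -m)))
  # shared latent factor recovered
  u <- rnorm(n)
  Y <- sapply(1:5, function(i) u + rnorm(n, sd = 0.6))
  expect_gt(abs(cor(group_pca_collapse(Y), u)), 0.9)
  expect_error(group_pca_collapse(matrix(1:3, 3, 1)), "M >= 2")
})

test_that("q-values match Benjamini-Hochberg in BH mode and handle edge cases", {
  set.seed(28)
  p <- runif(200)^2
  bh <- qvalues(p, method = "bh")
  # brute-force BH oracle
  o <- order(p)
  q_oracle <- numeric(200)
  q_oracle[o] <- rev(cummin(rev(p[o] * 200 / seq_len(200))))
  expect_equal(bh$qvalue, pmin(q_oracle, 1), tolerance = 1e-12)
  expect_equal(bh$pi0, 1)
  # all p = 1 -> all q = 1
  expect_equal(suppressWarnings(qvalues(rep(1, 50)))$qvalue, rep(1, 50))
  expect_warning(qvalues(rep(0.5, 50)), "fewer than 100")
})

test_that("Storey pi0 estimates the null proportion on a known mixture", {
  set.seed(29)
  p <- c(runif(8000), rbeta(2000, 0.1, 10))
  est <- qvalues(p)
  expect_gt(est$pi0, 0.7)
  expect_lt(est$pi0, 0.9)
  # q monotone non-decreasing in p
  o <- order(p)
  expect_true(all(diff(est$qvalue[o]) >= -1e-12))
})

test_that("grouped and ungrouped schemes coincide for singleton groups", {
  spec <- simulation_spec(n_samples = 60, n_variants = 12,
                          group_sizes = rep(1L, 6))
  sim <- simulate_dataset(spec, seed = 31)
  p <- sim$phenotypes
  p$phenotypes$group_id <- p$phenotypes$phenotype_id
  a <- suppressWarnings(cis_permutation_scan(sim$genotypes, p, n_perm = 100,
                                             seed = 4, grouped = "best"))
  b <- suppressWarnings(cis_permutation_scan(sim$genotypes, p, n_perm = 100,
                                             seed = 4, grouped = "none"))
  expect_identical(a, b)
})
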