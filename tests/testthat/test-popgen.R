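test_that("HWE chi-square matches the hand oracle and exact-proportion cases", {
  ## exactly at HWE proportions: chi2 = 0, P = 1
  g0 <- genotype_counts("p", "s", 25L, 50L, 25L)
  r0 <- hwe_chisq(g0)
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p, 1)
  ## (30, 40, 30): p_hat = 0.5, expected (25, 50, 25), chi2 = 4,
  ## P = exp(-2) at df = 2
  g <- genotype_counts("p", "s", 30L, 40L, 30L)
  r <- hwe_chisq(g)
  expect_equal(r$p_hat, 0.5)
  expect_equal(r$expected, c(25, 50, 25))
  expect_equal(r$chi2, 4)
  expect_equal(r$df, 2L)
  expect_equal(r$p, exp(-2), tolerance = 1e-12)
  r1 <- hwe_chisq(g, df_convention = "standard1")
  expect_equal(r1$df, 1L)
  expect_equal(r1$p, pchisq(4, 1, lower.tail = FALSE))
  ## invariance under allele-label swap
  asym <- hwe_chisq(genotype_counts("p", "s", 50L, 20L, 30L))
  asym_sw <- hwe_chisq(genotype_counts("p", "s", 30L, 20L, 50L))
  expect_equal(asym$chi2, asym_sw$chi2)
  expect_error(hwe_chisq(genotype_counts("p", "s", 10L, 0L, 0L)), "monomorphic")
})

test_that("HWE type-I error sits near the nominal level under null simulation", {
  n <- 200L; p <- 0.3; reps <- 2000L
  g <- simulate_genotypes(sprintf("p%04d", seq_len(reps)), p, 0, n, seed = 123)
  pvals <- vapply(seq_len(reps), function(i)
    tryCatch(hwe_chisq(g[i, ], df_convention = "standard1")$p,
             error = function(e) NA_real_), 0)
  rate <- mean(pvals <= 0.05, na.rm = TRUE)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("pairwise F_ST reproduces its trivial and hand-computed values", {
  a <- genotype_counts("a", "s", 16L, 48L, 36L)  # p = 0.4
  b <- genotype_counts("b", "s", 16L, 48L, 36L)
  expect_equal(fst_pairwise(a, b)$fst, 0)
  fixed_a <- genotype_counts("a", "s", 100L, 0L, 0L)
  fixed_b <- genotype_counts("b", "s", 0L, 0L, 100L)
  expect_equal(fst_pairwise(fixed_a, fixed_b)$fst, 1)
  ## p = 0.2 vs 0.8: H_S = 0.32, H_T = 0.5, F_ST = 0.36
  p2 <- genotype_counts("a", "s", 4L, 32L, 64L)   # p = 0.2
  p8 <- genotype_counts("b", "s", 64L, 32L, 4L)   # p = 0.8
  r <- fst_pairwise(p2, p8)
  expect_equal(r$h_s, 0.32)
  expect_equal(r$h_t, 0.5)
  expect_equal(r$fst, 0.36)
  ## symmetry
  expect_equal(fst_pairwise(p8, p2)$fst, r$fst)
  ## monomorphic everywhere: undefined, flagged
  mono <- fst_pairwise(genotype_counts("a", "s", 10L, 0L, 0L),
                       genotype_counts("b", "s", 10L, 0L, 0L))
  expect_false(mono$defined)
})

test_that("UPGMA clustering recovers planted blocks and matches the oracle", {
  pops <- sprintf("p%02d", 1:8)
  m <- matrix(0.01, 8, 8, dimnames = list(pops, pops))
  m[1:4, 5:8] <- 0.2; m[5:8, 1:4] <- 0.2
  diag(m) <- 0
  cl <- cluster_populations(m)
  expect_equal(cl$k, 2L)
  expect_equal(unname(cl$subdivisions[1:4]), rep(1L, 4))
  expect_equal(unname(cl$subdivisions[5:8]), rep(2L, 4))
  ## all-zero matrix: one subdivision
  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_equal(cluster_populations(z)$k, 1L)
  expect_error(cluster_populations(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  ## linkage heights match the textbook UPGMA oracle
  set.seed(29)
  for (rep in 1:20) {
    n <- sample(3:6, 1L)
    d <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
    v <- runif(n * (n - 1) / 2)
    d[lower.tri(d)] <- v; d <- d + t(d)
    hc <- cluster_populations(d)$hclust
    expect_equal(sort(hc$height), oracle_upgma_heights(d), tolerance = 1e-12)
  }
})

test_that("the subdivision permutation test is seeded, calibrated and powerful", {
  pops <- sprintf("p%02d", 1:10)
  groups <- setNames(rep(1:2, each = 5L), pops)
  ## deterministic under seed
  g <- simulate_genotypes(pops, c(rep(0.1, 5), rep(0.9, 5)), 0, 200L, seed = 31)
  r1 <- fst_subdivision_permutation(g, groups, n_perm = 500L, seed = 7)
  r2 <- fst_subdivision_permutation(g, groups, n_perm = 500L, seed = 7)
  expect_identical(r1$p_perm, r2$p_perm)
  ## planted subdivision: highly significant
  expect_lte(r1$p_perm, 0.01)
  expect_gt(r1$fst, 0.3)
  ## add-one correction keeps p in (0, 1]
  expect_gt(r1$p_perm, 0)
  expect_lte(r1$p_perm, 1)
  ## few populations: exact enumeration with warning
  small <- simulate_genotypes(sprintf("q%d", 1:4), 0.5, 0, 50L, seed = 32)
  gr <- setNames(c(1L, 1L, 2L, 2L), small$population)
  expect_warning(rs <- fst_subdivision_permutation(small, gr, n_perm = 100L),
                 "enumerating")
  expect_equal(rs$n_perm, choose(4, 2))
})

test_that("permutation p-values are approximately uniform under the null", {
  ## 12 populations: enough distinct label permutations that ties with the
  ## observed partition are rare and the test is close to exact
  pops <- sprintf("p%02d", 1:12)
  groups <- setNames(rep(1:2, each = 6L), pops)
  reps <- 400L
  pv <- vapply(seq_len(reps), function(i) {
    g <- simulate_genotypes(pops, 0.4, 0, 100L, seed = 5000L + i)
    fst_subdivision_permutation(g, groups, n_perm = 199L, seed = i)$p_perm
  }, 0)
  frac <- mean(pv <= 0.05)
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.09)
})
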