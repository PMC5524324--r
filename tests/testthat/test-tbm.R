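# Voxel-wise t-maps, exhaustive permutation p-values, FDR masking and
# direction maps.

groups47 <- function() rep(c("mptp", "control"), c(7, 4))

test_that("voxel t equals the textbook pooled two-sample t", {
  set.seed(101)
  X <- matrix(rnorm(11 * 200), 11, 200)
  r <- perm_ttest_matrix(X, factor(groups47(), c("mptp", "control")))
  for (v in sample(200, 20)) {
    expect_equal(r$t[v], oracle_t(X[1:7, v], X[8:11, v]),
                 tolerance = 1e-10)
  }
})

test_that("identical subjects give p = 1 everywhere and are flagged", {
  X <- matrix(rep(rnorm(40), each = 11), 11, 40)
  r <- suppressWarnings(perm_ttest_matrix(X, groups47()))
  expect_true(all(r$p == 1))
  expect_equal(r$zero_variance, 40)
})

test_that("the 4 vs 7 design enumerates exactly 330 relabelings", {
  set.seed(5)
  X <- matrix(rnorm(11 * 30), 11, 30)
  r <- perm_ttest_matrix(X, groups47())
  expect_true(r$exact)
  expect_equal(r$n_perm, choose(11, 4))
  expect_true(all(r$p >= 1 / 330))
  expect_true(all(abs(r$p * 330 - round(r$p * 330)) < 1e-9))
  # exhaustive mode ignores the seed entirely
  r2 <- perm_ttest_matrix(X, groups47(), seed = 999L)
  expect_identical(r$p, r2$p)
})

test_that("permutation p matches brute-force enumeration, incl. separation", {
  set.seed(42)
  # generic columns
  X <- matrix(rnorm(11 * 8), 11, 8)
  # a completely separated column: all group-A values below all group-B
  X <- cbind(X, c(sort(rnorm(7, 10, 1)), sort(rnorm(4, 0, 1))))
  r <- perm_ttest_matrix(X, factor(groups47(), c("mptp", "control")))
  for (v in seq_len(ncol(X))) {
    # oracle enumerates 7-subsets as its group A, first 7 rows observed
    expect_equal(r$p[v], oracle_perm_p(X[, v], 7), tolerance = 1e-12)
  }
  expect_lte(r$p[9], 2 / 330)
})

test_that("Monte-Carlo mode is used beyond the cap and is seed-stable", {
  set.seed(7)
  X <- matrix(rnorm(11 * 20), 11, 20)
  r <- perm_ttest_matrix(X, groups47(), exhaustive_cap = 100, n_mc = 400,
                         seed = 3L)
  expect_false(r$exact)
  expect_true(all(r$p >= 1 / 401))
  r2 <- perm_ttest_matrix(X, groups47(), exhaustive_cap = 100, n_mc = 400,
                          seed = 3L)
  expect_identical(r$p, r2$p)
  rex <- perm_ttest_matrix(X, groups47())
  expect_lt(max(abs(r$p - rex$p)), 0.12)
})

test_that("BH masking equals the brute-force step-up on random vectors", {
  expect_equal(sum(fdr_mask(c(0.001, 0.01, 0.02, 0.03, 0.5), 0.05)), 4)
  expect_equal(sum(fdr_mask(rep(1, 50), 0.05)), 0)
  # the all-p-equal corner case, judged by the oracle rather than a priori
  p_eq <- rep(1 / 330, 1000)
  expect_identical(fdr_mask(p_eq, 0.05), oracle_bh(p_eq, 0.05))
  set.seed(11)
  for (i in 1:1000) {
    m <- sample(1:40, 1)
    p <- round(runif(m)^sample(1:3, 1), 3)
    p[p == 0] <- 1e-4
    q <- sample(c(0.01, 0.05, 0.1), 1)
    expect_identical(fdr_mask(p, q), oracle_bh(p, q))
  }
})

test_that("voxelwise maps carry t, p, direction and masks coherently", {
  g <- grid_spec(c(10, 10, 8))
  mask <- array(TRUE, dim = g$shape)
  mask[1, , ] <- FALSE
  set.seed(21)
  base <- array(exp(rnorm(prod(g$shape), 0, 0.05)), dim = g$shape)
  shrunk <- region <- array(FALSE, dim = g$shape)
  region[4:7, 4:7, 3:6] <- TRUE
  maps <- lapply(1:11, function(i) {
    d <- base * exp(array(rnorm(prod(g$shape), 0, 0.02), dim = g$shape))
    if (i <= 7) d[region] <- d[region] * 0.9   # first 7 = treated group
    image_volume(d, g)
  })
  groups <- factor(groups47(), c("mptp", "control"))
  res <- tbm_voxelwise(maps, groups, mask)
  expect_true(res$exact)
  expect_equal(res$n_perm, 330)
  expect_true(all(res$p_map$data[mask] >= 1 / 330))
  expect_true(all(res$p_map$data[!mask] == 1))
  # injected 10% shrinkage shows as negative direction inside the region
  expect_true(all(res$direction$data[region & mask] == -1))
  expect_true(all(res$fdr_mask[!mask] == FALSE))
  expect_identical(res$fdr_mask[mask], oracle_bh(res$p_map$data[mask], res$q))

  # direction map is antisymmetric under swapping the groups
  ga <- maps[groups == "mptp"]; gb <- maps[groups == "control"]
  d1 <- direction_map(ga, gb, mask)
  d2 <- direction_map(gb, ga, mask)
  expect_equal(d1$data, -d2$data)
  # identical groups give all-zero direction
  d3 <- direction_map(ga, ga, mask)
  expect_true(all(d3$data == 0))
})

test_that("brain mask excludes skull/background and erodes the border", {
  atlas <- small_atlas()
  bm <- brain_mask(atlas)
  expect_false(any(bm & atlas$labels == 0))
  expect_false(any(bm & atlas$labels == 1))
  expect_lt(sum(bm), sum(atlas$labels >= 2))
})
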