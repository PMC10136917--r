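# Bootstrap settings here are deliberately small (nboots 100-200, coarse
# drop grids) to keep the suite fast; the statistical contracts under test
# do not depend on replicate counts.

test_that("bootstrap replicate stores are seed-reproducible", {
  coh <- small_cohort(n = 200, seed = 6)
  b1 <- bootstrap_network(coh$responses, nboots = 100, seed = 42,
                          n_lambdas = 40)
  b2 <- bootstrap_network(coh$responses, nboots = 100, seed = 42,
                          n_lambdas = 40)
  expect_identical(b1$edges, b2$edges)
  expect_identical(b1$ei, b2$ei)
  b3 <- bootstrap_network(coh$responses, nboots = 100, seed = 43,
                          n_lambdas = 40)
  expect_false(identical(b1$edges, b3$edges))
})

test_that("edge CIs bracket the bootstrap median and record settings", {
  coh <- small_cohort(n = 200, seed = 6)
  b <- bootstrap_network(coh$responses, nboots = 100, seed = 1,
                         n_lambdas = 40)
  ci <- edge_ci(b)
  med <- apply(b$edges, 2, median)
  expect_true(all(ci$lower <= med + 1e-12))
  expect_true(all(ci$upper >= med - 1e-12))
  expect_true(all(ci$lower <= ci$upper))
  expect_equal(attr(ci, "nboots"), 100L)
  expect_equal(attr(ci, "method"), "percentile")
})

test_that("a cohort without item variance fails loudly", {
  one <- matrix(rep(c(0L, 1L, 2L, 1L), each = 50), 50,
                dimnames = list(NULL, c("a", "b", "c", "d")))
  x <- toy_item_matrix(one)
  expect_error(bootstrap_network(x, nboots = 100, seed = 1),
               "zero variance")
})

test_that("CI width shrinks with sample size", {
  # n = 500 rather than smaller: below that the penalty shrinks weak edges
  # to exact zero in most resamples and their intervals collapse to a point
  net_small <- sample_cohort(generator_spec(n_subjects = 500, seed = 9))
  net_big <- sample_cohort(generator_spec(n_subjects = 2000, seed = 9))
  bs <- bootstrap_network(net_small$responses, nboots = 100, seed = 2,
                          n_lambdas = 40)
  bb <- bootstrap_network(net_big$responses, nboots = 100, seed = 2,
                          n_lambdas = 40)
  truth_edges <- which(abs(net_small$truth$W[upper.tri(net_small$truth$W)])
                       > 1e-10)
  width <- function(b) {
    ci <- edge_ci(b)
    (ci$upper - ci$lower)[truth_edges]
  }
  expect_lt(median(width(bb)), median(width(bs)))
})

test_that("case-dropping at proportion zero reproduces the original metric", {
  coh <- small_cohort(n = 200, seed = 3)
  cs <- cs_coefficient(coh$responses, "expected_influence",
                       drop_proportions = 0, nboots = 10, seed = 5,
                       n_lambdas = 40)
  expect_equal(unname(cs$curve$mean_cor), 1, tolerance = 1e-12)
  expect_true(all(cs$correlations == 1))
})

test_that("CS is nonincreasing in the correlation threshold", {
  coh <- small_cohort(n = 300, seed = 3)
  cs <- cs_coefficient(coh$responses, "expected_influence",
                       drop_proportions = seq(0.1, 0.7, by = 0.2),
                       nboots = 40, seed = 5, n_lambdas = 40)
  expect_lte(cs_at_threshold(cs, 0.8), cs$cs)
  expect_lte(cs_at_threshold(cs, 0.9), cs_at_threshold(cs, 0.8))
  expect_equal(cs_at_threshold(cs, cs$threshold), cs$cs)
})

test_that("CS on a study-scale cohort clears the minimum acceptability bound", {
  coh <- sample_cohort(generator_spec(seed = 3)) # 566 subjects
  cs <- cs_coefficient(coh$responses, "expected_influence",
                       drop_proportions = seq(0.05, 0.45, by = 0.10),
                       nboots = 60, seed = 7, n_lambdas = 60)
  expect_gte(cs$cs, 0.25)
})

test_that("CS grows with cohort size on the same generator", {
  # the smaller cohort must still support a nonempty full-sample network,
  # otherwise the centrality is constant and CS is undefined
  cs_at <- function(n) {
    coh <- sample_cohort(generator_spec(n_subjects = n, seed = 3))
    cs_coefficient(coh$responses, "expected_influence",
                   drop_proportions = seq(0.1, 0.7, by = 0.2),
                   nboots = 40, seed = 7, n_lambdas = 40)$cs
  }
  expect_lte(cs_at(300), cs_at(1000))
})

test_that("duplicated items never differ significantly", {
  set.seed(4)
  base <- small_cohort(n = 250, seed = 10)$responses$values[, 1:5]
  vals <- cbind(base, dup = base[, 1])
  colnames(vals) <- c(colnames(base), "dup")
  comm <- setNames(c(rep("c1", 3), rep("c2", 3)), colnames(vals))
  x <- item_matrix(vals, communities = comm)
  b <- bootstrap_network(x, nboots = 100, seed = 11, n_lambdas = 40)
  dt <- difference_tests(b, "expected_influence")
  expect_false(dt$significant[colnames(base)[1], "dup"])
})

test_that("difference tests are symmetric with an insignificant diagonal", {
  coh <- small_cohort(n = 250, seed = 10)
  b <- bootstrap_network(coh$responses, nboots = 100, seed = 11,
                         n_lambdas = 40)
  for (tgt in c("edges", "expected_influence",
                "bridge_expected_influence")) {
    dt <- difference_tests(b, tgt)
    expect_true(isSymmetric(dt$significant))
    expect_false(any(diag(dt$significant)))
  }
})

test_that("a planted hub's expected influence differs from the periphery", {
  spec <- generator_spec(n_subjects = 2000, planted_bridges = "A7",
                         n_bridge_edges = 5, bridge_weight = 0.2, seed = 15)
  coh <- sample_cohort(spec)
  b <- bootstrap_network(coh$responses, nboots = 100, seed = 21,
                         n_lambdas = 40)
  dt <- difference_tests(b, "expected_influence")
  ei <- expected_influence(b$point)
  hub <- names(which.max(ei))
  peripheral <- names(which.min(ei))
  expect_true(dt$significant[hub, peripheral])
  share <- significant_share(dt, hub)
  expect_gt(unname(share), 0)
})
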