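test_that("degenerate generator settings produce the expected truths", {
  # no cross edges: separated communities, all true BEI zero
  sep <- make_truth_network(generator_spec(cross_density = 0,
                                           planted_bridges = NULL,
                                           seed = 2))
  expect_true(all(sep$bei == 0))

  # no edges at all: identity precision
  ind <- make_truth_network(generator_spec(within_density = 0,
                                           cross_density = 0,
                                           planted_bridges = NULL,
                                           seed = 2))
  expect_equal(ind$K, diag(16), ignore_attr = TRUE)
})

test_that("planted bridges carry the maximal true bridge influence", {
  for (s in 1:5) {
    truth <- make_truth_network(generator_spec(seed = s))
    planted <- truth$bei[truth$bridges]
    others <- truth$bei[setdiff(names(truth$bei), truth$bridges)]
    expect_gt(min(planted), max(others))
  }
})

test_that("truth matrices are internally consistent", {
  truth <- make_truth_network(generator_spec(seed = 4))
  expect_equal(truth$W, precision_to_partial(truth$K), tolerance = 1e-12)
  ev <- eigen(truth$K, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 0.05 - 1e-10)
  expect_equal(diag(truth$Sigma), setNames(rep(1, 16), rownames(truth$K)),
               tolerance = 1e-12)
  expect_true(all(truth$predictability >= 0 & truth$predictability < 1))
})

test_that("cohorts have the study shape, range and determinism", {
  spec <- generator_spec(seed = 11)
  coh <- sample_cohort(spec)
  expect_equal(dim(coh$responses$values), c(566L, 16L))
  expect_true(all(coh$responses$values %in% 0:3))
  expect_equal(unname(table(coh$responses$communities)),
               c(7L, 9L), ignore_attr = TRUE)
  coh2 <- sample_cohort(generator_spec(seed = 11))
  expect_identical(coh$responses$values, coh2$responses$values)
  coh3 <- sample_cohort(generator_spec(seed = 12))
  expect_false(identical(coh$responses$values, coh3$responses$values))
})

test_that("observed marginals match the threshold-implied analytic moments", {
  spec <- generator_spec(n_subjects = 50000, seed = 19)
  coh <- sample_cohort(spec)
  obs_mean <- colMeans(coh$responses$values)
  for (it in spec$items) {
    mm <- discretized_moments(spec$thresholds[[it]])
    expect_lt(abs(obs_mean[[it]] - mm$mean), 0.03)
  }
})

test_that("threshold calibration hits target means closely", {
  marg <- default_item_marginals()
  spec <- generator_spec(seed = 1)
  for (i in seq_len(nrow(marg))) {
    mm <- discretized_moments(spec$thresholds[[marg$item[i]]])
    expect_lt(abs(mm$mean - marg$mean[i]), 0.005)
    expect_lt(abs(mm$sd - marg$sd[i]), 0.15)
  }
})

test_that("recovery report is exact when the estimate equals the truth", {
  coh <- sample_cohort(generator_spec(seed = 5))
  truth_net <- symptom_network(coh$truth$W,
                               communities = coh$truth$communities)
  r <- recovery_report(coh, truth_net)
  expect_equal(r$rmse, 0)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_equal(r$n_true_edges, r$n_estimated_edges)
  expect_equal(r$bridge_hit_rate, 1)

  bad <- symptom_network(coh$truth$W[c(2:16, 1), c(2:16, 1)],
                         communities = coh$truth$communities)
  expect_error(recovery_report(coh, symptom_network(
    matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3])))),
    "labels")
})

test_that("independence truths yield highly specific estimates", {
  specs <- sapply(1:5, function(s) {
    coh <- sample_cohort(generator_spec(n_subjects = 1000,
                                        within_density = 0,
                                        cross_density = 0,
                                        planted_bridges = NULL, seed = s))
    net <- estimate_network(coh$responses)
    recovery_report(coh, net)$specificity
  })
  expect_true(all(specs >= 0.95))
})

test_that("discretization attenuates estimated edge weights", {
  spec <- generator_spec(n_subjects = 5000, seed = 23)
  coh <- sample_cohort(spec)
  net_disc <- estimate_network(coh$responses)
  set.seed(77)
  Z <- MASS::mvrnorm(5000, rep(0, 16), coh$truth$Sigma)
  colnames(Z) <- spec$items
  R <- cor(Z, method = "spearman")
  cm <- nearest_psd(cor_matrix(R, n = 5000,
                               communities = spec$communities))
  net_lat <- estimate_network(cm)
  ut <- upper.tri(coh$truth$W)
  true_edge <- abs(coh$truth$W[ut]) > 1e-10
  expect_lt(median(abs(net_disc$W[ut][true_edge])),
            median(abs(net_lat$W[ut][true_edge])))
})

test_that("estimated expected influence tracks the truth ranking", {
  for (s in 1:5) {
    coh <- sample_cohort(generator_spec(n_subjects = 5000, seed = s))
    net <- estimate_network(coh$responses)
    expect_gte(recovery_report(coh, net)$ei_rank_cor, 0.8)
  }
})

test_that("exported cohorts round-trip through validation", {
  coh <- small_cohort(n = 40, seed = 6)
  dir <- withr::local_tempdir()
  paths <- write_cohort(coh, dir)
  raw <- read.csv(file.path(dir, "cohort.csv"), check.names = FALSE)
  x <- validate_responses(raw, list(phq9(), gad7()), id_col = "subject")
  expect_equal(unname(x$values), unname(coh$responses$values))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_setequal(unlist(truth$bridges), coh$truth$bridges)
  expect_equal(length(truth$edges),
               sum(coh$truth$W[upper.tri(coh$truth$W)] != 0))
})
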