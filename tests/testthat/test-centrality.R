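test_that("expected influence is the signed edge sum", {
  net <- toy_net3() # AB = 0.5, AC = -0.2
  expect_equal(expected_influence(net), c(A = 0.3, B = 0.5, C = -0.2))

  empty <- symptom_network(matrix(0, 3, 3,
    dimnames = list(letters[1:3], letters[1:3])))
  expect_equal(unname(expected_influence(empty)), rep(0, 3))

  # all-positive node: expected influence equals strength
  pos <- net_from_edges(c("a", "b", "c"),
                        list(list("a", "b", 0.4), list("a", "c", 0.1)))
  expect_equal(expected_influence(pos)[["a"]],
               sum(abs(pos$W["a", ])))
})

test_that("bridge expected influence sums cross-community edges only", {
  labs <- c("d1", "d2", "a1", "a2")
  comm <- setNames(c("dep", "dep", "anx", "anx"), labs)
  net <- net_from_edges(labs, list(list("d1", "d2", 0.5),
                                   list("a1", "a2", 0.3),
                                   list("d2", "a1", 0.4)), comm)
  bei <- bridge_expected_influence(net)
  expect_equal(bei, c(d1 = 0, d2 = 0.4, a1 = 0.4, a2 = 0))

  # no cross edges -> all zero
  sep <- net_from_edges(labs, list(list("d1", "d2", 0.5),
                                   list("a1", "a2", 0.3)), comm)
  expect_equal(unname(bridge_expected_influence(sep)), rep(0, 4))

  # EI - BEI equals the within-community signed degree
  ei <- expected_influence(net)
  within <- ei - bei
  expect_equal(within, c(d1 = 0.5, d2 = 0.5, a1 = 0.3, a2 = 0.3))

  nc <- symptom_network(net$W)
  expect_error(bridge_expected_influence(nc), "community")
})

test_that("centrality sums satisfy the signed handshake identities", {
  set.seed(31)
  for (rep in 1:5) {
    p <- 6
    W <- matrix(0, p, p)
    W[upper.tri(W)] <- runif(p * (p - 1) / 2, -0.2, 0.3) *
      rbinom(p * (p - 1) / 2, 1, 0.6)
    W <- W + t(W)
    dimnames(W) <- list(paste0("n", 1:p), paste0("n", 1:p))
    comm <- setNames(rep(c("x", "y"), each = 3), rownames(W))
    net <- symptom_network(W, communities = comm)
    expect_equal(sum(expected_influence(net)),
                 2 * sum(W[upper.tri(W)]))
    cross <- outer(comm, comm, `!=`) & upper.tri(W)
    expect_equal(sum(bridge_expected_influence(net)), 2 * sum(W[cross]))
  }
})

test_that("the 80th-percentile rule selects 3 of 16 distinct scores", {
  bei <- setNames(seq(0.01, 0.16, by = 0.01), paste0("n", 1:16))
  sel <- select_bridges(bei)
  # oracle: threshold interpolates between the 13th and 14th order
  # statistics, so exactly the top three scores qualify
  expect_setequal(sel, c("n14", "n15", "n16"))

  # degenerate tie: everyone is at the threshold
  flat <- setNames(rep(0.2, 5), paste0("n", 1:5))
  expect_setequal(select_bridges(flat), names(flat))
})

test_that("bridge selection is monotone in a node's own score", {
  set.seed(13)
  for (rep in 1:20) {
    bei <- setNames(runif(10), paste0("n", 1:10))
    sel <- select_bridges(bei)
    pick <- sample(sel, 1)
    bei2 <- bei
    bei2[pick] <- bei2[pick] + runif(1, 0, 0.5)
    expect_true(pick %in% select_bridges(bei2))
  }
})

test_that("z-standardization matches hand arithmetic and is affine-invariant", {
  v <- c(1, 2, 3, 6)
  z <- z_standardize(v)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  # hand computation: mean 3, sample sd sqrt(14/3)
  expect_equal(z, (v - 3) / sqrt(14 / 3), tolerance = 1e-12)
  expect_equal(z_standardize(5 * v - 2), z, tolerance = 1e-12)
  expect_error(z_standardize(rep(1, 4)), "constant")
})

test_that("flow decomposition layers nodes by BFS hop distance", {
  # star: all nodes direct
  star <- net_from_edges(c("f", "a", "b", "c"),
                         list(list("f", "a", 0.2), list("f", "b", -0.3),
                              list("f", "c", 0.1)))
  fl <- flow_network(star, "f")
  expect_setequal(fl$direct$node, c("a", "b", "c"))
  expect_equal(nrow(fl$indirect), 0L)
  # ranked by |weight|
  expect_equal(fl$direct$node[1], "b")

  # chain a-b-c
  chain <- net_from_edges(c("a", "b", "c"),
                          list(list("a", "b", 0.4), list("b", "c", 0.2)))
  fc <- flow_network(chain, "a")
  expect_equal(fc$direct$node, "b")
  expect_equal(fc$indirect, data.frame(node = "c", layer = 2L))

  # toy with 3 direct, 2 indirect (layers 2 and 3), 1 isolated
  toy <- net_from_edges(c("f", "a", "b", "c", "d", "e", "iso"),
                        list(list("f", "a", 0.3), list("f", "b", 0.2),
                             list("f", "c", -0.1), list("a", "d", 0.2),
                             list("d", "e", 0.4)))
  ft <- flow_network(toy, "f")
  expect_equal(c(nrow(ft$direct), nrow(ft$indirect),
                 length(ft$unreachable)), c(3L, 2L, 1L))
  expect_equal(ft$indirect$layer[ft$indirect$node == "d"], 2L)
  expect_equal(ft$indirect$layer[ft$indirect$node == "e"], 3L)
  expect_equal(ft$unreachable, "iso")

  expect_error(flow_network(toy, "zz"), "not in network")
})

test_that("flow layers equal brute-force BFS distances on random graphs", {
  bfs_dist <- function(A, s) {
    # hand-rolled breadth-first search oracle
    n <- nrow(A); d <- rep(NA_integer_, n); d[s] <- 0L
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(A[v, ] != 0 & is.na(d))
        d[nb] <- d[v] + 1L
        nxt <- c(nxt, nb)
      }
      frontier <- unique(nxt)
    }
    d
  }
  set.seed(99)
  for (rep in 1:10) {
    p <- 8
    W <- matrix(0, p, p)
    W[upper.tri(W)] <- runif(p * (p - 1) / 2, 0.05, 0.3) *
      rbinom(p * (p - 1) / 2, 1, 0.25)
    W <- W + t(W)
    dimnames(W) <- list(paste0("n", 1:p), paste0("n", 1:p))
    net <- symptom_network(W)
    fl <- flow_network(net, "n1")
    d <- bfs_dist(W, 1L)
    expect_setequal(fl$direct$node, rownames(W)[which(d == 1L)])
    for (k in seq_len(nrow(fl$indirect))) {
      expect_equal(fl$indirect$layer[k],
                   d[match(fl$indirect$node[k], rownames(W))])
    }
    expect_setequal(fl$unreachable, rownames(W)[-1][is.na(d[-1])])
    # partition: every non-focal node appears exactly once
    all_nodes <- c(fl$direct$node, fl$indirect$node, fl$unreachable)
    expect_setequal(all_nodes, rownames(W)[-1])
    expect_equal(anyDuplicated(all_nodes), 0L)
  }
})

test_that("centrality profile combines metrics with bridge flags", {
  coh <- small_cohort(n = 400, seed = 1)
  net <- estimate_network(coh$responses)
  prof <- centrality_profile(net)
  expect_equal(prof$node, net$labels)
  expect_equal(mean(prof$ei_z), 0, tolerance = 1e-10)
  expect_equal(sd(prof$bei_z), 1, tolerance = 1e-10)
  expect_equal(prof$is_bridge,
               prof$node %in% select_bridges(
                 bridge_expected_influence(net)))
})
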