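test_that("internal-node move matches the worked example", {
  tr <- timetree(c("A", "B", "C"), c(4L, 4L, 5L, 5L, NA),
                 c(0, 0, 0, 1, 10), c(0.1, 0.2, 0.04, 0.04, NA))
  pr <- propose_internal_node(tr, node = 4L, a = 1)
  expect_true(pr$valid)
  expect_equal(pr$tree$times[4], 2)
  expect_equal(pr$tree$rates[4], 0.045)    # 0.04 * 9 / 8
  expect_equal(pr$tree$rates[1], 0.05)     # 0.1 * 1 / 2
  expect_equal(pr$tree$rates[2], 0.10)     # 0.2 * 1 / 2
  expect_equal(exp(pr$log_green), (9 / 8) * (1 / 2) * (1 / 2))  # 0.28125

  # a = 0 is the identity with ratio 1
  id <- propose_internal_node(tr, node = 4L, a = 0)
  expect_equal(id$log_green, 0)
  expect_equal(id$tree$rates, tr$rates)

  # below the children: reject
  rej <- propose_internal_node(tr, node = 4L, a = -2)
  expect_false(rej$valid)
  expect_error(propose_internal_node(tr, node = 1L), "non-root internal")
})

test_that("simple-distance move matches the worked example", {
  # root at 10 with children at 1 and 0
  fx <- make_fixture("simple_distance")
  pr <- propose_simple_distance(fx$tree, a = 2)
  expect_true(pr$valid)
  expect_equal(exp(pr$log_green), (9 / 11) * (10 / 12))
  expect_equal(propose_simple_distance(fx$tree, a = 0)$log_green, 0)
  expect_false(propose_simple_distance(fx$tree, a = -9.5)$valid)
})

test_that("per-branch distances are conserved to 1e-12 (sweep)", {
  set.seed(31)
  for (i in 1:250) {
    tr <- rand_timetree(7)
    d0 <- branch_distances(tr)
    X <- sample(internal_nodes(tr, include_root = FALSE), 1)
    pr <- propose_internal_node(tr, cfg = operator_config(w = 0.5),
                                node = X)
    if (pr$valid)
      expect_lt(max(abs(branch_distances(pr$tree) - d0)), 1e-12)
    pr2 <- propose_simple_distance(tr, cfg = operator_config(w = 0.5))
    if (pr2$valid)
      expect_lt(max(abs(branch_distances(pr2$tree) - d0)), 1e-12)
  }
})

test_that("small pulley conserves the root distance sum with ratio 1", {
  set.seed(32)
  for (i in 1:250) {
    tr <- rand_timetree(6)
    kids <- tr$children[[tr$root]]
    D0 <- sum(branch_distances(tr)[as.character(kids)])
    pr <- propose_small_pulley(tr, cfg = operator_config(v = 0.2))
    if (pr$valid) {
      expect_identical(pr$log_green, 0)
      expect_lt(abs(sum(branch_distances(pr$tree)[as.character(kids)]) -
                      D0), 1e-12)
    }
  }
  # boundary behaviour
  fx <- make_fixture("small_pulley")
  dL <- branch_distance(fx$tree, fx$tree$children[[fx$tree$root]][1])
  expect_false(propose_small_pulley(fx$tree, b = -dL)$valid)
  expect_true(propose_small_pulley(fx$tree, b = -dL + 1e-6)$valid)
})

test_that("exchange adjusts distances per the re-hang rules", {
  # dS, dM, dN, dC = 0.1, 0.5, 0.2, 0.1 and b = 0.05
  tr <- timetree(c("S", "M", "N"), c(4L, 4L, 5L, 5L, NA),
                 c(0, 0, 0, 2, 5),
                 c(0.1 / 2, 0.5 / 2, 0.2 / 5, 0.1 / 3, NA))
  ex <- exchange_nodes(tr, M = 2L, N = 3L, b = 0.05)
  expect_true(ex$valid)
  expect_equal(ex$d[4], 0.15)              # d_C' = d_C + b
  expect_equal(ex$d[2], 0.35)              # d_M' = d_M - d_C'
  expect_equal(ex$d[3], 0.30)              # d_N' = d_N + d_C
  expect_equal(ex$d[1], 0.10)              # d_S unchanged
  # pairwise distances among S, M, N conserved (paths in the new shape:
  # M hangs at the root, N below C)
  expect_equal(ex$d[1] + ex$d[2] + ex$d[4], 0.1 + 0.5)         # S-M
  expect_equal(ex$d[1] + ex$d[3], 0.1 + 0.1 + 0.2)             # S-N
  expect_equal(ex$d[2] + ex$d[4] + ex$d[3], 0.5 + 0.1 + 0.2)   # M-N
  # boundary: d_C' must stay inside (0, d_C + d_N)
  expect_false(exchange_nodes(tr, 2L, 3L, b = -0.1)$valid)
  expect_true(exchange_nodes(tr, 2L, 3L, b = -0.1 + 1e-9)$valid)
})

test_that("a big-pulley move followed by its mirror restores the state", {
  set.seed(33)
  done <- 0
  while (done < 20) {
    tr <- rand_timetree(7)
    mv <- draw_big_pulley(tr)
    pr <- propose_big_pulley(tr, a = mv$a, a2 = mv$a2, b = mv$b, M = mv$M)
    if (!pr$valid) next
    C <- pr$info$C; N <- pr$info$N
    back <- propose_big_pulley(pr$tree, a = -mv$a, a2 = -mv$a2, b = -mv$b,
                               M = N)
    if (!back$valid) next
    done <- done + 1
    expect_equal(back$tree$parent, tr$parent)
    expect_equal(back$tree$times, tr$times, tolerance = 1e-12)
    expect_equal(back$tree$rates, tr$rates, tolerance = 1e-12)
    # ratio of a reversible pair multiplies to one
    expect_equal(pr$log_green + back$log_green, 0, tolerance = 1e-9)
    expect_equal(pr$info$mu * back$info$mu, 1)
    expect_equal(topology_proposal_ratio(tr, pr$tree), pr$info$mu)
  }
})

test_that("big pulley conserves the tip-pairwise distance matrix", {
  set.seed(34)
  done <- 0
  while (done < 100) {
    tr <- rand_timetree(8)
    m0 <- pairwise_distances(tr)
    pr <- propose_big_pulley(tr, cfg = operator_config(w = 0.4, v = 0.05))
    if (!pr$valid) next
    done <- done + 1
    expect_lt(max(abs(pairwise_distances(pr$tree) - m0)), 1e-10)
    expect_true(validate_timetree(pr$tree))
  }
})

test_that("topology-selection probabilities follow the shape rules", {
  set.seed(35)
  # symmetric <-> symmetric: 0.25 / 0.25 = 1
  done_sym <- FALSE
  while (!done_sym) {
    tr <- rand_timetree(8)
    kids <- tr$children[[tr$root]]
    if (any(vapply(kids, function(k) is_tip(tr, k), TRUE))) next
    mv <- draw_big_pulley(tr)
    if (is_tip(tr, mv$M)) next              # promoted node internal
    pr <- propose_big_pulley(tr, a = mv$a, a2 = mv$a2, b = mv$b, M = mv$M)
    if (!pr$valid) next
    expect_equal(pr$info$mu, 1)
    done_sym <- TRUE
  }
  # asymmetric forced move (elder grandchild must be displaced, prob 1)
  # whose reverse is a free 0.5 choice: mu = 0.5.  The elder grandchild is
  # a heterochronous tip at age 1.5, so forcing requires t_O' < 1.5 and
  # the proposed tree is again asymmetric.
  tr <- timetree(c("Y", "G1", "G2"),
                 parent = c(5L, 4L, 4L, 5L, NA),
                 times = c(0, 1.5, 0, 2.5, 6),
                 rates = c(0.1, 1, 0.1, 0.1, NA))
  pr <- propose_big_pulley(tr, a = 0.5, a2 = -1.2, b = 0.01)
  expect_true(pr$valid)
  expect_identical(pr$info$M, 2L)
  expect_equal(pr$info$mu, 0.5)
  expect_equal(topology_proposal_ratio(tr, pr$tree), 0.5)
  # and the reverse pair gives the reciprocal: 1 / 0.5 = 2
  expect_equal(topology_proposal_ratio(pr$tree, tr), 2)
})

test_that("Green ratios equal finite-difference Jacobians (spot sweep)", {
  set.seed(36)
  checked <- c(internal = 0, simple = 0, big = 0)
  while (min(checked) < 40) {
    tr <- rand_timetree(7)
    if (checked["internal"] < 40) {
      X <- sample(internal_nodes(tr, include_root = FALSE), 1)
      a <- runif(1, -0.2, 0.2)
      pr <- propose_internal_node(tr, node = X, a = a)
      if (pr$valid) {
        expect_equal(fd_green_internal(tr, X, a), exp(pr$log_green),
                     tolerance = 1e-6)
        checked["internal"] <- checked["internal"] + 1
      }
    }
    if (checked["simple"] < 40) {
      a <- runif(1, -0.2, 0.2)
      pr <- propose_simple_distance(tr, a = a)
      if (pr$valid) {
        expect_equal(fd_green_simple_distance(tr, a), exp(pr$log_green),
                     tolerance = 1e-6)
        checked["simple"] <- checked["simple"] + 1
      }
    }
    if (checked["big"] < 40) {
      mv <- draw_big_pulley(tr)
      res <- fd_green_big_pulley(tr, mv$a, mv$a2, mv$b, mv$M)
      if (!is.null(res)) {
        expect_equal(res$fd * res$mu, res$green, tolerance = 1e-6)
        checked["big"] <- checked["big"] + 1
      }
    }
  }
  # small pulley: the rate-map Jacobian is the identity
  tr <- rand_timetree(6)
  f <- fd_green_small_pulley(tr, b = 0.02)
  expect_equal(f, 1, tolerance = 1e-8)
})
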