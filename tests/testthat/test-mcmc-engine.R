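test_that("chains are deterministic given a seed and record the start", {
  fx <- make_fixture("scenario1")
  st <- fixture_state(fx)
  cfg <- operator_config(w = 2)
  mk <- function() run_chain(list(state = st,
                                  schedule = operator_schedule(
                                    op_internal_node(cfg)),
                                  chain_length = 2000, sample_every = 10,
                                  seed = 99))
  r1 <- mk(); r2 <- mk()
  expect_identical(r1$trace, r2$trace)
  expect_equal(r1$trace$Sample[1], 0L)
  # zero-length chain: the initial state only
  r0 <- run_chain(list(state = st,
                       schedule = operator_schedule(op_internal_node(cfg)),
                       chain_length = 0, sample_every = 10))
  expect_equal(nrow(r0$trace), 1L)
})

test_that("config validation lists problems before running", {
  expect_error(run_chain(list(chain_length = 10)), "missing config field")
  fx <- make_fixture("scenario1")
  st <- fixture_state(fx)
  st$mode <- "fixed-distances"
  expect_error(
    run_chain(list(state = st,
                   schedule = operator_schedule(op_rate_walk()),
                   chain_length = 10, sample_every = 1)),
    "distance-changing")
})

test_that("acceptance bookkeeping is complete", {
  fx <- make_fixture("scenario1")
  st <- fixture_state(fx)
  run <- run_chain(list(state = st,
                        schedule = operator_schedule(
                          op_internal_node(operator_config(w = 8)),
                          op_simple_distance(operator_config(w = 8))),
                        chain_length = 3000, sample_every = 100,
                        seed = 3))
  expect_equal(sum(run$counts[, "proposed"]), 3000)
  expect_true(all(run$counts[, "accepted"] + run$counts[, "invalid"] <=
                    run$counts[, "proposed"]))
  expect_true(all(run$counts[, "invalid"] > 0))   # window big enough to
  expect_true(all(run$counts[, "accepted"] > 0))  # hit both outcomes
})

test_that("a flat target with symmetric proposals samples uniformly", {
  # internal scalar Metropolis kernel on a constant density over (0, 1)
  set.seed(44)
  r <- constclock:::mh_scalar(function(x) 0, init = 0.5, lo = 0, hi = 1,
                              w = 0.4, steps = 1e5, thin = 10, burnin = 1e3)
  ks <- suppressWarnings(ks.test(r$samples, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("prior-only engine chain matches the operator's stationary law", {
  # 3-taxon fixture, internal-node kernel alone: the chain must reproduce
  # the quadrature density of the coalescent-times-rates prior on the
  # constant-distance manifold (measure factors included)
  fx <- make_fixture("scenario1")
  st <- fixture_state(fx)
  run <- run_chain(list(state = st,
                        schedule = operator_schedule(
                          op_internal_node(operator_config(w = 2))),
                        chain_length = 4e4, sample_every = 10, seed = 5,
                        keep_trees = TRUE, audit_every = 5000))
  tD <- vapply(run$trees, function(tr) tr$times[4], 1)[-(1:400)]
  oracle <- marginal_internal_node(fx, tree_prior = TRUE,
                                   change_of_var = TRUE)
  rep <- compare_chain_to_oracle(tD, oracle)
  expect_true(rep$pass)
  # the same samples disagree with a deliberately shifted density
  wrong <- fx; wrong$coalescent <- coalescent_prior(3)
  bad <- compare_chain_to_oracle(
    tD, marginal_internal_node(wrong, tree_prior = TRUE,
                               change_of_var = TRUE))
  expect_false(bad$pass)
})

test_that("engine and specialized fixture sampler agree", {
  fx <- make_fixture("scenario1")
  lean <- sample_fixture_prior(fx, steps = 2e5, seed = 6, target = "state")
  st <- fixture_state(fx)
  run <- run_chain(list(state = st,
                        schedule = operator_schedule(
                          op_internal_node(operator_config(w = 2))),
                        chain_length = 3e4, sample_every = 10, seed = 7,
                        keep_trees = TRUE))
  tD <- vapply(run$trees, function(tr) tr$times[4], 1)[-(1:300)]
  se <- sd(tD) / sqrt(as.numeric(effective_sample_size(tD)))
  expect_lt(abs(mean(tD) - mean(lean$samples$t_D)), 4 * se)
})

test_that("ESS: iid, AR(1) and constant series", {
  set.seed(45)
  x <- rnorm(10000)
  ess <- effective_sample_size(x)
  expect_gt(ess, 0.8 * 10000)
  expect_lte(ess, 1.2 * 10000)
  n <- 1e5; rho <- 0.9
  ar <- as.numeric(arima.sim(list(ar = rho), n))
  target <- n * (1 - rho) / (1 + rho)
  expect_lt(abs(as.numeric(effective_sample_size(ar)) - target),
            0.2 * target)
  cst <- effective_sample_size(rep(3.14, 100))
  expect_equal(as.numeric(cst), 1)
  expect_true(attr(cst, "degenerate"))
  expect_error(effective_sample_size(1:5), "at least 10")
})

test_that("audit mode catches a corrupted cache", {
  fx <- make_fixture("scenario1")
  st <- fixture_state(fx)
  st$log_prior <- st$log_prior + 5   # corrupt deliberately
  # a huge window makes every proposal invalid, so the corrupted cache
  # survives to the first audit
  expect_error(
    run_chain(list(state = st,
                   schedule = operator_schedule(
                     op_internal_node(operator_config(w = 1e9))),
                   chain_length = 10, sample_every = 1, seed = 1,
                   audit_every = 1)),
    "audit failure")
})

test_that("trace log is tab-separated with Sample first", {
  fx <- make_fixture("scenario1")
  st <- fixture_state(fx)
  run <- run_chain(list(state = st,
                        schedule = operator_schedule(
                          op_internal_node(operator_config(w = 2))),
                        chain_length = 100, sample_every = 10, seed = 1))
  f <- tempfile()
  write_trace(run, f)
  hdr <- readLines(f, n = 1)
  expect_match(hdr, "^Sample\t")
})
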