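# Reference statistics of the fixture densities, frozen from converged
# quadrature of the fixtures' reference densities (see the methods
# vignette).
REF <- list(
  scenario1       = c(mean = 3.2669, sd = 0.5553),
  scenario2       = c(mean = 0.4667, sd = 0.0262),
  simple_distance = c(mean = 7.8187, sd = 1.2992),
  small_pulley    = c(mean = 0.3476, sd = 0.0494),
  big_pulley_tE   = c(mean = 3.3095, sd = 0.6912))

test_that("fixture densities normalize and are stable to refinement", {
  fx <- make_fixture("scenario1")
  o1 <- marginal_internal_node(fx, grid_n = 2048)
  o2 <- marginal_internal_node(fx, grid_n = 4096)
  expect_true(all(o1$pdf >= 0))
  # tabulated pdf integrates to one
  mass <- sum(diff(o1$x) * (o1$pdf[-1] + o1$pdf[-length(o1$pdf)]) / 2)
  expect_equal(mass, 1, tolerance = 1e-8)
  expect_equal(o1$mean, o2$mean, tolerance = 1e-9)

  # big pulley: grid refinement and truncation doubling
  fb <- make_fixture("big_pulley")
  b1 <- marginal_big_pulley(fb, n_E = 200, n_D = 80, n_Q = 40, t_max = 60)
  b2 <- marginal_big_pulley(fb, n_E = 300, n_D = 120, n_Q = 60,
                            t_max = 120)
  expect_equal(b1$t_E$mean, b2$t_E$mean, tolerance = 1e-6)
  expect_equal(b1$d_D$mean, b2$d_D$mean, tolerance = 1e-6)
})

test_that("root-time oracle: truncation doubling changes nothing", {
  fx <- make_fixture("simple_distance")
  o <- marginal_root_time(fx)
  # re-evaluate with a doubled explicit domain through the raw integrand
  expect_gt(o$settings$upper, 20)
  o2 <- marginal_root_time(fx, grid_n = 2048)
  expect_equal(o$mean, o2$mean, tolerance = 1e-8)
  # Monte-Carlo cross-check by rejection sampling from the tabulated pdf
  set.seed(51)
  n <- 4e4
  x <- sample(o$x, n, replace = TRUE, prob = o$pdf)
  expect_lt(abs(mean(x) - o$mean), 3 * sd(x) / sqrt(n) + 1e-3)
})

test_that("small-pulley marginal: mirror symmetry and symmetric case", {
  fx <- make_fixture("small_pulley")
  oc <- marginal_small_pulley(fx, variable = "d_C")
  od <- marginal_small_pulley(fx, variable = "d_D")
  D <- oc$settings$D
  expect_equal(oc$mean + od$mean, D, tolerance = 1e-9)
  expect_equal(oc$sd, od$sd, tolerance = 1e-9)
  # with equal time spans on both root branches the split is symmetric,
  # so the mean is D/2 regardless of the prior
  sym <- fx; sym$t_D <- 0                   # both spans equal t_E
  osym <- marginal_small_pulley(sym, variable = "d_D")
  expect_equal(osym$mean, D / 2, tolerance = 1e-9)
})

test_that("quadrature reproduces the frozen reference statistics", {
  o1 <- marginal_internal_node(make_fixture("scenario1"))
  expect_equal(o1$mean, REF$scenario1["mean"], tolerance = 2e-4,
               ignore_attr = TRUE)
  expect_equal(o1$sd, REF$scenario1["sd"], tolerance = 2e-4,
               ignore_attr = TRUE)
  o2 <- marginal_internal_node(make_fixture("scenario2"))
  expect_equal(o2$mean, REF$scenario2["mean"], tolerance = 2e-4,
               ignore_attr = TRUE)
  o3 <- marginal_root_time(make_fixture("simple_distance"))
  expect_equal(o3$mean, REF$simple_distance["mean"], tolerance = 1e-3,
               ignore_attr = TRUE)
  o4 <- marginal_small_pulley(make_fixture("small_pulley"))
  expect_equal(o4$mean, REF$small_pulley["mean"], tolerance = 2e-4,
               ignore_attr = TRUE)
})

test_that("each kernel's prior chain matches its oracle (joint check)", {
  # one consistency sweep: the density variant that reproduces the frozen
  # reference statistics is also the one the sampling chains realize
  fx <- make_fixture("scenario1")
  ch <- sample_fixture_prior(fx, steps = 2e5, seed = 52)
  expect_true(compare_chain_to_oracle(ch, marginal_internal_node(fx))$pass)

  fs <- make_fixture("simple_distance")
  ch2 <- sample_fixture_prior(fs, steps = 2e5, seed = 53)
  expect_true(compare_chain_to_oracle(ch2, marginal_root_time(fs))$pass)

  fp <- make_fixture("small_pulley")
  ch3 <- sample_fixture_prior(fp, steps = 2e5, seed = 54)
  expect_true(compare_chain_to_oracle(ch3, marginal_small_pulley(fp))$pass)

  fb <- make_fixture("big_pulley")
  ch4 <- sample_fixture_prior(fb, steps = 4e5, seed = 55)
  ob <- marginal_big_pulley(fb)
  expect_true(compare_chain_to_oracle(ch4, ob$t_E)$pass)
  expect_true(compare_chain_to_oracle(ch4, ob$d_D)$pass)
  # the big pulley visits the three rooted trees uniformly
  tab <- table(ch4$samples$topology)
  expect_equal(length(tab), 3L)
  expect_lt(max(abs(tab / length(ch4$samples$topology) - 1 / 3)), 0.05)

  # negative control: the same chain against a wrong-density oracle fails
  wrong <- fx
  wrong$d["D"] <- 0.54                      # doubled root-side distance
  expect_false(
    compare_chain_to_oracle(ch, marginal_internal_node(wrong))$pass)
  # mismatched fixture identifiers are refused outright
  expect_error(compare_chain_to_oracle(ch2, marginal_internal_node(fx)),
               "fixture mismatch")
})

test_that("state-target chains match the measure-corrected densities", {
  fx <- make_fixture("scenario1")
  ch <- sample_fixture_prior(fx, steps = 2e5, seed = 56, target = "state")
  o <- marginal_internal_node(fx, tree_prior = TRUE, change_of_var = TRUE)
  expect_true(compare_chain_to_oracle(ch, o)$pass)
  fb <- make_fixture("big_pulley")
  ch2 <- sample_fixture_prior(fb, steps = 4e5, seed = 57, target = "state")
  o2 <- marginal_big_pulley(fb, change_of_var = TRUE)
  expect_true(compare_chain_to_oracle(ch2, o2$t_E)$pass)
})

test_that("oracle reports serialize to a summary table", {
  fx <- make_fixture("small_pulley")
  ch <- sample_fixture_prior(fx, steps = 5e4, seed = 58)
  rep <- compare_chain_to_oracle(ch, marginal_small_pulley(fx))
  f <- tempfile()
  df <- write_oracle_report(list(small_pulley = rep), f)
  expect_true(file.exists(f))
  expect_equal(df$fixture, "small_pulley")
})
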