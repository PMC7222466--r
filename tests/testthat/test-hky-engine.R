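test_that("transition matrix limits: identity at d=0, frequencies at d=Inf", {
  m <- hky_model(3.2, c(0.31, 0.18, 0.27, 0.24))
  expect_equal(unname(hky_transition_matrix(m, 0)), diag(4))
  P <- hky_transition_matrix(m, 60)
  expect_equal(unname(P), matrix(unname(m$pi), 4, 4, byrow = TRUE),
               tolerance = 1e-12)
  expect_error(hky_transition_matrix(m, -0.1), ">= 0")
})

test_that("kappa=1 with uniform frequencies collapses to Jukes-Cantor", {
  m <- hky_model(1, rep(0.25, 4))
  for (d in c(0.05, 0.3, 1.2)) {
    P <- hky_transition_matrix(m, d)
    expect_equal(unname(diag(P)), rep(0.25 + 0.75 * exp(-4 * d / 3), 4))
    expect_equal(unname(P[1, 2]), 0.25 - 0.25 * exp(-4 * d / 3))
  }
})

test_that("closed form agrees with a generic matrix exponential", {
  skip_if_not_installed("Matrix")
  set.seed(3)
  for (i in 1:10) {
    m <- hky_model(runif(1, 0.5, 6), rdirich <- {
      g <- rgamma(4, 5); g / sum(g)
    })
    d <- runif(1, 0.01, 4)
    P1 <- hky_transition_matrix(m, d)
    P2 <- as.matrix(Matrix::expm(hky_rate_matrix(m) * d))
    expect_lt(max(abs(unname(P1) - unname(P2))), 1e-10)
    expect_lt(max(abs(rowSums(P1) - 1)), 1e-12)
    # detailed balance of the generator
    Q <- hky_rate_matrix(m)
    expect_lt(max(abs(m$pi * Q - t(m$pi * Q))), 1e-14)
    expect_lt(abs(sum(-m$pi * diag(Q)) - 1), 1e-12)  # unit mean rate
  }
})

test_that("pruning equals brute-force summation over ancestral states", {
  m <- hky_model(2.7, c(0.3, 0.2, 0.2, 0.3))
  tr <- timetree(c("A", "B", "C"), c(4L, 4L, 5L, 5L, NA), c(0, 0, 0, 1, 3),
                 c(0.2, 0.15, 0.1, 0.12, NA))
  aln <- alignment(c("A", "B", "C"), matrix(c("A", "C", "G",
                                              "G", "T", "A"), 3, 2))
  d <- branch_distances(tr)
  b <- c("A", "C", "G", "T")
  Pd <- lapply(c("1", "2", "3", "4"),
               function(k) hky_transition_matrix(m, d[k]))
  brute <- 0
  for (s in 1:2) {
    tot <- 0
    for (x4 in 1:4) for (x5 in 1:4)
      tot <- tot + m$pi[x5] * Pd[[4]][x5, x4] *
        Pd[[3]][x5, match(aln$seqs[3, s], b)] *
        Pd[[1]][x4, match(aln$seqs[1, s], b)] *
        Pd[[2]][x4, match(aln$seqs[2, s], b)]
    brute <- brute + log(tot)
  }
  expect_equal(pruning_log_likelihood(tr, aln, m), unname(brute),
               tolerance = 1e-12)
})

test_that("identical sequences at zero distance score log pi", {
  m <- hky_model(2, c(0.4, 0.2, 0.2, 0.2))
  tr <- timetree(c("A", "B"), c(3L, 3L, NA), c(0, 0, 1),
                 c(1e-300, 1e-300, NA))
  aln <- alignment(c("A", "B"), matrix(c("A", "A"), 2, 1))
  expect_equal(pruning_log_likelihood(tr, aln, m), log(0.4),
               tolerance = 1e-9)
  expect_error(
    pruning_log_likelihood(tr, alignment(c("A", "X"),
                                         matrix(c("A", "A"), 2, 1)), m),
    "taxa differ")
})

test_that("gaps and ambiguity codes act as partial uncertainty", {
  m <- hky_model(2, rep(0.25, 4))
  tr <- timetree(c("A", "B"), c(3L, 3L, NA), c(0, 0, 1),
                 c(0.05, 0.05, NA))
  full <- alignment(c("A", "B"), matrix(c("A", "-"), 2, 1))
  # a gap integrates to 1, so the site reduces to the marginal of 'A'
  expect_equal(pruning_log_likelihood(tr, full, m), log(0.25),
               tolerance = 1e-12)
  r <- alignment(c("A", "B"), matrix(c("A", "R"), 2, 1))
  a <- alignment(c("A", "B"), matrix(c("A", "A"), 2, 1))
  g <- alignment(c("A", "B"), matrix(c("A", "G"), 2, 1))
  expect_equal(exp(pruning_log_likelihood(tr, r, m)),
               exp(pruning_log_likelihood(tr, a, m)) +
                 exp(pruning_log_likelihood(tr, g, m)), tolerance = 1e-12)
})

test_that("likelihood is invariant under re-rooting (pulley property)", {
  set.seed(21)
  m <- hky_model(2.4, c(0.22, 0.23, 0.3, 0.25))
  fb <- make_fixture("big_pulley")
  aln <- simulate_alignment(fb$tree, m, 80, seed = 1)
  l0 <- pruning_log_likelihood(fb$tree, aln, m)
  hits <- 0
  while (hits < 10) {
    pr <- propose_big_pulley(fb$tree, operator_config(w = 2, v = 0.1))
    if (pr$valid) {
      hits <- hits + 1
      expect_lt(abs(pruning_log_likelihood(pr$tree, aln, m) - l0), 1e-10)
    }
  }
})

test_that("simulation is degenerate at d=0 and stationary at large d", {
  m <- hky_model(2, c(0.35, 0.15, 0.2, 0.3))
  tr <- rand_timetree(4)
  tr$rates[setdiff(seq_along(tr$parent), tr$root)] <- 1e-12
  aln <- simulate_alignment(tr, m, 50, seed = 2)
  expect_true(all(apply(aln$seqs, 2, function(col)
    length(unique(col)) == 1L)))
  # long branch: child composition approaches pi
  tr2 <- timetree(c("A", "B"), c(3L, 3L, NA), c(0, 0, 1), c(50, 50, NA))
  a2 <- simulate_alignment(tr2, m, 10000, seed = 3)
  freq <- table(factor(a2$seqs[1, ], c("A", "C", "G", "T"))) / 10000
  se <- sqrt(m$pi * (1 - m$pi) / 10000)
  expect_true(all(abs(freq - m$pi) < 3 * se + 1e-12))
})

test_that("a simulated pairwise distance is recovered by ML", {
  tr <- timetree(c("A", "B"), c(3L, 3L, NA), c(0, 0, 1),
                 c(0.12, 0.08, NA))           # total distance 0.2
  m <- hky_model(2, rep(0.25, 4))
  aln <- simulate_alignment(tr, m, 50000, seed = 9)
  nll <- function(d) {
    t2 <- tr; t2$rates[1] <- d; t2$rates[2] <- 1e-9
    -pruning_log_likelihood(t2, aln, m)
  }
  dhat <- optimize(nll, c(0.01, 1))$minimum
  # Fisher SE of an HKY distance at this length is ~0.002 at 50k sites
  expect_lt(abs(dhat - 0.2), 0.008)
})

test_that("FASTA round-trips an alignment", {
  tr <- rand_timetree(5)
  aln <- simulate_alignment(tr, hky_model(), 30, seed = 4)
  f <- tempfile(fileext = ".fasta")
  write_fasta(aln, f)
  back <- read_fasta(f)
  expect_equal(back$seqs[aln$taxa, ], aln$seqs)
})
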