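#' Quadrature oracles for the prior-sampling fixtures
#'
#' Each `marginal_*` function integrates the joint prior-sampling density of
#' a fixture over its free coordinate(s) and returns a normalized marginal
#' with mean and standard deviation.  Two density conventions are
#' available and must be kept straight:
#'
#' * `change_of_var = FALSE` (default): the density of the implied branch
#'   rates, one log-normal factor per varying-rate branch, optionally times
#'   the coalescent factor (`tree_prior`).  With each fixture's recorded
#'   defaults this is the *reference density* whose moments the sampler
#'   validation compares against, and it is what a Metropolis chain with
#'   symmetric moves on the fixture coordinate samples.
#' * `change_of_var = TRUE`: additionally one `1/dt` factor per varying-rate
#'   branch -- the change of variable from rates to the manifold
#'   coordinate.  This is the exact stationary density of the full
#'   Metropolis-Hastings-Green operator chain (Green ratios included) under
#'   the coalescent-times-rates prior, and is what the operator chains are
#'   property-tested against.
#'
#' @param fx a [make_fixture()] result.
#' @param tree_prior include the coalescent factor?  Defaults to the
#'   fixture's recorded reference setting.
#' @param change_of_var include the rate-to-coordinate `1/dt` factors?
#' @param grid_n grid size of the returned tabulated density.
#' @return An object of class `"prior_marginal"`: `x`, `pdf`, `cdf`,
#'   `mean`, `sd`, `fixture`, `variable`, `settings`.
#' @name prior_oracles
NULL

lnormpdf <- function(x, m, s) -log(x) - log(s) - 0.91893853320467274178 -
  (log(x) - m)^2 / (2 * s^2)

marginal_from_logf <- function(logf, lo, hi, grid_n, fixture, variable,
                               settings) {
  xs <- seq(lo, hi, length.out = 1001)
  peak <- max(logf(xs), na.rm = TRUE)
  f <- function(x) exp(logf(x) - peak)
  Z <- stats::integrate(f, lo, hi, rel.tol = 1e-12, abs.tol = 0,
                        subdivisions = 500L)$value
  m1 <- stats::integrate(function(x) x * f(x), lo, hi, rel.tol = 1e-12,
                         abs.tol = 0, subdivisions = 500L)$value / Z
  m2 <- stats::integrate(function(x) (x - m1)^2 * f(x), lo, hi,
                         rel.tol = 1e-10, abs.tol = 0,
                         subdivisions = 500L)$value / Z
  x <- seq(lo, hi, length.out = grid_n)
  pdf <- f(x) / Z
  cdf <- cumsum(c(0, diff(x) * (pdf[-1] + pdf[-grid_n]) / 2))
  cdf <- pmin(cdf / cdf[grid_n], 1)
  structure(list(x = x, pdf = pdf, cdf = cdf, mean = m1, sd = sqrt(m2),
                 fixture = fixture, variable = variable,
                 settings = settings),
            class = "prior_marginal")
}

#' @export
print.prior_marginal <- function(x, ...) {
  cat("Marginal of", x$variable, "for fixture", x$fixture, ":\n")
  cat("  mean =", format(x$mean, digits = 6),
      " sd =", format(x$sd, digits = 6), "\n")
  invisible(x)
}

#' @rdname prior_oracles
#' @export
marginal_internal_node <- function(fx,
                                   tree_prior = fx$reference_tree_prior,
                                   change_of_var = FALSE, grid_n = 4096) {
  stopifnot(fx$varying[1] == "t_D")
  d <- fx$d; tE <- fx$t_E
  m <- fx$rate_prior$m; s <- fx$rate_prior$s
  N <- fx$coalescent$N
  logf <- function(t) {
    out <- lnormpdf(d["A"] / t, m, s) + lnormpdf(d["B"] / t, m, s) +
      lnormpdf(d["D"] / (tE - t), m, s)
    if (tree_prior) out <- out - 2 * t / N      # coalescent t_D-dependence
    if (change_of_var) out <- out - 2 * log(t) - log(tE - t)
    out
  }
  eps <- tE * 1e-9
  marginal_from_logf(logf, eps, tE - eps, grid_n, fx$name, "t_D",
                     list(tree_prior = tree_prior,
                          change_of_var = change_of_var))
}

#' @rdname prior_oracles
#' @export
marginal_root_time <- function(fx, tree_prior = fx$reference_tree_prior,
                               change_of_var = FALSE, grid_n = 4096) {
  stopifnot(fx$varying[1] == "t_E")
  d <- fx$d; tD <- fx$t_D
  m <- fx$rate_prior$m; s <- fx$rate_prior$s
  N <- fx$coalescent$N
  logf <- function(t) {
    out <- lnormpdf(d["D"] / (t - tD), m, s) + lnormpdf(d["C"] / t, m, s)
    if (tree_prior) out <- out - t / N
    if (change_of_var) out <- out - log(t - tD) - log(t)
    out
  }
  # adaptive truncation: extend until the tail is negligible
  hi <- tD + 50
  repeat {
    tail_ratio <- exp(logf(hi) - logf(tD + 2))
    if (tail_ratio < 1e-14 || hi > tD + 1e5) break
    hi <- hi * 2
  }
  marginal_from_logf(logf, tD + tD * 1e-9, hi, grid_n, fx$name, "t_E",
                     list(tree_prior = tree_prior,
                          change_of_var = change_of_var, upper = hi))
}

#' @rdname prior_oracles
#' @param variable which root branch distance to report: `"d_C"` (span
#'   `t_E`; the branch whose reference statistics the fixture records) or
#'   `"d_D"` (span `t_E - t_D`).  The two are mirror images summing to the
#'   conserved `D`.
#' @export
marginal_small_pulley <- function(fx, variable = c("d_C", "d_D"),
                                  grid_n = 4096) {
  stopifnot(fx$varying[1] == "root_split")
  variable <- match.arg(variable)
  d <- fx$d; tD <- fx$t_D; tE <- fx$t_E
  m <- fx$rate_prior$m; s <- fx$rate_prior$s
  D <- unname(d["C"] + d["D"])
  # x is the reported branch's distance; the complement takes up D - x
  logf <- if (variable == "d_C")
    function(x) lnormpdf((D - x) / (tE - tD), m, s) +
      lnormpdf(x / tE, m, s)
  else
    function(x) lnormpdf(x / (tE - tD), m, s) +
      lnormpdf((D - x) / tE, m, s)
  eps <- D * 1e-9
  marginal_from_logf(logf, eps, D - eps, grid_n, fx$name, variable,
                     list(D = D))
}

#' @rdname prior_oracles
#' @param n_E,n_D,n_Q Gauss-Legendre node counts for the root age, the
#'   internal age fraction, and the distance split.
#' @param t_max root-age truncation (checked for convergence in the tests
#'   by doubling).
#' @return For [marginal_big_pulley()], a list of class
#'   `"prior_marginal_3d"` with elements `t_E` and `d_D` (each a
#'   `"prior_marginal"`), plus the normalizing mass.
#' @export
marginal_big_pulley <- function(fx, tree_prior = fx$reference_tree_prior,
                                change_of_var = FALSE,
                                n_E = 300, n_D = 120, n_Q = 60,
                                t_max = 80) {
  stopifnot(fx$name == "big_pulley")
  dA <- unname(fx$d["A"]); dB <- unname(fx$d["B"])
  D <- unname(fx$d["C"] + fx$d["D"])
  m <- fx$rate_prior$m; s <- fx$rate_prior$s
  N <- fx$coalescent$N
  gE <- pracma::gaussLegendre(n_E, 1e-9, t_max)
  gU <- pracma::gaussLegendre(n_D, 1e-12, 1 - 1e-12)
  gQ <- pracma::gaussLegendre(n_Q, D * 1e-12, D * (1 - 1e-12))
  Q <- matrix(gQ$x, n_D, n_Q, byrow = TRUE)
  Z <- 0; fE <- numeric(n_E)
  mE <- 0; mE2 <- 0; mQ <- 0; mQ2 <- 0
  fQ <- numeric(n_Q)
  for (i in seq_len(n_E)) {
    tE <- gE$x[i]
    tD <- gU$x * tE; wD <- gU$w * tE
    TD <- matrix(tD, n_D, n_Q)
    lf <- lnormpdf(dA / TD, m, s) + lnormpdf(dB / TD, m, s) +
      lnormpdf(Q / (tE - TD), m, s) + lnormpdf((D - Q) / tE, m, s)
    if (tree_prior) lf <- lf - (tE - TD) / N - 3 * TD / N
    if (change_of_var) lf <- lf - 2 * log(TD) - log(tE - TD) - log(tE)
    f <- exp(lf)
    wm <- outer(wD, gQ$w)
    s0 <- sum(f * wm)
    fE[i] <- s0
    Z <- Z + gE$w[i] * s0
    mE <- mE + gE$w[i] * s0 * tE
    mE2 <- mE2 + gE$w[i] * s0 * tE^2
    qmass <- colSums(f * wm)                  # cell mass, for the moments
    fQ <- fQ + gE$w[i] * colSums(f * matrix(wD, n_D, n_Q))  # density in q
    mQ <- mQ + gE$w[i] * sum(qmass * gQ$x)
    mQ2 <- mQ2 + gE$w[i] * sum(qmass * gQ$x^2)
  }
  mk <- function(x, f, mean, sd, variable) {
    o <- order(x); x <- x[o]; pdf <- f[o] / Z
    cdf <- cumsum(c(0, diff(x) * (pdf[-1] + pdf[-length(x)]) / 2))
    cdf <- pmin(cdf / max(cdf), 1)
    structure(list(x = x, pdf = pdf, cdf = cdf, mean = mean, sd = sd,
                   fixture = fx$name, variable = variable,
                   settings = list(tree_prior = tree_prior,
                                   change_of_var = change_of_var,
                                   t_max = t_max)),
              class = "prior_marginal")
  }
  structure(list(
    t_E = mk(gE$x, fE, mE / Z, sqrt(mE2 / Z - (mE / Z)^2), "t_E"),
    d_D = mk(gQ$x, fQ, mQ / Z, sqrt(mQ2 / Z - (mQ / Z)^2), "d_D"),
    mass = Z), class = "prior_marginal_3d")
}

#' Compare chain samples with a quadrature oracle
#'
#' Mean and sd deltas with a Monte-Carlo standard error from the effective
#' sample size, and a Kolmogorov-Smirnov statistic of an approximately
#' independent (thinned) subsample against the oracle cdf.  The comparison
#' passes when the mean agrees within `3 * SE` and the KS statistic is
#' below the 1% critical value for the effective sample size.
#'
#' @param samples numeric chain samples (or a `"fixture_chain"`).
#' @param oracle a `"prior_marginal"`.
#' @return A list of class `"oracle_report"`: `mean_chain`, `mean_oracle`,
#'   `delta_mean`, `se`, `sd_chain`, `sd_oracle`, `ks`, `ks_crit`, `ess`,
#'   `pass`.
#' @export
compare_chain_to_oracle <- function(samples, oracle) {
  if (inherits(samples, "fixture_chain")) {
    if (!identical(samples$fixture, oracle$fixture))
      stop("fixture mismatch: chain is '", samples$fixture,
           "', oracle is '", oracle$fixture, "'")
    if (is.null(samples$samples[[oracle$variable]]))
      stop("chain did not record variable '", oracle$variable, "'")
    samples <- samples$samples[[oracle$variable]]
  }
  samples <- as.numeric(samples)
  ess <- as.numeric(effective_sample_size(samples))
  se <- stats::sd(samples) / sqrt(ess)
  # thin to roughly two autocorrelation times so the KS comparison sees an
  # approximately independent subsample
  thin <- max(1L, ceiling(2 * length(samples) / ess))
  sub <- samples[seq(1L, length(samples), by = thin)]
  cdf_at <- stats::approxfun(oracle$x, oracle$cdf, yleft = 0, yright = 1)
  ks <- max(abs(cdf_at(sort(sub)) -
                  (seq_along(sub) - 0.5) / length(sub)))
  ks_crit <- 1.63 / sqrt(length(sub))
  delta <- mean(samples) - oracle$mean
  structure(list(mean_chain = mean(samples), mean_oracle = oracle$mean,
                 delta_mean = delta, se = se,
                 sd_chain = stats::sd(samples), sd_oracle = oracle$sd,
                 ks = ks, ks_crit = ks_crit, ess = ess,
                 pass = abs(delta) <= 3 * se && ks <= ks_crit),
            class = "oracle_report")
}

#' @export
print.oracle_report <- function(x, ...) {
  cat(sprintf("chain mean %.4f vs oracle %.4f (delta %.2e, 3*SE %.2e)\n",
              x$mean_chain, x$mean_oracle, x$delta_mean, 3 * x$se))
  cat(sprintf("chain sd %.4f vs oracle %.4f; KS %.4f (crit %.4f); ESS %.0f\n",
              x$sd_chain, x$sd_oracle, x$ks, x$ks_crit, x$ess))
  cat("verdict:", if (x$pass) "PASS" else "FAIL", "\n")
  invisible(x)
}

#' Tab-separated oracle summary
#'
#' @param reports named list of `"oracle_report"`s.
#' @param file output path.
#' @export
write_oracle_report <- function(reports, file) {
  df <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(fixture = nm, mean_chain = r$mean_chain,
               mean_oracle = r$mean_oracle, sd_chain = r$sd_chain,
               sd_oracle = r$sd_oracle, ks = r$ks, ess = r$ess,
               pass = r$pass)
  }))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
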