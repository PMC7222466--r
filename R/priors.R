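#' Log-normal prior
#'
#' Log-normal density with parameters in log space: `m` is the mean and `s`
#' the standard deviation of `ln x`.
#'
#' @param m mean in log space.
#' @param s standard deviation in log space (> 0).
#' @return An object of class `"lognormal_prior"`.
#' @export
lognormal_prior <- function(m = -3, s = 0.25) {
  stopifnot(is.finite(m), is.finite(s), s > 0)
  structure(list(m = m, s = s), class = "lognormal_prior")
}

#' Log-normal log density
#'
#' Equals `-ln x - ln s - ln(2*pi)/2 - (ln x - m)^2 / (2 s^2)`.  Off-support
#' values (`x <= 0`) return `-Inf` with a warning rather than an error, so
#' that an out-of-support proposal is rejected, not fatal.
#'
#' @param x evaluation points (vectorized).
#' @param prior a [lognormal_prior()].
#' @return Log densities.
#' @export
lognormal_logpdf <- function(x, prior) {
  out <- rep(-Inf, length(x))
  ok <- is.finite(x) & x > 0
  if (!all(ok)) warning("lognormal_logpdf: values <= 0 have zero density")
  out[ok] <- stats::dlnorm(x[ok], prior$m, prior$s, log = TRUE)
  out
}

#' Constant-population coalescent prior
#'
#' @param N constant (effective) population size, in time units.
#' @return An object of class `"coalescent_prior"`.
#' @export
coalescent_prior <- function(N = 0.3) {
  stopifnot(is.finite(N), N > 0)
  structure(list(N = N), class = "coalescent_prior")
}

#' Coalescent log density of node ages
#'
#' Constant-population-size coalescent for contemporaneous tips: with `k`
#' lineages an interval of length `w` contributes `exp(-choose(k,2) w / N)`,
#' and each of the `n-1` coalescences a factor `1/N`.  For three taxa with
#' internal age `t_D` and root age `t_E` this is
#' `(1/N) exp(-(t_E - t_D)/N) * (1/N) exp(-3 t_D / N)`.
#'
#' @param times internal-node ages, sorted ascending (length `n - 1` for `n`
#'   tips, the last being the root age).
#' @param N population size (> 0).
#' @return Log density.
#' @export
coalescent_log_density <- function(times, N) {
  if (!(is.finite(N) && N > 0)) stop("population size N must be > 0")
  if (any(times < 0) || is.unsorted(times))
    stop("internal ages must be non-negative and sorted ascending")
  k <- (length(times) + 1L):2L            # lineage count entering each interval
  w <- diff(c(0, times))                  # interval lengths
  sum(-log(N) - choose(k, 2) * w / N)
}

#' Yule (pure-birth) prior
#'
#' @param lambda birth rate (1/time, > 0).
#' @return An object of class `"yule_prior"`.
#' @export
yule_prior <- function(lambda = 1) {
  stopifnot(is.finite(lambda), lambda > 0)
  structure(list(lambda = lambda), class = "yule_prior")
}

#' Yule log density of node ages
#'
#' Density over the internal ages of a labelled history with `n` tips: the
#' interval with `k` lineages is exponential with rate `k * lambda`, so
#' `log p = sum_k [log(k lambda) - k lambda w_k]`, `k = 2..n`.  Invariant
#' under taxon relabelling; only relative values matter in the chain.
#'
#' @param tree a [timetree()] with contemporaneous tips, or a sorted vector
#'   of internal ages.
#' @param lambda birth rate (> 0).
#' @return Log density.
#' @export
yule_log_density <- function(tree, lambda) {
  if (!(is.finite(lambda) && lambda > 0)) stop("birth rate must be > 0")
  times <- if (inherits(tree, "timetree"))
    sort(tree$times[internal_nodes(tree)]) else sort(tree)
  k <- (length(times) + 1L):2L
  w <- diff(c(0, times))
  sum(log(k * lambda) - k * lambda * w)
}

#' Simulate internal ages and topology from the Yule model
#'
#' Backward construction: starting from the `n` tips, each successive join
#' happens after an exponential waiting time with rate `k * lambda` (`k`
#' current lineages) and merges a uniformly chosen pair, which yields
#' uniformly distributed labelled histories -- the same model
#' [yule_log_density()] scores.
#'
#' @param n number of taxa.
#' @param lambda birth rate.
#' @param taxa optional tip labels.
#' @param rates branch rates for the returned tree (recycled; default 1).
#' @return A [timetree()].
#' @export
simulate_yule_tree <- function(n, lambda, taxa = paste0("t", seq_len(n)),
                               rates = 1) {
  stopifnot(n >= 2, lambda > 0)
  nnode <- 2L * n - 1L
  parent <- rep(NA_integer_, nnode)
  times <- numeric(nnode)
  active <- seq_len(n)
  age <- 0
  nxt <- n + 1L
  while (length(active) > 1L) {
    k <- length(active)
    age <- age + stats::rexp(1, k * lambda)
    pair <- sample(k, 2L)
    parent[active[pair]] <- nxt
    times[nxt] <- age
    active <- c(active[-pair], nxt)
    nxt <- nxt + 1L
  }
  r <- rep(NA_real_, nnode)
  r[-(nnode)] <- rep_len(rates, nnode - 1L)
  r[nnode] <- NA_real_
  timetree(taxa, parent, times, r)
}

#' Relaxed-clock model with mean-one rate prior
#'
#' Uncorrelated log-normal clock: branch rates are iid log-normal with the
#' real-space mean fixed at 1, which pins the log-space mean at
#' `m = -s1^2 / 2` for log-space standard deviation `s1` (the "ucld"
#' standard deviation).
#'
#' @param ucld_stdev log-space standard deviation `s1` (> 0).
#' @return An object of class `"clock_model"` containing the implied
#'   [lognormal_prior()].
#' @export
clock_model <- function(ucld_stdev = 0.1) {
  stopifnot(ucld_stdev > 0)
  structure(list(ucld_stdev = ucld_stdev,
                 rate_prior = lognormal_prior(m = -ucld_stdev^2 / 2,
                                              s = ucld_stdev)),
            class = "clock_model")
}

#' Prior specification for a sampler run
#'
#' Bundles the tree prior, the branch-rate prior and (optionally) the
#' hyperprior on the clock standard deviation.  The default `ucld_stdev`
#' hyperprior is gamma with shape 0.5396 and scale 0.3819.
#'
#' @param tree_prior a [coalescent_prior()] or [yule_prior()] (or `NULL` for
#'   no tree-prior factor).
#' @param rate_prior a [lognormal_prior()] or [clock_model()].
#' @param stdev_hyperprior `NULL`, or `list(shape=, scale=)` for a gamma
#'   hyperprior on `ucld_stdev` (used when the clock model's stdev is
#'   sampled).
#' @return An object of class `"prior_spec"`.
#' @export
prior_spec <- function(tree_prior = coalescent_prior(0.3),
                       rate_prior = lognormal_prior(-3, 0.25),
                       stdev_hyperprior = list(shape = 0.5396,
                                               scale = 0.3819)) {
  structure(list(tree_prior = tree_prior, rate_prior = rate_prior,
                 stdev_hyperprior = stdev_hyperprior),
            class = "prior_spec")
}

rate_prior_of <- function(spec) {
  rp <- spec$rate_prior
  if (inherits(rp, "clock_model")) rp$rate_prior else rp
}

tree_prior_log_density <- function(tree, spec) {
  tp <- spec$tree_prior
  if (is.null(tp)) return(0)
  times <- sort(tree$times[internal_nodes(tree)])
  if (inherits(tp, "coalescent_prior"))
    coalescent_log_density(times, tp$N)
  else if (inherits(tp, "yule_prior"))
    yule_log_density(times, tp$lambda)
  else stop("unknown tree prior")
}

#' Joint prior log density of a clock state
#'
#' Additive combination: tree-prior term on the node ages plus one
#' log-normal term per branch rate, plus the `ucld_stdev` hyperprior term
#' when the rate prior is a sampled [clock_model()].  Off-support components
#' propagate `-Inf`.
#'
#' @param tree a [timetree()].
#' @param spec a [prior_spec()].
#' @return Log density.
#' @export
joint_prior_log_density <- function(tree, spec) {
  rp <- rate_prior_of(spec)
  rates <- tree$rates[-tree$root]
  if (any(rates <= 0)) return(-Inf)
  lp <- tree_prior_log_density(tree, spec) +
    sum(stats::dlnorm(rates, rp$m, rp$s, log = TRUE))
  if (inherits(spec$rate_prior, "clock_model") &&
      !is.null(spec$stdev_hyperprior)) {
    h <- spec$stdev_hyperprior
    lp <- lp + stats::dgamma(spec$rate_prior$ucld_stdev, shape = h$shape,
                             scale = h$scale, log = TRUE)
  }
  lp
}
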