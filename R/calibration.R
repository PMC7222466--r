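#' Highest posterior density interval
#'
#' Shortest interval containing a `prob` fraction of the sorted samples.
#'
#' @param x numeric samples.
#' @param prob interval mass.
#' @return `c(lower, upper)`.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  k <- max(1L, ceiling(prob * n))
  if (k >= n) return(c(x[1], x[n]))
  width <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(width)
  c(x[i], x[i + k])
}

#' Exact binomial band for coverage checks
#'
#' The central `level` probability band for the observed coverage fraction
#' when the true coverage is `p`, over `n` replicates.
#'
#' @param n replicate count.
#' @param p nominal coverage.
#' @param level band mass.
#' @return `c(lower, upper)` as fractions.
#' @export
coverage_band <- function(n, p = 0.95, level = 0.99) {
  a <- (1 - level) / 2
  c(stats::qbinom(a, n, p), stats::qbinom(1 - a, n, p)) / n
}

default_study_hyperpriors <- function() {
  list(kappa = list(meanlog = 1, sdlog = 1.25),
       lambda = list(meanlog = log(5), sdlog = 0.5),
       pi_alpha = 4,
       stdev = list(shape = 0.5396, scale = 0.3819))
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

# Operator mix for the study.  The topology is held at truth, so only
# topology-preserving kernels are used (the big pulley re-roots and is
# validated separately by the prior-sampling oracles).  Step sizes follow
# the replicate's scale: time windows from the initial tree height, the
# rate-walk width from the clock spread (a tight clock pins the rates, so
# proposals must be correspondingly small -- tuning that affects mixing
# speed only, never the target).
study_schedule <- function(tree0, s1 = 0.2) {
  h <- tree_height(tree0)
  cfg <- operator_config(w = h / 10, v = 0.1)
  delta <- min(0.8, max(0.05, 2 * s1))
  operator_schedule(
    op_internal_node(cfg, weight = 12),
    op_simple_distance(cfg, weight = 4),
    op_small_pulley(cfg, weight = 2),
    op_rate_walk(delta = delta, weight = 12),
    op_node_time_uniform(weight = 10),
    op_root_walk(w = h / 3, weight = 5),
    op_times_scale(0.7, weight = 4),
    op_up_down(0.7, weight = 6),
    op_ucld_stdev(0.5, weight = 5),
    op_stdev_scale_plain(0.75, weight = 12),
    op_kappa_scale(0.7, weight = 2),
    op_lambda_scale(0.5, weight = 3),
    op_pi_exchange(0.05, weight = 2))
}

#' Scaled well-calibrated simulation study
#'
#' Draws model parameters from their priors, simulates a Yule tree,
#' log-normal branch rates (real-space mean one) and an HKY alignment,
#' re-infers under the same model with the tree topology held at truth, and
#' reports the fraction of replicates whose true parameter value falls in
#' the 95% HPD interval.  A correctly implemented sampler gives coverages
#' inside the exact binomial band around 95%.
#'
#' `misspecify_rate_mean` is a deliberate-miscalibration hook for negative
#' controls: generating branch rates with real-space mean `!= 1` while
#' analysing under the mean-one clock makes the inferred time scale -- and
#' with it the tree-height coverage -- collapse.
#'
#' @param n_taxa,n_reps,n_sites study size.
#' @param chain_length,sample_every,burnin_frac chain settings per
#'   replicate.
#' @param seed RNG seed for the whole study.
#' @param misspecify_rate_mean real-space mean of the *generating* rate
#'   distribution (analysis always assumes 1).
#' @param ess_floor replicates whose posterior ESS (of tree height) falls
#'   below this are flagged, and reported separately rather than silently
#'   pooled.
#' @param hyperpriors hyperprior settings shared by generation and
#'   analysis; see `default_study_hyperpriors()` in the sources.
#' @return A list of class `"calibration_study"`: `coverage` (data frame
#'   with per-parameter counts, fractions and the 99% binomial band),
#'   `flagged` (low-ESS replicate indices), `n_reps`, `details` (per-rep
#'   matrix of hit indicators).
#' @export
well_calibrated_study <- function(n_taxa = 20, n_reps = 50, n_sites = 100,
                                  chain_length = 32000, sample_every = 15,
                                  burnin_frac = 0.25, seed = 1,
                                  misspecify_rate_mean = 1,
                                  ess_floor = 20,
                                  hyperpriors = default_study_hyperpriors()) {
  set.seed(seed)
  params <- c("tree_height", "tree_length", "kappa", "ucld_stdev", "lambda")
  hits <- matrix(NA, n_reps, length(params),
                 dimnames = list(NULL, params))
  flagged <- integer(0)
  for (rep in seq_len(n_reps)) {
    # ---- draw truth from the model
    s1 <- stats::rgamma(1, shape = hyperpriors$stdev$shape,
                        scale = hyperpriors$stdev$scale)
    s1 <- max(s1, 1e-3)
    lambda <- stats::rlnorm(1, hyperpriors$lambda$meanlog,
                            hyperpriors$lambda$sdlog)
    kappa <- stats::rlnorm(1, hyperpriors$kappa$meanlog,
                           hyperpriors$kappa$sdlog)
    pi <- rdirichlet1(rep(hyperpriors$pi_alpha, 4))
    tree <- simulate_yule_tree(n_taxa, lambda)
    nonroot <- setdiff(seq_along(tree$parent), tree$root)
    gen_m <- log(misspecify_rate_mean) - s1^2 / 2
    tree$rates[nonroot] <- stats::rlnorm(length(nonroot), gen_m, s1)
    model <- hky_model(kappa, pi)
    aln <- simulate_alignment(tree, model, n_sites)
    truth <- c(tree_height = tree_height(tree),
               tree_length = tree_length(tree),
               kappa = kappa, ucld_stdev = s1, lambda = lambda)
    # ---- re-infer with the topology fixed at truth
    st <- mcmc_state(tree,
                     prior_spec(tree_prior = yule_prior(lambda),
                                rate_prior = clock_model(s1),
                                stdev_hyperprior = hyperpriors$stdev),
                     mode = "full", model = model, aln = aln,
                     hyperpriors = hyperpriors[c("kappa", "lambda",
                                                 "pi_alpha")])
    run <- run_chain(list(state = st, schedule = study_schedule(tree, s1),
                          chain_length = chain_length,
                          sample_every = sample_every))
    tr <- run$trace
    keep <- tr$Sample > burnin_frac * chain_length
    tr <- tr[keep, , drop = FALSE]
    ess <- as.numeric(effective_sample_size(tr$tree_height))
    if (ess < ess_floor) flagged <- c(flagged, rep)
    for (p in params) {
      ci <- hpd_interval(tr[[p]], 0.95)
      hits[rep, p] <- truth[p] >= ci[1] && truth[p] <= ci[2]
    }
  }
  band <- coverage_band(n_reps)
  cov <- data.frame(parameter = params,
                    covered = colSums(hits),
                    n = n_reps,
                    coverage = colMeans(hits),
                    band_lower = band[1], band_upper = band[2])
  cov$in_band <- cov$coverage >= cov$band_lower &
    cov$coverage <= cov$band_upper
  structure(list(coverage = cov, flagged = flagged, n_reps = n_reps,
                 details = hits),
            class = "calibration_study")
}

#' @export
print.calibration_study <- function(x, ...) {
  cat("Well-calibrated study,", x$n_reps, "replicates\n")
  print(x$coverage, row.names = FALSE)
  if (length(x$flagged))
    cat("low-ESS replicates flagged:", paste(x$flagged, collapse = ", "),
        "\n")
  invisible(x)
}

topology_key <- function(tree) {
  rec <- function(v) {
    if (is_tip(tree, v)) return(tree$taxa[v])
    kids <- sort(vapply(tree$children[[v]], rec, ""))
    paste0("(", paste(kids, collapse = ","), ")")
  }
  rec(tree$root)
}

#' Rate / branch-length correlation report
#'
#' Restricts a posterior tree sample to its modal topology and computes
#' Pearson correlations, in log space, between every branch rate and every
#' branch length in time.  On posteriors dominated by the genetic-distance
#' signal the diagonal (a branch's own rate against its own length) is
#' negative, since `r_i = d_i / l_i`.
#'
#' @param trees list of [timetree()]s (e.g. `run$trees` from a
#'   [run_chain()] with `keep_trees = TRUE`).
#' @return A list of class `"correlation_report"`: `cor` (branches x
#'   branches, rows rates, columns lengths), `diagonal`, `n_trees`,
#'   `topology`.
#' @export
correlation_report <- function(trees) {
  keys <- vapply(trees, topology_key, "")
  modal <- names(sort(table(keys), decreasing = TRUE))[1]
  trees <- trees[keys == modal]
  if (length(trees) < 10)
    stop("fewer than 10 trees share the modal topology")
  t0 <- trees[[1]]
  nonroot <- setdiff(seq_along(t0$parent), t0$root)
  logr <- t(vapply(trees, function(tr) log(tr$rates[nonroot]),
                   numeric(length(nonroot))))
  logl <- t(vapply(trees, function(tr)
    log(tr$times[tr$parent[nonroot]] - tr$times[nonroot]),
    numeric(length(nonroot))))
  cm <- suppressWarnings(stats::cor(logr, logl))
  dimnames(cm) <- list(paste0("r", nonroot), paste0("l", nonroot))
  structure(list(cor = cm, diagonal = diag(cm), n_trees = length(trees),
                 topology = modal),
            class = "correlation_report")
}
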