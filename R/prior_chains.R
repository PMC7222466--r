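#' Prior-sampling validation chains on the fixtures
#'
#' Long, dependency-free Metropolis chains specialized to the three-taxon
#' fixtures, used to validate the proposal kernels against the quadrature
#' oracles.  Because every kernel confines a prior-only chain to the
#' manifold of fixed genetic distances, the fixture state reduces to one
#' coordinate (internal age, root age, or root distance split) -- three
#' coordinates plus the rooted topology for the big pulley -- and the chain
#' can be run for millions of steps in seconds.
#'
#' `target` picks the density convention (see [marginal_internal_node()]):
#' * `"reference"`: the fixture's reference density (log-normal rate
#'   factors at the implied rates, coalescent factor only where the fixture
#'   records it, no measure factor).  Moves are symmetric in the
#'   coordinate, so the acceptance ratio is the plain density ratio.
#' * `"state"`: the stationary density of the full
#'   Metropolis-Hastings-Green operator under the coalescent-times-rates
#'   prior; the acceptance ratio is the prior ratio times the operator's
#'   analytic Green ratio, which is algebraically the reference ratio times
#'   the `1/dt` measure factors.
#'
#' @param fx a [make_fixture()] result.
#' @param steps number of Metropolis steps.
#' @param window half-width of the uniform displacement (time units, or
#'   substitutions for the small pulley).
#' @param target `"reference"` or `"state"`.
#' @param thin keep every `thin`-th post-burn-in sample.
#' @param burnin steps discarded before recording.
#' @param seed optional RNG seed.
#' @return A list of class `"fixture_chain"`: `samples` (named list of
#'   numeric vectors), `fixture`, `operator`, `target`, `acc_rate`.
#' @export
sample_fixture_prior <- function(fx, steps = 1e6,
                                 window = NULL,
                                 target = c("reference", "state"),
                                 thin = 10L, burnin = floor(steps / 10),
                                 seed = NULL) {
  target <- match.arg(target)
  if (!is.null(seed)) set.seed(seed)
  op <- switch(fx$name,
               scenario1 = , scenario2 = "internal_node",
               simple_distance = "simple_distance",
               small_pulley = "small_pulley",
               big_pulley = "big_pulley")
  out <- switch(op,
    internal_node = chain_internal_node(fx, steps, window %||% fx$t_E / 5,
                                        target, thin, burnin),
    simple_distance = chain_simple_distance(fx, steps, window %||% 3,
                                            target, thin, burnin),
    small_pulley = chain_small_pulley(fx, steps, window %||% 0.15,
                                      thin, burnin),
    big_pulley = chain_big_pulley(fx, steps, window %||% 2, target,
                                  thin, burnin))
  structure(c(out, list(fixture = fx$name, operator = op, target = target,
                        steps = steps)),
            class = "fixture_chain")
}

#' @export
print.fixture_chain <- function(x, ...) {
  cat("Prior-only chain on fixture", x$fixture, "(", x$operator, ",",
      x$target, "target ):", x$steps, "steps, acceptance",
      format(x$acc_rate, digits = 3), "\n")
  for (nm in names(x$samples))
    cat(sprintf("  %s: mean %.4f sd %.4f (n=%d)\n", nm,
                mean(x$samples[[nm]]), stats::sd(x$samples[[nm]]),
                length(x$samples[[nm]])))
  invisible(x)
}

# Shared scalar Metropolis loop.  logf must be vector-safe; bounds
# rejections count as rejected proposals ("reject, do not resample").
mh_scalar <- function(logf, init, lo, hi, w, steps, thin, burnin) {
  t <- init; lp <- logf(t)
  keep <- (steps - burnin) %/% thin
  out <- numeric(keep)
  acc <- 0L; j <- 0L
  block <- 100000L
  done <- 0L
  while (done < steps) {
    nb <- min(block, steps - done)
    a <- stats::runif(nb, -w, w)
    lu <- log(stats::runif(nb))
    for (i in seq_len(nb)) {
      tp <- t + a[i]
      if (tp > lo && tp < hi) {
        lpp <- logf(tp)
        if (lu[i] < lpp - lp) { t <- tp; lp <- lpp; acc <- acc + 1L }
      }
      done <- done + 1L
      if (done > burnin && (done - burnin) %% thin == 0L && j < keep) {
        j <- j + 1L; out[j] <- t
      }
    }
  }
  list(samples = out[seq_len(j)], acc = acc / steps)
}

chain_internal_node <- function(fx, steps, w, target, thin, burnin) {
  d <- fx$d; tE <- fx$t_E
  m <- fx$rate_prior$m; s <- fx$rate_prior$s; N <- fx$coalescent$N
  coal_on <- fx$reference_tree_prior || target == "state"
  cov_on <- target == "state"
  logf <- function(t) {
    out <- lnormpdf(d[["A"]] / t, m, s) + lnormpdf(d[["B"]] / t, m, s) +
      lnormpdf(d[["D"]] / (tE - t), m, s)
    if (coal_on) out <- out - 2 * t / N
    if (cov_on) out <- out - 2 * log(t) - log(tE - t)
    out
  }
  r <- mh_scalar(logf, fx$t_D, 0, tE, w, steps, thin, burnin)
  list(samples = list(t_D = r$samples), acc_rate = r$acc)
}

chain_simple_distance <- function(fx, steps, w, target, thin, burnin) {
  d <- fx$d; tD <- fx$t_D
  m <- fx$rate_prior$m; s <- fx$rate_prior$s; N <- fx$coalescent$N
  coal_on <- fx$reference_tree_prior || target == "state"
  cov_on <- target == "state"
  logf <- function(t) {
    out <- lnormpdf(d[["D"]] / (t - tD), m, s) + lnormpdf(d[["C"]] / t, m, s)
    if (coal_on) out <- out - t / N
    if (cov_on) out <- out - log(t - tD) - log(t)
    out
  }
  r <- mh_scalar(logf, fx$t_E, tD, Inf, w, steps, thin, burnin)
  list(samples = list(t_E = r$samples), acc_rate = r$acc)
}

chain_small_pulley <- function(fx, steps, v, thin, burnin) {
  # the split is measured as d_C (span t_E); Green ratio is exactly 1 and
  # the coalescent factor is constant, so reference and state coincide
  tD <- fx$t_D; tE <- fx$t_E
  m <- fx$rate_prior$m; s <- fx$rate_prior$s
  D <- unname(fx$d["C"] + fx$d["D"])
  logf <- function(x) lnormpdf((D - x) / (tE - tD), m, s) +
    lnormpdf(x / tE, m, s)
  r <- mh_scalar(logf, unname(fx$d["C"]), 0, D, v, steps, thin, burnin)
  list(samples = list(d_C = r$samples, d_D = D - r$samples),
       acc_rate = r$acc)
}

# Big pulley on the 3-taxon fixture.  All three unrooted legs have equal
# length, so in any rooted topology the state is (t_E, t_D, q) with q the
# root-side distance above the internal node, plus the topology label (the
# taxon alone at the root).  Both grandchildren of the root are tips at age
# 0, so the elder-grandchild rule never forces a move and mu = 1.
chain_big_pulley <- function(fx, steps, w, target, thin, burnin) {
  m <- fx$rate_prior$m; s <- fx$rate_prior$s; N <- fx$coalescent$N
  leg <- unname(fx$d["A"])
  D <- unname(fx$d["C"] + fx$d["D"])
  cov_on <- target == "state"
  logf <- function(tE, tD, q) {
    out <- 2 * lnormpdf(leg / tD, m, s) + lnormpdf(q / (tE - tD), m, s) +
      lnormpdf((D - q) / tE, m, s) - (tE - tD) / N - 3 * tD / N
    if (cov_on) out <- out - 2 * log(tD) - log(tE - tD) - log(tE)
    out
  }
  tE <- fx$t_E; tD <- fx$t_D; q <- unname(fx$d["D"]); topo <- 3L
  lp <- logf(tE, tD, q)
  keep <- (steps - burnin) %/% thin
  sE <- numeric(keep); sD <- numeric(keep); sQ <- numeric(keep)
  sT <- integer(keep)
  acc <- 0L; j <- 0L
  block <- 50000L; done <- 0L
  v <- D / 3
  while (done < steps) {
    nb <- min(block, steps - done)
    a1 <- stats::runif(nb, -w, w); a2 <- stats::runif(nb, -w, w)
    bb <- stats::runif(nb, -v, v); lu <- log(stats::runif(nb))
    pick <- sample.int(2L, nb, replace = TRUE)
    for (i in seq_len(nb)) {
      tEp <- tE + a1[i]; tDp <- tD + a2[i]; qp <- q + bb[i]
      ok <- qp > 0 && qp < D && tDp > 0 && tEp > tDp
      if (ok) {
        lpp <- logf(tEp, tDp, qp)
        # displacements are symmetric and mu = 1 here, so the acceptance
        # ratio is the density ratio in either convention
        if (lu[i] < lpp - lp) {
          # promoted tip: one of the two tips currently under the internal
          # node becomes the lone root child
          under <- setdiff(1:3, topo)
          topo <- under[pick[i]]
          tE <- tEp; tD <- tDp; q <- qp; lp <- lpp; acc <- acc + 1L
        }
      }
      done <- done + 1L
      if (done > burnin && (done - burnin) %% thin == 0L && j < keep) {
        j <- j + 1L
        sE[j] <- tE; sD[j] <- tD; sQ[j] <- q; sT[j] <- topo
      }
    }
  }
  idx <- seq_len(j)
  list(samples = list(t_E = sE[idx], t_D = sD[idx], d_D = sQ[idx],
                      topology = sT[idx]),
       acc_rate = acc / steps)
}
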