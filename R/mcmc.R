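#' MCMC state
#'
#' Bundles the time tree, the prior specification (which owns any sampled
#' hyperparameters such as the clock standard deviation or the birth rate),
#' the substitution model and data for the full-posterior mode, and cached
#' log prior / log likelihood.
#'
#' Modes: `"prior"` samples the prior alone; `"fixed-distances"` treats a
#' fixed unrooted substitution tree as the data, where the likelihood is
#' constant under distance-preserving moves and is therefore omitted from
#' the target; `"full"` uses the HKY pruning likelihood of an alignment.
#'
#' @param tree a [timetree()].
#' @param priors a [prior_spec()].
#' @param mode `"prior"`, `"fixed-distances"` or `"full"`.
#' @param model an [hky_model()] (full mode).
#' @param aln an [alignment()] (full mode).
#' @param hyperpriors optional list with entries `kappa = list(meanlog,
#'   sdlog)`, `lambda = list(meanlog, sdlog)`, `pi_alpha` (Dirichlet
#'   concentration) describing hyperpriors on sampled substitution/tree
#'   parameters.
#' @return An object of class `"mcmc_state"`.
#' @export
mcmc_state <- function(tree, priors,
                       mode = c("prior", "fixed-distances", "full"),
                       model = NULL, aln = NULL, hyperpriors = list()) {
  mode <- match.arg(mode)
  if (mode == "full" && (is.null(model) || is.null(aln)))
    stop("full mode needs a substitution model and an alignment")
  st <- structure(list(tree = tree, priors = priors, mode = mode,
                       model = model, aln = aln,
                       hyperpriors = hyperpriors, lik_cache = NULL,
                       log_prior = NA_real_, log_lik = NA_real_),
                  class = "mcmc_state")
  st$log_prior <- state_log_prior(st)
  if (mode == "full") {
    full <- pruning_full(st$tree, st$aln, st$model)
    st$log_lik <- full$loglik
    st$lik_cache <- full$cache
  } else st$log_lik <- 0
  st
}

ddirichlet_log <- function(x, alpha) {
  alpha <- rep_len(alpha, length(x))
  if (any(x <= 0) || abs(sum(x) - 1) > 1e-9) return(-Inf)
  lgamma(sum(alpha)) - sum(lgamma(alpha)) + sum((alpha - 1) * log(x))
}

state_log_prior <- function(state) {
  lp <- joint_prior_log_density(state$tree, state$priors)
  h <- state$hyperpriors
  if (!is.null(h$kappa) && !is.null(state$model))
    lp <- lp + stats::dlnorm(state$model$kappa, h$kappa$meanlog,
                             h$kappa$sdlog, log = TRUE)
  if (!is.null(h$pi_alpha) && !is.null(state$model))
    lp <- lp + ddirichlet_log(state$model$pi, h$pi_alpha)
  if (!is.null(h$lambda) && inherits(state$priors$tree_prior, "yule_prior"))
    lp <- lp + stats::dlnorm(state$priors$tree_prior$lambda,
                             h$lambda$meanlog, h$lambda$sdlog, log = TRUE)
  lp
}

state_log_lik <- function(state) {
  if (state$mode != "full") return(0)
  pruning_log_likelihood(state$tree, state$aln, state$model)
}

# Incremental likelihood for a proposal: recompute only the ancestors of
# the branches the proposal reports as changed; fall back to a full pass
# when the proposal changed the substitution model or everything.
proposal_log_lik <- function(new, pr) {
  if (new$mode != "full") return(new)
  if (!pr$changed_distances) {
    # distance-preserving moves keep the likelihood; a topology change
    # still invalidates the cached partials
    if (isTRUE(pr$invalidate_cache)) new$lik_cache <- NULL
    return(new)
  }
  res <- if (is.null(pr$dirty) || is.null(new$lik_cache))
    pruning_full(new$tree, new$aln, new$model)
  else pruning_update(new$tree, new$model, new$lik_cache, pr$dirty)
  new$log_lik <- res$loglik
  new$lik_cache <- res$cache
  new
}

state_log_target <- function(state) {
  state$log_prior + if (state$mode == "full") state$log_lik else 0
}

#' Operator schedule
#'
#' A weighted list of state-level operators.  Each operator is a list with a
#' `name`, a non-negative `weight`, a `propose(state)` function returning
#' `list(state, log_green, valid, changed_distances)`, and a flag
#' `distance_preserving` used to validate fixed-distance runs.
#'
#' @param ... operator entries (see the `op_*` constructors).
#' @return An object of class `"operator_schedule"`.
#' @export
operator_schedule <- function(...) {
  ops <- list(...)
  w <- vapply(ops, `[[`, 1, "weight")
  if (any(w < 0) || sum(w) <= 0) stop("operator weights must be >= 0 and sum > 0")
  structure(list(ops = ops, probs = w / sum(w)), class = "operator_schedule")
}

tree_op <- function(name, fun, distance_preserving = TRUE, weight = 1) {
  list(name = name, weight = weight, distance_preserving = distance_preserving,
       propose = fun)
}

#' Constant-distance operator entries for a schedule
#'
#' State-level wrappers around the four constant-distance kernels plus the
#' standard helper operators used in the calibration study (random-walk on a
#' log rate, node-time moves, scale moves on hyperparameters, a Dirichlet
#' delta exchange on base frequencies, and the clock-stdev quantile
#' operator).
#'
#' @param cfg an [operator_config()].
#' @param weight schedule weight.
#' @name schedule_ops
#' @return An operator entry for [operator_schedule()].
NULL

wrap_tree_proposal <- function(state, pr) {
  st <- state; st$tree <- pr$tree
  list(state = st, log_green = pr$log_green, valid = pr$valid,
       changed_distances = pr$changed_distances)
}

#' @rdname schedule_ops
#' @export
op_internal_node <- function(cfg = operator_config(), weight = 1)
  tree_op("constant_distance_internal", function(state)
    wrap_tree_proposal(state, propose_internal_node(state$tree, cfg)),
    TRUE, weight)

#' @rdname schedule_ops
#' @export
op_simple_distance <- function(cfg = operator_config(), weight = 1)
  tree_op("simple_distance", function(state)
    wrap_tree_proposal(state, propose_simple_distance(state$tree, cfg)),
    TRUE, weight)

#' @rdname schedule_ops
#' @export
op_small_pulley <- function(cfg = operator_config(), weight = 1)
  tree_op("small_pulley", function(state)
    wrap_tree_proposal(state, propose_small_pulley(state$tree, cfg)),
    TRUE, weight)

#' @rdname schedule_ops
#' @export
op_big_pulley <- function(cfg = operator_config(), weight = 1)
  tree_op("big_pulley", function(state) {
    out <- wrap_tree_proposal(state, propose_big_pulley(state$tree, cfg))
    out$invalidate_cache <- TRUE        # re-rooting invalidates partials
    out
  }, TRUE, weight)

#' @rdname schedule_ops
#' @param delta half-width of the uniform log-space random walk.
#' @export
op_rate_walk <- function(delta = 0.5, weight = 1)
  tree_op("rate_random_walk", function(state) {
    tr <- state$tree
    nonroot <- setdiff(seq_along(tr$parent), tr$root)
    i <- nonroot[sample.int(length(nonroot), 1L)]
    u <- stats::runif(1, -delta, delta)
    tr$rates[i] <- tr$rates[i] * exp(u)
    st <- state; st$tree <- tr
    list(state = st, log_green = u, valid = TRUE, changed_distances = TRUE,
         dirty = i)
  }, FALSE, weight)

#' @rdname schedule_ops
#' @export
op_node_time_uniform <- function(weight = 1)
  tree_op("node_time_uniform", function(state) {
    tr <- state$tree
    cand <- internal_nodes(tr, include_root = FALSE)
    if (!length(cand))
      return(list(state = state, log_green = -Inf, valid = FALSE,
                  changed_distances = FALSE))
    i <- cand[sample.int(length(cand), 1L)]
    lo <- max(tr$times[tr$children[[i]]]); hi <- tr$times[tr$parent[i]]
    tr$times[i] <- stats::runif(1, lo, hi)
    st <- state; st$tree <- tr
    list(state = st, log_green = 0, valid = TRUE, changed_distances = TRUE,
         dirty = c(i, tr$children[[i]]))
  }, FALSE, weight)

#' @rdname schedule_ops
#' @param w half-width of the uniform root-age random walk.
#' @export
op_root_walk <- function(w = 1, weight = 1)
  tree_op("root_age_walk", function(state) {
    tr <- state$tree
    a <- stats::runif(1, -w, w)
    tp <- tr$times[tr$root] + a
    if (tp <= max(tr$times[tr$children[[tr$root]]]))
      return(list(state = state, log_green = -Inf, valid = FALSE,
                  changed_distances = FALSE))
    tr$times[tr$root] <- tp
    st <- state; st$tree <- tr
    list(state = st, log_green = 0, valid = TRUE, changed_distances = TRUE,
         dirty = tr$children[[tr$root]])
  }, FALSE, weight)

scale_draw <- function(factor) {
  factor + stats::runif(1) * (1 / factor - factor)
}

#' @rdname schedule_ops
#' @param factor scale boldness in (0, 1).
#' @export
op_times_scale <- function(factor = 0.75, weight = 1)
  tree_op("all_node_times_scale", function(state) {
    tr <- state$tree
    s <- scale_draw(factor)
    idx <- internal_nodes(tr)
    tr$times[idx] <- tr$times[idx] * s
    st <- state; st$tree <- tr
    list(state = st, log_green = (length(idx) - 2) * log(s), valid = TRUE,
         changed_distances = TRUE)
  }, FALSE, weight)

#' @rdname schedule_ops
#' @export
op_up_down <- function(factor = 0.75, weight = 1)
  tree_op("constant_distance_up_down", function(state) {
    # scale all node ages up and all rates down by the same factor: every
    # genetic distance, and hence the likelihood, is untouched.  Needs
    # contemporaneous tips (age 0), otherwise tip-adjacent spans would not
    # scale.  Green ratio: k internal times and m rates scaled by s and
    # 1/s plus the s -> 1/s kernel, giving |J| = s^(k - m - 2).
    tr <- state$tree
    if (any(tr$times[seq_len(tr$ntaxa)] != 0))
      return(list(state = state, log_green = -Inf, valid = FALSE,
                  changed_distances = FALSE))
    s <- scale_draw(factor)
    idx <- internal_nodes(tr)
    nonroot <- setdiff(seq_along(tr$parent), tr$root)
    tr$times[idx] <- tr$times[idx] * s
    tr$rates[nonroot] <- tr$rates[nonroot] / s
    st <- state; st$tree <- tr
    list(state = st,
         log_green = (length(idx) - length(nonroot) - 2) * log(s),
         valid = TRUE, changed_distances = FALSE)
  }, TRUE, weight)

#' @rdname schedule_ops
#' @export
op_kappa_scale <- function(factor = 0.75, weight = 1)
  tree_op("kappa_scale", function(state) {
    s <- scale_draw(factor)
    st <- state
    st$model <- hky_model(state$model$kappa * s, state$model$pi)
    list(state = st, log_green = -log(s), valid = TRUE,
         changed_distances = TRUE)
  }, FALSE, weight)

#' @rdname schedule_ops
#' @export
op_lambda_scale <- function(factor = 0.75, weight = 1)
  tree_op("birth_rate_scale", function(state) {
    s <- scale_draw(factor)
    st <- state
    st$priors$tree_prior <- yule_prior(state$priors$tree_prior$lambda * s)
    list(state = st, log_green = -log(s), valid = TRUE,
         changed_distances = FALSE)
  }, TRUE, weight)

#' @rdname schedule_ops
#' @param delta maximum frequency mass moved per proposal.
#' @export
op_pi_exchange <- function(delta = 0.05, weight = 1)
  tree_op("frequencies_delta_exchange", function(state) {
    pi <- state$model$pi
    ij <- sample.int(4L, 2L)
    u <- stats::runif(1, 0, delta)
    pi[ij[1]] <- pi[ij[1]] - u; pi[ij[2]] <- pi[ij[2]] + u
    if (any(pi <= 0))
      return(list(state = state, log_green = -Inf, valid = FALSE,
                  changed_distances = FALSE))
    st <- state
    st$model <- hky_model(state$model$kappa, pi)
    list(state = st, log_green = 0, valid = TRUE, changed_distances = TRUE)
  }, FALSE, weight)

#' @rdname schedule_ops
#' @export
op_ucld_stdev <- function(factor = 0.75, weight = 1)
  tree_op("ucld_stdev_scale", function(state) {
    cm <- state$priors$rate_prior
    if (!inherits(cm, "clock_model"))
      stop("ucld_stdev operator needs a clock_model rate prior")
    pr <- propose_stdev_and_rates(state$tree, cm$ucld_stdev, factor)
    st <- state
    st$tree <- pr$tree
    st$priors$rate_prior <- clock_model(pr$ucld_stdev)
    list(state = st, log_green = pr$log_green, valid = pr$valid,
         changed_distances = TRUE)
  }, FALSE, weight)

#' @rdname schedule_ops
#' @export
op_stdev_scale_plain <- function(factor = 0.6, weight = 1)
  tree_op("ucld_stdev_scale_plain", function(state) {
    # scale the clock stdev alone; the rates stay put, so the move is
    # cheap (no likelihood change) and is judged purely by how well the
    # current rates fit the rescaled prior
    cm <- state$priors$rate_prior
    if (!inherits(cm, "clock_model"))
      stop("ucld_stdev operator needs a clock_model rate prior")
    s <- scale_draw(factor)
    st <- state
    st$priors$rate_prior <- clock_model(cm$ucld_stdev * s)
    list(state = st, log_green = -log(s), valid = TRUE,
         changed_distances = FALSE)
  }, TRUE, weight)

#' One Metropolis-Hastings-Green step
#'
#' Draws an operator proportionally to its weight, proposes, and accepts
#' with probability `min(1, exp(dlog target + log Green ratio))`.  Invalid
#' proposals leave the state unchanged and are counted separately.
#'
#' @param state an [mcmc_state()].
#' @param schedule an [operator_schedule()].
#' @param counts optional bookkeeping matrix (rows: operators; columns
#'   `proposed`, `accepted`, `invalid`), updated by reference semantics via
#'   the returned value.
#' @return `list(state, accepted, op_index, counts)`.
#' @export
metropolis_step <- function(state, schedule, counts = NULL) {
  if (!is.finite(state_log_target(state)))
    stop("current state has non-finite log target; chain is corrupt")
  k <- sample.int(length(schedule$ops), 1L, prob = schedule$probs)
  op <- schedule$ops[[k]]
  pr <- op$propose(state)
  accepted <- FALSE
  if (pr$valid) {
    new <- pr$state
    new$log_prior <- state_log_prior(new)
    new <- proposal_log_lik(new, pr)
    dlt <- state_log_target(new) - state_log_target(state)
    if (is.finite(new$log_prior) &&
        log(stats::runif(1)) < dlt + pr$log_green) {
      state <- new
      accepted <- TRUE
    }
  }
  if (!is.null(counts)) {
    counts[k, "proposed"] <- counts[k, "proposed"] + 1L
    if (accepted) counts[k, "accepted"] <- counts[k, "accepted"] + 1L
    if (!pr$valid) counts[k, "invalid"] <- counts[k, "invalid"] + 1L
  }
  list(state = state, accepted = accepted, op_index = k, counts = counts)
}

validate_run_config <- function(config) {
  errs <- character(0)
  need <- c("state", "schedule", "chain_length", "sample_every")
  for (f in need) if (is.null(config[[f]]))
    errs <- c(errs, paste0("missing config field '", f, "'"))
  if (!is.null(config$chain_length) && config$chain_length < 0)
    errs <- c(errs, "chain_length must be >= 0")
  if (!is.null(config$sample_every) && config$sample_every < 1)
    errs <- c(errs, "sample_every must be >= 1")
  if (!is.null(config$state) && !inherits(config$state, "mcmc_state"))
    errs <- c(errs, "state must be an mcmc_state")
  if (!is.null(config$state) && !is.null(config$schedule) &&
      config$state$mode == "fixed-distances") {
    bad <- vapply(config$schedule$ops,
                  function(o) !isTRUE(o$distance_preserving), TRUE)
    if (any(bad))
      errs <- c(errs, paste0(
        "fixed-distances mode cannot use distance-changing operators: ",
        paste(vapply(config$schedule$ops[bad], `[[`, "", "name"),
              collapse = ", ")))
  }
  if (length(errs)) stop(paste(errs, collapse = "\n"), call. = FALSE)
  invisible(TRUE)
}

#' Run an MCMC chain
#'
#' Deterministic given `seed`.  The trace records the initial state as its
#' first row and then one row every `sample_every` steps.  With
#' `audit_every > 0` the cached log prior / likelihood are recomputed from
#' scratch periodically and must agree with the caches to 1e-8.
#'
#' @param config list with `state` ([mcmc_state()]), `schedule`
#'   ([operator_schedule()]), `chain_length`, `sample_every`, optional
#'   `seed`, `audit_every`, `keep_trees`.
#' @return A list of class `"mcmc_run"`: `trace` (data frame, BEAST-style
#'   with a `Sample` first column), `state` (final), `counts` (per-operator
#'   bookkeeping), optionally `trees`.
#' @export
run_chain <- function(config) {
  validate_run_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  state <- config$state
  schedule <- config$schedule
  audit_every <- config$audit_every %||% 0L
  keep_trees <- isTRUE(config$keep_trees)
  nsteps <- as.integer(config$chain_length)
  every <- as.integer(config$sample_every)
  counts <- matrix(0L, length(schedule$ops), 3,
                   dimnames = list(vapply(schedule$ops, `[[`, "", "name"),
                                   c("proposed", "accepted", "invalid")))
  nsamp <- nsteps %/% every + 1L
  cols <- c("Sample", "posterior", "prior", "likelihood", "tree_height",
            "tree_length", "ucld_stdev", "kappa", "lambda")
  buf <- matrix(NA_real_, nsamp, length(cols), dimnames = list(NULL, cols))
  trees <- if (keep_trees) vector("list", nsamp) else NULL
  record <- function(row, step, st) {
    buf[row, ] <<- c(step, state_log_target(st), st$log_prior, st$log_lik,
                     tree_height(st$tree), tree_length(st$tree),
                     if (inherits(st$priors$rate_prior, "clock_model"))
                       st$priors$rate_prior$ucld_stdev else NA_real_,
                     if (!is.null(st$model)) st$model$kappa else NA_real_,
                     if (inherits(st$priors$tree_prior, "yule_prior"))
                       st$priors$tree_prior$lambda else NA_real_)
    if (keep_trees) trees[[row]] <<- st$tree
  }
  record(1L, 0L, state)
  row <- 2L
  if (nsteps > 0) for (i in seq_len(nsteps)) {
    stp <- metropolis_step(state, schedule, counts)
    state <- stp$state; counts <- stp$counts
    if (audit_every > 0 && i %% audit_every == 0L) {
      if (abs(state$log_prior - state_log_prior(state)) > 1e-8 ||
          abs(state$log_lik - state_log_lik(state)) > 1e-8)
        stop("audit failure: cached log densities diverged at step ", i)
    }
    if (i %% every == 0L) { record(row, i, state); row <- row + 1L }
  }
  trace <- as.data.frame(buf)
  trace$Sample <- as.integer(trace$Sample)
  structure(list(trace = trace, state = state, counts = counts,
                 trees = trees),
            class = "mcmc_run")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Effective sample size
#'
#' `ESS = n / (1 + 2 * sum(rho_k))` with sample autocorrelations summed up
#' to (excluding) the first non-positive lag, clamped into `[1, n]`.  A
#' constant series reports 1 with a `degenerate` attribute.
#'
#' @param x numeric series (length >= 10).
#' @return ESS (scalar) with attribute `degenerate`.
#' @export
effective_sample_size <- function(x) {
  n <- length(x)
  if (n < 10) stop("need at least 10 samples")
  if (stats::sd(x) == 0 || !is.finite(stats::sd(x)))
    return(structure(1, degenerate = TRUE))
  rho <- stats::acf(x, lag.max = min(n - 1L, 10000L), plot = FALSE,
                    demean = TRUE)$acf[-1]
  stop_at <- which(rho <= 0)
  if (length(stop_at)) rho <- rho[seq_len(stop_at[1] - 1L)]
  ess <- n / (1 + 2 * sum(rho))
  structure(min(max(ess, 1), n), degenerate = FALSE)
}

#' Write a BEAST/Tracer-style trace log
#'
#' Tab-separated with a header row and `Sample` first column.
#'
#' @param run an `"mcmc_run"` (or its `trace` data frame).
#' @param file output path.
#' @export
write_trace <- function(run, file) {
  tr <- if (inherits(run, "mcmc_run")) run$trace else run
  utils::write.table(tr, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
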