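#' Three-taxon validation fixtures
#'
#' Programmatic regeneration of the prior-sampling test settings: a
#' three-taxon tree (tips `A`, `B`, `C`, internal node `D`, root `E`) with
#' fixed genetic distances, initial ages, and the rate/coalescent priors of
#' the validation experiments.  `d_A`, `d_B` hang below `D`; `d_D` is the
#' root-side branch above `D` and `d_C` the branch above tip `C` (spans
#' `t_E - t_D` and `t_E`).
#'
#' Available fixtures and what varies under the operator being validated:
#' \describe{
#'   \item{`scenario1`}{internal-node move; `t_D` varies in (0, 10);
#'     distances 0.1/0.2/0.4/0.27, initial rates 0.1/0.2/0.04/0.03.}
#'   \item{`scenario2`}{internal-node move; `t_D` varies in (0, 0.8);
#'     distances 0.4/0.8/2.4/1.6, initial rates 1/2/3/4.}
#'   \item{`simple_distance`}{root-time move; `t_E` varies in (1, Inf).}
#'   \item{`small_pulley`}{root distance split; `d_D + d_C = 0.67` fixed,
#'     the split varies.}
#'   \item{`big_pulley`}{root re-hang; `t_E`, `t_D`, the root split
#'     `d_D + d_C = 0.5` and the rooted topology all vary; all tip pairwise
#'     distances equal 1.  The reference density for this fixture keeps the
#'     coalescent factor and uses rate spread `s = 0.5` (the settings under
#'     which its recorded reference statistics are reproduced; see the
#'     methods vignette).}
#' }
#'
#' @param name fixture name.
#' @return A list of class `"fixture_spec"`: `name`, `d` (named A/B/C/D),
#'   `t_D`, `t_E`, `varying`, `rate_prior` ([lognormal_prior()]),
#'   `coalescent` ([coalescent_prior()]), `reference_tree_prior` (does the
#'   fixture's reference density include the coalescent factor?), and
#'   `tree`, the initial [timetree()] whose rates reproduce the recorded
#'   initial rates exactly.
#' @export
make_fixture <- function(name = c("scenario1", "scenario2",
                                  "simple_distance", "small_pulley",
                                  "big_pulley")) {
  name <- match.arg(name)
  fx <- switch(name,
    scenario1 = list(d = c(A = 0.1, B = 0.2, C = 0.4, D = 0.27),
                     t_D = 1, t_E = 10, varying = "t_D", s = 0.25,
                     reference_tree_prior = FALSE),
    scenario2 = list(d = c(A = 0.4, B = 0.8, C = 2.4, D = 1.6),
                     t_D = 0.4, t_E = 0.8, varying = "t_D", s = 0.25,
                     reference_tree_prior = FALSE),
    simple_distance = list(d = c(A = 0.1, B = 0.2, C = 0.4, D = 0.27),
                           t_D = 1, t_E = 10, varying = "t_E", s = 0.25,
                           reference_tree_prior = FALSE),
    small_pulley = list(d = c(A = 0.1, B = 0.2, C = 0.4, D = 0.27),
                        t_D = 1, t_E = 10, varying = "root_split",
                        s = 0.25, reference_tree_prior = FALSE),
    big_pulley = list(d = c(A = 0.5, B = 0.5, C = 0.3, D = 0.2),
                      t_D = 5, t_E = 10,
                      varying = c("t_E", "t_D", "root_split", "topology"),
                      s = 0.5, reference_tree_prior = TRUE))
  fx$name <- name
  fx$rate_prior <- lognormal_prior(m = -3, s = fx$s)
  fx$coalescent <- coalescent_prior(0.3)
  fx$tree <- fixture_tree(fx)
  class(fx) <- "fixture_spec"
  fx
}

# tips A=1, B=2, C=3; D=4; root E=5
fixture_tree <- function(fx) {
  parent <- c(4L, 4L, 5L, 5L, NA)
  times <- c(0, 0, 0, fx$t_D, fx$t_E)
  rates <- c(fx$d["A"] / fx$t_D, fx$d["B"] / fx$t_D,
             fx$d["C"] / fx$t_E, fx$d["D"] / (fx$t_E - fx$t_D), NA)
  timetree(c("A", "B", "C"), parent, times, rates)
}

#' @export
print.fixture_spec <- function(x, ...) {
  cat("Fixture", x$name, "- distances",
      paste(sprintf("%s=%g", names(x$d), x$d), collapse = ", "), "\n")
  cat("  t_D =", x$t_D, ", t_E =", x$t_E,
      "; varying:", paste(x$varying, collapse = ", "), "\n")
  cat("  rate prior LogNormal(m =", x$rate_prior$m, ", s =",
      x$rate_prior$s, "), coalescent N =", x$coalescent$N, "\n")
  invisible(x)
}

#' Initial MCMC state for a fixture
#'
#' The fixture tree plus its priors, ready for a prior-mode [run_chain()].
#'
#' @param fx a [make_fixture()] result.
#' @return An [mcmc_state()] in `"prior"` mode.
#' @export
fixture_state <- function(fx) {
  mcmc_state(fx$tree,
             prior_spec(tree_prior = fx$coalescent,
                        rate_prior = fx$rate_prior,
                        stdev_hyperprior = NULL),
             mode = "prior")
}
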