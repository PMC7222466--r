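#' Clock standard-deviation scale operator with rate quantile matching
#'
#' Rescales the relaxed-clock standard deviation
#' `s' = s * scale`, with `scale = Factor + xi * (1/Factor - Factor)` and
#' `xi ~ Uniform(0, 1)`, and maps every branch rate through quantile
#' matching so that each rate keeps its percentile under the mean-one
#' log-normal clock prior:
#' `r_i' = icdf_{s'}(cdf_s(r_i))`.
#'
#' The mean-one constraint (`m(s) = -s^2/2` in log space) gives the
#' quantile map the closed form
#' `ln r' = m(s') + (s'/s) (ln r - m(s))`; the operator evaluates the
#' generic cdf/icdf composition, which must (and, in the tests, does) agree
#' with that closed form.  The log Hastings term is
#' `-ln scale + sum_i ln d r_i'/d r_i`, the scale-kernel ratio plus the
#' Jacobian of the quantile map, with the product running over the actual
#' branch rates of the state (`2n - 2` on a rooted binary tree).
#'
#' @param tree a [timetree()] whose rates follow the clock model.
#' @param ucld_stdev current log-space standard deviation `s`.
#' @param factor scale boldness, in (0, 1); `scale` then lies in
#'   `(factor, 1/factor)`.
#' @param xi optional fixed uniform draw (testing hook).
#' @return A list: `tree` (rates remapped), `ucld_stdev` (new `s'`),
#'   `scale`, `log_green`, `valid`.
#' @export
propose_stdev_and_rates <- function(tree, ucld_stdev, factor = 0.75,
                                    xi = NULL) {
  stopifnot(ucld_stdev > 0, factor > 0, factor < 1)
  if (is.null(xi)) xi <- stats::runif(1)
  scale <- factor + xi * (1 / factor - factor)
  s <- ucld_stdev; sp <- s * scale
  m <- -s^2 / 2; mp <- -sp^2 / 2
  nonroot <- setdiff(seq_along(tree$parent), tree$root)
  r <- tree$rates[nonroot]
  # generic quantile matching: r' = icdf_{s'}(cdf_s(r))
  rp <- stats::qlnorm(stats::plnorm(r, m, s), mp, sp)
  if (any(!is.finite(rp)) || any(rp <= 0))
    return(list(tree = tree, ucld_stdev = ucld_stdev, scale = scale,
                log_green = -Inf, valid = FALSE))
  # d r'/d r = pdf_s(r) / pdf_{s'}(r')
  dlog <- stats::dlnorm(r, m, s, log = TRUE) -
    stats::dlnorm(rp, mp, sp, log = TRUE)
  new <- tree
  new$rates[nonroot] <- rp
  list(tree = new, ucld_stdev = sp, scale = scale,
       log_green = -log(scale) + sum(dlog), valid = TRUE)
}

#' Closed-form log-normal quantile map
#'
#' Reference implementation of the quantile-matching map between mean-one
#' log-normal distributions: `ln r' = -s'^2/2 + (s'/s)(ln r + s^2/2)`.
#' Used as a strong oracle against the generic cdf/icdf route.
#'
#' @param r rate(s).
#' @param s,sp old and new log-space standard deviations.
#' @return Mapped rate(s).
#' @export
lognormal_quantile_map <- function(r, s, sp) {
  exp(-sp^2 / 2 + (sp / s) * (log(r) + s^2 / 2))
}
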