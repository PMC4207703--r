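#' Build an offset-lognormal calibration prior from a fossil constraint
#'
#' The prior on the constrained node's age is `offset + X` where
#' `X ~ Lognormal(mu, sigma)` and the offset is the fossil's minimum age, so
#' the density is zero below the fossil age (a hard minimum). To model
#' taphonomic bias — the oldest recovered fossil postdates the lineage's
#' origin — `mu` is set so the exceedance's real-space median is
#' `offset_fraction * min_age`: `mu = ln(offset_fraction * min_age)`,
#' placing the prior median `offset_fraction` (e.g. 10% or 50%) above the
#' fossil age. `mu` is rounded to one decimal by default, matching how such
#' priors are reported.
#'
#' @param fossil a [fossil_constraint()].
#' @param offset_fraction how far above the fossil age the prior median sits,
#'   as a fraction of the minimum age: 0.10 and 0.50 are the two standard
#'   scenarios (`plus10`, `plus50`).
#' @param sigma log-space standard deviation, default 0.5.
#' @param round_mu round `mu` to one decimal place (default `TRUE`).
#' @param scenario label; inferred from `offset_fraction` when `NULL`.
#' @return an object of class `calibration_prior` with fields `fossil_id`,
#'   `taxon_set`, `offset`, `mu`, `sigma`, `scenario`.
#' @export
#' @examples
#' f <- fossil_constraint("cup", c("X", "Y"), min_age = 160)
#' build_prior(f, 0.5)$mu   # ln(80) rounded: 4.4
#' build_prior(f, 0.1)$mu   # ln(16) rounded: 2.8
build_prior <- function(fossil, offset_fraction, sigma = 0.5,
                        round_mu = TRUE, scenario = NULL) {
  stopifnot(inherits(fossil, "fossil_constraint"))
  if (!is.numeric(offset_fraction) || offset_fraction <= 0)
    stop("offset_fraction must be > 0")
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0")
  mu <- log(offset_fraction * fossil$min_age)
  if (round_mu) mu <- round(mu, 1)
  if (is.null(scenario))
    scenario <- if (isTRUE(all.equal(offset_fraction, 0.1))) "plus10"
                else if (isTRUE(all.equal(offset_fraction, 0.5))) "plus50"
                else "custom"
  structure(list(fossil_id = fossil$id, taxon_set = fossil$taxon_set,
                 offset = fossil$min_age, mu = mu, sigma = sigma,
                 scenario = scenario),
            class = "calibration_prior")
}

#' @export
print.calibration_prior <- function(x, ...) {
  ci <- prior_ci(x)
  cat(sprintf(
    "offset-lognormal prior '%s' [%s]: offset %g Ma, mu %g, sigma %g (95%% CI %.4g-%.4g Ma)\n",
    x$fossil_id, x$scenario, x$offset, x$mu, x$sigma, ci[1], ci[2]))
  invisible(x)
}

#' Central confidence interval of an offset-lognormal prior
#'
#' The central `level` interval of `offset + Lognormal(mu, sigma)`:
#' `offset + exp(mu -/+ z * sigma)` with `z` the standard-normal
#' `(1 + level)/2` quantile. As `level -> 0` both ends collapse onto the
#' prior median `offset + exp(mu)`.
#'
#' @param prior a [build_prior()] object (or any list with `offset`, `mu`,
#'   `sigma`).
#' @param level interval mass in `(0, 1)`, default 0.95.
#' @return `c(low, high)` in Ma.
#' @export
prior_ci <- function(prior, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  z <- stats::qnorm((1 + level) / 2)
  prior$offset + exp(prior$mu + c(-1, 1) * z * prior$sigma)
}

#' Stratigraphic upper bound on a lineage's time of origin
#'
#' The classical nonparametric confidence bound on the true time of origin of
#' a lineage given the age of its oldest fossil and the number `n` of
#' (consistent) fossil horizons: `age * (1 - confidence)^(-1/d)`, with the
#' exponent denominator `d` equal to `n` (default) or `n - 1`. Under uniform
#' fossil recovery the oldest of `n` finds underestimates the origin by a
#' factor with this quantile.
#'
#' @param oldest_fossil_age age of the oldest fossil in Ma.
#' @param n number of fossils in the consistent set.
#' @param confidence confidence level in `[0, 1)`; 0 returns the fossil age
#'   itself.
#' @param exponent_denominator `"n"` or `"n_minus_1"`.
#' @return the upper bound in Ma.
#' @export
#' @examples
#' marshall_upper_bound(100, n = 5, confidence = 0.95)             # 182.06
#' marshall_upper_bound(100, 5, 0.95, "n_minus_1")                 # 211.47
marshall_upper_bound <- function(oldest_fossil_age, n, confidence = 0.95,
                                 exponent_denominator = c("n", "n_minus_1")) {
  exponent_denominator <- match.arg(exponent_denominator)
  if (!is.numeric(oldest_fossil_age) || oldest_fossil_age <= 0)
    stop("oldest_fossil_age must be > 0")
  if (confidence < 0 || confidence >= 1) stop("confidence must be in [0, 1)")
  d <- if (exponent_denominator == "n") n else n - 1
  if (!is.numeric(n) || n < 1 || d < 1)
    stop("need n >= 1 (n >= 2 when the denominator is n - 1)")
  oldest_fossil_age * (1 - confidence)^(-1 / d)
}

#' Does a calibration prior bracket a stratigraphic bound?
#'
#' Checks that the upper end of the prior's central interval reaches at least
#' the given bound (inclusive): the prior leaves room for the node to be as
#' old as the stratigraphic confidence bound allows.
#'
#' @inheritParams prior_ci
#' @param bound the bound in Ma, e.g. from [marshall_upper_bound()].
#' @return `TRUE` or `FALSE`.
#' @export
check_bracketing <- function(prior, bound, level = 0.95) {
  if (!is.numeric(bound) || bound <= 0) stop("bound must be > 0")
  prior_ci(prior, level)[2] >= bound
}

#' Fit a lognormal prior to a stated median and confidence interval
#'
#' Solves for `(mu, sigma)` of a plain lognormal from a central interval:
#' `sigma = ln(high/low) / (2 z)`, `mu = ln(center)`. The fit is exact when
#' `center` is the geometric mean of `low` and `high`; otherwise the achieved
#' interval (returned) differs slightly from the requested one. Used for root
#' priors stated as, e.g., "mean c. 300 Ma, 95% CI 260-350 Ma".
#'
#' @param center the prior's central value in Ma (used as the median).
#' @param low,high the stated interval in Ma; `0 < low < center < high`.
#' @param level interval mass, default 0.95.
#' @return a list with `mu`, `sigma`, and `achieved_ci` (the fitted
#'   distribution's central interval).
#' @export
#' @examples
#' fit_lognormal_from_ci(300, 260, 350)
fit_lognormal_from_ci <- function(center, low, high, level = 0.95) {
  if (!(0 < low && low < center && center < high))
    stop("need 0 < low < center < high")
  z <- stats::qnorm((1 + level) / 2)
  sigma <- log(high / low) / (2 * z)
  mu <- log(center)
  list(mu = mu, sigma = sigma,
       achieved_ci = exp(mu + c(-1, 1) * z * sigma))
}

#' Tabulate calibration priors with bracketing diagnostics
#'
#' One row per prior: offset, parameters, central interval, the stratigraphic
#' bound and whether the prior brackets it.
#'
#' @param priors a list of [build_prior()] objects.
#' @param bound stratigraphic upper bound in Ma (recycled), or `NA` to skip
#'   the bracketing check.
#' @param level interval mass, default 0.95.
#' @return a data frame with columns `fossil_id`, `scenario`, `offset_ma`,
#'   `sigma`, `mu`, `ci_low`, `ci_high`, `marshall_bound`, `bracketing_ok`.
#' @export
prior_table <- function(priors, bound = NA_real_, level = 0.95) {
  if (inherits(priors, "calibration_prior")) priors <- list(priors)
  rows <- lapply(priors, function(p) {
    ci <- prior_ci(p, level)
    data.frame(fossil_id = p$fossil_id, scenario = p$scenario,
               offset_ma = p$offset, sigma = p$sigma, mu = p$mu,
               ci_low = ci[1], ci_high = ci[2],
               marshall_bound = bound,
               bracketing_ok = if (is.na(bound)) NA
                               else check_bracketing(p, bound, level),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
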