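#' Posterior draws of the reappearance rate
#'
#' The reappearance rate pi is the probability that a female observed
#' breeding in one year is observed at the same colony the next year. With
#' `successes` reappearances out of `trials` observations and a uniform
#' prior, the posterior is Beta(successes + 1, trials - successes + 1).
#'
#' @param successes Number of trials reappearing at the same colony.
#' @param trials Number of year-1 breeding observations.
#' @param M Number of Monte-Carlo draws (default 1e5).
#' @param seed Optional RNG seed.
#' @return Numeric vector of `M` draws of pi.
#' @export
posterior_pi <- function(successes, trials, M = 1e5, seed = NULL) {
  if (trials <= 0) stop("trials must be positive")
  if (successes < 0 || successes > trials)
    stop("successes must lie in [0, trials]")
  if (!is.null(seed)) set.seed(seed)
  stats::rbeta(M, successes + 1, trials - successes + 1)
}

#' Construct a return-rate fit from a slope estimate and its error
#'
#' Container for the annual return rate tau (survival x tag retention) as
#' estimated on the probability scale with a standard error, e.g. from
#' [fit_return_rate()] or from a published estimate with an interval.
#'
#' @param estimate Point estimate of tau in (0, 1).
#' @param se Standard error of the estimate (> 0).
#' @param age_range Ages used by the fit (informational).
#' @param n_points Number of age classes used (informational).
#' @return An object of class `return_rate_fit`.
#' @export
return_rate_fit <- function(estimate, se, age_range = c(NA, NA),
                            n_points = NA_integer_) {
  if (!is.finite(estimate) || estimate <= 0 || estimate >= 1)
    stop("return-rate estimate must lie in (0, 1)")
  if (!is.finite(se) || se <= 0) stop("se must be positive")
  structure(list(estimate = estimate, se = se,
                 age_range = age_range, n_points = n_points),
            class = "return_rate_fit")
}

#' @export
print.return_rate_fit <- function(x, ...) {
  cat(sprintf("Return rate tau = %.4f (se %.4f), ages %s-%s, %s points\n",
              x$estimate, x$se, x$age_range[1], x$age_range[2],
              x$n_points))
  invisible(x)
}

#' Estimate the annual return rate from an age distribution
#'
#' Under constant detection across years and adult ages, the observed count
#' of breeding females at age a is proportional to tau^a, so tau is
#' recovered from the slope of an ordinary least-squares regression of
#' log(count) on age. The slope standard error is carried to the tau scale
#' by the delta method (se_tau = exp(slope) * se_slope).
#'
#' @param age_counts data.frame with columns `age` and `count` for one
#'   colony, e.g. one colony's rows of [tally_ages()] output.
#' @param a_min,a_max Age range used for the fit (defaults 4 and 14; age 3
#'   is excluded because not all females have recruited by then).
#' @return A [return_rate_fit()] object.
#' @export
fit_return_rate <- function(age_counts, a_min = 4, a_max = 14) {
  use <- age_counts[age_counts$age >= a_min & age_counts$age <= a_max, ,
                    drop = FALSE]
  zero <- use$count <= 0
  if (any(zero)) {
    warning("dropping ", sum(zero), " age class(es) with zero count")
    use <- use[!zero, , drop = FALSE]
  }
  if (nrow(use) < 3)
    stop("fewer than 3 usable age classes in [", a_min, ", ", a_max, "]")
  fit <- stats::lm(log(count) ~ age, data = use)
  slope <- unname(stats::coef(fit)["age"])
  ## noise-free geometric input gives a perfect fit; that is fine here
  se_slope <- withCallingHandlers(
    unname(sqrt(diag(stats::vcov(fit)))["age"]),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  tau <- exp(slope)
  if (tau >= 1)
    warning("age counts do not decay (tau >= 1); fit invalid")
  return_rate_fit(estimate = min(tau, 1 - 1e-12),
                  se = max(tau * se_slope, 1e-12),
                  age_range = range(use$age), n_points = nrow(use))
}

#' Posterior draws of the return rate
#'
#' Draws tau from Normal(estimate, se) truncated to (0, 1). A warning is
#' issued when truncation removes more than 10% of the Normal mass, which
#' indicates a badly shaped fit.
#'
#' @param fit A [return_rate_fit()] object.
#' @param M Number of draws.
#' @param seed Optional RNG seed.
#' @return Numeric vector of `M` draws of tau.
#' @export
posterior_tau <- function(fit, M = 1e5, seed = NULL) {
  stopifnot(inherits(fit, "return_rate_fit"))
  if (!is.null(seed)) set.seed(seed)
  lo <- stats::pnorm(0, fit$estimate, fit$se)
  hi <- stats::pnorm(1, fit$estimate, fit$se)
  if (hi - lo < 0.9)
    warning("truncation to (0,1) discards ",
            sprintf("%.1f%%", 100 * (1 - (hi - lo))),
            " of the Normal mass; tau prior badly shaped")
  stats::qnorm(stats::runif(M, lo, hi), fit$estimate, fit$se)
}

#' Annual detection from reappearance and return draws
#'
#' Annual detection is the probability a tagged female present in a season
#' is observed at least once that season: delta = pi / tau, because
#' reappearance requires both returning (alive and tagged) and being
#' detected.
#'
#' @param pi_draws,tau_draws Equal-length draw vectors, paired
#'   element-wise.
#' @return Vector of delta draws. Draws of 1 or more are left in place but
#'   flagged with a warning and an `"n_above_one"` attribute.
#' @export
annual_detection <- function(pi_draws, tau_draws) {
  if (length(pi_draws) != length(tau_draws))
    stop("draw vectors must have equal length")
  if (any(tau_draws <= 0)) stop("tau draws must be positive")
  delta <- pi_draws / tau_draws
  n_bad <- sum(delta >= 1)
  if (n_bad > 0) {
    warning(n_bad, " delta draw(s) at or above 1; pi and tau are in ",
            "tension (detection cannot exceed certainty)")
    attr(delta, "n_above_one") <- n_bad
  }
  delta
}

#' Lifetime detection from annual detection and return rate
#'
#' The probability that a female who breeds at least once is ever observed:
#' Delta = delta / (1 - tau (1 - delta)). The factor 1 / (1 - tau(1 -
#' delta)) is the expected number of seasons until detection, so lifetime
#' detection is annual detection times expected detection age.
#'
#' @param delta_draws,tau_draws Equal-length vectors in (0, 1), paired
#'   element-wise.
#' @return Vector of Delta draws.
#' @export
lifetime_detection <- function(delta_draws, tau_draws) {
  if (length(delta_draws) != length(tau_draws))
    stop("draw vectors must have equal length")
  if (any(delta_draws < 0) || any(delta_draws > 1))
    stop("delta draws must lie in [0, 1]")
  if (any(tau_draws < 0) || any(tau_draws >= 1))
    stop("tau draws must lie in [0, 1)")
  delta_draws / (1 - tau_draws * (1 - delta_draws))
}

#' Ratio of lifetime detection between colonies
#'
#' The dispersal correction depends only on the ratio of lifetime
#' detection probabilities between destination and origin colony,
#' Delta_ji = Delta_j / Delta_i; the opposite direction uses the
#' reciprocal.
#'
#' @param delta_draws_j Lifetime-detection draws at the destination colony.
#' @param delta_draws_i Lifetime-detection draws at the origin colony.
#' @return Vector of ratio draws.
#' @export
detection_ratio <- function(delta_draws_j, delta_draws_i) {
  if (length(delta_draws_j) != length(delta_draws_i))
    stop("draw vectors must have equal length")
  if (any(delta_draws_i <= 0)) stop("origin draws must be positive")
  delta_draws_j / delta_draws_i
}

#' Full detection posterior for a two-colony system
#'
#' Builds the Monte-Carlo detection posterior consumed by the dispersal
#' sampler: per-colony draws of reappearance pi (Beta posterior from
#' counts), return tau (truncated Normal from a regression fit), annual
#' detection delta = pi/tau, lifetime detection Delta, and the
#' between-colony ratio draws in both directions. pi and tau are treated as
#' independent posteriors and paired element-wise.
#'
#' @param reapp Reappearance counts (`colony`, `trials`, `same`), e.g. from
#'   [tally_reappearance()] or [seal_reappearance()].
#' @param tau_fits Named list of [return_rate_fit()] objects, one per
#'   colony label appearing in `reapp`.
#' @param M Number of draws (default 1e5).
#' @param seed RNG seed for the whole draw set.
#' @return An object of class `detection_posterior`: a list with `colonies`
#'   (per-colony lists of `pi`, `tau`, `delta`, `Delta` draw vectors) and
#'   `ratio` (named list of ratio draw vectors `"j/i"` for both orderings).
#' @export
estimate_detection <- function(reapp, tau_fits, M = 1e5, seed = NULL) {
  labs <- reapp$colony
  if (length(labs) != 2) stop("exactly two colonies required")
  if (!all(labs %in% names(tau_fits)))
    stop("tau_fits must be a named list covering: ",
         paste(labs, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  cols <- list()
  for (k in seq_along(labs)) {
    lab <- labs[k]
    pi_d <- posterior_pi(reapp$same[k], reapp$trials[k], M)
    tau_d <- posterior_tau(tau_fits[[lab]], M)
    delta_d <- annual_detection(pi_d, tau_d)
    Delta_d <- lifetime_detection(pmin(delta_d, 1 - 1e-12), tau_d)
    cols[[lab]] <- list(pi = pi_d, tau = tau_d, delta = delta_d,
                        Delta = Delta_d)
  }
  ratio <- list()
  ratio[[paste(labs[1], labs[2], sep = "/")]] <-
    detection_ratio(cols[[labs[1]]]$Delta, cols[[labs[2]]]$Delta)
  ratio[[paste(labs[2], labs[1], sep = "/")]] <-
    detection_ratio(cols[[labs[2]]]$Delta, cols[[labs[1]]]$Delta)
  structure(list(colonies = cols, ratio = ratio, M = M),
            class = "detection_posterior")
}

#' Summarize a detection posterior
#'
#' @param det A `detection_posterior` from [estimate_detection()].
#' @return data.frame with one row per (colony, parameter) and per ratio:
#'   posterior mean and central 95% interval.
#' @export
summarize_detection <- function(det) {
  stopifnot(inherits(det, "detection_posterior"))
  row <- function(colony, parameter, x)
    data.frame(colony = colony, parameter = parameter, mean = mean(x),
               lower = unname(stats::quantile(x, 0.025)),
               upper = unname(stats::quantile(x, 0.975)))
  out <- list()
  for (lab in names(det$colonies)) {
    cc <- det$colonies[[lab]]
    out[[length(out) + 1]] <- row(lab, "pi", cc$pi)
    out[[length(out) + 1]] <- row(lab, "tau", cc$tau)
    out[[length(out) + 1]] <- row(lab, "delta", cc$delta)
    out[[length(out) + 1]] <- row(lab, "Delta", cc$Delta)
  }
  for (nm in names(det$ratio))
    out[[length(out) + 1]] <- row(nm, "Delta_ratio", det$ratio[[nm]])
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.detection_posterior <- function(x, ...) {
  cat("Detection posterior (", x$M, " draws)\n", sep = "")
  print(summarize_detection(x), digits = 3)
  invisible(x)
}
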