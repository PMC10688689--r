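#' Observed (naive) natal dispersal ratio
#'
#' The fraction of observed breeders from one birth cohort first seen
#' breeding at the opposite colony: mu = b_emigrant / (b_emigrant +
#' b_resident). Biased when the two colonies differ in lifetime detection.
#'
#' @param b_emigrant,b_resident Observed emigrant and resident counts.
#' @return Proportion in [0, 1].
#' @export
naive_dispersal <- function(b_emigrant, b_resident) {
  if (any(b_emigrant < 0) || any(b_resident < 0)) stop("negative counts")
  tot <- b_emigrant + b_resident
  if (any(tot == 0)) stop("no observed breeders; rate undefined")
  b_emigrant / tot
}

#' Detection-corrected natal dispersal (point form)
#'
#' Corrects the observed dispersal ratio for unequal lifetime detection
#' using only the destination/origin detection ratio:
#' mu_hat = b_emigrant / (b_emigrant + b_resident * ratio). With ratio = 1
#' this reduces to the naive ratio.
#'
#' @inheritParams naive_dispersal
#' @param ratio Lifetime-detection ratio Delta_destination /
#'   Delta_origin (> 0).
#' @return Corrected proportion in [0, 1].
#' @export
corrected_dispersal_point <- function(b_emigrant, b_resident, ratio) {
  if (any(ratio <= 0)) stop("detection ratio must be positive")
  denom <- b_emigrant + b_resident * ratio
  if (any(denom == 0)) stop("zero denominator; rate undefined")
  b_emigrant / denom
}

#' Expected observed emigrant count given a corrected rate
#'
#' The data-facing inverse of the correction: the number of emigrants
#' expected to be *observed* out of `B_obs` observed breeders when the true
#' corrected dispersal rate is `mu_hat` and detection differs by `ratio`:
#' b = B mu ratio / (1 - mu (1 - ratio)). Feeding the result back through
#' [corrected_dispersal_point()] with residents `B_obs - b` recovers
#' `mu_hat` exactly.
#'
#' @param B_obs Observed number of breeders from the cohort.
#' @param mu_hat Corrected dispersal rate in [0, 1).
#' @param ratio Detection ratio Delta_destination / Delta_origin (> 0).
#' @return Expected observed emigrant count (not rounded).
#' @export
predict_observed <- function(B_obs, mu_hat, ratio) {
  if (any(B_obs < 0)) stop("B_obs must be non-negative")
  if (any(mu_hat < 0 | mu_hat >= 1)) stop("mu_hat must lie in [0, 1)")
  if (any(ratio <= 0)) stop("detection ratio must be positive")
  denom <- 1 - mu_hat * (1 - ratio)
  if (any(denom <= 0)) stop("non-positive denominator in prediction")
  B_obs * mu_hat * ratio / denom
}

#' Poisson log-likelihood of an observed emigrant count
#'
#' @param b_obs Observed count (non-negative integer).
#' @param b_expected Expected count under the model (>= 0). A zero
#'   expectation with a zero observation contributes 0 by convention.
#' @return Poisson log-probability of `b_obs`.
#' @export
loglik_counts <- function(b_obs, b_expected) {
  if (any(b_expected < 0)) stop("expected count must be non-negative")
  if (any(b_obs < 0) || any(b_obs != round(b_obs)))
    stop("observed count must be a non-negative integer")
  stats::dpois(b_obs, b_expected, log = TRUE)
}

#' Hierarchical (hyper-level) log-likelihood of annual rates
#'
#' Normal log-density of the per-cohort corrected rates given the
#' hyper-parameters: a common mean `theta` in the constant variant, or a
#' linear trend `nu * t + eta` in the trend variant, with residual
#' standard deviation `sigma` in both.
#'
#' @param mu_hats Vector of per-cohort corrected rates.
#' @param theta Hyper-mean (constant variant).
#' @param sigma Hyper standard deviation (> 0; non-positive values return
#'   -Inf so the sampler rejects them).
#' @param variant `"constant"` or `"trend"`.
#' @param nu,eta Trend slope and intercept (trend variant).
#' @param t Centered year covariate, one value per cohort (trend variant).
#' @return Sum of Normal log-densities.
#' @export
loglik_hyper <- function(mu_hats, theta = NULL, sigma, variant = "constant",
                         nu = NULL, eta = NULL, t = NULL) {
  if (!is.finite(sigma) || sigma <= 0) return(-Inf)
  m <- switch(variant,
              constant = rep(theta, length(mu_hats)),
              trend = nu * t + eta,
              stop("unknown variant: ", variant))
  sum(stats::dnorm(mu_hats, m, sigma, log = TRUE))
}

#' Configuration for the dispersal sampler
#'
#' @param n_steps Total Metropolis steps per chain (default 6000).
#' @param burn_in Steps discarded from the front of each chain (default
#'   2000); proposal scales are tuned during burn-in only.
#' @param n_chains Number of independent chains (default 4).
#' @param proposal_sd Initial random-walk proposal standard deviation
#'   applied to every parameter before tuning (default 0.05).
#' @param seed RNG seed; chain c uses `seed + c - 1`.
#' @param variant `"constant"` (hyper-mean theta) or `"trend"` (theta =
#'   nu * t + eta).
#' @param year_center Calendar year subtracted from birth years to form
#'   the trend covariate t (default 2002).
#' @param hierarchy If `FALSE`, the hyper-level is dropped and each annual
#'   rate gets an independent flat prior on (0, 1); used for validation
#'   against direct integration.
#' @return A list of class `dispersal_config`.
#' @export
dispersal_config <- function(n_steps = 6000, burn_in = 2000, n_chains = 4,
                             proposal_sd = 0.05, seed = 1,
                             variant = c("constant", "trend"),
                             year_center = 2002, hierarchy = TRUE) {
  variant <- match.arg(variant)
  if (burn_in >= n_steps) stop("burn_in must be smaller than n_steps")
  if (proposal_sd <= 0) stop("proposal_sd must be positive")
  structure(list(n_steps = n_steps, burn_in = burn_in,
                 n_chains = n_chains, proposal_sd = proposal_sd,
                 seed = seed, variant = variant,
                 year_center = year_center, hierarchy = hierarchy),
            class = "dispersal_config")
}

## One Metropolis chain. Per step: refresh the detection ratio by a uniform
## draw from its stored prior sample (never data-updated), then update each
## parameter one at a time with a Gaussian random walk. Proposal scales are
## adapted toward ~0.3 acceptance during burn-in and frozen afterwards.
run_chain <- function(b_obs, B, tt, ratio_draws, cfg, chain_seed) {
  set.seed(chain_seed)
  K <- length(b_obs)
  hier <- cfg$hierarchy
  trend <- cfg$variant == "trend"
  mu <- pmin(pmax((b_obs + 0.5) / (B + 1), 1e-6), 1 - 1e-6)
  theta <- mean(mu); sigma <- max(stats::sd(mu), 0.02)
  if (is.na(sigma)) sigma <- 0.02
  nu <- 0; eta <- mean(mu)

  hyper_mean <- function() if (trend) nu * tt + eta else rep(theta, K)
  n_par <- K + if (!hier) 0L else if (trend) 3L else 2L
  step_sd <- rep(cfg$proposal_sd, n_par)
  acc <- int_try <- rep(0L, n_par)
  tune_acc <- tune_try <- rep(0L, n_par)

  keep <- cfg$n_steps - cfg$burn_in
  out <- matrix(NA_real_, keep, n_par + 1L)
  n_ratio <- length(ratio_draws)

  ll_mu <- function(i, mu_i, r, hm) {
    bp <- B[i] * mu_i * r / (1 - mu_i * (1 - r))
    ll <- stats::dpois(b_obs[i], bp, log = TRUE)
    if (hier) ll <- ll + stats::dnorm(mu_i, hm[i], sigma, log = TRUE)
    ll
  }

  for (s in seq_len(cfg$n_steps)) {
    r <- ratio_draws[sample.int(n_ratio, 1L)]
    hm <- hyper_mean()
    ## annual rates, one at a time
    for (i in seq_len(K)) {
      prop <- mu[i] + stats::rnorm(1, 0, step_sd[i])
      tune_try[i] <- tune_try[i] + 1L
      if (prop > 0 && prop < 1) {
        lr <- ll_mu(i, prop, r, hm) - ll_mu(i, mu[i], r, hm)
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          mu[i] <- prop
          tune_acc[i] <- tune_acc[i] + 1L
        }
      }
    }
    if (hier) {
      if (!trend) {
        j <- K + 1L
        prop <- theta + stats::rnorm(1, 0, step_sd[j])
        tune_try[j] <- tune_try[j] + 1L
        lr <- sum(stats::dnorm(mu, prop, sigma, log = TRUE)) -
          sum(stats::dnorm(mu, theta, sigma, log = TRUE))
        if (log(stats::runif(1)) < lr) {
          theta <- prop; tune_acc[j] <- tune_acc[j] + 1L
        }
      } else {
        j <- K + 1L
        prop <- nu + stats::rnorm(1, 0, step_sd[j])
        tune_try[j] <- tune_try[j] + 1L
        lr <- sum(stats::dnorm(mu, prop * tt + eta, sigma, log = TRUE)) -
          sum(stats::dnorm(mu, nu * tt + eta, sigma, log = TRUE))
        if (log(stats::runif(1)) < lr) {
          nu <- prop; tune_acc[j] <- tune_acc[j] + 1L
        }
        j <- K + 2L
        prop <- eta + stats::rnorm(1, 0, step_sd[j])
        tune_try[j] <- tune_try[j] + 1L
        lr <- sum(stats::dnorm(mu, nu * tt + prop, sigma, log = TRUE)) -
          sum(stats::dnorm(mu, nu * tt + eta, sigma, log = TRUE))
        if (log(stats::runif(1)) < lr) {
          eta <- prop; tune_acc[j] <- tune_acc[j] + 1L
        }
      }
      j <- n_par
      prop <- sigma + stats::rnorm(1, 0, step_sd[j])
      tune_try[j] <- tune_try[j] + 1L
      if (prop > 0) {
        hm2 <- hyper_mean()
        lr <- sum(stats::dnorm(mu, hm2, prop, log = TRUE)) -
          sum(stats::dnorm(mu, hm2, sigma, log = TRUE))
        if (log(stats::runif(1)) < lr) {
          sigma <- prop; tune_acc[j] <- tune_acc[j] + 1L
        }
      }
    }
    if (s <= cfg$burn_in) {
      if (s %% 50L == 0L) {
        rate <- ifelse(tune_try > 0, tune_acc / tune_try, 0.3)
        step_sd <- step_sd * exp(rate - 0.3)
        step_sd <- pmin(pmax(step_sd, 1e-4), 1)
        tune_acc[] <- tune_try[] <- 0L
      }
      ## acceptance is reported for the retained part only
      if (s == cfg$burn_in) tune_acc[] <- tune_try[] <- 0L
    } else {
      acc <- acc + tune_acc; int_try <- int_try + tune_try
      tune_acc[] <- tune_try[] <- 0L
      hyp <- if (!hier) numeric(0)
             else if (trend) c(nu, eta, sigma) else c(theta, sigma)
      out[s - cfg$burn_in, ] <- c(mu, hyp, r)
    }
  }
  list(draws = out,
       accept = ifelse(int_try > 0, acc / int_try, NA_real_),
       step_sd = step_sd)
}

#' Fit the hierarchical dispersal model by Metropolis sampling
#'
#' Samples the joint posterior of the per-cohort corrected dispersal rates
#' and their hyper-parameters for one direction of movement. The
#' observation model is Poisson on the observed emigrant count with mean
#' given by [predict_observed()]; the hierarchy places a common Normal
#' across the annual rates ([loglik_hyper()]). At every Metropolis step the
#' lifetime-detection ratio is refreshed by a uniform draw from the stored
#' prior sample `ratio_draws` — it is never updated by the count data — and
#' every model parameter is then updated one at a time by a Gaussian
#' random walk. Chains start from the observed per-cohort ratios.
#'
#' @param counts data.frame with columns `birth_year`, `resident`,
#'   `emigrant`: one direction's cohort rows.
#' @param ratio_draws Monte-Carlo draws of the detection ratio
#'   Delta_destination / Delta_origin, e.g. one element of
#'   `estimate_detection()$ratio`.
#' @param config A [dispersal_config()].
#' @return Object of class `dispersal_fit`: `draws` (matrix of retained
#'   samples pooled over chains; columns `mu_<year>`, hyper-parameters,
#'   and the per-step detection `ratio`), `accept` (per-chain acceptance
#'   rates), plus the inputs and configuration.
#' @export
run_sampler <- function(counts, ratio_draws, config = dispersal_config()) {
  stopifnot(inherits(config, "dispersal_config"))
  req <- c("birth_year", "resident", "emigrant")
  if (!all(req %in% names(counts)))
    stop("counts needs columns: ", paste(req, collapse = ", "))
  if (length(ratio_draws) == 0 || any(ratio_draws <= 0))
    stop("ratio_draws must be a non-empty positive vector")
  counts <- counts[order(counts$birth_year), , drop = FALSE]
  b_obs <- counts$emigrant
  B <- counts$resident + counts$emigrant
  tt <- counts$birth_year - config$year_center
  K <- length(b_obs)
  if (K < 1) stop("no cohorts")
  if (config$variant == "trend" && !config$hierarchy)
    stop("trend variant requires the hierarchy")

  hyp_names <- if (!config$hierarchy) character(0)
               else if (config$variant == "trend") c("nu", "eta", "sigma")
               else c("theta", "sigma")
  par_names <- c(paste0("mu_", counts$birth_year), hyp_names, "ratio")

  chains <- lapply(seq_len(config$n_chains), function(cc)
    run_chain(b_obs, B, tt, ratio_draws, config, config$seed + cc - 1L))
  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  colnames(draws) <- par_names
  accept <- do.call(rbind, lapply(chains, `[[`, "accept"))
  colnames(accept) <- par_names[seq_len(ncol(accept))]
  structure(list(draws = draws, accept = accept, counts = counts,
                 config = config, par_names = par_names),
            class = "dispersal_fit")
}

#' Summarize a dispersal posterior
#'
#' Posterior mean and central 95% credible interval for every sampled
#' parameter. For the trend variant the summary records whether the year
#' effect `nu` is distinguishable from zero (its interval excluding zero).
#'
#' @param fit A `dispersal_fit` from [run_sampler()].
#' @param prob Credible mass (default 0.95, the central 95th percentiles).
#' @return data.frame with columns `parameter`, `mean`, `lower`, `upper`;
#'   for trend fits, attribute `"trend_nonzero"` (logical).
#' @export
summarize_posterior <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "dispersal_fit"))
  d <- fit$draws
  if (nrow(d) == 0) stop("empty chain")
  a <- (1 - prob) / 2
  keep <- setdiff(colnames(d), "ratio")
  res <- data.frame(
    parameter = keep,
    mean = colMeans(d[, keep, drop = FALSE]),
    lower = apply(d[, keep, drop = FALSE], 2, stats::quantile, probs = a),
    upper = apply(d[, keep, drop = FALSE], 2, stats::quantile,
                  probs = 1 - a))
  rownames(res) <- NULL
  if ("nu" %in% keep) {
    nu <- res[res$parameter == "nu", ]
    attr(res, "trend_nonzero") <- (nu$lower > 0 || nu$upper < 0)
  }
  res
}

#' @export
summary.dispersal_fit <- function(object, ...) summarize_posterior(object, ...)

#' @export
print.dispersal_fit <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Dispersal fit: %d cohorts, %s variant, %d chain(s) x %d steps (%d burn-in)\n",
              nrow(x$counts), cfg$variant, cfg$n_chains, cfg$n_steps,
              cfg$burn_in))
  print(summarize_posterior(x), digits = 3)
  invisible(x)
}

#' Fit natal dispersal for one direction from tallies and detection
#'
#' Convenience wrapper: selects the origin colony's cohort rows from a
#' [tally_cohorts()]-shaped table, picks the destination/origin
#' detection-ratio draws from a [estimate_detection()] posterior, and runs
#' the sampler.
#'
#' @param tally Cohort table with columns `birth_year`, `colony`,
#'   `resident`, `emigrant`.
#' @param det A `detection_posterior`.
#' @param from,to Origin and destination colony labels.
#' @param config A [dispersal_config()].
#' @return A `dispersal_fit` (with a `direction` element `"from->to"`).
#' @export
fit_dispersal <- function(tally, det, from, to,
                          config = dispersal_config()) {
  stopifnot(inherits(det, "detection_posterior"))
  rows <- tally[tally$colony == from, , drop = FALSE]
  if (nrow(rows) == 0) stop("no cohorts for origin colony ", from)
  key <- paste(to, from, sep = "/")
  if (!key %in% names(det$ratio))
    stop("no detection-ratio draws for ", key)
  fit <- run_sampler(rows[c("birth_year", "resident", "emigrant")],
                     det$ratio[[key]], config)
  fit$direction <- paste0(from, "->", to)
  fit
}
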