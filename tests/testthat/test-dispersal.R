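# Reduced-size study fits shared across blocks in this file (the full-size
# reproduction lives in the acceptance suite).
study_fits <- local({
  det <- study_detection(M = 2e4, seed = 42)
  cfg <- dispersal_config(n_steps = 3000, burn_in = 1000, n_chains = 2,
                          seed = 11)
  tab <- seal_cohorts()
  list(det = det,
       pb = fit_dispersal(tab, det, "PB", "AN", cfg),
       an = fit_dispersal(tab, det, "AN", "PB", cfg))
})

test_that("observed dispersal ratios match the published pooled fractions", {
  expect_equal(naive_dispersal(35, 566), 35 / 601)
  expect_equal(round(100 * naive_dispersal(35, 566), 1), 5.8)
  expect_equal(round(100 * naive_dispersal(124, 344), 1), 26.5)
  expect_equal(naive_dispersal(0, 7), 0)
  expect_error(naive_dispersal(0, 0), "undefined")
})

test_that("the detection correction restores the truth in the worked bias example", {
  # colony 2 under-observed (lifetime detection 0.5 vs 0.8): raw rates are
  # biased in opposite directions, the ratio correction recovers 10% both ways
  expect_equal(round(naive_dispersal(5, 72), 3), 0.065)
  expect_equal(round(naive_dispersal(8, 45), 2), 0.15)
  expect_equal(corrected_dispersal_point(5, 72, 0.5 / 0.8), 0.10)
  expect_equal(corrected_dispersal_point(8, 45, 0.8 / 0.5), 0.10)
  # no correction when detection is equal
  expect_equal(corrected_dispersal_point(7, 20, 1), naive_dispersal(7, 20))
  expect_error(corrected_dispersal_point(5, 72, 0), "positive")
})

test_that("predicted observed counts invert the correction exactly", {
  expect_equal(predict_observed(53, 0.10, 1.6), 8.0)
  expect_equal(predict_observed(40, 0, 1.3), 0)
  expect_equal(predict_observed(40, 0.25, 1), 10)
  # algebraic round-trip over random inputs
  set.seed(31)
  for (k in 1:200) {
    B <- sample(1:500, 1)
    mu <- runif(1, 0, 0.99)
    r <- exp(runif(1, -1.5, 1.5))
    b <- predict_observed(B, mu, r)
    expect_equal(corrected_dispersal_point(b, B - b, r), mu,
                 tolerance = 1e-12)
  }
  expect_error(predict_observed(-1, 0.1, 1), "non-negative")
  expect_error(predict_observed(10, 1, 1), "mu_hat")
})

test_that("count log-likelihood is the Poisson log-pmf", {
  # independent brute-force pmf: product form k*log(l) - l - log(k!)
  brute <- function(k, l) {
    if (l == 0) return(if (k == 0) 0 else -Inf)
    logfac <- if (k == 0) 0 else sum(log(seq_len(k)))
    k * log(l) - l - logfac
  }
  expect_equal(loglik_counts(3, 3.0), brute(3, 3.0))
  expect_equal(round(loglik_counts(3, 3.0), 4), -1.4959)
  expect_equal(loglik_counts(0, 0), 0)
  for (k in c(0L, 1L, 5L, 20L)) for (l in c(0.5, 2, 10))
    expect_equal(loglik_counts(k, l), brute(k, l), tolerance = 1e-10)
  expect_error(loglik_counts(2, -1), "non-negative")
  expect_error(loglik_counts(2.5, 1), "integer")
})

test_that("hyper-level log-likelihood sums Normal densities over cohorts", {
  mu <- rep(0.2, 17)
  expect_equal(loglik_hyper(mu, theta = 0.2, sigma = 0.3),
               17 * dnorm(0, 0, 0.3, log = TRUE))
  # direct density-product oracle on 3 cohorts
  mu3 <- c(0.1, 0.25, 0.4)
  direct <- log(prod(exp(-(mu3 - 0.2)^2 / (2 * 0.09)) /
                       sqrt(2 * pi * 0.09)))
  expect_equal(loglik_hyper(mu3, theta = 0.2, sigma = 0.3), direct)
  # trend with zero slope nests the constant model
  tt <- -8:8
  expect_equal(
    loglik_hyper(mu, sigma = 0.1, variant = "trend", nu = 0, eta = 0.2,
                 t = tt),
    loglik_hyper(mu, theta = 0.2, sigma = 0.1))
  expect_identical(loglik_hyper(mu, theta = 0.2, sigma = -1), -Inf)
})

test_that("single-cohort flat-prior sampler matches grid integration", {
  counts <- data.frame(birth_year = 2000L, resident = 15L, emigrant = 5L)
  r <- 1.3
  fit <- run_sampler(counts, r,
                     dispersal_config(n_steps = 20000, burn_in = 4000,
                                      n_chains = 2, seed = 8,
                                      hierarchy = FALSE))
  # independent oracle: Poisson likelihood x uniform prior on a fine grid
  mu_grid <- seq(5e-4, 1 - 5e-4, by = 1e-3)
  lam <- 20 * mu_grid * r / (1 - mu_grid * (1 - r))
  w <- exp(dpois(5L, lam, log = TRUE))
  oracle_mean <- sum(mu_grid * w) / sum(w)
  oracle_sd <- sqrt(sum(mu_grid^2 * w) / sum(w) - oracle_mean^2)
  ch <- fit$draws[, "mu_2000"]
  mc_se <- oracle_sd / sqrt(200)  # generous effective sample size floor
  expect_lt(abs(mean(ch) - oracle_mean), 3 * mc_se)
  expect_equal(sd(ch), oracle_sd, tolerance = 0.15)
})

test_that("flat hierarchy with unit detection ratio recovers naive rates", {
  counts <- data.frame(birth_year = 2000:2002,
                       resident = c(700L, 600L, 800L),
                       emigrant = c(300L, 200L, 400L))
  fit <- run_sampler(counts, 1,
                     dispersal_config(n_steps = 8000, burn_in = 2000,
                                      n_chains = 2, seed = 9,
                                      hierarchy = FALSE))
  s <- summarize_posterior(fit)
  naive <- counts$emigrant / (counts$resident + counts$emigrant)
  expect_equal(s$mean[match(paste0("mu_", 2000:2002), s$parameter)],
               naive, tolerance = 0.02)
})

test_that("sampler handles the no-signal and shrinkage regimes", {
  # all-zero emigrants, ratio 1: hyper-mean concentrates near zero
  zero <- data.frame(birth_year = 2000:2008, resident = 40L,
                     emigrant = 0L)
  f0 <- run_sampler(zero, 1, dispersal_config(n_steps = 4000,
                                              burn_in = 1000,
                                              n_chains = 2, seed = 12))
  s0 <- summarize_posterior(f0)
  expect_lt(s0$mean[s0$parameter == "theta"], 0.05)

  # hierarchical shrinkage on the study data: zero-emigrant cohorts get a
  # strictly positive rate below the largest annual naive rate
  s <- summarize_posterior(study_fits$pb)
  tab <- seal_cohorts()
  pb <- tab[tab$colony == "PB", ]
  zero_years <- pb$birth_year[pb$emigrant == 0]
  naive_max <- max(pb$emigrant / pmax(pb$breeding, 1))
  for (y in zero_years) {
    m <- s$mean[s$parameter == paste0("mu_", y)]
    expect_gt(m, 0)
    expect_lt(m, naive_max)
  }
})

test_that("chains are valid: tuned acceptance, seed-stable means", {
  f <- study_fits$pb
  expect_true(all(f$accept > 0.1 & f$accept < 0.6))
  cfg2 <- f$config; cfg2$seed <- 101
  f2 <- run_sampler(f$counts, study_fits$det$ratio[["AN/PB"]], cfg2)
  th1 <- mean(f$draws[, "theta"]); th2 <- mean(f2$draws[, "theta"])
  expect_lt(abs(th1 - th2), sd(f$draws[, "theta"]))
})

test_that("posterior summaries report means, intervals, and the trend test", {
  # degenerate chain: mean equals the constant, zero-width interval
  const <- structure(list(
    draws = cbind(mu_2000 = rep(0.3, 100), theta = rep(0.3, 100),
                  sigma = rep(0.1, 100), ratio = rep(1, 100))),
    class = "dispersal_fit")
  s <- summarize_posterior(const)
  expect_equal(s$mean, c(0.3, 0.3, 0.1))
  expect_equal(s$lower, s$upper)

  # known-distribution chain: summary within Monte-Carlo error of truth
  set.seed(21)
  g <- rnorm(4000, 0.2, 0.05)
  known <- structure(list(draws = cbind(theta = g, ratio = rep(1, 4000))),
                     class = "dispersal_fit")
  sk <- summarize_posterior(known)
  expect_equal(sk$mean, 0.2, tolerance = 3 * 0.05 / sqrt(4000) / 0.2)
  expect_equal(sk$lower, qnorm(0.025, 0.2, 0.05), tolerance = 0.1)

  # trend fit carries the nu-different-from-zero test
  tab <- seal_cohorts()
  ft <- fit_dispersal(tab, study_fits$det, "PB", "AN",
                      dispersal_config(n_steps = 3000, burn_in = 1000,
                                       n_chains = 2, seed = 13,
                                       variant = "trend"))
  st <- summarize_posterior(ft)
  expect_true(all(c("nu", "eta", "sigma") %in% st$parameter))
  expect_type(attr(st, "trend_nonzero"), "logical")
  expect_true(all(st$lower <= st$mean & st$mean <= st$upper))

  expect_error(summarize_posterior(
    structure(list(draws = matrix(numeric(0), 0, 1,
                                  dimnames = list(NULL, "ratio"))),
              class = "dispersal_fit")), "empty")
})

test_that("direction wiring picks the right cohorts and ratio draws", {
  tab <- seal_cohorts()
  f <- study_fits$an
  expect_equal(f$direction, "AN->PB")
  expect_equal(f$counts$emigrant,
               tab$emigrant[tab$colony == "AN"])
  expect_error(fit_dispersal(tab, study_fits$det, "XX", "PB"),
               "no cohorts")
  expect_error(run_sampler(tab[tab$colony == "PB",
                               c("birth_year", "resident", "emigrant")],
                           numeric(0)), "non-empty")
})
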