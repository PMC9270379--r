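test_that("bisegmented log-likelihood matches direct Gaussian density arithmetic", {
  # one observation exactly at its regression mean with variance 1/(2*pi)
  # has density 1, so log-likelihood 0
  expect_equal(biseg_loglik(y = 5, index = -1, t_value = 0,
                            beta = c(6, 1, 0), sigma2 = 1 / (2 * pi)), 0)
  set.seed(4)
  y <- rnorm(10, 100, 5)
  idx <- c(rep(-2, 5), rep(3, 5)); tv <- c(rep(0, 5), rep(0.8, 5))
  beta <- c(99, 1.1, 0.4); s2 <- 7
  mu <- ifelse(idx <= 0, beta[1] + beta[2] * idx,
               beta[1] + beta[2] * idx + beta[3] * tv)
  oracle <- -length(y) / 2 * log(2 * pi * s2) - sum((y - mu)^2) / (2 * s2)
  expect_equal(biseg_loglik(y, idx, tv, beta, s2), oracle)
  # doubling the variance at the perfectly fitting point costs log(sqrt(2))
  # per observation
  yfit <- mu
  l1 <- biseg_loglik(yfit, idx, tv, beta, s2)
  l2 <- biseg_loglik(yfit, idx, tv, beta, 2 * s2)
  expect_equal(l1 - l2, length(y) * log(sqrt(2)))
  expect_error(biseg_loglik(y, idx, tv, beta, -1), "positive")
})

test_that("vague prior carries the stated hyperparameters", {
  p <- minimally_informative_prior()
  expect_equal(p$mean, c(0, 0, 0))
  expect_equal(p$variance, c(1e5, 1e5, 1e5))
  expect_equal(p$shape, 0.001)
  expect_equal(p$rate, 0.001)
  expect_equal(p$shape / p$rate, 1)  # implied prior mean of the precision
})

test_that("prior elicitation moment-matches previous fits with inflation", {
  prev <- data.frame(genotype = "G01", beta0 = 100, beta1 = 1, beta2 = 0.5,
                     se_beta0 = 5, se_beta1 = 0.2, se_beta2 = 0.3,
                     sigma2 = 25)
  p1 <- elicit_prior_from_fits(prev, inflation = 1)[["G01"]]
  expect_equal(p1$mean, c(100, 1, 0.5))
  expect_equal(p1$variance[1], 25)
  p10 <- elicit_prior_from_fits(prev, inflation = 10)[["G01"]]
  expect_equal(p10$variance[1], 250)
  # precision prior centered at 1/s2 with relative variance = inflation
  expect_equal(p10$shape / p10$rate, 1 / 25)
  expect_equal((p10$shape / p10$rate^2) / (p10$shape / p10$rate)^2, 10)
  prev$sigma2 <- NA
  expect_error(elicit_prior_from_fits(prev), "non-finite")
})

test_that("Gibbs marginals match the analytic conjugate posterior at fixed precision", {
  set.seed(77)
  zs <- numeric(0)
  for (rep in 1:20) {
    n <- sample(8:16, 1)
    idx <- sort(c(runif(ceiling(n / 2), -5, 0), runif(floor(n / 2), 0.5, 5)))
    idx <- idx - mean(idx)
    ipb <- mean(idx[idx > 0])
    tv <- transform_index(idx, ipb)
    tau0 <- 1 / runif(1, 1, 9)
    y <- 100 + 1.2 * idx + 0.5 * tv + rnorm(n, 0, sqrt(1 / tau0))
    prior <- fixed_tau_prior(tau0, mean = c(90, 0, 0),
                             variance = c(100, 4, 4))
    ana <- conjugate_posterior(y, idx, tv, prior, tau0)
    dat <- data.frame(environment = paste0("E", seq_len(n)), yield = y)
    des <- design_from_index(idx, dat$environment)
    ch <- gibbs_fit(dat, des, prior,
                    quick_settings(seed = 1000 + rep, n_chains = 1,
                                   n_iterations = 3000, burn_in = 500))
    for (j in 1:3) {
      p <- c("beta0", "beta1", "beta2")[j]
      zs <- c(zs, abs(mean(ch$draws[, , p]) - ana$mean[j]) /
                mcse_batch(ch$draws[, , p]))
    }
  }
  # each comparison is a ~99.7% event; assert the calibrated aggregate
  expect_gte(mean(zs < 3), 0.95)
  expect_lt(max(zs), 5)
})

test_that("with vague priors the posterior means agree with OLS", {
  beta <- cbind(c(100, 92, 108), c(0.6, 1.3, 1.0), c(0.4, -0.2, 0.8))
  tab <- simulate_biseg_trial(beta, index = c(-5, -3, -1, 1, 3, 5),
                              sigma = 4, r = 3, seed = 55)
  des <- compute_index(tab)
  ols <- frequentist_fit(tab, des)
  fit <- fit_biseg(tab, des, minimally_informative_prior(),
                   quick_settings(seed = 9, n_chains = 2,
                                  n_iterations = 4000, burn_in = 500))
  for (i in 1:3) {
    for (p in c("beta0", "beta1", "beta2")) {
      post <- fit$summaries[[paste0(p, "_mean")]][i]
      mcse <- fit$summaries[[paste0(p, "_mcse")]][i]
      expect_lt(abs(post - ols$estimates[[p]][i]), 3 * mcse + 1e-9)
    }
  }
})

test_that("a near-degenerate prior pins a coefficient at its prior mean", {
  tab <- simulate_biseg_trial(cbind(100, 1, 2), index = c(-3, -1, 1, 3),
                              sigma = 2, r = 3, seed = 8)
  des <- design_from_index(c(-3, -1, 1, 3))
  pinned <- prior_spec(mean = c(0, 0, 0.25),
                       variance = c(1e5, 1e5, 1e-12))
  ch <- gibbs_fit(tab[tab$genotype == "G01", ], des, pinned,
                  quick_settings(seed = 3))
  b2 <- ch$draws[, , "beta2"]
  expect_equal(mean(b2), 0.25, tolerance = 1e-3)
  expect_lt(sd(as.vector(b2)), 1e-4)
})

test_that("identical settings and seed give bit-identical chains", {
  tab <- simulate_biseg_trial(cbind(100, 1, 0.5), index = c(-2, -1, 1, 2),
                              sigma = 3, r = 3, seed = 5)
  des <- design_from_index(c(-2, -1, 1, 2))
  s <- quick_settings(seed = 99, n_chains = 2, n_iterations = 500,
                      burn_in = 100)
  a <- gibbs_fit(tab[tab$genotype == "G01", ], des, settings = s)
  b <- gibbs_fit(tab[tab$genotype == "G01", ], des, settings = s)
  expect_identical(a$draws, b$draws)
  f1 <- fit_biseg(tab, des, settings = s)
  f2 <- fit_biseg(tab, des, settings = s)
  expect_identical(f1$summaries, f2$summaries)
})

test_that("degenerate designs fall back to a single-slope sampler with a warning", {
  one_pos <- tiny_additive_table(base = c(100, 104, 96, 101),
                                 env = c(-4, -2, -3, 9), r = 2)
  des <- compute_index(one_pos)
  expect_warning(
    ch <- gibbs_fit(one_pos[one_pos$genotype == "G1", ], des,
                    settings = quick_settings(seed = 2, n_chains = 1,
                                              n_iterations = 800,
                                              burn_in = 200)),
    "single-slope")
  # beta2 pinned at the (vague) prior mean 0, carrying no information
  expect_lt(abs(mean(ch$draws[, , "beta2"])), 1e-3)
  # noiseless table also triggers perfect-fit warnings from the OLS step
  w <- capture_warnings(frequentist_fit(one_pos, des))
  expect_true(any(grepl("single-slope", w)))
})

test_that("stability transform is draw-wise linear in MSR/r", {
  arr <- array(1, dim = c(50, 2, 5),
               dimnames = list(NULL, NULL, c("beta0", "beta1", "beta2",
                                             "tau", "sigma2")))
  set.seed(12)
  arr[, , "tau"] <- rgamma(100, 5, 1)
  arr[, , "sigma2"] <- 1 / arr[, , "tau"]
  ch <- posterior_chains(arr, "G")
  st <- stability(ch, msr = 575, r = 3)
  expect_equal(mean(st$draws), mean(arr[, , "sigma2"]) - 575 / 3)
  expect_equal(575 / 3, 191.6667, tolerance = 1e-4)
  # a draw exactly at MSR/r maps to zero; MSR = 0 is the identity
  arr0 <- arr; arr0[, , "sigma2"] <- 575 / 3; arr0[, , "tau"] <- 3 / 575
  expect_equal(stability(posterior_chains(arr0, "G"), 575, 3)$mean, 0)
  expect_equal(stability(ch, 0, 3)$draws[, 1], arr[, 1, "sigma2"])
})

test_that("R-squared equals the direct 1 - SSE/SST computation", {
  tab <- simulate_biseg_trial(cbind(100, 1, 0.5), index = c(-2, -1, 1, 2),
                              sigma = 0, r = 2, seed = 2)
  des <- design_from_index(c(-2, -1, 1, 2))
  dat <- tab[tab$genotype == "G01", ]
  expect_equal(as.numeric(r_squared(dat, des, c(100, 1, 0.5))), 1)
  # mean-only fit on centered data explains nothing
  r0 <- r_squared(dat, des, c(mean(dat$yield), 0, 0))
  expect_equal(as.numeric(r0), 0, tolerance = 1e-12)
  # arbitrary parameters: direct arithmetic oracle
  bh <- c(99, 0.8, 0.1)
  dc <- list(index = rep(c(-2, -1, 1, 2), 2),
             t_value = rep(transform_index(c(-2, -1, 1, 2), 1.5), 2))
  dat_ord <- dat[order(dat$replication, dat$environment), ]
  mu <- bh[1] + bh[2] * dc$index + bh[3] * dc$t_value
  oracle <- 1 - sum((dat_ord$yield - mu)^2) /
    sum((dat_ord$yield - mean(dat_ord$yield))^2)
  expect_equal(as.numeric(r_squared(dat_ord, des, bh)), oracle)
  flat <- data.frame(environment = dat$environment, yield = rep(1, 8))
  expect_warning(expect_true(is.na(r_squared(flat, des, c(1, 0, 0)))),
                 "undefined")
})

test_that("frequentist fit solves the normal equations with t intervals", {
  beta <- cbind(100, 1.1, 0.6)
  tab <- simulate_biseg_trial(beta, index = c(-4, -2, 1, 2, 3),
                              sigma = 3, r = 3, seed = 19)
  des <- design_from_index(c(-4, -2, 1, 2, 3))
  ff <- frequentist_fit(tab, des)
  dat <- tab[tab$genotype == "G01", ]
  dc <- list(index = des$index[match(dat$environment, des$environment)],
             t_value = des$t_value[match(dat$environment,
                                         des$environment)])
  X <- cbind(1, dc$index, dc$t_value)
  bhat <- solve(crossprod(X), crossprod(X, dat$yield))
  expect_equal(c(ff$estimates$beta0, ff$estimates$beta1,
                 ff$estimates$beta2), drop(bhat), tolerance = 1e-8)
  # interval width grows with the confidence level
  w <- sapply(c(0.8, 0.95, 0.99), function(cl) {
    f <- frequentist_fit(tab, des, confidence = cl)$estimates
    f$hi_beta1 - f$lo_beta1
  })
  expect_true(all(diff(w) > 0))
  # zero noise: exact recovery
  tab0 <- simulate_biseg_trial(beta, index = c(-4, -2, 1, 2, 3),
                               sigma = 0, r = 3, seed = 19)
  f0 <- suppressWarnings(
    frequentist_fit(tab0, design_from_index(c(-4, -2, 1, 2, 3))))$estimates
  expect_equal(c(f0$beta0, f0$beta1, f0$beta2), c(100, 1.1, 0.6),
               tolerance = 1e-8)
  expect_equal(f0$sigma2, 0, tolerance = 1e-16)
  expect_equal(f0$r_squared, 1, tolerance = 1e-12)
})

test_that("elicited priors matching the truth shorten credibility intervals", {
  beta <- cbind(c(100, 95), c(1.0, 0.7), c(0.5, 0.2))
  idx <- c(-4, -2, 2, 4)
  # a previous trial provides the elicitation source
  prev_tab <- simulate_biseg_trial(beta, idx, sigma = 4, r = 3, seed = 71)
  prev_fit <- frequentist_fit(prev_tab, compute_index(prev_tab))
  elicited <- elicit_prior_from_fits(prev_fit, inflation = 10)
  new_tab <- simulate_biseg_trial(beta, idx, sigma = 4, r = 3, seed = 72)
  des <- compute_index(new_tab)
  s <- quick_settings(seed = 5, n_chains = 2, n_iterations = 3000,
                      burn_in = 500)
  fit_v <- fit_biseg(new_tab, des, minimally_informative_prior(), s)
  fit_e <- fit_biseg(new_tab, des, elicited, s)
  width <- function(f, p) mean(f$summaries[[paste0(p, "_upper")]] -
                                 f$summaries[[paste0(p, "_lower")]])
  # averaged over parameters and genotypes, informed priors tighten CIs
  w_v <- mean(sapply(c("beta0", "beta1", "beta2"), width, f = fit_v))
  w_e <- mean(sapply(c("beta0", "beta1", "beta2"), width, f = fit_e))
  expect_lt(w_e, w_v)
})

test_that("posterior recovery: truth within 3 posterior sds for nearly all parameters", {
  g <- 12
  set.seed(31)
  beta <- cbind(rnorm(g, 100, 8), runif(g, 0.4, 1.6), rnorm(g, 0, 0.6))
  tab <- simulate_biseg_trial(beta, index = c(-6, -4, -2, 1, 2, 3, 6),
                              sigma = 5, r = 3, seed = 32)
  fit <- fit_biseg(tab, settings = quick_settings(seed = 33, n_chains = 2,
                                                  n_iterations = 2500,
                                                  burn_in = 500))
  ok <- 0L; tot <- 0L
  for (i in seq_len(g)) for (j in 1:3) {
    p <- c("beta0", "beta1", "beta2")[j]
    m <- fit$summaries[[paste0(p, "_mean")]][i]
    s <- fit$summaries[[paste0(p, "_sd")]][i]
    tot <- tot + 1L
    if (abs(m - beta[i, j]) < 3 * s) ok <- ok + 1L
  }
  expect_gte(ok / tot, 0.95)
})
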