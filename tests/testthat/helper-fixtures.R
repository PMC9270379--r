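# Shared fixtures and independent oracles, built in code at test time.

# A small balanced table with known cell means and no noise: genotype g's
# mean in environment j is base_g + env_j (purely additive, no GxE).
tiny_additive_table <- function(base = c(100, 104, 96),
                                env = c(-10, -5, 5, 10), r = 2) {
  grid <- expand.grid(g = seq_along(base), e = seq_along(env),
                      k = seq_len(r))
  trial_table(paste0("G", grid$g), paste0("E", grid$e), paste0("R", grid$k),
              base[grid$g] + env[grid$e])
}

# Independent sums-of-squares oracle: brute-force accumulation of squared
# deviations over explicitly subsetted cells (no marginal-mean algebra).
brute_force_joint_ss <- function(tab) {
  y <- tab$yield; gm <- mean(y)
  gl <- unique(tab$genotype); el <- unique(tab$environment)
  rl <- unique(tab$replication)
  g <- length(gl); e <- length(el); r <- length(rl)
  mg <- sapply(gl, function(a) mean(y[tab$genotype == a]))
  me <- sapply(el, function(a) mean(y[tab$environment == a]))
  mr <- sapply(rl, function(a) mean(y[tab$replication == a]))
  ss_g <- 0; for (a in gl) ss_g <- ss_g + e * r * (mg[a] - gm)^2
  ss_e <- 0; for (a in el) ss_e <- ss_e + g * r * (me[a] - gm)^2
  ss_r <- 0; for (a in rl) ss_r <- ss_r + g * e * (mr[a] - gm)^2
  ss_ge <- 0
  for (a in gl) for (b in el) {
    m <- mean(y[tab$genotype == a & tab$environment == b])
    ss_ge <- ss_ge + r * (m - mg[a] - me[b] + gm)^2
  }
  ss_re <- 0
  for (a in rl) for (b in el) {
    m <- mean(y[tab$replication == a & tab$environment == b])
    ss_re <- ss_re + g * (m - mr[a] - me[b] + gm)^2
  }
  ss_tot <- sum((y - gm)^2)
  c(Environment = unname(ss_e), Repetition = unname(ss_r),
    Genotypes = unname(ss_g), RE = unname(ss_re), GxE = unname(ss_ge),
    Residuals = unname(ss_tot - ss_e - ss_r - ss_g - ss_re - ss_ge))
}

# Analytic normal posterior of (beta0, beta1, beta2) for *known* residual
# precision tau0: the conjugate Bayesian linear-regression formula.
conjugate_posterior <- function(y, x1, x2, prior, tau0) {
  X <- cbind(1, x1, x2)
  P0 <- diag(1 / prior$variance)
  V <- solve(tau0 * crossprod(X) + P0)
  m <- V %*% (tau0 * crossprod(X, y) + P0 %*% prior$mean)
  list(mean = drop(m), cov = V)
}

# Effectively fixes tau at tau0 inside the Gibbs sampler: a Gamma prior
# with enormous shape/rate concentrates the full conditional at tau0.
fixed_tau_prior <- function(tau0, mean = c(0, 0, 0),
                            variance = c(1e4, 1e4, 1e4)) {
  prior_spec(mean = mean, variance = variance,
             shape = 1e12 * tau0, rate = 1e12)
}

quick_settings <- function(seed = 1, n_chains = 2, n_iterations = 2000,
                           burn_in = 400, thin = 1) {
  mcmc_settings(n_chains, n_iterations, burn_in, thin, seed = seed)
}
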