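#' MCMC settings
#'
#' Defaults follow the protocol used for the coffee trial: four chains of
#' 100,000 iterations, the first 10,000 discarded as burn-in, and every
#' fourth post-burn-in draw kept.  Short test runs simply shrink these.
#'
#' @param n_chains number of independent chains.
#' @param n_iterations Gibbs iterations per chain.
#' @param burn_in iterations discarded at the start of each chain
#'   (\code{burn_in < n_iterations}).
#' @param thin keep every \code{thin}-th post-burn-in draw.
#' @param seed master seed; chain and genotype substreams are derived
#'   from it deterministically.
#' @return An \code{mcmc_settings} list.
#' @export
mcmc_settings <- function(n_chains = 4, n_iterations = 100000,
                          burn_in = 10000, thin = 4, seed = 1) {
  stopifnot(n_chains >= 1, n_iterations >= 1, burn_in >= 0,
            burn_in < n_iterations, thin >= 1)
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_settings")
}

#' Bisegmented-regression log-likelihood for one genotype
#'
#' Gaussian log-likelihood of the two-regime model: each observation has
#' mean \eqn{\beta_{i0} + \beta_{i1} I_j} in unfavorable environments
#' (\eqn{I_j \le 0}, where \eqn{T(I_j) = 0}) and
#' \eqn{\beta_{i0} + \beta_{i1} I_j + \beta_{i2} T(I_j)} in favorable
#' ones, with common variance \eqn{\sigma^2_{ie}}.
#'
#' @param y observed yields.
#' @param index,t_value environment index \eqn{I_j} and hinge
#'   \eqn{T(I_j)} per observation.
#' @param beta length-3 coefficient vector
#'   \eqn{(\beta_{i0}, \beta_{i1}, \beta_{i2})}.
#' @param sigma2 positive residual variance.
#' @return The log-likelihood (a scalar).
#' @export
biseg_loglik <- function(y, index, t_value, beta, sigma2) {
  stopifnot(length(y) >= 1, length(index) == length(y),
            length(t_value) == length(y), length(beta) == 3L)
  if (!is.finite(sigma2) || sigma2 <= 0)
    stop("sigma2 must be positive and finite")
  mu <- beta[1] + beta[2] * index + beta[3] * t_value
  sum(stats::dnorm(y, mu, sqrt(sigma2), log = TRUE))
}

## Component-wise Gibbs sampler on the hinge design.  The posterior of a
## normal likelihood x normal priors x Gamma(precision) prior is
## fully conjugate: each beta_j has a normal full conditional obtained by
## completing the square,
##   prec_j = tau * sum(x_j^2) + 1/v_j,
##   mean_j = (tau * x_j'(y - X_{-j} beta_{-j}) + m_j/v_j) / prec_j,
## and tau has Gamma(shape + n/2, rate + SSE/2).  All inner products are
## precomputed, so one iteration costs O(1) in the number of observations.
gibbs_core <- function(y, x1, x2, prior, settings, drop_x2 = FALSE) {
  n <- length(y)
  X <- cbind(1, x1, if (drop_x2) 0 * x2 else x2)
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  yty <- sum(y * y)
  m <- prior$mean; v <- prior$variance
  if (drop_x2) {
    # pin beta2 at its prior (the column is zeroed): acts as a
    # single-slope model while keeping the parameter layout fixed
    v <- c(v[1:2], min(v[3], 1e-12))
  }
  a0 <- prior$shape; b0 <- prior$rate
  n_keep <- (settings$n_iterations - settings$burn_in) %/% settings$thin
  if (n_keep < 1) stop("no draws kept: increase iterations or reduce thinning")
  draws <- array(NA_real_,
                 dim = c(n_keep, settings$n_chains, 5L),
                 dimnames = list(NULL, NULL,
                                 c("beta0", "beta1", "beta2", "tau",
                                   "sigma2")))
  chain_seeds <- derive_seeds(settings$seed, settings$n_chains, "chain")
  for (ch in seq_len(settings$n_chains)) {
    with_seed(chain_seeds[ch], {
      # overdispersed start: draw from the priors, clamped to finite range
      beta <- stats::rnorm(3, m, sqrt(pmin(v, 1e10)))
      tau <- min(max(stats::rgamma(1, a0, rate = b0), 1e-10), 1e10)
      kept <- 0L
      for (t in seq_len(settings$n_iterations)) {
        for (j in 1:3) {
          prec <- tau * XtX[j, j] + 1 / v[j]
          resid_ip <- Xty[j] - sum(XtX[j, -j] * beta[-j])
          mu_j <- (tau * resid_ip + m[j] / v[j]) / prec
          beta[j] <- stats::rnorm(1, mu_j, sqrt(1 / prec))
        }
        sse <- max(yty - 2 * sum(beta * Xty) +
                     drop(crossprod(beta, XtX %*% beta)), 0)
        tau <- stats::rgamma(1, a0 + n / 2, rate = b0 + sse / 2)
        tau <- min(max(tau, 1e-300), 1e300)
        if (t > settings$burn_in &&
            (t - settings$burn_in) %% settings$thin == 0L) {
          kept <- kept + 1L
          draws[kept, ch, ] <- c(beta, tau, 1 / tau)
        }
      }
    })
  }
  draws
}

#' Gibbs sampler for one genotype's bisegmented regression
#'
#' Samples the joint posterior of
#' \eqn{(\beta_{i0}, \beta_{i1}, \beta_{i2}, \tau_{ie})} for a single
#' genotype by component-wise Gibbs with closed-form full conditionals:
#' normal updates for each coefficient (precision-weighted combination of
#' prior and data) and a Gamma update
#' \eqn{\tau \sim Gamma(\alpha + n/2, \beta + SSE/2)} for the precision.
#' Chains start overdispersed (initial values drawn from the priors) and
#' are reproducible from \code{settings$seed}.
#'
#' On a degenerate design (fewer than two environments on either side of
#' the hinge) the sampler falls back to a single-slope model with a
#' warning: \eqn{\beta_{i2}} is pinned at its prior mean and carries no
#' likelihood information.
#'
#' @param data observations for one genotype: a data frame with columns
#'   \code{environment} and \code{yield} (e.g. one genotype's rows of a
#'   \code{\link{trial_table}}).
#' @param design a \code{\link{compute_index}} design.
#' @param prior a \code{\link{prior_spec}}.
#' @param settings an \code{\link{mcmc_settings}}.
#' @return A \code{\link{posterior_chains}} object.
#' @examples
#' tab <- simulate_biseg_trial(cbind(100, 1, 0.5), c(-2, -1, 1, 2),
#'                             sigma = 2, r = 3, seed = 7)
#' des <- compute_index(tab)
#' ch <- gibbs_fit(tab[tab$genotype == "G01", ], des,
#'                 minimally_informative_prior(),
#'                 mcmc_settings(2, 2000, 500, 1, seed = 7))
#' @export
gibbs_fit <- function(data, design, prior = minimally_informative_prior(),
                      settings = mcmc_settings()) {
  stopifnot(inherits(prior, "prior_spec"), inherits(settings, "mcmc_settings"))
  if (!all(c("environment", "yield") %in% names(data)))
    stop("data must have 'environment' and 'yield' columns")
  y <- as.numeric(data$yield)
  if (any(!is.finite(y))) stop("non-finite yields")
  if (length(y) < 4)
    stop("at least 4 observations are needed (3 coefficients + variance)")
  dc <- design_columns(design, data$environment)
  degen <- isTRUE(attr(design, "degenerate")) ||
    length(unique(dc$index[dc$index > 0])) < 2L ||
    length(unique(dc$index[dc$index <= 0])) < 2L
  if (degen)
    warning("degenerate bisegmented design: ",
            "falling back to a single-slope model (beta2 pinned at prior mean)")
  draws <- gibbs_core(y, dc$index, dc$t_value, prior, settings,
                      drop_x2 = degen)
  gl <- unique(as.character(data$genotype))
  posterior_chains(draws,
                   genotype = if (length(gl) == 1L) gl else NA_character_,
                   settings = settings)
}
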