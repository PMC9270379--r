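#' Simulate a balanced trial with additive ANOVA structure
#'
#' Generates replicate-level yields from the additive decomposition the
#' joint ANOVA assumes:
#' \deqn{Y_{ijk} = \mu + r/e_{k(j)} + e_j + g_i + ge_{ij} + \varepsilon_{ijk},}
#' with environment, genotype, replication-within-environment and
#' interaction effects drawn once per level from centered normal
#' distributions with the requested standard deviations, and iid normal
#' residuals.  Effects are sum-constrained to zero within each factor
#' (the interaction matrix is double-centered), so the simulated
#' environmental index of \code{\link{compute_index}} equals the
#' environment effect up to residual noise.
#'
#' Randomness is split into one named substream per factor (environment,
#' genotype, interaction, replication, residual), each seeded
#' deterministically from \code{seed}; adding or resizing one factor does
#' not reshuffle the draws of the others.
#'
#' @param g,e,r numbers of genotypes, environments, replications (all
#'   \eqn{\ge 1}; the joint ANOVA itself needs \eqn{\ge 2} of each).
#' @param grand_mean overall mean yield.
#' @param sd_environment,sd_genotype,sd_gxe,sd_rep_within_env,sd_residual
#'   standard deviations of the effect distributions, all \eqn{\ge 0}.
#' @param seed integer seed; identical seeds give bit-identical tables.
#' @return A balanced \code{\link{trial_table}} with \code{g*e*r} rows and
#'   a \code{"true_effects"} attribute (list of the drawn effect vectors).
#' @examples
#' tab <- simulate_anova_trial(g = 6, e = 4, r = 3, seed = 1)
#' joint_anova(tab)
#' @export
simulate_anova_trial <- function(g = 43, e = 4, r = 3, grand_mean = 100,
                                 sd_environment = 15, sd_genotype = 10,
                                 sd_gxe = 5, sd_rep_within_env = 2,
                                 sd_residual = 8, seed = 1) {
  stopifnot(g >= 1, e >= 1, r >= 1,
            sd_environment >= 0, sd_genotype >= 0, sd_gxe >= 0,
            sd_rep_within_env >= 0, sd_residual >= 0)
  g <- as.integer(g); e <- as.integer(e); r <- as.integer(r)
  if (g * e * r == 0L) stop("zero-size design")

  center <- function(x) if (length(x) > 1L) x - mean(x) else x * 0
  env_eff  <- with_seed(seed + utf8_offset("environment"),
                        center(stats::rnorm(e, 0, sd_environment)))
  gen_eff  <- with_seed(seed + utf8_offset("genotype"),
                        center(stats::rnorm(g, 0, sd_genotype)))
  gxe_eff  <- with_seed(seed + utf8_offset("gxe"), {
    m <- matrix(stats::rnorm(g * e, 0, sd_gxe), g, e)
    if (g > 1L && e > 1L) {
      m <- m - rowMeans(m)
      m <- sweep(m, 2L, colMeans(m))
    } else m <- m * 0
    m
  })
  rep_eff  <- with_seed(seed + utf8_offset("replication"), {
    m <- matrix(stats::rnorm(r * e, 0, sd_rep_within_env), r, e)
    if (r > 1L) m <- sweep(m, 2L, colMeans(m)) else m <- m * 0
    m
  })
  resid    <- with_seed(seed + utf8_offset("residual"),
                        stats::rnorm(g * e * r, 0, sd_residual))

  grid <- expand.grid(genotype = seq_len(g), environment = seq_len(e),
                      replication = seq_len(r))
  yield <- grand_mean +
    env_eff[grid$environment] +
    gen_eff[grid$genotype] +
    gxe_eff[cbind(grid$genotype, grid$environment)] +
    rep_eff[cbind(grid$replication, grid$environment)] +
    resid

  tab <- trial_table(sprintf("G%02d", grid$genotype),
                     sprintf("E%d", grid$environment),
                     sprintf("R%d", grid$replication),
                     yield)
  attr(tab, "true_effects") <- list(environment = env_eff,
                                    genotype = gen_eff, gxe = gxe_eff,
                                    rep_within_env = rep_eff)
  tab
}

#' Simulate a trial from the bisegmented regression model
#'
#' Generates replicate-level yields for each genotype directly from the
#' two-regime model
#' \eqn{Y_{ij} = \beta_{i0} + \beta_{i1} I_j + \beta_{i2} T(I_j) + e_{ij}},
#' with known coefficients, so that downstream fits can be checked
#' against ground truth.  The environment indices are taken as given
#' (they need not be re-derivable from the data when residual noise is
#' large); \code{\link{compute_index}} applied to the simulated table
#' recovers them up to sampling noise because the hinge term is centered.
#'
#' @param beta matrix (or data frame) with one row per genotype and
#'   columns \code{beta0}, \code{beta1}, \code{beta2}: the genotype mean,
#'   the unfavorable-regime slope, and the slope change (so
#'   \code{beta1 + beta2} is the favorable-regime slope).
#' @param index numeric vector of environment indices \eqn{I_j}; should
#'   be centered (sum approximately zero) and contain at least one
#'   positive value.
#' @param sigma residual standard deviation(s) \eqn{\sigma_{ie}}: scalar
#'   or one value per genotype, all \eqn{\ge 0}.
#' @param r replications per cell.
#' @param seed integer seed (one substream per genotype).
#' @return A balanced \code{\link{trial_table}} with
#'   \code{nrow(beta) * length(index) * r} rows and attributes
#'   \code{"true_beta"}, \code{"true_sigma"}, \code{"true_index"}.
#' @examples
#' beta <- cbind(beta0 = c(100, 110), beta1 = c(0.8, 1.4),
#'               beta2 = c(0, 0.5))
#' simulate_biseg_trial(beta, index = c(-2, -1, 1, 2), sigma = 0, r = 2)
#' @export
simulate_biseg_trial <- function(beta, index, sigma = 5, r = 3, seed = 1) {
  beta <- as.matrix(beta)
  if (ncol(beta) != 3L)
    stop("beta must have three columns (beta0, beta1, beta2)")
  if (is.null(colnames(beta))) colnames(beta) <- c("beta0", "beta1", "beta2")
  g <- nrow(beta); e <- length(index); r <- as.integer(r)
  stopifnot(g >= 1, e >= 1, r >= 1, all(is.finite(beta)),
            all(is.finite(index)))
  sigma <- rep_len(sigma, g)
  if (length(sigma) != g) stop("sigma must be scalar or one per genotype")
  if (any(sigma < 0)) stop("sigma must be nonnegative")
  if (abs(sum(index)) > 1e-6 * max(1, max(abs(index))))
    warning("environment indices do not sum to zero; ",
            "they will not be recovered exactly by compute_index")
  if (!any(index > 0))
    stop("at least one environment index must be positive")
  ipb <- mean(index[index > 0])
  tv  <- transform_index(index, ipb)

  seeds <- derive_seeds(seed, g, "biseg")
  rows <- vector("list", g)
  for (i in seq_len(g)) {
    mu <- beta[i, 1] + beta[i, 2] * index + beta[i, 3] * tv
    eps <- with_seed(seeds[i], stats::rnorm(e * r, 0, sigma[i]))
    rows[[i]] <- data.frame(
      genotype = sprintf("G%02d", i),
      environment = rep(sprintf("E%d", seq_len(e)), times = r),
      replication = rep(sprintf("R%d", seq_len(r)), each = e),
      yield = rep(mu, times = r) + eps,
      stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, rows)
  tab <- trial_table(all$genotype, all$environment, all$replication,
                     all$yield)
  rownames(beta) <- sprintf("G%02d", seq_len(g))
  attr(tab, "true_beta")  <- beta
  attr(tab, "true_sigma") <- sigma
  attr(tab, "true_index") <- index
  tab
}
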