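#' Frequentist (OLS) bisegmented fits
#'
#' Ordinary least squares of each genotype's yields on the two-column
#' hinge design \eqn{(I_j, T(I_j))}, with confidence intervals from the
#' t distribution on \eqn{n - 3} df.  Used to elicit informative priors
#' (\code{\link{elicit_prior_from_fits}}) and to contrast interval widths
#' with the Bayesian credibility intervals.  On a degenerate design the
#' fit falls back to a single slope (\eqn{\beta_{i2} = 0}) with a warning.
#'
#' @param table a \code{\link{trial_table}} (one or many genotypes).
#' @param design a \code{\link{compute_index}} design.
#' @param confidence confidence level for the intervals.
#' @return A \code{biseg_freq_fit} list with \code{estimates}: a data
#'   frame per genotype of coefficients, standard errors, interval
#'   bounds, residual mean square \code{sigma2} (SSE/(n-3)) and
#'   \code{r_squared}; and \code{confidence}.
#' @export
frequentist_fit <- function(table, design, confidence = 0.95) {
  stopifnot(confidence > 0, confidence < 1)
  degen <- isTRUE(attr(design, "degenerate"))
  if (degen)
    warning("degenerate bisegmented design: single-slope OLS fallback")
  rows <- lapply(split(seq_len(nrow(table)), table$genotype), function(ix) {
    y <- table$yield[ix]
    n <- length(y)
    if (n <= 3) stop("each genotype needs more than 3 observations")
    dc <- design_columns(design, table$environment[ix])
    df <- data.frame(y = y, index = dc$index, t_value = dc$t_value)
    fit <- if (degen) stats::lm(y ~ index, data = df)
           else stats::lm(y ~ index + t_value, data = df)
    cf <- summary(fit)$coefficients
    ci <- stats::confint(fit, level = confidence)
    get <- function(tab, nm, col) if (nm %in% rownames(tab)) tab[nm, col] else 0
    est <- c(cf["(Intercept)", 1], cf["index", 1],
             get(cf, "t_value", 1))
    se  <- c(cf["(Intercept)", 2], cf["index", 2], get(cf, "t_value", 2))
    lo  <- c(ci["(Intercept)", 1], ci["index", 1], get(ci, "t_value", 1))
    hi  <- c(ci["(Intercept)", 2], ci["index", 2], get(ci, "t_value", 2))
    sse <- sum(stats::residuals(fit)^2)
    sst <- sum((y - mean(y))^2)
    data.frame(genotype = table$genotype[ix][1],
               beta0 = est[1], beta1 = est[2], beta2 = est[3],
               se_beta0 = se[1], se_beta1 = se[2], se_beta2 = se[3],
               lo_beta0 = lo[1], lo_beta1 = lo[2], lo_beta2 = lo[3],
               hi_beta0 = hi[1], hi_beta1 = hi[2], hi_beta2 = hi[3],
               sigma2 = sse / stats::df.residual(fit),
               r_squared = if (sst > 0) 1 - sse / sst else NA_real_,
               stringsAsFactors = FALSE)
  })
  est <- do.call(rbind, rows)
  rownames(est) <- NULL
  structure(list(estimates = est, confidence = confidence),
            class = "biseg_freq_fit")
}

#' @export
print.biseg_freq_fit <- function(x, ...) {
  cat(sprintf("OLS bisegmented fits for %d genotypes (%.0f%% CIs)\n",
              nrow(x$estimates), 100 * x$confidence))
  print.data.frame(
    utils::head(x$estimates[c("genotype", "beta0", "beta1", "beta2",
                              "sigma2", "r_squared")], 10), ...)
  invisible(x)
}

#' Stability statistic from posterior precision draws
#'
#' The deviation variance \eqn{\hat\sigma^2_{di} = \hat\sigma^2_{ie} - MSR/r}
#' measures how much a genotype's residual variance about its own
#' bisegmented response exceeds the trial's pooled error variance per
#' cell mean; small or negative values indicate a stable (predictable)
#' genotype.  The transform is applied draw-wise to
#' \eqn{\sigma^2_{ie} = 1/\tau} and then summarised, so
#' \code{mean(draws) == mean(sigma2 draws) - MSR/r} exactly.  Negative
#' summaries are legitimate (the raw statistic is reported as-is, with a
#' flag).
#'
#' @param chains a \code{\link{posterior_chains}} object.
#' @param msr residual mean square of the \code{\link{joint_anova}}
#'   (\eqn{\ge 0}).
#' @param r number of replications (\eqn{\ge 1}).
#' @param level credibility level for the equal-tailed interval.
#' @return A list: \code{draws} (matrix iteration x chain), \code{mean},
#'   \code{sd}, \code{lower}, \code{upper}, \code{negative} flag.
#' @export
stability <- function(chains, msr, r, level = 0.95) {
  stopifnot(inherits(chains, "posterior_chains"), msr >= 0, r >= 1)
  d <- chains$draws[, , "sigma2", drop = FALSE] - msr / r
  dim(d) <- dim(chains$draws)[1:2]
  a <- (1 - level) / 2
  q <- stats::quantile(d, c(a, 1 - a))
  list(draws = d, mean = mean(d), sd = stats::sd(as.vector(d)),
       lower = unname(q[1]), upper = unname(q[2]),
       negative = mean(d) < 0)
}

#' Coefficient of determination at the posterior means
#'
#' \eqn{R^2 = 1 - SSE/SST} with the error sum of squares evaluated at the
#' posterior-mean coefficients.  The raw value (which can be negative for
#' a badly misfitting model) is returned; a \code{"display"} attribute
#' carries the value clipped to \eqn{[0, 1]}.
#'
#' @param data one genotype's observations (\code{environment},
#'   \code{yield} columns).
#' @param design a \code{\link{compute_index}} design.
#' @param beta_hat posterior-mean coefficient vector
#'   \eqn{(\beta_0, \beta_1, \beta_2)}.
#' @return Numeric scalar (NA with a warning if all yields are equal).
#' @export
r_squared <- function(data, design, beta_hat) {
  y <- as.numeric(data$yield)
  if (length(unique(y)) < 2) {
    warning("zero total sum of squares: R^2 undefined")
    return(NA_real_)
  }
  dc <- design_columns(design, data$environment)
  mu <- beta_hat[1] + beta_hat[2] * dc$index + beta_hat[3] * dc$t_value
  raw <- 1 - sum((y - mu)^2) / sum((y - mean(y))^2)
  attr(raw, "display") <- min(max(raw, 0), 1)
  raw
}

#' Batch-means Monte Carlo standard error
#'
#' MCSE of the posterior mean from non-overlapping batch means with batch
#' size \eqn{\lfloor\sqrt{n}\rfloor}, computed per chain and pooled.
#'
#' @param x numeric vector of draws, or an (iterations x chains) matrix.
#' @return The Monte Carlo standard error of the overall mean.
#' @export
mcse_batch <- function(x) {
  x <- as.matrix(x)
  per_chain_var <- apply(x, 2L, function(v) {
    n <- length(v)
    b <- max(floor(sqrt(n)), 1L)
    nb <- n %/% b
    if (nb < 2) return(stats::var(v) / n)
    bm <- colMeans(matrix(v[seq_len(nb * b)], nrow = b))
    b * stats::var(bm) / n
  })
  sqrt(mean(per_chain_var) / ncol(x))
}

summarize_param <- function(draws2d, level = 0.95) {
  a <- (1 - level) / 2
  q <- stats::quantile(draws2d, c(a, 1 - a))
  c(mean = mean(draws2d), sd = stats::sd(as.vector(draws2d)),
    lower = unname(q[1]), upper = unname(q[2]),
    mcse = mcse_batch(draws2d))
}

#' Fit the Bayesian bisegmented model to every genotype
#'
#' End-to-end Bayesian stage: computes (or accepts) the environmental
#' index design, runs the Gibbs sampler for each genotype independently
#' (each with its own residual variance), and assembles posterior
#' summaries — means, sds, equal-tailed 95% credibility intervals and
#' batch-means MCSEs per parameter, the favorable-regime slope
#' \eqn{\beta_{i1} + \beta_{i2}}, the stability statistic
#' \eqn{\hat\sigma^2_{di}} (when \code{msr} and \code{r} are available)
#' and \eqn{R^2} at the posterior means.
#'
#' @param table a balanced \code{\link{trial_table}}.
#' @param design optional precomputed \code{\link{compute_index}} design.
#' @param prior a single \code{\link{prior_spec}} applied to every
#'   genotype, or a named list with one spec per genotype (as from
#'   \code{\link{elicit_prior_from_fits}}).
#' @param settings an \code{\link{mcmc_settings}}; per-genotype seeds are
#'   derived from \code{settings$seed}.
#' @param msr,r residual mean square and replication count for the
#'   stability statistic; taken from \code{\link{joint_anova}} when
#'   \code{NULL} and the table is balanced with all factors \eqn{\ge 2}.
#' @param level credibility level.
#' @return A \code{biseg_fit} list: \code{chains} (named list of
#'   \code{\link{posterior_chains}}), \code{summaries} (one row per
#'   genotype), \code{design}, \code{prior}, \code{settings}, \code{msr},
#'   \code{r}.
#' @examples
#' tab <- simulate_biseg_trial(cbind(c(100, 104), c(0.7, 1.2), c(0, 0.6)),
#'                             index = c(-3, -1, 1, 3), sigma = 2, r = 3,
#'                             seed = 11)
#' fit <- fit_biseg(tab, settings = mcmc_settings(2, 1500, 300, 1, seed = 2))
#' fit$summaries[, c("genotype", "beta0_mean", "slope_fav_mean")]
#' @export
fit_biseg <- function(table, design = NULL,
                      prior = minimally_informative_prior(),
                      settings = mcmc_settings(), msr = NULL, r = NULL,
                      level = 0.95) {
  if (is.null(design)) design <- compute_index(table)
  d <- design_of(table)
  if (is.null(msr) && d$balanced && d$g >= 2 && d$e >= 2 && d$r >= 2) {
    an <- joint_anova(table)
    msr <- attr(an, "msr"); r <- attr(an, "r")
  }
  genotypes <- unique(table$genotype)
  per_geno_prior <- is.list(prior) && !inherits(prior, "prior_spec")
  if (per_geno_prior && !all(genotypes %in% names(prior)))
    stop("per-genotype prior list must cover every genotype")
  geno_seeds <- derive_seeds(settings$seed, length(genotypes), "genotype")

  chains <- vector("list", length(genotypes)); names(chains) <- genotypes
  srows <- vector("list", length(genotypes))
  for (i in seq_along(genotypes)) {
    gdat <- table[table$genotype == genotypes[i], , drop = FALSE]
    gset <- settings; gset$seed <- geno_seeds[i]
    gprior <- if (per_geno_prior) prior[[genotypes[i]]] else prior
    ch <- gibbs_fit(gdat, design, gprior, gset)
    chains[[i]] <- ch
    s <- sapply(c("beta0", "beta1", "beta2", "sigma2"), function(p)
      summarize_param(ch$draws[, , p], level))
    slope <- summarize_param(ch$draws[, , "beta1"] + ch$draws[, , "beta2"],
                             level)
    bhat <- c(s["mean", "beta0"], s["mean", "beta1"], s["mean", "beta2"])
    r2 <- r_squared(gdat, design, bhat)
    row <- data.frame(genotype = genotypes[i], stringsAsFactors = FALSE)
    for (p in c("beta0", "beta1", "beta2", "sigma2"))
      for (stat in rownames(s))
        row[[paste(p, stat, sep = "_")]] <- s[stat, p]
    for (stat in names(slope))
      row[[paste0("slope_fav_", stat)]] <- unname(slope[stat])
    if (!is.null(msr)) {
      st <- stability(ch, msr, r, level)
      row$sigma2_di_mean <- st$mean; row$sigma2_di_sd <- st$sd
      row$sigma2_di_lower <- st$lower; row$sigma2_di_upper <- st$upper
      row$sigma2_di_negative <- st$negative
    }
    row$r_squared <- as.numeric(r2)
    row$r_squared_display <- if (is.na(r2)) NA_real_ else attr(r2, "display")
    srows[[i]] <- row
  }
  structure(list(chains = chains, summaries = do.call(rbind, srows),
                 design = design, prior = prior, settings = settings,
                 msr = msr, r = r, level = level),
            class = "biseg_fit")
}

#' @export
print.biseg_fit <- function(x, ...) {
  cat(sprintf(
    "Bayesian bisegmented fit: %d genotypes, %d chains x %d kept draws\n",
    length(x$chains), dim(x$chains[[1]]$draws)[2],
    dim(x$chains[[1]]$draws)[1]))
  cols <- intersect(c("genotype", "beta0_mean", "beta1_mean", "beta2_mean",
                      "sigma2_di_mean", "r_squared"), names(x$summaries))
  print.data.frame(utils::head(x$summaries[cols], 10), digits = 4, ...)
  if (nrow(x$summaries) > 10) cat("...\n")
  invisible(x)
}
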