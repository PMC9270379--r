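#' Prior specification for one genotype's bisegmented regression
#'
#' Independent normal priors on the three regression coefficients and a
#' Gamma prior (shape/rate parameterisation; mean \eqn{\alpha/\beta},
#' variance \eqn{\alpha/\beta^2}) on the residual precision
#' \eqn{\tau_{ie} = 1/\sigma^2_{ie}}.
#'
#' @param mean length-3 numeric: prior means of
#'   \eqn{(\beta_{i0}, \beta_{i1}, \beta_{i2})}.
#' @param variance length-3 positive numeric: prior variances.
#' @param shape,rate positive Gamma hyperparameters of \eqn{\tau_{ie}}.
#' @return A \code{prior_spec} list with elements \code{mean},
#'   \code{variance}, \code{shape}, \code{rate}.
#' @seealso \code{\link{minimally_informative_prior}},
#'   \code{\link{elicit_prior_from_fits}}
#' @export
prior_spec <- function(mean = c(0, 0, 0), variance = c(1e5, 1e5, 1e5),
                       shape = 0.001, rate = 0.001) {
  mean <- rep_len(as.numeric(mean), 3L)
  variance <- rep_len(as.numeric(variance), 3L)
  stopifnot(all(is.finite(mean)), all(variance > 0),
            length(shape) == 1L, length(rate) == 1L, shape > 0, rate > 0)
  structure(list(mean = mean, variance = variance,
                 shape = as.numeric(shape), rate = as.numeric(rate)),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf(
    "beta0 ~ N(%.4g, %.4g); beta1 ~ N(%.4g, %.4g); beta2 ~ N(%.4g, %.4g)\n",
    x$mean[1], x$variance[1], x$mean[2], x$variance[2],
    x$mean[3], x$variance[3]))
  cat(sprintf("tau ~ Gamma(shape = %.4g, rate = %.4g)  [prior mean %.4g]\n",
              x$shape, x$rate, x$shape / x$rate))
  invisible(x)
}

#' Minimally informative (vague) prior
#'
#' The reference prior of the analysis: \eqn{N(0, 100000)} on each
#' regression coefficient and \eqn{Gamma(0.001, 0.001)} on the residual
#' precision (prior mean \eqn{\alpha/\beta = 1}, prior variance
#' \eqn{\alpha/\beta^2 = 1000}).  With these variances the posterior is
#' dominated by the likelihood; posterior means agree with ordinary least
#' squares up to Monte Carlo error.
#'
#' @return A \code{\link{prior_spec}}.
#' @export
minimally_informative_prior <- function() {
  prior_spec(mean = c(0, 0, 0), variance = c(1e5, 1e5, 1e5),
             shape = 0.001, rate = 0.001)
}

#' Elicit priors from previous frequentist fits
#'
#' Turns per-genotype OLS estimates from earlier trials into informative
#' priors: each coefficient prior is centered at the previous point
#' estimate with variance \eqn{se^2 \times} \code{inflation}, and the
#' precision prior is moment-matched to the previous residual-variance
#' estimate \eqn{s^2} with the same relative inflation — prior mean of
#' \eqn{\tau} equal to \eqn{1/s^2} and squared coefficient of variation
#' equal to \code{inflation}, i.e. \eqn{\alpha = 1/\mathrm{inflation}},
#' \eqn{\beta = s^2/\mathrm{inflation}}.  Inflation keeps the historical
#' information from dominating the new likelihood; the default 10 is
#' weakly informative.
#'
#' @param fits a \code{biseg_freq_fit} from \code{\link{frequentist_fit}},
#'   or a data frame with columns \code{genotype}, \code{beta0},
#'   \code{beta1}, \code{beta2}, \code{se_beta0}, \code{se_beta1},
#'   \code{se_beta2}, \code{sigma2}.
#' @param inflation positive variance-inflation factor.
#' @return A named list of \code{\link{prior_spec}}, one per genotype.
#' @export
elicit_prior_from_fits <- function(fits, inflation = 10) {
  stopifnot(inflation > 0)
  if (inherits(fits, "biseg_freq_fit")) fits <- fits$estimates
  need <- c("genotype", "beta0", "beta1", "beta2",
            "se_beta0", "se_beta1", "se_beta2", "sigma2")
  if (!all(need %in% names(fits)))
    stop("fits must contain columns: ", paste(need, collapse = ", "))
  num <- fits[setdiff(need, "genotype")]
  if (any(!is.finite(as.matrix(num)))) stop("non-finite previous estimates")
  out <- lapply(seq_len(nrow(fits)), function(i) {
    prior_spec(
      mean = c(fits$beta0[i], fits$beta1[i], fits$beta2[i]),
      variance = inflation * c(fits$se_beta0[i], fits$se_beta1[i],
                               fits$se_beta2[i])^2,
      shape = 1 / inflation,
      rate = fits$sigma2[i] / inflation)
  })
  names(out) <- fits$genotype
  out
}
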