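## Spectral density of a stationary series at frequency zero, by a
## lag-window autocovariance estimator: Tukey-Hanning taper over
## L = floor(4 (n/100)^{1/3}) lags.  S(0)/n estimates Var(mean(x)) in the
## presence of autocorrelation.
spectrum0 <- function(x) {
  n <- length(x)
  m <- mean(x)
  xc <- x - m
  L <- min(floor(4 * (n / 100)^(1 / 3)), n - 1L)
  g0 <- sum(xc * xc) / n
  if (g0 <= 0) stop("constant chain segment: spectral density undefined")
  if (L < 1L) return(g0)
  gl <- vapply(seq_len(L), function(l)
    sum(xc[seq_len(n - l)] * xc[(l + 1):n]) / n, numeric(1))
  w <- 0.5 * (1 + cos(pi * seq_len(L) / L))
  max(g0 + 2 * sum(w * gl), g0 / n)
}

#' Geweke convergence diagnostic
#'
#' Compares the mean of the first \code{first} fraction of a chain with
#' the mean of the last \code{last} fraction by a z-test whose standard
#' errors use spectral-density-at-zero estimates (so autocorrelation is
#' accounted for):
#' \deqn{z = (\bar x_{first} - \bar x_{last}) /
#'       \sqrt{S_1(0)/n_1 + S_2(0)/n_2}.}
#' A stationary, converged chain gives \eqn{|z| < 1.96} about 95% of the
#' time; large \eqn{|z|} flags non-convergence.
#'
#' @param x numeric vector of one parameter's draws from one chain, or a
#'   \code{\link{posterior_chains}} object (diagnosed per chain and
#'   parameter).
#' @param first,last window fractions in (0,1); windows must not overlap
#'   (\code{first + last <= 1}).
#' @return For a vector: a \code{geweke_result} list with \code{z},
#'   \code{pass} (\eqn{|z| < 1.96}), \code{first}, \code{last}.  For
#'   chains: a data frame with columns \code{chain}, \code{parameter},
#'   \code{z}, \code{pass}.
#' @export
geweke_diag <- function(x, first = 0.1, last = 0.5) {
  stopifnot(first > 0, first < 1, last > 0, last < 1, first + last <= 1)
  if (inherits(x, "posterior_chains")) {
    d <- dim(x$draws); pars <- dimnames(x$draws)[[3]]
    pars <- setdiff(pars, "tau")  # sigma2 = 1/tau is the reported scale
    out <- expand.grid(chain = seq_len(d[2]), parameter = pars,
                       stringsAsFactors = FALSE)
    out$z <- mapply(function(ch, p)
      geweke_diag(x$draws[, ch, p], first, last)$z,
      out$chain, out$parameter)
    out$pass <- abs(out$z) < 1.96
    return(out)
  }
  n <- length(x)
  if (n < 100) stop("chain too short for the Geweke diagnostic (need >= 100)")
  n1 <- floor(first * n); n2 <- floor(last * n)
  x1 <- x[seq_len(n1)]; x2 <- x[(n - n2 + 1):n]
  se2 <- spectrum0(x1) / n1 + spectrum0(x2) / n2
  z <- (mean(x1) - mean(x2)) / sqrt(se2)
  structure(list(z = z, pass = abs(z) < 1.96, first = first, last = last),
            class = "geweke_result")
}

#' @export
print.geweke_result <- function(x, ...) {
  cat(sprintf("Geweke z = %.3f (windows %.0f%%/%.0f%%): %s\n", x$z,
              100 * x$first, 100 * x$last,
              if (x$pass) "no evidence against convergence"
              else "FAILS at |z| < 1.96"))
  invisible(x)
}

#' Running-mean trace summary for visual convergence inspection
#'
#' For each parameter and chain, the running posterior mean after each
#' kept iteration — the quantity one inspects to see independent chains
#' agree on a common value.  The between-chain spread of the final
#' running means summarises disagreement numerically; it shrinks as
#' chains lengthen on a converging sampler.
#'
#' @param chains a \code{\link{posterior_chains}} object with at least
#'   two chains.
#' @return A list: \code{traces}, a data frame (\code{parameter},
#'   \code{chain}, \code{iteration}, \code{running_mean}); and
#'   \code{final_spread}, a named vector of the sd of final running
#'   means across chains per parameter.
#' @export
trace_summary <- function(chains) {
  stopifnot(inherits(chains, "posterior_chains"))
  d <- dim(chains$draws)
  if (d[2] < 2) stop("trace comparison needs at least 2 chains")
  pars <- dimnames(chains$draws)[[3]]
  traces <- do.call(rbind, lapply(pars, function(p) {
    do.call(rbind, lapply(seq_len(d[2]), function(ch) {
      v <- chains$draws[, ch, p]
      data.frame(parameter = p, chain = ch, iteration = seq_along(v),
                 running_mean = cumsum(v) / seq_along(v),
                 stringsAsFactors = FALSE)
    }))
  }))
  finals <- vapply(pars, function(p)
    stats::sd(vapply(seq_len(d[2]), function(ch)
      mean(chains$draws[, ch, p]), numeric(1))), numeric(1))
  list(traces = traces, final_spread = finals)
}
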