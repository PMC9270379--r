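## Factor means and sums of squares are computed from marginal means of
## the balanced lattice; the residual is obtained by subtraction from the
## total corrected SS, as in the classical fixed-effects decomposition.

anova_row <- function(factor, df, ss, msr = NA_real_, df_res = NA_integer_,
                      test = TRUE) {
  ms <- if (df > 0) ss / df else NA_real_
  f <- p <- NA_real_
  if (test && df > 0 && is.finite(msr) && msr > 0 && df_res > 0) {
    f <- ms / msr
    p <- stats::pf(f, df, df_res, lower.tail = FALSE)
  }
  data.frame(factor = factor, df = df, ss = ss, ms = ms, f = f, p = p,
             stringsAsFactors = FALSE)
}

#' Joint analysis of variance of a balanced multi-environment trial
#'
#' Fixed-effects decomposition of replicate-level yields into environment,
#' replication, genotype, replication-within-environment (R/E) and
#' genotype-by-environment (GxE) effects, each tested by F against the
#' pooled residual mean square.  The replication structure is decomposed
#' into a main effect with \eqn{r - 1} df and an R/E interaction with
#' \eqn{(r-1)(e-1)} df; the residual df follow by subtraction from
#' \eqn{ger - 1}.  A significant GxE term is the entry condition for the
#' adaptability/stability analysis.
#'
#' @param table a balanced \code{\link{trial_table}} with at least two
#'   genotypes, environments and replications.
#' @return An \code{anova_table}: data frame with columns \code{factor}
#'   (Environment, Repetition, Genotypes, R/E, GxE, Residuals), \code{df},
#'   \code{ss}, \code{ms}, \code{f}, \code{p}; attributes \code{msr}
#'   (residual mean square) and \code{r} (replications), the inputs of
#'   the stability statistic \eqn{\hat\sigma^2_{di} = \hat\sigma^2_{ie} - MSR/r}.
#' @seealso \code{\link{per_environment_anova}}, \code{\link{hartley_test}},
#'   \code{\link{stability}}
#' @export
joint_anova <- function(table) {
  d <- design_of(table)
  if (!d$balanced)
    stop("joint ANOVA requires a balanced trial ",
         "(every genotype x environment x replication cell present once)")
  if (d$g < 2 || d$e < 2 || d$r < 2)
    stop("joint ANOVA needs at least 2 genotypes, environments and replications")
  g <- d$g; e <- d$e; r <- d$r
  y <- table$yield
  gm <- mean(y)
  N <- length(y)

  m_g  <- tapply(y, table$genotype, mean)
  m_e  <- tapply(y, table$environment, mean)
  m_r  <- tapply(y, table$replication, mean)
  m_ge <- tapply(y, list(table$genotype, table$environment), mean)
  m_re <- tapply(y, list(table$replication, table$environment), mean)

  ss_e  <- g * r * sum((m_e - gm)^2)
  ss_r  <- g * e * sum((m_r - gm)^2)
  ss_g  <- e * r * sum((m_g - gm)^2)
  ss_re <- g * sum((m_re - outer(m_r, rep(1, e)) -
                      outer(rep(1, r), m_e) + gm)^2)
  ss_ge <- r * sum((m_ge - outer(m_g, rep(1, e)) -
                      outer(rep(1, g), m_e) + gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_res <- ss_tot - ss_e - ss_r - ss_g - ss_re - ss_ge
  ss_res <- max(ss_res, 0)

  df_res <- (N - 1L) - (e - 1L) - (r - 1L) - (g - 1L) -
    (r - 1L) * (e - 1L) - (g - 1L) * (e - 1L)
  msr <- if (df_res > 0) ss_res / df_res else NA_real_

  rows <- rbind(
    anova_row("Environment (E)", e - 1L, ss_e, msr, df_res),
    anova_row("Repetition (R)",  r - 1L, ss_r, msr, df_res),
    anova_row("Genotypes (G)",   g - 1L, ss_g, msr, df_res),
    anova_row("R/E", (r - 1L) * (e - 1L), ss_re, msr, df_res),
    anova_row("Genotypes x Environment (GxE)",
              (g - 1L) * (e - 1L), ss_ge, msr, df_res),
    anova_row("Residuals", df_res, ss_res, test = FALSE))
  structure(rows, msr = msr, r = r, design = d,
            class = c("anova_table", "data.frame"))
}

#' @export
print.anova_table <- function(x, ...) {
  out <- as.data.frame(x)
  out$ss <- signif(out$ss, 6); out$ms <- signif(out$ms, 6)
  out$f <- signif(out$f, 4)
  out$p <- ifelse(is.na(out$p), NA,
                  ifelse(out$p < 1e-16, "<1e-16", signif(out$p, 3)))
  print.data.frame(out, row.names = FALSE, ...)
  invisible(x)
}

#' Per-environment randomized-complete-block ANOVA
#'
#' Fits, within each environment, the RCBD decomposition of yields into
#' genotype and replication (block) effects, exposing the residual
#' variances that Hartley's homogeneity test compares before the joint
#' analysis pools them.
#'
#' @param table a \code{\link{trial_table}}, balanced within each
#'   environment (every genotype in every replication).
#' @return A list with one \code{anova_table} per environment (rows
#'   Genotypes, Repetition, Residuals), plus attributes
#'   \code{residual_variances} (named vector) and \code{residual_df}
#'   (common residual df \eqn{(g-1)(r-1)}).
#' @export
per_environment_anova <- function(table) {
  envs <- unique(table$environment)
  out <- vector("list", length(envs)); names(out) <- envs
  vars <- numeric(length(envs)); names(vars) <- envs
  dfs <- integer(length(envs))
  for (k in seq_along(envs)) {
    sub <- table[table$environment == envs[k], , drop = FALSE]
    gl <- unique(sub$genotype); rl <- unique(sub$replication)
    g <- length(gl); r <- length(rl)
    if (g < 2 || r < 2)
      stop("environment ", envs[k],
           " has fewer than 2 genotypes or replications")
    if (nrow(sub) != g * r ||
        anyDuplicated(paste(sub$genotype, sub$replication)))
      stop("environment ", envs[k], " is not a complete block design")
    y <- sub$yield; gm <- mean(y)
    m_g <- tapply(y, sub$genotype, mean)
    m_r <- tapply(y, sub$replication, mean)
    ss_g <- r * sum((m_g - gm)^2)
    ss_r <- g * sum((m_r - gm)^2)
    ss_res <- max(sum((y - gm)^2) - ss_g - ss_r, 0)
    df_res <- (g - 1L) * (r - 1L)
    msr <- ss_res / df_res
    rows <- rbind(
      anova_row("Genotypes (G)", g - 1L, ss_g, msr, df_res),
      anova_row("Repetition (R)", r - 1L, ss_r, msr, df_res),
      anova_row("Residuals", df_res, ss_res, test = FALSE))
    out[[k]] <- structure(rows, msr = msr, r = r,
                          class = c("anova_table", "data.frame"))
    vars[k] <- msr; dfs[k] <- df_res
  }
  structure(out, residual_variances = vars,
            residual_df = if (length(unique(dfs)) == 1L) dfs[1] else dfs)
}

#' Hartley's Fmax test of variance homogeneity
#'
#' Tests whether the per-environment residual variances can be pooled,
#' using Hartley's statistic \eqn{F_{max} = \max s^2_k / \min s^2_k}.
#' The critical value for \eqn{k} variances on a common residual df is
#' obtained by Monte Carlo under the null: \code{n_mc} draws of \eqn{k}
#' independent \eqn{\chi^2_{df}/df} variates, taking the
#' \eqn{1 - \alpha} quantile of their max/min ratio.  Monte Carlo rather
#' than printed tables supports arbitrary \eqn{(k, df)} reproducibly.
#'
#' @param variances per-environment residual variances (length \eqn{\ge 2},
#'   all positive).
#' @param df common residual degrees of freedom (balanced design).
#' @param alpha significance level.
#' @param n_mc Monte Carlo draws for the critical value.
#' @param seed seed for the critical-value draws.
#' @param critical optional precomputed critical value (from
#'   \code{hartley_critical}); supply it when testing many variance sets
#'   of the same \eqn{(k, df)} to avoid redrawing.
#' @return A \code{hartley_result} list: \code{variances}, \code{fmax},
#'   \code{df}, \code{k}, \code{critical}, \code{alpha}, and the flag
#'   \code{homogeneous} (\code{fmax < critical}).
#' @export
hartley_test <- function(variances, df, alpha = 0.05, n_mc = 100000,
                         seed = 20220708, critical = NULL) {
  variances <- as.numeric(variances)
  k <- length(variances)
  if (k < 2) stop("Hartley's test needs at least 2 variances")
  if (any(variances <= 0) || any(!is.finite(variances)))
    stop("degenerate data: all variances must be positive and finite")
  if (length(df) != 1L || df < 1)
    stop("unsupported design: a single common residual df is required")
  fmax <- max(variances) / min(variances)
  crit <- if (is.null(critical)) hartley_critical(k, df, alpha, n_mc, seed)
          else critical
  structure(list(variances = variances, fmax = fmax, df = df, k = k,
                 critical = crit, alpha = alpha,
                 homogeneous = fmax < crit),
            class = "hartley_result")
}

#' @rdname hartley_test
#' @export
hartley_critical <- function(k, df, alpha = 0.05, n_mc = 100000,
                             seed = 20220708) {
  with_seed(seed, {
    s2 <- matrix(stats::rchisq(n_mc * k, df) / df, n_mc, k)
    ratio <- apply(s2, 1L, max) / apply(s2, 1L, min)
    unname(stats::quantile(ratio, 1 - alpha))
  })
}

#' @export
print.hartley_result <- function(x, ...) {
  cat(sprintf(
    "Hartley's Fmax test: Fmax = %.4g, critical(k = %d, df = %d, alpha = %g) = %.4g -> %s\n",
    x$fmax, x$k, x$df, x$alpha, x$critical,
    if (x$homogeneous) "homogeneous" else "heterogeneous"))
  invisible(x)
}
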