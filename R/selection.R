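#' Deviance Information Criterion for one genotype's fit
#'
#' Computes \eqn{\bar D} (posterior mean deviance over the kept draws),
#' \eqn{D(\hat\theta)} (deviance at the posterior means of the
#' coefficients and residual variance), the effective number of
#' parameters \eqn{p_D = \bar D - D(\hat\theta)}, and
#' \eqn{DIC = D(\hat\theta) + 2 p_D = \bar D + p_D}.  Lower is better; a
#' correctly specified vague-prior fit with four free parameters gives
#' \eqn{p_D \approx 4}.
#'
#' @param chains a \code{\link{posterior_chains}} object.
#' @param data the genotype's observations (\code{environment},
#'   \code{yield}).
#' @param design a \code{\link{compute_index}} design.
#' @return A \code{dic_result} list: \code{d_bar}, \code{d_hat},
#'   \code{p_d}, \code{dic}, \code{n}.
#' @export
dic <- function(chains, data, design) {
  stopifnot(inherits(chains, "posterior_chains"))
  y <- as.numeric(data$yield)
  dc <- design_columns(design, data$environment)
  n <- length(y)
  X <- cbind(1, dc$index, dc$t_value)
  XtX <- crossprod(X); Xty <- drop(crossprod(X, y)); yty <- sum(y * y)
  flat <- function(p) as.vector(chains$draws[, , p])
  B <- cbind(flat("beta0"), flat("beta1"), flat("beta2"))
  s2 <- flat("sigma2")
  sse <- pmax(yty - 2 * drop(B %*% Xty) + rowSums((B %*% XtX) * B), 0)
  dev <- n * log(2 * pi * s2) + sse / s2
  if (any(!is.finite(dev)))
    stop("non-finite deviance at draw(s) ",
         paste(utils::head(which(!is.finite(dev)), 5), collapse = ", "))
  d_bar <- mean(dev)
  bhat <- colMeans(B); s2hat <- mean(s2)
  sse_hat <- max(yty - 2 * sum(bhat * Xty) +
                   drop(crossprod(bhat, XtX %*% bhat)), 0)
  d_hat <- n * log(2 * pi * s2hat) + sse_hat / s2hat
  p_d <- d_bar - d_hat
  structure(list(d_bar = d_bar, d_hat = d_hat, p_d = p_d,
                 dic = d_hat + 2 * p_d, n = n),
            class = "dic_result")
}

#' @export
print.dic_result <- function(x, ...) {
  cat(sprintf("DIC = %.2f (Dbar = %.2f, D(theta_hat) = %.2f, p_D = %.2f)\n",
              x$dic, x$d_bar, x$d_hat, x$p_d))
  invisible(x)
}

#' Compare prior models by DIC
#'
#' Selects among candidate prior specifications by the lowest DIC, with
#' an equivalence band: models whose DIC is within \code{threshold} of
#' the minimum carry no meaningful increment in informative capacity
#' (\eqn{|\Delta| < 2} by default), and among equivalent models the one
#' listed first is kept — list the vaguest/simplest prior first so that
#' an informative prior must earn its keep.
#'
#' @param dics named numeric vector of DIC values (or a named list of
#'   \code{\link{dic}} results), in preference order.
#' @param threshold equivalence band on \eqn{|\Delta DIC|}.
#' @return A \code{prior_comparison} list: \code{dic} (named vector),
#'   \code{selected} (model name), \code{delta} (DIC minus minimum),
#'   \code{equivalent} (names within the band), \code{no_increment}
#'   (TRUE when more than one model sits in the band).
#' @export
compare_priors <- function(dics, threshold = 2) {
  if (is.list(dics)) dics <- vapply(dics, function(d)
    if (inherits(d, "dic_result")) d$dic else as.numeric(d), numeric(1))
  if (is.null(names(dics)))
    names(dics) <- paste0("model", seq_along(dics))
  if (length(dics) < 1) stop("at least one model is required")
  delta <- dics - min(dics)
  equivalent <- names(dics)[delta < threshold]
  structure(list(dic = dics, selected = equivalent[1], delta = delta,
                 equivalent = equivalent,
                 no_increment = length(equivalent) > 1,
                 threshold = threshold),
            class = "prior_comparison")
}

#' @export
print.prior_comparison <- function(x, ...) {
  for (nm in names(x$dic))
    cat(sprintf("  %-12s DIC = %.2f (delta = %.2f)%s\n", nm, x$dic[nm],
                x$delta[nm], if (nm == x$selected) "  <- selected" else ""))
  if (x$no_increment)
    cat(sprintf("|delta| < %g among {%s}: no increment in informative capacity\n",
                x$threshold, paste(x$equivalent, collapse = ", ")))
  invisible(x)
}

#' k-fold cross-validated predictive correlation
#'
#' Splits the replicate-level observations into \code{n_folds} folds
#' (stratified by genotype, so every genotype appears in nearly every
#' training set), refits the Gibbs sampler per genotype on each training
#' set, predicts the held-out observations from the posterior means via
#' \eqn{\hat\beta_{i0} + \hat\beta_{i1} I_j + \hat\beta_{i2} T(I_j)}, and
#' correlates predictions with held-out observed yields within each
#' fold.  The environmental design is held fixed (computed from the full
#' table), matching its role as a known covariate.
#'
#' @param table a \code{\link{trial_table}}.
#' @param design a \code{\link{compute_index}} design; computed from
#'   \code{table} when \code{NULL}.
#' @param prior a \code{\link{prior_spec}} (or per-genotype list).
#' @param settings an \code{\link{mcmc_settings}}.
#' @param n_folds number of folds (default 10: 90% training, 10%
#'   validation).
#' @param seed seed for the fold assignment and the per-fold fits.
#' @return A \code{cv_result} list: \code{n_folds}, \code{fold_cor}
#'   (per-fold correlations), \code{mean_cor}, \code{folds} (the fold
#'   index of every row of \code{table}).
#' @export
cross_validate <- function(table, design = NULL,
                           prior = minimally_informative_prior(),
                           settings = mcmc_settings(), n_folds = 10,
                           seed = 1) {
  if (is.null(design)) design <- compute_index(table)
  n <- nrow(table)
  stopifnot(n_folds >= 2, n >= n_folds)
  ## stratified assignment: within each genotype, shuffled indices get
  ## fold labels round-robin from a random starting fold
  folds <- integer(n)
  with_seed(seed + utf8_offset("folds"), {
    for (ix in split(seq_len(n), table$genotype)) {
      sh <- sample(ix)
      start <- sample.int(n_folds, 1L)
      folds[sh] <- ((start + seq_along(sh) - 2L) %% n_folds) + 1L
    }
  })
  genotypes <- unique(table$genotype)
  fold_cor <- rep(NA_real_, n_folds)
  per_geno_prior <- is.list(prior) && !inherits(prior, "prior_spec")
  fit_seeds <- derive_seeds(seed, n_folds * length(genotypes), "cvfit")
  k <- 0L
  for (f in seq_len(n_folds)) {
    test_ix <- which(folds == f)
    pred <- obs <- numeric(0)
    for (gi in seq_along(genotypes)) {
      k <- k + 1L
      gname <- genotypes[gi]
      tr <- which(folds != f & table$genotype == gname)
      te <- test_ix[table$genotype[test_ix] == gname]
      if (length(te) == 0L) next
      gtrain <- table[tr, , drop = FALSE]
      if (length(tr) < 4 ||
          length(unique(gtrain$environment)) < 3) {
        warning("fold ", f, ": genotype ", gname,
                " unfittable on its training split; skipped")
        next
      }
      gset <- settings; gset$seed <- fit_seeds[k]
      ch <- suppressWarnings(gibbs_fit(gtrain, design, if (per_geno_prior)
        prior[[gname]] else prior, gset))
      bhat <- vapply(c("beta0", "beta1", "beta2"),
                     function(p) mean(ch$draws[, , p]), numeric(1))
      dc <- design_columns(design, table$environment[te])
      pred <- c(pred, bhat[1] + bhat[2] * dc$index + bhat[3] * dc$t_value)
      obs <- c(obs, table$yield[te])
    }
    if (length(pred) >= 3 && stats::sd(pred) > 0 && stats::sd(obs) > 0)
      fold_cor[f] <- stats::cor(pred, obs)
  }
  structure(list(n_folds = n_folds, fold_cor = fold_cor,
                 mean_cor = mean(fold_cor, na.rm = TRUE), folds = folds),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation: mean predictive correlation %.4f\n",
              x$n_folds, x$mean_cor))
  cat("per fold:", paste(sprintf("%.3f", x$fold_cor), collapse = " "), "\n")
  invisible(x)
}
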