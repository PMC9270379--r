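#' Hinge transform of the environmental index
#'
#' The bisegmented regression regresses each genotype's response on the
#' coded environmental index \eqn{I_j} and on its hinge transform
#' \deqn{T(I_j) = 0 \ \mathrm{if}\ I_j \le 0, \qquad
#'       T(I_j) = I_j - \bar I_+ \ \mathrm{if}\ I_j > 0,}
#' where \eqn{\bar I_+} is the mean of the positive indices.  Centering
#' the hinge at \eqn{\bar I_+} makes \eqn{\sum_{I_j>0} T(I_j) = 0}, which
#' decorrelates the slope-change coefficient from the intercept.
#' \eqn{I_j = 0} is classified with the unfavorable (zero) branch.
#'
#' @param i_j coded environmental index (vectorised).
#' @param i_plus_bar mean of the positive indices.
#' @return \eqn{T(I_j)}, same length as \code{i_j}.
#' @export
transform_index <- function(i_j, i_plus_bar) {
  stopifnot(is.finite(i_plus_bar))
  ifelse(i_j > 0, i_j - i_plus_bar, 0)
}

#' Coded environmental index and bisegmented design
#'
#' Computes, for each environment \eqn{j}, the coded environmental index
#' \eqn{I_j}: the mean yield of all genotypes and replications in
#' environment \eqn{j} minus the grand mean.  Positive \eqn{I_j} mark
#' favorable environments, non-positive unfavorable ones.  On balanced
#' data the indices sum to zero.  The hinge transform
#' \code{\link{transform_index}} and its centering constant
#' \eqn{\bar I_+} complete the per-genotype regression design.
#'
#' With fewer than two positive or fewer than two non-positive indices
#' the two-regime design matrix is rank-deficient in one of the slopes;
#' the design is flagged \code{degenerate} and downstream fits fall back
#' to a single-slope model with a warning.
#'
#' @param table a balanced \code{\link{trial_table}}.
#' @return A \code{biseg_design}: data frame with columns
#'   \code{environment}, \code{index} (\eqn{I_j}), \code{t_value}
#'   (\eqn{T(I_j)}), \code{favorable}; attributes \code{i_plus_bar},
#'   \code{n_positive}, \code{grand_mean}, \code{degenerate}.
#' @export
compute_index <- function(table) {
  d <- design_of(table)
  if (!d$balanced)
    stop("environmental indices require a balanced trial")
  em <- tapply(table$yield, table$environment, mean)
  gm <- mean(table$yield)
  idx <- as.numeric(em) - gm
  env <- names(em)
  pos <- idx > 0
  if (!any(pos))
    stop("no environment has a positive index; ",
         "the hinge mean is undefined and the bisegmented model collapses")
  ipb <- mean(idx[pos])
  out <- data.frame(environment = env, index = idx,
                    t_value = transform_index(idx, ipb),
                    favorable = pos, stringsAsFactors = FALSE)
  degenerate <- sum(pos) < 2L || sum(!pos) < 2L
  structure(out, i_plus_bar = ipb, n_positive = sum(pos),
            grand_mean = gm, degenerate = degenerate,
            class = c("biseg_design", "data.frame"))
}

#' Build a bisegmented design from known indices
#'
#' Constructs the regression design directly from a given index vector
#' instead of deriving it from trial data.  This is the exact-oracle
#' companion of \code{\link{simulate_biseg_trial}}: the index derived by
#' \code{\link{compute_index}} from simulated data equals the generating
#' index only when the average genotype has unit slope and zero slope
#' change (as holds automatically when the index is computed from the
#' data being analysed); with arbitrary known coefficients, fits should
#' be checked against the design built here.
#'
#' @param index numeric index vector, at least one positive entry.
#' @param environments environment labels (default \code{E1, E2, ...},
#'   matching the simulator).
#' @return A \code{biseg_design}, as from \code{\link{compute_index}}.
#' @export
design_from_index <- function(index,
                              environments = sprintf("E%d",
                                                     seq_along(index))) {
  stopifnot(all(is.finite(index)), length(environments) == length(index))
  pos <- index > 0
  if (!any(pos)) stop("at least one index must be positive")
  ipb <- mean(index[pos])
  out <- data.frame(environment = as.character(environments),
                    index = index,
                    t_value = transform_index(index, ipb),
                    favorable = pos, stringsAsFactors = FALSE)
  structure(out, i_plus_bar = ipb, n_positive = sum(pos),
            grand_mean = NA_real_,
            degenerate = sum(pos) < 2L || sum(!pos) < 2L,
            class = c("biseg_design", "data.frame"))
}

#' @export
print.biseg_design <- function(x, ...) {
  cat(sprintf(
    "Bisegmented design: %d environments (%d favorable), Ibar+ = %.4g%s\n",
    nrow(x), attr(x, "n_positive"), attr(x, "i_plus_bar"),
    if (isTRUE(attr(x, "degenerate"))) " [degenerate]" else ""))
  print.data.frame(as.data.frame(x), ...)
  invisible(x)
}

## Design rows matched to a vector of environment labels.
design_columns <- function(design, environment) {
  m <- match(environment, design$environment)
  if (anyNA(m)) stop("environment label(s) not present in the design: ",
                     paste(unique(environment[is.na(m)]), collapse = ", "))
  list(index = design$index[m], t_value = design$t_value[m])
}
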