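#' Posterior chains container
#'
#' Holds the kept MCMC draws of one genotype's bisegmented-regression fit:
#' an array indexed by (kept iteration, chain, parameter), the parameters
#' being the intercept \code{beta0}, the unfavorable-regime slope
#' \code{beta1}, the slope change \code{beta2}, the residual precision
#' \code{tau} and the derived residual variance \code{sigma2 = 1/tau}.
#'
#' @param draws numeric array with dimensions (iteration, chain, parameter)
#'   and parameter dimnames.
#' @param genotype genotype label.
#' @param settings the \code{\link{mcmc_settings}} used.
#' @return A \code{posterior_chains} object.
#' @export
posterior_chains <- function(draws, genotype = NA_character_,
                             settings = NULL) {
  stopifnot(is.array(draws), length(dim(draws)) == 3L)
  if (any(!is.finite(draws))) stop("draws must be finite")
  if ("tau" %in% dimnames(draws)[[3]] &&
      any(draws[, , "tau"] <= 0)) stop("tau draws must be positive")
  structure(list(draws = draws, genotype = genotype, settings = settings),
            class = "posterior_chains")
}

#' @export
print.posterior_chains <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("Posterior chains%s: %d chains x %d kept draws, parameters: %s\n",
              if (is.na(x$genotype)) "" else paste0(" [", x$genotype, "]"),
              d[2], d[1], paste(dimnames(x$draws)[[3]], collapse = ", ")))
  invisible(x)
}

## Flatten to a long data.frame (genotype, chain, iteration, parameter, value).
chains_long <- function(chains) {
  stopifnot(inherits(chains, "posterior_chains"))
  d <- dim(chains$draws)
  pars <- dimnames(chains$draws)[[3]]
  data.frame(
    genotype  = chains$genotype,
    chain     = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    iteration = rep(seq_len(d[1]), times = d[2] * d[3]),
    parameter = rep(pars, each = d[1] * d[2]),
    value     = as.vector(chains$draws),
    stringsAsFactors = FALSE)
}

#' Write and read posterior chains as plain text
#'
#' Chains are serialised to a long-format text table with columns
#' \code{genotype}, \code{chain}, \code{iteration}, \code{parameter},
#' \code{value}.  Values are written with 17 significant digits, so the
#' round trip \code{read_chains(write_chains(x))} reproduces every draw
#' bit-exactly.
#'
#' @param chains a \code{posterior_chains} object or a list of them (one
#'   per genotype, as returned by \code{\link{fit_biseg}}).
#' @param path output file path.
#' @return \code{write_chains}: \code{path}, invisibly.
#' @export
write_chains <- function(chains, path) {
  if (inherits(chains, "posterior_chains")) chains <- list(chains)
  if (inherits(chains, "biseg_fit")) chains <- chains$chains
  if (length(chains) == 0L) stop("no chains to write")
  long <- do.call(rbind, lapply(chains, chains_long))
  if (nrow(long) == 0L) stop("no chains to write")
  long$value <- sprintf("%.17g", long$value)
  utils::write.csv(long, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_chains
#' @return \code{read_chains}: a named list of \code{posterior_chains},
#'   one per genotype found in the file.
#' @export
read_chains <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(genotype = "character"))
  need <- c("genotype", "chain", "iteration", "parameter", "value")
  if (!all(need %in% names(long)))
    stop("not a chains file: expected columns ",
         paste(need, collapse = ", "))
  out <- lapply(split(long, long$genotype), function(gl) {
    pars   <- unique(gl$parameter)
    chains <- sort(unique(gl$chain))
    iters  <- sort(unique(gl$iteration))
    arr <- array(NA_real_, dim = c(length(iters), length(chains),
                                   length(pars)),
                 dimnames = list(NULL, NULL, pars))
    idx <- cbind(match(gl$iteration, iters), match(gl$chain, chains),
                 match(gl$parameter, pars))
    arr[idx] <- gl$value
    posterior_chains(arr, genotype = gl$genotype[1])
  })
  out[unique(long$genotype)]
}

#' Write a summaries table as CSV
#'
#' Writes any data frame of numeric summaries (posterior summaries,
#' genotype classifications, ANOVA tables) as CSV with numeric columns at
#' 15 significant digits.
#'
#' @param summaries a data frame.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_summaries <- function(summaries, path) {
  stopifnot(is.data.frame(summaries))
  out <- as.data.frame(summaries)
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.15g", out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
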