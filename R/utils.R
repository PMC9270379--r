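#' @keywords internal
"_PACKAGE"

## Run code under a temporary RNG seed, restoring the caller's RNG state.
## All randomness in the package flows through this, so a single integer
## seed makes any pipeline bit-reproducible without clobbering the session.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

## Deterministically derive n independent sub-seeds from one master seed.
## Used for stream splitting (one substream per simulation factor, per
## chain, per genotype) so that adding a consumer does not reshuffle the
## draws of the others.  Values stay below 2^31 - 1.
derive_seeds <- function(seed, n, stream = "") {
  with_seed(seed + utf8_offset(stream),
            sample.int(.Machine$integer.max - 1L, n))
}

utf8_offset <- function(s) {
  if (!nzchar(s)) return(0L)
  as.integer(sum(utf8ToInt(s)) %% 10000L)
}

## Population (divide-by-n) standard deviation.
sd_pop <- function(x) {
  n <- length(x)
  sqrt(sum((x - mean(x))^2) / n)
}

#' Plants per hectare from rectangular spacing
#'
#' Converts a rectangular planting spacing (distance between rows and
#' between plants within a row, both in metres) into a planting density in
#' plants per hectare: \eqn{10000 / (\mathrm{row} \times \mathrm{plant})}.
#' A 3.5 m x 1.0 m spacing, typical of clonal conilon coffee trials, gives
#' 2857 plants per hectare.
#'
#' @param row_spacing_m distance between rows, metres.
#' @param plant_spacing_m distance between plants within a row, metres.
#' @return Planting density in plants per hectare.
#' @examples
#' plants_per_hectare(3.5, 1.0)
#' @export
plants_per_hectare <- function(row_spacing_m, plant_spacing_m) {
  stopifnot(row_spacing_m > 0, plant_spacing_m > 0)
  10000 / (row_spacing_m * plant_spacing_m)
}
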