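#' Construct a trial table
#'
#' A trial table holds replicate-level phenotype records of a
#' genotype x environment x replication experiment in long ("tidy")
#' format, the canonical representation throughout the package; wide
#' genotype-by-environment mean matrices are derived views
#' (\code{\link{cell_means}}).  The yield column is a unitless continuous
#' trait to the engine; a unit label (e.g. \code{"bags/ha"}, 60-kg bags of
#' green coffee per hectare) can be attached as metadata.
#'
#' Replication labels are semantically nested within environment but
#' stored as plain labels; the ANOVA decomposition imposes the nesting.
#'
#' @param genotype,environment,replication label vectors (coerced to
#'   character), one entry per plot record.
#' @param yield numeric vector of finite trait values.
#' @param units optional unit label, metadata only.
#' @return A \code{trial_table}: a data frame with columns
#'   \code{genotype}, \code{environment}, \code{replication},
#'   \code{yield}, carrying a \code{\link{trial_design}} attribute.
#' @seealso \code{\link{read_trial_table}}, \code{\link{simulate_anova_trial}}
#' @export
trial_table <- function(genotype, environment, replication, yield,
                        units = NULL) {
  genotype    <- as.character(genotype)
  environment <- as.character(environment)
  replication <- as.character(replication)
  yield       <- as.numeric(yield)
  n <- length(yield)
  if (length(genotype) != n || length(environment) != n ||
      length(replication) != n)
    stop("genotype, environment, replication and yield must have equal length")
  if (n == 0L) stop("trial table must contain at least one record")
  if (any(!nzchar(genotype)) || any(!nzchar(environment)) ||
      any(!nzchar(replication)) ||
      anyNA(genotype) || anyNA(environment) || anyNA(replication))
    stop("labels must be non-empty strings")
  if (any(!is.finite(yield)))
    stop("yield values must be finite reals")
  key <- paste(genotype, environment, replication, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicated (genotype, environment, replication) triple: ",
         gsub("\r", " / ", dup))
  }
  tab <- data.frame(genotype = genotype, environment = environment,
                    replication = replication, yield = yield,
                    stringsAsFactors = FALSE)
  attr(tab, "design") <- infer_design(tab)
  attr(tab, "units")  <- units
  class(tab) <- c("trial_table", "data.frame")
  tab
}

#' Trial design dimensions
#'
#' @param g,e,r counts of genotypes, environments and replications.
#' @param balanced logical; \code{TRUE} iff every one of the
#'   \code{g * e * r} cells is present exactly once.
#' @return A \code{trial_design} list with elements \code{g}, \code{e},
#'   \code{r}, \code{balanced}.
#' @export
trial_design <- function(g, e, r, balanced = TRUE) {
  structure(list(g = as.integer(g), e = as.integer(e), r = as.integer(r),
                 balanced = isTRUE(balanced)),
            class = "trial_design")
}

## Balance holds iff the observed triples enumerate the full g x e x r
## lattice exactly once (checked against the brute-force cross product).
infer_design <- function(tab) {
  gl <- unique(tab$genotype); el <- unique(tab$environment)
  rl <- unique(tab$replication)
  full <- expand.grid(genotype = gl, environment = el, replication = rl,
                      stringsAsFactors = FALSE)
  have <- paste(tab$genotype, tab$environment, tab$replication, sep = "\r")
  want <- paste(full$genotype, full$environment, full$replication, sep = "\r")
  trial_design(length(gl), length(el), length(rl),
               balanced = length(have) == length(want) &&
                 all(want %in% have))
}

#' @export
print.trial_table <- function(x, ...) {
  d <- design_of(x)
  cat(sprintf(
    "Trial table: %d records, %d genotypes x %d environments x %d replications (%s)\n",
    nrow(x), d$g, d$e, d$r, if (d$balanced) "balanced" else "unbalanced"))
  if (!is.null(attr(x, "units"))) cat("Units:", attr(x, "units"), "\n")
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("... and", nrow(x) - 6L, "more records\n")
  invisible(x)
}

#' Extract the design attribute of a trial table
#' @param table a \code{trial_table}.
#' @return Its \code{trial_design}.
#' @export
design_of <- function(table) {
  d <- attr(table, "design")
  if (is.null(d)) d <- infer_design(table)
  d
}

#' Genotype-by-environment cell means
#'
#' Derived wide view of a trial table: the mean yield of each genotype in
#' each environment, averaged over replications.
#'
#' @param table a \code{trial_table}.
#' @return Numeric matrix, genotypes in rows, environments in columns.
#' @export
cell_means <- function(table) {
  tapply(table$yield, list(table$genotype, table$environment), mean)
}

#' Read a trial table from a delimited file
#'
#' Reads a long-format CSV/TSV phenotype file with a header and validates
#' it into a \code{\link{trial_table}}.  Column names can be remapped via
#' \code{dialect}, either a named character vector/list
#' (\code{c(genotype = "gen", ...)}) or the path to a YAML file of
#' \code{key: value} pairs with the same keys.
#'
#' @param path file path.
#' @param dialect column-name mapping for any of \code{genotype},
#'   \code{environment}, \code{replication}, \code{yield}; names not
#'   mentioned keep their defaults.
#' @param sep field separator; \code{","} by default, use \code{"\t"} for TSV.
#' @return A validated \code{trial_table}; its design (and balance flag)
#'   is inferred from the records.
#' @export
read_trial_table <- function(path, dialect = NULL, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  cols <- c(genotype = "genotype", environment = "environment",
            replication = "replication", yield = "yield")
  if (is.character(dialect) && length(dialect) == 1L && is.null(names(dialect))
      && file.exists(dialect)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a dialect file requires the 'yaml' package")
    dialect <- yaml::read_yaml(dialect)
  }
  if (!is.null(dialect)) {
    dialect <- unlist(dialect)
    unknown <- setdiff(names(dialect), names(cols))
    if (length(unknown))
      stop("unknown dialect keys: ", paste(unknown, collapse = ", "))
    cols[names(dialect)] <- dialect
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(unname(cols), names(raw))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  y <- raw[[cols[["yield"]]]]
  if (!is.numeric(y)) {
    y2 <- suppressWarnings(as.numeric(y))
    if (anyNA(y2)) stop("non-numeric yield values in column '",
                        cols[["yield"]], "'")
    y <- y2
  }
  trial_table(raw[[cols[["genotype"]]]], raw[[cols[["environment"]]]],
              raw[[cols[["replication"]]]], y)
}

#' Write a trial table to CSV
#'
#' @param table a \code{trial_table}.
#' @param path output file path.
#' @return \code{path}, invisibly.  Yields are written with 15 significant
#'   digits so that \code{read_trial_table(write_trial_table(x))} restores
#'   the values to double precision.
#' @export
write_trial_table <- function(table, path) {
  out <- as.data.frame(table)
  out$yield <- sprintf("%.17g", out$yield)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
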