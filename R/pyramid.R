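#' Population pyramid
#'
#' Persons per single year of age, ages 30-99, used to weight the 70
#' age cohorts of the cross-sectional population projection.
#'
#' @param counts Nonnegative numeric vector of length 70 (ages 30-99).
#' @param reference_year Label for the reference population.
#' @return An object of class `population_pyramid` with fields `age`
#'   (30:99), `counts` and `reference_year`.
#' @export
population_pyramid <- function(counts, reference_year = "synthetic") {
  counts <- as.numeric(counts)
  if (length(counts) != 70L)
    stop("'counts' must give persons for each single year of age 30-99")
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("pyramid counts must be finite and nonnegative")
  if (sum(counts) <= 0) stop("pyramid total must be positive")
  structure(list(age = 30:99, counts = counts,
                 reference_year = reference_year),
            class = "population_pyramid")
}

#' @export
print.population_pyramid <- function(x, ...) {
  in55_74 <- sum(x$counts[x$age >= 55 & x$age <= 74])
  cat(sprintf("Population pyramid (%s): %s persons aged 30-99, %s aged 55-74 (%.1f%%)\n",
              x$reference_year, format(sum(x$counts), big.mark = ","),
              format(in55_74, big.mark = ","),
              100 * in55_74 / sum(x$counts)))
  invisible(x)
}

#' Read or write a population pyramid
#'
#' Delimited table with header `age,count`, one row per year of age 30-99.
#'
#' @param path File path.
#' @param pyramid A [population_pyramid()].
#' @return `read_pyramid()` returns a `population_pyramid`.
#' @export
read_pyramid <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("age", "count") %in% names(d)))
    stop("pyramid file must have columns 'age' and 'count': ", path)
  d <- d[order(d$age), ]
  if (!identical(as.integer(d$age), 30:99))
    stop("pyramid file must cover ages 30-99 exactly: ", path)
  population_pyramid(d$count)
}

#' @rdname read_pyramid
#' @export
write_pyramid <- function(pyramid, path) {
  utils::write.csv(data.frame(age = pyramid$age, count = pyramid$counts),
                   path, row.names = FALSE)
  invisible(path)
}
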