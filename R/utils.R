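#' Round half away from zero
#'
#' Frequency tables in forensic/population-genetic reports conventionally
#' round 5 up, unlike [base::round()]'s banker's rounding.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_positive <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", what), call. = FALSE)
  }
  invisible(x)
}

#' Provenance comment block for tabular outputs
#'
#' @param params named list recorded in the header.
#' @return character vector of '#'-prefixed lines.
#' @keywords internal
provenance_header <- function(params = list()) {
  ver <- tryCatch(as.character(utils::packageVersion("ylineage")),
                  error = function(e) "dev")
  # no timestamp: identical runs must produce byte-identical outputs
  lines <- sprintf("# ylineage %s", ver)
  if (length(params)) {
    kv <- vapply(names(params), function(k) {
      sprintf("# %s: %s", k, paste(format(params[[k]]), collapse = ","))
    }, character(1))
    lines <- c(lines, kv)
  }
  lines
}
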