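#' Alignment scoring schemes
#'
#' A scoring scheme holds the four affine-gap alignment parameters. A gap of
#' length `L` costs `gap_open + (L - 1) * gap_extend` (both negative), so the
#' first gapped base pays the opening penalty and each further base pays the
#' extension penalty.
#'
#' Two stock schemes are provided: [binning_scheme()] (match 3, mismatch -6,
#' open -10, extend -5), used for unique-region read binning, and
#' [report_scheme()] (match 5, mismatch -4, open -10, extend -0.5), the
#' needle-style defaults used for the final consensus-versus-reference
#' comparison. Half-point penalties are handled exactly: scores are doubled
#' internally and rescaled on output.
#'
#' @param match score per identical base pair; must be positive.
#' @param mismatch score per substituted pair; must be negative.
#' @param gap_open score for a length-1 gap; must satisfy
#'   `gap_open <= gap_extend <= 0`.
#' @param gap_extend score per additional gap position.
#' @return An object of class `scoring_scheme`.
#' @examples
#' scoring_scheme(3, -6, -10, -5)
#' binning_scheme()
#' @export
scoring_scheme <- function(match, mismatch, gap_open, gap_extend) {
  stopifnot(is.numeric(match), is.numeric(mismatch),
            is.numeric(gap_open), is.numeric(gap_extend))
  if (match <= 0) stop("match score must be positive")
  if (mismatch >= 0) stop("mismatch score must be negative")
  if (!(gap_open <= gap_extend && gap_extend <= 0))
    stop("need gap_open <= gap_extend <= 0")
  s <- list(match = match, mismatch = mismatch,
            gap_open = gap_open, gap_extend = gap_extend)
  # doubled integer representation keeps half-point extends exact
  s2 <- lapply(s, function(x) {
    x2 <- x * 2
    if (abs(x2 - round(x2)) > 1e-9)
      stop("scores must be multiples of 0.5")
    as.integer(round(x2))
  })
  structure(c(s, list(.x2 = s2)), class = "scoring_scheme")
}

#' @rdname scoring_scheme
#' @export
binning_scheme <- function() scoring_scheme(3, -6, -10, -5)

#' @rdname scoring_scheme
#' @export
report_scheme <- function() scoring_scheme(5, -4, -10, -0.5)

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("scoring scheme: match %+g mismatch %+g gap open %+g extend %+g\n",
              x$match, x$mismatch, x$gap_open, x$gap_extend))
  invisible(x)
}
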