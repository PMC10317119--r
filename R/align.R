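#' Pairwise affine-gap alignment
#'
#' Optimal pairwise alignment under an affine gap model (Gotoh three-state
#' recurrence), in three flavours:
#'
#' * `global_align()` - Needleman-Wunsch; both sequences fully consumed.
#' * `local_align()` - Smith-Waterman; best positive-scoring segment pair, the
#'   empty alignment (score 0) is allowed.
#' * `semiglobal_align()` - read-versus-reference overlap alignment: gaps at
#'   reference ends are free, and the read is clipped free only where the
#'   alignment runs off a reference end. Optionally banded around a seeded
#'   diagonal for long sequences.
#'
#' `N` never matches anything, including another `N`; it always scores as a
#' mismatch. Among co-optimal alignments the traceback is deterministic:
#' matches are preferred over gaps and deletions over insertions.
#'
#' @param a,b sequences (character scalars over A/C/G/T/N); `a` is the query
#'   (the read), `b` the target (the reference).
#' @param scheme a [scoring_scheme()].
#' @param band half-width of the alignment band, or `NULL` for exact unbanded
#'   alignment. Only supported for `semiglobal_align()`.
#' @param diag seeded band centre: expected value of `target_pos - query_pos`.
#' @return An object of class `pairwise_alignment`: a list with elements
#'   `mode`, `score`, `ops` (data frame of run-length edit operations with
#'   `op` in `M` match, `X` mismatch, `I` insertion in the query, `D` deletion
#'   from the query), `query_interval` and `target_interval` (0-based
#'   half-open), `identity_pct`, `n_match`, `n_cols`, `orientation`.
#'   `semiglobal_align()` returns `NULL` if the band excludes every path
#'   (callers may retry unbanded).
#' @examples
#' global_align("ACGT", "ACGT", binning_scheme())$score    # 12
#' global_align("ACGT", "AGT", binning_scheme())$score     # -1
#' local_align("TTTACGTTTT", "ACGT", binning_scheme())$score  # 12
#' @name pairwise-alignment
NULL

.align <- function(a, b, scheme, mode, band, diag, orientation = "forward") {
  if (!inherits(scheme, "scoring_scheme")) stop("scheme must be a scoring_scheme")
  if (!is.character(a) || length(a) != 1L || !nzchar(a) ||
      !is.character(b) || length(b) != 1L || !nzchar(b))
    stop("sequences must be non-empty character scalars")
  x2 <- scheme$.x2
  res <- gotoh_cpp(a, b, x2$match, x2$mismatch, x2$gap_open, x2$gap_extend,
                   mode,
                   if (is.null(band)) -1 else as.integer(band),
                   if (is.null(diag)) 0L else as.integer(diag))
  if (!isTRUE(res$ok)) return(NULL)
  ops <- data.frame(op = as.character(res$op), len = as.integer(res$len),
                    stringsAsFactors = FALSE)
  structure(list(
    mode = c("global", "local", "semiglobal")[mode + 1L],
    score = res$score2 / 2,
    ops = ops,
    query_interval = c(res$q0, res$q1),
    target_interval = c(res$t0, res$t1),
    identity_pct = if (res$ncols > 0) 100 * res$nmatch / res$ncols else 0,
    n_match = res$nmatch,
    n_cols = res$ncols,
    orientation = orientation,
    scheme = scheme
  ), class = "pairwise_alignment")
}

#' @rdname pairwise-alignment
#' @export
global_align <- function(a, b, scheme = binning_scheme()) {
  .align(a, b, scheme, 0L, NULL, NULL)
}

#' @rdname pairwise-alignment
#' @export
local_align <- function(a, b, scheme = binning_scheme()) {
  .align(a, b, scheme, 1L, NULL, NULL)
}

#' @rdname pairwise-alignment
#' @export
semiglobal_align <- function(a, b, scheme = binning_scheme(),
                             band = NULL, diag = 0L) {
  .align(a, b, scheme, 2L, band, diag)
}

#' Normalize an alignment score to a 0-100 scale
#'
#' Raw affine-gap scores depend on the target length, so thresholds are
#' applied on a percent-of-maximum scale: 100 times the raw score divided by
#' the score of a perfect full-length match of the target
#' (`match * target_len`), floored at 0. A perfect hit scores 100.
#'
#' @param aln a [pairwise_alignment][pairwise-alignment] (or anything with a
#'   `score` element).
#' @param target_len length of the target the score is normalized against.
#' @param scheme the [scoring_scheme()] the alignment was computed under.
#' @return A percent in `[0, 100]` (can exceed 100 only if `target_len` is
#'   shorter than the aligned span, which two-stage binning never does).
#' @export
normalized_score <- function(aln, target_len, scheme = binning_scheme()) {
  stopifnot(target_len > 0)
  max(0, 100 * aln$score / (scheme$match * target_len))
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cigar <- paste0(x$ops$len, x$ops$op, collapse = "")
  cat(sprintf("%s alignment: score %g, identity %.1f%% (%d/%d), %s\n",
              x$mode, x$score, x$identity_pct, x$n_match, x$n_cols,
              x$orientation))
  cat(sprintf("  query [%d,%d) target [%d,%d)  %s\n",
              x$query_interval[1], x$query_interval[2],
              x$target_interval[1], x$target_interval[2],
              if (nchar(cigar) > 60) paste0(substr(cigar, 1, 57), "...") else cigar))
  invisible(x)
}

#' Reverse complement
#'
#' @param s a character vector of DNA sequences (A/C/G/T/N, case preserved
#'   as upper case in the result; other characters become N).
#' @return the reverse-complemented sequences.
#' @export
revcomp <- function(s) vapply(s, revcomp_cpp, "", USE.NAMES = FALSE)

# expand run-length ops into per-column op characters
expand_ops <- function(ops) rep(ops$op, ops$len)

# score an ops table under a scheme (per-op contributions); used for
# internal consistency checks and reporting
score_from_ops <- function(ops, scheme) {
  s <- 0
  for (k in seq_len(nrow(ops))) {
    op <- ops$op[k]; len <- ops$len[k]
    s <- s + switch(op,
      M = len * scheme$match,
      X = len * scheme$mismatch,
      I = scheme$gap_open + (len - 1) * scheme$gap_extend,
      D = scheme$gap_open + (len - 1) * scheme$gap_extend,
      stop("unknown op ", op))
  }
  s
}
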