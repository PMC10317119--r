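# Needle-style plain-text pairwise alignment report: summary header plus
# 60-column wrapped alignment blocks with a match line ('|' match,
# '.' substitution, ' ' gap) and 1-based coordinates.

# reconstruct the two gapped rows of a global alignment from its ops
gapped_rows <- function(aln, a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  ops <- expand_ops(aln$ops)
  qi <- aln$query_interval[1]; ti <- aln$target_interval[1]
  qa <- character(length(ops)); tb <- character(length(ops)); mk <- character(length(ops))
  for (k in seq_along(ops)) {
    op <- ops[k]
    if (op %in% c("M", "X")) {
      qi <- qi + 1L; ti <- ti + 1L
      qa[k] <- av[qi]; tb[k] <- bv[ti]
      mk[k] <- if (op == "M") "|" else "."
    } else if (op == "I") {
      qi <- qi + 1L
      qa[k] <- av[qi]; tb[k] <- "-"; mk[k] <- " "
    } else {
      ti <- ti + 1L
      qa[k] <- "-"; tb[k] <- bv[ti]; mk[k] <- " "
    }
  }
  list(query = qa, target = tb, marks = mk)
}

#' Write a needle-style pairwise alignment report
#'
#' Renders a global alignment the way EMBOSS needle does: a commented summary
#' header (length, identity, gaps, score) followed by 60-column alignment
#' blocks with a match line and 1-based closed coordinates.
#'
#' @param aln a global [pairwise_alignment][pairwise-alignment] of `a` vs `b`.
#' @param id_a,id_b display names for the query (first) and target (second)
#'   sequence.
#' @param a,b the two sequences that were aligned.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pairwise_report <- function(aln, id_a, id_b, a, b, path) {
  stopifnot(aln$mode == "global")
  rows <- gapped_rows(aln, a, b)
  n <- length(rows$marks)
  n_gap <- sum(rows$marks == " ")
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  writeLines("########################################", con)
  w("# Program: plasmidpool")
  w("# Aligned_sequences: 2")
  w("# 1: %s", id_a)
  w("# 2: %s", id_b)
  w("# Matrix: match %g, mismatch %g", aln$scheme$match, aln$scheme$mismatch)
  w("# Gap_penalty: %.1f", -aln$scheme$gap_open)
  w("# Extend_penalty: %.1f", -aln$scheme$gap_extend)
  w("#")
  w("# Length: %d", n)
  w("# Identity: %6d/%d (%.1f%%)", aln$n_match, n, 100 * aln$n_match / n)
  w("# Gaps:     %6d/%d (%.1f%%)", n_gap, n, 100 * n_gap / n)
  w("# Score: %.1f", aln$score)
  writeLines("########################################", con)
  writeLines("", con)

  name_w <- max(13L, nchar(id_a), nchar(id_b))
  qpos <- aln$query_interval[1]; tpos <- aln$target_interval[1]
  for (s in seq.int(1L, n, by = 60L)) {
    e <- min(s + 59L, n)
    qseg <- rows$query[s:e]; tseg <- rows$target[s:e]
    nq <- sum(qseg != "-"); nt <- sum(tseg != "-")
    q_from <- if (nq > 0) qpos + 1L else qpos
    t_from <- if (nt > 0) tpos + 1L else tpos
    w("%-*s %7d %s %d", name_w, id_a, q_from, paste(qseg, collapse = ""), qpos + nq)
    w("%-*s %7s %s", name_w, "", "", paste(rows$marks[s:e], collapse = ""))
    w("%-*s %7d %s %d", name_w, id_b, t_from, paste(tseg, collapse = ""), tpos + nt)
    writeLines("", con)
    qpos <- qpos + nq; tpos <- tpos + nt
  }
  invisible(path)
}
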